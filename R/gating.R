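#' Gating configuration
#'
#' Parameters of the six-step gating strategy. Scatter floors and the
#' absolute CD45 cut are instrument-scale quantities (arbitrary units); the
#' defaults are calibrated to the simulator's channel scales and should be
#' reviewed for real instruments. `control_quantile` implements the rule that
#' positivity thresholds are set so the matched control tube has no positive
#' events: 1.0 (the default) uses the control maximum, while a slightly
#' smaller value such as 0.999 is more robust to single-event outliers.
#'
#' @param fsc_min,ssc_min Scatter floors removing debris (a.u.).
#' @param control_quantile Quantile of the control tube used as the
#'   positivity threshold, in (0, 1]. Default 1.0 (maximum).
#' @param cd45_quantile Quantile used to derive the CD45 cut from a CD45-low
#'   reference when no absolute cut is given, in (0, 1].
#' @param cd45_cut Absolute CD45 exclusion threshold (a.u.); events above it
#'   are treated as leukocytes and dropped. Set to `NULL` to derive the cut
#'   from the isotype tube via `cd45_quantile` instead (only sensible for
#'   panels without a dominant CD45-high population).
#' @param blocking_ratio_min Minimum blocking ratio for the
#'   gefitinib-competition specificity check to pass, in `[0, 1]`.
#' @return An object of class `gate_config`.
#' @export
gate_config <- function(fsc_min = 15000, ssc_min = 6000,
                        control_quantile = 1.0, cd45_quantile = 0.999,
                        cd45_cut = 300, blocking_ratio_min = 0.5) {
  for (q in c(control_quantile, cd45_quantile))
    if (!is.numeric(q) || q <= 0 || q > 1)
      stop("quantiles must lie in (0, 1]", call. = FALSE)
  if (blocking_ratio_min < 0 || blocking_ratio_min > 1)
    stop("'blocking_ratio_min' must be in [0, 1]", call. = FALSE)
  if (!is.null(cd45_cut) && (!is.numeric(cd45_cut) || !is.finite(cd45_cut)))
    stop("'cd45_cut' must be a finite number or NULL", call. = FALSE)
  structure(list(fsc_min = fsc_min, ssc_min = ssc_min,
                 control_quantile = control_quantile,
                 cd45_quantile = cd45_quantile, cd45_cut = cd45_cut,
                 blocking_ratio_min = blocking_ratio_min),
            class = "gate_config")
}

scatter_gate <- function(events, cfg) {
  events[events$fsc >= cfg$fsc_min & events$ssc >= cfg$ssc_min, , drop = FALSE]
}

#' Derive positivity thresholds from the control tubes
#'
#' Computes the probe-channel cut from the DMSO tube and the antibody-channel
#' cut from the isotype tube, each as the `control_quantile` quantile (linear
#' interpolation) of the channel among events that survive the scatter and
#' CD45 gates -- with the default quantile of 1 this is the control maximum,
#' so no control event is called positive. The CD45 cut is taken from the
#' configuration, or, when `cfg$cd45_cut` is `NULL`, as the `cd45_quantile`
#' quantile of the isotype tube's scatter-gated CD45 signal.
#'
#' @param panel A `sample_panel` with DMSO and isotype tubes.
#' @param cfg A [gate_config()].
#' @return An object of class `gate_thresholds` with elements `hx103_cut`,
#'   `egfr_cut`, `cd45_cut`, `n_events_after_scatter`, `n_events_after_cd45`
#'   (counts refer to the DMSO tube).
#' @export
derive_thresholds <- function(panel, cfg = gate_config()) {
  stopifnot(inherits(panel, "sample_panel"), inherits(cfg, "gate_config"))
  for (tube in c("dmso_control", "isotype_control")) {
    ev <- panel$tubes[[tube]]
    if (is.null(ev) || nrow(ev) == 0)
      stop("missing control tube '", tube, "'", call. = FALSE)
  }
  dmso_sc <- scatter_gate(panel$tubes$dmso_control, cfg)
  iso_sc <- scatter_gate(panel$tubes$isotype_control, cfg)
  cd45_cut <- if (is.null(cfg$cd45_cut))
    stats::quantile(iso_sc$cd45, cfg$cd45_quantile, names = FALSE, type = 7)
  else cfg$cd45_cut

  dmso_g <- dmso_sc[dmso_sc$cd45 <= cd45_cut, , drop = FALSE]
  iso_g <- iso_sc[iso_sc$cd45 <= cd45_cut, , drop = FALSE]
  if (nrow(dmso_g) < 100 || nrow(iso_g) < 100)
    stop("too few gated control events (need >= 100 after scatter + CD45 gates)",
         call. = FALSE)
  structure(list(
    hx103_cut = stats::quantile(dmso_g$hx103, cfg$control_quantile,
                                names = FALSE, type = 7),
    egfr_cut = stats::quantile(iso_g$egfr_ab, cfg$control_quantile,
                               names = FALSE, type = 7),
    cd45_cut = cd45_cut,
    n_events_after_scatter = nrow(dmso_sc),
    n_events_after_cd45 = nrow(dmso_g)),
    class = "gate_thresholds")
}

#' @export
print.gate_thresholds <- function(x, ...) {
  cat(sprintf(
    "Gate thresholds: hx103 > %.4g, egfr_ab > %.4g, cd45 <= %.4g (DMSO tube: %d after scatter, %d after CD45)\n",
    x$hx103_cut, x$egfr_cut, x$cd45_cut,
    x$n_events_after_scatter, x$n_events_after_cd45))
  invisible(x)
}

#' Apply the gate chain and assign dot-plot quadrants
#'
#' Retains events passing the scatter floor, removes CD45-positive events,
#' and labels each survivor with its quadrant in the antibody-vs-probe dot
#' plot. Positivity is strict (`value > cut`); an event exactly at a cut is
#' called negative, consistent with thresholds chosen so that control tubes
#' contain no positive events. Quadrants: Q1 = antibody(+) probe(-),
#' Q2 = double positive, Q3 = antibody(-) probe(+), Q4 = double negative.
#'
#' @param events A per-event data frame (one tube).
#' @param th A `gate_thresholds` object.
#' @param cfg A [gate_config()].
#' @return The gated events with a `quadrant` factor column; per-stage counts
#'   are attached as attribute `"gate_counts"`.
#' @export
apply_gates <- function(events, th, cfg = gate_config()) {
  stopifnot(inherits(th, "gate_thresholds"), inherits(cfg, "gate_config"))
  if (is.null(events) || nrow(events) == 0)
    stop("empty event table", call. = FALSE)
  n0 <- nrow(events)
  ev <- scatter_gate(events, cfg)
  if (nrow(ev) == 0)
    stop("empty gate: no events survive the scatter stage", call. = FALSE)
  n1 <- nrow(ev)
  ev <- ev[ev$cd45 <= th$cd45_cut, , drop = FALSE]
  if (nrow(ev) == 0)
    stop("empty gate: no events survive the CD45 stage", call. = FALSE)
  egfr_pos <- ev$egfr_ab > th$egfr_cut
  hx_pos <- ev$hx103 > th$hx103_cut
  ev$quadrant <- factor(ifelse(egfr_pos & !hx_pos, "Q1",
                        ifelse(egfr_pos & hx_pos, "Q2",
                        ifelse(!egfr_pos & hx_pos, "Q3", "Q4"))),
                        levels = c("Q1", "Q2", "Q3", "Q4"))
  attr(ev, "gate_counts") <- c(total = n0, after_scatter = n1,
                               after_cd45 = nrow(ev))
  ev
}

raw_percentages <- function(gated) {
  tab <- table(gated$quadrant)
  n <- nrow(gated)
  c(egfr_pos = 100 * (tab[["Q1"]] + tab[["Q2"]]) / n,
    hx103_pos = 100 * (tab[["Q2"]] + tab[["Q3"]]) / n,
    double_pos = 100 * tab[["Q2"]] / n)
}

#' Quantify probe labeling for one specimen panel
#'
#' Runs the full gating strategy on all four tubes and reports the three
#' labeling parameters -- antibody-positive (Q1+Q2), probe-positive (Q2+Q3)
#' and double-positive (Q2) percentages of gated single cells -- raw per tube
#' and background-corrected by subtracting the DMSO-tube raw percentages from
#' the stained-tube ones (corrected values can therefore be negative).
#' Probe-channel MFIs (arithmetic means over gated events) are reported per
#' tube, and binding specificity is summarised by the blocking ratio
#' `1 - (MFI_blocked - MFI_dmso) / (MFI_stained - MFI_dmso)`, clamped to
#' `[0, 1]`. When the stained-minus-DMSO MFI is not positive the ratio is not
#' evaluable and is reported as `NA` with `specificity_pass = NA`.
#'
#' @param panel A `sample_panel` with all four tubes.
#' @param cfg A [gate_config()].
#' @return An object of class `labeling_result`: `specimen_id`, `raw` (tube x
#'   parameter matrix of raw percentages), `corrected` (named vector),
#'   `mfi_stained`, `mfi_dmso`, `mfi_blocked`, `blocking_ratio`,
#'   `specificity_pass`, `thresholds`, `gate_counts`.
#' @examples
#' panel <- preset_panel("mutant_high", seed = 7, n_events = 2000)
#' quantify(panel)
#' @export
quantify <- function(panel, cfg = gate_config()) {
  stopifnot(inherits(panel, "sample_panel"))
  missing_tubes <- setdiff(tube_conditions(), names(panel$tubes))
  if (length(missing_tubes))
    stop("panel lacks tube(s): ", paste(missing_tubes, collapse = ", "),
         call. = FALSE)
  th <- derive_thresholds(panel, cfg)
  gated <- lapply(panel$tubes, function(ev) apply_gates(ev, th, cfg))
  raw <- t(vapply(gated, raw_percentages, numeric(3)))
  corrected <- raw["stained", ] - raw["dmso_control", ]
  mfi <- vapply(gated, function(g) mean(g$hx103), numeric(1))
  denom <- mfi[["stained"]] - mfi[["dmso_control"]]
  if (denom > 0) {
    br <- 1 - (mfi[["gefitinib_blocked"]] - mfi[["dmso_control"]]) / denom
    br <- min(max(br, 0), 1)
    pass <- br >= cfg$blocking_ratio_min
  } else {
    br <- NA_real_   # not evaluable: no specific staining signal
    pass <- NA
  }
  structure(list(specimen_id = panel$specimen_id,
                 raw = raw, corrected = corrected,
                 mfi_stained = mfi[["stained"]],
                 mfi_dmso = mfi[["dmso_control"]],
                 mfi_blocked = mfi[["gefitinib_blocked"]],
                 blocking_ratio = br, specificity_pass = pass,
                 thresholds = th,
                 gate_counts = lapply(gated, attr, "gate_counts")),
            class = "labeling_result")
}

#' @export
print.labeling_result <- function(x, ...) {
  cat(sprintf("Labeling result for '%s'\n", x$specimen_id))
  cat(sprintf("  corrected: EGFR(+) %.2f%%, HX103(+) %.2f%%, EGFR(+)HX103(+) %.2f%%\n",
              x$corrected[["egfr_pos"]], x$corrected[["hx103_pos"]],
              x$corrected[["double_pos"]]))
  cat(sprintf("  probe MFI: stained %.1f, DMSO %.1f, blocked %.1f\n",
              x$mfi_stained, x$mfi_dmso, x$mfi_blocked))
  if (is.na(x$blocking_ratio)) {
    cat("  blocking ratio: not evaluable\n")
  } else {
    cat(sprintf("  blocking ratio: %.3f (specificity %s)\n", x$blocking_ratio,
                if (isTRUE(x$specificity_pass)) "pass" else "fail"))
  }
  invisible(x)
}

#' @export
as.data.frame.labeling_result <- function(x, ...) {
  data.frame(specimen_id = x$specimen_id,
             egfr_pos_raw = x$raw["stained", "egfr_pos"],
             hx103_pos_raw = x$raw["stained", "hx103_pos"],
             double_pos_raw = x$raw["stained", "double_pos"],
             egfr_pos_corrected = x$corrected[["egfr_pos"]],
             hx103_pos_corrected = x$corrected[["hx103_pos"]],
             double_pos_corrected = x$corrected[["double_pos"]],
             mfi_stained = x$mfi_stained, mfi_dmso = x$mfi_dmso,
             mfi_blocked = x$mfi_blocked,
             blocking_ratio = x$blocking_ratio,
             specificity_pass = x$specificity_pass,
             row.names = NULL)
}
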