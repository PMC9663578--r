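#' Cost scenario for mutation-testing triage
#'
#' Parameters of the decision model comparing two testing strategies for
#' EGFR-mutation triage: sequencing every patient (NGS-only), or running the
#' cheap probe-based FACS assay first and sequencing only FACS-negative
#' patients. The model prices testing only; treatment costs and the
#' downstream consequences of false positives are deliberately outside it.
#'
#' @param prevalence Fraction of patients carrying an activating mutation.
#' @param sens,spec FACS operating characteristics, fractions in `[0, 1]`.
#'   Defaults 0.733 and 1.0, the double-positive parameter's biopsy-cohort
#'   performance.
#' @param cost_facs,cost_ngs Per-sample testing costs in any common currency
#'   unit; defaults 14 and 140 (the itemised FACS estimate of ~14 dollars per
#'   biopsy and a nominal 10x sequencing cost).
#' @return An object of class `cost_scenario`.
#' @export
cost_scenario <- function(prevalence, sens = 0.733, spec = 1.0,
                          cost_facs = 14, cost_ngs = 140) {
  for (p in c(prevalence, sens, spec))
    if (!is.numeric(p) || p < 0 || p > 1)
      stop("'prevalence', 'sens' and 'spec' must lie in [0, 1]", call. = FALSE)
  if (cost_facs <= 0 || cost_ngs <= 0)
    stop("costs must be positive", call. = FALSE)
  structure(list(prevalence = prevalence, sens = sens, spec = spec,
                 cost_facs = cost_facs, cost_ngs = cost_ngs),
            class = "cost_scenario")
}

#' Probability that a patient tests FACS-positive
#'
#' `pi * sens + (1 - pi) * (1 - spec)`: true positives among mutation
#' carriers plus false positives among wild-type patients. This probability
#' is the pivot of the cost model, because FACS-positive patients skip
#' sequencing entirely.
#'
#' @param prevalence,sens,spec Fractions in `[0, 1]`; vectorised.
#' @return Probability of a positive FACS call.
#' @export
p_facs_positive <- function(prevalence, sens, spec) {
  for (p in list(prevalence, sens, spec))
    if (any(p < 0 | p > 1)) stop("arguments must lie in [0, 1]", call. = FALSE)
  prevalence * sens + (1 - prevalence) * (1 - spec)
}

#' Expected per-patient testing cost of each strategy
#'
#' NGS-only always costs one sequencing test. FACS-first costs the FACS test
#' plus, for the FACS-negative fraction, a sequencing test on top:
#' `C_F + (1 - p_pos) * C_N`. The FACS-first cost therefore lies between
#' `C_F` (everyone positive) and `C_F + C_N` (everyone negative, the most
#' expensive situation).
#'
#' @param scn A [cost_scenario()].
#' @return A list of class `strategy_costs`: `ngs_only`, `facs_first`,
#'   `p_facs_positive`.
#' @examples
#' expected_costs(cost_scenario(prevalence = 0.4))
#' @export
expected_costs <- function(scn) {
  stopifnot(inherits(scn, "cost_scenario"))
  p_pos <- p_facs_positive(scn$prevalence, scn$sens, scn$spec)
  structure(list(ngs_only = scn$cost_ngs,
                 facs_first = scn$cost_facs + (1 - p_pos) * scn$cost_ngs,
                 p_facs_positive = p_pos),
            class = "strategy_costs")
}

#' @export
print.strategy_costs <- function(x, ...) {
  cat(sprintf("Expected testing cost per patient: NGS-only %.2f, FACS-first %.2f (P[FACS+] = %.4f)\n",
              x$ngs_only, x$facs_first, x$p_facs_positive))
  invisible(x)
}

#' Break-even sequencing-to-FACS cost ratio
#'
#' The ratio `r* = C_N / C_F` at which the two strategies cost the same;
#' FACS-first triage is cheaper exactly when sequencing costs more than `r*`
#' times the FACS assay. Algebraically `r* = 1 / P(FACS positive)`, so with
#' perfect specificity `r* = 1 / (prevalence * sens)`.
#'
#' @param prevalence,sens,spec Fractions in `[0, 1]`; vectorised.
#' @return The break-even ratio; `Inf` (with a warning) when the positive
#'   probability is zero.
#' @examples
#' breakeven_ratio(0.50, 0.733, 1)   # ~3: FACS must be ~3x cheaper
#' breakeven_ratio(0.10, 0.733, 1)   # low-prevalence setting, ~13.6
#' @export
breakeven_ratio <- function(prevalence, sens, spec = 1.0) {
  p_pos <- p_facs_positive(prevalence, sens, spec)
  if (any(p_pos == 0))
    warning("P(FACS positive) is zero; break-even ratio is infinite")
  1 / p_pos
}

#' Break-even ratio over prevalence and sensitivity grids
#'
#' Evaluates [breakeven_ratio()] on the cross product of prevalence and
#' sensitivity grids at a fixed specificity, and (when `sens + spec > 1`,
#' i.e. the test is informative) asserts the ratio decreases in both
#' prevalence and sensitivity.
#'
#' @param prevalence_grid,sens_grid Non-empty numeric grids in `[0, 1]`.
#' @param spec Fixed specificity, default 1.
#' @return A data frame with columns `prevalence`, `sens`, `spec`,
#'   `p_facs_positive`, `breakeven_ratio`.
#' @export
breakeven_sweep <- function(prevalence_grid, sens_grid, spec = 1.0) {
  if (length(prevalence_grid) == 0 || length(sens_grid) == 0)
    stop("grids must be non-empty", call. = FALSE)
  grid <- expand.grid(prevalence = sort(prevalence_grid),
                      sens = sort(sens_grid))
  grid$spec <- spec
  grid$p_facs_positive <- p_facs_positive(grid$prevalence, grid$sens, spec)
  grid$breakeven_ratio <- 1 / grid$p_facs_positive
  informative <- all(grid$sens + spec > 1)
  if (informative) {
    by_sens <- split(grid, grid$sens)
    mono_prev <- all(vapply(by_sens, function(g)
      all(diff(g$breakeven_ratio[order(g$prevalence)]) < 0), logical(1)))
    by_prev <- split(grid, grid$prevalence)
    mono_sens <- all(vapply(by_prev, function(g)
      all(diff(g$breakeven_ratio[order(g$sens)]) < 0), logical(1)))
    stopifnot(mono_prev, mono_sens)
  }
  grid
}
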