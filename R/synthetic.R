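#' Cell-population specification for the event simulator
#'
#' One row of the mixture model behind a simulated specimen: a named
#' population with its event fraction, log-normal scatter parameters, CD45
#' staining level, a per-cell receptor-count distribution (log10 scale) and
#' the fraction of those receptors in the active, probe-bindable
#' conformation. `kd_apparent` is the apparent probe dissociation constant
#' used for that population's occupancy (cellular apparent values are treated
#' as interchangeable with recombinant-protein ones).
#'
#' @param name Population label, carried into the truth columns.
#' @param fraction Expected proportion of events, in `[0, 1]`.
#' @param fsc_mean,ssc_mean Median scatter signal (a.u.); events are drawn
#'   log-normally around `log(mean)`.
#' @param fsc_sd,ssc_sd Log-scale standard deviations (dimensionless).
#' @param cd45_level Expected CD45 stain signal (a.u.); leukocytes are bright,
#'   epithelial/tumour cells and debris essentially unstained.
#' @param egfr_receptor_log10_mean,egfr_receptor_log10_sd Per-cell total EGFR
#'   receptor count, log10-normal.
#' @param active_fraction Fraction of that cell's receptors in the active
#'   conformation, in `[0, 1]`. Populations with `active_fraction >= 0.5` are
#'   marked truth-active.
#' @param kd_apparent Apparent probe Kd for this population (uM).
#' @return An object of class `population_spec`.
#' @seealso [simulate_panel()], [preset_panel()], [tumor_mixture_populations()]
#' @export
population_spec <- function(name, fraction,
                            fsc_mean, fsc_sd, ssc_mean, ssc_sd,
                            cd45_level,
                            egfr_receptor_log10_mean, egfr_receptor_log10_sd,
                            active_fraction, kd_apparent = 2.7) {
  stopifnot(is.character(name), length(name) == 1L)
  if (fraction < 0 || fraction > 1) stop("'fraction' must be in [0, 1]", call. = FALSE)
  if (fsc_sd < 0 || ssc_sd < 0 || egfr_receptor_log10_sd < 0)
    stop("standard deviations must be >= 0", call. = FALSE)
  if (active_fraction < 0 || active_fraction > 1)
    stop("'active_fraction' must be in [0, 1]", call. = FALSE)
  if (kd_apparent <= 0) stop("'kd_apparent' must be positive", call. = FALSE)
  structure(list(name = name, fraction = fraction,
                 fsc_mean = fsc_mean, fsc_sd = fsc_sd,
                 ssc_mean = ssc_mean, ssc_sd = ssc_sd,
                 cd45_level = cd45_level,
                 egfr_receptor_log10_mean = egfr_receptor_log10_mean,
                 egfr_receptor_log10_sd = egfr_receptor_log10_sd,
                 active_fraction = active_fraction,
                 kd_apparent = kd_apparent),
            class = "population_spec")
}

# canonical cellular archetypes; fractions supplied by the caller ------------

#' Building blocks for simulated specimens
#'
#' Convenience constructors for the recurring cellular archetypes:
#' constitutively active mutant tumour cells, autoinhibited wild-type tumour
#' cells, EGFR-overexpressing wild-type cells, normal epithelium, CD45(+)
#' leukocytes and sub-cellular debris. Each returns a [population_spec()]
#' with documented default channel parameters; only the event fraction is
#' required.
#'
#' @param fraction Event fraction for the population.
#' @param active_fraction,egfr_log10_mean,kd_apparent Overridable defaults,
#'   see [population_spec()].
#' @param name Population label.
#' @return A [population_spec()].
#' @name population_presets
NULL

#' @rdname population_presets
#' @export
pop_tumor_active <- function(fraction, active_fraction = 0.95,
                             egfr_log10_mean = 5.0, kd_apparent = 0.8,
                             name = "tumor_active") {
  population_spec(name, fraction,
                  fsc_mean = 5e4, fsc_sd = 0.35, ssc_mean = 3e4, ssc_sd = 0.40,
                  cd45_level = 20,
                  egfr_receptor_log10_mean = egfr_log10_mean,
                  egfr_receptor_log10_sd = 0.35,
                  active_fraction = active_fraction, kd_apparent = kd_apparent)
}

#' @rdname population_presets
#' @export
pop_tumor_inactive <- function(fraction, active_fraction = 0.02,
                               egfr_log10_mean = 5.0, kd_apparent = 2.7,
                               name = "tumor_inactive") {
  population_spec(name, fraction,
                  fsc_mean = 5e4, fsc_sd = 0.35, ssc_mean = 3e4, ssc_sd = 0.40,
                  cd45_level = 20,
                  egfr_receptor_log10_mean = egfr_log10_mean,
                  egfr_receptor_log10_sd = 0.35,
                  active_fraction = active_fraction, kd_apparent = kd_apparent)
}

#' @rdname population_presets
#' @export
pop_normal_epithelium <- function(fraction, name = "normal_epithelium") {
  population_spec(name, fraction,
                  fsc_mean = 4e4, fsc_sd = 0.35, ssc_mean = 2.5e4, ssc_sd = 0.40,
                  cd45_level = 20,
                  egfr_receptor_log10_mean = 3.9, egfr_receptor_log10_sd = 0.35,
                  active_fraction = 0.02, kd_apparent = 2.7)
}

#' @rdname population_presets
#' @export
pop_leukocyte <- function(fraction, name = "leukocyte") {
  population_spec(name, fraction,
                  fsc_mean = 3e4, fsc_sd = 0.30, ssc_mean = 1.8e4, ssc_sd = 0.35,
                  cd45_level = 1000,
                  egfr_receptor_log10_mean = 2.0, egfr_receptor_log10_sd = 0.30,
                  active_fraction = 0, kd_apparent = 2.7)
}

#' @rdname population_presets
#' @export
pop_debris <- function(fraction, name = "debris") {
  population_spec(name, fraction,
                  fsc_mean = 5e3, fsc_sd = 0.40, ssc_mean = 2e3, ssc_sd = 0.50,
                  cd45_level = 0,
                  egfr_receptor_log10_mean = 0, egfr_receptor_log10_sd = 0,
                  active_fraction = 0, kd_apparent = 2.7)
}

#' Tumour mixture with a prescribed active share
#'
#' Population set for parameter-recovery studies: tumour cells split between
#' an active (mutant-like) and an inactive (autoinhibited wild-type-like)
#' compartment so that `active_share` of the tumour cells are truth-active,
#' plus leukocytes and debris.
#'
#' @param active_share Target fraction of truth-active cells among tumour
#'   cells, in `[0, 1]`.
#' @param tumor_fraction,leukocyte_fraction,debris_fraction Event fractions;
#'   must sum to 1.
#' @return A list of [population_spec()] objects.
#' @export
tumor_mixture_populations <- function(active_share, tumor_fraction = 0.85,
                                      leukocyte_fraction = 0.08,
                                      debris_fraction = 0.07) {
  stopifnot(active_share >= 0, active_share <= 1)
  pops <- list()
  if (active_share > 0)
    pops <- c(pops, list(pop_tumor_active(tumor_fraction * active_share)))
  if (active_share < 1)
    pops <- c(pops, list(pop_tumor_inactive(tumor_fraction * (1 - active_share))))
  c(pops, list(pop_leukocyte(leukocyte_fraction), pop_debris(debris_fraction)))
}

#' Assay model: staining chemistry and detector behaviour
#'
#' Groups everything the simulator needs besides the cell populations: the
#' fluorogenic probe's turn-on model, probe/competitor working concentrations,
#' the competitor's dissociation constant, the EGFR-antibody channel gain and
#' background, the CD45 channel background, and the multiplicative noise level
#' applied to all specific signals.
#'
#' @param fluor A [fluorophore_model()].
#' @param probe_conc Probe staining concentration (uM), default 5.
#' @param competitor_conc Competitor concentration in the blocked tube (uM),
#'   default 50 (gefitinib preincubation).
#' @param ki_competitor Competitor dissociation constant (uM), default 0.5.
#' @param ab_gain Antibody-channel a.u. per receptor, default 3e-3.
#' @param ab_background_mean,ab_background_sd Antibody-channel background
#'   (a.u.); this is also the isotype-control signal.
#' @param cd45_background_mean,cd45_background_sd CD45-channel background
#'   (a.u.).
#' @param noise_cv Log-normal coefficient of variation applied
#'   multiplicatively to every specific (non-background) signal, default 0.25.
#' @return An object of class `assay_model`.
#' @export
assay_model <- function(fluor = fluorophore_model(),
                        probe_conc = 5, competitor_conc = 50,
                        ki_competitor = 0.5,
                        ab_gain = 3e-3,
                        ab_background_mean = 30, ab_background_sd = 10,
                        cd45_background_mean = 10, cd45_background_sd = 5,
                        noise_cv = 0.25) {
  stopifnot(inherits(fluor, "fluorophore_model"),
            probe_conc >= 0, competitor_conc >= 0, ki_competitor > 0,
            ab_gain > 0, noise_cv >= 0)
  structure(list(fluor = fluor, probe_conc = probe_conc,
                 competitor_conc = competitor_conc,
                 ki_competitor = ki_competitor,
                 ab_gain = ab_gain,
                 ab_background_mean = ab_background_mean,
                 ab_background_sd = ab_background_sd,
                 cd45_background_mean = cd45_background_mean,
                 cd45_background_sd = cd45_background_sd,
                 noise_cv = noise_cv),
            class = "assay_model")
}

tube_conditions <- function() {
  c("dmso_control", "isotype_control", "stained", "gefitinib_blocked")
}

# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# multiplicative log-normal noise with unit mean and the given CV
rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

simulate_tube <- function(populations, n_events, tube, assay) {
  fracs <- vapply(populations, `[[`, numeric(1), "fraction")
  idx <- sample.int(length(populations), n_events, replace = TRUE, prob = fracs)
  fl <- assay$fluor
  get <- function(field) vapply(populations, `[[`, numeric(1), field)[idx]
  nm <- vapply(populations, `[[`, character(1), "name")[idx]

  fsc <- stats::rlnorm(n_events, log(get("fsc_mean")), get("fsc_sd"))
  ssc <- stats::rlnorm(n_events, log(get("ssc_mean")), get("ssc_sd"))
  cd45 <- get("cd45_level") * rlnorm_cv(n_events, assay$noise_cv) +
    stats::rnorm(n_events, assay$cd45_background_mean, assay$cd45_background_sd)

  n_receptors <- 10^stats::rnorm(n_events, get("egfr_receptor_log10_mean"),
                                 get("egfr_receptor_log10_sd"))
  active_fraction <- get("active_fraction")
  n_active <- active_fraction * n_receptors

  # antibody channel: isotype tube sees background only
  egfr_ab <- stats::rnorm(n_events, assay$ab_background_mean, assay$ab_background_sd)
  if (tube != "isotype_control")
    egfr_ab <- egfr_ab + assay$ab_gain * n_receptors * rlnorm_cv(n_events, assay$noise_cv)

  # probe channel: occupancy depends on the tube condition
  probe <- if (tube == "dmso_control") 0 else assay$probe_conc
  competitor <- if (tube == "gefitinib_blocked") assay$competitor_conc else 0
  kds <- get("kd_apparent")
  if (probe > 0) {
    alpha <- if (competitor > 0) 1 + competitor / assay$ki_competitor else 1
    occ <- probe / (probe + kds * alpha)
  } else {
    occ <- rep(0, n_events)
  }
  specific <- fl$per_molecule_gain * (fl$phi_bound / fl$phi_free) * n_active * occ
  hx103 <- specific * rlnorm_cv(n_events, assay$noise_cv) +
    stats::rnorm(n_events, fl$autofluorescence_mean, fl$autofluorescence_sd)

  data.frame(event_id = seq_len(n_events),
             fsc = pmax(fsc, 0), ssc = pmax(ssc, 0),
             cd45 = pmax(cd45, 0), egfr_ab = pmax(egfr_ab, 0),
             hx103 = pmax(hx103, 0),
             truth_population = nm,
             truth_active = as.integer(active_fraction >= 0.5))
}

#' Simulate a matched four-tube specimen panel
#'
#' Generates per-event tables for the four tube conditions of one specimen:
#' a DMSO control (antibodies but no probe, so the probe channel is pure
#' autofluorescence), an isotype control (probe but antibody background only),
#' the stained tube (probe at its working concentration) and the
#' gefitinib-blocked tube (probe plus excess competitor, reducing occupancy
#' through the competitive isotherm). Channel noise is multiplicative
#' log-normal on specific signals plus an additive Gaussian background floor,
#' truncated at zero. All four tubes are drawn from the same population
#' specification; the same seed reproduces the panel bit-for-bit.
#'
#' @param populations List of [population_spec()] objects whose fractions sum
#'   to 1.
#' @param n_events Events per tube, at least 100.
#' @param seed Integer seed; all randomness flows through it.
#' @param assay An [assay_model()].
#' @param specimen_id Identifier carried into results.
#' @param tissue_type `"surgical"` or `"biopsy"`.
#' @return An object of class `sample_panel`: a list with `specimen_id`,
#'   `tissue_type`, `seed`, `n_events` and `tubes` (a named list of per-event
#'   data frames, one per tube condition, with simulation truth columns).
#' @examples
#' panel <- simulate_panel(tumor_mixture_populations(0.8),
#'                         n_events = 2000, seed = 1)
#' sapply(panel$tubes, nrow)
#' @export
simulate_panel <- function(populations, n_events, seed,
                           assay = assay_model(),
                           specimen_id = "SIM-1", tissue_type = "surgical") {
  if (inherits(populations, "population_spec")) populations <- list(populations)
  stopifnot(length(populations) >= 1L,
            all(vapply(populations, inherits, logical(1), "population_spec")),
            inherits(assay, "assay_model"))
  if (n_events < 100) stop("'n_events' must be at least 100", call. = FALSE)
  n_events <- as.integer(n_events)
  fracs <- vapply(populations, `[[`, numeric(1), "fraction")
  if (abs(sum(fracs) - 1) > 1e-9)
    stop("population fractions must sum to 1 (got ", sum(fracs), ")", call. = FALSE)
  if (!tissue_type %in% c("surgical", "biopsy"))
    stop("'tissue_type' must be \"surgical\" or \"biopsy\"", call. = FALSE)

  tubes <- with_local_seed(seed, {
    out <- lapply(tube_conditions(), function(tube)
      simulate_tube(populations, n_events, tube, assay))
    names(out) <- tube_conditions()
    out
  })
  structure(list(specimen_id = specimen_id, tissue_type = tissue_type,
                 seed = seed, n_events = n_events,
                 populations = populations, tubes = tubes),
            class = "sample_panel")
}

#' @export
print.sample_panel <- function(x, ...) {
  cat(sprintf("Sample panel '%s' (%s tissue, %d events/tube, seed %s)\n",
              x$specimen_id, x$tissue_type, x$n_events, format(x$seed)))
  cat("  populations:",
      paste(sprintf("%s (%.0f%%)",
                    vapply(x$populations, `[[`, character(1), "name"),
                    100 * vapply(x$populations, `[[`, numeric(1), "fraction")),
            collapse = ", "), "\n")
  invisible(x)
}

preset_definitions <- function() {
  list(
    mutant_high = list(
      pops = list(pop_tumor_active(0.85), pop_leukocyte(0.08), pop_debris(0.07)),
      note = "mutant tumour dominant, near-complete EGFR activation"),
    mutant_low_egfr = list(
      pops = list(pop_tumor_active(0.80, egfr_log10_mean = 4.1),
                  pop_leukocyte(0.12), pop_debris(0.08)),
      note = "activating mutation with low total-EGFR expression"),
    wt_overexpressing = list(
      pops = list(pop_tumor_inactive(0.80, egfr_log10_mean = 5.7),
                  pop_leukocyte(0.12), pop_debris(0.08)),
      note = "wild-type tumour with unusually high EGFR copy number"),
    wt_normal = list(
      pops = list(pop_tumor_inactive(0.80, egfr_log10_mean = 4.0),
                  pop_leukocyte(0.12), pop_debris(0.08)),
      note = "wild-type tumour, autoinhibited receptor, modest expression"),
    adjacent_normal = list(
      pops = list(pop_normal_epithelium(0.55), pop_leukocyte(0.30), pop_debris(0.15)),
      note = "paired adjacent normal tissue, leukocyte rich"))
}

#' Simulate a documented specimen archetype
#'
#' Wraps [simulate_panel()] with fixed population constants for five
#' archetypes seen across real specimens: `mutant_high` (mutant tumour with
#' near-complete activation), `mutant_low_egfr` (activating mutation but low
#' total-EGFR expression), `wt_overexpressing` (wild-type with very high
#' receptor numbers but autoinhibited kinase), `wt_normal`, and
#' `adjacent_normal` (normal tissue, leukocyte rich).
#'
#' @param archetype One of the five archetype labels.
#' @param seed Integer seed.
#' @param n_events Events per tube; defaults to 1e4 for biopsy and 1e5 for
#'   surgical panels, echoing typical live-cell yields of the two specimen
#'   routes.
#' @param tissue_type `"biopsy"` (default) or `"surgical"`.
#' @return A `sample_panel`.
#' @export
preset_panel <- function(archetype, seed,
                         n_events = if (tissue_type == "biopsy") 1e4 else 1e5,
                         tissue_type = "biopsy") {
  defs <- preset_definitions()
  if (!archetype %in% names(defs))
    stop("unknown archetype '", archetype, "'; choose one of: ",
         paste(names(defs), collapse = ", "), call. = FALSE)
  simulate_panel(defs[[archetype]]$pops, n_events = n_events, seed = seed,
                 specimen_id = archetype, tissue_type = tissue_type)
}

#' Write / read a panel as per-tube CSV files plus a JSON manifest
#'
#' Each tube is written as `<tube>.csv` with columns `event_id, fsc, ssc,
#' cd45, egfr_ab, hx103, truth_population, truth_active`; `manifest.json`
#' records the specimen metadata, seed and tube file names. `read_panel()`
#' accepts the directory or the manifest path and restores the panel; truth
#' columns are optional in user-supplied files.
#'
#' @param panel A `sample_panel`.
#' @param dir Directory to write into (created if needed).
#' @return `write_panel()` returns the manifest path invisibly;
#'   `read_panel()` returns a `sample_panel`.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "sample_panel"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- vapply(names(panel$tubes), function(tube) {
    f <- file.path(dir, paste0(tube, ".csv"))
    utils::write.csv(panel$tubes[[tube]], f, row.names = FALSE)
    basename(f)
  }, character(1))
  manifest <- list(specimen_id = panel$specimen_id,
                   tissue_type = panel$tissue_type,
                   seed = panel$seed, n_events = panel$n_events,
                   tubes = as.list(files))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel
#' @param path Directory containing `manifest.json`, or the manifest path.
#' @export
read_panel <- function(path) {
  manifest_path <- if (dir.exists(path)) file.path(path, "manifest.json") else path
  if (!file.exists(manifest_path))
    stop("no panel manifest at '", manifest_path, "'", call. = FALSE)
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  missing_tubes <- setdiff(tube_conditions(), names(m$tubes))
  if (length(missing_tubes))
    stop("manifest lacks tube(s): ", paste(missing_tubes, collapse = ", "),
         call. = FALSE)
  dir <- dirname(manifest_path)
  tubes <- lapply(m$tubes, function(f) {
    df <- utils::read.csv(file.path(dir, f))
    need <- c("event_id", "fsc", "ssc", "cd45", "egfr_ab", "hx103")
    if (!all(need %in% names(df)))
      stop("tube file '", f, "' lacks required columns", call. = FALSE)
    df
  })
  structure(list(specimen_id = m$specimen_id, tissue_type = m$tissue_type,
                 seed = m$seed, n_events = as.integer(m$n_events),
                 populations = NULL, tubes = tubes[tube_conditions()]),
            class = "sample_panel")
}
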