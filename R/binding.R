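#' Competitive binding parameters
#'
#' Bundles the equilibrium parameters of the probe--kinase interaction: the
#' probe's dissociation constant, its working concentration, and (optionally)
#' a competing ATP-pocket inhibitor characterised by its own dissociation
#' constant. All concentrations are in micromolar.
#'
#' @param kd Probe dissociation constant (uM), must be positive.
#' @param probe_conc Free probe concentration (uM), non-negative.
#'   Default 5 uM, the staining concentration used in the assay.
#' @param competitor_conc Competitor concentration (uM), non-negative.
#'   Default 0 (no competition).
#' @param ki_competitor Competitor dissociation constant (uM). `NULL` means
#'   no competitor is modelled even if `competitor_conc > 0` is supplied
#'   (an error in that case). Default 0.5 uM when a competitor is present,
#'   an order-of-magnitude working value for gefitinib chosen so that 50 uM
#'   competitor suppresses the bulk of probe labeling; it is configurable
#'   because the assay never measures it directly.
#' @return An object of class `binding_params`.
#' @examples
#' binding_params(kd = 0.8)                          # mutant-like affinity
#' binding_params(kd = 2.7, competitor_conc = 50)    # wild-type, blocked
#' @export
binding_params <- function(kd, probe_conc = 5, competitor_conc = 0,
                           ki_competitor = if (competitor_conc > 0) 0.5 else NULL) {
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("'kd' must be a single positive number (uM)", call. = FALSE)
  if (!is.numeric(probe_conc) || probe_conc < 0 || !is.finite(probe_conc))
    stop("'probe_conc' must be a non-negative number (uM)", call. = FALSE)
  if (!is.numeric(competitor_conc) || competitor_conc < 0 || !is.finite(competitor_conc))
    stop("'competitor_conc' must be a non-negative number (uM)", call. = FALSE)
  if (!is.null(ki_competitor)) {
    if (!is.numeric(ki_competitor) || length(ki_competitor) != 1L ||
        !is.finite(ki_competitor) || ki_competitor <= 0)
      stop("'ki_competitor' must be a single positive number (uM)", call. = FALSE)
  } else if (competitor_conc > 0) {
    stop("competitor_conc > 0 requires a 'ki_competitor'", call. = FALSE)
  }
  structure(list(kd = kd, probe_conc = probe_conc,
                 competitor_conc = competitor_conc,
                 ki_competitor = ki_competitor),
            class = "binding_params")
}

#' Fractional receptor occupancy under competitive binding
#'
#' Equilibrium fraction of probe-bindable (active-conformation) kinase sites
#' occupied by the probe, from the standard competitive isotherm
#' \deqn{\theta = \frac{P}{P + K_d\,(1 + I/K_i)}}
#' where `P` is the probe concentration, `I` the competitor concentration and
#' `K_i` its dissociation constant. With no competitor the expression reduces
#' exactly to the one-site isotherm `P / (P + Kd)`.
#'
#' @param params A [binding_params()] object.
#' @return Occupancy as a fraction in `[0, 1]`.
#' @examples
#' fractional_occupancy(binding_params(kd = 0.8))                 # stained
#' fractional_occupancy(binding_params(kd = 0.8,
#'                                     competitor_conc = 50))     # blocked
#' @export
fractional_occupancy <- function(params) {
  stopifnot(inherits(params, "binding_params"))
  alpha <- if (params$competitor_conc > 0)
    1 + params$competitor_conc / params$ki_competitor else 1
  p <- params$probe_conc
  p / (p + params$kd * alpha)
}

#' Turn-on fluorophore brightness model
#'
#' Describes the environment-sensitive fluorophore: nearly dark in aqueous
#' solution and bright in the hydrophobic kinase pocket. The bound-state
#' quantum yield is proxied by the value measured in DMSO, since no
#' protein-bound quantum yield is available; the free/bound quotient sets the
#' turn-on contrast applied on top of a per-bound-molecule detection gain.
#'
#' @param phi_free Quantum yield of the free (aqueous) probe, in (0, 1].
#'   Default 0.058 (measured in PBS).
#' @param phi_bound Quantum yield of the bound probe, in (0, 1].
#'   Default 0.424 (DMSO proxy for the hydrophobic pocket).
#' @param per_molecule_gain Arbitrary fluorescence units contributed per bound
#'   probe molecule before the turn-on contrast is applied. Default 1e-3.
#' @param autofluorescence_mean,autofluorescence_sd Additive cellular
#'   autofluorescence floor of the probe channel (a.u.).
#' @return An object of class `fluorophore_model`.
#' @export
fluorophore_model <- function(phi_free = 0.058, phi_bound = 0.424,
                              per_molecule_gain = 1e-3,
                              autofluorescence_mean = 50,
                              autofluorescence_sd = 15) {
  for (phi in c(phi_free, phi_bound))
    if (!is.numeric(phi) || phi <= 0 || phi > 1)
      stop("quantum yields must lie in (0, 1]", call. = FALSE)
  if (per_molecule_gain <= 0) stop("'per_molecule_gain' must be positive", call. = FALSE)
  if (autofluorescence_sd < 0) stop("'autofluorescence_sd' must be >= 0", call. = FALSE)
  structure(list(phi_free = phi_free, phi_bound = phi_bound,
                 per_molecule_gain = per_molecule_gain,
                 autofluorescence_mean = autofluorescence_mean,
                 autofluorescence_sd = autofluorescence_sd),
            class = "fluorophore_model")
}

#' Expected per-cell probe fluorescence
#'
#' Deterministic expectation of the probe-channel signal for a cell carrying
#' `n_active_receptors` probe-bindable kinase sites at a given occupancy:
#' autofluorescence plus `gain * (phi_bound/phi_free) * n * occupancy`. Only
#' bound probe contributes above background (unbound probe is washed out and
#' nearly dark); measurement noise is the simulator's concern, not this
#' function's.
#'
#' @param n_active_receptors Number of active-conformation receptors (>= 0).
#' @param occupancy Fraction of those receptors occupied by probe, in `[0, 1]`.
#' @param fluor A [fluorophore_model()].
#' @return Expected signal in arbitrary units. Vectorised over
#'   `n_active_receptors` and `occupancy`.
#' @export
expected_cell_fluorescence <- function(n_active_receptors, occupancy, fluor) {
  stopifnot(inherits(fluor, "fluorophore_model"))
  if (any(n_active_receptors < 0) || any(occupancy < 0) || any(occupancy > 1))
    stop("'n_active_receptors' must be >= 0 and 'occupancy' in [0, 1]", call. = FALSE)
  fluor$autofluorescence_mean +
    fluor$per_molecule_gain * (fluor$phi_bound / fluor$phi_free) *
    n_active_receptors * occupancy
}

# asymptotic covariance of a nls.lm fit: resvar * (J'J)^-1; all-NA on a
# singular Jacobian (e.g. zero-residual fits keep SEs of exactly 0)
lm_vcov <- function(fit) {
  p <- length(fit$par)
  rdf <- length(fit$fvec) - p
  tryCatch(chol2inv(chol(fit$hessian)) * fit$deviance / rdf,
           error = function(e) matrix(NA_real_, p, p))
}

#' Fit a one-site saturation binding curve
#'
#' Least-squares fit of `B = Bmax * c / (c + Kd)` to concentration--response
#' data, used to recover apparent dissociation constants from titrations.
#' The optimisation is a trust-region Levenberg-Marquardt search over
#' `(Bmax, log10 Kd)`; starting values come from the response maximum and the
#' geometric-mean concentration.
#'
#' @param conc Concentrations (uM), at least 4 distinct positive values.
#' @param response Measured binding signal (a.u.), same length as `conc`.
#' @return A list of class `saturation_fit` with elements `kd`, `bmax`,
#'   `kd_se`, `bmax_se` (asymptotic standard errors), `fitted` and
#'   `residuals`.
#' @examples
#' conc <- c(0.1, 0.3, 0.6, 1, 2, 4, 8, 16)
#' resp <- 100 * conc / (conc + 0.8)
#' fit <- saturation_binding_fit(conc, resp)
#' fit$kd
#' @export
saturation_binding_fit <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  keep <- is.finite(conc) & is.finite(response) & conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(unique(conc)) < 4L)
    stop("need at least 4 distinct positive concentrations", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("fit failure: response is constant across concentrations", call. = FALSE)
  model <- function(par) par[["bmax"]] * conc / (conc + 10^par[["lkd"]])
  start <- c(bmax = max(response), lkd = log10(exp(mean(log(conc)))))
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(par) response - model(par),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("fit failure: ", conditionMessage(e), call. = FALSE))
  if (!fit$info %in% 1:4)
    stop("fit failure: no convergence (", fit$message, ")", call. = FALSE)
  est <- fit$par
  vc <- lm_vcov(fit)
  kd <- 10^est[["lkd"]]
  # delta method for se(Kd) from se(log10 Kd)
  kd_se <- kd * log(10) * sqrt(vc[2, 2])
  if (!is.finite(kd) || kd <= 0 || est[["bmax"]] <= 0)
    stop("fit failure: degenerate parameter estimates", call. = FALSE)
  structure(list(kd = kd, bmax = est[["bmax"]],
                 kd_se = unname(kd_se), bmax_se = sqrt(vc[1, 1]),
                 fitted = model(est), residuals = response - model(est)),
            class = "saturation_fit")
}

#' Dose-response (four-parameter logistic) parameters
#'
#' @param ic50 Half-maximal inhibitory concentration (nM), positive.
#' @param hill Hill slope, dimensionless.
#' @param top,bottom Response asymptotes as fractions of control; `top` must
#'   be at least `bottom`.
#' @return An object of class `dose_response_params`.
#' @export
dose_response_params <- function(ic50, hill = 1, top = 1, bottom = 0) {
  if (!is.numeric(ic50) || ic50 <= 0 || !is.finite(ic50))
    stop("'ic50' must be positive", call. = FALSE)
  if (top < bottom) stop("'top' must be >= 'bottom'", call. = FALSE)
  structure(list(ic50 = ic50, hill = hill, top = top, bottom = bottom),
            class = "dose_response_params")
}

#' Four-parameter logistic dose-response curve
#'
#' Forward model for log(inhibitor) vs normalised response with variable
#' slope:
#' \deqn{y = bottom + \frac{top - bottom}{1 + 10^{(\log_{10} IC_{50} - \log_{10} c)\,hill}}}
#' At `c = ic50` the response is the midpoint `(top + bottom) / 2`.
#'
#' @param conc Inhibitor concentrations (nM), positive; vectorised.
#' @param params A [dose_response_params()] object.
#' @return Response fractions, same length as `conc`.
#' @export
four_param_logistic <- function(conc, params) {
  stopifnot(inherits(params, "dose_response_params"))
  if (any(conc <= 0)) stop("'conc' must be positive", call. = FALSE)
  params$bottom + (params$top - params$bottom) /
    (1 + 10^((log10(params$ic50) - log10(conc)) * params$hill))
}

#' Fit an IC50 from dose-response data
#'
#' Fits the four-parameter logistic by trust-region nonlinear least squares on
#' log-concentration. Starting values: asymptotes from the response extremes,
#' IC50 at the geometric-mean concentration, unit Hill slope. Returns the
#' fitted parameters together with an asymptotic 95% confidence interval for
#' the IC50 (Wald interval on the log10 scale, back-transformed).
#'
#' @param conc Concentrations (nM), at least 5 values bracketing the
#'   inflection.
#' @param response Normalised responses, same length as `conc`.
#' @return A list of class `ic50_fit`: `params` (a
#'   [dose_response_params()]), `ic50_ci95` (length-2 numeric), `fitted`.
#' @export
fit_ic50 <- function(conc, response) {
  stopifnot(length(conc) == length(response))
  keep <- is.finite(conc) & is.finite(response) & conc > 0
  conc <- conc[keep]; response <- response[keep]
  if (length(conc) < 5L)
    stop("need at least 5 concentrations bracketing the inflection", call. = FALSE)
  if (stats::sd(response) == 0)
    stop("fit failure: all responses identical", call. = FALSE)
  model <- function(par)
    par[["bottom"]] + (par[["top"]] - par[["bottom"]]) /
      (1 + 10^((par[["lic50"]] - log10(conc)) * par[["hill"]]))
  start <- c(top = max(response), bottom = min(response),
             lic50 = log10(exp(mean(log(conc)))), hill = 1)
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(par) response - model(par),
                       control = minpack.lm::nls.lm.control(
                         maxiter = 1000, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("fit failure: ", conditionMessage(e), call. = FALSE))
  if (!fit$info %in% 1:4)
    stop("fit failure: no convergence (", fit$message, ")", call. = FALSE)
  est <- fit$par
  se_l <- sqrt(lm_vcov(fit)[3, 3])
  ic50 <- 10^est[["lic50"]]
  if (!is.finite(ic50) || ic50 <= 0)
    stop("fit failure: degenerate IC50 estimate", call. = FALSE)
  structure(list(
    params = dose_response_params(ic50 = ic50, hill = est[["hill"]],
                                  top = est[["top"]], bottom = est[["bottom"]]),
    ic50_ci95 = 10^(est[["lic50"]] + c(-1, 1) * 1.96 * se_l),
    fitted = model(est)),
    class = "ic50_fit")
}

#' @export
print.saturation_fit <- function(x, ...) {
  cat(sprintf("One-site saturation fit: Kd = %.4g +/- %.2g uM, Bmax = %.4g +/- %.2g\n",
              x$kd, x$kd_se, x$bmax, x$bmax_se))
  invisible(x)
}

#' @export
print.ic50_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("4PL fit: IC50 = %.4g nM (95%% CI %.4g-%.4g), hill = %.3g, top = %.3g, bottom = %.3g\n",
              p$ic50, x$ic50_ci95[1], x$ic50_ci95[2], p$hill, p$top, p$bottom))
  invisible(x)
}
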