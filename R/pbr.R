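# Potential biological removal: the annual removable number is
# PBR = 0.5 * N * r0 * Fr, i.e. a constant fraction Fp = 0.5 * r0 * Fr of
# every age class, with r0 the low-density growth rate (lambda0 - 1) fixed
# at its calibration value and Fr a recovery factor in (0, 1].

#' Annual potential biological removal
#'
#' `PBR = 0.5 * N * r0 * Fr`: the number of individuals that may be removed
#' per year from a stock of size `N` with low-density growth rate `r0 > 0`
#' under recovery factor `Fr`. Homogeneous of degree 1 in `N`.
#'
#' @param N Stock size (`>= 0`), vectorized.
#' @param r0 Low-density growth rate per year; must be `> 0` (the quota is
#'   undefined for declining populations).
#' @param fr Recovery factor in `(0, 1]` (0.1 for threatened stocks, 1 for
#'   robust ones).
#' @return Individuals per year.
#' @examples
#' pbr_quota(1000, 0.1, 1)    # 50
#' pbr_quota(1000, 0.1, 0.1)  # 5
#' @export
pbr_quota <- function(N, r0, fr) {
  check_pbr_args(r0, fr)
  stopifnot(all(N >= 0))
  0.5 * N * r0 * fr
}

#' Annual harvestable fraction under PBR
#'
#' `Fp = PBR / N = 0.5 * r0 * Fr`, the constant per-year fraction of the
#' population the quota amounts to.
#'
#' @inheritParams pbr_quota
#' @return Fraction per year.
#' @examples
#' harvest_fraction(0.1, 1)  # 0.05
#' @export
harvest_fraction <- function(r0, fr) {
  check_pbr_args(r0, fr)
  0.5 * r0 * fr
}

check_pbr_args <- function(r0, fr) {
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop("PBR is undefined for r0 <= 0 (declining population)")
  if (any(!is.finite(fr)) || any(fr <= 0) || any(fr > 1))
    stop("recovery factor fr must lie in (0, 1]")
  invisible(TRUE)
}

#' Response of a density-dependent model to constant PBR harvesting
#'
#' Each simulated year, after the matrix transition, every age class loses
#' the fraction `Fp = 0.5 * r0 * Fr` of its count, with `r0 = lambda0 - 1`
#' held at its calibration value. Returns the [response_summary()] of the
#' harvested model against the unharvested baseline: the leftover `r0` is
#' measured with the harvest applied at low density, `N*` from equilibrium
#' runs with common random numbers.
#'
#' @param model A [dd_model()] calibrated with `lambda0 > 1` and no extra
#'   mortality.
#' @param fr Recovery factor in `(0, 1]`.
#' @param ... Passed on to [response_summary()] (`n_reps`, `seed`,
#'   `nstar_method`, ...).
#' @return A one-row `data.frame` with `r0_response_pct` and
#'   `nstar_response_pct`.
#' @export
simulate_pbr <- function(model, fr, ...) {
  if (model$lambda0 <= 1)
    stop("PBR harvesting is undefined for lambda0 <= 1")
  fp <- harvest_fraction(model$lambda0 - 1, fr)
  response_summary(model, model, harvest_fraction = fp, ...)
}

#' Recovery-factor sweep of PBR responses
#'
#' Crosses every fixture with every `lambda0` and every recovery factor and
#' tabulates the percentage responses of the leftover growth rate and the
#' equilibrium density under constant PBR harvesting. The attribute
#' `eq3_max_dev` carries the largest absolute deviation of the `r0`
#' responses (as fractions) from the `-Fr/2` approximation.
#'
#' @param catalog A [vital_rate_catalog()] (may be empty).
#' @param lambda0_grid Low-density growth rates (all `> 1`).
#' @param fr_grid Recovery factors in `(0, 1]`.
#' @param nstar_method `"simulate"` (stochastic equilibria, the published-protocol
#'   protocol) or `"deterministic"` (mean-matrix fixed point; fast).
#' @param n_reps,seed,burn_in,window Stochastic protocol settings.
#' @return A `data.frame` with columns `species, population, period,
#'   lambda0, fr, r0_response_pct, nstar_response_pct` and attribute
#'   `eq3_max_dev`.
#' @export
fr_sweep <- function(catalog, lambda0_grid = c(1.01, 1.03, 1.1),
                     fr_grid = seq(0.1, 1, by = 0.1),
                     nstar_method = c("simulate", "deterministic"),
                     n_reps = 150, seed = 1, burn_in = 300, window = 200) {
  nstar_method <- match.arg(nstar_method)
  if (length(lambda0_grid) == 0) stop("lambda0 grid is empty")
  if (length(fr_grid) == 0) stop("fr grid is empty")
  check_pbr_args(lambda0_grid - 1, fr_grid)
  out <- list()
  for (v in catalog) {
    for (lam0 in lambda0_grid) {
      model <- dd_model(v, lam0)
      r0 <- lam0 - 1
      n_b <- equilibrium_density(model, n_reps, seed, burn_in, window,
                                 nstar_method)
      for (fr in fr_grid) {
        fp <- harvest_fraction(r0, fr)
        r0_t <- leftover_r0(model, harvest_fraction = fp)
        n_t <- equilibrium_density(model, n_reps, seed, burn_in, window,
                                   nstar_method, harvest_fraction = fp)
        out[[length(out) + 1L]] <- data.frame(
          species = v$species, population = v$population, period = v$period,
          lambda0 = lam0, fr = fr,
          r0_response_pct = 100 * (r0_t - r0) / r0,
          nstar_response_pct = max(-100, 100 * (n_t - n_b) / n_b))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(species = character(), population = character(),
               period = character(), lambda0 = numeric(), fr = numeric(),
               r0_response_pct = numeric(), nstar_response_pct = numeric())
  attr(res, "eq3_max_dev") <-
    if (nrow(res)) max(abs(res$r0_response_pct / 100 + res$fr / 2)) else NA_real_
  res
}
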