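# The allowable-mortality mini-model: rearranging the PBR fraction so the
# acceptable proportional reduction of the equilibrium density R_N* sets the
# allowable annual kill fraction directly, Fp ~= r0 * R_N*. Valid only for
# density-dependent populations with positive low-density growth.

#' Allowable annual mortality fraction for an acceptable density reduction
#'
#' `Fp = r0 * R_Nstar`: the per-year fraction of a density-dependently
#' regulated population that can be removed while keeping the equilibrium
#' density within an acceptable proportional reduction `R_Nstar`. Identical
#' to [harvest_fraction()] with `Fr = 2 * R_Nstar`.
#'
#' @param r0 Low-density growth rate per year; must be `> 0` (the method is
#'   inapplicable to declining populations).
#' @param R_nstar Acceptable proportional reduction of the equilibrium
#'   density, in `[0, 1)`.
#' @return `Fp` per year.
#' @examples
#' allowable_fraction(0.1, 0.01)  # 0.001: 0.1% of the population per year
#' @export
allowable_fraction <- function(r0, R_nstar) {
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop("the allowable-mortality method requires r0 > 0")
  if (any(!is.finite(R_nstar)) || any(R_nstar < 0) || any(R_nstar >= 1))
    stop("R_nstar must lie in [0, 1)")
  r0 * R_nstar
}

#' Extra-mortality fraction implied by a percent-of-natural-mortality limit
#'
#' The ORNIS-style criteria allow additional kill up to a percentage of the
#' overall annual natural mortality; in the simulations this is the scenario
#' in which every cohort's mortality is multiplied by `1 + pct/100`. The
#' mapping is species-independent.
#'
#' @param pct Percentage of annual natural mortality (`>= 0`), e.g. 1 for
#'   the ORNIS criterion, 5 for the laxer variant, 10 for a cumulative
#'   multi-wind-farm case.
#' @return The extra-mortality fraction `x = pct / 100` to feed to
#'   [apply_extra_mortality()], [projection_config()] or [dd_model()].
#' @export
ornis_criterion_mortality <- function(pct) {
  stopifnot(all(is.finite(pct)), all(pct >= 0))
  pct / 100
}

#' Per-year kill fraction implied by proportional extra mortality
#'
#' The mini-model works in a scalar world: one population, one annual kill
#' fraction. A `%`-of-natural-mortality scenario scales each cohort's
#' mortality instead, so it is mapped to a single fraction as `x` times the
#' stable-age-weighted mean natural mortality, `F = x * sum(w_j (1 - S_j))`
#' with `w` the stable age distribution of the mean matrix.
#'
#' `mapping = "weighted_mortality"` (the default) counts heads: the expected
#' extra deaths per standing individual per year. Because a death's impact
#' on `lambda` depends on the age class it hits (reproductive value), this
#' proxy understates the growth-rate impact of a mortality multiplier.
#' `mapping = "lambda_equivalent"` instead returns the kill fraction whose
#' proportional growth-rate effect equals the scenario's,
#' `1 - lambda(x) / lambda(0)`, which is the scale on which the mini-model
#' and a uniform harvest are exactly comparable.
#'
#' @param v A [vital_rates()] object.
#' @param x Extra-mortality fraction.
#' @param weights Optional class weights replacing the stable age
#'   distribution (`weighted_mortality` mapping only).
#' @param mapping `"weighted_mortality"` or `"lambda_equivalent"`.
#' @return Kill fraction per year.
#' @export
implied_kill_fraction <- function(v, x, weights = NULL,
                                  mapping = c("weighted_mortality",
                                              "lambda_equivalent")) {
  stopifnot(x >= 0)
  mapping <- match.arg(mapping)
  if (mapping == "lambda_equivalent")
    return(1 - lambda1(v, extra_mortality = x) / lambda1(v))
  if (is.null(weights)) weights <- dominant_eigen(build_matrix(v))$w
  x * sum(weights * (1 - class_survival(v)))
}

#' Compare the mini-model against full matrix responses
#'
#' For every fixture x `lambda0` x extra-mortality combination, pairs the
#' matrix-model equilibrium-density response (via [dd_response()]) with the
#' mini-model prediction `-100 * F / r0`, where `F` is the
#' [implied_kill_fraction()] of the scenario. Also fits a least-squares
#' regression of matrix on mini-model responses over the non-extinct,
#' small-response subset (both responses within `100 * subset_limit` in
#' magnitude and the matrix response above the -100 floor), attached as
#' attributes `slope`, `intercept` and `n_subset`.
#'
#' @param catalog A [vital_rate_catalog()].
#' @param lambda0_grid Low-density growth rates.
#' @param x_grid Extra-mortality fractions.
#' @param nstar_method Passed to [response_summary()]; deterministic by
#'   default for a reproducible, fast comparison.
#' @param mapping Kill-fraction mapping for the mini-model axis; see
#'   [implied_kill_fraction()].
#' @param subset_limit Small-response cutoff as a fraction (default 0.2).
#' @param ... Passed on to [dd_response()] (`n_reps`, `seed`, ...).
#' @return A `data.frame` with one row per combination: identifiers,
#'   `lambda0`, `x`, `mini_response_pct`, `matrix_response_pct`.
#' @export
compare_minimodel_vs_matrix <- function(catalog,
                                        lambda0_grid = c(1.01, 1.03, 1.1),
                                        x_grid = c(0.01, 0.02, 0.05, 0.10),
                                        nstar_method = "deterministic",
                                        mapping = "weighted_mortality",
                                        subset_limit = 0.2, ...) {
  out <- list()
  for (v in catalog) {
    for (lam0 in lambda0_grid) {
      r0 <- lam0 - 1
      for (x in x_grid) {
        mini <- -100 * implied_kill_fraction(v, x, mapping = mapping) / r0
        mat <- dd_response(v, lam0, x, nstar_method = nstar_method,
                           ...)$nstar_response_pct
        out[[length(out) + 1L]] <- data.frame(
          species = v$species, population = v$population, period = v$period,
          lambda0 = lam0, x = x,
          mini_response_pct = mini, matrix_response_pct = mat)
      }
    }
  }
  res <- do.call(rbind, out)
  lim <- 100 * subset_limit
  sub <- res[res$matrix_response_pct > -100 &
               abs(res$matrix_response_pct) <= lim &
               abs(res$mini_response_pct) <= lim, ]
  if (nrow(sub) >= 2) {
    fit <- stats::lm(matrix_response_pct ~ mini_response_pct, data = sub)
    attr(res, "slope") <- unname(stats::coef(fit)[2])
    attr(res, "intercept") <- unname(stats::coef(fit)[1])
  } else {
    attr(res, "slope") <- NA_real_
    attr(res, "intercept") <- NA_real_
  }
  attr(res, "n_subset") <- nrow(sub)
  res
}
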