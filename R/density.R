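# Density-dependent models: recruitment (the whole fecundity row) is
# calibrated by a scalar c so the density-free matrix has a chosen
# low-density growth rate lambda0, then multiplied each year by
# (1 - A/K') where A is the breeding-probability-weighted adult count and K'
# the adult count at which recruitment vanishes. Density acts on recruitment
# only; survival and age at first reproduction are density-independent.

#' Calibrate recruitment to a target low-density growth rate
#'
#' Finds the scalar `c` such that multiplying the fecundity row by `c` makes
#' the dominant eigenvalue of the (density-free, baseline-mortality) matrix
#' equal `lambda0_target`. Solved by [stats::uniroot()] on a bracket whose
#' upper end is doubled until it encloses the target; the result is refined
#' to `1e-8` in `lambda`.
#'
#' @param v A [vital_rates()] object.
#' @param lambda0_target Target growth rate at low density (e.g. 1.01, 1.03,
#'   1.1). Must exceed the terminal-class survival rate, the growth rate
#'   left when recruitment is removed entirely.
#' @return The recruitment scalar `c > 0`.
#' @examples
#' v <- fixture(packaged_vital_rates(), "starling", "1960")
#' calibrate_recruitment(v, 1.01)  # (1.01 - 0.677) / (0.331 * 2.56 / 2)
#' @export
calibrate_recruitment <- function(v, lambda0_target) {
  floor_lambda <- v$survival$mean[3]          # all-fecundity-zero growth rate
  if (lambda0_target <= floor_lambda)
    stop(sprintf(paste0("lambda0 target %.4f is unreachable by fecundity ",
                        "scaling: it does not exceed the adult-survival ",
                        "self-loop %.4f"), lambda0_target, floor_lambda))
  f <- function(cc) lambda1(v, fecundity_scale = cc) - lambda0_target
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  stats::uniroot(f, c(1e-12, hi), tol = 1e-12)$root
}

#' Density-dependent model
#'
#' Bundles a vital-rate set with a calibrated recruitment scalar, the target
#' low-density growth rate, the zero-recruitment adult count `K'`, and an
#' extra-mortality scenario. Calibration always uses the baseline
#' (untreated) rates; `extra_mortality` is applied on top at simulation
#' time, which is what makes the "leftover" low-density growth rate move.
#'
#' @param v A [vital_rates()] object.
#' @param lambda0 Target low-density growth rate.
#' @param kprime Adult count at which recruitment is zero (`> 0`).
#' @param extra_mortality Extra-mortality fraction `x >= 0`.
#' @return An object of class `"dd_model"`.
#' @export
dd_model <- function(v, lambda0, kprime = 1e4, extra_mortality = 0) {
  validate_vital_rates(v)
  stopifnot(kprime > 0, extra_mortality >= 0)
  cc <- calibrate_recruitment(v, lambda0)
  got <- lambda1(v, fecundity_scale = cc)
  stopifnot(abs(got - lambda0) < 1e-8)
  structure(list(vital_rates = v, recruitment_scalar = cc, lambda0 = lambda0,
                 kprime = kprime, extra_mortality = extra_mortality),
            class = "dd_model")
}

#' @export
print.dd_model <- function(x, ...) {
  cat(sprintf("<dd_model> %s %s: lambda0 = %g (c = %.5f), K' = %g, x = %g\n",
              x$vital_rates$species, x$vital_rates$period, x$lambda0,
              x$recruitment_scalar, x$kprime, x$extra_mortality))
  invisible(x)
}

#' Density-dependent recruitment multiplier
#'
#' `max(0, 1 - A / kprime)`: recruitment declines linearly in the number of
#' reproducing adults `A` and is floored at zero once `A >= kprime`.
#'
#' @param A Reproducing-adult count (`>= 0`), vectorized.
#' @param kprime Adult count at which recruitment is zero (`> 0`).
#' @return Factor in `[0, 1]`.
#' @export
dd_multiplier <- function(A, kprime) {
  if (!is.finite(kprime) || kprime <= 0) stop("kprime must be > 0")
  stopifnot(all(A >= 0))
  pmax(0, 1 - A / kprime)
}

#' Leftover low-density growth rate under extra mortality
#'
#' The growth rate (per year, as `r0 = lambda - 1`) that remains at very low
#' density once the model's extra mortality is applied. The default
#' estimator is deterministic: the dominant eigenvalue of the
#' mean-parameter matrix with the density multiplier fixed at 1 and the
#' calibrated recruitment in place. `method = "stochastic"` instead measures
#' the mean annual log-growth of a small population over seeded replicates
#' (density multiplier ~ 1) and returns `expm1` of it.
#'
#' @param model A [dd_model()].
#' @param method `"deterministic"` (default) or `"stochastic"`.
#' @param n_reps,years,seed Stochastic-estimator settings.
#' @param harvest_fraction Constant per-class harvest fraction applied each
#'   year (used by the PBR analysis; default 0).
#' @return `r0` per year.
#' @export
leftover_r0 <- function(model, method = c("deterministic", "stochastic"),
                        n_reps = 200, years = 50, seed = 1,
                        harvest_fraction = 0) {
  method <- match.arg(method)
  if (method == "deterministic") {
    lam <- lambda1(model$vital_rates, extra_mortality = model$extra_mortality,
                   fecundity_scale = model$recruitment_scalar)
    return(lam * max(0, 1 - harvest_fraction) - 1)
  }
  v <- model$vital_rates
  w <- dominant_eigen(build_matrix(v, fecundity_scale = model$recruitment_scalar))$w
  # tiny population relative to K' so the density multiplier stays ~1
  sim <- simulate_cohorts(v, years = years, n_reps = n_reps,
                          init_state = 1e-6 * model$kprime * w,
                          extra_mortality = model$extra_mortality,
                          fecundity_scale = model$recruitment_scalar,
                          harvest_fraction = harvest_fraction, seed = seed)
  lg <- log(sim$totals[years + 1L, ] / sim$totals[1L, ]) / years
  expm1(mean(lg))
}

#' Equilibrium population size of the density-dependent model
#'
#' Default protocol (`method = "simulate"`, the stochastic reference protocol):
#' start at 1% of `K'` on the stable structure, project the stochastic
#' density-dependent model for `burn_in + window` years with annual rate
#' draws, and return the mean total population over the window and the
#' replicates. A replicate whose total drops below one individual is extinct
#' and contributes zero from then on. `method = "deterministic"` instead
#' solves the fixed point of the mean-parameter model: the recruitment
#' multiplier `m*` at which the effective annual growth equals 1, mapped
#' back to a total population via the stable structure at equilibrium;
#' it returns 0 when even full recruitment cannot reach growth 1.
#'
#' @param model A [dd_model()].
#' @param n_reps,seed,burn_in,window Simulation protocol settings.
#' @param method `"simulate"` or `"deterministic"`.
#' @param harvest_fraction Constant per-class harvest fraction (PBR).
#' @return `N*` in individuals (0 if extinct).
#' @export
equilibrium_density <- function(model, n_reps = 200, seed = 1,
                                burn_in = 300, window = 200,
                                method = c("simulate", "deterministic"),
                                harvest_fraction = 0) {
  method <- match.arg(method)
  v <- model$vital_rates
  cc <- model$recruitment_scalar
  x <- model$extra_mortality
  hf <- harvest_fraction
  if (method == "deterministic") {
    g <- function(m) lambda1(v, x, cc * m) * (1 - hf) - 1
    if (g(1) <= 0) return(0)
    m_star <- stats::uniroot(g, c(1e-12, 1), tol = 1e-12)$root
    Mstar <- build_matrix(v, x, cc * m_star)
    w <- dominant_eigen(Mstar)$w
    A_star <- model$kprime * (1 - m_star)
    return(A_star / sum(class_breeding(v) * w))
  }
  w <- dominant_eigen(build_matrix(v, fecundity_scale = cc))$w
  sim <- simulate_cohorts(v, years = burn_in + window, n_reps = n_reps,
                          init_state = 0.01 * model$kprime * w,
                          extra_mortality = x, fecundity_scale = cc,
                          dd = list(kprime = model$kprime),
                          harvest_fraction = hf, extinction_floor = TRUE,
                          seed = seed)
  mean(sim$totals[burn_in + 1L + seq_len(window), ])
}

#' Response of the growth rate and equilibrium density to a treatment
#'
#' Compares two density-dependent models that share species, `lambda0` and
#' `K'` but differ in extra mortality (or harvest rule) and returns the
#' percentage responses used throughout the density-dependent analysis:
#' `r0` response `100 (r0_t - r0_b) / r0_b` and `N*` response
#' `100 (N*_t - N*_b) / N*_b`, the latter floored at -100 (an extinct
#' treatment reads -100: growth rate 0 or extinct population). `N*` is
#' measured stochastically with common random numbers (same seed both arms);
#' `r0` deterministically by default.
#'
#' @param baseline,treated [dd_model()]s differing only in the treatment.
#' @param n_reps,seed,burn_in,window Passed to [equilibrium_density()].
#' @param nstar_method `"simulate"` (default) or `"deterministic"`.
#' @param harvest_fraction Harvest applied in the treated arm (PBR use).
#' @return A one-row `data.frame` with `r0_response_pct` and
#'   `nstar_response_pct`.
#' @export
response_summary <- function(baseline, treated, n_reps = 200, seed = 1,
                             burn_in = 300, window = 200,
                             nstar_method = c("simulate", "deterministic"),
                             harvest_fraction = 0) {
  nstar_method <- match.arg(nstar_method)
  same <- function(f) identical(f(baseline), f(treated))
  if (!same(function(m) m$vital_rates$species) ||
      !same(function(m) m$lambda0) || !same(function(m) m$kprime))
    stop("baseline and treated must share species, lambda0 and kprime")
  r0_b <- leftover_r0(baseline)
  if (r0_b <= 0)
    stop("baseline r0 <= 0: response percentages are undefined for ",
         "declining populations")
  r0_t <- leftover_r0(treated, harvest_fraction = harvest_fraction)
  n_b <- equilibrium_density(baseline, n_reps, seed, burn_in, window,
                             nstar_method)
  n_t <- equilibrium_density(treated, n_reps, seed, burn_in, window,
                             nstar_method, harvest_fraction = harvest_fraction)
  if (n_b <= 0) stop("baseline equilibrium density is zero")
  data.frame(r0_response_pct = 100 * (r0_t - r0_b) / r0_b,
             nstar_response_pct = max(-100, 100 * (n_t - n_b) / n_b))
}

#' One response-grid cell: extra-mortality response of a fixture
#'
#' Convenience wrapper building the baseline and treated [dd_model()]s for
#' one fixture, one `lambda0` and one extra-mortality fraction and returning
#' their [response_summary()].
#'
#' @param v A [vital_rates()] object.
#' @param lambda0 Target low-density growth rate.
#' @param x Extra-mortality fraction.
#' @param kprime Zero-recruitment adult count.
#' @param ... Passed on to [response_summary()].
#' @return A one-row `data.frame`.
#' @examples
#' \donttest{
#' v <- fixture(packaged_vital_rates(), "starling", "1960")
#' dd_response(v, lambda0 = 1.1, x = 0.10, n_reps = 100)  # N* response -100
#' }
#' @export
dd_response <- function(v, lambda0, x, kprime = 1e4, ...) {
  base <- dd_model(v, lambda0, kprime)
  treat <- dd_model(v, lambda0, kprime, extra_mortality = x)
  response_summary(base, treat, ...)
}
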