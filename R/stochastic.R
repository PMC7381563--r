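# Environmental stochasticity: each simulated year every replicate gets a
# fresh matrix whose survival and fledgling rates are drawn independently
# from normal distributions around the (possibly mortality-transformed)
# means, clipped to their valid ranges. Populations are continuous-valued
# (no demographic stochasticity).

# run RNG-dependent code under a seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    set.seed(seed)
  }
  force(code)
}

#' Projection configuration
#'
#' Settings for a density-independent stochastic projection: horizon,
#' replicate count, seed, initial population (spread over the stable age
#' distribution of the mean matrix) and the extra-mortality scenario.
#' Replicates default to 1e4, a desk-scale stand-in for the full 1e6; the
#' recorded statistic is a ratio of means, so the replicate count only sets
#' Monte-Carlo error.
#'
#' @param years Projection horizon in years (`>= 1`).
#' @param n_reps Number of replicates (`>= 1`).
#' @param seed Integer seed; fixes the whole draw sequence.
#' @param initial_population Total initial individuals.
#' @param extra_mortality Extra-mortality fraction `x >= 0`.
#' @return A list of class `"projection_config"`.
#' @export
projection_config <- function(years = 100, n_reps = 1e4, seed = 1,
                              initial_population = 1000,
                              extra_mortality = 0) {
  stopifnot(years >= 1, n_reps >= 1, initial_population > 0,
            extra_mortality >= 0)
  structure(list(years = as.integer(years), n_reps = as.integer(n_reps),
                 seed = as.integer(seed),
                 initial_population = initial_population,
                 extra_mortality = extra_mortality),
            class = "projection_config")
}

#' Draw a single-year realization of the vital rates
#'
#' Each survival rate is drawn from `Normal(mean, sd)` clipped to `[0, 1]`;
#' the fledgling rate from `Normal(mean, sd)` clipped at 0. Draws are
#' mutually independent, and a rate with `sd = 0` comes back exactly at its
#' mean. Clipping (draw-then-clamp) is the truncation rule used throughout
#' the stochastic simulations.
#'
#' @param v A [vital_rates()] object.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A `"vital_rates"` object whose means are the drawn values and
#'   whose SDs are zeroed (it is a realization, not a distribution).
#' @export
draw_annual_rates <- function(v, seed = NULL) {
  with_seed(seed, {
    s <- pmin(1, pmax(0, stats::rnorm(3, v$survival$mean, v$survival$sd)))
    m <- max(0, stats::rnorm(1, v$fledglings_mean, v$fledglings_sd))
    v$survival$mean <- s
    v$fledglings_mean <- m
    zero_sds(v)
  })
}

# Core projection engine, vectorized across replicates. Each year draws one
# standard-normal deviate per printed rate (first/second/older survival,
# fledglings) per replicate, so two runs from the same seed consume the same
# stream (common random numbers across scenarios).
#
# dd: NULL or list(kprime=, fecundity_scale=) -> recruitment multiplied by
#     max(0, 1 - A/K') with A the breeding-probability-weighted adult count.
# harvest_fraction: constant per-class fraction removed after each
#     transition (PBR harvesting).
# extinction_floor: replicates whose total drops below 1 individual are set
#     to 0 (quasi-extinction; used by the density-dependent runs).
simulate_cohorts <- function(v, years, n_reps, init_state,
                             extra_mortality = 0, fecundity_scale = 1,
                             dd = NULL, harvest_fraction = 0,
                             extinction_floor = FALSE,
                             state_at = integer(0), seed = NULL) {
  vt <- if (extra_mortality > 0) apply_extra_mortality(v, extra_mortality) else v
  n <- n_classes(v)
  lab <- class_survival_label(v)
  mu <- vt$survival$mean
  sd3 <- vt$survival$sd
  msd <- vt$fledglings_sd
  bnext <- breeding_at_age(v, seq_len(n))      # breeding prob at age j+1
  bcls <- class_breeding(v)                    # breeding prob of class j
  half <- 0.5 * fecundity_scale
  N <- matrix(init_state, n, n_reps)
  totals <- matrix(NA_real_, years + 1L, n_reps)
  totals[1L, ] <- colSums(N)
  states <- list()
  with_seed(seed, {
    for (t in seq_len(years)) {
      z <- matrix(stats::rnorm(3L * n_reps), 3L)
      S3 <- pmin(pmax(mu + sd3 * z, 0), 1)     # 3 x reps (recycled by column)
      m <- pmax(v$fledglings_mean + msd * stats::rnorm(n_reps), 0)
      Scls <- S3[lab, , drop = FALSE]          # n x reps
      fec_scale_rep <- if (is.null(dd)) rep(half, n_reps) else {
        A <- colSums(bcls * N)
        half * pmax(0, 1 - A / dd$kprime)
      }
      Fec <- Scls * bnext * rep(m * fec_scale_rep, each = n)
      top <- colSums(Fec * N)
      Nn <- matrix(0, n, n_reps)
      Nn[1L, ] <- top
      if (n > 1L)
        Nn[2:n, ] <- Nn[2:n, ] + Scls[seq_len(n - 1L), , drop = FALSE] *
          N[seq_len(n - 1L), , drop = FALSE]
      Nn[n, ] <- Nn[n, ] + Scls[n, ] * N[n, ]
      if (harvest_fraction > 0) Nn <- Nn * max(0, 1 - harvest_fraction)
      tot <- colSums(Nn)
      if (extinction_floor && any(dead <- tot < 1)) {
        Nn[, dead] <- 0
        tot[dead] <- 0
      }
      N <- Nn
      totals[t + 1L, ] <- tot
      if (t %in% state_at) states[[as.character(t)]] <- N
    }
  })
  list(totals = totals, states = states, final_state = N)
}

#' Project a population with annual environmental stochasticity
#'
#' Runs `cfg$n_reps` independent replicates for `cfg$years` years. Each year
#' the population vector is multiplied by a new Leslie matrix parameterized
#' with rates drawn as in [draw_annual_rates()] from the
#' mortality-transformed means. All replicates start from
#' `cfg$initial_population` individuals spread over the stable age
#' distribution of the mean (baseline) matrix. Given the same seed the whole
#' trajectory set is reproducible bit-for-bit, and runs that differ only in
#' the mortality scenario share their random deviates (common random
#' numbers).
#'
#' @param v A [vital_rates()] object.
#' @param cfg A [projection_config()].
#' @return An object of class `"projection_result"`: list with `totals`
#'   (`(years + 1) x n_reps` matrix of total population size, year 0 first),
#'   `state_year10` (age-structured state at year 10, if the horizon covers
#'   it), `mean_by_year`, and the configuration.
#' @examples
#' v <- fixture(packaged_vital_rates(), "starling", "1990")
#' p <- project(v, projection_config(years = 10, n_reps = 100, seed = 1))
#' p$mean_by_year[11]  # ~1000 * 0.797^10
#' @export
project <- function(v, cfg = projection_config()) {
  validate_vital_rates(v)
  w <- dominant_eigen(build_matrix(v))$w
  sim <- simulate_cohorts(v, years = cfg$years, n_reps = cfg$n_reps,
                          init_state = cfg$initial_population * w,
                          extra_mortality = cfg$extra_mortality,
                          state_at = if (cfg$years >= 10) 10L else integer(0),
                          seed = cfg$seed)
  structure(list(totals = sim$totals,
                 state_year10 = sim$states[["10"]],
                 mean_by_year = rowMeans(sim$totals),
                 config = cfg, vital_rates = v),
            class = "projection_result")
}

#' @export
print.projection_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<projection_result> %s %s: %d reps x %d years, x = %g, seed %d\n",
              x$vital_rates$species, x$vital_rates$period,
              cfg$n_reps, cfg$years, cfg$extra_mortality, cfg$seed))
  cat(sprintf("  mean total: year 0 %.1f -> year %d %.1f\n",
              x$mean_by_year[1], cfg$years, x$mean_by_year[cfg$years + 1]))
  invisible(x)
}

#' Percentage population decline after 10 years
#'
#' `100 * (1 - mean10(treated) / mean10(baseline))`, where `mean10` is the
#' across-replicate mean total population at year 10. Both runs must share
#' the horizon (`>= 10` years) and replicate count; pairing them on the same
#' seed (as [decline_10()] does) variance-reduces the estimate.
#'
#' @param baseline,treated [project()] results.
#' @return Percentage decline (positive = treated below baseline).
#' @export
decline_after_10_years <- function(baseline, treated) {
  if (baseline$config$years < 10 || treated$config$years < 10)
    stop("both projections must cover at least 10 years")
  if (baseline$config$n_reps != treated$config$n_reps)
    stop("projections must share the replicate count")
  m_b <- mean(baseline$totals[11L, ])
  m_t <- mean(treated$totals[11L, ])
  if (m_b <= 0) stop("baseline mean population at year 10 is zero; ",
                     "decline statistic undefined")
  100 * (1 - m_t / m_b)
}

#' One-call decline statistic for an extra-mortality scenario
#'
#' Convenience wrapper: projects the baseline (`x = 0`) and the treated
#' scenario with identical seeds and returns [decline_after_10_years()].
#'
#' @param v A [vital_rates()] object.
#' @param x Extra-mortality fraction.
#' @param cfg A [projection_config()]; its `extra_mortality` field is
#'   overridden by 0 / `x`.
#' @return Percentage decline after 10 years.
#' @export
decline_10 <- function(v, x, cfg = projection_config(years = 10)) {
  cfg$extra_mortality <- 0
  base <- project(v, cfg)
  cfg$extra_mortality <- x
  decline_after_10_years(base, project(v, cfg))
}
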