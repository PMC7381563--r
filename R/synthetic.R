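# Random but valid life histories, so every stage of the pipeline can be
# exercised without the packaged fixtures. The default ranges bracket the
# observed vital rates of the eleven shipped parameter sets.

#' Specification for synthetic life-history generation
#'
#' @param seed Integer seed; generation is deterministic given the spec.
#' @param afr_range Age of first reproduction range (integers, years).
#' @param adult_survival_range Annual adult (after-first-year) survival.
#' @param first_year_survival_range First-year survival.
#' @param fledglings_range Fledglings per breeding pair per year.
#' @param relative_sd_range Between-year SD as a fraction of each mean
#'   (survival SDs may push draws against the `[0, 1]` bounds, which is
#'   intended: it exercises the clipping rule).
#' @param breeding_prob_range Terminal breeding probability.
#' @return A list of class `"synthesis_spec"`.
#' @export
synthesis_spec <- function(seed = 1, afr_range = c(1L, 6L),
                           adult_survival_range = c(0.55, 0.95),
                           first_year_survival_range = c(0.05, 0.75),
                           fledglings_range = c(0.3, 4.5),
                           relative_sd_range = c(0, 0.2),
                           breeding_prob_range = c(0.4, 1.0)) {
  chk <- function(r, lo, hi, what) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < lo || r[2] > hi)
      stop("impossible range for ", what)
  }
  chk(afr_range, 1, 50, "afr")
  chk(adult_survival_range, 0, 1, "adult survival")
  chk(first_year_survival_range, 0, 1, "first-year survival")
  chk(fledglings_range, 0, Inf, "fledglings")
  chk(relative_sd_range, 0, Inf, "relative sd")
  chk(breeding_prob_range, 0, 1, "breeding probability")
  if (breeding_prob_range[2] <= 0)
    stop("impossible range for breeding probability: upper bound must be > 0")
  structure(list(seed = as.integer(seed), afr_range = as.integer(afr_range),
                 adult_survival_range = adult_survival_range,
                 first_year_survival_range = first_year_survival_range,
                 fledglings_range = fledglings_range,
                 relative_sd_range = relative_sd_range,
                 breeding_prob_range = breeding_prob_range),
            class = "synthesis_spec")
}

#' Generate random valid life histories
#'
#' Draws `n` vital-rate sets uniformly from the spec's ranges. Second-year
#' survival is drawn between first-year and adult survival. For
#' `AFR >= 3` a breeding-participation ramp is generated: participation
#' rises linearly over three age steps from 60% of the terminal probability,
#' mirroring the delayed-ramp structure of long-lived colonial breeders.
#' Every record passes [validate_vital_rates()]; with the default ranges a
#' batch of 20 or more spans both growing and declining life histories.
#'
#' @param spec A [synthesis_spec()].
#' @param n Number of records (`>= 1`).
#' @return A [vital_rate_catalog()] with `n` entries.
#' @examples
#' cat5 <- generate_species(synthesis_spec(seed = 42), 5)
#' sapply(cat5, function(v) dominant_eigen(build_matrix(v))$lambda)
#' @export
generate_species <- function(spec, n) {
  stopifnot(inherits(spec, "synthesis_spec"), n >= 1)
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  with_seed(spec$seed, {
    records <- lapply(seq_len(n), function(i) {
      afr <- sample(seq(spec$afr_range[1], spec$afr_range[2]), 1)
      s_ad <- runif2(spec$adult_survival_range)
      s_fy <- runif2(spec$first_year_survival_range)
      s_sy <- stats::runif(1, min(s_fy, s_ad), max(s_fy, s_ad))
      m <- runif2(spec$fledglings_range)
      rsd <- function(mean) runif2(spec$relative_sd_range) * mean
      b_end <- runif2(spec$breeding_prob_range)
      if (afr >= 3) {
        ramp <- b_end * seq(0.6, 1, length.out = 3)
        b <- c(rep(0, afr - 1), ramp)
      } else {
        b <- c(rep(0, afr - 1), b_end)
      }
      vital_rates(species = sprintf("Synthetic %03d", i),
                  population = "synthetic", period = sprintf("seed%d", spec$seed),
                  afr = afr, fledglings_mean = m, fledglings_sd = rsd(m),
                  survival = data.frame(
                    age_class = c("first", "second", "older"),
                    mean = c(s_fy, s_sy, s_ad),
                    sd = c(rsd(s_fy), rsd(s_sy), rsd(s_ad))),
                  breeding_prob = b)
    })
    vital_rate_catalog(records)
  })
}
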