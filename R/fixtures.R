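# The eleven species-population-period vital-rate sets used throughout.
# Values are the printed means and between-year SDs; where a breeding-
# participation ramp is printed only as a range, intermediate ages are filled
# by linear interpolation (Spoonbill: 0.63 at age 4 to 0.95 at age 6+;
# White Stork: 0.475 at age 3 to 1.0 at age 6+). White-tailed Eagle survival
# is printed without SDs; those are stored as 0 and the rates treated as
# constants.
.packaged_rows <- list(
  list("Common Starling", "The Netherlands", "1960-1978", 1L,
       2.56, 0, c(0.331, 0.677, 0.677), c(0.035, 0.049, 0.049), 1),
  list("Common Starling", "The Netherlands", "1978-1990", 1L,
       4.17, 0.238, c(0.181, 0.615, 0.615), c(0.051, 0.039, 0.039), 1),
  list("Common Starling", "The Netherlands", "1990-2012", 1L,
       3.73, 0.546, c(0.102, 0.607, 0.607), c(0.034, 0.151, 0.151), 1),
  list("Black-tailed Godwit", "Kuststrook", "2011-2016", 2L,
       1.800, 0.618, c(0.169, 0.858, 0.858), c(0.074, 0.007, 0.007), c(0, 1)),
  list("Black-tailed Godwit", "Skriezekrite", "2012-2016", 2L,
       2.461, 0.787, c(0.169, 0.859, 0.859), c(0.113, 0.007, 0.007), c(0, 1)),
  list("Marsh Harrier", "The Netherlands", "1997-2015", 3L,
       2.124, 0.409, c(0.641, 0.804, 0.804), c(0.093, 0.063, 0.063),
       c(0, 0, 0.5)),
  list("Spoonbill", "The Netherlands", "1994-2008", 3L,
       1.859, 0.696, c(0.607, 0.893, 0.877), c(0.126, 0.026, 0.010),
       c(0, 0, 0, 0.63, 0.79, 0.95)),
  list("White Stork", "Switzerland", "1977-2000", 3L,
       1.560, 0.463, c(0.390, 0.861, 0.861), c(0.096, 0.047, 0.047),
       c(0, 0, 0.475, 0.65, 0.825, 1.0)),
  list("Common Tern", "IJsselmeer", "1994-2008", 4L,
       1.294, 1.024, c(0.555, 0.588, 0.724), c(0.186, 0.208, 0.131),
       c(0, 0, 0, 1)),
  list("White-tailed Eagle", "Schleswig-Holstein", "1947-1974", 5L,
       0.454, 0.278, c(0.720, 0.889, 0.816), c(0, 0, 0),
       c(0, 0, 0, 0, 0.954)),
  list("White-tailed Eagle", "Schleswig-Holstein", "1975-2008", 5L,
       1.573, 0.387, c(0.741, 0.800, 0.813), c(0, 0, 0),
       c(0, 0, 0, 0, 0.954))
)

#' The packaged catalog of eleven bird vital-rate sets
#'
#' Returns the eleven species-population-period parameter sets (three Common
#' Starling periods, two Black-tailed Godwit populations, Marsh Harrier,
#' Spoonbill, White Stork, Common Tern, and two White-tailed Eagle periods)
#' as a validated [vital_rate_catalog()]. The same data ship as a plain CSV
#' under `inst/extdata/vital_rates.csv` in the [read_vital_rates()] schema.
#'
#' @return A [vital_rate_catalog()] with 11 entries.
#' @examples
#' cat11 <- packaged_vital_rates()
#' sapply(cat11, function(v) dominant_eigen(build_matrix(v))$lambda)
#' @export
packaged_vital_rates <- function() {
  vital_rate_catalog(lapply(.packaged_rows, function(r)
    vital_rates(species = r[[1]], population = r[[2]], period = r[[3]],
                afr = r[[4]], fledglings_mean = r[[5]], fledglings_sd = r[[6]],
                survival = data.frame(age_class = c("first", "second", "older"),
                                      mean = r[[7]], sd = r[[8]]),
                breeding_prob = r[[9]])))
}
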