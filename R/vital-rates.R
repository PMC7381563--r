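#' Construct a vital-rate set
#'
#' A vital-rate set bundles everything needed to parameterize a female-based,
#' postbreeding-census Leslie matrix for one bird population over one period:
#' age of first reproduction (AFR), fledglings produced per breeding pair per
#' year (mean and between-year SD), age-class survival rates (first-year,
#' second-year, older birds; each with a between-year SD), and the
#' age-specific probability that an adult actually breeds.
#'
#' The number of age classes in the matrix is implied by the breeding
#' schedule: `length(breeding_prob) + 1`. Classes are ages `0, 1, ...,
#' n_classes - 1`, with the last class a terminal "and older" class that
#' self-loops on adult survival. `breeding_prob[a]` is the probability that a
#' bird of age `a` breeds; the last element applies to all older ages.
#'
#' @param species Species name (e.g. `"Common Starling"`).
#' @param population Population / region label.
#' @param period Period label, e.g. `"1960-1978"`.
#' @param afr Age of first reproduction in years (integer `>= 1`).
#' @param fledglings_mean Mean fledglings per breeding pair per year (`>= 0`).
#' @param fledglings_sd Between-year SD of the fledgling rate (`>= 0`).
#' @param survival A `data.frame` with columns `age_class`
#'   (`"first"`, `"second"`, `"older"`), `mean` (in `[0, 1]`) and `sd`
#'   (`>= 0`), one row per age-class label, in that order.
#' @param breeding_prob Numeric vector of breeding probabilities for ages
#'   `1, 2, ..., n_classes - 1`; the final element covers all older ages.
#'   Must be 0 below `afr`.
#'
#' @return An object of class `"vital_rates"`.
#' @seealso [build_matrix()], [read_vital_rates()], [packaged_vital_rates()]
#' @examples
#' starling <- vital_rates(
#'   species = "Common Starling", population = "The Netherlands",
#'   period = "1960-1978", afr = 1,
#'   fledglings_mean = 2.56, fledglings_sd = 0,
#'   survival = data.frame(age_class = c("first", "second", "older"),
#'                         mean = c(0.331, 0.677, 0.677),
#'                         sd = c(0.035, 0.049, 0.049)),
#'   breeding_prob = 1)
#' dominant_eigen(build_matrix(starling))$lambda
#' @export
vital_rates <- function(species, population = "", period = "",
                        afr, fledglings_mean, fledglings_sd = 0,
                        survival, breeding_prob) {
  v <- structure(list(
    species = as.character(species),
    population = as.character(population),
    period = as.character(period),
    afr = as.integer(afr),
    fledglings_mean = as.numeric(fledglings_mean),
    fledglings_sd = as.numeric(fledglings_sd),
    survival = data.frame(age_class = as.character(survival$age_class),
                          mean = as.numeric(survival$mean),
                          sd = as.numeric(survival$sd),
                          stringsAsFactors = FALSE),
    breeding_prob = as.numeric(breeding_prob)
  ), class = "vital_rates")
  validate_vital_rates(v)
  v
}

#' Validate a vital-rate set
#'
#' Checks the domain invariants: survival means in `[0, 1]`, SDs `>= 0`,
#' non-negative fecundity, `afr >= 1`, breeding probability 0 below AFR and
#' positive for the terminal class, and at least `afr + 1` age classes.
#'
#' @param v A `"vital_rates"` object (or bare list with the same fields).
#' @return `v`, invisibly, if valid; otherwise an error naming the offending
#'   field.
#' @export
validate_vital_rates <- function(v) {
  fail <- function(field, msg)
    stop(sprintf("invalid vital rates [%s %s %s]: field '%s' %s",
                 v$species, v$population, v$period, field, msg), call. = FALSE)
  if (!is.finite(v$afr) || v$afr < 1) fail("afr", "must be an integer >= 1")
  if (!is.finite(v$fledglings_mean) || v$fledglings_mean < 0)
    fail("fledglings_mean", "must be >= 0")
  if (!is.finite(v$fledglings_sd) || v$fledglings_sd < 0)
    fail("fledglings_sd", "must be >= 0")
  if (!identical(v$survival$age_class, c("first", "second", "older")))
    fail("survival", "must have rows 'first', 'second', 'older' in order")
  if (any(!is.finite(v$survival$mean)) ||
      any(v$survival$mean < 0) || any(v$survival$mean > 1))
    fail("survival$mean", "must lie in [0, 1]")
  if (any(!is.finite(v$survival$sd)) || any(v$survival$sd < 0))
    fail("survival$sd", "must be >= 0")
  b <- v$breeding_prob
  n <- length(b) + 1L
  if (n < v$afr + 1L)
    fail("breeding_prob", sprintf(
      "implies %d age classes; need at least afr + 1 = %d", n, v$afr + 1L))
  if (any(!is.finite(b)) || any(b < 0) || any(b > 1))
    fail("breeding_prob", "must lie in [0, 1]")
  if (v$afr > 1 && any(b[seq_len(v$afr - 1L)] != 0))
    fail("breeding_prob", "must be 0 for ages below afr")
  # intermediate ages at/above AFR may still sit at 0 (delayed ramps, e.g.
  # colonial breeders whose participation starts after the printed AFR), but
  # the terminal class must actually breed
  if (b[length(b)] <= 0)
    fail("breeding_prob", "must be positive for the terminal age class")
  invisible(v)
}

#' @export
print.vital_rates <- function(x, ...) {
  cat(sprintf("<vital_rates> %s | %s | %s\n", x$species, x$population, x$period))
  cat(sprintf("  AFR %d, %d age classes; fledglings/pair %.3f +- %.3f\n",
              x$afr, n_classes(x), x$fledglings_mean, x$fledglings_sd))
  s <- x$survival
  cat(sprintf("  survival  first %.3f+-%.3f  second %.3f+-%.3f  older %.3f+-%.3f\n",
              s$mean[1], s$sd[1], s$mean[2], s$sd[2], s$mean[3], s$sd[3]))
  cat("  breeding prob by age: ", paste(format(x$breeding_prob), collapse = ", "),
      " (last = older)\n", sep = "")
  invisible(x)
}

#' Number of age classes of the projection matrix
#' @param v A `"vital_rates"` object.
#' @return Integer number of classes (ages `0 ... n - 1`, last terminal).
#' @export
n_classes <- function(v) length(v$breeding_prob) + 1L

# survival label index per class: 1 = first-year, 2 = second-year, 3 = older.
# The terminal class always carries older-bird survival (for a 2-class model
# the printed second-year and older-bird values coincide).
class_survival_label <- function(v) {
  n <- n_classes(v)
  vapply(seq_len(n) - 1L, function(j) {
    if (j == 0L) 1L else if (j == 1L && j < n - 1L) 2L else 3L
  }, integer(1))
}

# survival mean per class, given the three (possibly transformed) label means
class_survival <- function(v, means = v$survival$mean) {
  means[class_survival_label(v)]
}

# breeding probability at a given age (vectorized); last entry covers older
breeding_at_age <- function(v, age) {
  b <- v$breeding_prob
  ifelse(age < 1, 0, b[pmin(age, length(b))])
}

# breeding probability of each class (class j has age j; terminal j = n-1+)
class_breeding <- function(v) breeding_at_age(v, seq_len(n_classes(v)) - 1L)

# stable identifier used as catalog key
vr_id <- function(v) {
  slug <- function(s) gsub("_+", "_", gsub("[^a-z0-9]+", "_", tolower(s)))
  paste(slug(v$species), slug(v$population), slug(v$period), sep = ".")
}

#' Bundle vital-rate sets into a catalog
#'
#' A catalog is a named list of [vital_rates()] records keyed by
#' `species.population.period` slugs; keys must be unique.
#'
#' @param records List of `"vital_rates"` objects.
#' @return An object of class `"vital_rate_catalog"`.
#' @export
vital_rate_catalog <- function(records = list()) {
  stopifnot(all(vapply(records, inherits, logical(1), "vital_rates")))
  ids <- vapply(records, vr_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate catalog keys: ", paste(ids[duplicated(ids)], collapse = ", "))
  names(records) <- ids
  structure(records, class = "vital_rate_catalog")
}

#' @export
print.vital_rate_catalog <- function(x, ...) {
  cat(sprintf("<vital_rate_catalog> %d record(s)\n", length(x)))
  for (id in names(x)) cat("  ", id, "\n", sep = "")
  invisible(x)
}

#' Look up one record in a catalog by partial key
#'
#' @param catalog A [vital_rate_catalog()].
#' @param ... Character snippets that must all match the key
#'   (case-insensitive), e.g. `fixture(cat, "starling", "1960")`.
#' @return The matching `"vital_rates"` record; error if the snippets match
#'   no record or more than one.
#' @export
fixture <- function(catalog, ...) {
  pats <- tolower(unlist(list(...)))
  keys <- names(catalog)
  hit <- keys
  for (p in pats) hit <- hit[grepl(p, tolower(hit), fixed = TRUE)]
  if (length(hit) == 0L)
    stop("no catalog entry matches: ", paste(pats, collapse = " + "))
  if (length(hit) > 1L)
    stop("ambiguous catalog lookup (", paste(pats, collapse = " + "),
         ") matches: ", paste(hit, collapse = ", "))
  catalog[[hit]]
}

csv_columns <- c("species", "population", "period", "afr",
                 "fledglings_mean", "fledglings_sd",
                 "param_kind", "age_class", "mean", "sd")

#' Read vital-rate sets from CSV
#'
#' Reads the package's long ("tidy") CSV schema: one row per parameter, with
#' columns `species, population, period, afr, fledglings_mean, fledglings_sd,
#' param_kind, age_class, mean, sd`. `param_kind` is `"survival"`
#' (`age_class` one of `first`/`second`/`older`) or `"breeding_prob"`
#' (`age_class` the age in years; the highest age doubles as "and older").
#' Comment lines starting with `#` are ignored.
#'
#' @param path Path to a CSV file.
#' @return A [vital_rate_catalog()]; every record is validated.
#' @examples
#' cat11 <- read_vital_rates(system.file("extdata", "vital_rates.csv",
#'                                       package = "birdpva"))
#' length(cat11)
#' @export
read_vital_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!identical(names(d), csv_columns))
    stop("malformed vital-rates file: header must be ",
         paste(csv_columns, collapse = ","))
  if (nrow(d) == 0L) return(vital_rate_catalog())
  key <- paste(d$species, d$population, d$period, sep = "\r")
  records <- lapply(split(d, factor(key, levels = unique(key))), function(g) {
    surv <- g[g$param_kind == "survival", ]
    bp <- g[g$param_kind == "breeding_prob", ]
    where <- sprintf("%s %s %s", g$species[1], g$population[1], g$period[1])
    if (nrow(surv) != 3L)
      stop("malformed rows for ", where, ": need 3 survival rows", call. = FALSE)
    if (nrow(bp) < 1L)
      stop("malformed rows for ", where, ": need breeding_prob rows", call. = FALSE)
    bp <- bp[order(as.integer(bp$age_class)), ]
    if (!identical(as.integer(bp$age_class), seq_len(nrow(bp))))
      stop("malformed rows for ", where,
           ": breeding_prob ages must be 1..n", call. = FALSE)
    ord <- match(c("first", "second", "older"), surv$age_class)
    if (anyNA(ord))
      stop("malformed rows for ", where,
           ": survival age_class must be first/second/older", call. = FALSE)
    vital_rates(species = g$species[1], population = g$population[1],
                period = g$period[1], afr = g$afr[1],
                fledglings_mean = g$fledglings_mean[1],
                fledglings_sd = g$fledglings_sd[1],
                survival = surv[ord, c("age_class", "mean", "sd")],
                breeding_prob = bp$mean)
  })
  names(records) <- NULL
  vital_rate_catalog(records)
}

#' Write vital-rate sets to CSV
#'
#' Inverse of [read_vital_rates()]: `read_vital_rates(write_vital_rates(c))`
#' reproduces the catalog field-for-field.
#'
#' @param catalog A [vital_rate_catalog()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vital_rates <- function(catalog, path) {
  rows <- lapply(catalog, function(v) {
    head <- data.frame(species = v$species, population = v$population,
                       period = v$period, afr = v$afr,
                       fledglings_mean = v$fledglings_mean,
                       fledglings_sd = v$fledglings_sd,
                       stringsAsFactors = FALSE)
    surv <- cbind(head[rep(1, 3), ], param_kind = "survival",
                  age_class = v$survival$age_class,
                  mean = v$survival$mean, sd = v$survival$sd)
    nb <- length(v$breeding_prob)
    bp <- cbind(head[rep(1, nb), ], param_kind = "breeding_prob",
                age_class = as.character(seq_len(nb)),
                mean = v$breeding_prob, sd = 0)
    rbind(surv, bp)
  })
  d <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else
    stats::setNames(data.frame(matrix(ncol = length(csv_columns), nrow = 0)),
                    csv_columns)
  utils::write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# vital rates with all SDs set to zero (deterministic limit)
zero_sds <- function(v) {
  v$fledglings_sd <- 0
  v$survival$sd <- c(0, 0, 0)
  v
}
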