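#' Build a postbreeding-census Leslie matrix
#'
#' Constructs the female-based projection matrix implied by a vital-rate set.
#' With a census taken right after breeding, the first class holds birds aged
#' 0, and the fecundity of class `j` is `S_j * b(j + 1) * m / 2`: a female
#' must survive its class-specific rate `S_j` to reach age `j + 1`, breeds
#' there with probability `b(j + 1)`, and a breeding pair produces `m`
#' fledglings of which half are assumed female. Survival rates occupy the
#' subdiagonal and the terminal "and older" class self-loops on adult
#' survival.
#'
#' @param v A [vital_rates()] object.
#' @param extra_mortality Additional mortality fraction `x >= 0`; survival
#'   rates are transformed as in [apply_extra_mortality()] before the matrix
#'   is assembled.
#' @param fecundity_scale Scalar multiplier on the whole fecundity row (the
#'   recruitment calibration scalar of the density-dependent models; see
#'   [calibrate_recruitment()]).
#' @return A non-negative square matrix of class `"leslie_matrix"` with the
#'   source rates attached as attribute `"vital_rates"`.
#' @examples
#' M <- build_matrix(fixture(packaged_vital_rates(), "starling", "1960"))
#' M
#' dominant_eigen(M)$lambda
#' @export
build_matrix <- function(v, extra_mortality = 0, fecundity_scale = 1) {
  validate_vital_rates(v)
  if (extra_mortality > 0) v <- apply_extra_mortality(v, extra_mortality)
  n <- n_classes(v)
  S <- class_survival(v)
  M <- matrix(0, n, n)
  M[1, ] <- S * breeding_at_age(v, seq_len(n)) * v$fledglings_mean / 2 *
    fecundity_scale
  if (n > 1)
    M[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- S[seq_len(n - 1)]
  M[n, n] <- M[n, n] + S[n]
  structure(M, class = c("leslie_matrix", "matrix", "array"),
            vital_rates = v)
}

#' @export
print.leslie_matrix <- function(x, digits = 4, ...) {
  v <- attr(x, "vital_rates")
  cat(sprintf("<leslie_matrix> %dx%d (%s, %s)\n", nrow(x), ncol(x),
              v$species, v$period))
  print(round(unclass(x)[, , drop = FALSE], digits))
  invisible(x)
}

#' Dominant eigenvalue and stable age distribution
#'
#' The dominant eigenvalue of a non-negative Leslie matrix is its spectral
#' radius (real and positive by Perron-Frobenius) and equals the annual
#' multiplicative growth rate `lambda`; the associated right eigenvector,
#' normalized to sum to one, is the stable age distribution.
#'
#' @param M A square non-negative matrix (e.g. from [build_matrix()]).
#' @return A list with `lambda` (numeric scalar) and `w` (non-negative
#'   numeric vector summing to 1).
#' @export
dominant_eigen <- function(M) {
  e <- eigen(unclass(M))
  i <- which.max(Re(e$values))
  w <- abs(Re(e$vectors[, i]))
  list(lambda = Re(e$values[i]), w = w / sum(w))
}

# growth rate of the matrix built from v (internal shorthand)
lambda1 <- function(v, extra_mortality = 0, fecundity_scale = 1) {
  dominant_eigen(build_matrix(v, extra_mortality, fecundity_scale))$lambda
}

#' Elasticity of the growth rate to adult survival
#'
#' Proportional change in `lambda` per proportional change in adult survival,
#' treating survival as a lower-level parameter that appears in several
#' matrix entries at once (subdiagonal, terminal self-loop, and every
#' fecundity term built from an adult survival rate). By default all
#' after-first-year survival rates are perturbed together (`which =
#' "adult"`), which reproduces the printed per-population elasticities;
#' `which = "older"` perturbs only the older-bird rate.
#'
#' Computed two ways that must agree: the eigenvector sensitivity formula
#' (`method = "eigen"`, the default; sums the entry elasticities
#' `v_i w_j a_ij / (lambda v'w)` over the entries proportional to the
#' perturbed rates) and a central finite difference on a shared multiplier
#' (`method = "fd"`, relative step 1e-6).
#'
#' @param M Leslie matrix built from `v` (optional; rebuilt if `NULL`).
#' @param v The [vital_rates()] the matrix was built from. Defaults to the
#'   rates attached to `M`.
#' @param which `"adult"` (all survival after the first year) or `"older"`
#'   (older-bird survival only).
#' @param method `"eigen"` or `"fd"`.
#' @return Elasticity in `[0, 1]`.
#' @examples
#' v <- fixture(packaged_vital_rates(), "starling", "1960")
#' adult_survival_elasticity(v = v)  # ~0.616
#' @export
adult_survival_elasticity <- function(M = NULL, v = NULL,
                                      which = c("adult", "older"),
                                      method = c("eigen", "fd")) {
  which <- match.arg(which)
  method <- match.arg(method)
  if (is.null(v)) v <- attr(M, "vital_rates")
  if (is.null(M)) M <- build_matrix(v)
  labels <- if (which == "adult") c(2L, 3L) else 3L
  hit <- class_survival_label(v) %in% labels   # classes whose S is perturbed
  if (method == "fd") {
    h <- 1e-6
    bump <- function(f) {
      vv <- v
      vv$survival$mean[labels] <- vv$survival$mean[labels] * f
      lambda1(vv)
    }
    lam <- lambda1(v)
    return((bump(1 + h) - bump(1 - h)) / (2 * h) / lam)
  }
  e <- eigen(unclass(M))
  i <- which.max(Re(e$values))
  lam <- Re(e$values[i])
  w <- abs(Re(e$vectors[, i]))
  vl <- abs(Re(eigen(t(unclass(M)))$vectors[, which.max(Re(eigen(t(unclass(M)))$values))]))
  sens <- outer(vl, w) / sum(vl * w)           # d lambda / d a_ij
  elas <- sens * unclass(M) / lam              # entry elasticities
  n <- n_classes(v)
  mask <- matrix(FALSE, n, n)
  mask[1, ] <- hit                             # fecundity terms carry S_j
  if (n > 1)
    mask[cbind(seq_len(n - 1) + 1L, seq_len(n - 1))] <- hit[seq_len(n - 1)]
  mask[n, n] <- mask[n, n] || hit[n]           # terminal self-loop
  sum(elas[mask])
}

#' Apply proportional extra mortality to a vital-rate set
#'
#' Scales every age class's annual mortality by `1 + x` (so mortality `m`
#' goes to `1.01 m` for `x = 0.01`): each survival mean `s` becomes
#' `1 - (1 - s) (1 + x)`, floored at 0. SDs, fecundity and breeding
#' probabilities are unchanged; the transform acts on the means before any
#' stochastic draw.
#'
#' @param v A [vital_rates()] object.
#' @param x Extra-mortality fraction `>= 0`.
#' @return The transformed `"vital_rates"` object.
#' @examples
#' v <- apply_extra_mortality(fixture(packaged_vital_rates(), "starling", "1960"), 0.10)
#' v$survival$mean  # 0.677 -> 0.6447
#' @export
apply_extra_mortality <- function(v, x) {
  if (!is.finite(x) || x < 0) stop("extra mortality x must be >= 0")
  v$survival$mean <- pmax(0, 1 - (1 - v$survival$mean) * (1 + x))
  v
}
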