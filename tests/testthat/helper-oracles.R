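# Shared fixtures and independent closed-form oracles.

CAT11 <- packaged_vital_rates()
STARLING60 <- fixture(CAT11, "starling", "1960")
STARLING78 <- fixture(CAT11, "starling", "1978_1990")
STARLING90 <- fixture(CAT11, "starling", "1990_2012")
GODWIT_K <- fixture(CAT11, "kuststrook")

# tiny two-class life history for unit tests
toy_rates <- function(s0 = 0.3, s_ad = 0.7, m = 2, sd0 = 0, sd_ad = 0,
                      msd = 0, b = 1, afr = 1) {
  vital_rates(species = "Toy", population = "test", period = "t",
              afr = afr, fledglings_mean = m, fledglings_sd = msd,
              survival = data.frame(age_class = c("first", "second", "older"),
                                    mean = c(s0, s_ad, s_ad),
                                    sd = c(sd0, sd_ad, sd_ad)),
              breeding_prob = c(rep(0, afr - 1), b))
}

# AFR-1 closed form: the 2x2 matrix [[c*b*m/2*S0, c*b*m/2*S1], [S0, S1]] is
# rank one plus the survival row, with dominant eigenvalue S1 + c*b*m/2*S0
afr1_lambda <- function(v, x = 0, fec_scale = 1) {
  s <- pmax(0, 1 - (1 - v$survival$mean) * (1 + x))
  s[3] + fec_scale * v$breeding_prob[1] * v$fledglings_mean / 2 * s[1]
}

# AFR-2 (three-class, equal adult survival) closed form: the characteristic
# polynomial reduces exactly to lambda^2 = s*lambda + F*S0 with
# F = s*b*m/2 the (calibratable) fecundity
afr2_lambda <- function(v, x = 0, fec_scale = 1) {
  s0 <- max(0, 1 - (1 - v$survival$mean[1]) * (1 + x))
  s <- max(0, 1 - (1 - v$survival$mean[3]) * (1 + x))
  FF <- fec_scale * s * v$breeding_prob[2] * v$fledglings_mean / 2
  (s + sqrt(s^2 + 4 * FF * s0)) / 2
}

# mean of a normal draw clamped to [lo, hi]
clipped_normal_mean <- function(mu, sigma, lo = 0, hi = 1) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  lo * pnorm(a) + hi * (1 - pnorm(b)) +
    mu * (pnorm(b) - pnorm(a)) - sigma * (dnorm(b) - dnorm(a))
}

# brute-force dominant root of the characteristic polynomial
charpoly_lambda <- function(M) {
  r <- polyroot(rev(charpoly_coefs(M)))
  max(Re(r[abs(Im(r)) < 1e-8]))
}
charpoly_coefs <- function(M) {
  # coefficients of det(lambda I - M) via Faddeev-LeVerrier
  n <- nrow(M)
  cs <- numeric(n + 1)
  cs[1] <- 1
  Mk <- diag(n)
  for (k in 1:n) {
    Mk <- unclass(M) %*% Mk
    cs[k + 1] <- -sum(diag(Mk)) / k
    if (k < n) Mk <- Mk + diag(cs[k + 1], n)
  }
  cs
}

# deterministic-limit copy of a vital-rate set
zero_sds_local <- function(v) {
  v$survival$sd <- c(0, 0, 0)
  v$fledglings_sd <- 0
  v
}
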