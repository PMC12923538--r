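# Independent oracles used to check the package's implementations.

# Definitional Benjamini-Hochberg step-up: sort p ascending, q_i = p_i * n/i,
# enforce monotonicity from the largest down, cap at 1, restore order.
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) q[i] <- min(q[i], q[i + 1])
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

# Brute-force two-way ANOVA mean squares and ICC(2,1) from first principles.
iccOracle <- function(m) {
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  ssr <- 0; ssc <- 0; sst <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - grand)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - grand)^2
  for (i in seq_len(n)) for (j in seq_len(k)) sst <- sst + (m[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse,
       icc = (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n))
}

# Single-level Gamma log-link GLM by hand-rolled IRLS (unit working weights
# under the log link for the Gamma family).
irlsGammaOracle <- function(X, y, tol = 1e-12, maxit = 200) {
  beta <- numeric(ncol(X))
  beta[1] <- log(mean(y))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    betaNew <- drop(solve(crossprod(X), crossprod(X, z)))
    if (max(abs(betaNew - beta)) < tol) return(betaNew)
    beta <- betaNew
  }
  beta
}

# Dense zero-padded FFT single-bin power at f0, normalized to A^2/2 for a
# pure sinusoid of amplitude A: requires f0 to fall exactly on a bin of the
# padded grid.
fftPowerOracle <- function(x, fs, f0, nfft = 2^16) {
  x <- x - mean(x)
  k <- f0 * nfft / fs
  stopifnot(abs(k - round(k)) < 1e-9)
  X <- stats::fft(c(x, rep(0, nfft - length(x))))
  (2 / length(x)^2) * Mod(X[round(k) + 1L])^2
}

# High-resolution trapezoid quadrature of a rate function (bpm) -> expected
# beat count over [t0, t1].
beatCountOracle <- function(rateFun, t0, t1, fsFine = 1000) {
  t <- seq(t0, t1, by = 1 / fsFine)
  r <- rateFun(t) / 60
  floor(sum((r[-1] + r[-length(r)]) / 2 * diff(t)))
}

# Closed-form Johnson-Neyman boundaries for slope(m) = b1 + b3 m with
# Var = v11 + m^2 v33 + 2 m v13: solve (b1 + b3 m)^2 = c^2 Var(m).
jnQuadOracle <- function(b1, b3, v11, v33, v13, crit) {
  A <- b3^2 - crit^2 * v33
  B <- 2 * (b1 * b3 - crit^2 * v13)
  C <- b1^2 - crit^2 * v11
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
}
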