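# Internal helpers shared across modules.

# Run code under a local RNG state; restores .Random.seed afterwards so
# library code never perturbs the caller's stream.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic child seed from a root seed and a stream index; stays
# inside the 32-bit integer range set.seed() accepts.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807 + 11) %%
               2147483647)
}

# von Mises sampler (Best & Fisher 1979 wrapped-Cauchy rejection).
# kappa = 0 is uniform on (-pi, pi]; kappa = Inf is a point mass at mu.
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (n == 0) return(numeric(0))
  if (!is.finite(kappa)) return(rep(mu, n))
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(m)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    nf <- sum(ok)
    if (nf > 0) {
      u3 <- stats::runif(nf)
      out[(got + 1):(got + nf)] <- sign(u3 - 0.5) * acos(f[ok])
      got <- got + nf
    }
  }
  th <- out + mu
  ((th + pi) %% (2 * pi)) - pi
}

# 1/f-shaped Gaussian noise via FFT spectral shaping, unit variance.
pink_noise <- function(n) {
  white <- stats::rnorm(n)
  X <- stats::fft(white)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)            # symmetric frequency index
  X <- X / sqrt(f)
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Euclidean norm
l2 <- function(x) sqrt(sum(x^2))
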