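#' @useDynLib phondecode, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd var cor qt pt t.test wilcox.test lm residuals coef
#' @importFrom utils head tail
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All randomised operations in the
# package go through this so that a stored seed fully determines the draws.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    had <- exists(".Random.seed", envir = env, inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = env)
    on.exit({
      if (had) assign(".Random.seed", old, envir = env)
      else if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic stream splitting: derive an independent sub-seed from a
# master seed and an index, staying inside the 32-bit integer range.
sub_seed <- function(seed, i) {
  s <- (as.numeric(seed) * 48271 + as.numeric(i) * 16807 + 12345) %% 2147483647
  as.integer(s)
}

# 1/f ("pink") noise with unit variance, generated by shaping white
# Gaussian noise in the frequency domain with amplitude 1/sqrt(f).
pink_noise <- function(n) {
  if (n < 2L) return(stats::rnorm(n))
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1))            # guard DC
  f <- pmin(f, n - f + 1)              # mirror for negative frequencies
  shaped <- spec / sqrt(f)
  x <- Re(stats::fft(shaped, inverse = TRUE)) / n
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s > 0) x <- x / s
  x
}

# Analytic signal via FFT (Hilbert transform helper).
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# FFT-based linear convolution, truncated to the length of x ("full" head).
fft_conv <- function(x, kernel) {
  n <- length(x) + length(kernel) - 1L
  nfft <- stats::nextn(n, 2)
  y <- Re(stats::fft(stats::fft(c(x, rep(0, nfft - length(x)))) *
                     stats::fft(c(kernel, rep(0, nfft - length(kernel)))),
                     inverse = TRUE)) / nfft
  y[seq_along(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
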