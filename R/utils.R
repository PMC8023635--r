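`%||%` <- function(a, b) if (is.null(a)) b else a

#' Trapezoidal integration on an irregular grid
#' @noRd
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Analytic signal via FFT (Hilbert transform)
#'
#' Returns the complex analytic signal of a real vector: positive
#' frequencies doubled, negative zeroed, DC/Nyquist untouched.
#' @noRd
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

stop_eegprog <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "eegprog_error")))
}

#' Draw sub-seeds from one master seed
#'
#' Keeps every derived seed a valid 32-bit integer.
#' @noRd
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Evaluate an expression with a local RNG state
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}
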