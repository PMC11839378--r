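# Internal helpers shared across modules.

bp_stop <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(class, "bp_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(fmt, ...) bp_stop("bp_validation_error", fmt, ...)
stop_schema <- function(fmt, ...) bp_stop("bp_schema_error", fmt, ...)
stop_contract <- function(fmt, ...) bp_stop("bp_contract_error", fmt, ...)
stop_io <- function(fmt, ...) bp_stop("bp_io_error", fmt, ...)

# Round half away from zero (base round() is round-half-even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# 1-based index of the "center" sample along an axis of length n,
# defined as floor(n / 2) in 0-based terms.
center_index <- function(n) floor(n / 2) + 1L

#' Analytic signal of a real vector
#'
#' Frequency-domain construction: zero the negative frequencies and double
#' the positive ones, keeping DC (and Nyquist for even lengths) unchanged.
#' The real part of the result equals the input; the magnitude is the
#' envelope.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @keywords internal
#' @noRd
analytic_signal <- function(x) {
  n <- length(x)
  if (n == 1L) return(as.complex(x))
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

# Valid-mode 2D convolution with a small kernel: output has dimensions
# (nrow(x) - nrow(k) + 1, ncol(x) - ncol(k) + 1); every output pixel sees a
# fully contained window. Implemented as a shift-and-add loop over kernel
# taps, which is fast for the 11x11 kernels used here.
conv2_valid <- function(x, k) {
  kr <- nrow(k); kc <- ncol(k)
  nr <- nrow(x) - kr + 1L
  nc <- ncol(x) - kc + 1L
  if (nr < 1L || nc < 1L) {
    stop_validation("window (%dx%d) larger than image (%dx%d)",
                    kr, kc, nrow(x), ncol(x))
  }
  out <- matrix(0, nr, nc)
  for (i in seq_len(kr)) {
    for (j in seq_len(kc)) {
      out <- out + k[i, j] * x[i:(i + nr - 1L), j:(j + nc - 1L), drop = FALSE]
    }
  }
  out
}

# Normalized 2D Gaussian kernel, size x size, standard deviation sigma
# (in pixels), centered.
gaussian_kernel2 <- function(size, sigma) {
  if (size %% 2 == 0) stop_validation("window size must be odd, got %d", size)
  r <- (size - 1) / 2
  g <- exp(-((-r:r)^2) / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
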