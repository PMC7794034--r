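# Shared numeric helpers: z-scores, block means, circular statistics.

#' Z-scores with a zero-variance convention
#'
#' Standardizes `x` by its mean and standard deviation. A degenerate input
#' (zero or undefined SD) returns all-zero scores so that constant channels
#' reject nothing under threshold rules.
#'
#' @param x Numeric vector; `NA`s are ignored for the moments and propagate
#'   through the result.
#' @return Numeric vector of z-scores, same length as `x`.
#' @export
zscore <- function(x) {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    z <- rep(0, length(x))
    z[is.na(x)] <- NA_real_
    return(z)
  }
  (x - mean(x, na.rm = TRUE)) / s
}

#' Non-overlapping block means
#'
#' Averages `x` over consecutive blocks of `k` samples, dropping a trailing
#' partial block. `NA`s are excluded from each block mean; a block with no
#' finite samples yields `NA`.
#'
#' @param x Numeric vector.
#' @param k Integer block length (samples).
#' @return List with `mean` (block means) and `n_valid` (finite samples per
#'   block).
#' @export
block_means <- function(x, k) {
  k <- as.integer(k)
  stopifnot(k >= 1)
  nb <- length(x) %/% k
  if (nb == 0) {
    return(list(mean = numeric(0), n_valid = integer(0)))
  }
  m <- matrix(x[seq_len(nb * k)], nrow = k)
  n_valid <- colSums(!is.na(m))
  s <- colSums(m, na.rm = TRUE)
  mu <- ifelse(n_valid > 0, s / n_valid, NA_real_)
  list(mean = as.numeric(mu), n_valid = as.integer(n_valid))
}

#' Wrap angles to (-180, 180]
#'
#' @param deg Angles in degrees.
#' @return Angles mapped to the half-open interval (-180, 180].
#' @export
wrap180 <- function(deg) {
  w <- (deg + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Circular mean of angles in degrees
#'
#' Resultant-vector (unit-phasor) average, the correct way to pool wrapped
#' phase angles: `{+170, -170}` averages to 180, not 0.
#'
#' @param deg Angles in degrees; `NA`s dropped.
#' @return Mean angle in (-180, 180], or `NA` if no finite input.
#' @export
circ_mean_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0) return(NA_real_)
  z <- mean(exp(1i * deg * pi / 180))
  wrap180(Arg(z) * 180 / pi)
}

#' Circular standard deviation in degrees
#'
#' `sqrt(-2 log R)` on the mean resultant length R, reported in degrees.
#'
#' @param deg Angles in degrees; `NA`s dropped.
#' @return Circular SD (degrees); 0 for a single angle, `NA` if empty.
#' @export
circ_sd_deg <- function(deg) {
  deg <- deg[is.finite(deg)]
  if (length(deg) == 0) return(NA_real_)
  r <- Mod(mean(exp(1i * deg * pi / 180)))
  r <- min(max(r, .Machine$double.eps), 1)
  sqrt(-2 * log(r)) * 180 / pi
}

# Unwrap a phase sequence (radians): remove 2*pi jumps between samples.
unwrap_phase <- function(p) {
  if (length(p) < 2) return(p)
  dp <- diff(p)
  jumps <- round(dp / (2 * pi))
  p - c(0, cumsum(jumps)) * 2 * pi
}
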