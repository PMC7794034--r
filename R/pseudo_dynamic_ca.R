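# Pseudo-dynamic autoregulation: the pressure reactivity index (PRx) and
# its CPP-resolved, Fisher-Z-averaged profile.

#' Down-sample an aligned series to 0.1 Hz
#'
#' Non-overlapping 10-s block means of MAP, ICP and CPP; the block mean is
#' also the slow-wave smoothing that precedes the PRx correlation.
#'
#' @param s An `aligned_series` (5 Hz).
#' @return Data frame with `t` (block centers, s), `map`, `icp`, `cpp`.
#' @export
downsample_10s <- function(s) {
  k <- as.integer(round(10 * s$sample_rate))
  m <- block_means(s$map, k); i <- block_means(s$icp, k)
  c_ <- block_means(s$cpp, k)
  nb <- length(m$mean)
  data.frame(t = s$t[1] + (seq_len(nb) - 0.5) * 10,
             map = m$mean, icp = i$mean, cpp = c_$mean)
}

#' Moving-window pressure reactivity index
#'
#' Pearson correlation of 0.1 Hz MAP and ICP over sliding windows (default
#' 5 min, stepped by 1 min), each paired with its window-mean CPP. Windows
#' with missing points or zero variance in either channel are skipped and
#' counted.
#'
#' @param map10,icp10 Co-sampled 0.1 Hz series.
#' @param cpp10 Matching CPP series; defaults to `map10 - icp10`.
#' @param window_s Window length (s), default 300.
#' @param step_s Window step (s), default 60.
#' @param sample_interval Sampling interval of the inputs (s), default 10.
#' @return Data frame with `t_center`, `r`, `mean_cpp`, `n`; attribute
#'   `dropped` counts skipped windows.
#' @export
windowed_prx <- function(map10, icp10, cpp10 = map10 - icp10,
                         window_s = 300, step_s = 60, sample_interval = 10) {
  if (length(map10) != length(icp10)) stop("length mismatch")
  w <- as.integer(round(window_s / sample_interval))
  st <- as.integer(round(step_s / sample_interval))
  starts <- seq(1, length(map10) - w + 1, by = st)
  if (length(map10) < w) starts <- integer(0)
  out <- vector("list", length(starts))
  dropped <- 0L
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + w - 1)
    m <- map10[idx]; i <- icp10[idx]
    if (anyNA(m) || anyNA(i) || sum(!is.na(m)) < w) {
      dropped <- dropped + 1L
      next
    }
    if (stats::sd(m) == 0 || stats::sd(i) == 0) {
      dropped <- dropped + 1L
      next
    }
    out[[j]] <- data.frame(
      t_center = mean(idx - 1) * sample_interval,
      r = stats::cor(m, i),
      mean_cpp = mean(cpp10[idx], na.rm = TRUE),
      n = w)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(t_center = numeric(0), r = numeric(0),
                      mean_cpp = numeric(0), n = integer(0))
  }
  attr(res, "dropped") <- dropped
  res
}

#' Fisher-Z average of correlation coefficients
#'
#' `tanh(mean(atanh(r)))`: correlations are mapped to the approximately
#' normal Z scale, averaged, and mapped back. Coefficients at the open
#' boundary are clipped to +/-(1 - 1e-12) so that noise-free unit
#' correlations stay finite.
#'
#' @param rs Correlation coefficients in [-1, 1]; `NA`s dropped.
#' @return The averaged correlation, or `NA` for an empty input.
#' @export
fisher_mean <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) return(NA_real_)
  if (any(abs(rs) > 1)) stop("correlation outside [-1, 1]")
  lim <- 1 - 1e-12
  rs <- pmin(pmax(rs, -lim), lim)
  tanh(mean(atanh(rs)))
}

#' CPP-resolved PRx profile
#'
#' Sorts PRx windows into 150 half-open CPP groups spanning [0, 180) mmHg
#' (width 180/150 = 1.2 mmHg), pooling windows across the subjects of one
#' anesthesia group, and averages each group through Fisher's Z. The SD is
#' reported on the correlation scale. Windows with CPP outside [0, 180)
#' are dropped and counted.
#'
#' @param windows Data frame from [windowed_prx()] (possibly row-bound
#'   across subjects).
#' @param group Group label to attach.
#' @param n_groups Number of CPP groups, default 150.
#' @param cpp_range CPP span covered, default `c(0, 180)` mmHg.
#' @return A `prx_profile`: data frame with one row per CPP group
#'   (`group_index`, `cpp_lo`, `cpp_hi`, `mean_prx`, `sd`, `n_windows`);
#'   attribute `dropped` counts out-of-range windows.
#' @export
prx_by_cpp <- function(windows, group = NA_character_, n_groups = 150,
                       cpp_range = c(0, 180)) {
  width <- diff(cpp_range) / n_groups
  idx <- floor((windows$mean_cpp - cpp_range[1]) / width)
  inb <- !is.na(idx) & idx >= 0 & idx < n_groups
  dropped <- sum(!inb)
  idx <- idx[inb]; r <- windows$r[inb]
  mean_prx <- rep(NA_real_, n_groups)
  sdv <- rep(NA_real_, n_groups)
  nw <- integer(n_groups)
  if (length(idx) > 0) {
    for (g in unique(idx)) {
      rg <- r[idx == g]
      mean_prx[g + 1] <- fisher_mean(rg)
      sdv[g + 1] <- if (length(rg) >= 2) stats::sd(rg) else NA_real_
      nw[g + 1] <- length(rg)
    }
  }
  out <- data.frame(group_index = 0:(n_groups - 1),
                    cpp_lo = cpp_range[1] + width * (0:(n_groups - 1)),
                    cpp_hi = cpp_range[1] + width * (1:n_groups),
                    mean_prx = mean_prx, sd = sdv, n_windows = nw)
  attr(out, "group") <- group
  attr(out, "dropped") <- dropped
  class(out) <- c("prx_profile", "data.frame")
  out
}

#' Pooled Fisher-Z PRx over a CPP span
#'
#' Convenience summary: the Fisher-Z mean of all windows whose CPP group
#' interval lies entirely within `span`.
#'
#' @param windows Data frame from [windowed_prx()].
#' @param span CPP interval `c(lo, hi)` in mmHg.
#' @param n_groups,cpp_range Grouping parameters as in [prx_by_cpp()].
#' @return Fisher-Z mean PRx over the span (`NA` if no windows).
#' @export
prx_pooled_span <- function(windows, span, n_groups = 150,
                            cpp_range = c(0, 180)) {
  width <- diff(cpp_range) / n_groups
  idx <- floor((windows$mean_cpp - cpp_range[1]) / width)
  glo <- cpp_range[1] + width * idx
  ghi <- glo + width
  keep <- !is.na(idx) & idx >= 0 & idx < n_groups &
    glo >= span[1] & ghi <= span[2]
  fisher_mean(windows$r[keep])
}
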