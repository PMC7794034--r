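# Static autoregulation: Lassen's curve over 1 mmHg CPP bins, per-subject
# normalization, group averaging, plateau (LLA/ULA) estimation, pooled
# pressure histograms and the group rank-sum comparison.

#' Subject-level Lassen curve
#'
#' Averages 10-s flow means within half-open 1 mmHg CPP bins `[k, k+1)`.
#' Bins that receive no data are absent, never zero-filled. Flow-outlier
#' bins and bins without valid optical samples are excluded.
#'
#' @param binned A `binned_series` (10-s means with QC masks applied).
#' @param value Which flow channel feeds the curve: the raw flow index
#'   (`"alpha_db"`, used for subsequent normalization) or the
#'   baseline-referenced fractional change (`"dcbf"`).
#' @param bin_width CPP bin width in mmHg.
#' @return A `subject_curve`: data frame with `bin_left`, `bin_center`,
#'   `value` and `n`, plus subject metadata attributes.
#' @export
lassen_curve_subject <- function(binned, value = c("alpha_db", "dcbf"),
                                 bin_width = 1) {
  value <- match.arg(value)
  v <- binned[[value]]
  keep <- !is.na(v) & !is.na(binned$cpp) & !binned$cbf_outlier &
    binned$n_valid > 0
  if (!any(keep)) stop("no valid 10-s bins for the Lassen curve")
  cpp <- binned$cpp[keep]
  v <- v[keep]
  lab <- floor(cpp / bin_width) * bin_width
  agg <- tapply(v, lab, mean)
  cnt <- tapply(v, lab, length)
  out <- data.frame(bin_left = as.numeric(names(agg)),
                    bin_center = as.numeric(names(agg)) + bin_width / 2,
                    value = as.numeric(agg),
                    n = as.integer(cnt))
  out <- out[order(out$bin_left), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "subject_id") <- binned$subject_id
  attr(out, "group") <- binned$group
  attr(out, "normalized") <- FALSE
  class(out) <- c("subject_curve", "data.frame")
  out
}

#' Mean-subtract and mean-divide a subject curve
#'
#' Each bin value v becomes (v - m) / m with m the unweighted mean over the
#' subject's populated bins, yielding a dimensionless flow change whose
#' unweighted mean is exactly zero.
#'
#' @param curve A `subject_curve`.
#' @return The normalized `subject_curve`.
#' @export
normalize_subject_curve <- function(curve) {
  m <- mean(curve$value)
  if (m == 0) stop("per-subject mean is zero: normalization undefined")
  curve$value <- (curve$value - m) / m
  attr(curve, "normalized") <- TRUE
  curve
}

#' Group-averaged Lassen curve
#'
#' Per-bin unweighted mean and SD across the subjects possessing that bin.
#' The SD is reported only where at least two subjects contribute.
#'
#' @param curves List of normalized `subject_curve`s (one group).
#' @param group Group label.
#' @param plateau If TRUE, attach a three-segment plateau fit via
#'   [estimate_plateau()].
#' @return A `lassen_curve`: data frame with `bin_center`, `mean_dcbf`,
#'   `sd`, `n_subjects` and optionally a `plateau` attribute.
#' @export
group_lassen <- function(curves, group, plateau = TRUE) {
  if (length(curves) == 0) stop("empty group")
  if (!all(vapply(curves, function(c) isTRUE(attr(c, "normalized")),
                  logical(1)))) {
    stop("all subject curves must be normalized first")
  }
  all_bins <- sort(unique(unlist(lapply(curves, `[[`, "bin_left"))))
  vals <- vapply(curves, function(c) {
    c$value[match(all_bins, c$bin_left)]
  }, numeric(length(all_bins)))
  vals <- matrix(vals, nrow = length(all_bins))
  n_subj <- rowSums(!is.na(vals))
  mu <- rowMeans(vals, na.rm = TRUE)
  sdv <- apply(vals, 1, function(r) {
    r <- r[!is.na(r)]
    if (length(r) >= 2) stats::sd(r) else NA_real_
  })
  bw <- curves[[1]]$bin_center[1] - curves[[1]]$bin_left[1]
  out <- data.frame(bin_center = all_bins + bw,
                    mean_dcbf = mu, sd = sdv, n_subjects = n_subj)
  attr(out, "group") <- group
  class(out) <- c("lassen_curve", "data.frame")
  if (plateau) {
    attr(out, "plateau") <- tryCatch(estimate_plateau(out),
                                     error = function(e) NULL)
  }
  out
}

# Closed-form least squares for a continuous three-segment curve with a flat
# middle: f(x) = level + s_lo*min(x-a, 0) + s_hi*max(x-b, 0), slopes clamped
# to be non-negative (rising/flat/rising).
fit_three_segment <- function(x, y, a, b) {
  x1 <- pmin(x - a, 0)
  x2 <- pmax(x - b, 0)
  X <- cbind(1, x1, x2)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  if (cf[2] < 0 || cf[3] < 0) {
    # drop offending slope terms (slope pinned at zero) and refit
    keep <- c(TRUE, cf[2] >= 0, cf[3] >= 0)
    fit2 <- stats::lm.fit(X[, keep, drop = FALSE], y)
    cf2 <- rep(0, 3)
    cf2[keep] <- fit2$coefficients
    cf2[is.na(cf2)] <- 0
    cf <- cf2
  }
  cf <- unname(cf)
  resid <- y - (cf[1] + cf[2] * x1 + cf[3] * x2)
  list(level = cf[1], slope_lo = cf[2], slope_hi = cf[3],
       sse = sum(resid^2))
}

#' Estimate the autoregulatory plateau (LLA, ULA)
#'
#' Continuous three-segment piecewise-linear least squares over the group
#' bin means: rising below the lower limit (LLA), flat between the limits,
#' rising above the upper limit (ULA). Breakpoints are searched on a 1 mmHg
#' grid and polished by Nelder-Mead. A plateau narrower than `degenerate_width`
#' is flagged degenerate (no resolvable plateau).
#'
#' @param l A `lassen_curve` (or data frame with `bin_center`, `mean_dcbf`).
#' @param min_bins Minimum number of populated bins required.
#' @param degenerate_width Plateau width (mmHg) below which the fit is
#'   flagged degenerate.
#' @return List with `lla`, `ula`, `level`, `slope_lo`, `slope_hi`, `sse`
#'   and `degenerate`.
#' @export
estimate_plateau <- function(l, min_bins = 20, degenerate_width = 10) {
  ok <- !is.na(l$mean_dcbf)
  x <- l$bin_center[ok]; y <- l$mean_dcbf[ok]
  if (length(x) < min_bins) stop("too few populated bins for a plateau fit")
  lo <- min(x); hi <- max(x)
  cand <- seq(ceiling(lo + 1), floor(hi - 1), by = 1)
  if (length(cand) < 2) stop("CPP range too narrow for a plateau fit")
  best <- NULL
  for (a in cand) {
    for (b in cand[cand >= a]) {
      f <- fit_three_segment(x, y, a, b)
      # ties in SSE (e.g. an all-flat curve) resolve to the widest plateau
      if (is.null(best) || f$sse < best$sse - 1e-12 ||
          (f$sse < best$sse + 1e-12 && (b - a) > (best$ula - best$lla))) {
        best <- c(f, list(lla = a, ula = b))
      }
    }
  }
  # polish breakpoints continuously
  obj <- function(p) {
    a <- min(max(p[1], lo), hi); b <- min(max(p[2], a), hi)
    fit_three_segment(x, y, a, b)$sse
  }
  op <- stats::optim(c(best$lla, best$ula), obj, method = "Nelder-Mead")
  if (op$value < best$sse - 1e-12) {
    # accept the polish only on a real improvement; on a flat SSE surface
    # (all-plateau data) the simplex drifts without gaining anything
    a <- min(max(op$par[1], lo), hi)
    b <- min(max(op$par[2], a), hi)
  } else {
    a <- best$lla
    b <- best$ula
  }
  f <- fit_three_segment(x, y, a, b)
  res <- list(lla = a, ula = b, level = f$level, slope_lo = f$slope_lo,
              slope_hi = f$slope_hi, sse = f$sse,
              degenerate = (b - a) < degenerate_width)
  res
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# choose(n, n_a) group assignments (midranks under ties).
ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na_ <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na_)]) - na_ * (na_ + 1) / 2
  combos <- utils::combn(n, na_)
  u_all <- colSums(matrix(r[combos], nrow = na_)) - na_ * (na_ + 1) / 2
  center <- na_ * (n - na_) / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

#' Two-group rank-sum comparison (Mann-Whitney U)
#'
#' Exact permutation enumeration for combined n up to `exact_max`; the
#' normal approximation with tie correction (no continuity correction)
#' otherwise. Intended for per-subject summary values (one value per
#' subject) to avoid pseudo-replication; pooled samples can be passed, but
#' their interdependence inflates significance.
#'
#' @param a,b Numeric vectors of per-subject values.
#' @param exact_max Largest combined sample size for the exact branch.
#' @return List with `statistic` (U of group `a`), `p.value`, `method`.
#' @export
distribution_test <- function(a, b, exact_max = 20) {
  if (length(a) < 1 || length(b) < 1) stop("both groups must be non-empty")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  if (length(unique(pooled)) == 1) {
    return(list(statistic = u, p.value = 1, method = "degenerate (all tied)"))
  }
  if (length(pooled) <= exact_max) {
    p <- ranksum_exact(a, b)
    method <- "exact permutation"
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
    p <- wt$p.value
    method <- "normal approximation with tie correction"
  }
  list(statistic = u, p.value = min(p, 1), method = method)
}

#' Pooled pressure histograms
#'
#' Group-pooled sample counts in half-open 1 mmHg bins for a pressure
#' channel of the aligned series.
#'
#' @param series_list List of `aligned_series`.
#' @param channel One of `"cpp"`, `"map"`, `"icp"`.
#' @param bin_width Histogram bin width (mmHg).
#' @return Data frame with `group`, `bin_left`, `count`.
#' @export
pressure_histograms <- function(series_list, channel = c("cpp", "map", "icp"),
                                bin_width = 1) {
  channel <- match.arg(channel)
  rows <- lapply(series_list, function(s) {
    v <- s[[channel]]
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NULL)
    lab <- floor(v / bin_width) * bin_width
    cnt <- table(lab)
    data.frame(group = s$group, bin_left = as.numeric(names(cnt)),
               count = as.integer(cnt))
  })
  rows <- do.call(rbind, rows)
  agg <- stats::aggregate(count ~ group + bin_left, data = rows, FUN = sum)
  agg[order(agg$group, agg$bin_left), , drop = FALSE]
}
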