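# Recording data model, delimited-text I/O, derived pressures, alignment,
# binning and quality-control masking.
#
# A recording directory holds one delimited file per channel group:
#   pressures.tsv  time_s, abp_mmhg, icp_mmhg          (typically 100 Hz)
#   dcs.tsv        time_s, alpha_db, beta              (typically 1 Hz)
#   vitals.tsv     time_s, heart_rate_bpm, etco2_mmhg  (~2 samples/min)
#   anesthesia.tsv time_s, isoflurane_pct, fentanyl_ug_kg_hr
#   events.tsv     t_start_s, t_end_s, kind, freq_hz, icp_target_mmhg
#   meta.json      subject_id, group
# ABP and ICP are mandatory; a recording without the optical flow index is
# flagged "pressure-only" (PRx and phase analyses still run).

PROTOCOL_FREQUENCIES <- c(0.009, 0.017, 0.025, 0.033, 0.059)
CMH2O_TO_MMHG <- 0.7355

#' Construct a raw multimodal recording
#'
#' @param subject_id Subject label.
#' @param group Anesthesia group, `"isoflurane"` or `"fentanyl"`.
#' @param channels Named list; each element a list with numeric `t`
#'   (seconds, strictly increasing), `v` (values) and a `units` string.
#'   Recognized names: `abp`, `icp` (mmHg), `alpha_db` (cm^2/s), `beta`.
#' @param markers Data frame of protocol events with columns `t_start`,
#'   `t_end` (s), `kind` (`"baseline"`, `"icp_osc"`, `"abp_osc"`),
#'   `freq_hz` (0 for baseline) and `icp_target_mmhg`.
#' @param vitals Optional data frame `t`, `heart_rate_bpm`, `etco2_mmhg`.
#' @param anesthesia_log Optional data frame `t`, `isoflurane_pct`,
#'   `fentanyl_ug_kg_hr`.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(subject_id, group, channels, markers = NULL,
                          vitals = NULL, anesthesia_log = NULL) {
  group <- match.arg(group, c("isoflurane", "fentanyl"))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (length(ch$t) != length(ch$v)) {
      stop("channel '", nm, "': time and value lengths differ")
    }
    bad <- which(diff(ch$t) <= 0)
    if (length(bad) > 0) {
      stop("channel '", nm, "': timestamps not strictly increasing at row ",
           bad[1] + 1)
    }
  }
  if (!is.null(markers)) {
    markers <- as.data.frame(markers)
    if (any(markers$t_end <= markers$t_start)) {
      stop("markers: t_end must exceed t_start")
    }
    okf <- markers$freq_hz == 0 |
      vapply(markers$freq_hz,
             function(f) any(abs(f - PROTOCOL_FREQUENCIES) < 1e-9), logical(1))
    if (!all(okf)) stop("markers: frequency outside the protocol set")
  }
  structure(
    list(subject_id = subject_id, group = group, channels = channels,
         markers = markers, vitals = vitals, anesthesia_log = anesthesia_log,
         pressure_only = !("alpha_db" %in% names(channels))),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("<raw_recording>", x$subject_id, sprintf("[%s]", x$group), "\n")
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-9s %7d samples  %.1f..%.1f s  [%s]\n", nm,
                length(ch$t), min(ch$t), max(ch$t), ch$units))
  }
  cat("  markers:", if (is.null(x$markers)) 0 else nrow(x$markers), "\n")
  invisible(x)
}

#' Write a recording to a directory of delimited text files
#'
#' @param rec A `raw_recording`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(path, file), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (all(c("abp", "icp") %in% names(rec$channels))) {
    a <- rec$channels$abp; i <- rec$channels$icp
    if (length(a$t) == length(i$t) && all(a$t == i$t)) {
      wt(data.frame(time_s = a$t, abp_mmhg = a$v, icp_mmhg = i$v),
         "pressures.tsv")
    } else {
      wt(data.frame(time_s = a$t, abp_mmhg = a$v), "abp.tsv")
      wt(data.frame(time_s = i$t, icp_mmhg = i$v), "icp.tsv")
    }
  } else if ("abp" %in% names(rec$channels)) {
    a <- rec$channels$abp
    wt(data.frame(time_s = a$t, abp_mmhg = a$v), "abp.tsv")
  } else if ("icp" %in% names(rec$channels)) {
    i <- rec$channels$icp
    wt(data.frame(time_s = i$t, icp_mmhg = i$v), "icp.tsv")
  }
  if ("alpha_db" %in% names(rec$channels)) {
    d <- rec$channels$alpha_db; b <- rec$channels$beta
    wt(data.frame(time_s = d$t, alpha_db = d$v, beta = b$v), "dcs.tsv")
  }
  if (!is.null(rec$vitals)) {
    wt(data.frame(time_s = rec$vitals$t,
                  heart_rate_bpm = rec$vitals$heart_rate_bpm,
                  etco2_mmhg = rec$vitals$etco2_mmhg), "vitals.tsv")
  }
  if (!is.null(rec$anesthesia_log)) {
    wt(data.frame(time_s = rec$anesthesia_log$t,
                  isoflurane_pct = rec$anesthesia_log$isoflurane_pct,
                  fentanyl_ug_kg_hr = rec$anesthesia_log$fentanyl_ug_kg_hr),
       "anesthesia.tsv")
  }
  if (!is.null(rec$markers)) {
    wt(data.frame(t_start_s = rec$markers$t_start,
                  t_end_s = rec$markers$t_end,
                  kind = rec$markers$kind,
                  freq_hz = rec$markers$freq_hz,
                  icp_target_mmhg = rec$markers$icp_target_mmhg),
       "events.tsv")
  }
  writeLines(jsonlite::toJSON(list(subject_id = rec$subject_id,
                                   group = rec$group),
                              auto_unbox = TRUE),
             file.path(path, "meta.json"))
  invisible(path)
}

#' Read a recording directory
#'
#' Missing ABP or ICP is a hard error; a missing optical channel flags the
#' recording pressure-only. Non-monotonic timestamps are reported with the
#' first offending row.
#'
#' @param path Directory written by [write_recording()] (or hand-assembled
#'   with the same schema).
#' @return A `raw_recording`.
#' @export
read_recording <- function(path) {
  rd <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) return(NULL)
    utils::read.table(f, header = TRUE, sep = "\t")
  }
  meta <- jsonlite::fromJSON(file.path(path, "meta.json"))
  channels <- list()
  pr <- rd("pressures.tsv")
  if (!is.null(pr)) {
    channels$abp <- list(t = pr$time_s, v = pr$abp_mmhg, units = "mmHg")
    channels$icp <- list(t = pr$time_s, v = pr$icp_mmhg, units = "mmHg")
  } else {
    ab <- rd("abp.tsv"); ic <- rd("icp.tsv")
    if (!is.null(ab)) channels$abp <- list(t = ab$time_s, v = ab$abp_mmhg, units = "mmHg")
    if (!is.null(ic)) channels$icp <- list(t = ic$time_s, v = ic$icp_mmhg, units = "mmHg")
  }
  if (!("abp" %in% names(channels)) || !("icp" %in% names(channels))) {
    stop("recording at '", path, "' lacks a mandatory pressure channel (ABP/ICP)")
  }
  dc <- rd("dcs.tsv")
  if (!is.null(dc)) {
    channels$alpha_db <- list(t = dc$time_s, v = dc$alpha_db, units = "cm^2/s")
    channels$beta <- list(t = dc$time_s, v = dc$beta, units = "")
  }
  ev <- rd("events.tsv")
  markers <- NULL
  if (!is.null(ev)) {
    markers <- data.frame(t_start = ev$t_start_s, t_end = ev$t_end_s,
                          kind = ev$kind, freq_hz = ev$freq_hz,
                          icp_target_mmhg = ev$icp_target_mmhg)
  }
  vi <- rd("vitals.tsv")
  vitals <- if (!is.null(vi)) {
    data.frame(t = vi$time_s, heart_rate_bpm = vi$heart_rate_bpm,
               etco2_mmhg = vi$etco2_mmhg)
  }
  an <- rd("anesthesia.tsv")
  anesthesia <- if (!is.null(an)) {
    data.frame(t = an$time_s, isoflurane_pct = an$isoflurane_pct,
               fentanyl_ug_kg_hr = an$fentanyl_ug_kg_hr)
  }
  raw_recording(meta$subject_id, meta$group, channels, markers = markers,
                vitals = vitals, anesthesia_log = anesthesia)
}

#' Beat-wise systolic and diastolic pressure estimates
#'
#' Running extrema of the arterial waveform over non-overlapping windows
#' (default 2 s, at least two cardiac cycles at typical heart rates), held
#' constant back onto the waveform grid.
#'
#' @param abp Numeric arterial pressure waveform (mmHg).
#' @param sample_rate Waveform rate in Hz.
#' @param window_s Extraction window length (s).
#' @return List with `systolic` and `diastolic`, each on the waveform grid.
#' @export
estimate_beat_pressures <- function(abp, sample_rate = 100, window_s = 2) {
  if (length(abp) < 2 * sample_rate) stop("waveform shorter than 2 s")
  if (diff(range(abp, na.rm = TRUE)) < 1) {
    warning("flat-line arterial waveform: systolic set equal to diastolic")
    return(list(systolic = abp, diastolic = abp))
  }
  k <- as.integer(round(window_s * sample_rate))
  nb <- length(abp) %/% k
  idx <- rep(seq_len(nb), each = k)
  head_n <- nb * k
  sys_w <- tapply(abp[seq_len(head_n)], idx, max, na.rm = TRUE)
  dia_w <- tapply(abp[seq_len(head_n)], idx, min, na.rm = TRUE)
  # hold each window value across its own samples; trailing remnant extends
  # the last window
  expand <- function(w) {
    out <- rep(as.numeric(w), each = k)
    if (length(abp) > head_n) out <- c(out, rep(w[nb], length(abp) - head_n))
    out
  }
  list(systolic = expand(sys_w), diastolic = expand(dia_w))
}

#' Mean arterial pressure from beat extrema
#'
#' Clinical standard: MAP = 2/3 diastolic + 1/3 systolic.
#'
#' @param systolic,diastolic Pressures in mmHg (vectors of equal length).
#' @return MAP in mmHg.
#' @export
compute_map <- function(systolic, diastolic) {
  if (length(systolic) != length(diastolic)) stop("length mismatch")
  if (any(systolic < diastolic, na.rm = TRUE)) {
    stop("systolic below diastolic")
  }
  (2 / 3) * diastolic + (1 / 3) * systolic
}

#' Cerebral perfusion pressure
#'
#' CPP = MAP - ICP, element-wise; negative values are preserved.
#'
#' @param map_series,icp_series Co-sampled pressures (mmHg).
#' @return CPP series (mmHg).
#' @export
compute_cpp <- function(map_series, icp_series) {
  if (length(map_series) != length(icp_series)) stop("length mismatch")
  map_series - icp_series
}

#' Fractional cerebral blood-flow change from the flow index
#'
#' \eqn{\Delta CBF = (\alpha D_b - \alpha D_{b,0}) / \alpha D_{b,0}}, with the
#' baseline \eqn{\alpha D_{b,0}} the mean flow index over the opening baseline
#' window (masked samples excluded).
#'
#' @param alpha_db Flow-index series.
#' @param t Sample times (s); defaults to a unit grid.
#' @param baseline_window Baseline length (s), counted from the first sample;
#'   must cover at least 60 s of unmasked samples.
#' @param mask Optional logical rejection mask (TRUE = rejected).
#' @return Fractional flow-change series.
#' @export
compute_delta_cbf <- function(alpha_db, t = seq_along(alpha_db) - 1,
                              baseline_window = 60, mask = NULL) {
  if (is.null(mask)) mask <- rep(FALSE, length(alpha_db))
  inb <- t <= t[1] + baseline_window & !mask & !is.na(alpha_db)
  if (sum(inb) == 0) stop("no unmasked samples in the baseline window")
  span <- diff(range(t[inb]))
  if (span < 60 - 1e-9 && baseline_window >= 60) {
    # tolerate sparse channels only when the window itself is >= 60 s
    if (sum(inb) < 2) stop("baseline window covers fewer than 60 s")
  }
  a0 <- mean(alpha_db[inb])
  if (a0 <= 0) stop("non-positive baseline flow index")
  (alpha_db - a0) / a0
}

#' Laser-stability rejection mask from the DCS quality value
#'
#' A sample is rejected when its per-recording beta z-score exceeds 0.5 in
#' magnitude, or beta falls more than 0.01 below the recording median.
#' The mask applies equally to co-timed flow-index samples.
#'
#' @param beta Quality values in (0, 1].
#' @param z_threshold Z-score rejection threshold (strict inequality).
#' @param median_drop Rejection margin below the median.
#' @return Logical vector, TRUE = rejected.
#' @export
beta_quality_mask <- function(beta, z_threshold = 0.5, median_drop = 0.01) {
  if (length(beta) < 10) {
    warning("fewer than 10 beta samples: no quality rejection applied")
    return(rep(FALSE, length(beta)))
  }
  z <- zscore(beta)
  rej <- abs(z) > z_threshold |
    beta < stats::median(beta, na.rm = TRUE) - median_drop
  rej[is.na(rej)] <- TRUE
  rej
}

#' Align channels and derive 5 Hz analysis series
#'
#' Computes MAP from beat extrema, down-samples pressures by block (boxcar)
#' averaging onto the target grid, holds slower channels constant between
#' samples, derives CPP and the fractional flow change, and attaches the
#' quality-control masks.
#'
#' @param rec A `raw_recording`.
#' @param target_rate Output rate (Hz), default 5.
#' @param baseline_window Baseline for the flow-change reference (s).
#' @return An `aligned_series`: list with `t`, `map`, `icp`, `cpp`, `dcbf`,
#'   `alpha_db`, `qc$beta_reject`, `sample_rate`, plus carried markers and
#'   identity fields.
#' @export
align_resample <- function(rec, target_rate = 5, baseline_window = 60) {
  chans <- rec$channels
  starts <- vapply(chans[c("abp", "icp")], function(c) c$t[1], numeric(1))
  ends <- vapply(chans[c("abp", "icp")], function(c) c$t[length(c$t)], numeric(1))
  t0 <- max(starts); t1 <- min(ends)
  spans <- ends - starts
  if ((t1 - t0) < 0.5 * max(spans)) {
    stop("pressure channels overlap for less than 50% of the recording")
  }
  dt_out <- 1 / target_rate
  n_out <- ceiling((t1 - t0) / dt_out - 1e-9)
  grid <- t0 + (seq_len(n_out) - 1) * dt_out

  # block-average a channel into the output intervals [g, g + dt_out)
  to_grid_mean <- function(t, v) {
    i <- findInterval(t - t0, seq(0, length(grid) * dt_out, by = dt_out),
                      left.open = FALSE)
    keep <- i >= 1 & i <= length(grid)
    out <- rep(NA_real_, length(grid))
    s <- tapply(v[keep], i[keep], mean, na.rm = TRUE)
    out[as.integer(names(s))] <- as.numeric(s)
    out
  }
  # zero-order hold for channels slower than the grid
  to_grid_hold <- function(t, v) {
    i <- findInterval(grid, t)
    out <- rep(NA_real_, length(grid))
    out[i >= 1] <- v[i[i >= 1]]
    out
  }

  abp_rate <- 1 / stats::median(diff(chans$abp$t))
  bp <- estimate_beat_pressures(chans$abp$v, sample_rate = abp_rate)
  map_native <- compute_map(bp$systolic, bp$diastolic)
  map5 <- to_grid_mean(chans$abp$t, map_native)
  icp5 <- to_grid_mean(chans$icp$t, chans$icp$v)
  cpp5 <- compute_cpp(map5, icp5)

  alpha5 <- dcbf5 <- rep(NA_real_, length(grid))
  beta_reject5 <- rep(FALSE, length(grid))
  if (!rec$pressure_only) {
    dcs_t <- chans$alpha_db$t
    mask_native <- beta_quality_mask(chans$beta$v)
    dcbf_native <- compute_delta_cbf(chans$alpha_db$v, t = dcs_t,
                                     baseline_window = baseline_window,
                                     mask = mask_native)
    dcs_rate <- 1 / stats::median(diff(dcs_t))
    if (dcs_rate >= target_rate) {
      alpha5 <- to_grid_mean(dcs_t, chans$alpha_db$v)
      dcbf5 <- to_grid_mean(dcs_t, dcbf_native)
      beta_reject5 <- to_grid_mean(dcs_t, as.numeric(mask_native)) > 0
    } else {
      alpha5 <- to_grid_hold(dcs_t, chans$alpha_db$v)
      dcbf5 <- to_grid_hold(dcs_t, dcbf_native)
      hold <- to_grid_hold(dcs_t, as.numeric(mask_native))
      beta_reject5 <- !is.na(hold) & hold > 0
    }
    beta_reject5[is.na(beta_reject5)] <- TRUE
  }

  structure(
    list(t = grid, map = map5, icp = icp5, cpp = cpp5, dcbf = dcbf5,
         alpha_db = alpha5,
         qc = list(beta_reject = beta_reject5),
         sample_rate = target_rate,
         markers = rec$markers, subject_id = rec$subject_id,
         group = rec$group, pressure_only = rec$pressure_only),
    class = "aligned_series")
}

#' @export
print.aligned_series <- function(x, ...) {
  cat(sprintf("<aligned_series> %s [%s] %d samples @ %g Hz (%.0f s)\n",
              x$subject_id, x$group, length(x$t), x$sample_rate,
              length(x$t) / x$sample_rate))
  invisible(x)
}

#' Time-average an aligned series into fixed bins
#'
#' Non-overlapping, left-aligned bins; a trailing partial bin is dropped.
#' Optical samples flagged by the beta quality mask are excluded from the
#' flow means; a bin with no valid samples is missing.
#'
#' @param s An `aligned_series`.
#' @param bin_width Bin width in seconds (integer multiple of the sample
#'   interval), default 10.
#' @return A `binned_series`: data frame-like list with `t_center`, per-
#'   channel means, `n` (samples per bin) and `n_valid` (unmasked optical
#'   samples per bin).
#' @export
bin_average <- function(s, bin_width = 10) {
  k <- bin_width * s$sample_rate
  if (abs(k - round(k)) > 1e-9) {
    stop("bin width must be an integer multiple of the sample interval")
  }
  k <- as.integer(round(k))
  masked <- function(x) {
    y <- x
    y[s$qc$beta_reject] <- NA_real_
    y
  }
  bm_map <- block_means(s$map, k)
  bm_icp <- block_means(s$icp, k)
  bm_cpp <- block_means(s$cpp, k)
  bm_dcbf <- block_means(masked(s$dcbf), k)
  bm_alpha <- block_means(masked(s$alpha_db), k)
  nb <- length(bm_map$mean)
  structure(
    list(bin_width = bin_width,
         t_center = s$t[1] + (seq_len(nb) - 0.5) * bin_width,
         map = bm_map$mean, icp = bm_icp$mean, cpp = bm_cpp$mean,
         dcbf = bm_dcbf$mean, alpha_db = bm_alpha$mean,
         n = rep(k, nb), n_valid = bm_dcbf$n_valid,
         cbf_outlier = rep(FALSE, nb),
         subject_id = s$subject_id, group = s$group),
    class = "binned_series")
}

#' Flow-outlier rejection on 10-s bin means
#'
#' Rejects any bin whose flow mean lies strictly outside two standard
#' deviations of the subject's bin distribution (z computed over all bins).
#'
#' @param binned A `binned_series`.
#' @param z_threshold Rejection threshold, default 2 (strict inequality).
#' @return The `binned_series` with its `cbf_outlier` mask set.
#' @export
cbf_outlier_mask <- function(binned, z_threshold = 2) {
  x <- binned$dcbf
  if (sum(!is.na(x)) < 10) {
    warning("fewer than 10 flow bins: no outlier rejection applied")
    return(binned)
  }
  z <- zscore(x)
  binned$cbf_outlier <- !is.na(z) & abs(z) > z_threshold
  binned
}
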