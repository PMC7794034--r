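# Study orchestration: per-subject preprocessing, the three autoregulation
# analyses, group bookkeeping, vitals summaries and table export. Every
# threshold and every dropped-sample count is surfaced in the QC report.

#' Study configuration
#'
#' @param subjects List of subject entries; each a list with `subject_id`,
#'   `group` and either `path` (a recording directory) or `recording`
#'   (an in-memory `raw_recording`).
#' @param out_dir Output directory for the report bundle.
#' @param seed Seed recorded in the report (and used by any simulation
#'   stage the caller performs).
#' @param thresholds Named overrides of the analysis defaults: `beta_z`,
#'   `beta_median_drop`, `cbf_z`, `bin_width_s`, `cpp_bin_mmhg`,
#'   `prx_window_s`, `prx_step_s`, `cpp_groups`, `cpp_range`,
#'   `noise_floor_mmhg`, `phase_rate_hz`, `target_rate_hz`.
#' @return A `study_config` list.
#' @export
study_config <- function(subjects, out_dir, seed = 1, thresholds = list()) {
  defaults <- list(beta_z = 0.5, beta_median_drop = 0.01, cbf_z = 2,
                   bin_width_s = 10, cpp_bin_mmhg = 1,
                   prx_window_s = 300, prx_step_s = 60,
                   cpp_groups = 150, cpp_range = c(0, 180),
                   noise_floor_mmhg = 0.5, phase_rate_hz = 1,
                   target_rate_hz = 5)
  gr <- vapply(subjects, `[[`, character(1), "group")
  if (!all(gr %in% c("isoflurane", "fentanyl"))) {
    stop("every subject must map to exactly one known group")
  }
  structure(list(subjects = subjects, out_dir = out_dir,
                 seed = as.integer(seed),
                 thresholds = utils::modifyList(defaults, thresholds)),
            class = "study_config")
}

#' Per-subject vitals summary
#'
#' Whole-recording mean and SD of end-tidal CO2 and mean heart rate.
#'
#' @param rec A `raw_recording`.
#' @return One-row data frame (`subject_id`, `mean_etco2`, `sd_etco2`,
#'   `mean_heart_rate`), or `NULL` with a warning when vitals are absent.
#' @export
vitals_summary <- function(rec) {
  v <- rec$vitals
  if (is.null(v) || nrow(v) == 0) {
    warning("no vitals recorded for subject ", rec$subject_id)
    return(NULL)
  }
  data.frame(subject_id = rec$subject_id, group = rec$group,
             mean_etco2 = mean(v$etco2_mmhg, na.rm = TRUE),
             sd_etco2 = stats::sd(v$etco2_mmhg),
             mean_heart_rate = mean(v$heart_rate_bpm, na.rm = TRUE))
}

#' Run the full autoregulation study
#'
#' For every subject: load (or take) the recording, align and derive the
#' 5 Hz series, then run the static (Lassen curve), pseudo-dynamic (PRx)
#' and dynamic (phase lag) analyses. Group-level tables are written as
#' delimited text together with a JSON QC report recording all thresholds,
#' per-stage failures and dropped-sample accounting. A stage failure for
#' one subject is recorded and the run continues.
#'
#' @param cfg A `study_config`.
#' @return Invisibly, a list with the group tables (`lassen`,
#'   `prx_profile`, `phase`, `histograms`, `vitals`) and the `qc` report.
#' @export
run_study <- function(cfg) {
  th <- cfg$thresholds
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  qc <- list(seed = cfg$seed, thresholds = th, subjects = list())
  aligned <- list(); curves <- list(); windows <- list(); phases <- list()
  vitals <- list()
  filters <- NULL

  for (sub in cfg$subjects) {
    sid <- sub$subject_id
    sqc <- list(group = sub$group, stages = list())
    rec <- tryCatch({
      if (!is.null(sub$recording)) sub$recording else read_recording(sub$path)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      sqc$stages$read <- conditionMessage(rec)
      qc$subjects[[sid]] <- sqc
      next
    }
    vs <- tryCatch(suppressWarnings(vitals_summary(rec)),
                   error = function(e) NULL)
    if (!is.null(vs)) vitals[[sid]] <- vs

    s <- tryCatch(
      align_resample(rec, target_rate = th$target_rate_hz),
      error = function(e) e)
    if (inherits(s, "error")) {
      sqc$stages$preprocess <- conditionMessage(s)
      qc$subjects[[sid]] <- sqc
      next
    }
    sqc$samples <- length(s$t)
    sqc$beta_rejected <- sum(s$qc$beta_reject)

    # static branch requires the optical channel
    if (!s$pressure_only) {
      cur <- tryCatch({
        b <- bin_average(s, th$bin_width_s)
        b <- cbf_outlier_mask(b, th$cbf_z)
        sqc$cbf_outlier_bins <- sum(b$cbf_outlier)
        normalize_subject_curve(
          lassen_curve_subject(b, bin_width = th$cpp_bin_mmhg))
      }, error = function(e) e)
      if (inherits(cur, "error")) {
        sqc$stages$static <- conditionMessage(cur)
      } else {
        curves[[sid]] <- cur
      }
    } else {
      sqc$stages$static <- "pressure-only recording: no optical channel"
    }

    w <- tryCatch({
      d10 <- downsample_10s(s)
      ww <- windowed_prx(d10$map, d10$icp, d10$cpp,
                         window_s = th$prx_window_s,
                         step_s = th$prx_step_s)
      sqc$prx_windows <- nrow(ww)
      sqc$prx_windows_dropped <- attr(ww, "dropped")
      ww$group <- s$group
      ww
    }, error = function(e) e)
    if (inherits(w, "error")) {
      sqc$stages$prx <- conditionMessage(w)
    } else {
      windows[[sid]] <- w
    }

    ph <- tryCatch({
      pd <- subject_phase_delays(s, filters = filters,
                                 analysis_rate = th$phase_rate_hz,
                                 noise_floor = th$noise_floor_mmhg)
      filters <- attr(pd, "filters")
      sqc$phase_segments <- nrow(pd)
      sqc$phase_unreliable <- sum(!pd$reliable)
      pd
    }, error = function(e) e)
    if (inherits(ph, "error")) {
      sqc$stages$phase <- conditionMessage(ph)
    } else {
      phases[[sid]] <- ph
    }

    aligned[[sid]] <- s
    qc$subjects[[sid]] <- sqc
  }

  wt <- function(df, file) {
    utils::write.table(df, file.path(cfg$out_dir, file), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  # --- Lassen curves per group ---------------------------------------
  lassen_rows <- list()
  for (g in c("isoflurane", "fentanyl")) {
    gc <- curves[vapply(curves, function(c) attr(c, "group") == g,
                        logical(1))]
    if (length(gc) == 0) next
    lc <- group_lassen(unname(gc), g)
    pl <- attr(lc, "plateau")
    lc$group <- g
    lassen_rows[[g]] <- as.data.frame(lc)
    qc$plateau[[g]] <- if (is.null(pl)) "fit unavailable" else pl
  }
  lassen_tab <- if (length(lassen_rows)) do.call(rbind, lassen_rows)
  if (!is.null(lassen_tab)) {
    rownames(lassen_tab) <- NULL
    wt(lassen_tab, "lassen.tsv")
    writeLines(jsonlite::toJSON(qc$plateau, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(cfg$out_dir, "plateau.json"))
  }

  # --- PRx profiles per group ----------------------------------------
  prx_rows <- list()
  prx_tab <- NULL
  allw <- do.call(rbind, unname(windows))
  if (!is.null(allw)) {
    for (g in unique(allw$group)) {
      pr <- prx_by_cpp(allw[allw$group == g, ], group = g,
                       n_groups = th$cpp_groups, cpp_range = th$cpp_range)
      qc$prx_out_of_range[[g]] <- attr(pr, "dropped")
      pr$group <- g
      prx_rows[[g]] <- as.data.frame(pr)
    }
    prx_tab <- do.call(rbind, prx_rows)
    rownames(prx_tab) <- NULL
    wt(prx_tab, "prx_profile.tsv")
  }

  # --- phase lags per modality/frequency/group -----------------------
  allp <- do.call(rbind, unname(phases))
  if (!is.null(allp)) {
    wt(phase_by_frequency(allp), "phase.tsv")
  }

  # --- histograms and vitals -----------------------------------------
  hist_rows <- list()
  for (ch in c("cpp", "map", "icp")) {
    h <- pressure_histograms(unname(aligned), ch)
    h$channel <- ch
    hist_rows[[ch]] <- h
  }
  hist_tab <- do.call(rbind, hist_rows)
  rownames(hist_tab) <- NULL
  wt(hist_tab, "histograms.tsv")
  vit_tab <- do.call(rbind, unname(vitals))
  if (!is.null(vit_tab)) wt(vit_tab, "vitals.tsv")

  writeLines(jsonlite::toJSON(qc, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(cfg$out_dir, "qc_report.json"))

  invisible(list(lassen = lassen_tab,
                 prx_profile = prx_tab,
                 phase = if (!is.null(allp)) phase_by_frequency(allp),
                 histograms = hist_tab, vitals = vit_tab, qc = qc,
                 aligned = aligned))
}
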