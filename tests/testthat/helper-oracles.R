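# Independent brute-force oracles used by the oracle-equivalence and
# exactness checks. These deliberately avoid the package's own code paths.

pearson_bf <- function(x, y) {
  dx <- x - sum(x) / length(x)
  dy <- y - sum(y) / length(y)
  sum(dx * dy) / sqrt(sum(dx * dx) * sum(dy * dy))
}

fisher_bf <- function(rs) {
  lim <- 1 - 1e-12
  rs <- pmin(pmax(rs, -lim), lim)
  m <- mean(0.5 * log((1 + rs) / (1 - rs)))
  (exp(2 * m) - 1) / (exp(2 * m) + 1)
}

block_means_bf <- function(x, k) {
  nb <- length(x) %/% k
  out <- numeric(nb)
  for (j in seq_len(nb)) {
    seg <- x[((j - 1) * k + 1):(j * k)]
    out[j] <- mean(seg[!is.na(seg)])
  }
  out
}

# interval-scan group assignment: walk the half-open edges until the value
# fits, rather than dividing
assign_bf <- function(v, width, lo = 0, n_groups = Inf) {
  edge <- lo
  idx <- 0
  while (!(v >= edge & v < edge + width)) {
    edge <- edge + width
    idx <- idx + 1
    if (idx > n_groups + 1) return(NA_integer_)
  }
  idx
}

# exhaustive two-sided rank-sum p by bitmask subset enumeration
ranksum_bitmask_p <- function(a, b) {
  r <- rank(c(a, b))
  na_ <- length(a); n <- length(r)
  u_obs <- sum(r[seq_len(na_)])
  center <- na_ * (n + 1) / 2
  hits <- 0L; total <- 0L
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(sel) != na_) next
    total <- total + 1L
    if (abs(sum(r[sel]) - center) >= abs(u_obs - center) - 1e-9) {
      hits <- hits + 1L
    }
  }
  hits / total
}

protocol_filters <- function() {
  sim_cache("filters", function() {
    fr <- c(0.009, 0.017, 0.025, 0.033, 0.059)
    fl <- lapply(fr, design_narrowband)
    names(fl) <- as.character(fr)
    fl
  })
}

cached_plateau_sweep <- function(gain) {
  sim_cache(paste0("sweep", gain), function() {
    proto <- oscillation_protocol(icp_baselines = 6,
                                  modalities = character(0))
    cfg <- simulation_config(seed = 21, baseline_duration = 3600,
                             tail_duration = 0, abp_baseline = 75,
                             map_ramp = c(-45, 65),
                             noise = list(map_ou_sd = 1.5))
    rec <- simulate_hemodynamics(cfg, ca_parameters(ca_gain = gain), proto)
    b <- cbf_outlier_mask(bin_average(align_resample(rec)))
    cur <- normalize_subject_curve(lassen_curve_subject(b))
    estimate_plateau(data.frame(bin_center = cur$bin_center,
                                mean_dcbf = cur$value))
  })
}

study_recordings <- function() {
  sim_cache("study_recs", function() {
    proto <- oscillation_protocol(frequencies = c(0.017, 0.033),
                                  icp_baselines = 6,
                                  modalities = c("icp_osc", "abp_osc"))
    mk <- function(seed, group, gain, abp) {
      cfg <- simulation_config(seed = seed,
                               subject_id = sprintf("%s%02d", group, seed),
                               group = group, abp_baseline = abp)
      simulate_hemodynamics(cfg, ca_parameters(ca_gain = gain), proto)
    }
    list(mk(1, "fentanyl", 1, 95), mk(2, "isoflurane", 0, 70))
  })
}
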