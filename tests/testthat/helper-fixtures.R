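# Shared fixture builders: tiny aligned series assembled in code, and a
# cached reduced-scale simulation so several test files can share one run.

make_aligned <- function(map, icp = rep(10, length(map)),
                         dcbf = rep(0, length(map)),
                         alpha_db = dcbf + 1,
                         beta_reject = rep(FALSE, length(map)),
                         sample_rate = 5, subject_id = "fix",
                         group = "fentanyl", markers = NULL) {
  structure(
    list(t = (seq_along(map) - 1) / sample_rate,
         map = map, icp = icp, cpp = map - icp,
         dcbf = dcbf, alpha_db = alpha_db,
         qc = list(beta_reject = beta_reject),
         sample_rate = sample_rate, markers = markers,
         subject_id = subject_id, group = group, pressure_only = FALSE),
    class = "aligned_series")
}

make_binned <- function(cpp, value, subject_id = "fix", group = "fentanyl") {
  structure(
    list(bin_width = 10, t_center = seq_along(cpp) * 10 - 5,
         map = cpp + 10, icp = rep(10, length(cpp)), cpp = cpp,
         dcbf = value, alpha_db = value,
         n = rep(50L, length(cpp)), n_valid = rep(50L, length(cpp)),
         cbf_outlier = rep(FALSE, length(cpp)),
         subject_id = subject_id, group = group),
    class = "binned_series")
}

markers_one <- function(t_start, t_end, kind, freq_hz, icp_target = 10) {
  data.frame(t_start = t_start, t_end = t_end, kind = kind,
             freq_hz = freq_hz, icp_target_mmhg = icp_target)
}

# Reduced-scale simulated recordings, cached across test files in the
# session's temporary directory.
sim_cache <- local({
  cache <- new.env(parent = emptyenv())
  function(key, builder) {
    if (!exists(key, envir = cache)) assign(key, builder(), envir = cache)
    get(key, envir = cache)
  }
})

small_phase_sim <- function(seed, ca_gain, modalities,
                            frequencies = c(0.009, 0.017),
                            icp_baselines = 6, abp_baseline = 95) {
  proto <- oscillation_protocol(frequencies = frequencies,
                                icp_baselines = icp_baselines,
                                modalities = modalities)
  cfg <- simulation_config(seed = seed, subject_id = paste0("sim", seed),
                           abp_baseline = abp_baseline)
  simulate_hemodynamics(cfg, ca_parameters(ca_gain = ca_gain), proto)
}

small_baseline_sim <- function(seed, ca_gain, abp_baseline,
                               icp_baselines = c(10, 12),
                               baseline_duration = 1500,
                               group = "fentanyl") {
  proto <- oscillation_protocol(icp_baselines = icp_baselines,
                                modalities = character(0))
  cfg <- simulation_config(seed = seed, subject_id = paste0("sim", seed),
                           group = group, abp_baseline = abp_baseline,
                           baseline_duration = baseline_duration)
  simulate_hemodynamics(cfg, ca_parameters(ca_gain = ca_gain), proto)
}
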