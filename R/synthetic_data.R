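# Seeded lumped-parameter cerebral-hemodynamics simulator with a tunable
# autoregulation state. Reproduces the study-style perturbation protocols
# (reservoir-driven ICP oscillations and baseline staircase, PEEP-driven
# ABP oscillations) so that the static, pseudo-dynamic and dynamic
# autoregulation pipelines can be exercised end to end without animal data.
#
# Model sketch (stepped at 100 Hz):
#   systemic MAP  = baseline (+ optional ramp) + Cushing coupling to ICP
#                   + PEEP coupling + slow Ornstein-Uhlenbeck waves
#   vascular tone = radius tracking the static autoregulation curve with a
#                   rate-sensitive first-order law, time constant
#                   1/(2 pi f_c); passive elastic distension always present
#   R ~ r^-4 (Poiseuille), CBV ~ r^2, CBF = CPP / R
#   ICP           = reservoir state (staircase + protocol sinusoids,
#                   first-order equilibration) + elastance * (CBV - CBV0)
#                   + pulsatile and stochastic components
#   waveforms     = cardiac pulse shaped so that max/min extrema satisfy
#                   MAP = 2/3 diastolic + 1/3 systolic, plus respiration
#                   and white measurement noise
#   DCS           = flow index proportional to CBF at 1 Hz with
#                   multiplicative noise; beta quality value with jitter
#                   and optional laser-instability artifacts

#' Autoregulation parameters for the simulator
#'
#' @param ca_gain Autoregulation state in [0, 1]: 1 = intact, 0 = pressure-
#'   passive. Intermediate values blend the static curve with the passive
#'   proportional line through the plateau point at 80 mmHg.
#' @param f_c Autoregulation cutoff frequency (Hz); the vascular tone time
#'   constant is `1/(2 pi f_c)`.
#' @param lla,ula Lower/upper limit of autoregulation (mmHg).
#' @param plateau_cbf Plateau flow level (normalized flow units).
#' @param below_lla_slope,above_ula_slope Static-curve slopes outside the
#'   plateau (flow units per mmHg).
#' @param lead_fraction Rate sensitivity of the tone response: the tracker
#'   is `(1 + a tau s) / (1 + tau s)` with `a` this fraction, modeling the
#'   fast myogenic component; 0 gives a pure first-order lag.
#' @param grubb_exponent Power-law exponent relating blood-volume to
#'   blood-flow changes; used only as a steady-state consistency check.
#' @return A `ca_parameters` list.
#' @export
ca_parameters <- function(ca_gain = 1, f_c = 0.03, lla = 60, ula = 100,
                          plateau_cbf = 1, below_lla_slope = 0.015,
                          above_ula_slope = 0.008, lead_fraction = 0.9,
                          grubb_exponent = 0.38) {
  stopifnot(ca_gain >= 0, ca_gain <= 1, lla < ula, f_c > 0)
  structure(list(ca_gain = ca_gain, f_c = f_c, lla = lla, ula = ula,
                 plateau_cbf = plateau_cbf,
                 below_lla_slope = below_lla_slope,
                 above_ula_slope = above_ula_slope,
                 lead_fraction = lead_fraction,
                 grubb_exponent = grubb_exponent),
            class = "ca_parameters")
}

#' Oscillation protocol description
#'
#' Defaults encode the study protocol: five frequencies in one fixed
#' randomized order, 5 mmHg reservoir-driven ICP oscillations of 4 cycles
#' (8 at the fastest 0.059 Hz), an ICP baseline staircase from 3 to
#' 40 mmHg, and PEEP-driven ABP oscillations (baseline 6 cmH2O, magnitude
#' 4 cmH2O) repeated at every baseline after the ICP set.
#'
#' @param frequencies Oscillation frequencies (Hz), in protocol order.
#' @param icp_magnitude Reservoir oscillation magnitude (mmHg).
#' @param cycles Oscillation cycles per frequency.
#' @param cycles_fast Cycles at the fastest frequency.
#' @param fast_frequency Frequency (Hz) that receives `cycles_fast`.
#' @param icp_baselines Target ICP baseline staircase (mmHg).
#' @param peep_baseline,peep_magnitude PEEP settings (cmH2O).
#' @param modalities Which oscillation families to run.
#' @return An `oscillation_protocol` list.
#' @export
oscillation_protocol <- function(frequencies = c(0.025, 0.059, 0.017,
                                                 0.033, 0.009),
                                 icp_magnitude = 5, cycles = 4,
                                 cycles_fast = 8, fast_frequency = 0.059,
                                 icp_baselines = c(3, 6, 9, 12, 15, 20,
                                                   30, 40),
                                 peep_baseline = 6, peep_magnitude = 4,
                                 modalities = c("icp_osc", "abp_osc")) {
  stopifnot(cycles >= 4, all(frequencies > 0))
  structure(list(frequencies = frequencies, icp_magnitude = icp_magnitude,
                 cycles = cycles, cycles_fast = cycles_fast,
                 fast_frequency = fast_frequency,
                 icp_baselines = icp_baselines,
                 peep_baseline = peep_baseline,
                 peep_magnitude = peep_magnitude,
                 modalities = modalities),
            class = "oscillation_protocol")
}

#' Simulator configuration
#'
#' Physiological operating points and noise scales. Defaults give an
#' intact-style operating point with CPP near the middle of the
#' autoregulatory plateau.
#'
#' @param seed Integer seed fixing every stochastic draw.
#' @param subject_id,group Identity attached to the emitted recording.
#' @param baseline_duration Settling time at each ICP baseline (s).
#' @param tail_duration Trailing baseline after the protocol (s).
#' @param segment_gap Quiet gap between oscillation segments (s).
#' @param sample_rate Pressure waveform rate (Hz).
#' @param dcs_rate Optical channel rate (Hz).
#' @param heart_rate,respiration_rate Cardiac and ventilation rates (Hz).
#' @param abp_baseline Systemic mean pressure operating point (mmHg).
#' @param map_ramp Optional length-2 offset (mmHg) added linearly to the
#'   baseline from start to end, for steady-state pressure sweeps.
#' @param pulse_pressure Systolic-minus-diastolic excursion (mmHg).
#' @param cushing_gain Systemic pressure rise per mmHg of ICP.
#' @param cushing_fast_fraction Fraction of the Cushing coupling that acts
#'   without the slow (tau 60 s) low-pass.
#' @param cushing_tau Slow Cushing time constant (s).
#' @param peep_coupling ABP change per cmH2O of PEEP.
#' @param icp_elastance ICP change per unit of relative blood-volume
#'   change (mmHg per CBV0).
#' @param passive_distension Passive radius strain per mmHg of perfusion
#'   pressure (always present; the only ABP-to-ICP path when `ca_gain = 0`).
#' @param icp_eq_tau Reservoir equilibration time constant (s).
#' @param alpha_db0 Baseline optical flow index (cm^2/s).
#' @param beta_nominal Nominal DCS quality value.
#' @param icp_pulse,resp_abp,resp_icp Pulsatile amplitudes (mmHg).
#' @param noise List of noise scales: white `abp`/`icp` (mmHg), slow-wave
#'   `map_ou_sd`/`map_ou_tau`, `icp_ou_sd`/`icp_ou_tau`, multiplicative
#'   `alpha_db_frac`, additive `beta_jitter`.
#' @param dcs_artifact_rate Laser-instability events per hour.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1, subject_id = "sim01",
                              group = c("fentanyl", "isoflurane"),
                              baseline_duration = 600, tail_duration = 600,
                              segment_gap = 60,
                              sample_rate = 100, dcs_rate = 1,
                              heart_rate = 2, respiration_rate = 0.25,
                              abp_baseline = 95, map_ramp = NULL,
                              pulse_pressure = 30,
                              cushing_gain = 0.3,
                              cushing_fast_fraction = 0.8,
                              cushing_tau = 60,
                              peep_coupling = 1.8, icp_elastance = 120,
                              passive_distension = 5e-4, icp_eq_tau = 5,
                              alpha_db0 = 2e-8, beta_nominal = 0.5,
                              icp_pulse = 1.5, resp_abp = 2, resp_icp = 0.5,
                              noise = list(), dcs_artifact_rate = 0) {
  group <- match.arg(group)
  stopifnot(baseline_duration >= 600)
  noise_def <- list(abp = 1, icp = 0.3, map_ou_sd = 3, map_ou_tau = 30,
                    icp_ou_sd = 0.3, icp_ou_tau = 20,
                    alpha_db_frac = 0.05, beta_jitter = 0.005)
  noise <- utils::modifyList(noise_def, noise)
  structure(list(seed = as.integer(seed), subject_id = subject_id,
                 group = group,
                 baseline_duration = baseline_duration,
                 tail_duration = tail_duration, segment_gap = segment_gap,
                 sample_rate = sample_rate, dcs_rate = dcs_rate,
                 heart_rate = heart_rate,
                 respiration_rate = respiration_rate,
                 abp_baseline = abp_baseline, map_ramp = map_ramp,
                 pulse_pressure = pulse_pressure,
                 cushing_gain = cushing_gain,
                 cushing_fast_fraction = cushing_fast_fraction,
                 cushing_tau = cushing_tau,
                 peep_coupling = peep_coupling,
                 icp_elastance = icp_elastance,
                 passive_distension = passive_distension,
                 icp_eq_tau = icp_eq_tau, alpha_db0 = alpha_db0,
                 beta_nominal = beta_nominal, icp_pulse = icp_pulse,
                 resp_abp = resp_abp, resp_icp = resp_icp, noise = noise,
                 dcs_artifact_rate = dcs_artifact_rate),
            class = "simulation_config")
}

#' Steady-state autoregulation curve
#'
#' Piecewise-linear Lassen-style flow curve: rising below the lower limit,
#' flat across the plateau, rising above the upper limit. With gain g the
#' effective curve is `g * piecewise + (1 - g) * passive`, the passive
#' component being the proportional line through the plateau value at
#' 80 mmHg.
#'
#' @param cpp Perfusion pressure (mmHg), vectorized.
#' @param p A `ca_parameters` object.
#' @return Steady-state flow (normalized units).
#' @export
static_cbf_curve <- function(cpp, p) {
  pw <- p$plateau_cbf + p$below_lla_slope * pmin(cpp - p$lla, 0) +
    p$above_ula_slope * pmax(cpp - p$ula, 0)
  passive <- cpp * (p$plateau_cbf / 80)
  p$ca_gain * pw + (1 - p$ca_gain) * passive
}

#' Build the protocol timeline
#'
#' Emits the event markers: one baseline marker per staircase level,
#' followed at that level by the ICP-oscillation segments in protocol
#' order and then the PEEP (ABP) segments in the same order. Segment
#' duration is `cycles / frequency`.
#'
#' @param proto An `oscillation_protocol`.
#' @param cfg A `simulation_config` (supplies settling and gap durations).
#' @return Data frame of markers (`t_start`, `t_end`, `kind`, `freq_hz`,
#'   `icp_target_mmhg`) with attribute `duration` (total protocol span, s).
#' @export
build_protocol <- function(proto, cfg = simulation_config()) {
  rows <- list()
  t <- 0
  for (lvl in proto$icp_baselines) {
    rows[[length(rows) + 1]] <- data.frame(
      t_start = t, t_end = t + cfg$baseline_duration, kind = "baseline",
      freq_hz = 0, icp_target_mmhg = lvl)
    t <- t + cfg$baseline_duration
    for (mod in proto$modalities) {
      for (f in proto$frequencies) {
        t <- t + cfg$segment_gap
        ncyc <- if (abs(f - proto$fast_frequency) < 1e-12) {
          proto$cycles_fast
        } else {
          proto$cycles
        }
        dur <- ncyc / f
        rows[[length(rows) + 1]] <- data.frame(
          t_start = t, t_end = t + dur, kind = mod, freq_hz = f,
          icp_target_mmhg = lvl)
        t <- t + dur
      }
    }
  }
  mk <- do.call(rbind, rows)
  attr(mk, "duration") <- t + cfg$tail_duration
  mk
}

# Stationary AR(1) sampled from a seeded generator: discretized
# Ornstein-Uhlenbeck slow-wave noise.
ou_noise <- function(n, sd, tau, dt) {
  if (sd == 0) return(numeric(n))
  phi <- exp(-dt / tau)
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  e[1] <- stats::rnorm(1, 0, sd)
  as.numeric(stats::filter(e, phi, method = "recursive"))
}

#' Simulate a full multimodal recording
#'
#' Steps the coupled systemic/cerebrovascular model at the waveform rate
#' and emits a complete `raw_recording` (pressure waveforms, optical flow
#' index and quality value, vitals, anesthesia log, protocol markers). All
#' randomness comes from `cfg$seed`: identical inputs give bit-identical
#' recordings.
#'
#' @param cfg A `simulation_config`.
#' @param p A `ca_parameters` object.
#' @param proto An `oscillation_protocol`.
#' @return A `raw_recording`.
#' @export
simulate_hemodynamics <- function(cfg = simulation_config(),
                                  p = ca_parameters(),
                                  proto = oscillation_protocol()) {
  set.seed(cfg$seed)
  markers <- build_protocol(proto, cfg)
  dur <- attr(markers, "duration")
  dt <- 1 / cfg$sample_rate
  n <- as.integer(round(dur / dt))
  t <- (seq_len(n) - 1) * dt

  # --- protocol forcing (vectorized) ---------------------------------
  icp_target <- rep(proto$icp_baselines[1], n)
  bl <- markers[markers$kind == "baseline", , drop = FALSE]
  for (j in seq_len(nrow(bl))) {
    icp_target[t >= bl$t_start[j]] <- bl$icp_target_mmhg[j]
  }
  peep_drive <- numeric(n) # mmHg contribution to systemic pressure
  osc <- markers[markers$kind != "baseline", , drop = FALSE]
  for (j in seq_len(nrow(osc))) {
    seg <- t >= osc$t_start[j] & t < osc$t_end[j]
    w <- sin(2 * pi * osc$freq_hz[j] * (t[seg] - osc$t_start[j]))
    if (osc$kind[j] == "icp_osc") {
      icp_target[seg] <- icp_target[seg] + proto$icp_magnitude * w
    } else {
      peep_drive[seg] <- cfg$peep_coupling * proto$peep_magnitude * w
    }
  }
  base_drift <- if (is.null(cfg$map_ramp)) {
    numeric(n)
  } else {
    seq(cfg$map_ramp[1], cfg$map_ramp[2], length.out = n)
  }
  ou_map <- ou_noise(n, cfg$noise$map_ou_sd, cfg$noise$map_ou_tau, dt)
  ou_icp <- ou_noise(n, cfg$noise$icp_ou_sd, cfg$noise$icp_ou_tau, dt)

  # --- reference operating point -------------------------------------
  icp0 <- proto$icp_baselines[1]
  map0 <- (cfg$abp_baseline + base_drift[1] + cfg$cushing_gain * icp0)
  cpp0 <- map0 - icp0
  if (cpp0 <= 5) {
    stop("configuration yields non-positive CPP at the operating point; ",
         "adjust the baselines")
  }
  cbf0 <- static_cbf_curve(cpp0, p)
  R0 <- cpp0 / cbf0

  # --- sequential state loop -----------------------------------------
  a_res <- dt / cfg$icp_eq_tau
  a_lp <- dt / cfg$cushing_tau
  a_ca <- dt * 2 * pi * p$f_c
  lead <- p$lead_fraction
  wfast <- cfg$cushing_fast_fraction
  cg <- cfg$cushing_gain
  cdist <- cfg$passive_distension
  E <- cfg$icp_elastance
  g <- p$ca_gain
  plateau <- p$plateau_cbf
  lla <- p$lla; ula <- p$ula
  s_lo <- p$below_lla_slope; s_hi <- p$above_ula_slope

  map_sys <- numeric(n); icp_slow <- numeric(n); cbf <- numeric(n)
  cbv <- numeric(n)
  icp_res <- icp0
  lp <- icp0
  r <- 1
  u_prev <- 1
  icp_prev <- icp0
  abp_b <- cfg$abp_baseline
  for (i in seq_len(n)) {
    icp_res <- icp_res + a_res * (icp_target[i] - icp_res)
    lp <- lp + a_lp * (icp_prev - lp)
    m <- abp_b + base_drift[i] + cg * (wfast * icp_prev + (1 - wfast) * lp) +
      peep_drive[i] + ou_map[i]
    cpp <- m - icp_prev
    cpp_f <- if (cpp < 5) 5 else cpp
    # static-curve tone target (inlined static_cbf_curve + Poiseuille map)
    dl <- cpp_f - lla; du <- cpp_f - ula
    pw <- plateau + s_lo * (if (dl < 0) dl else 0) +
      s_hi * (if (du > 0) du else 0)
    cbf_t <- g * pw + (1 - g) * cpp_f * (plateau / 80)
    dist <- 1 + cdist * (cpp - cpp0)
    if (g > 0) {
      # active tone targets the total radius achieving the static curve,
      # net of the instantaneous passive distension it rides on
      u <- (R0 * cbf_t / cpp_f)^0.25 / dist
      r <- r + a_ca * (u - r) + lead * (u - u_prev)
      u_prev <- u
    }
    rr <- r * dist
    cbv_i <- rr * rr
    ic <- icp_res + E * (cbv_i - 1) + ou_icp[i]
    map_sys[i] <- m
    icp_slow[i] <- ic
    cbf[i] <- cpp / (R0 / (rr^4))
    cbv[i] <- cbv_i
    icp_prev <- ic
  }
  if (mean((map_sys - icp_slow) <= 0) > 0.01) {
    stop("configuration yields non-positive CPP for more than 1% of ",
         "samples; adjust the operating point")
  }

  # --- measurement-level waveforms -----------------------------------
  ph_card <- 2 * pi * cfg$heart_rate * t
  ph_resp <- 2 * pi * cfg$respiration_rate * t
  # cardiac shape with extrema at +2/3 and -1/3 of pulse pressure so that
  # the clinical MAP formula recovers the systemic mean exactly
  shape <- ((1 + cos(ph_card)) / 2)^2 - 1 / 3
  abp <- map_sys + cfg$pulse_pressure * shape +
    cfg$resp_abp * sin(ph_resp) + stats::rnorm(n, 0, cfg$noise$abp)
  icp <- icp_slow + cfg$icp_pulse * sin(ph_card) +
    cfg$resp_icp * sin(ph_resp) + stats::rnorm(n, 0, cfg$noise$icp)

  # --- optical channel at dcs_rate -----------------------------------
  stride <- as.integer(round(cfg$sample_rate / cfg$dcs_rate))
  di <- seq(1, n, by = stride)
  alpha <- cfg$alpha_db0 * (cbf[di] / cbf0) *
    (1 + stats::rnorm(length(di), 0, cfg$noise$alpha_db_frac))
  beta <- cfg$beta_nominal + stats::rnorm(length(di), 0,
                                          cfg$noise$beta_jitter)

  # --- vitals and anesthesia log -------------------------------------
  vt <- seq(0, dur - 1, by = 30)
  hr_bpm <- cfg$heart_rate * 60 + stats::rnorm(length(vt), 0, 2)
  etco2 <- 38 + 1.5 * sin(2 * pi * vt / 1800) +
    stats::rnorm(length(vt), 0, 0.8)
  at <- seq(0, dur - 1, by = 900)
  anes <- if (cfg$group == "isoflurane") {
    data.frame(t = at, isoflurane_pct = 2 + stats::rnorm(length(at), 0, 0.1),
               fentanyl_ug_kg_hr = 0)
  } else {
    data.frame(t = at,
               isoflurane_pct = 0.8 + stats::rnorm(length(at), 0, 0.05),
               fentanyl_ug_kg_hr = 20)
  }

  rec <- raw_recording(
    cfg$subject_id, cfg$group,
    channels = list(
      abp = list(t = t, v = abp, units = "mmHg"),
      icp = list(t = t, v = icp, units = "mmHg"),
      alpha_db = list(t = t[di], v = alpha, units = "cm^2/s"),
      beta = list(t = t[di], v = beta, units = "")),
    markers = markers,
    vitals = data.frame(t = vt, heart_rate_bpm = hr_bpm,
                        etco2_mmhg = etco2),
    anesthesia_log = anes)
  if (cfg$dcs_artifact_rate > 0) {
    rec <- inject_dcs_artifacts(rec, cfg$dcs_artifact_rate,
                                seed = cfg$seed + 10000L)
  }
  rec
}

#' Inject laser-instability artifacts into the optical channel
#'
#' Draws a Poisson number of events for the recording duration; each event
#' depresses the quality value well below the median-minus-0.01 rejection
#' threshold with high-variance jitter and corrupts the co-timed flow
#' index with 50% multiplicative noise, for a random 5-30 s stretch.
#'
#' @param rec A `raw_recording` with a beta channel.
#' @param rate Events per hour.
#' @param seed Seed for the artifact draws.
#' @return The corrupted `raw_recording`.
#' @export
inject_dcs_artifacts <- function(rec, rate, seed = 1L) {
  if (!("beta" %in% names(rec$channels))) stop("no beta channel present")
  if (rate <= 0) return(rec)
  set.seed(seed)
  bt <- rec$channels$beta$t
  dur <- bt[length(bt)] - bt[1]
  k <- stats::rpois(1, rate * dur / 3600)
  if (k == 0) return(rec)
  med <- stats::median(rec$channels$beta$v)
  starts <- stats::runif(k, bt[1], bt[length(bt)] - 30)
  lens <- stats::runif(k, 5, 30)
  for (j in seq_len(k)) {
    idx <- which(bt >= starts[j] & bt <= starts[j] + lens[j])
    if (length(idx) == 0) next
    rec$channels$beta$v[idx] <- med - 0.05 +
      stats::rnorm(length(idx), 0, 0.015)
    rec$channels$alpha_db$v[idx] <- rec$channels$alpha_db$v[idx] *
      pmax(1 + stats::rnorm(length(idx), 0, 0.5), 0.05)
  }
  rec
}
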