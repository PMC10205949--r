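# Deterministic piecewise sessions with known metrics, built in code.
#
# The injection arm jumps to `peak` at t = t_peak and sits at `plateau_in`
# afterwards; the contralateral arm sits at `plateau_con` from t_peak on.
# Every metric is then known in closed form: dr_in_max = peak,
# dr_in_mean = plateau_in, delta_r = plateau_in - plateau_con.
toy_session <- function(peak = 1000, plateau_in = 100, plateau_con = 80,
                        t_peak = 120, duration = 700, a_in = 200) {
  t <- 0:duration
  inj <- ifelse(t < t_peak, 1, ifelse(t == t_peak, peak, plateau_in))
  con <- ifelse(t < t_peak, 1, plateau_con)
  administration_session(
    patient_id = "toy", injected_activity = a_in,
    injection_curve = dose_rate_curve(t, inj, "injection"),
    contralateral_curve = dose_rate_curve(t, con, "contralateral"),
    min_overlap = 120)
}

# brute-force plateau scan: first start index whose full stability window
# satisfies the consecutive-change criterion (independent of the cumsum
# trick used by detect_plateau)
brute_plateau <- function(times, values, tol = 15, dur = 60) {
  dt <- median(diff(times))
  n_pairs <- max(1, round(dur / dt))
  for (i in seq_len(length(values) - n_pairs)) {
    seg <- values[i:(i + n_pairs)]
    if (all(abs(diff(seg)) <= tol)) return(times[i])
  }
  NA_real_
}

# brute-force relative-threshold segmentation by explicit voxel loops
brute_segment <- function(values, voxel_size, fraction) {
  peak <- max(values)
  sel <- c()
  for (i in seq_along(values)) {
    if (values[i] >= fraction * peak) sel <- c(sel, values[i])
  }
  list(volume = length(sel) * prod(rep_len(voxel_size, 3)) / 1000,
       mean_concentration = mean(sel))
}

# Table of the paper-era dosimetry fixture shipped with the package
ship_dose_table <- function() {
  read_dose_table(system.file("extdata", "sphere_dose_factors_f18.csv",
                              package = "extrawatch"))
}
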