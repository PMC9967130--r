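# Shared fixtures: small cohorts and hand-built runs, generated in code.

# a fast 5-group cohort for unit tests
small_design <- function(seed = 1, ...) {
  args <- list(...)
  defaults <- list(n_proteins = 12L, n_planted = 3L,
                   peptides_per_protein = c(3L, 3L),
                   rt_range_s = c(300, 900), seed = seed)
  do.call(cohort_design, utils::modifyList(defaults, args))
}

# identity-drift, unit-bias, noise-free variant of a design
clean_design <- function(seed = 1, ...) {
  d0 <- small_design(seed = seed)
  base <- list(
    seed = seed,
    rt_drift_spec = data.frame(run_id = d0$run_id, slope = 1, offset = 0),
    intensity_bias_spec = setNames(rep(1, length(d0$run_id)), d0$run_id),
    noise_cv = 0, mz_jitter_ppm = 0, outlier_fraction = 0,
    ms2_sampling_rate = 1)
  do.call(small_design, utils::modifyList(base, list(...)))
}

# hand-built run: scans at given RTs, peaks as data.frame(scan_id, mz, intensity)
make_run <- function(run_id, rt, peaks = NULL, ms2 = NULL) {
  ms1 <- data.frame(scan_id = seq_along(rt), rt_seconds = rt)
  if (is.null(peaks))
    peaks <- data.frame(scan_id = integer(0), mz = numeric(0),
                        intensity = numeric(0))
  if (is.null(ms2))
    ms2 <- data.frame(scan_id = integer(0), rt_seconds = numeric(0),
                      precursor_mz = numeric(0), precursor_intensity = numeric(0),
                      precursor_scan_id = integer(0))
  spectrum_run(run_id, ms1, peaks, ms2)
}

# run with one Gaussian peptide peak per (mz, apex) pair
gaussian_run <- function(run_id, mz, apex, amp, rt = seq(0, 600, by = 2),
                         sigma = 6) {
  pk <- do.call(rbind, lapply(seq_along(mz), function(i) {
    sel <- abs(rt - apex[i]) <= 3 * sigma
    data.frame(scan_id = which(sel), mz = mz[i],
               intensity = amp[i] * exp(-(rt[sel] - apex[i])^2 / (2 * sigma^2)))
  }))
  ms2 <- data.frame(scan_id = length(rt) + seq_along(mz),
                    rt_seconds = apex,
                    precursor_mz = mz, precursor_intensity = amp,
                    precursor_scan_id = vapply(apex, function(a)
                      which.min(abs(rt - a)), integer(1)))
  make_run(run_id, rt, pk, ms2)
}

# brute-force frame area: explicit loop over all scans and peaks
brute_frame_area <- function(run, mz_center, rt_center, ppm = 10,
                             rt_window_s = 60) {
  rts <- run$ms1$rt_seconds
  cycle <- if (length(rts) > 1) median(diff(rts)) else 1
  in_rt <- which(abs(rts - rt_center) <= rt_window_s / 2)
  if (!length(in_rt)) return(0)
  trace <- vapply(in_rt, function(s) {
    sel <- run$peaks$scan_id == run$ms1$scan_id[s] &
      abs(run$peaks$mz - mz_center) / mz_center * 1e6 <= ppm
    if (any(sel)) max(run$peaks$intensity[sel]) else 0
  }, numeric(1))
  if (length(in_rt) == 1) return(trace * cycle)
  sum(0.5 * (trace[-1] + trace[-length(trace)]) * diff(rts[in_rt]))
}
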