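#' Design of a synthetic LC-MS exosome cohort
#'
#' Describes a multi-group, replicated DDA LC-MS cohort with known ground
#' truth: per-protein fold changes relative to a control group, per-run
#' monotone retention-time drift, per-run global intensity bias, stochastic
#' MS2 sampling (so some runs lack an identification for a given precursor),
#' "outlier" peptides whose abundance profile is decoupled from their
#' protein, and multiplicative measurement noise.
#'
#' The default design emulates a five-cell-line exosome study: a
#' non-tumorigenic control (`EpH4`), a tumorigenic non-metastatic line
#' (`116`), a primary-site metastatic line (`1424`) and its kidney- and
#' lung-metastasis derivatives (`1424.1`, `1424.2`), four replicates each,
#' 200 proteins with 5 peptides per protein, 20 proteins planted at
#' |log2 fold change| = 1 in a random subset of tumor groups, 1% outlier
#' peptides, per-run bias in \[0.5, 2\], linear RT drift up to +/-60 s, and
#' a biological coefficient of variation of 0.15.
#'
#' Noise has two multiplicative log-normal components: `noise_cv` acts per
#' protein and run (shared by all peptides of the protein, emulating
#' biological replicate variability, so protein-level intra-group CV tracks
#' `noise_cv`), and `peptide_noise_cv` (default `noise_cv / 3`) acts per
#' peptide and run (measurement jitter seen by the peptide outlier
#' detector). Setting `noise_cv = 0` therefore gives a fully noise-free
#' cohort.
#'
#' @param groups Ordered character vector of group labels; first is control
#'   unless `control_group` says otherwise.
#' @param control_group,non_metastatic_group,metastatic_groups Group roles
#'   used to derive the ground-truth altered / metastasis-specific sets.
#' @param replicates_per_group Runs per group (>= 2).
#' @param n_proteins,peptides_per_protein Proteome size; the latter is a
#'   length-2 inclusive range (min >= 2).
#' @param fold_change_spec Optional proteins x groups matrix of true linear
#'   fold changes vs control (control column must be 1). If `NULL`, a
#'   default is drawn: `n_planted` proteins at `2^(+/-planted_log2fc)` in a
#'   random non-empty subset of tumor groups.
#' @param n_planted,planted_log2fc Default fold-change plant (see above).
#' @param rt_drift_spec Optional data.frame (`run_id`, `slope`, `offset`)
#'   mapping reference RT to run RT as `slope * rt + offset`; slopes > 0.
#'   Default: slope in \[0.99, 1.01\], offset in \[-60, 60\] s.
#' @param intensity_bias_spec Optional named numeric of per-run global
#'   multiplicative factors (> 0). Default: log-uniform in \[0.5, 2\].
#' @param ms2_sampling_rate Probability in (0, 1] that a precursor receives
#'   an MS2 identification in a given run.
#' @param outlier_fraction Fraction of peptides given an independent random
#'   group profile.
#' @param noise_cv,peptide_noise_cv Multiplicative noise CVs (see Details).
#' @param mz_jitter_ppm Gaussian m/z error (ppm, 1 sd) applied to peak and
#'   precursor m/z.
#' @param rt_range_s Reference retention-time span of the gradient (s).
#' @param elution_sigma_s Gaussian elution peak width (1 sd, s).
#' @param cycle_s MS1 cycle time (s).
#' @param seed Integer seed; the design and everything simulated from it
#'   are deterministic functions of the arguments.
#' @return An object of class `cohort_design`.
#' @seealso [simulate_cohort()]
#' @export
cohort_design <- function(groups = c("EpH4", "116", "1424", "1424.1", "1424.2"),
                          control_group = groups[1],
                          non_metastatic_group = "116",
                          metastatic_groups = c("1424", "1424.1", "1424.2"),
                          replicates_per_group = 4L,
                          n_proteins = 200L,
                          peptides_per_protein = c(5L, 5L),
                          fold_change_spec = NULL,
                          n_planted = 20L,
                          planted_log2fc = 1,
                          rt_drift_spec = NULL,
                          intensity_bias_spec = NULL,
                          ms2_sampling_rate = 0.7,
                          outlier_fraction = 0.01,
                          noise_cv = 0.15,
                          peptide_noise_cv = noise_cv / 3,
                          mz_jitter_ppm = 1.5,
                          rt_range_s = c(300, 3000),
                          elution_sigma_s = 6,
                          cycle_s = 2,
                          seed = 1L) {
  if (replicates_per_group < 2)
    .stopf("replicates_per_group must be >= 2 (ANOVA needs within-group variance)")
  if (length(groups) < 2 || anyDuplicated(groups))
    .stopf("groups must be >= 2 distinct labels")
  if (!control_group %in% groups) .stopf("control_group not in groups")
  if (length(peptides_per_protein) == 1)
    peptides_per_protein <- rep(peptides_per_protein, 2)
  if (peptides_per_protein[1] < 2)
    .stopf("peptides_per_protein minimum must be >= 2")
  if (ms2_sampling_rate <= 0 || ms2_sampling_rate > 1)
    .stopf("ms2_sampling_rate must be in (0, 1]")
  if (outlier_fraction < 0 || outlier_fraction >= 1)
    .stopf("outlier_fraction must be in [0, 1)")
  if (noise_cv < 0 || peptide_noise_cv < 0) .stopf("noise CVs must be >= 0")

  tumor_groups <- setdiff(groups, control_group)
  proteins <- sprintf("P%04d", seq_len(n_proteins))
  run_id <- as.vector(t(outer(groups, seq_len(replicates_per_group),
                              function(g, r) paste(g, r, sep = "_"))))
  run_group <- rep(groups, each = replicates_per_group)
  names(run_group) <- run_id

  defaults <- with_seed(seed, {
    fc <- NULL
    if (is.null(fold_change_spec)) {
      if (n_planted > n_proteins)
        .stopf("n_planted exceeds n_proteins")
      fc <- matrix(1, n_proteins, length(groups),
                   dimnames = list(proteins, groups))
      if (n_planted > 0) {
        planted <- sort(sample.int(n_proteins, n_planted))
        for (i in planted) {
          k <- which(runif(length(tumor_groups)) < 0.5)
          if (!length(k)) k <- sample.int(length(tumor_groups), 1)
          fc[i, tumor_groups[k]] <- 2^(sample(c(-1, 1), 1) * planted_log2fc)
        }
      }
    }
    drift <- data.frame(run_id = run_id,
                        slope = runif(length(run_id), 0.99, 1.01),
                        offset = runif(length(run_id), -60, 60))
    bias <- exp(runif(length(run_id), log(0.5), log(2)))
    names(bias) <- run_id
    list(fc = fc, drift = drift, bias = bias)
  })
  if (is.null(fold_change_spec)) fold_change_spec <- defaults$fc
  if (is.null(rt_drift_spec)) rt_drift_spec <- defaults$drift
  if (is.null(intensity_bias_spec)) intensity_bias_spec <- defaults$bias

  fold_change_spec <- as.matrix(fold_change_spec)
  if (any(fold_change_spec <= 0)) .stopf("all fold changes must be > 0")
  if (any(fold_change_spec[, control_group] != 1))
    .stopf("control group's fold change must be 1 for every protein")
  if (any(rt_drift_spec$slope <= 0))
    .stopf("drift functions must be strictly increasing (slope > 0)")
  if (any(intensity_bias_spec <= 0)) .stopf("intensity bias must be > 0")

  structure(list(
    groups = groups, control_group = control_group,
    non_metastatic_group = non_metastatic_group,
    metastatic_groups = metastatic_groups,
    replicates_per_group = as.integer(replicates_per_group),
    run_id = run_id, run_group = run_group,
    proteins = rownames(fold_change_spec),
    n_proteins = nrow(fold_change_spec),
    peptides_per_protein = as.integer(peptides_per_protein),
    fold_change_spec = fold_change_spec,
    rt_drift_spec = rt_drift_spec,
    intensity_bias_spec = intensity_bias_spec,
    ms2_sampling_rate = ms2_sampling_rate,
    outlier_fraction = outlier_fraction,
    noise_cv = noise_cv, peptide_noise_cv = peptide_noise_cv,
    mz_jitter_ppm = mz_jitter_ppm,
    rt_range_s = rt_range_s, elution_sigma_s = elution_sigma_s,
    cycle_s = cycle_s, seed = as.integer(seed)
  ), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat(sprintf("cohort_design: %d groups x %d replicates, %d proteins, seed %d\n",
              length(x$groups), x$replicates_per_group, x$n_proteins, x$seed))
  invisible(x)
}

# log-normal with unit mean and given coefficient of variation
.rlnorm_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' One LC-MS run
#'
#' A lightweight container for a centroided DDA run: MS1 scans (retention
#' time plus peak list) and MS2 precursor events linked to their MS1 scan.
#'
#' @param run_id Character scalar.
#' @param ms1 data.frame with `scan_id`, `rt_seconds` (strictly increasing).
#' @param peaks data.frame with `scan_id`, `mz`, `intensity` (>= 0); zero or
#'   more rows per MS1 scan.
#' @param ms2 data.frame with `scan_id`, `rt_seconds`, `precursor_mz`,
#'   `precursor_intensity`, `precursor_scan_id`.
#' @param group Optional group label.
#' @return An object of class `spectrum_run`.
#' @export
spectrum_run <- function(run_id, ms1, peaks, ms2, group = NA_character_) {
  if (nrow(ms1) < 1) .stopf("run '%s' has no MS1 scans", run_id)
  if (is.unsorted(ms1$rt_seconds, strictly = TRUE))
    .stopf("run '%s': MS1 retention times must be strictly increasing", run_id)
  if (nrow(peaks) && any(peaks$intensity < 0))
    .stopf("run '%s': negative peak intensity", run_id)
  if (nrow(peaks) && !all(peaks$scan_id %in% ms1$scan_id))
    .stopf("run '%s': peak references unknown MS1 scan", run_id)
  structure(list(run_id = run_id, group = group, ms1 = ms1,
                 peaks = peaks, ms2 = ms2),
            class = "spectrum_run")
}

#' @export
print.spectrum_run <- function(x, ...) {
  cat(sprintf("spectrum_run '%s': %d MS1 scans (%d peaks), %d MS2 events, RT %.0f-%.0f s\n",
              x$run_id, nrow(x$ms1), nrow(x$peaks), nrow(x$ms2),
              min(x$ms1$rt_seconds), max(x$ms1$rt_seconds)))
  invisible(x)
}

.random_peptides <- function(n) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(aa, sample(9:15, 1), replace = TRUE), collapse = ""),
    character(1))
  while (anyDuplicated(seqs)) {
    d <- which(duplicated(seqs))
    seqs[d] <- vapply(d, function(i)
      paste(sample(aa, sample(9:15, 1), replace = TRUE), collapse = ""),
      character(1))
  }
  seqs
}

#' Simulate a DDA LC-MS cohort with ground truth
#'
#' Generates one `spectrum_run` per cohort run, the matching filtered PSM
#' table, and a `ground_truth` record. Each peptide elutes as a Gaussian
#' (width `elution_sigma_s`) sampled on the run's MS1 cycle; peak
#' intensities carry the protein's group fold change, the run's global
#' bias, and multiplicative noise; scan times carry the run's linear drift
#' (`rt_run = slope * rt_ref + offset`). Where a precursor is "sampled"
#' (probability `ms2_sampling_rate`), an MS2 event is placed at the peak
#' apex and a PSM row is emitted, so runs differ in which peptides carry
#' identifications — the run-to-run missingness the frame pipeline is built
#' to remove.
#'
#' @param design A [cohort_design()].
#' @return A list with components `runs` (list of [spectrum_run()]),
#'   `psm_table` (data.frame in the documented PSM schema) and `truth`
#'   (class `ground_truth`: true fold-change matrix, outlier peptide set,
#'   drift and bias parameters, and the implied `true_altered` /
#'   `true_metastasis_specific` accession sets).
#' @examples
#' d <- cohort_design(n_proteins = 10, n_planted = 2, seed = 7)
#' sim <- simulate_cohort(d)
#' sim$runs[[1]]
#' head(sim$psm_table)
#' @export
simulate_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  with_seed(design$seed + 1L, .simulate_cohort_impl(design))
}

.simulate_cohort_impl <- function(design) {
  d <- design
  n_prot <- d$n_proteins
  npp <- if (d$peptides_per_protein[1] == d$peptides_per_protein[2])
    rep(d$peptides_per_protein[1], n_prot)
  else sample(seq(d$peptides_per_protein[1], d$peptides_per_protein[2]),
              n_prot, replace = TRUE)
  n_pep <- sum(npp)
  pep_protein <- rep(d$proteins, npp)
  pep_seq <- .random_peptides(n_pep)
  pep_mz <- runif(n_pep, 400, 1500)
  pep_rt <- runif(n_pep, d$rt_range_s[1] + 30, d$rt_range_s[2] - 30)
  pep_base <- rlnorm(n_pep, meanlog = 20, sdlog = 1.5)

  # outlier peptides: independent random tumor-group profile
  n_out <- round(d$outlier_fraction * n_pep)
  out_idx <- if (n_out > 0) sort(sample.int(n_pep, n_out)) else integer(0)
  tumor_groups <- setdiff(d$groups, d$control_group)
  pep_fc <- d$fold_change_spec[pep_protein, , drop = FALSE]
  rownames(pep_fc) <- NULL
  for (i in out_idx)
    pep_fc[i, tumor_groups] <- 2^runif(length(tumor_groups), -2, 2)

  runs_n <- length(d$run_id)
  noise_prot <- matrix(.rlnorm_cv(n_prot * runs_n, d$noise_cv), n_prot, runs_n,
                       dimnames = list(d$proteins, d$run_id))
  noise_pep <- matrix(.rlnorm_cv(n_pep * runs_n, d$peptide_noise_cv),
                      n_pep, runs_n)
  half <- 3 * d$elution_sigma_s

  runs <- vector("list", runs_n)
  names(runs) <- d$run_id
  psm <- vector("list", runs_n)
  for (r in seq_len(runs_n)) {
    rid <- d$run_id[r]
    grp <- d$run_group[[rid]]
    slope <- d$rt_drift_spec$slope[d$rt_drift_spec$run_id == rid]
    offset <- d$rt_drift_spec$offset[d$rt_drift_spec$run_id == rid]
    amp <- pep_base * pep_fc[, grp] * d$intensity_bias_spec[[rid]] *
      noise_prot[pep_protein, r] * noise_pep[, r]
    t0 <- slope * d$rt_range_s[1] + offset
    t1 <- slope * d$rt_range_s[2] + offset
    scan_rt <- seq(t0, t1, by = d$cycle_s)
    n_scan <- length(scan_rt)
    apex <- slope * pep_rt + offset
    k0 <- pmax(1L, as.integer(ceiling((apex - half - t0) / d$cycle_s)) + 1L)
    k1 <- pmin(n_scan, as.integer(floor((apex + half - t0) / d$cycle_s)) + 1L)
    nk <- pmax(0L, k1 - k0 + 1L)
    scan_of_peak <- sequence(nk, from = k0)
    pep_of_peak <- rep.int(seq_len(n_pep), nk)
    t_pk <- scan_rt[scan_of_peak]
    inten <- amp[pep_of_peak] *
      exp(-(t_pk - apex[pep_of_peak])^2 / (2 * d$elution_sigma_s^2))
    mz_pk <- pep_mz[pep_of_peak]
    if (d$mz_jitter_ppm > 0)
      mz_pk <- mz_pk * (1 + rnorm(length(mz_pk), 0, d$mz_jitter_ppm * 1e-6))
    ms1 <- data.frame(scan_id = seq_len(n_scan), rt_seconds = scan_rt)
    peaks <- data.frame(scan_id = scan_of_peak, mz = mz_pk, intensity = inten)

    sampled <- which(runif(n_pep) < d$ms2_sampling_rate)
    prec_scan <- pmin(n_scan, pmax(1L,
      as.integer(round((apex[sampled] - t0) / d$cycle_s)) + 1L))
    prec_mz <- pep_mz[sampled]
    if (d$mz_jitter_ppm > 0)
      prec_mz <- prec_mz * (1 + rnorm(length(prec_mz), 0, d$mz_jitter_ppm * 1e-6))
    ms2 <- data.frame(
      scan_id = n_scan + seq_along(sampled),
      rt_seconds = scan_rt[prec_scan],
      precursor_mz = prec_mz,
      precursor_intensity = amp[sampled] *
        exp(-(scan_rt[prec_scan] - apex[sampled])^2 / (2 * d$elution_sigma_s^2)),
      precursor_scan_id = prec_scan)
    runs[[r]] <- spectrum_run(rid, ms1, peaks, ms2, group = grp)
    psm[[r]] <- data.frame(
      run_id = rid, ms2_scan_id = ms2$scan_id,
      peptide = pep_seq[sampled], charge = 2L,
      protein_accession = pep_protein[sampled], is_unique = TRUE)
  }
  psm_table <- do.call(rbind, psm)
  psm_table <- cbind(psm_id = sprintf("PSM%06d", seq_len(nrow(psm_table))),
                     psm_table)
  rownames(psm_table) <- NULL

  truth <- ground_truth(d, outlier_peptides = pep_seq[out_idx])
  truth$peptide_map <- data.frame(peptide = pep_seq, protein = pep_protein,
                                  mz = pep_mz, rt_ref = pep_rt,
                                  is_outlier = seq_len(n_pep) %in% out_idx)
  list(runs = runs, psm_table = psm_table, truth = truth)
}

#' Ground truth implied by a cohort design
#'
#' Derives, by direct application of the fold-change thresholds, the set of
#' truly altered proteins (any tumor-vs-control fold change > `ratio_up` or
#' < `ratio_down`) and of truly metastasis-specific proteins (altered, and
#' any metastatic-vs-non-metastatic fold-change ratio outside the same
#' band).
#'
#' @param design A [cohort_design()].
#' @param outlier_peptides Character vector of peptide keys decoupled from
#'   their protein (filled in by [simulate_cohort()]).
#' @param ratio_up,ratio_down Strict thresholds defining "altered".
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(design, outlier_peptides = character(0),
                         ratio_up = 1.5, ratio_down = 0.67) {
  fc <- design$fold_change_spec
  tumor <- setdiff(design$groups, design$control_group)
  alt <- rownames(fc)[apply(fc[, tumor, drop = FALSE], 1,
                            function(x) any(x > ratio_up | x < ratio_down))]
  mfc <- fc[, design$metastatic_groups, drop = FALSE] /
    fc[, design$non_metastatic_group]
  met <- rownames(fc)[apply(mfc, 1,
                            function(x) any(x > ratio_up | x < ratio_down))]
  structure(list(
    true_fold_changes = fc,
    outlier_peptides = outlier_peptides,
    rt_drift = design$rt_drift_spec,
    intensity_bias = design$intensity_bias_spec,
    true_altered = sort(alt),
    true_metastasis_specific = sort(intersect(alt, met))
  ), class = "ground_truth")
}

#' Simulate a survival cohort tied to marker expression
#'
#' Event times are exponential with hazard `h0 * exp(sum(marker_effect *
#' z))`, where `z` is the standardized log expression of each marker gene
#' (independent log-normal across subjects). A positive `marker_effect`
#' therefore makes high expression hazardous. Censoring is uniform over the
#' subject's own follow-up: with probability `censor_rate` the subject is
#' censored at a uniform time before the event.
#'
#' @param n_subjects Number of subjects (>= 10).
#' @param marker_effect Named (or scalar, gene "marker") numeric of
#'   log-hazard coefficients per standardized log expression.
#' @param censor_rate Probability of censoring, in \[0, 1).
#' @param seed Integer seed.
#' @param baseline_hazard Events per month at z = 0.
#' @return data.frame of class `survival_cohort`: `subject`, `time_months`,
#'   `event`, one `expr_<gene>` column per marker.
#' @examples
#' sc <- simulate_survival(100, c(TP53 = 0.5), censor_rate = 0.2, seed = 1)
#' head(sc)
#' @export
simulate_survival <- function(n_subjects, marker_effect = 0, censor_rate = 0.3,
                              seed = 1L, baseline_hazard = 1 / 40) {
  if (n_subjects < 10) .stopf("n_subjects must be >= 10")
  if (censor_rate < 0 || censor_rate >= 1) .stopf("censor_rate must be in [0, 1)")
  if (is.null(names(marker_effect)))
    names(marker_effect) <- if (length(marker_effect) == 1) "marker"
      else sprintf("marker%d", seq_along(marker_effect))
  with_seed(seed, {
    expr <- sapply(marker_effect, function(e) rlnorm(n_subjects, log(10), 0.8))
    expr <- matrix(expr, nrow = n_subjects,
                   dimnames = list(NULL, names(marker_effect)))
    z <- scale(log(expr))
    lp <- drop(z %*% marker_effect)
    tt <- rexp(n_subjects, rate = baseline_hazard * exp(lp))
    cens <- runif(n_subjects) < censor_rate
    time <- ifelse(cens, runif(n_subjects) * tt, tt)
    out <- data.frame(subject = sprintf("S%04d", seq_len(n_subjects)),
                      time_months = time, event = as.integer(!cens))
    for (g in names(marker_effect)) out[[paste0("expr_", g)]] <- expr[, g]
    class(out) <- c("survival_cohort", "data.frame")
    out
  })
}
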