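# two runs holding the same peptide with controllable precursor m/z / RT gaps
two_event_fixture <- function(dmz_ppm = 2, drt = 10) {
  mz1 <- 800
  mz2 <- mz1 * (1 + dmz_ppm * 1e-6)
  r1 <- gaussian_run("r1", mz = mz1, apex = 300, amp = 1e5)
  r2 <- gaussian_run("r2", mz = mz2, apex = 300 + drt, amp = 1e5)
  psm <- data.frame(psm_id = c("q1", "q2"), run_id = c("r1", "r2"),
                    ms2_scan_id = c(r1$ms2$scan_id, r2$ms2$scan_id),
                    peptide = "ELVISLIVESK", charge = 2L,
                    protein_accession = "P1", is_unique = TRUE)
  list(runs = list(r1 = r1, r2 = r2), psm = psm)
}

test_that("PSMs inside the 10 ppm / 1 min window merge to one frame target", {
  fx <- two_event_fixture(dmz_ppm = 2, drt = 10)
  tg <- build_frame_targets(fx$psm, fx$runs)
  expect_equal(nrow(tg), 1)
  expect_equal(tg$n_events, 2)
  fx2 <- two_event_fixture(drt = 120)
  expect_equal(nrow(build_frame_targets(fx2$psm, fx2$runs)), 2)
  fx3 <- two_event_fixture(dmz_ppm = 25)
  expect_equal(nrow(build_frame_targets(fx3$psm, fx3$runs)), 2)
  # unresolvable scan id names the PSM
  fx$psm$ms2_scan_id[1] <- 99999L
  expect_error(build_frame_targets(fx$psm, fx$runs), "q1")
})

test_that("target counts equal an exhaustive single-linkage clustering oracle", {
  d <- small_design(seed = 13, ms2_sampling_rate = 0.6)
  sim <- simulate_cohort(d)
  al <- align_runs(sim$runs)
  tg <- build_frame_targets(sim$psm_table, al$runs)
  # oracle: per peptide, transitive closure over the pairwise merge relation
  ms2 <- do.call(rbind, lapply(al$runs, function(r)
    data.frame(run_id = r$run_id, ms2_scan_id = r$ms2$scan_id,
               rt = r$ms2$rt_seconds, pmz = r$ms2$precursor_mz)))
  ev <- merge(sim$psm_table, ms2, by = c("run_id", "ms2_scan_id"))
  n_oracle <- sum(vapply(split(ev, ev$peptide), function(g) {
    n <- nrow(g)
    adj <- matrix(FALSE, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      adj[i, j] <- abs(g$rt[i] - g$rt[j]) <= 60 &&
        abs(g$pmz[i] - g$pmz[j]) / ((g$pmz[i] + g$pmz[j]) / 2) * 1e6 <= 10
    reach <- adj
    for (k in seq_len(n)) reach <- reach | (reach %*% reach > 0)
    length(unique(apply(reach, 1, function(x) min(which(x)))))
  }, numeric(1)))
  expect_equal(nrow(tg), n_oracle)
  # every PSM maps to exactly one target
  expect_equal(sum(tg$n_events), nrow(ev))
})

test_that("frame areas match the brute-force trace oracle", {
  run <- gaussian_run("r", mz = c(600, 900), apex = c(200, 420),
                      amp = c(5e4, 2e5))
  for (tgt in list(list(mz_center = 600, rt_center = 200),
                   list(mz_center = 900, rt_center = 430),
                   list(mz_center = 750, rt_center = 300))) {
    got <- extract_frame(run, tgt)
    want <- brute_frame_area(run, tgt$mz_center, tgt$rt_center)
    if (want == 0) expect_equal(got$area, 0)
    else expect_equal(got$area, want, tolerance = 1e-9)
  }
  # empty window yields area 0
  expect_equal(extract_frame(run, list(mz_center = 1200, rt_center = 300))$area, 0)
})

test_that("a single-scan window uses the intensity-times-cycle rule", {
  run <- make_run("r", rt = c(100, 200, 300),
                  peaks = data.frame(scan_id = 2, mz = 500, intensity = 1000))
  # rt window of 60 s around 200 holds only scan 2 (cycle = 100 s)
  got <- extract_frame(run, list(mz_center = 500, rt_center = 200))
  expect_equal(got$area, 1000 * 100)
  expect_equal(got$apex_rt, 200)
})

test_that("extraction is linear and invariant to peak-list permutation", {
  d <- clean_design(seed = 3)
  sim <- simulate_cohort(d)
  tg <- build_frame_targets(sim$psm_table, sim$runs)
  fq <- extract_frames(sim$runs, tg)
  # permute peak rows within a run
  perm <- sim$runs
  for (i in seq_along(perm)) {
    o <- sample(nrow(perm[[i]]$peaks))
    perm[[i]]$peaks <- perm[[i]]$peaks[o, ]
  }
  expect_equal(extract_frames(perm, tg)$area, fq$area)
  # doubling every intensity in one run doubles that run's areas only
  dbl <- sim$runs
  dbl[[4]]$peaks$intensity <- dbl[[4]]$peaks$intensity * 2
  fq2 <- extract_frames(dbl, tg)
  expect_equal(fq2$area[, 4], 2 * fq$area[, 4])
  expect_equal(fq2$area[, -4], fq$area[, -4])
})

test_that("noise-free area ratios equal fold change times bias before normalization", {
  groups <- c("EpH4", "116", "1424", "1424.1", "1424.2")
  rid <- paste(rep(groups, each = 4), 1:4, sep = "_")
  fc <- matrix(1, 6, 5, dimnames = list(sprintf("P%04d", 1:6), groups))
  fc["P0002", "1424"] <- 3
  bias <- setNames(rep(1, 20), rid); bias["1424_1"] <- 1.7
  d <- cohort_design(n_proteins = 6L, peptides_per_protein = c(2L, 2L),
                     fold_change_spec = fc,
                     rt_drift_spec = data.frame(run_id = rid, slope = 1, offset = 0),
                     intensity_bias_spec = bias, noise_cv = 0,
                     mz_jitter_ppm = 0, outlier_fraction = 0,
                     ms2_sampling_rate = 1, rt_range_s = c(300, 800), seed = 2)
  sim <- simulate_cohort(d)
  tg <- build_frame_targets(sim$psm_table, sim$runs)
  fq <- extract_frames(sim$runs, tg)
  ann <- annotate_frames(tg, sim$psm_table)
  rows <- which(ann$protein_accession == "P0002")
  r <- fq$area[rows, "1424_1"] / fq$area[rows, "EpH4_1"]
  expect_equal(unname(r), rep(3 * 1.7, length(rows)), tolerance = 1e-9)
  # structurally complete: an area for every (frame, run) pair
  expect_false(anyNA(fq$area))
  expect_equal(dim(fq$area), c(nrow(tg), 20))
})
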