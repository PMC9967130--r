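test_that("median-of-ratios normalization has the closed-form solution", {
  a <- matrix(rlnorm(60, 10, 1), 20, 3,
              dimnames = list(NULL, c("r1", "r2", "r3")))
  # identical runs: all factors 1
  m <- cbind(r1 = a[, 1], r2 = a[, 1])
  nf <- normalize_frames(m)
  expect_equal(unname(nf$factors), c(1, 1))
  # constant-ratio runs: factors 2^(-1/2), 2^(1/2)
  m2 <- cbind(A = a[, 1], B = 2 * a[, 1])
  nf2 <- normalize_frames(m2)
  expect_equal(unname(nf2$factors), c(2^(-0.5), 2^(0.5)))
  expect_equal(nf2$area[, "A"], nf2$area[, "B"])
  # all-zero run is an error naming the run
  m3 <- cbind(A = a[, 1], BAD = 0)
  expect_error(normalize_frames(m3), "BAD")
})

test_that("normalization is idempotent and scale-equivariant", {
  set.seed(21)
  a <- matrix(rlnorm(400, 12, 1.5), 100, 4,
              dimnames = list(NULL, paste0("r", 1:4)))
  a <- sweep(a, 2, c(0.5, 1, 1.6, 2), "*")
  n1 <- normalize_frames(a)
  n2 <- normalize_frames(n1$area)
  expect_true(all(abs(n2$factors - 1) < 1e-9))
  # multiplying one run by c changes only that run's factor (up to renorm)
  b <- a; b[, 2] <- b[, 2] * 8
  nb <- normalize_frames(b)
  ratio <- nb$factors / n1$factors
  expect_equal(unname(ratio[2] / ratio[1]), 8, tolerance = 1e-9)
  expect_equal(unname(ratio[3] / ratio[1]), 1, tolerance = 1e-9)
})

test_that("injected per-run bias factors are recovered from a noisy cohort", {
  d <- small_design(seed = 17, n_proteins = 40L, noise_cv = 0.1)
  sim <- simulate_cohort(d)
  al <- align_runs(sim$runs)
  tg <- build_frame_targets(sim$psm_table, al$runs)
  fq <- extract_frames(al$runs, tg)
  nf <- normalize_frames(fq$area)
  bias <- sim$truth$intensity_bias[colnames(fq$area)]
  expect_gte(cor(nf$factors, bias), 0.99)
})

test_that("the PC outlier detector flags injected outliers and spares clean blocks", {
  profile <- rep(c(0, 0, 1, 1, 0.5), each = 4)   # log2 group profile
  hits <- logical(200)
  false_rate <- numeric(200)
  for (s in 1:200) {
    set.seed(s)
    block <- t(vapply(1:5, function(i) 10 + profile + rnorm(20, 0, 0.1),
                      numeric(20)))
    out <- 10 - profile + rnorm(20, 0, 0.1)     # anti-correlated peptide
    b6 <- rbind(block, out)
    rownames(b6) <- paste0("pep", 1:6)
    fl <- detect_peptide_outliers(b6)
    hits[s] <- identical(names(which(fl)), "pep6")
    false_rate[s] <- mean(detect_peptide_outliers(block))
  }
  expect_gte(mean(hits), 0.95)
  # per-peptide false-flag rate on clean proteins stays below 5%
  expect_lte(mean(false_rate), 0.05)
})

test_that("outlier guards: perfect blocks, 2-peptide proteins, survivor floor", {
  # perfectly parallel profiles never flag
  base <- matrix(rep(c(1, 2, 3, 4, 5), each = 3), 3, 5, byrow = FALSE)
  expect_false(any(detect_peptide_outliers(base + 10)))
  # a 2-peptide protein is never flagged regardless of disagreement
  b2 <- rbind(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_false(any(detect_peptide_outliers(b2)))
  expect_error(detect_peptide_outliers(b2[1, , drop = FALSE]), "2 peptides")
  # at least 2 peptides always survive
  set.seed(1)
  wild <- matrix(rnorm(12, 0, 5), 3, 4)
  expect_lte(sum(detect_peptide_outliers(wild)), 1)
})

test_that("annotation is a bijection onto targets and flags shared peptides", {
  d <- clean_design(seed = 7)
  sim <- simulate_cohort(d)
  tg <- build_frame_targets(sim$psm_table, sim$runs)
  ann <- annotate_frames(tg, sim$psm_table)
  expect_equal(nrow(ann), nrow(tg))
  # oracle: exhaustive join by peptide
  want <- sim$psm_table$protein_accession[match(tg$peptide, sim$psm_table$peptide)]
  expect_equal(ann$protein_accession, want)
  expect_true(all(ann$is_unique))
  # a peptide mapped to two accessions gets flagged non-unique
  psm2 <- sim$psm_table
  shared_pep <- psm2$peptide[1]
  extra <- psm2[psm2$peptide == shared_pep, ][1, ]
  extra$psm_id <- "PSMX"; extra$protein_accession <- "OTHER"
  ann2 <- annotate_frames(tg, rbind(psm2, extra))
  expect_false(any(ann2$is_unique[ann2$peptide == shared_pep]))
})

test_that("protein roll-up sums surviving peptides and enforces the 2-peptide rule", {
  area <- matrix(c(10, 20, 5,   12, 22, 6), 3, 2,
                 dimnames = list(c("F1", "F2", "F3"), c("s1", "s2")))
  ann <- data.frame(frame_id = c("F1", "F2", "F3"),
                    peptide = c("AAA", "BBB", "CCC"),
                    protein_accession = c("P1", "P1", "P2"),
                    is_unique = TRUE)
  groups <- c(s1 = "g1", s2 = "g2")
  expect_error(aggregate_proteins(ann, area, outliers = c("AAA", "BBB", "CCC"),
                                  groups), "unique")
  pm <- aggregate_proteins(ann, area, groups = groups)
  # P2 has one peptide -> dropped; P1 = sum of its two frames
  expect_equal(rownames(pm$abundance), "P1")
  expect_equal(unname(pm$abundance["P1", ]), c(30, 34))
  # dropping one P1 peptide as outlier leaves < 2 -> protein dropped
  expect_error(aggregate_proteins(ann, area, outliers = "AAA", groups),
               "2 unique")
})

test_that("zero cells are floored and the matrix has no missing values", {
  area <- matrix(c(10, 20, 0, 30,   12, 22, 7, 31), 4, 2,
                 dimnames = list(paste0("F", 1:4), c("s1", "s2")))
  ann <- data.frame(frame_id = paste0("F", 1:4),
                    peptide = c("AAA", "BBB", "AAA", "BBB"),
                    protein_accession = "P1", is_unique = TRUE)
  pm <- aggregate_proteins(ann, area, groups = c(s1 = "g1", s2 = "g2"))
  expect_true(all(pm$abundance > 0))
  expect_false(anyNA(pm$abundance))
})

test_that("noise-free end-to-end ratios equal the true fold changes exactly", {
  d <- clean_design(seed = 12)
  sim <- simulate_cohort(d)
  tg <- build_frame_targets(sim$psm_table, sim$runs)
  fq <- extract_frames(sim$runs, tg)
  ann <- annotate_frames(tg, sim$psm_table)
  nf <- normalize_frames(fq$area)
  pm <- aggregate_proteins(ann, nf, groups = d$run_group)
  ratios <- compare_ratios(pm, d$control_group)
  fc <- sim$truth$true_fold_changes[rownames(ratios), colnames(ratios)]
  expect_equal(ratios, fc, tolerance = 1e-9)
})
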