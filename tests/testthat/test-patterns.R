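# independent re-statement of the decision cascade, used as a rule oracle
pattern_oracle <- function(z, delta = 0.5) {
  nm <- z[1]; p <- z[2]; k <- z[3]; l <- z[4]
  others <- function(i) max(z[-i])
  if (nm - others(1) >= delta) return("NON_METASTATIC")
  if (p - nm >= delta && k - nm >= delta && l - nm >= delta) return("METASTATIC")
  if (p - others(2) >= delta) return("PRIMARY_SITE")
  if (k - nm >= delta && k - p >= delta && l - nm >= delta && l - p >= delta)
    return("KIDNEY_LUNG")
  if (k - others(3) >= delta) return("KIDNEY")
  if (l - others(4) >= delta) return("LUNG")
  c("NON_METASTATIC", "PRIMARY_SITE", "KIDNEY", "LUNG")[which.max(z)]
}

test_that("profile standardization matches hand-computed z-scores", {
  m <- 2^matrix(c(1, 2, 3, 4), 1, 4, dimnames = list("P1", paste0("s", 1:4)))
  # one sample per group is not enough for the matrix path; test the math
  z <- (c(1, 2, 3, 4) - 2.5) / sd(c(1, 2, 3, 4))
  expect_equal(round(z, 2), c(-1.16, -0.39, 0.39, 1.16))
  # via the matrix interface (2 identical samples per group)
  mm <- 2^matrix(rep(c(1, 2, 3, 4), each = 2), 1, 8,
                 dimnames = list("P1", paste0("s", 1:8)))
  pm <- protein_matrix(mm, setNames(rep(c("nm", "p", "k", "l"), each = 2),
                                    colnames(mm)))
  zt <- standardize_profiles(pm, c("nm", "p", "k", "l"))
  expect_equal(unname(zt[1, ]), z)
  # constant profiles give z = 0 with a warning
  mc <- matrix(4, 1, 8, dimnames = list("P1", paste0("s", 1:8)))
  pmc <- protein_matrix(mc, setNames(rep(c("nm", "p", "k", "l"), each = 2),
                                     colnames(mc)))
  expect_warning(zc <- standardize_profiles(pmc, c("nm", "p", "k", "l")),
                 "constant")
  expect_equal(unname(zc[1, ]), rep(0, 4))
})

test_that("standardization is equivariant under group permutation", {
  mm <- 2^matrix(c(1, 1, 3, 3, 2, 2, 5, 5), 1, 8,
                 dimnames = list("P1", paste0("s", 1:8)))
  pm <- protein_matrix(mm, setNames(rep(c("nm", "p", "k", "l"), each = 2),
                                    colnames(mm)))
  z1 <- standardize_profiles(pm, c("nm", "p", "k", "l"))
  z2 <- standardize_profiles(pm, c("k", "l", "nm", "p"))
  expect_equal(unname(z2[1, ]), unname(z1[1, c(3, 4, 1, 2)]))
})

test_that("the pattern cascade handles the archetype cases", {
  expect_equal(assign_pattern(c(-1.5, 0.5, 0.5, 0.5)), "METASTATIC")
  expect_equal(assign_pattern(c(1.5, -0.5, -0.5, -0.5)), "NON_METASTATIC")
  expect_equal(assign_pattern(c(-0.5, 1.5, -0.5, -0.5)), "PRIMARY_SITE")
  expect_equal(assign_pattern(c(-0.87, -0.87, 0.87, 0.87)), "KIDNEY_LUNG")
  expect_equal(assign_pattern(c(-0.5, -0.5, 1.5, -0.5)), "KIDNEY")
  expect_equal(assign_pattern(c(-0.5, -0.5, -0.5, 1.5)), "LUNG")
  expect_error(assign_pattern(c(1, 2, 3)), "4-vector")
})

test_that("the cascade agrees with an independently coded rule table", {
  set.seed(11)
  for (i in 1:500) {
    z <- rnorm(4)
    z <- (z - mean(z)) / max(sd(z), 1e-9)
    expect_equal(assign_pattern(z), pattern_oracle(z))
  }
  # specific mixed case from the rule table
  z <- c(-0.9, -0.3, 0.4, 0.8)
  expect_equal(assign_pattern(z), pattern_oracle(z))
  # invariance to adding a constant
  for (i in 1:50) {
    z <- rnorm(4)
    expect_equal(assign_pattern(z), assign_pattern(z + 3.7))
  }
})

test_that("labels partition the input and archetypes classify perfectly", {
  arch <- rbind(
    METASTATIC = c(0, 1, 1, 1), NON_METASTATIC = c(1, 0, 0, 0),
    PRIMARY_SITE = c(0, 1, 0, 0), KIDNEY_LUNG = c(0, 0, 1, 1),
    KIDNEY = c(0, 0, 1, 0), LUNG = c(0, 0, 0, 1))
  z <- t(apply(arch, 1, function(x) (x - mean(x)) / sd(x)))
  colnames(z) <- c("NM", "P", "K", "L")
  asg <- assign_patterns(z)
  expect_equal(as.character(asg$pattern), rownames(arch))
  expect_equal(sum(table(asg$pattern)), nrow(z))
  expect_equal(asg$excluded, rownames(arch) == "NON_METASTATIC")
  # random inputs always get exactly one label
  set.seed(3)
  zr <- matrix(rnorm(120), 30, 4, dimnames = list(sprintf("P%02d", 1:30), NULL))
  ar <- assign_patterns(zr)
  expect_false(anyNA(ar$pattern))
  expect_equal(sum(table(ar$pattern)), 30)
})

test_that("non-metastatic exclusion is pure set arithmetic", {
  set.seed(8)
  z <- matrix(rnorm(94 * 4), 94, 4, dimnames = list(sprintf("P%02d", 1:94), NULL))
  asg <- assign_patterns(z)
  kept <- exclude_non_metastatic(asg)
  expect_equal(nrow(kept), 94 - sum(asg$pattern == "NON_METASTATIC"))
  expect_false(any(kept$excluded))
  # degenerate cases: none / all excluded
  asg0 <- asg[!asg$excluded, ]
  expect_equal(nrow(exclude_non_metastatic(asg0)), nrow(asg0))
  asg1 <- asg[asg$excluded, ]
  expect_equal(nrow(exclude_non_metastatic(asg1)), 0)
})

test_that("profile clustering matches a brute-force agglomerative oracle", {
  # identical profiles merge first at distance 0
  z2 <- rbind(a = c(-1, 0, 0, 1), b = c(-1, 0, 0, 1), c = c(1, 0, 0, -1))
  cl <- cluster_profiles(z2, k = 2)
  expect_equal(cl$hclust$height[1], 0)
  expect_equal(unname(cl$clusters["a"]), unname(cl$clusters["b"]))
  # anti-correlated pair merges last at distance ~ 2
  expect_equal(max(cl$hclust$height), 2, tolerance = 1e-9)
  # brute-force average-linkage agglomeration on 8 profiles
  set.seed(5)
  z8 <- matrix(rnorm(32), 8, 4, dimnames = list(letters[1:8], NULL))
  got <- cluster_profiles(z8, k = 3)$clusters
  d <- 1 - cor(t(z8))
  # oracle: naive agglomeration tracking average linkage between clusters
  clusters <- as.list(seq_len(8))
  heights <- c()
  while (length(clusters) > 3) {
    best <- c(NA, NA); bd <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dd <- mean(d[clusters[[i]], clusters[[j]]])
      if (dd < bd) { bd <- dd; best <- c(i, j) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  oracle <- integer(8)
  for (i in seq_along(clusters)) oracle[clusters[[i]]] <- i
  # same partition up to label renaming
  expect_equal(length(unique(got)), length(unique(oracle)))
  for (cc in unique(oracle)) {
    members <- which(oracle == cc)
    expect_equal(length(unique(got[members])), 1)
  }
  # permutation invariance of memberships
  perm <- sample(8)
  got_p <- cluster_profiles(z8[perm, ], k = 3)$clusters[rownames(z8)]
  tab <- table(got, got_p[names(got)])
  expect_true(all(rowSums(tab > 0) == 1))
  # single protein: single leaf
  one <- cluster_profiles(z8[1, , drop = FALSE])
  expect_null(one$hclust)
  expect_equal(unname(one$clusters), 1L)
})
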