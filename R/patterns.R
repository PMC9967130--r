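#' Standardize per-group abundance profiles
#'
#' For each protein, the mean log2 abundance per tumorigenic group is
#' z-scored across the four groups (sample sd, n - 1), so patterns are
#' defined by profile shape, not magnitude. Constant profiles get z = 0
#' with a warning.
#'
#' @param pm A [protein_matrix()].
#' @param tumor_groups The four tumorigenic groups in fixed role order:
#'   non-metastatic, primary site, kidney metastasis, lung metastasis.
#' @param proteins Optional subset of accessions (e.g. the
#'   metastasis-specific set); default all.
#' @return Proteins x 4 matrix of z-scores, columns named `NM`, `P`, `K`,
#'   `L`; the original group labels are kept in the `group_labels`
#'   attribute.
#' @export
standardize_profiles <- function(pm, tumor_groups, proteins = rownames(pm$abundance)) {
  stopifnot(inherits(pm, "protein_matrix"))
  if (length(tumor_groups) != 4) .stopf("exactly four tumorigenic groups required")
  if (!all(tumor_groups %in% pm$groups)) .stopf("tumor group not in matrix")
  means <- sapply(tumor_groups, function(g)
    rowMeans(log2(pm$abundance[proteins, pm$groups == g, drop = FALSE])))
  means <- matrix(means, ncol = 4,
                  dimnames = list(proteins, c("NM", "P", "K", "L")))
  sds <- apply(means, 1, sd)
  if (any(sds == 0)) {
    .warnf("%d constant profile(s): z-scores set to 0", sum(sds == 0))
    sds[sds == 0] <- Inf
  }
  z <- (means - rowMeans(means)) / sds
  attr(z, "group_labels") <- setNames(tumor_groups, c("NM", "P", "K", "L"))
  z
}

.pattern_levels <- c("METASTATIC", "NON_METASTATIC", "PRIMARY_SITE",
                     "KIDNEY_LUNG", "KIDNEY", "LUNG")

#' Assign one abundance pattern
#'
#' Deterministic decision cascade on a standardized 4-vector of group
#' z-scores (NM = non-metastatic, P = primary site, K = kidney metastasis,
#' L = lung metastasis), with margin `delta`:
#' \enumerate{
#'   \item NM strictly largest by >= delta: `NON_METASTATIC`
#'   \item all of P, K, L exceed NM by >= delta: `METASTATIC`
#'   \item P strictly largest by >= delta: `PRIMARY_SITE`
#'   \item K and L both exceed NM and P by >= delta: `KIDNEY_LUNG`
#'   \item K strictly largest by >= delta: `KIDNEY`
#'   \item L strictly largest by >= delta: `LUNG`
#' }
#' Fallback: the label of the largest z (NM, P, K, L mapping to
#' `NON_METASTATIC`, `PRIMARY_SITE`, `KIDNEY`, `LUNG`), ties broken in that
#' fixed order.
#'
#' @param z Numeric 4-vector in (NM, P, K, L) order.
#' @param delta Margin for "more significant" (default 0.5 z units).
#' @return Pattern label (character scalar).
#' @export
assign_pattern <- function(z, delta = 0.5) {
  if (length(z) != 4) .stopf("z must be a 4-vector (NM, P, K, L)")
  nm <- z[[1]]; p <- z[[2]]; k <- z[[3]]; l <- z[[4]]
  if (nm - max(p, k, l) >= delta) return("NON_METASTATIC")
  if (min(p, k, l) - nm >= delta) return("METASTATIC")
  if (p - max(nm, k, l) >= delta) return("PRIMARY_SITE")
  if (k - max(nm, p) >= delta && l - max(nm, p) >= delta) return("KIDNEY_LUNG")
  if (k - max(nm, p, l) >= delta) return("KIDNEY")
  if (l - max(nm, p, k) >= delta) return("LUNG")
  c("NON_METASTATIC", "PRIMARY_SITE", "KIDNEY", "LUNG")[which.max(z)]
}

#' Classify metastasis-specific proteins into six abundance patterns
#'
#' Applies [assign_pattern()] to every row of a [standardize_profiles()]
#' table and marks the non-metastatic pattern as excluded (the one pattern
#' that, by definition, does not represent a metastasis-driven change).
#'
#' @param z Proteins x 4 z-score matrix (columns NM, P, K, L).
#' @param delta Margin passed to [assign_pattern()].
#' @return data.frame of class `pattern_assignments`: `protein`, `z_NM`,
#'   `z_P`, `z_K`, `z_L`, `pattern`, `excluded`.
#' @export
assign_patterns <- function(z, delta = 0.5) {
  z <- as.matrix(z)
  lab <- apply(z, 1, assign_pattern, delta = delta)
  out <- data.frame(protein = rownames(z),
                    z_NM = z[, 1], z_P = z[, 2], z_K = z[, 3], z_L = z[, 4],
                    pattern = factor(lab, levels = .pattern_levels),
                    excluded = lab == "NON_METASTATIC")
  rownames(out) <- NULL
  class(out) <- c("pattern_assignments", "data.frame")
  out
}

#' Hierarchically cluster standardized profiles
#'
#' Average-linkage agglomerative clustering under the correlation distance
#' 1 - Pearson on z-scored group means; flat clusters by cutting at
#' `k` groups. Deterministic; used for ordering/visualization, not for the
#' pattern labels themselves.
#'
#' @param z Proteins x groups z-score matrix (>= 2 rows for a dendrogram).
#' @param k Number of flat clusters (capped at the number of proteins).
#' @return List with `hclust` (or NULL for a single protein), `clusters`
#'   (named integer vector) and `order` (leaf order).
#' @export
cluster_profiles <- function(z, k = 6) {
  z <- as.matrix(z)
  if (nrow(z) < 2)
    return(list(hclust = NULL,
                clusters = setNames(1L, rownames(z)), order = 1L))
  d <- as.dist(1 - cor(t(z)))
  hc <- hclust(d, method = "average")
  list(hclust = hc,
       clusters = cutree(hc, k = min(k, nrow(z))),
       order = hc$order)
}

#' Drop the non-metastatic pattern
#'
#' Removes proteins assigned `NON_METASTATIC`; the remainder are the
#' metastasis-specific proteins carried into the survival screen.
#'
#' @param assignments An [assign_patterns()] data.frame.
#' @return The filtered data.frame (possibly zero rows).
#' @export
exclude_non_metastatic <- function(assignments) {
  assignments[!assignments$excluded, , drop = FALSE]
}
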