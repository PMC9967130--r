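#' Annotate frames with peptide/protein assignments
#'
#' Joins frame targets back to the PSM table by peptide sequence, attaching
#' the protein accession and a uniqueness flag. A peptide mapping to more
#' than one accession (or carrying `is_unique = FALSE` in the PSM table) is
#' flagged non-unique and excluded from protein roll-up downstream. Every
#' frame must annotate (targets are built from the same PSM table, so a
#' frame without a PSM indicates corrupted input).
#'
#' @param targets A [build_frame_targets()] result.
#' @param psm_table The PSM table the targets were built from.
#' @return data.frame of class `annotated_frames`: the target columns plus
#'   `protein_accession` and `is_unique`.
#' @export
annotate_frames <- function(targets, psm_table) {
  pt <- data.table::as.data.table(psm_table)
  map <- pt[, list(protein_accession = paste(sort(unique(protein_accession)),
                                             collapse = ";"),
                   n_acc = length(unique(protein_accession)),
                   psm_unique = all(is_unique)),
            by = peptide]
  i <- match(targets$peptide, map$peptide)
  if (anyNA(i))
    .stopf("frame '%s': peptide '%s' absent from the PSM table",
           targets$frame_id[which(is.na(i))[1]],
           targets$peptide[which(is.na(i))[1]])
  out <- targets
  out$protein_accession <- map$protein_accession[i]
  out$is_unique <- map$n_acc[i] == 1L & map$psm_unique[i]
  class(out) <- c("annotated_frames", "data.frame")
  out
}

#' Dataset-wide median-of-ratios normalization
#'
#' Computes one multiplicative factor per run as the median, over frames,
#' of the ratio of that run's area to the frame's geometric mean across
#' runs (log-space median of ratios; only frames positive in every run
#' enter the factor estimate). Factors are renormalized so their log mean
#' is 0, then divided out. Equalizes global intensity bias without
#' assuming any frame-level structure beyond "most frames unchanged".
#'
#' @param area Frames x runs matrix of areas (>= 0).
#' @return List of class `normalized_frames`: `area` (normalized matrix),
#'   `factors` (named per-run multiplicative factors).
#' @export
normalize_frames <- function(area) {
  area <- as.matrix(area)
  if (ncol(area) < 2) .stopf("normalization needs >= 2 runs")
  zero_run <- colSums(area > 0) == 0
  if (any(zero_run))
    .stopf("run '%s' has no nonzero frame areas", colnames(area)[which(zero_run)[1]])
  if (nrow(area) < 10)
    .warnf("only %d frames: normalization factors will be unstable", nrow(area))
  pos <- rowSums(area > 0) == ncol(area)
  if (!any(pos)) .stopf("no frame is positive in every run; cannot normalize")
  la <- log(area[pos, , drop = FALSE])
  ref <- rowMeans(la)
  lf <- apply(la - ref, 2, median)
  lf <- lf - mean(lf)           # factors multiply to 1 in log space
  factors <- exp(lf)
  structure(list(area = sweep(area, 2, factors, "/"), factors = factors),
            class = "normalized_frames")
}

#' Detect outlier peptides within one protein
#'
#' Scores each peptide against the first principal component of the
#' *other* peptides' row-centered profiles — the leave-one-out consensus.
#' The component is oriented towards the majority of the remaining
#' peptides, and the residual is the peptide's distance to the positive
#' half-line: a peptide tracking the consensus keeps only its orthogonal
#' noise, an anti-correlated peptide (negative projection) keeps its full
#' norm, and an outlier in an otherwise flat protein cannot hide inside a
#' component its own profile dominates. Peptides whose residual exceeds
#' median + 3 x MAD of the residuals are flagged. Guards: a protein with
#' fewer than 3 peptides is never flagged, and at least 2 peptides always
#' survive (excess flags are released in increasing residual order).
#'
#' @param block Numeric matrix, peptides x samples, of normalized log2
#'   areas; >= 2 rows.
#' @return Named logical vector of outlier flags (one per peptide row).
#' @export
detect_peptide_outliers <- function(block) {
  block <- as.matrix(block)
  n <- nrow(block)
  if (n < 2) .stopf("protein has < 2 peptides; should have been excluded")
  flags <- setNames(rep(FALSE, n), rownames(block))
  if (n < 3) return(flags)
  x <- block - rowMeans(block)
  resid <- vapply(seq_len(n), function(i) {
    v <- svd(x[-i, , drop = FALSE], nu = 0, nv = 1)$v[, 1]
    if (sum(sign(x[-i, , drop = FALSE] %*% v)) < 0) v <- -v  # orient to majority
    p_i <- sum(x[i, ] * v)
    if (p_i > 0) sqrt(sum((x[i, ] - p_i * v)^2)) else sqrt(sum(x[i, ]^2))
  }, numeric(1))
  thr <- median(resid) + 3 * mad(resid)
  flags[] <- resid > pmax(thr, 1e-8)
  if (sum(flags) > n - 2) {       # keep at least two peptides
    keep_off <- order(resid, decreasing = TRUE)[seq_len(n - 2)]
    flags[] <- FALSE
    flags[keep_off] <- TRUE
  }
  flags
}

#' Flag outlier peptides across all proteins
#'
#' Rolls normalized frame areas up to peptide-level profiles (summing
#' charge states), then runs [detect_peptide_outliers()] per protein on
#' log2 profiles (zeros floored to half the smallest positive value of the
#' protein's block). Shared (non-unique) peptides are ignored.
#'
#' @param annotated An [annotate_frames()] result.
#' @param norm A [normalize_frames()] result (or a frames x runs matrix).
#' @return Character vector of flagged peptide sequences.
#' @export
flag_outlier_peptides <- function(annotated, norm) {
  area <- if (inherits(norm, "normalized_frames")) norm$area else as.matrix(norm)
  pep_mat <- rowsum(area[annotated$frame_id, , drop = FALSE],
                    group = annotated$peptide)
  pep_prot <- annotated$protein_accession[match(rownames(pep_mat), annotated$peptide)]
  pep_uni <- annotated$is_unique[match(rownames(pep_mat), annotated$peptide)]
  flagged <- character(0)
  for (acc in unique(pep_prot[pep_uni])) {
    rows <- which(pep_prot == acc & pep_uni)
    if (length(rows) < 3) next
    b <- pep_mat[rows, , drop = FALSE]
    floor_v <- if (any(b > 0)) min(b[b > 0]) / 2 else 1
    fl <- detect_peptide_outliers(log2(pmax(b, floor_v)))
    flagged <- c(flagged, rownames(b)[fl])
  }
  flagged
}

#' Aggregate frames to a protein abundance matrix
#'
#' Sums normalized areas of surviving unique-peptide frames per protein and
#' sample. Proteins with fewer than two surviving unique peptides are
#' dropped (the two-unique-peptide identification contract). Remaining
#' zero cells are floored to half the smallest positive value of the
#' matrix, so the result has no missing values and every ratio is
#' computable.
#'
#' @param annotated An [annotate_frames()] result.
#' @param norm A [normalize_frames()] result (or a frames x runs matrix).
#' @param outliers Character vector of peptides to exclude (from
#'   [flag_outlier_peptides()]).
#' @param groups Named character vector: sample id -> group label.
#' @return An object of class `protein_matrix`: list with `abundance`
#'   (proteins x samples, all cells > 0), `groups`, `peptide_counts`.
#' @export
aggregate_proteins <- function(annotated, norm, outliers = character(0),
                               groups = NULL) {
  area <- if (inherits(norm, "normalized_frames")) norm$area else as.matrix(norm)
  keep <- annotated$is_unique & !(annotated$peptide %in% outliers)
  ann <- annotated[keep, , drop = FALSE]
  if (!nrow(ann)) .stopf("no unique, non-outlier frames to aggregate")
  npep <- tapply(ann$peptide, ann$protein_accession,
                 function(p) length(unique(p)))
  ok <- names(npep)[npep >= 2]
  ann <- ann[ann$protein_accession %in% ok, , drop = FALSE]
  if (!nrow(ann)) .stopf("no protein retains >= 2 unique peptides")
  ab <- rowsum(area[ann$frame_id, , drop = FALSE], group = ann$protein_accession)
  if (any(ab == 0)) ab[ab == 0] <- min(ab[ab > 0]) / 2
  if (is.null(groups))
    groups <- setNames(rep(NA_character_, ncol(ab)), colnames(ab))
  protein_matrix(ab, groups[colnames(ab)], npep[rownames(ab)])
}

#' Protein abundance matrix
#'
#' @param abundance Proteins x samples numeric matrix, all cells > 0.
#' @param groups Named character vector, one group label per sample column.
#' @param peptide_counts Named integer vector of surviving unique peptides
#'   per protein.
#' @return Object of class `protein_matrix`.
#' @export
protein_matrix <- function(abundance, groups, peptide_counts = NULL) {
  abundance <- as.matrix(abundance)
  if (anyNA(abundance) || any(abundance <= 0))
    .stopf("protein_matrix must have a positive value in every cell")
  if (length(groups) != ncol(abundance))
    .stopf("one group label per sample column required")
  names(groups) <- colnames(abundance)
  structure(list(abundance = abundance, groups = groups,
                 peptide_counts = peptide_counts),
            class = "protein_matrix")
}

#' @export
print.protein_matrix <- function(x, ...) {
  cat(sprintf("protein_matrix: %d proteins x %d samples (%d groups), no missing cells\n",
              nrow(x$abundance), ncol(x$abundance),
              length(unique(x$groups))))
  invisible(x)
}
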