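#' One-way ANOVA p-values across all groups
#'
#' Classical fixed-effects one-way ANOVA on log2 abundances, one test per
#' protein, across every group of the matrix. A protein with zero variance
#' everywhere (all samples identical) gets p = 1.
#'
#' @param pm A [protein_matrix()].
#' @return Named numeric vector of p-values in (0, 1].
#' @export
anova_pvalues <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  g <- factor(pm$groups)
  if (nlevels(g) < 2) .stopf("ANOVA needs >= 2 groups")
  if (any(table(g) < 2)) .stopf("every group needs >= 2 samples")
  la <- log2(pm$abundance)
  apply(la, 1, function(x) {
    if (var(x) == 0) return(1)
    oneway.test(x ~ g, var.equal = TRUE)$p.value
  })
}

#' Group-vs-control abundance ratios
#'
#' Linear-scale ratio of arithmetic group means: `mean(group) /
#' mean(control)` per protein, for each comparison group.
#'
#' @param pm A [protein_matrix()].
#' @param control_group Control group label.
#' @param comparison_groups Labels to compare against the control; default
#'   all non-control groups.
#' @param geometric Use geometric instead of arithmetic means.
#' @return Proteins x comparisons matrix of ratios (> 0).
#' @export
compare_ratios <- function(pm, control_group,
                           comparison_groups = setdiff(unique(pm$groups), control_group),
                           geometric = FALSE) {
  stopifnot(inherits(pm, "protein_matrix"))
  all_g <- unique(pm$groups)
  unknown <- setdiff(c(control_group, comparison_groups), all_g)
  if (length(unknown)) .stopf("unknown group label '%s'", unknown[1])
  gmean <- function(cols) {
    m <- pm$abundance[, cols, drop = FALSE]
    if (geometric) exp(rowMeans(log(m))) else rowMeans(m)
  }
  ctl <- gmean(names(pm$groups)[pm$groups == control_group])
  out <- sapply(comparison_groups, function(g)
    gmean(names(pm$groups)[pm$groups == g]) / ctl)
  matrix(out, nrow = nrow(pm$abundance),
         dimnames = list(rownames(pm$abundance), comparison_groups))
}

#' Per-protein differential records
#'
#' Assembles the differential table: one-way ANOVA p-value, one
#' tumor-vs-control ratio per tumor group, one metastatic-vs-non-metastatic
#' ratio per metastatic group, plus the `altered` and
#' `metastasis_specific` gate flags.
#'
#' @param pm A [protein_matrix()].
#' @param control_group,non_metastatic_group,metastatic_groups Group roles.
#' @param p_threshold ANOVA gate (strict; default 0.05).
#' @param ratio_up,ratio_down Fold-change gates (strict; defaults 1.5 and
#'   0.67).
#' @param p_adjust_method Optional multiple-testing correction applied to
#'   the ANOVA p-values before gating (e.g. `"BH"`); `"none"` (the
#'   default) mirrors a raw p < 0.05 gate.
#' @return data.frame of class `differential_records` with columns
#'   `protein`, `p_anova`, `ratio_<group>`, `mratio_<group>`, `altered`,
#'   `metastasis_specific`.
#' @export
differential_records <- function(pm, control_group, non_metastatic_group,
                                 metastatic_groups,
                                 p_threshold = 0.05, ratio_up = 1.5,
                                 ratio_down = 0.67,
                                 p_adjust_method = "none") {
  p <- anova_pvalues(pm)
  if (p_adjust_method != "none") p <- p.adjust(p, method = p_adjust_method)
  tumor <- setdiff(unique(pm$groups), control_group)
  tr <- compare_ratios(pm, control_group, tumor)
  mr <- compare_ratios(pm, non_metastatic_group, metastatic_groups)
  out <- data.frame(protein = rownames(pm$abundance), p_anova = unname(p))
  for (g in tumor) out[[paste0("ratio_", g)]] <- tr[, g]
  for (g in metastatic_groups) out[[paste0("mratio_", g)]] <- mr[, g]
  hit <- function(m) apply(m, 1, function(x) any(x > ratio_up | x < ratio_down))
  out$altered <- p < p_threshold & hit(tr)
  out$metastasis_specific <- out$altered & hit(mr)
  rownames(out) <- NULL
  attr(out, "thresholds") <- c(p = p_threshold, up = ratio_up, down = ratio_down)
  class(out) <- c("differential_records", "data.frame")
  out
}

#' Select altered proteins
#'
#' A protein is altered when its ANOVA p-value is strictly below
#' `p_threshold` and at least one tumor-vs-control ratio is strictly
#' outside (`ratio_down`, `ratio_up`).
#'
#' @param records A [differential_records()] data.frame.
#' @param p_threshold,ratio_up,ratio_down Gate thresholds (strict).
#' @return Character vector of altered protein accessions.
#' @export
select_altered <- function(records, p_threshold = 0.05, ratio_up = 1.5,
                           ratio_down = 0.67) {
  rc <- grep("^ratio_", names(records), value = TRUE)
  hit <- apply(records[rc] > ratio_up | records[rc] < ratio_down, 1, any)
  sort(records$protein[records$p_anova < p_threshold & hit])
}

#' Select metastasis-specific proteins
#'
#' The subset of altered proteins with at least one
#' metastatic-vs-non-metastatic ratio strictly outside (`ratio_down`,
#' `ratio_up`).
#'
#' @inheritParams select_altered
#' @return Character vector of metastasis-specific accessions (always a
#'   subset of [select_altered()]).
#' @export
select_metastasis_specific <- function(records, p_threshold = 0.05,
                                       ratio_up = 1.5, ratio_down = 0.67) {
  alt <- select_altered(records, p_threshold, ratio_up, ratio_down)
  mc <- grep("^mratio_", names(records), value = TRUE)
  hit <- apply(records[mc] > ratio_up | records[mc] < ratio_down, 1, any)
  sort(intersect(alt, records$protein[hit]))
}

#' Mean intra-group coefficient of variation
#'
#' Per protein and group, CV = sample sd / mean on the linear scale;
#' reported as the per-group mean across proteins, in percent. Gauges
#' replicate reproducibility of the quantification.
#'
#' @param pm A [protein_matrix()].
#' @return Named numeric vector: mean CV (%) per group.
#' @export
intragroup_cv <- function(pm) {
  stopifnot(inherits(pm, "protein_matrix"))
  g <- unique(pm$groups)
  if (any(table(pm$groups) < 2)) .stopf("every group needs >= 2 samples")
  vapply(setNames(g, g), function(grp) {
    m <- pm$abundance[, pm$groups == grp, drop = FALSE]
    mu <- rowMeans(m)
    if (any(mu == 0)) {
      .warnf("group '%s': %d zero-mean protein(s) skipped", grp, sum(mu == 0))
      m <- m[mu > 0, , drop = FALSE]; mu <- mu[mu > 0]
    }
    mean(apply(m, 1, sd) / mu) * 100
  }, numeric(1))
}
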