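#' Kaplan-Meier product-limit estimate
#'
#' @param times Positive follow-up times.
#' @param events Binary event indicators (1 = event, 0 = censored).
#' @return data.frame of class `km_curve`: one row per distinct observed
#'   time with `time`, `n_risk`, `n_event`, `n_censor`, `survival` (the
#'   product-limit estimate just after that time). Survival starts at 1,
#'   is non-increasing and stays in \[0, 1\]; an all-censored input gives a
#'   flat curve at 1.
#' @export
km_estimate <- function(times, events) {
  if (!length(times)) .stopf("empty survival input")
  if (any(times <= 0)) .stopf("times must be > 0")
  if (!all(events %in% c(0, 1))) .stopf("events must be 0/1")
  o <- order(times)
  times <- times[o]; events <- events[o]
  ut <- unique(times)
  n <- length(times)
  n_risk <- vapply(ut, function(t) sum(times >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(times == t & events == 1), numeric(1))
  n_censor <- vapply(ut, function(t) sum(times == t & events == 0), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, survival = surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

# two-group log-rank: O-E/V over the pooled distinct event times
.logrank <- function(times, events, arm) {
  ut <- sort(unique(times[events == 1]))
  o1 <- e1 <- v <- 0
  for (t in ut) {
    n <- sum(times >= t)
    n1 <- sum(times >= t & arm)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & arm)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  list(o1 = o1, e1 = e1, v = v)
}

#' Median-split log-rank survival test for one marker gene
#'
#' Splits the cohort at the median expression of `expr_<gene>` (ties at
#' the median go to the low arm), estimates both Kaplan-Meier curves, and
#' tests high vs low with the standard two-group log-rank statistic
#' (1 df). The hazard direction is +1 when the high-expression arm has
#' more observed than expected events (high expression = worse survival),
#' -1 otherwise.
#'
#' @param cohort A `survival_cohort` data.frame (`time_months`, `event`,
#'   `expr_<gene>` columns); see [simulate_survival()].
#' @param gene Marker gene name.
#' @return List of class `logrank_result`: `gene`, `chisq`, `p`,
#'   `direction`, `n_high`, `n_low`, `km_high`, `km_low`.
#' @export
logrank_median_split <- function(cohort, gene) {
  col <- paste0("expr_", gene)
  if (!col %in% names(cohort)) .stopf("gene '%s' not in cohort", gene)
  expr <- cohort[[col]]
  high <- expr > median(expr)     # ties at the median fall to the low arm
  if (sum(high) < 2 || sum(!high) < 2)
    .stopf("gene '%s': degenerate arm after median split", gene)
  lr <- .logrank(cohort$time_months, cohort$event, high)
  chisq <- if (lr$v > 0) (lr$o1 - lr$e1)^2 / lr$v else 0
  structure(list(
    gene = gene, chisq = chisq,
    p = if (lr$v > 0) pchisq(chisq, df = 1, lower.tail = FALSE) else 1,
    direction = if (lr$o1 >= lr$e1) 1L else -1L,
    n_high = sum(high), n_low = sum(!high),
    km_high = km_estimate(cohort$time_months[high], cohort$event[high]),
    km_low = km_estimate(cohort$time_months[!high], cohort$event[!high])
  ), class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank '%s': chi2 = %.3f, p = %.4g, direction %+d (n = %d/%d)\n",
              x$gene, x$chisq, x$p, x$direction, x$n_high, x$n_low))
  invisible(x)
}

#' Screen markers for exosome-abundance / survival concordance
#'
#' For each gene present in both tables, compares the direction of the
#' exosome abundance change in metastatic cells (ratio > 1 up, < 1 down)
#' with the hazard direction of its expression in the survival cohort. A
#' marker is concordant when abundance up coincides with high expression
#' being hazardous, or abundance down with low expression being hazardous.
#' Raw log-rank p-values are tiered: `significant` (p < 0.05),
#' `suggestive` (0.05 <= p < 0.1), `ns`; an optional BH adjustment is
#' reported alongside but does not change the tiers.
#'
#' @param ratios data.frame with columns `gene` and `ratio` (the
#'   metastatic-vs-non-metastatic ratio with the largest absolute log, as
#'   produced by the pipeline).
#' @param logrank_results List of [logrank_median_split()] results.
#' @param p_adjust_method Method for the additional adjusted-p column
#'   (default `"none"`, mirroring a raw-p screen).
#' @return data.frame: `gene`, `ratio`, `chisq`, `p`, `p_adjusted`,
#'   `direction`, `tier`, `concordant`.
#' @export
concordance_screen <- function(ratios, logrank_results,
                               p_adjust_method = "none") {
  lr_genes <- vapply(logrank_results, function(x) x$gene, character(1))
  common <- intersect(ratios$gene, lr_genes)
  missing <- union(setdiff(ratios$gene, lr_genes), setdiff(lr_genes, ratios$gene))
  if (length(missing))
    .warnf("%d gene(s) missing from one table were skipped: %s",
           length(missing), paste(head(missing, 5), collapse = ", "))
  if (!length(common)) .stopf("no genes shared between tables")
  lr <- logrank_results[match(common, lr_genes)]
  ratio <- ratios$ratio[match(common, ratios$gene)]
  p <- vapply(lr, `[[`, numeric(1), "p")
  dir <- vapply(lr, `[[`, integer(1), "direction")
  padj <- if (p_adjust_method == "none") p else p.adjust(p, p_adjust_method)
  data.frame(
    gene = common, ratio = ratio,
    chisq = vapply(lr, `[[`, numeric(1), "chisq"),
    p = p, p_adjusted = padj, direction = dir,
    tier = ifelse(p < 0.05, "significant",
                  ifelse(p < 0.1, "suggestive", "ns")),
    concordant = (ratio > 1 & dir == 1L) | (ratio < 1 & dir == -1L))
}
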