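#' Base peak chromatogram of a run
#'
#' One point per MS1 scan: the maximum centroided peak intensity in that
#' scan (0 for a scan with an empty peak list). The BPC is the alignment
#' substrate and, summed, one of the two reference-selection criteria.
#'
#' @param run A [spectrum_run()].
#' @return data.frame of class `bpc` with `rt_seconds`, `intensity`, and a
#'   `run_id` attribute.
#' @export
base_peak_chromatogram <- function(run) {
  stopifnot(inherits(run, "spectrum_run"))
  if (nrow(run$ms1) < 1) .stopf("run '%s' has no MS1 scans", run$run_id)
  v <- numeric(nrow(run$ms1))
  names(v) <- as.character(run$ms1$scan_id)
  if (nrow(run$peaks)) {
    dt <- data.table::as.data.table(run$peaks)
    mx <- dt[, list(bp = max(intensity)), by = scan_id]
    v[as.character(mx$scan_id)] <- mx$bp
  }
  out <- data.frame(rt_seconds = run$ms1$rt_seconds, intensity = unname(v))
  attr(out, "run_id") <- run$run_id
  class(out) <- c("bpc", "data.frame")
  out
}

# Max-bin a BPC onto a fixed grid of bin centers (empty bins -> 0).
.bin_bpc <- function(bpc, centers, bin_s) {
  idx <- round((bpc$rt_seconds - centers[1]) / bin_s) + 1L
  keep <- idx >= 1L & idx <= length(centers)
  v <- numeric(length(centers))
  if (any(keep)) {
    dt <- data.table::data.table(i = idx[keep], x = bpc$intensity[keep])
    mx <- dt[, list(x = max(x)), by = i]
    v[mx$i] <- mx$x
  }
  v
}

#' Monotone retention-time warp
#'
#' A strictly increasing piecewise-linear map from a run's own RT scale to
#' the reference RT scale, represented by anchor points. Evaluation is
#' linear interpolation between anchors; outside the anchor span values are
#' clamped (with a warning at application time).
#'
#' @param run_id Run the warp belongs to.
#' @param rt_from,rt_to Anchor RTs (seconds) on the run and reference
#'   scales; both strictly increasing.
#' @param score Alignment score in \[-1, 1\] (Pearson correlation of the
#'   DTW-matched base peak chromatograms), if known.
#' @return An object of class `warp_function`.
#' @export
warp_function <- function(run_id, rt_from, rt_to, score = NA_real_) {
  if (length(rt_from) != length(rt_to) || length(rt_from) < 2)
    .stopf("need >= 2 anchor pairs")
  if (is.unsorted(rt_from, strictly = TRUE) || is.unsorted(rt_to, strictly = TRUE))
    .stopf("warp anchors must be strictly increasing")
  structure(list(run_id = run_id,
                 anchors = data.frame(rt_from = rt_from, rt_to = rt_to),
                 score = score),
            class = "warp_function")
}

#' @export
print.warp_function <- function(x, ...) {
  cat(sprintf("warp_function '%s': %d anchors, RT %.0f-%.0f s -> %.0f-%.0f s, score %.4f\n",
              x$run_id, nrow(x$anchors),
              min(x$anchors$rt_from), max(x$anchors$rt_from),
              min(x$anchors$rt_to), max(x$anchors$rt_to), x$score))
  invisible(x)
}

#' Evaluate a warp at given retention times
#'
#' @param warp A [warp_function()].
#' @param rt Numeric vector of RTs (seconds) on the run's scale.
#' @param warn Warn when values fall outside the anchor span (clamped).
#' @return Mapped RTs on the reference scale.
#' @export
warp_rt <- function(warp, rt, warn = TRUE) {
  a <- warp$anchors
  if (warn && (any(rt < min(a$rt_from) - 1e-9) || any(rt > max(a$rt_from) + 1e-9)))
    .warnf("run '%s': %d RT value(s) outside warp domain were clamped",
           warp$run_id, sum(rt < min(a$rt_from) - 1e-9 | rt > max(a$rt_from) + 1e-9))
  approx(a$rt_from, a$rt_to, xout = rt, rule = 2)$y
}

#' Invert a warp
#'
#' Swaps the anchor columns; exact for the piecewise-linear representation.
#' @param warp A [warp_function()].
#' @return The inverse `warp_function` (reference scale -> run scale).
#' @export
invert_warp <- function(warp)
  warp_function(warp$run_id, warp$anchors$rt_to, warp$anchors$rt_from, warp$score)

.identity_warp <- function(run_id, span, score = 1)
  warp_function(run_id, span, span, score = score)

# z-normalized log intensity: DTW then matches shape, not the global
# intensity bias between runs
.zsig <- function(v) {
  v <- log1p(v)
  s <- sd(v)
  if (s == 0) v - mean(v) else (v - mean(v)) / s
}

# Refine DTW anchors by local cross-correlation: around each coarse anchor
# (af -> at) the shift maximizing the correlation between the run signal in
# a +/- half_w window and the interpolated reference signal is searched on a
# step_s grid within +/- search_s, with parabolic sub-step interpolation.
# Anchors whose best local correlation stays < 0.5 keep the DTW estimate.
.refine_anchors <- function(centers, x, y, af, at, half_w = 60,
                            search_s = 30, step_s = 1) {
  shifts <- seq(-search_s, search_s, by = step_s)
  fine_t <- seq(centers[1], centers[length(centers)], by = step_s)
  y_fine <- approx(centers, y, xout = fine_t, rule = 2)$y
  nf <- length(y_fine)
  vapply(seq_along(af), function(i) {
    sel <- which(abs(centers - af[i]) <= half_w)
    if (length(sel) < 5) return(at[i])
    xs <- x[sel]
    if (sd(xs) == 0) return(at[i])
    base_idx <- round((centers[sel] + (at[i] - af[i]) - fine_t[1]) / step_s) + 1
    idx <- outer(base_idx, round(shifts / step_s), "+")
    idx[idx < 1] <- 1; idx[idx > nf] <- nf
    Y <- matrix(y_fine[idx], nrow = length(sel))
    sdy <- apply(Y, 2, sd)
    cc <- suppressWarnings(as.vector(cor(xs, Y)))
    cc[sdy == 0] <- NA_real_
    if (all(is.na(cc)) || max(cc, na.rm = TRUE) < 0.5) return(at[i])
    k <- which.max(cc)
    s_best <- shifts[k]
    if (k > 1 && k < length(shifts) && !anyNA(cc[(k - 1):(k + 1)])) {
      den <- cc[k - 1] - 2 * cc[k] + cc[k + 1]
      if (den < 0) s_best <- s_best + 0.5 * step_s * (cc[k - 1] - cc[k + 1]) / den
    }
    at[i] + s_best
  }, numeric(1))
}

# force strict increase with minimal perturbation
.strictify <- function(x, eps = 1e-6) {
  x <- cummax(x)
  for (i in seq_along(x)[-1]) if (x[i] <= x[i - 1]) x[i] <- x[i - 1] + eps
  x
}

#' Estimate a retention-time warp between two runs
#'
#' Aligns the run's base peak chromatogram to the reference's by banded
#' dynamic time warping on log-intensity BPCs binned at `bin_s` seconds
#' (Sakoe-Chiba band `band_s`), then summarizes the optimal path into
#' monotone piecewise-linear anchors every `anchor_s` seconds. The reported
#' alignment score is the Pearson correlation of the path-matched binned
#' log intensities, in \[-1, 1\].
#'
#' @param run,reference [spectrum_run()]s overlapping in RT span.
#' @param bin_s BPC bin width (s).
#' @param band_s Maximum RT deviation searched (s).
#' @param anchor_s Anchor spacing (s).
#' @return A [warp_function()] mapping `run` RTs onto the reference scale;
#'   identity with score 1 when `run` is the reference.
#' @export
estimate_warp <- function(run, reference, bin_s = 5, band_s = 240, anchor_s = 60) {
  b_run <- base_peak_chromatogram(run)
  b_ref <- base_peak_chromatogram(reference)
  span_run <- range(b_run$rt_seconds)
  span_ref <- range(b_ref$rt_seconds)
  if (span_run[1] > span_ref[2] || span_ref[1] > span_run[2])
    .stopf("runs '%s' and '%s' do not overlap in RT", run$run_id, reference$run_id)
  if (identical(run$run_id, reference$run_id))
    return(.identity_warp(run$run_id, span_run))

  lo <- min(span_run[1], span_ref[1]); hi <- max(span_run[2], span_ref[2])
  centers <- seq(lo + bin_s / 2, hi, by = bin_s)
  x <- .zsig(.bin_bpc(b_run, centers, bin_s))
  y <- .zsig(.bin_bpc(b_ref, centers, bin_s))
  path <- .dtw_band_path(x, y, max(1L, as.integer(round(band_s / bin_s))))
  score <- if (sd(x[path[, 1]]) == 0 || sd(y[path[, 2]]) == 0) 0
    else cor(x[path[, 1]], y[path[, 2]])

  tx <- centers[path[, 1]]; ty <- centers[path[, 2]]
  cuts <- seq(lo, hi + anchor_s, by = anchor_s)
  grpidx <- findInterval(tx, cuts)
  ug <- sort(unique(grpidx))
  af <- vapply(ug, function(k) median(tx[grpidx == k]), numeric(1))
  at <- vapply(ug, function(k) median(ty[grpidx == k]), numeric(1))
  at <- .refine_anchors(centers, x, y, af, at, half_w = anchor_s,
                        search_s = 30, step_s = 1)
  # running median over anchor offsets: drift is locally smooth, so an
  # isolated anchor that locked onto a spurious correlation peak is replaced
  # by its neighborhood consensus
  if (length(af) >= 3) {
    k <- min(5L, length(af) - 1L + length(af) %% 2L)
    at <- af + stats::runmed(at - af, k, endrule = "median")
  }
  # extend to the run's exact span with the edge slopes
  slope1 <- if (length(af) > 1) (at[2] - at[1]) / max(af[2] - af[1], 1e-9) else 1
  slopeN <- if (length(af) > 1) (at[length(at)] - at[length(at) - 1]) /
      max(af[length(af)] - af[length(af) - 1], 1e-9) else 1
  af <- c(span_run[1] - 1, af, span_run[2] + 1)
  at <- c(at[1] - slope1 * (af[2] - af[1]), at,
          at[length(at)] + slopeN * (af[length(af)] - af[length(af) - 1]))
  keep <- !duplicated(af)
  warp_function(run$run_id, .strictify(af[keep]), .strictify(at[keep]), score)
}

#' Apply a warp to a run
#'
#' Maps every MS1 and MS2 retention time through the warp; peak lists and
#' scan order are unchanged. RTs outside the warp's anchor span are clamped
#' with a warning.
#'
#' @param run A [spectrum_run()].
#' @param warp A [warp_function()] whose domain covers the run's RT span.
#' @return The aligned [spectrum_run()].
#' @export
apply_warp <- function(run, warp) {
  stopifnot(inherits(run, "spectrum_run"), inherits(warp, "warp_function"))
  out <- run
  out$ms1$rt_seconds <- warp_rt(warp, run$ms1$rt_seconds)
  if (nrow(run$ms2))
    out$ms2$rt_seconds <- warp_rt(warp, run$ms2$rt_seconds, warn = FALSE)
  out
}

#' Select the reference run for alignment
#'
#' Scores every run by the sum of two ranks: the rank of its mean pairwise
#' alignment score against all other runs, and the rank of its total base
#' peak chromatogram intensity. The run with the highest rank sum wins;
#' ties break to the lexicographically smallest run id. Alignment scores
#' are rounded to 3 decimals before ranking so floating-point noise cannot
#' separate effectively identical alignments.
#'
#' @param runs List of [spectrum_run()]s.
#' @param bin_s,band_s Passed to the pairwise DTW (see [estimate_warp()]).
#' @return The selected run id (character scalar).
#' @export
select_reference <- function(runs, bin_s = 5, band_s = 240) {
  ids <- vapply(runs, function(r) r$run_id, character(1))
  if (length(runs) < 2) {
    .warnf("single run: returning it as its own reference")
    return(ids[1])
  }
  bpcs <- lapply(runs, base_peak_chromatogram)
  lo <- min(vapply(bpcs, function(b) min(b$rt_seconds), numeric(1)))
  hi <- max(vapply(bpcs, function(b) max(b$rt_seconds), numeric(1)))
  centers <- seq(lo + bin_s / 2, hi, by = bin_s)
  sig <- lapply(bpcs, function(b) .zsig(.bin_bpc(b, centers, bin_s)))
  n <- length(runs)
  band <- max(1L, as.integer(round(band_s / bin_s)))
  scores <- matrix(1, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    p <- .dtw_band_path(sig[[i]], sig[[j]], band)
    s <- if (sd(sig[[i]][p[, 1]]) == 0 || sd(sig[[j]][p[, 2]]) == 0) 0
      else cor(sig[[i]][p[, 1]], sig[[j]][p[, 2]])
    scores[i, j] <- scores[j, i] <- s
  }
  mean_score <- vapply(seq_len(n), function(i) mean(scores[i, -i]), numeric(1))
  total_bpc <- vapply(bpcs, function(b) sum(b$intensity), numeric(1))
  rank_sum <- rank(round(mean_score, 3), ties.method = "average") +
    rank(total_bpc, ties.method = "average")
  best <- which(rank_sum == max(rank_sum))
  ids[best][order(ids[best])][1]
}

#' Align a cohort of runs onto a common reference timescale
#'
#' Convenience wrapper: selects the reference (unless given), estimates a
#' warp per run, and applies it.
#'
#' @param runs List of [spectrum_run()]s.
#' @param reference Optional reference run id; chosen by
#'   [select_reference()] when `NULL`.
#' @param bin_s,band_s,anchor_s Passed to [estimate_warp()].
#' @return List with `runs` (aligned), `warps` (named list of
#'   [warp_function()]s) and `reference` (run id).
#' @export
align_runs <- function(runs, reference = NULL, bin_s = 5, band_s = 240,
                       anchor_s = 60) {
  ids <- vapply(runs, function(r) r$run_id, character(1))
  names(runs) <- ids
  if (is.null(reference)) reference <- select_reference(runs, bin_s, band_s)
  if (!reference %in% ids) .stopf("reference '%s' not among runs", reference)
  ref_run <- runs[[reference]]
  warps <- lapply(runs, estimate_warp, reference = ref_run,
                  bin_s = bin_s, band_s = band_s, anchor_s = anchor_s)
  aligned <- mapply(apply_warp, runs, warps, SIMPLIFY = FALSE)
  list(runs = aligned, warps = warps, reference = reference)
}
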