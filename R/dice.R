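#' Build frame targets from PSM identifications
#'
#' Resolves every PSM to its MS2 precursor event in the aligned runs, then
#' merges, per peptide and charge, events whose precursor m/z agree within
#' `ppm` and whose aligned RTs agree within `rt_window_s` (single-linkage).
#' Each resulting cluster is one quantitative frame target: its m/z center
#' is the precursor-intensity-weighted mean m/z, its RT center the median
#' aligned MS2 RT. Every PSM maps to exactly one target.
#'
#' @param psm_table PSM data.frame (see [read_psm_table()] for the schema).
#' @param runs Named list of aligned [spectrum_run()]s.
#' @param ppm m/z merge tolerance and extraction half-width, parts per
#'   million (default 10).
#' @param rt_window_s RT merge tolerance and extraction full width, seconds
#'   (default 60, i.e. 1 min).
#' @return data.frame of class `frame_targets`: `frame_id`, `peptide`,
#'   `charge`, `mz_center`, `rt_center`, `n_events`, plus a list column
#'   `scans` of contributing (run_id, ms2_scan_id) tables. `ppm` and
#'   `rt_window_s` are carried as attributes.
#' @export
build_frame_targets <- function(psm_table, runs, ppm = 10, rt_window_s = 60) {
  ids <- vapply(runs, function(r) r$run_id, character(1))
  names(runs) <- ids
  ms2 <- data.table::rbindlist(lapply(runs, function(r)
    data.table::data.table(run_id = r$run_id, ms2_scan_id = r$ms2$scan_id,
                           rt = r$ms2$rt_seconds, pmz = r$ms2$precursor_mz,
                           pint = r$ms2$precursor_intensity)))
  psm <- data.table::as.data.table(psm_table)
  ev <- merge(psm, ms2, by = c("run_id", "ms2_scan_id"), all.x = TRUE)
  bad <- which(is.na(ev$pmz))
  if (length(bad))
    .stopf("PSM '%s': ms2_scan_id %s not found in run '%s'",
           ev$psm_id[bad[1]], ev$ms2_scan_id[bad[1]], ev$run_id[bad[1]])

  data.table::setorder(ev, peptide, charge, rt, run_id, ms2_scan_id)
  key <- paste(ev$peptide, ev$charge, sep = "/")
  groups <- split(seq_len(nrow(ev)), key)
  res <- vector("list", length(groups))
  fid <- 0L
  for (g in groups) {
    cl <- .single_linkage(ev$pmz[g], ev$rt[g], ppm, rt_window_s)
    for (c_idx in split(seq_along(g), cl)) {
      fid <- fid + 1L
      rows <- g[c_idx]
      w <- ev$pint[rows]
      if (!all(is.finite(w)) || sum(w) <= 0) w <- rep(1, length(rows))
      res[[fid]] <- data.table::data.table(
        peptide = ev$peptide[rows[1]], charge = ev$charge[rows[1]],
        mz_center = sum(ev$pmz[rows] * w) / sum(w),
        rt_center = median(ev$rt[rows]),
        n_events = length(rows),
        scans = list(data.frame(run_id = ev$run_id[rows],
                                ms2_scan_id = ev$ms2_scan_id[rows])))
    }
  }
  out <- data.table::rbindlist(res[seq_len(fid)])
  data.table::setorder(out, peptide, charge, rt_center)
  out <- as.data.frame(out)
  out <- cbind(frame_id = sprintf("F%05d", seq_len(nrow(out))), out)
  attr(out, "ppm") <- ppm
  attr(out, "rt_window_s") <- rt_window_s
  class(out) <- c("frame_targets", "data.frame")
  out
}

# single-linkage clusters under (<= ppm relative m/z) AND (<= rt window)
.single_linkage <- function(mz, rt, ppm, rt_window_s) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (abs(rt[i] - rt[j]) <= rt_window_s &&
        abs(mz[i] - mz[j]) / ((mz[i] + mz[j]) / 2) * 1e6 <= ppm) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Extract frame ion current across all runs
#'
#' For every frame target and every run — whether or not that run carried
#' an MS2 identification for the target — forms the extracted-ion trace:
#' per MS1 scan with aligned RT within `rt_window_s / 2` of the frame
#' center, the most intense peak within `ppm` of the frame m/z center (0 if
#' none). The frame area is the trapezoidal integral of this trace over
#' RT; a window holding a single scan uses area = intensity x cycle time.
#' This per-run exhaustive extraction is what removes run-level missingness
#' at the frame level: every (frame, run) cell gets an area (possibly 0).
#'
#' @param runs Named list of aligned [spectrum_run()]s.
#' @param targets A [build_frame_targets()] result.
#' @param ppm,rt_window_s Extraction window; defaults taken from the
#'   `targets` attributes.
#' @return List of class `frame_quant`: `area` (frames x runs matrix),
#'   `apex_rt` (same shape), `targets`.
#' @export
extract_frames <- function(runs, targets,
                           ppm = attr(targets, "ppm") %||% 10,
                           rt_window_s = attr(targets, "rt_window_s") %||% 60) {
  ids <- vapply(runs, function(r) r$run_id, character(1))
  names(runs) <- ids
  mz_lo <- targets$mz_center * (1 - ppm * 1e-6)
  mz_hi <- targets$mz_center * (1 + ppm * 1e-6)
  rt_lo <- targets$rt_center - rt_window_s / 2
  rt_hi <- targets$rt_center + rt_window_s / 2
  area <- apex <- matrix(NA_real_, nrow(targets), length(runs),
                         dimnames = list(targets$frame_id, ids))
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    scan_rt <- run$ms1$rt_seconds
    cycle <- if (length(scan_rt) > 1) median(diff(scan_rt)) else 1
    o <- order(run$peaks$mz)
    scan_idx <- match(run$peaks$scan_id, run$ms1$scan_id)[o] - 1L
    m <- .extract_frames_run(scan_rt, scan_idx, run$peaks$mz[o],
                             run$peaks$intensity[o],
                             mz_lo, mz_hi, rt_lo, rt_hi, cycle)
    area[, r] <- m[, 1]
    apex[, r] <- m[, 2]
  }
  stopifnot(!anyNA(area))  # structural: one area per (frame, run)
  structure(list(area = area, apex_rt = apex, targets = targets),
            class = "frame_quant")
}

#' Extract a single frame from a single run
#'
#' @param run An aligned [spectrum_run()].
#' @param target One-row subset of a [build_frame_targets()] result (or any
#'   list with `mz_center` and `rt_center`).
#' @param ppm,rt_window_s Extraction window.
#' @return List with `area` and `apex_rt` (NA when the trace is all zero).
#' @export
extract_frame <- function(run, target, ppm = 10, rt_window_s = 60) {
  tg <- data.frame(frame_id = "F00001", mz_center = target$mz_center,
                   rt_center = target$rt_center)
  attr(tg, "ppm") <- ppm; attr(tg, "rt_window_s") <- rt_window_s
  q <- extract_frames(list(run), tg, ppm, rt_window_s)
  list(area = unname(q$area[1, 1]), apex_rt = unname(q$apex_rt[1, 1]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
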