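#' Write a run in the TSV peak-list dialect
#'
#' One row per MS1 peak (`ms_level` 1; empty scans keep one row with NA
#' m/z) and one row per MS2 precursor event (`ms_level` 2; `mz` NA,
#' `intensity` = precursor intensity at the triggering scan). Columns:
#' `scan_id`, `ms_level`, `rt_seconds`, `mz`, `intensity`, `precursor_mz`,
#' `precursor_scan_id`. The round trip through [read_spectra()] is
#' lossless.
#'
#' @param run A [spectrum_run()].
#' @param path Output file; conventionally `<run_id>.tsv`.
#' @export
write_spectra <- function(run, path) {
  stopifnot(inherits(run, "spectrum_run"))
  pk <- run$peaks
  empty <- setdiff(run$ms1$scan_id, pk$scan_id)
  ms1 <- data.frame(
    scan_id = c(pk$scan_id, empty), ms_level = 1L,
    rt_seconds = run$ms1$rt_seconds[match(c(pk$scan_id, empty), run$ms1$scan_id)],
    mz = c(pk$mz, rep(NA_real_, length(empty))),
    intensity = c(pk$intensity, rep(NA_real_, length(empty))),
    precursor_mz = NA_real_, precursor_scan_id = NA_integer_)
  ms2 <- if (nrow(run$ms2)) data.frame(
    scan_id = run$ms2$scan_id, ms_level = 2L,
    rt_seconds = run$ms2$rt_seconds, mz = NA_real_,
    intensity = run$ms2$precursor_intensity,
    precursor_mz = run$ms2$precursor_mz,
    precursor_scan_id = run$ms2$precursor_scan_id) else NULL
  out <- rbind(ms1, ms2)
  out <- out[order(out$rt_seconds, out$ms_level, out$scan_id, out$mz), ]
  data.table::fwrite(out, path, sep = "\t", na = "NA")
  invisible(path)
}

#' Read runs from the TSV peak-list dialect
#'
#' @param path A `.tsv` file (one run; run id = file name without
#'   extension) or a directory of them.
#' @return A [spectrum_run()], or a named list of them for a directory.
#' @export
read_spectra <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tsv$", full.names = TRUE))
    if (!length(files)) .stopf("no .tsv runs in %s", path)
    runs <- lapply(files, read_spectra)
    names(runs) <- vapply(runs, function(r) r$run_id, character(1))
    return(runs)
  }
  if (!file.exists(path)) .stopf("no such file: %s", path)
  d <- data.table::fread(path, sep = "\t", na.strings = "NA")
  need <- c("scan_id", "ms_level", "rt_seconds", "mz", "intensity",
            "precursor_mz", "precursor_scan_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) .stopf("%s: missing column '%s'", path, miss[1])
  rid <- sub("\\.tsv$", "", basename(path))
  m1 <- d[d$ms_level == 1L, ]
  if (!nrow(m1)) .stopf("%s: no MS1 scans", path)
  scans <- unique(m1[, c("scan_id", "rt_seconds")])
  scans <- scans[order(scans$rt_seconds, scans$scan_id), ]
  pk <- m1[!is.na(m1$mz), c("scan_id", "mz", "intensity")]
  m2 <- d[d$ms_level == 2L, ]
  ms2 <- data.frame(scan_id = m2$scan_id, rt_seconds = m2$rt_seconds,
                    precursor_mz = m2$precursor_mz,
                    precursor_intensity = m2$intensity,
                    precursor_scan_id = m2$precursor_scan_id)
  spectrum_run(rid, as.data.frame(scans), as.data.frame(pk), ms2)
}

.psm_columns <- c("psm_id", "run_id", "ms2_scan_id", "peptide", "charge",
                  "protein_accession", "is_unique")

#' Read a filtered PSM table
#'
#' Consumes the upstream search/FDR output in the documented TSV schema
#' (`psm_id`, `run_id`, `ms2_scan_id`, `peptide`, `charge`,
#' `protein_accession`, `is_unique`). FDR filtering itself is an input
#' contract, not performed here.
#'
#' @param path TSV file.
#' @return Validated data.frame.
#' @export
read_psm_table <- function(path) {
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  miss <- setdiff(.psm_columns, names(d))
  if (length(miss)) .stopf("%s: missing PSM column '%s'", path, miss[1])
  if (anyDuplicated(d$psm_id))
    .stopf("%s: duplicate psm_id '%s'", path, d$psm_id[duplicated(d$psm_id)][1])
  d$is_unique <- as.logical(d$is_unique)
  d
}

#' @rdname read_psm_table
#' @param psm_table The table to write.
#' @export
write_psm_table <- function(psm_table, path) {
  data.table::fwrite(psm_table[.psm_columns], path, sep = "\t")
  invisible(path)
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end pipeline with its default:
#' extraction window (10 ppm, 60 s), differential gates (p < 0.05, ratio
#' > 1.5 or < 0.67), pattern margin (0.5), and the group roles.
#'
#' @param groups Sample id -> group label named character vector.
#' @param control_group,non_metastatic_group,metastatic_groups Group roles.
#' @param ppm,rt_window_s Frame window.
#' @param p_threshold,ratio_up,ratio_down Differential gates.
#' @param margin Pattern-assignment margin.
#' @param bin_s,band_s Alignment parameters.
#' @param seed Seed recorded into outputs.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(groups, control_group, non_metastatic_group,
                            metastatic_groups,
                            ppm = 10, rt_window_s = 60,
                            p_threshold = 0.05, ratio_up = 1.5,
                            ratio_down = 0.67, margin = 0.5,
                            bin_s = 5, band_s = 240, seed = 1L) {
  if (!(ratio_down < 1 && 1 < ratio_up)) .stopf("need ratio_down < 1 < ratio_up")
  if (ppm <= 0 || rt_window_s <= 0 || p_threshold <= 0)
    .stopf("thresholds must be positive")
  if (is.null(names(groups)) || anyNA(groups))
    .stopf("every sample needs exactly one group label")
  roles <- c(control_group, non_metastatic_group, metastatic_groups)
  if (!all(roles %in% groups)) .stopf("group role not present among samples")
  structure(list(groups = groups, control_group = control_group,
                 non_metastatic_group = non_metastatic_group,
                 metastatic_groups = metastatic_groups,
                 ppm = ppm, rt_window_s = rt_window_s,
                 p_threshold = p_threshold, ratio_up = ratio_up,
                 ratio_down = ratio_down, margin = margin,
                 bin_s = bin_s, band_s = band_s, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param config A `pipeline_config` to write.
#' @param path JSON file path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!requireNamespace("jsonlite", quietly = TRUE))
    .stopf("config serialization needs the jsonlite package")
  x <- unclass(config)
  x$groups <- as.list(x$groups)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  if (!requireNamespace("jsonlite", quietly = TRUE))
    .stopf("config serialization needs the jsonlite package")
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$groups <- unlist(x$groups)
  x$seed <- as.integer(x$seed)
  do.call(pipeline_config, x)
}

# polynomial rolling hash over the serialized object; provenance fingerprint
.config_hash <- function(x) {
  b <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (v in b) h <- (h * 31 + v + 1) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the frame-quantification pipeline end to end
#'
#' Stages, in order: reference selection and RT alignment; frame-target
#' construction and per-run ion-current extraction; annotation merge;
#' dataset-wide normalization; peptide outlier flagging; protein roll-up;
#' differential gating (altered / metastasis-specific); pattern
#' classification with non-metastatic exclusion; optional survival screen
#' and gene-set over-representation. Deterministic: identical config and
#' inputs give identical outputs; the config hash and seed are carried in
#' the result's `log`.
#'
#' @param runs Named list of [spectrum_run()]s (unaligned).
#' @param psm_table PSM data.frame (see [read_psm_table()]).
#' @param config A [pipeline_config()].
#' @param survival_cohort Optional `survival_cohort` whose `expr_<gene>`
#'   columns are named by protein accessions.
#' @param gene_sets Optional named list of gene sets for
#'   over-representation against the quantified-protein universe.
#' @return List of class `pipeline_result`: `reference`, `warps`,
#'   `targets`, `frame_quant`, `normalization`, `outlier_peptides`,
#'   `protein_matrix`, `records`, `altered`, `metastasis_specific`,
#'   `patterns`, `metastasis_patterns`, `cv`, optional `survival` and
#'   `enrichment`, and `log`.
#' @export
run_pipeline <- function(runs, psm_table, config,
                         survival_cohort = NULL, gene_sets = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }
  al <- stage("align", align_runs(runs, bin_s = config$bin_s,
                                  band_s = config$band_s))
  targets <- stage("extract", build_frame_targets(psm_table, al$runs,
                                                  ppm = config$ppm,
                                                  rt_window_s = config$rt_window_s))
  fq <- stage("extract", extract_frames(al$runs, targets))
  ann <- stage("quantify", annotate_frames(targets, psm_table))
  norm <- stage("quantify", normalize_frames(fq$area))
  outl <- stage("quantify", flag_outlier_peptides(ann, norm))
  pm <- stage("quantify", aggregate_proteins(ann, norm, outl, config$groups))
  rec <- stage("diff", differential_records(
    pm, config$control_group, config$non_metastatic_group,
    config$metastatic_groups, p_threshold = config$p_threshold,
    ratio_up = config$ratio_up, ratio_down = config$ratio_down))
  altered <- select_altered(rec, config$p_threshold, config$ratio_up,
                            config$ratio_down)
  met <- select_metastasis_specific(rec, config$p_threshold, config$ratio_up,
                                    config$ratio_down)
  tumor4 <- c(config$non_metastatic_group, config$metastatic_groups)
  pat <- if (length(met)) stage("classify", {
    z <- standardize_profiles(pm, tumor4, proteins = met)
    assign_patterns(z, delta = config$margin)
  }) else NULL
  met_final <- if (!is.null(pat)) exclude_non_metastatic(pat) else NULL

  surv_res <- NULL
  if (!is.null(survival_cohort) && !is.null(met_final) && nrow(met_final)) {
    genes <- intersect(met_final$protein,
                       sub("^expr_", "", grep("^expr_", names(survival_cohort),
                                              value = TRUE)))
    if (length(genes)) surv_res <- stage("survival", {
      lrs <- lapply(genes, function(g) logrank_median_split(survival_cohort, g))
      mc <- grep("^mratio_", names(rec), value = TRUE)
      mr <- as.matrix(rec[match(genes, rec$protein), mc, drop = FALSE])
      pick <- apply(mr, 1, function(x) x[which.max(abs(log(x)))])
      concordance_screen(data.frame(gene = genes, ratio = pick), lrs)
    })
  }
  enr <- if (!is.null(gene_sets) && length(altered))
    stage("enrich", fisher_enrichment(altered, gene_sets,
                                      universe = rownames(pm$abundance)))
  else NULL

  structure(list(
    reference = al$reference, warps = al$warps, targets = targets,
    frame_quant = fq, normalization = norm, outlier_peptides = outl,
    protein_matrix = pm, records = rec, altered = altered,
    metastasis_specific = met, patterns = pat,
    metastasis_patterns = met_final, cv = intragroup_cv(pm),
    survival = surv_res, enrichment = enr,
    log = list(config = config, config_hash = .config_hash(config),
               seed = config$seed, reference = al$reference,
               n_runs = length(runs), n_psms = nrow(psm_table),
               n_frames = nrow(targets), n_proteins = nrow(pm$abundance),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(paste0(
    "pipeline_result (config %s, seed %d)\n",
    "  reference run: %s\n  frames: %d   proteins: %d\n",
    "  altered: %d   metastasis-specific: %d (%d after pattern exclusion)\n"),
    x$log$config_hash, x$log$seed, x$reference, x$log$n_frames,
    x$log$n_proteins, length(x$altered), length(x$metastasis_specific),
    if (!is.null(x$metastasis_patterns)) nrow(x$metastasis_patterns) else 0L))
  invisible(x)
}

#' Write the main pipeline outputs as CSV/TSV files
#'
#' @param result A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(x, name) {
    p <- file.path(dir, name)
    data.table::fwrite(x, p)
    paths <<- c(paths, p)
  }
  ab <- data.frame(protein = rownames(result$protein_matrix$abundance),
                   result$protein_matrix$abundance, check.names = FALSE)
  w(ab, "protein_matrix.csv")
  tg <- result$targets
  fr <- data.frame(frame_id = tg$frame_id, peptide = tg$peptide,
                   charge = tg$charge, mz_center = tg$mz_center,
                   rt_center = tg$rt_center,
                   result$frame_quant$area, check.names = FALSE)
  p <- file.path(dir, "frame_quant.tsv")
  data.table::fwrite(fr, p, sep = "\t"); paths <- c(paths, p)
  anchors <- do.call(rbind, lapply(result$warps, function(wp)
    data.frame(run_id = wp$run_id, rt_from = wp$anchors$rt_from,
               rt_to = wp$anchors$rt_to)))
  w(anchors, "warp_anchors.csv")
  w(data.frame(run = names(result$normalization$factors),
               factor = result$normalization$factors), "normalization_factors.csv")
  w(result$records, "differential_records.csv")
  if (!is.null(result$patterns)) w(result$patterns, "pattern_assignments.csv")
  if (!is.null(result$survival)) w(result$survival, "survival_screen.csv")
  if (!is.null(result$enrichment)) w(result$enrichment, "enrichment.csv")
  writeLines(c(sprintf("config_hash: %s", result$log$config_hash),
               sprintf("seed: %d", result$log$seed),
               sprintf("reference: %s", result$log$reference)),
             file.path(dir, "run_log.txt"))
  invisible(c(paths, file.path(dir, "run_log.txt")))
}
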