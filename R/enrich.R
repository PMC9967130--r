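#' Read a GMT gene-set file
#'
#' Standard tab-separated format: set name, description, then member
#' identifiers. Identifiers are case-normalized to upper case.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (unique members per set).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("empty GMT file: %s", path)
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3 || !nzchar(f[1]))
      .stopf("malformed GMT line (need name, description, >= 1 member): %.60s", l)
    unique(toupper(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  if (anyDuplicated(names(sets))) .stopf("duplicate set names in GMT")
  sets
}

#' Gene-set collection restricted to a background universe
#'
#' @param sets Named list of character vectors.
#' @param universe Background identifiers (e.g. all quantified proteins).
#' @return Object of class `gene_set_collection` (sets intersected with
#'   the universe; members outside it dropped with a warning).
#' @export
gene_set_collection <- function(sets, universe) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("every set needs a non-empty name")
  universe <- unique(toupper(universe))
  sets <- lapply(sets, toupper)
  dropped <- sum(vapply(sets, function(s) sum(!s %in% universe), numeric(1)))
  if (dropped > 0)
    .warnf("%d set member(s) outside the universe were dropped", dropped)
  structure(list(sets = lapply(sets, intersect, universe),
                 universe = universe),
            class = "gene_set_collection")
}

#' Fisher over-representation test against a gene-set collection
#'
#' One-sided (greater) Fisher exact test per set on the 2x2 table of
#' query/set membership within the background universe, with
#' Benjamini-Hochberg adjustment across all sets. Query members outside
#' the universe are dropped with a warning.
#'
#' @param query Character vector of identifiers (case-normalized).
#' @param collection A [gene_set_collection()] (or a named list of sets,
#'   in which case `universe` must be given).
#' @param universe Background universe when `collection` is a plain list.
#' @return data.frame sorted by adjusted p: `set`, `overlap`, `query_size`,
#'   `set_size`, `universe_size`, `p`, `p_adjusted`.
#' @export
fisher_enrichment <- function(query, collection, universe = NULL) {
  if (!inherits(collection, "gene_set_collection"))
    collection <- gene_set_collection(collection, universe)
  query <- unique(toupper(query))
  out <- setdiff(query, collection$universe)
  if (length(out)) {
    .warnf("%d query member(s) outside the universe were dropped", length(out))
    query <- intersect(query, collection$universe)
  }
  if (!length(query)) .stopf("empty query after universe restriction")
  U <- length(collection$universe); q <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    a <- length(intersect(query, s))
    tab <- matrix(c(a, q - a, length(s) - a, U - q - length(s) + a), 2, 2)
    data.frame(set = nm, overlap = a, query_size = q, set_size = length(s),
               universe_size = U,
               p = fisher.test(tab, alternative = "greater")$p.value)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- p.adjust(res$p, method = "BH")
  res[order(res$p_adjusted, res$p, res$set), ]
}

#' Overlap arithmetic between identifier lists
#'
#' Pairwise intersections plus union/intersection of all lists, reported
#' as counts and percentages of the query. Identifiers are
#' case-normalized.
#'
#' @param query Character vector.
#' @param ... Named reference character vectors.
#' @return List with `pairwise` (data.frame: reference, overlap,
#'   pct_of_query), `union_n`, `intersection_n`, `query_n`.
#' @export
list_overlap <- function(query, ...) {
  refs <- list(...)
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    names(refs) <- sprintf("reference%d", seq_along(refs))
  query <- unique(toupper(query))
  refs <- lapply(refs, function(r) unique(toupper(r)))
  pw <- do.call(rbind, lapply(names(refs), function(nm) {
    ov <- length(intersect(query, refs[[nm]]))
    data.frame(reference = nm, overlap = ov,
               pct_of_query = if (length(query)) 100 * ov / length(query) else 0)
  }))
  all_sets <- c(list(query = query), refs)
  list(pairwise = pw,
       union_n = length(Reduce(union, all_sets)),
       intersection_n = length(Reduce(intersect, all_sets)),
       query_n = length(query))
}
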