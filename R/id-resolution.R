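#' Build a gene-name universe from gene-set collections
#'
#' The union of all member names across one or more collections, with
#' duplicates removed. Quantified proteins are later resolved against this
#' universe so that differential results and gene sets speak the same
#' vocabulary.
#'
#' @param collections a `GeneSetCollection` or list of them; at least one
#'   member overall.
#' @return Character vector of unique gene names (class `Universe`).
#' @export
build_universe <- function(collections) {
  if (inherits(collections, "GeneSetCollection")) collections <- list(collections)
  names_all <- unique(unlist(lapply(collections, unlist, use.names = FALSE),
                             use.names = FALSE))
  if (length(names_all) == 0) stop("all collections are empty")
  structure(names_all, class = "Universe")
}

#' Resolve an ordered identifier list to one gene name
#'
#' Each quantified protein carries candidate identifiers ranked by
#' confidence. The earliest candidate present in the universe wins; when
#' none intersects the universe, the first (most confident) candidate is
#' used as-is.
#'
#' @param ordered_ids character vector of candidates, most confident first;
#'   or a single semicolon-delimited string.
#' @param universe a [build_universe()] result (or plain character vector).
#' @param normalize_case if `TRUE`, match case-insensitively (returning the
#'   universe's spelling). Off by default: GMT symbols are canonical.
#' @return A single gene name.
#' @export
resolve_identifier <- function(ordered_ids, universe, normalize_case = FALSE) {
  if (length(ordered_ids) == 1 && grepl(";", ordered_ids, fixed = TRUE))
    ordered_ids <- strsplit(ordered_ids, ";", fixed = TRUE)[[1]]
  if (length(ordered_ids) == 0) stop("`ordered_ids` must be non-empty")
  if (normalize_case) {
    hit <- match(toupper(ordered_ids), toupper(universe))
    ok <- which(!is.na(hit))
    if (length(ok) > 0) return(unclass(universe)[hit[ok[1]]])
  } else {
    ok <- which(ordered_ids %in% universe)
    if (length(ok) > 0) return(ordered_ids[ok[1]])
  }
  ordered_ids[1]
}

#' Resolve a table of identifier records
#'
#' @param records `data.frame` with an `ordered_ids` column
#'   (semicolon-delimited), e.g. from [generate_identifier_lists()].
#' @inheritParams resolve_identifier
#' @return The table with a `resolved` column appended.
#' @export
resolve_identifiers <- function(records, universe, normalize_case = FALSE) {
  records$resolved <- vapply(records$ordered_ids, resolve_identifier, "",
                             universe = universe,
                             normalize_case = normalize_case,
                             USE.NAMES = FALSE)
  records
}

#' Partition proteins by the tissues they were identified in
#'
#' The full Venn partition of post-filter identifications: every protein is
#' assigned to exactly one cell keyed by the sorted tissue subset it
#' appears in (e.g. `"islet+liver"`).
#'
#' @param matrices named list of per-tissue `IntensityMatrix` objects
#'   (>= 2 tissues).
#' @return Named list: subset key -> character vector of protein ids. Cells
#'   are disjoint and cover every protein.
#' @export
compute_tissue_overlap <- function(matrices) {
  if (length(matrices) < 2) stop("need >= 2 tissues")
  if (is.null(names(matrices))) stop("`matrices` must be named by tissue")
  membership <- lapply(matrices, function(m) rownames(values(m)))
  proteins <- unique(unlist(membership, use.names = FALSE))
  key <- vapply(proteins, function(p) {
    paste(sort(names(matrices)[vapply(membership, function(g) p %in% g, TRUE)]),
          collapse = "+")
  }, "")
  split(proteins, key)
}
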