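#' Gene-set collections and the GMT format
#'
#' A gene-set collection is represented as a named list of character vectors
#' (set name -> member gene names) with a parallel `descriptions` attribute,
#' mirroring the tab-separated GMT layout: one set per line, fields
#' `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param sets named list of character vectors; names unique, members
#'   non-empty.
#' @param descriptions optional character vector of per-set descriptions.
#' @return A `GeneSetCollection` (named list with class attribute).
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (length(sets) > 0) {
    if (is.null(names(sets)) || anyDuplicated(names(sets)))
      stop("set names must be present and unique")
    if (any(lengths(sets) == 0))
      stop("empty gene sets are not allowed: ",
           paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  names(descriptions) <- names(sets)
  structure(sets, descriptions = descriptions, class = "GeneSetCollection")
}

#' @export
print.GeneSetCollection <- function(x, ...) {
  cat(sprintf("GeneSetCollection: %d sets, %d distinct genes\n",
              length(x), length(unique(unlist(x, use.names = FALSE)))))
  invisible(x)
}

#' @export
`[.GeneSetCollection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], attr(x, "descriptions")[i])
}

#' @rdname gene_set_collection
#' @param path GMT file path.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(gene_set_collection(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1)
  gene_set_collection(sets, vapply(parts, `[[`, "", 2))
}

#' @rdname gene_set_collection
#' @param collection a `GeneSetCollection` to write.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  lines <- vapply(seq_along(collection), function(i) {
    paste(c(names(collection)[i], desc[[i]], collection[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
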