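#' Protein intensity matrix
#'
#' Container for a proteins x samples abundance matrix from label-free
#' quantification. Missing cells are `NA`; the missingness mask is therefore
#' `!is.na(values(m))`. The object tracks which tissue the matrix came from
#' and whether values are on the raw or log2 scale, so that scale-sensitive
#' steps (log transform, median sweep, imputation) can refuse wrong input.
#'
#' @param values numeric matrix, proteins in rows, samples in columns; both
#'   dimnames must be set and unique. `NA` marks a missing (unquantified)
#'   cell.
#' @param tissue single string labelling the tissue of origin.
#' @param scale `"raw"` (positive intensities) or `"log2"`.
#' @return An object of class `IntensityMatrix`.
#' @examples
#' v <- matrix(2^rnorm(12, 20), 3, 4,
#'             dimnames = list(paste0("P", 1:3), paste0("s", 1:4)))
#' m <- intensity_matrix(v, tissue = "liver", scale = "raw")
#' dim(m)
#' @export
intensity_matrix <- function(values, tissue = "tissue", scale = c("log2", "raw")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have protein row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicated protein ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicated sample ids in `values`")
  if (scale == "raw" && any(values < 0, na.rm = TRUE))
    stop("negative values are not allowed on the raw scale")
  structure(list(values = values, tissue = tissue, scale = scale),
            class = "IntensityMatrix")
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("IntensityMatrix: %d proteins x %d samples (tissue: %s, scale: %s)\n",
              nrow(v), ncol(v), x$tissue, x$scale))
  cat(sprintf("missing: %.1f%% of cells\n", 100 * mean(is.na(v))))
  invisible(x)
}

#' @export
dim.IntensityMatrix <- function(x) dim(x$values)

#' Extract the value matrix of an IntensityMatrix
#' @param m an `IntensityMatrix`.
#' @return The numeric proteins x samples matrix (with `NA` for missing).
#' @export
values <- function(m) {
  stopifnot(inherits(m, "IntensityMatrix"))
  m$values
}

#' Observed-cell mask of an IntensityMatrix
#' @param m an `IntensityMatrix`.
#' @return Logical matrix, `TRUE` where a value was observed.
#' @export
observed_mask <- function(m) !is.na(values(m))

with_values <- function(m, v) {
  m$values <- v
  m
}

#' Read / write an intensity matrix as TSV
#'
#' The file has a `protein_id` first column followed by one column per
#' sample; empty fields are missing values.
#'
#' @param path file path.
#' @param tissue,scale passed to [intensity_matrix()] on read.
#' @return `read_intensity_tsv()` returns an `IntensityMatrix`;
#'   `write_intensity_tsv()` returns `path` invisibly.
#' @export
read_intensity_tsv <- function(path, tissue = "tissue", scale = "log2") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "protein_id")
    stop("first column must be `protein_id`: ", path)
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- df$protein_id
  intensity_matrix(v, tissue = tissue, scale = scale)
}

#' @rdname read_intensity_tsv
#' @param m an `IntensityMatrix` to write.
#' @export
write_intensity_tsv <- function(m, path) {
  v <- values(m)
  df <- data.frame(protein_id = rownames(v), v, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
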