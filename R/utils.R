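#' @importFrom stats plogis rbinom runif setNames optim predict quantile var
#' @importFrom utils read.delim write.table head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

pathnn_error <- function(msg, class) {
  stop(structure(class = c(class, "pathnn_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

parse_error <- function(msg) pathnn_error(msg, "pathnn_parse_error")
structural_error <- function(msg) pathnn_error(msg, "pathnn_structural_error")
config_error <- function(msg) pathnn_error(msg, "pathnn_config_error")
validation_error <- function(msg) pathnn_error(msg, "pathnn_validation_error")

#' Build a binary mask matrix
#'
#' Masks encode which connections between two adjacent network layers exist:
#' the gene-membership adjacency (gene -> first pathway layer) and the
#' pathway parent-child masks. Stored as a sparse 0/1 `Matrix` with row
#' (target-layer) and column (source-layer) identifiers in the dimnames.
#'
#' @param row_ids character vector of target-layer node ids (the mask's rows).
#' @param col_ids character vector of source-layer node ids (columns).
#' @param links two-column data.frame (target id, source id), one nonzero per row.
#' @return a `dgCMatrix` with entries in \{0,1\} and `dimnames = list(row_ids, col_ids)`.
#' @export
mask_matrix <- function(row_ids, col_ids, links) {
  stopifnot(is.data.frame(links), ncol(links) >= 2)
  i <- match(links[[1]], row_ids)
  j <- match(links[[2]], col_ids)
  if (anyNA(i) || anyNA(j))
    structural_error("mask links reference ids absent from the layer node lists")
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(row_ids), length(col_ids)),
                            dimnames = list(row_ids, col_ids))
  m@x[] <- 1  # collapse duplicate triplets to binary
  m
}

write_mask_triplets <- function(mask, path) {
  idx <- Matrix::which(mask != 0, arr.ind = TRUE)
  rn <- rownames(mask)[idx[, 1]]
  cn <- colnames(mask)[idx[, 2]]
  o <- order(rn, cn)
  writeLines(paste(rn[o], cn[o], sep = "\t"), path)
}

read_mask_triplets <- function(path, row_ids, col_ids) {
  lines <- readLines(path)
  if (length(lines) == 0)
    return(mask_matrix(row_ids, col_ids, data.frame(r = character(), c = character())))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2)
  if (length(bad))
    parse_error(sprintf("%s: line %d is not 'row<TAB>col'", path, bad[1]))
  mask_matrix(row_ids, col_ids,
              data.frame(r = vapply(parts, `[[`, "", 1),
                         c = vapply(parts, `[[`, "", 2)))
}

# Full-precision numeric text round-trip ("%.17g" preserves doubles exactly).
format_full <- function(x) sprintf("%.17g", x)

write_numeric_tsv <- function(mat, path) {
  txt <- apply(mat, 1, function(r) paste(format_full(r), collapse = "\t"))
  writeLines(txt, path)
}

read_numeric_tsv <- function(path, nrow, ncol) {
  lines <- readLines(path)
  stopifnot(length(lines) == nrow)
  out <- matrix(0, nrow, ncol)
  for (r in seq_len(nrow)) out[r, ] <- as.numeric(strsplit(lines[r], "\t", fixed = TRUE)[[1]])
  out
}
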