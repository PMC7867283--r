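# Descriptor matrices: compounds x named numeric descriptors, the QSAR
# feature space. Internally a dense numeric matrix with compound ids as row
# names; the on-disk interface is a CSV whose first column is compound_id.

#' Coerce to a descriptor matrix
#'
#' Accepts a numeric matrix with row names, or a data frame whose first
#' column is `compound_id` followed by numeric descriptor columns. Validates
#' that values are finite and flags constant-valued columns via the
#' `"constant"` attribute (they carry no class signal and are dropped at
#' training time).
#'
#' @param x Matrix or data frame.
#' @return A numeric matrix, rows named by compound id, with a logical
#'   `"constant"` attribute per column.
#' @export
as_descriptor_matrix <- function(x) {
  if (is.data.frame(x)) {
    ids <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- ids
  } else if (is.matrix(x)) {
    m <- x
    storage.mode(m) <- "double"
    if (is.null(rownames(m))) {
      stop("descriptor matrix needs compound ids as row names", call. = FALSE)
    }
  } else {
    stop("cannot interpret `x` as a descriptor matrix", call. = FALSE)
  }
  if (ncol(m) == 0L) stop("descriptor matrix has no descriptor columns", call. = FALSE)
  if (is.null(colnames(m)) || any(!nzchar(colnames(m)))) {
    stop("every descriptor column must be named", call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)
    stop("non-finite descriptor value(s), first at compound ",
         rownames(m)[bad[1, 1]], ", descriptor ", colnames(m)[bad[1, 2]],
         call. = FALSE)
  }
  dup <- unique(rownames(m)[duplicated(rownames(m))])
  if (length(dup)) {
    stop("duplicate compound_id in descriptor matrix: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  attr(m, "constant") <- apply(m, 2, function(v) diff(range(v)) == 0)
  m
}

#' Read a descriptor matrix from CSV
#'
#' First column `compound_id`, remaining columns numeric descriptors, header
#' row mandatory.
#'
#' @param path CSV path.
#' @return A descriptor matrix (see [as_descriptor_matrix()]).
#' @export
read_descriptors <- function(path) {
  raw <- read.csv(path, check.names = FALSE)
  if (names(raw)[1] != "compound_id") {
    stop("descriptor CSV must have compound_id as its first column", call. = FALSE)
  }
  as_descriptor_matrix(raw)
}

#' Write a descriptor matrix to CSV
#'
#' @param m Descriptor matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptors <- function(m, path) {
  m <- as_descriptor_matrix(m)
  out <- data.frame(compound_id = rownames(m), m, check.names = FALSE,
                    row.names = NULL)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Align a descriptor matrix with a set of compound ids, preserving id order.
descriptor_rows <- function(m, ids) {
  missing <- setdiff(ids, rownames(m))
  if (length(missing)) {
    stop("no descriptors for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m[ids, , drop = FALSE]
}
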