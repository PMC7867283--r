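# Alignment-derived conservation statistics: pairwise percent identity and
# the fraction of a template's active-site residues conserved in a query,
# computed from a supplied multiple sequence alignment (aligned FASTA).
# Alignment construction itself is out of scope.

AA_ALPHABET <- c(LETTERS[!LETTERS %in% c("J")], "-", "*", ".")

#' Read a multiple sequence alignment from aligned FASTA
#'
#' All rows must have equal (gapped) length; residues are one-letter
#' amino-acid codes plus the gap character `-`. Sequences are upper-cased.
#'
#' @param path Aligned FASTA path.
#' @return An object of class `aligned_set`: a named character vector of
#'   gapped sequences.
#' @export
read_alignment <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  aligned_set(stats::setNames(toupper(as.character(seqs)), names(seqs)))
}

#' Construct an aligned sequence set
#'
#' @param sequences Named character vector of gapped sequences of equal
#'   length.
#' @return An `aligned_set`.
#' @export
aligned_set <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("every aligned sequence needs a name", call. = FALSE)
  }
  if (length(unique(nchar(sequences))) > 1L) {
    stop("aligned sequences must all have the same length", call. = FALSE)
  }
  sequences <- toupper(sequences)
  letters_used <- unique(unlist(strsplit(sequences, "", fixed = TRUE)))
  bad <- setdiff(letters_used, AA_ALPHABET)
  if (length(bad)) {
    stop("non amino-acid character(s) in alignment: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(sequences, class = "aligned_set")
}

aln_chars <- function(aln, id) {
  if (!id %in% names(aln)) {
    stop("sequence '", id, "' not found in the alignment", call. = FALSE)
  }
  strsplit(unclass(aln)[[id]], "", fixed = TRUE)[[1]]
}

#' Pairwise percent identity
#'
#' 100 times the number of identical-residue columns over the number of
#' columns where at least one of the pair carries a residue; columns gapped
#' in both sequences are excluded from the denominator. Optionally trims
#' terminal-gap columns (unshared end regions) of either sequence before
#' counting.
#'
#' @param aln An `aligned_set`.
#' @param id_a,id_b Sequence names.
#' @param trim_terminal_gaps If `TRUE`, columns falling in a leading or
#'   trailing gap run of either sequence are excluded entirely.
#' @return Percent identity in \[0, 100\]; symmetric in its two arguments.
#' @examples
#' aln <- aligned_set(c(a = "ACDG-K", b = "ACEG-K"))
#' percent_identity(aln, "a", "b") # 80
#' @export
percent_identity <- function(aln, id_a, id_b, trim_terminal_gaps = FALSE) {
  a <- aln_chars(aln, id_a)
  b <- aln_chars(aln, id_b)
  keep <- !(a == "-" & b == "-")
  if (trim_terminal_gaps) {
    keep <- keep & !terminal_gap_mask(a) & !terminal_gap_mask(b)
  }
  denom <- sum(keep)
  if (denom == 0L) return(NA_real_)
  100 * sum(a == b & a != "-" & keep) / denom
}

terminal_gap_mask <- function(chars) {
  res <- which(chars != "-")
  mask <- rep(TRUE, length(chars))
  if (length(res)) mask[min(res):max(res)] <- FALSE
  mask
}

#' Map ungapped template positions to alignment columns
#'
#' Positions are 1-based in the template's ungapped coordinate system (the
#' convention of residue labels such as W245). The mapping round-trips: the
#' returned column holds exactly the `position`-th residue of the template.
#'
#' @param aln An `aligned_set`.
#' @param template_id Template sequence name.
#' @param positions Integer vector of ungapped positions.
#' @return Integer vector of alignment column indices.
#' @export
alignment_columns <- function(aln, template_id, positions) {
  chars <- aln_chars(aln, template_id)
  residue_cols <- which(chars != "-")
  if (any(positions < 1 | positions > length(residue_cols))) {
    stop("site position(s) beyond the template's ungapped length (",
         length(residue_cols), ")", call. = FALSE)
  }
  residue_cols[positions]
}

#' Active-site conservation of a query sequence
#'
#' Maps each template active-site position to its alignment column and
#' reports 100 times the fraction of site columns where the query residue
#' equals the template residue. A query gap at a site column counts as not
#' conserved.
#'
#' @param aln An `aligned_set` containing template and query.
#' @param template_id,query_id Sequence names.
#' @param positions Ungapped 1-based template positions of the site.
#' @param expected_residues Optional one-letter codes asserted to be the
#'   template residues at `positions`; a mismatch is an error (guards
#'   against mis-numbered site lists).
#' @return Percent of site residues conserved, in \[0, 100\].
#' @export
site_conservation <- function(aln, template_id, positions, query_id,
                              expected_residues = NULL) {
  cols <- alignment_columns(aln, template_id, positions)
  tmpl <- aln_chars(aln, template_id)[cols]
  if (!is.null(expected_residues)) {
    expected_residues <- toupper(expected_residues)
    off <- which(tmpl != expected_residues)
    if (length(off)) {
      stop("template residue at position ", positions[off[1]], " is ",
           tmpl[off[1]], ", expected ", expected_residues[off[1]],
           call. = FALSE)
    }
  }
  qry <- aln_chars(aln, query_id)[cols]
  100 * mean(qry == tmpl & qry != "-")
}

#' Read active-site positions from CSV
#'
#' Two columns: `position` (1-based ungapped template coordinate) and
#' `expected_residue`.
#'
#' @param path CSV path.
#' @return Tibble with `position` and `expected_residue`.
#' @export
read_site_positions <- function(path) {
  raw <- read.csv(path, check.names = FALSE, strip.white = TRUE)
  if (!all(c("position", "expected_residue") %in% names(raw))) {
    stop("site CSV needs columns position and expected_residue", call. = FALSE)
  }
  tibble(position = as.integer(raw$position),
         expected_residue = toupper(as.character(raw$expected_residue)))
}

#' Pairwise identity matrix and per-query site conservation report
#'
#' Convenience wrapper computing the full pairwise percent-identity matrix
#' and, when a site list is given, each query's active-site conservation
#' against the template.
#'
#' @param aln An `aligned_set`.
#' @param template_id Template name (required for site conservation).
#' @param sites Optional tibble from [read_site_positions()].
#' @param trim_terminal_gaps Passed to [percent_identity()].
#' @return List with `identity` (matrix, percent) and `site_conservation`
#'   (named vector over non-template sequences, or `NULL`).
#' @export
conservation_report <- function(aln, template_id = NULL, sites = NULL,
                                trim_terminal_gaps = FALSE) {
  ids <- names(aln)
  identity <- matrix(100, length(ids), length(ids),
                     dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j) {
        identity[i, j] <- identity[j, i] <-
          percent_identity(aln, ids[i], ids[j], trim_terminal_gaps)
      }
    }
  }
  cons <- NULL
  if (!is.null(sites) && !is.null(template_id)) {
    queries <- setdiff(ids, template_id)
    cons <- vapply(queries, function(q) {
      site_conservation(aln, template_id, sites$position, q,
                        sites$expected_residue)
    }, numeric(1))
  }
  list(identity = identity, site_conservation = cons)
}
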