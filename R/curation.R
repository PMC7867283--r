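# Compound library ingestion and activity labelling.
#
# A library is a tibble with one row per compound: `compound_id` (unique),
# `smiles` (optional, may be NA), `plc50` (-log10 LC50, may be NA until
# labelling), `species_tag`. Labelling assigns active/inactive at a pLC50
# threshold; a compound exactly at the threshold is active.

SPECIES_TAGS <- c("aphis", "drosophila")
CLASS_LEVELS <- c("inactive", "active")

#' Read a compound library
#'
#' Ingests compound activity records from CSV or SDF (V2000). The CSV dialect
#' has a mandatory header with columns `compound_id`, `plc50`, `species_tag`
#' and an optional `smiles` column. For SDF input the pLC50 and species tag
#' are read from named data fields of each molecule block.
#'
#' Structures are validated syntactically only; no chemical standardization
#' (salt stripping, tautomer canonicalization) is attempted.
#'
#' @param path Path to a CSV or SDF file.
#' @param format `"csv"` or `"sdf"`. Defaults to guessing from the file
#'   extension.
#' @param plc50_field,species_field SDF data-field names holding the pLC50
#'   value and the species tag.
#' @return A tibble with columns `compound_id`, `smiles`, `plc50`,
#'   `species_tag`, one row per record in file order.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("compound_id,plc50,species_tag", "cpd1,5.1,aphis"), path)
#' read_library(path)
#' @export
read_library <- function(path, format = c("auto", "csv", "sdf"),
                         plc50_field = "pLC50", species_field = "species") {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "csv"
  }
  lib <- switch(format,
    csv = read_library_csv(path),
    sdf = read_library_sdf(path, plc50_field, species_field)
  )
  validate_library(lib)
  lib
}

read_library_csv <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  needed <- c("compound_id", "plc50", "species_tag")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("library CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0L) {
    return(tibble(compound_id = character(), smiles = character(),
                  plc50 = numeric(), species_tag = character()))
  }
  plc50 <- suppressWarnings(as.numeric(raw$plc50))
  bad <- which(!is.na(raw$plc50) & nzchar(raw$plc50) & is.na(plc50))
  if (length(bad)) {
    stop("non-numeric plc50 at record(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  tibble(
    compound_id = raw$compound_id,
    smiles = if ("smiles" %in% names(raw)) raw$smiles else NA_character_,
    plc50 = plc50,
    species_tag = raw$species_tag
  )
}

read_library_sdf <- function(path, plc50_field, species_field) {
  sdf <- ChemmineR::read.SDFset(path)
  n <- length(sdf)
  if (n == 0L) {
    return(tibble(compound_id = character(), smiles = character(),
                  plc50 = numeric(), species_tag = character()))
  }
  blocks <- ChemmineR::datablock(sdf)
  ids <- ChemmineR::sdfid(sdf)
  field_of <- function(block, field) {
    if (field %in% names(block)) unname(block[[field]]) else NA_character_
  }
  plc50_chr <- vapply(blocks, field_of, character(1), field = plc50_field)
  plc50 <- suppressWarnings(as.numeric(plc50_chr))
  bad <- which(!is.na(plc50_chr) & is.na(plc50))
  if (length(bad)) {
    stop("non-numeric ", plc50_field, " field at molecule(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  tibble(
    compound_id = unname(as.character(ids)),
    smiles = NA_character_,
    plc50 = unname(plc50),
    species_tag = unname(vapply(blocks, field_of, character(1),
                                field = species_field))
  )
}

validate_library <- function(lib) {
  if (anyNA(lib$compound_id) || any(!nzchar(lib$compound_id))) {
    stop("every record needs a non-empty compound_id", call. = FALSE)
  }
  dup <- unique(lib$compound_id[duplicated(lib$compound_id)])
  if (length(dup)) {
    stop("duplicate compound_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (any(is.infinite(lib$plc50))) {
    stop("plc50 must be finite where present", call. = FALSE)
  }
  invisible(lib)
}

#' Write a compound library to CSV
#'
#' Inverse of [read_library()] for the CSV dialect; pLC50 values survive a
#' round trip to at least six decimal places.
#'
#' @param lib A library tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  validate_library(lib)
  out <- data.frame(
    compound_id = lib$compound_id,
    smiles = lib$smiles %||% NA_character_,
    plc50 = formatC(lib$plc50, digits = 10, format = "g"),
    species_tag = lib$species_tag
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Label compounds as active or inactive
#'
#' Assigns the binary activity class from the pLC50 potency: a compound is
#' `active` iff its pLC50 is greater than or equal to `threshold` (the
#' boundary value itself counts as active), `inactive` otherwise.
#'
#' @param lib A library tibble from [read_library()]; every record must carry
#'   a pLC50 value.
#' @param threshold pLC50 activity cutoff. Default 4.5.
#' @return The input tibble with an added `label` factor
#'   (levels `inactive` < `active`); row order preserved.
#' @examples
#' lib <- tibble::tibble(compound_id = c("a", "b"), smiles = NA,
#'                       plc50 = c(4.5, 4.4999), species_tag = "aphis")
#' label_activity(lib)$label
#' @export
label_activity <- function(lib, threshold = 4.5) {
  stopifnot_scalar_number(threshold, "threshold")
  validate_library(lib)
  missing <- lib$compound_id[is.na(lib$plc50)]
  if (length(missing)) {
    stop("plc50 missing for compound(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lib$label <- factor(ifelse(lib$plc50 >= threshold, "active", "inactive"),
                      levels = CLASS_LEVELS)
  lib
}
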