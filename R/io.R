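# Reading and writing the standard input formats: FASTA sequences,
# tab-separated protein-pair lists with 0/1 labels, and per-protein
# subcellular-localization annotations.

#' Read protein sequences from a FASTA file
#'
#' Parses with `Biostrings::readAAStringSet()` after a light structural scan
#' that reports malformed entries (text before the first header, empty
#' sequences, empty or duplicate identifiers) with their line numbers.
#' Identifiers are the first whitespace-delimited token of the header;
#' sequences are uppercased; input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `seq`.
#' @export
read_fasta <- function(path) {
  assert_that(file.exists(path), paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  header_at <- grep("^>", lines)
  nonblank <- which(trimws(lines) != "")
  if (length(header_at) == 0) {
    stop("FASTA parse error: no '>' header found in ", path, call. = FALSE)
  }
  if (length(nonblank) > 0 && nonblank[1] < header_at[1]) {
    stop("FASTA parse error at line ", nonblank[1],
         ": sequence data before the first header", call. = FALSE)
  }
  ids <- sub("^>\\s*", "", lines[header_at])
  ids <- sub("\\s.*$", "", ids)
  empty_id <- which(ids == "")
  if (length(empty_id) > 0) {
    stop("FASTA parse error at line ", header_at[empty_id[1]],
         ": header with empty identifier", call. = FALSE)
  }
  ends <- c(header_at[-1] - 1L, length(lines))
  n_res <- vapply(seq_along(header_at), function(i) {
    if (ends[i] < header_at[i] + 1L) return(0L)
    sum(nchar(trimws(lines[(header_at[i] + 1L):ends[i]])))
  }, integer(1))
  if (any(n_res == 0L)) {
    bad <- which(n_res == 0L)[1]
    stop("FASTA parse error at line ", header_at[bad],
         ": entry '", ids[bad], "' has an empty sequence", call. = FALSE)
  }
  dup <- which(duplicated(ids))
  if (length(dup) > 0) {
    stop("FASTA parse error at line ", header_at[dup[1]],
         ": duplicate identifier '", ids[dup[1]], "'", call. = FALSE)
  }
  set <- Biostrings::readAAStringSet(path)
  tibble::tibble(id = ids, seq = toupper(as.character(set, use.names = FALSE)))
}

#' Write protein records to a FASTA file
#'
#' @param records A data frame with columns `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::AAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Construct a labelled protein-pair dataset
#'
#' Normalizes a table of pairs to the package's unordered-pair convention
#' (lexicographically smaller id first), checks that no unordered pair is
#' duplicated or carries both labels, and tags the result with a provenance
#' string.
#'
#' @param pairs A data frame with columns `idA`, `idB` and `label` (0/1).
#' @param provenance Free-text origin note stored as an attribute.
#' @return A tibble of class `ppi_pairs` with columns `idA`, `idB`, `label`.
#' @export
pair_dataset <- function(pairs, provenance = "unspecified") {
  assert_that(all(c("idA", "idB", "label") %in% names(pairs)),
              "`pairs` must have columns idA, idB, label")
  assert_that(all(pairs$label %in% c(0, 1)), "labels must be 0 or 1")
  assert_that(all(pairs$idA != pairs$idB), "self-pairs are not allowed")
  oriented <- orient_pairs(pairs$idA, pairs$idB)
  out <- tibble::tibble(idA = oriented$idA, idB = oriented$idB,
                        label = as.integer(pairs$label))
  key <- paste(out$idA, out$idB, sep = "\r")
  if (anyDuplicated(key)) {
    both <- tapply(out$label, key, function(l) length(unique(l)) > 1)
    if (any(both)) {
      stop("pair(s) present with both labels: ",
           paste(utils::head(gsub("\r", "/", names(both)[both]), 5),
                 collapse = ", "), call. = FALSE)
    }
    out <- out[!duplicated(key), ]
  }
  attr(out, "provenance") <- provenance
  class(out) <- c("ppi_pairs", class(tibble::tibble()))
  out
}

#' Read a tab-separated protein-pair list
#'
#' Expects columns `idA`, `idB`, `label` (0/1). Pairs are normalized to the
#' unordered-pair convention via [pair_dataset()].
#'
#' @param path Path to a TSV file.
#' @param provenance Provenance note; defaults to the file path.
#' @return A `ppi_pairs` tibble.
#' @export
read_pairs <- function(path, provenance = path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    idA = readr::col_character(),
    idB = readr::col_character(),
    label = readr::col_integer()
  ))
  pair_dataset(tab, provenance = provenance)
}

#' Write a protein-pair list to TSV
#'
#' @param pairs A data frame with columns `idA`, `idB`, `label`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs[, c("idA", "idB", "label")], path)
  invisible(path)
}

LOCALIZATIONS <- c("cytoplasm", "nucleus", "mitochondrion",
                   "endoplasmic reticulum", "Golgi apparatus",
                   "peroxisome", "vacuole", "other")

#' Read a per-protein subcellular-localization table
#'
#' Expects a TSV with columns `id` and `localization`; values must come from
#' the recognised compartment vocabulary (cytoplasm, nucleus, mitochondrion,
#' endoplasmic reticulum, Golgi apparatus, peroxisome, vacuole, other).
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `id` and `localization`.
#' @export
read_localization <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(),
    localization = readr::col_character()
  ))
  bad <- setdiff(unique(tab$localization), LOCALIZATIONS)
  if (length(bad) > 0) {
    stop("unknown localization label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(tab$id)) {
    stop("duplicate protein id(s) in localization table", call. = FALSE)
  }
  tab
}

#' Attach localization annotations to protein records
#'
#' @param records A tibble with columns `id`, `seq`.
#' @param annotations A tibble with columns `id`, `localization`.
#' @return `records` with a `localization` column.
#' @export
annotate_localization <- function(records, annotations) {
  hit <- match(records$id, annotations$id)
  records$localization <- annotations$localization[hit]
  records
}
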