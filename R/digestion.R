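#' In-silico tryptic digestion of a protein sequence
#'
#' Cleaves C-terminal to lysine (K) or arginine (R) unless the following
#' residue is proline (the Keil rule, the de-facto standard for trypsin and
#' the rule used by ion-trap search engines). With `missed_cleavages = 0`
#' the returned peptides partition the sequence; with `k` missed cleavages
#' every concatenation of up to `k + 1` adjacent fully-tryptic fragments is
#' emitted, ordered by number of missed cleavages and then by sequence
#' position.
#'
#' @param sequence amino-acid string, uppercase 20-letter alphabet.
#' @param missed_cleavages non-negative integer (default 0).
#' @return character vector of peptides.
#' @examples
#' tryptic_digest("GGKAAR")        # "GGK" "AAR"
#' tryptic_digest("GGKPAAR")       # cleavage suppressed before proline
#' tryptic_digest("AKCKDR", 1)
#' @export
tryptic_digest <- function(sequence, missed_cleavages = 0L) {
  stopifnot(length(sequence) == 1L, is.character(sequence),
            nzchar(sequence), missed_cleavages >= 0L)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% AA20)
  if (length(bad) > 0L)
    stop(sprintf("invalid amino-acid character '%s' at position %d",
                 chars[bad[1]], bad[1]))
  n <- length(chars)
  # cleavage after position i: residue K/R not followed by P
  cut_after <- which(chars %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & chars[pmin(cut_after + 1L, n)] != "P"]
  starts <- c(1L, cut_after + 1L)
  ends <- c(cut_after, n)
  nfrag <- length(starts)
  out <- character(0)
  for (k in 0:min(missed_cleavages, nfrag - 1L)) {
    for (i in seq_len(nfrag - k)) {
      out <- c(out, substr(sequence, starts[i], ends[i + k]))
    }
  }
  out
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Map observed peptides to all database proteins containing them
#'
#' Matching is exact, contiguous substring containment of the peptide in
#' the protein sequence (no I/L merging, no similarity search), performed
#' with `Biostrings::vcountPattern`. Peptides matching no record are
#' retained with an empty match set and `matched = FALSE` so callers can
#' drop them with a warning rather than fail.
#'
#' @param peptides character vector of peptide sequences (length >= 1 each).
#' @param database a protein database data.frame with columns `accession`,
#'   `name`, `sequence` (see [read_database_fasta()]).
#' @return data.frame with one row per input peptide: `peptide`, `matched`
#'   (logical), `n_matches`, and a list column `accessions`.
#' @export
map_peptides <- function(peptides, database) {
  stopifnot(is.character(peptides), all(nzchar(peptides)))
  check_database(database)
  subject <- Biostrings::AAStringSet(database$sequence)
  acc_list <- vector("list", length(peptides))
  for (i in seq_along(peptides)) {
    hit <- Biostrings::vcountPattern(peptides[i], subject, fixed = TRUE) > 0L
    acc_list[[i]] <- database$accession[hit]
  }
  n <- lengths(acc_list)
  out <- data.frame(peptide = peptides, matched = n > 0L, n_matches = n,
                    stringsAsFactors = FALSE)
  out$accessions <- acc_list
  out
}

#' @rdname map_peptides
#' @param peptide single peptide sequence.
#' @export
map_peptide <- function(peptide, database) {
  map_peptides(peptide, database)
}

#' Classify peptide uniqueness against a family partition
#'
#' The uniqueness of each peptide-to-protein assignment decides whether an
#' identification can be attributed to a specific protein or only to a
#' group of related proteins: a peptide matching exactly one accession is
#' `unique-to-protein`; one whose matches all lie in a single family is
#' `unique-to-family`; otherwise it is `shared-across-families`.
#'
#' @param assignments output of [map_peptides()] (unmatched rows get class
#'   `NA`).
#' @param family_partition data.frame with columns `accession`, `family`;
#'   must cover every matched accession.
#' @return `assignments` with an added `uniqueness_class` column.
#' @export
classify_uniqueness <- function(assignments, family_partition) {
  stopifnot(is.data.frame(assignments), !is.null(assignments$accessions),
            all(c("accession", "family") %in% names(family_partition)))
  fam <- setNames(as.character(family_partition$family),
                  family_partition$accession)
  cls <- character(nrow(assignments))
  for (i in seq_len(nrow(assignments))) {
    acc <- assignments$accessions[[i]]
    if (length(acc) == 0L) {
      cls[i] <- NA_character_
      next
    }
    missing <- setdiff(acc, names(fam))
    if (length(missing) > 0L)
      stop(sprintf("accession '%s' missing from family partition",
                   missing[1]))
    fams <- unique(fam[acc])
    cls[i] <- if (length(acc) == 1L) "unique-to-protein"
              else if (length(fams) == 1L) "unique-to-family"
              else "shared-across-families"
  }
  assignments$uniqueness_class <- cls
  assignments
}

check_database <- function(database) {
  if (!is.data.frame(database) ||
      !all(c("accession", "name", "sequence") %in% names(database)))
    stop("database must be a data.frame with accession, name, sequence")
  if (anyDuplicated(database$accession))
    stop("database accessions must be unique")
  invisible(database)
}

#' Read a protein database from FASTA
#'
#' Headers are parsed as `"accession description"` (first whitespace token
#' is the accession, remainder the descriptive name).
#'
#' @param path FASTA file path.
#' @return data.frame with columns `accession`, `name`, `sequence`.
#' @export
read_database_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  acc <- sub("\\s.*$", "", headers)
  nm <- sub("^\\S+\\s*", "", headers)
  data.frame(accession = acc, name = nm,
             sequence = as.character(aa), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Write a protein database to FASTA
#'
#' @param database data.frame with `accession`, `name`, `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_database_fasta <- function(database, path) {
  check_database(database)
  aa <- Biostrings::AAStringSet(database$sequence)
  names(aa) <- paste(database$accession, database$name)
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}
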