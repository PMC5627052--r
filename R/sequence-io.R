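#' Sequence records
#'
#' A `seq_record` is the package's light-weight carrier for a single
#' nucleotide or amino-acid sequence: an identifier, an optional free-text
#' description, an upper-case residue string and a declared alphabet.
#' Ambiguity is restricted to `N` (nucleotide) and `X` (amino acid); the stop
#' character `*` is permitted only in amino-acid records and the gap
#' character `-` only when `allow_gaps = TRUE` (alignment rows).
#'
#' @param id Non-empty identifier.
#' @param residues Residue string (will be upper-cased).
#' @param description Free text after the identifier in a FASTA header.
#' @param alphabet `"nt"` or `"aa"`.
#' @param allow_gaps Permit `-` characters (alignment rows).
#' @return An object of class `seq_record`.
#' @export
seq_record <- function(id, residues, description = "", alphabet = c("aa", "nt"),
                       allow_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    np_stop("npmine_bad_record", "record id must be a non-empty string")
  residues <- toupper(as.character(residues))
  if (!nzchar(residues))
    np_stop("npmine_bad_record", sprintf("record '%s' has no residues", id))
  check_alphabet(residues, alphabet, id, allow_gaps)
  structure(list(id = id, description = description, residues = residues,
                 alphabet = alphabet),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  res <- x$residues
  if (nchar(res) > 60L) res <- paste0(substr(res, 1L, 57L), "...")
  cat(sprintf("<seq_record %s [%s, %d]> %s\n", x$id, x$alphabet,
              nchar(x$residues), res))
  invisible(x)
}

nt_alphabet <- "ACGTN"
aa_alphabet <- "ACDEFGHIKLMNPQRSTVWYX"

check_alphabet <- function(residues, alphabet, id, allow_gaps = FALSE) {
  allowed <- if (alphabet == "nt") nt_alphabet else paste0(aa_alphabet, "*")
  if (allow_gaps) allowed <- paste0(allowed, "-")
  bad <- regexpr(sprintf("[^%s]", gsub("([*-])", "\\\\\\1", allowed)), residues)
  if (bad > 0L)
    np_stop("npmine_alphabet_error",
            sprintf("record '%s': illegal %s residue '%s' at position %d",
                    id, alphabet, substr(residues, bad, bad), bad),
            record = id, position = as.integer(bad))
  invisible(TRUE)
}

#' Read sequences from a FASTA file
#'
#' Accepts unaligned or aligned FASTA (LF or CRLF line endings); with
#' `strip_gaps = TRUE`, `-` characters are removed before validation so that
#' aligned FASTA can be loaded as plain sequences.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"aa"` or `"nt"`.
#' @param strip_gaps Remove `-` characters.
#' @return A list of [seq_record] objects, one per header, in file order.
#' @export
read_fasta <- function(path, alphabet = c("aa", "nt"), strip_gaps = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path))
    np_stop("npmine_empty_input", sprintf("no such file: %s", path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L)
    np_stop("npmine_empty_input", sprintf("no FASTA records in %s", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    np_stop("npmine_duplicate_id",
            sprintf("duplicate record id(s): %s", paste(unique(dup), collapse = ", ")))
  recs <- lapply(seq_along(set), function(i) {
    res <- toupper(as.character(set[[i]]))
    if (strip_gaps) res <- gsub("-", "", res, fixed = TRUE)
    seq_record(ids[i], res, desc[i], alphabet)
  })
  names(recs) <- ids
  recs
}

#' Write sequence records to FASTA
#'
#' @param records List of [seq_record] objects.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    header <- if (nzchar(r$description)) paste(r$id, r$description) else r$id
    writeLines(paste0(">", header), con)
    n <- nchar(r$residues)
    starts <- seq(1L, n, by = width)
    writeLines(substring(r$residues, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement of a nucleotide string
#'
#' @param s Nucleotide string (`N` allowed).
#' @return The reverse complement, upper case.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(s))))
}
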