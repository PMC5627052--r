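#' Annotate a neuropeptide precursor
#'
#' Composes [predict_signal_peptide()], [find_cleavage_sites()] and
#' [derive_mature_peptides()] into a full precursor annotation. When no
#' signal peptide is found (or the record is shorter than the minimum
#' signal length) the annotation is flagged `partial`: sites are still
#' scanned from position 0 and peptides derived, but downstream analyses
#' treat the copy count as unreliable (partial precursors are excluded
#' from copy-number matrices).
#'
#' The annotation satisfies a reconstruction invariant, checked on every
#' call: concatenating the signal region, the unprocessed peptide segments
#' and the cleavage-site motifs in order reproduces the record exactly.
#'
#' @param record Amino-acid [seq_record] (or plain string, which is wrapped).
#' @param config An [annotation_config].
#' @param signal_override Optional `signal_call` (e.g. from
#'   [read_signalp()]) replacing the built-in heuristic.
#' @param family Optional family label carried into downstream matrices.
#' @return An object of class `precursor_annotation` with fields `record`,
#'   `signal`, `sites`, `peptides`, `partial`, `family`.
#' @export
annotate_precursor <- function(record, config = annotation_config(),
                               signal_override = NULL, family = NA_character_) {
  if (is.character(record)) record <- seq_record("unnamed", record)
  if (!inherits(record, "seq_record") || record$alphabet != "aa")
    np_stop("npmine_bad_record", "annotate_precursor needs an amino-acid record")
  signal <- signal_override %||% predict_signal_peptide(record$residues, config)
  from <- if (isTRUE(signal$present)) signal$cleavage_pos else 0L
  sites <- find_cleavage_sites(record$residues, from, config)
  peptides <- derive_mature_peptides(record$residues, signal, sites, config)
  ann <- structure(list(record = record, signal = signal, sites = sites,
                        peptides = peptides, partial = !isTRUE(signal$present),
                        family = family),
                   class = "precursor_annotation")
  recon <- reconstruct_precursor(ann)
  if (!identical(recon, record$residues))
    np_stop("npmine_inconsistent",
            sprintf("annotation of '%s' does not reconstruct the precursor",
                    record$id))
  ann
}

#' Reconstruct a precursor from its annotation
#'
#' Concatenates the signal region, unprocessed peptide segments (amidation
#' glycines restored) and cleavage-site motifs in coordinate order. Equals
#' the precursor residues exactly for any valid annotation.
#'
#' @param ann A `precursor_annotation`.
#' @return Character string.
#' @export
reconstruct_precursor <- function(ann) {
  res <- ann$record$residues
  start0 <- if (isTRUE(ann$signal$present)) ann$signal$cleavage_pos else 0L
  pieces <- data.frame(start = integer(), end = integer(), text = character(),
                       stringsAsFactors = FALSE)
  if (start0 > 0L)
    pieces <- rbind(pieces, data.frame(start = 0L, end = start0,
                                       text = substr(res, 1L, start0)))
  if (nrow(ann$peptides))
    pieces <- rbind(pieces, data.frame(
      start = ann$peptides$start, end = ann$peptides$end,
      text = substring(res, ann$peptides$start + 1L, ann$peptides$end)))
  if (nrow(ann$sites))
    pieces <- rbind(pieces, data.frame(start = ann$sites$start,
                                       end = ann$sites$end,
                                       text = ann$sites$motif))
  pieces <- pieces[order(pieces$start), , drop = FALSE]
  paste(pieces$text, collapse = "")
}

#' @export
print.precursor_annotation <- function(x, ...) {
  cat(sprintf("<precursor_annotation %s: %d aa, %s, %d sites, %d peptides%s>\n",
              x$record$id, nchar(x$record$residues),
              if (x$partial) "partial (no signal)" else
                sprintf("signal 1-%d", x$signal$cleavage_pos),
              nrow(x$sites), nrow(x$peptides),
              if (!is.na(x$family)) paste0(", family ", x$family) else ""))
  if (nrow(x$peptides)) {
    shown <- utils::head(x$peptides$notation, 8L)
    cat("  ", paste(shown, collapse = ", "),
        if (nrow(x$peptides) > 8L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' Count mature-peptide copies matching a predicate
#'
#' C-terminal fragments are excluded unless the predicate opts in with the
#' `cterm` atom (see [parse_predicate()]).
#'
#' @param annotation A `precursor_annotation`.
#' @param predicate A `peptide_predicate` or predicate string.
#' @return Integer count.
#' @export
count_peptide_copies <- function(annotation, predicate) {
  predicate <- as_peptide_predicate(predicate)
  peps <- annotation$peptides
  if (!attr(predicate, "uses_cterm"))
    peps <- peps[!peps$c_terminal_fragment, , drop = FALSE]
  if (!nrow(peps)) return(0L)
  sum(predicate_matches(predicate, peps))
}

#' Serialise annotations
#'
#' `write_annotation_json()` stores the full structure of one or more
#' annotations; `write_peptides_tsv()` emits one row per mature peptide
#' (precursor id, coordinates, processed sequence, flags, notation).
#'
#' @param annotations A `precursor_annotation` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_annotation_json <- function(annotations, path) {
  if (inherits(annotations, "precursor_annotation"))
    annotations <- list(annotations)
  payload <- lapply(annotations, function(a) {
    list(id = a$record$id, family = a$family, partial = a$partial,
         residues = a$record$residues,
         signal = a$signal[c("present", "cleavage_pos", "score")],
         sites = a$sites, peptides = a$peptides)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_annotation_json
#' @export
write_peptides_tsv <- function(annotations, path) {
  if (inherits(annotations, "precursor_annotation"))
    annotations <- list(annotations)
  tabs <- lapply(annotations, function(a) {
    if (!nrow(a$peptides)) return(NULL)
    cbind(data.frame(precursor = a$record$id, stringsAsFactors = FALSE),
          a$peptides)
  })
  tab <- do.call(rbind, tabs[!vapply(tabs, is.null, logical(1))])
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
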