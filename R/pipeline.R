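#' Mine precursors from transcripts with known queries
#'
#' Chains the pipeline stages the way transcriptome mining is done with a
#' set of established precursors as queries: translated search →
#' extraction of the ORF containing each high-scoring segment pair →
#' precursor annotation. One candidate is kept per distinct ORF (the
#' best-E-value hit); candidates failing a stage are reported with the
#' reason (`no_orf`: the hit has no clean ORF; `no_signal`: no signal
#' peptide; `no_cleavage`: no cleavage site after the signal).
#'
#' @param queries List of amino-acid [seq_record]s.
#' @param transcripts List of nucleotide [seq_record]s.
#' @param config An [annotation_config].
#' @param scheme A [scoring_scheme].
#' @param preset `"discovery"` (E <= 1000) or `"crossspecies"`
#'   (E <= 1e-6); alternatively pass `evalue_cutoff` directly.
#' @param evalue_cutoff Overrides the preset when non-`NULL`.
#' @param require_sites Reject candidates with no cleavage site.
#' @return List with `annotations` (list of `precursor_annotation`, family
#'   set to the best query's id), `hits` (the full hit table) and
#'   `report` (per-candidate data frame with `transcript_id`, `frame`,
#'   `query_id`, `status` ∈ accepted/no_orf/no_signal/no_cleavage).
#' @export
run_mine <- function(queries, transcripts, config = annotation_config(),
                     scheme = scoring_scheme(),
                     preset = c("discovery", "crossspecies"),
                     evalue_cutoff = NULL, require_sites = TRUE) {
  cutoff <- evalue_cutoff %||% search_preset(match.arg(preset))
  hits <- translated_search(queries, transcripts, scheme, cutoff)
  tx_index <- setNames(transcripts, vapply(transcripts, `[[`, character(1), "id"))
  report <- list(); annotations <- list(); seen_orfs <- character()
  if (nrow(hits)) {
    # best hit per transcript x frame drives ORF extraction
    key <- paste(hits$transcript_id, hits$frame)
    best <- hits[!duplicated(key), , drop = FALSE]
    for (k in seq_len(nrow(best))) {
      h <- best[k, ]
      status <- "accepted"
      ann <- NULL
      orf <- tryCatch(
        extract_orf_containing(tx_index[[h$transcript_id]],
                               c(h$s_start, h$s_end), h$frame),
        npmine_error = function(e) NULL)
      if (is.null(orf)) {
        status <- "no_orf"
      } else {
        orf_key <- paste(h$transcript_id, orf$frame, orf$nt_start, orf$nt_end)
        if (orf_key %in% seen_orfs) next
        seen_orfs <- c(seen_orfs, orf_key)
        rec <- seq_record(sprintf("%s|%+d|%d-%d", h$transcript_id, orf$frame,
                                  orf$nt_start, orf$nt_end),
                          orf$protein)
        ann <- annotate_precursor(rec, config, family = h$query_id)
        if (ann$partial) status <- "no_signal"
        else if (require_sites && nrow(ann$sites) == 0L) status <- "no_cleavage"
      }
      if (status == "accepted")
        annotations[[length(annotations) + 1L]] <- ann
      report[[length(report) + 1L]] <- data.frame(
        transcript_id = h$transcript_id, frame = h$frame,
        query_id = h$query_id, status = status, stringsAsFactors = FALSE)
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(transcript_id = character(), frame = integer(),
               query_id = character(), status = character(),
               stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(annotations = annotations, hits = hits, report = report)
}

#' Copy-number matrix, clade summaries and outliers in one step
#'
#' @param entries Annotation entries as for [build_copy_matrix()].
#' @param clade_table Species-to-clade assignment (named vector, 2-column
#'   data frame, or `NULL` to skip clade-level output).
#' @param predicates Named predicates per family; families present in the
#'   predicate table but absent from the annotations are skipped with a
#'   warning.
#' @return List with `matrix`, `summaries` (named list of per-family
#'   clade summaries, `NULL` without a clade table) and `outliers` (named
#'   list of per-family outlier tables).
#' @export
run_count <- function(entries, clade_table = NULL, predicates) {
  fams_seen <- unique(vapply(entries, `[[`, character(1), "family"))
  unknown <- setdiff(names(predicates), fams_seen)
  if (length(unknown)) {
    warning(sprintf("no annotations for famil%s %s; skipped",
                    if (length(unknown) > 1) "ies" else "y",
                    paste(unknown, collapse = ", ")))
    predicates <- predicates[setdiff(names(predicates), unknown)]
  }
  m <- build_copy_matrix(entries, predicates)
  summaries <- NULL; outliers <- NULL
  if (!is.null(clade_table) && length(clade_table)) {
    clades <- normalize_clades(clade_table)
    summaries <- lapply(colnames(m), function(f) clade_summary(m, clades, f))
    outliers <- lapply(colnames(m), function(f) flag_outliers(m, clades, f))
    names(summaries) <- names(outliers) <- colnames(m)
  }
  list(matrix = m, summaries = summaries, outliers = outliers)
}
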