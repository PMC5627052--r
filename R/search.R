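#' E-value cut-off presets for the translated search
#'
#' Two regimes are used when mining transcriptomes: a permissive
#' `"discovery"` regime (E <= 1000) for finding candidate precursors with
#' known queries, and a stringent `"crossspecies"` regime (E <= 1e-6) for
#' pulling orthologues of established precursors out of many species.
#'
#' @param name `"discovery"` or `"crossspecies"`.
#' @return Numeric E-value cut-off.
#' @export
search_preset <- function(name = c("discovery", "crossspecies")) {
  name <- match.arg(name)
  c(discovery = 1000, crossspecies = 1e-6)[[name]]
}

#' Translated search of protein queries against transcripts
#'
#' For every query x transcript x frame the best local alignment of the
#' query against the six-frame translation is computed; the hit is retained
#' iff its E-value is at or below `evalue_cutoff`. The database length used
#' in the E-value is the total number of residues across all six frame
#' translations of all transcripts. Subject coordinates are amino-acid
#' positions within the frame translation (0-based half-open), ready for
#' [extract_orf_containing()].
#'
#' @param queries List of amino-acid [seq_record]s.
#' @param transcripts List of nucleotide [seq_record]s.
#' @param scheme A [scoring_scheme].
#' @param evalue_cutoff Positive E-value cut-off (see [search_preset()]).
#' @return `data.frame` with columns `query_id`, `transcript_id`, `frame`,
#'   `score`, `evalue`, `q_start`, `q_end`, `s_start`, `s_end`, `q_aln`,
#'   `s_aln`, sorted by ascending E-value then ids then frame.
#' @export
translated_search <- function(queries, transcripts, scheme = scoring_scheme(),
                              evalue_cutoff = search_preset("discovery")) {
  if (inherits(queries, "seq_record")) queries <- list(queries)
  if (inherits(transcripts, "seq_record")) transcripts <- list(transcripts)
  if (!length(transcripts))
    np_stop("npmine_empty_input", "empty transcript database")
  if (!length(queries))
    np_stop("npmine_empty_input", "no queries")
  stopifnot(evalue_cutoff > 0)
  frames6 <- lapply(transcripts, six_frame_translate)
  db_len <- sum(vapply(frames6, function(f) sum(nchar(f)), numeric(1)))
  rows <- list()
  for (q in queries) {
    m <- nchar(q$residues)
    for (ti in seq_along(transcripts)) {
      tr <- transcripts[[ti]]
      for (fr in names(frames6[[ti]])) {
        subj <- frames6[[ti]][[fr]]
        if (!nzchar(subj)) next
        aln <- smith_waterman(q$residues, subj, scheme)
        if (aln$score <= 0L) next
        ev <- evalue(aln$score, m, db_len, scheme)
        if (ev > evalue_cutoff) next
        rows[[length(rows) + 1L]] <- data.frame(
          query_id = q$id, transcript_id = tr$id, frame = frame_number(fr),
          score = aln$score, evalue = ev,
          q_start = aln$a_interval[1], q_end = aln$a_interval[2],
          s_start = aln$b_interval[1], s_end = aln$b_interval[2],
          q_aln = aln$a_aln, s_aln = aln$b_aln,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  hits[order(hits$evalue, hits$query_id, hits$transcript_id, hits$frame), ,
       drop = FALSE] -> hits
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(query_id = character(), transcript_id = character(),
             frame = integer(), score = integer(), evalue = numeric(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             q_aln = character(), s_aln = character(),
             stringsAsFactors = FALSE)
}

#' Write / read search hits as tab-separated tables
#'
#' `write_hits_tsv()` stores the full internal hit schema (0-based
#' half-open coordinates, alignment strings included). `read_blast_tab()`
#' reads an external BLAST tabular (outfmt 6) file into the same schema so
#' external searches can drive ORF extraction; fields BLAST does not emit
#' (frame, alignment strings) are `NA`, coordinates are converted from
#' 1-based inclusive, and the bit score is stored in `score`.
#'
#' @param hits Hit data frame from [translated_search()].
#' @param path File path.
#' @return `write_hits_tsv()`: `path` invisibly; readers: a hit data frame.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits_tsv
#' @export
read_hits_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname write_hits_tsv
#' @export
read_blast_tab <- function(path) {
  cols <- c("query_id", "transcript_id", "pident", "length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 12L)
    np_stop("npmine_bad_format", "expected >= 12 tab-separated BLAST columns")
  names(tab)[1:12] <- cols
  data.frame(query_id = as.character(tab$query_id),
             transcript_id = as.character(tab$transcript_id),
             frame = rep(NA_integer_, nrow(tab)),
             score = as.integer(round(tab$bitscore)),
             evalue = as.numeric(tab$evalue),
             q_start = as.integer(tab$qstart) - 1L,
             q_end = as.integer(tab$qend),
             s_start = as.integer(pmin(tab$sstart, tab$send)) - 1L,
             s_end = as.integer(pmax(tab$sstart, tab$send)),
             q_aln = rep(NA_character_, nrow(tab)),
             s_aln = rep(NA_character_, nrow(tab)),
             stringsAsFactors = FALSE)
}
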