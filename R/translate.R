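#' Six-frame translation of a transcript
#'
#' Translates a nucleotide record in all six reading frames under the
#' standard genetic code. Frames `+1..+3` read the forward strand from
#' offsets 0..2; frames `-1..-3` read the reverse complement from offsets
#' 0..2. Stop codons are rendered `*`; any codon containing `N` translates
#' to `X`.
#'
#' @param transcript A nucleotide [seq_record] (or plain string).
#' @return Named character vector with elements `"+1" ... "-3"`.
#' @export
six_frame_translate <- function(transcript) {
  nt <- transcript_residues(transcript)
  if (nchar(nt) < 3L)
    np_stop("npmine_too_short", "transcript shorter than one codon")
  frames <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out <- vapply(frames, function(f) translate_frame(nt, frame_number(f)),
                character(1))
  names(out) <- frames
  out
}

transcript_residues <- function(transcript) {
  if (inherits(transcript, "seq_record")) {
    if (transcript$alphabet != "nt")
      np_stop("npmine_bad_record", "six-frame translation needs a nucleotide record")
    transcript$residues
  } else toupper(as.character(transcript))
}

frame_number <- function(f) {
  if (is.character(f)) as.integer(sub("^\\+", "", f)) else as.integer(f)
}

translate_frame <- function(nt, frame) {
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    np_stop("npmine_bad_frame", sprintf("frame must be in +-1..3, got %s", frame))
  s <- if (frame > 0L) nt else revcomp(nt)
  off <- abs(frame) - 1L
  usable <- nchar(s) - off
  n_codons <- usable %/% 3L
  if (n_codons <= 0L) return("")
  sub <- substr(s, off + 1L, off + 3L * n_codons)
  as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                     no.init.codon = TRUE,
                                     if.fuzzy.codon = "X"))
}

#' Extract the open reading frame containing a similarity hit
#'
#' Given an amino-acid interval on one of the six frame translations of a
#' transcript (typically a high-scoring segment pair from
#' [translated_search()]), returns the maximal stop-free stretch of that
#' translation containing the interval, extended to the nearest stop codon
#' or sequence end on both sides. Nucleotide coordinates are reported
#' 0-based half-open on the forward strand; for reverse frames the frame
#' sign carries the strand. When the stretch is terminated downstream by a
#' stop codon, the stop codon is included in the nucleotide interval but
#' excluded from `protein`.
#'
#' @param transcript A nucleotide [seq_record].
#' @param hit_interval Integer pair `c(start, end)`, 0-based half-open, in
#'   amino-acid coordinates of the frame translation.
#' @param frame Frame in `{+1,+2,+3,-1,-2,-3}`.
#' @param require_met Trim the 5' end to the first methionine at or before
#'   the hit; by default stop-to-stop stretches are accepted without an
#'   initiator Met.
#' @return An object of class `open_reading_frame` with fields
#'   `transcript_id`, `frame`, `nt_start`, `nt_end`, `protein`.
#' @export
extract_orf_containing <- function(transcript, hit_interval, frame,
                                   require_met = FALSE) {
  frame <- frame_number(frame)
  if (!frame %in% c(1L, 2L, 3L, -1L, -2L, -3L))
    np_stop("npmine_bad_frame", sprintf("frame out of range: %s", frame))
  nt <- transcript_residues(transcript)
  aa <- translate_frame(nt, frame)
  len <- nchar(aa)
  hs <- as.integer(hit_interval[1]); he <- as.integer(hit_interval[2])
  if (is.na(hs) || is.na(he) || hs < 0L || he > len || hs >= he)
    np_stop("npmine_invalid_hit",
            sprintf("hit interval [%d,%d) outside frame translation of length %d",
                    hs, he, len))
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  if (any(chars[(hs + 1L):he] == "*"))
    np_stop("npmine_invalid_hit", "hit interval crosses a stop codon")
  s <- hs
  while (s > 0L && chars[s] != "*") s <- s - 1L
  e <- he
  while (e < len && chars[e + 1L] != "*") e <- e + 1L
  trailing_stop <- e < len  # chars[e + 1L] == "*"
  if (require_met) {
    mets <- which(chars == "M") - 1L
    mets <- mets[mets >= s & mets <= hs]
    if (!length(mets))
      np_stop("npmine_invalid_hit", "no initiator methionine upstream of the hit")
    s <- min(mets)
  }
  protein <- paste(chars[(s + 1L):e], collapse = "")
  off <- abs(frame) - 1L
  e_nt <- e + as.integer(trailing_stop)
  L <- nchar(nt)
  if (frame > 0L) {
    nt_start <- off + 3L * s
    nt_end <- off + 3L * e_nt
  } else {
    rc_start <- off + 3L * s
    rc_end <- off + 3L * e_nt
    nt_start <- L - rc_end
    nt_end <- L - rc_start
  }
  structure(list(transcript_id = if (inherits(transcript, "seq_record"))
                   transcript$id else NA_character_,
                 frame = frame, nt_start = nt_start, nt_end = nt_end,
                 protein = protein),
            class = "open_reading_frame")
}

#' @export
print.open_reading_frame <- function(x, ...) {
  cat(sprintf("<ORF %s frame %+d nt [%d,%d) %d aa>\n", x$transcript_id,
              x$frame, x$nt_start, x$nt_end, nchar(x$protein)))
  invisible(x)
}
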