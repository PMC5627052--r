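# Kyte-Doolittle hydropathy index.
kd_hydropathy <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2, X = 0, "*" = -4.5)

small_residues <- c("A", "G", "S", "C", "T", "V")

#' Predict an N-terminal signal peptide
#'
#' Built-in heuristic combining the two classical signatures of a signal
#' peptide: a hydrophobic core upstream of the cleavage site and small
#' residues at the (-3, -1) positions (the von Heijne rule). For each
#' candidate cleavage position `p` (0-based index of the first mature
#' residue) in `[min_signal_cleavage, max_signal_cleavage]` the score is
#'
#'   `0.7 * H(p) + 0.3 * S(p)`
#'
#' where `H(p)` is the mean Kyte-Doolittle hydropathy of residues
#' `[p-13, p-3)` rescaled linearly from \[-4.5, 4.5\] to \[0, 1\], and
#' `S(p)` is 1 when both positions `p-1` and `p-3` hold small residues
#' (A, G, S, C, T, V), 0.5 when exactly one does, 0 otherwise. Cleavage is
#' called at the argmax (ties to the smallest `p`); a signal peptide is
#' present iff the score reaches `signal_threshold`. An external SignalP
#' call parsed with [read_signalp()] can override this heuristic in
#' [annotate_precursor()].
#'
#' @param protein Amino-acid string.
#' @param config An [annotation_config].
#' @return An object of class `signal_call`: `present`, `cleavage_pos`
#'   (0-based first mature residue; `NA` when absent), `score`.
#' @export
predict_signal_peptide <- function(protein, config = annotation_config()) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  if (n < config$min_signal_cleavage + 1L)
    return(signal_call(FALSE, NA_integer_, 0))
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  kd <- unname(kd_hydropathy[chars]); kd[is.na(kd)] <- 0
  ps <- seq(config$min_signal_cleavage, min(config$max_signal_cleavage, n - 1L))
  scores <- vapply(ps, function(p) {
    win <- seq.int(max(0L, p - 13L), p - 4L) + 1L  # residues [p-13, p-3)
    h <- (mean(kd[win]) + 4.5) / 9
    h <- min(max(h, 0), 1)
    sm <- sum(chars[c(p, p - 2L)] %in% small_residues)  # positions p-1, p-3
    s <- c(0, 0.5, 1)[sm + 1L]
    0.7 * h + 0.3 * s
  }, numeric(1))
  best <- which.max(scores)
  score <- scores[best]
  present <- score >= config$signal_threshold
  signal_call(present, if (present) ps[best] else NA_integer_, score)
}

signal_call <- function(present, cleavage_pos, score) {
  structure(list(present = present, cleavage_pos = cleavage_pos,
                 score = score),
            class = "signal_call")
}

#' @export
print.signal_call <- function(x, ...) {
  if (x$present)
    cat(sprintf("<signal peptide: cleavage at %d, score %.3f>\n",
                x$cleavage_pos, x$score))
  else cat(sprintf("<no signal peptide (score %.3f)>\n", x$score))
  invisible(x)
}

#' Read SignalP short-format output
#'
#' Adapter for externally computed SignalP (v4) short-format tables so that
#' its calls can replace the built-in heuristic. The D score is used as the
#' signal score and the reported cleavage position (1-based, first mature
#' residue) converted to this package's 0-based convention.
#'
#' @param path SignalP short-format output file.
#' @param config An [annotation_config]; `signal_threshold` decides presence.
#' @return Named list of `signal_call` objects keyed by sequence name.
#' @export
read_signalp <- function(path, config = annotation_config()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    np_stop("npmine_empty_input", sprintf("no SignalP entries in %s", path))
  out <- list()
  for (ln in lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(f) < 9L)
      np_stop("npmine_bad_format", "unrecognised SignalP short-format line")
    name <- f[1]; d <- as.numeric(f[9]); ymax_pos <- as.integer(f[5])
    present <- !is.na(d) && d >= config$signal_threshold
    out[[name]] <- signal_call(present,
                               if (present) ymax_pos - 1L else NA_integer_,
                               d)
  }
  out
}
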