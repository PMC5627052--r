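#' Find prohormone-convertase cleavage sites
#'
#' Scans for maximal runs of basic residues (K/R) starting at or after
#' `from_pos`. A run of length >= 2 is a single site (dibasic for length 2,
#' polybasic for length >= 3), accepted when any adjacent pair within it is
#' in `dibasic_motifs`. A length-1 run is a monobasic site when that
#' residue is enabled in the config and no other basic run lies within
#' `monobasic_min_gap` residues on either side (see [annotation_config()]).
#' Cleavage is C-terminal to the run; basic residues belong to no peptide.
#'
#' @param protein Amino-acid string.
#' @param from_pos 0-based position (usually the signal cleavage site) from
#'   which to scan.
#' @param config An [annotation_config].
#' @return `data.frame` with columns `start`, `end` (0-based half-open),
#'   `kind` (`monobasic`/`dibasic`/`polybasic`) and `motif`; sorted,
#'   non-overlapping.
#' @export
find_cleavage_sites <- function(protein, from_pos = 0L,
                                config = annotation_config()) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  if (from_pos > n)
    np_stop("npmine_bad_index", "from_pos beyond end of protein")
  m <- gregexpr("[KR]+", protein)[[1]]
  empty <- data.frame(start = integer(), end = integer(),
                      kind = character(), motif = character(),
                      stringsAsFactors = FALSE)
  if (m[1] == -1L) return(empty)
  run_start <- as.integer(m) - 1L                  # 0-based
  run_len <- attr(m, "match.length")
  run_end <- run_start + run_len
  keep <- run_start >= from_pos
  rs <- run_start[keep]; re <- run_end[keep]; rl <- run_len[keep]
  if (!length(rs)) return(empty)
  motifs <- substring(protein, rs + 1L, re)
  kinds <- character(length(rs))
  keep2 <- logical(length(rs))
  for (k in seq_along(rs)) {
    if (rl[k] >= 2L) {
      pairs <- substring(motifs[k], seq_len(rl[k] - 1L), seq_len(rl[k] - 1L) + 1L)
      if (!any(pairs %in% config$dibasic_motifs)) next
      kinds[k] <- if (rl[k] == 2L) "dibasic" else "polybasic"
      keep2[k] <- TRUE
    } else {
      enabled <- (motifs[k] == "R" && config$allow_monobasic_R) ||
                 (motifs[k] == "K" && config$allow_monobasic_K)
      if (!enabled) next
      gap_prev <- if (k > 1L) rs[k] - re[k - 1L] else Inf
      gap_next <- if (k < length(rs)) rs[k + 1L] - re[k] else Inf
      if (min(gap_prev, gap_next) < config$monobasic_min_gap) next
      kinds[k] <- "monobasic"
      keep2[k] <- TRUE
    }
  }
  if (!any(keep2)) return(empty)
  data.frame(start = rs[keep2], end = re[keep2], kind = kinds[keep2],
             motif = motifs[keep2], stringsAsFactors = FALSE)
}

#' Derive mature peptides from a partitioned precursor
#'
#' Splits the propeptide (everything after the signal peptide) at the
#' cleavage sites. Empty segments are dropped. A segment whose last residue
#' is glycine and which is immediately followed by a cleavage site is
#' amidated: the glycine is the amide donor and is removed from the
#' processed sequence (coordinates keep the unprocessed segment). A segment
#' beginning with glutamine is flagged pyroglutamated. The final segment,
#' with no following site, is a C-terminal fragment and can never be
#' amidated.
#'
#' @param protein Amino-acid string.
#' @param signal A `signal_call` for the same protein.
#' @param sites Cleavage-site table from [find_cleavage_sites()] on the
#'   same protein.
#' @param config An [annotation_config].
#' @return `data.frame` with columns `sequence` (processed), `start`, `end`
#'   (unprocessed segment, 0-based half-open), `amidated`,
#'   `pyroglutamated`, `c_terminal_fragment`, `notation`.
#' @export
derive_mature_peptides <- function(protein, signal, sites,
                                   config = annotation_config()) {
  protein <- toupper(as.character(protein))
  n <- nchar(protein)
  start0 <- if (isTRUE(signal$present)) signal$cleavage_pos else 0L
  if (nrow(sites)) {
    sites <- sites[order(sites$start), , drop = FALSE]
    if (any(sites$start[-1] < sites$end[-nrow(sites)]) ||
        any(sites$start < start0))
      np_stop("npmine_invalid_sites", "cleavage sites overlap or precede the propeptide")
  }
  seg_start <- c(start0, sites$end)
  seg_end <- c(sites$start, n)
  followed_by_site <- c(rep(TRUE, nrow(sites)), FALSE)
  keep <- seg_end > seg_start
  peptide_table(protein, seg_start[keep], seg_end[keep],
                followed_by_site[keep])
}

# Vectorised construction of the mature-peptide table from segment
# coordinates; shared by the annotator and the synthetic generator.
peptide_table <- function(protein, seg_start, seg_end, followed_by_site) {
  if (!length(seg_start))
    return(data.frame(sequence = character(), start = integer(),
                      end = integer(), amidated = logical(),
                      pyroglutamated = logical(),
                      c_terminal_fragment = logical(), notation = character(),
                      stringsAsFactors = FALSE))
  raw <- substring(protein, seg_start + 1L, seg_end)
  amid <- followed_by_site & substring(raw, nchar(raw), nchar(raw)) == "G"
  seqp <- ifelse(amid, substring(raw, 1L, nchar(raw) - 1L), raw)
  pyro <- startsWith(seqp, "Q")
  data.frame(
    sequence = seqp, start = as.integer(seg_start), end = as.integer(seg_end),
    amidated = amid, pyroglutamated = pyro,
    c_terminal_fragment = !followed_by_site,
    notation = paste0(ifelse(pyro, paste0("pQ", substring(seqp, 2L)), seqp),
                      ifelse(amid, "amide", "")),
    stringsAsFactors = FALSE)
}

peptide_notation_string <- function(sequence, amidated, pyroglutamated) {
  base <- if (pyroglutamated) paste0("pQ", substr(sequence, 2L, nchar(sequence)))
          else sequence
  paste0(base, if (amidated) "amide" else "")
}

#' Display notation for a mature peptide
#'
#' `pQ` prefix for pyroglutamated peptides, `amide` suffix for amidated
#' ones, e.g. `pQGPRamide`.
#'
#' @param p One row of a mature-peptide table (or any list with `sequence`,
#'   `amidated`, `pyroglutamated`).
#' @return Character notation.
#' @export
peptide_notation <- function(p) {
  peptide_notation_string(p$sequence, isTRUE(p$amidated),
                          isTRUE(p$pyroglutamated))
}
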