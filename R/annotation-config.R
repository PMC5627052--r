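#' Annotation configuration
#'
#' Tunable parameters for precursor annotation.
#'
#' @param signal_threshold Signal-peptide score threshold in \[0,1\]. The
#'   default 0.34 is the sensitive cut-off conventionally used when mining
#'   neuropeptide precursors, where missing a precursor is costlier than a
#'   false signal call.
#' @param dibasic_motifs Residue pairs accepted as dibasic cleavage sites.
#' @param allow_monobasic_R,allow_monobasic_K Accept single-residue R / K
#'   cleavage sites. Monobasic R sites are common at multi-copy precursor
#'   separators; monobasic K sites are rare and off by default.
#' @param monobasic_min_gap A single basic residue is only treated as an
#'   independent cleavage site when no other basic run lies within this many
#'   residues on either side; closer singles are part of the neighbouring
#'   site's processing context (e.g. the R of a pQGPRamide copy two residues
#'   before its dibasic site is peptide, not site).
#' @param min_signal_cleavage,max_signal_cleavage Candidate window (0-based
#'   index of the first mature residue) for the signal-peptidase site.
#' @param spacer_max_acid_fraction Display-level classification: a peptide
#'   segment whose D/E fraction exceeds this value is rendered as an acidic
#'   spacer rather than a mature peptide in alignment reports. Counting is
#'   unaffected (classification is the predicate's job).
#' @return An object of class `annotation_config`.
#' @export
annotation_config <- function(signal_threshold = 0.34,
                              dibasic_motifs = c("KR", "RR", "KK", "RK"),
                              allow_monobasic_R = TRUE,
                              allow_monobasic_K = FALSE,
                              monobasic_min_gap = 2L,
                              min_signal_cleavage = 15L,
                              max_signal_cleavage = 35L,
                              spacer_max_acid_fraction = 0.5) {
  stopifnot(signal_threshold >= 0, signal_threshold <= 1,
            spacer_max_acid_fraction >= 0, spacer_max_acid_fraction <= 1,
            min_signal_cleavage < max_signal_cleavage,
            monobasic_min_gap >= 0)
  if (!all(grepl("^[KR]{2}$", dibasic_motifs)))
    np_stop("npmine_bad_config", "dibasic motifs must be K/R pairs")
  structure(list(signal_threshold = signal_threshold,
                 dibasic_motifs = dibasic_motifs,
                 allow_monobasic_R = allow_monobasic_R,
                 allow_monobasic_K = allow_monobasic_K,
                 monobasic_min_gap = as.integer(monobasic_min_gap),
                 min_signal_cleavage = as.integer(min_signal_cleavage),
                 max_signal_cleavage = as.integer(max_signal_cleavage),
                 spacer_max_acid_fraction = spacer_max_acid_fraction),
            class = "annotation_config")
}
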