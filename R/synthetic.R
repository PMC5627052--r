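#' Specification of a synthetic neuropeptide precursor
#'
#' Describes a preprohormone architecture with known ground truth: an
#' N-terminal signal peptide (Met + hydrophobic core + `ASA` ending, so
#' the (-3,-1) rule points at the designed boundary), `n_copies` peptide
#' repeats separated by mono-/dibasic cleavage sites, optional amidation
#' donor glycines, optional acidic spacers (each flanked by its own
#' cleavage site, as in real multi-copy precursors), and a short
#' C-terminal tail.
#'
#' @param n_copies Number of peptide copies (>= 1).
#' @param peptide_template Template sequence(s); a vector is recycled
#'   across copies (related, non-identical peptides). Templates may
#'   contain internal basic residues only where the processing context
#'   protects them (e.g. the R of `QGPR` two residues before a dibasic
#'   site); the generator verifies recoverability and raises `BadSpec`
#'   otherwise.
#' @param separator `"KR"`, `"RR"`, `"R"` (monobasic) or `"mixed"`
#'   (alternating KR / R).
#' @param amidation Append a C-terminal glycine donor to every copy.
#' @param spacer Optional acidic spacer sequence inserted between copies.
#' @param signal_core_len Length of the hydrophobic signal core.
#' @param c_tail Optional fixed C-terminal tail (default: sampled 6-mer).
#' @param id Record identifier.
#' @param seed Integer seed; everything downstream is deterministic in it.
#' @return Object of class `precursor_spec`.
#' @export
precursor_spec <- function(n_copies, peptide_template, separator = "KR",
                           amidation = TRUE, spacer = NULL,
                           signal_core_len = 12L, c_tail = NULL,
                           id = "synthetic", seed = 1L) {
  n_copies <- as.integer(n_copies)
  if (is.na(n_copies) || n_copies < 1L)
    np_stop("npmine_bad_spec", "n_copies must be a positive integer")
  peptide_template <- toupper(peptide_template)
  if (!length(peptide_template) || any(!nzchar(peptide_template)))
    np_stop("npmine_bad_spec", "peptide template(s) must be non-empty")
  if (!separator %in% c("KR", "RR", "R", "mixed"))
    np_stop("npmine_bad_spec", "separator must be KR, RR, R or mixed")
  if (!is.null(spacer)) {
    spacer <- toupper(spacer)
    if (nchar(spacer) < 2L || grepl("[KR]", spacer))
      np_stop("npmine_bad_spec", "spacer must be >= 2 residues and free of K/R")
  }
  if (signal_core_len < 8L)
    np_stop("npmine_bad_spec", "signal core too short to form a hydrophobic core")
  # templates whose own hydrophobicity rivals a signal core would defeat
  # boundary recovery; reject early with a clear message
  for (t in peptide_template) {
    kd <- kd_hydropathy[strsplit(t, "", fixed = TRUE)[[1]]]
    if (mean(kd, na.rm = TRUE) >= 3.0)
      np_stop("npmine_bad_spec",
              sprintf("template '%s' is too hydrophobic (signal-like)", t))
  }
  structure(list(n_copies = n_copies, peptide_template = peptide_template,
                 separator = separator, amidation = isTRUE(amidation),
                 spacer = spacer, signal_core_len = as.integer(signal_core_len),
                 c_tail = c_tail, id = id, seed = as.integer(seed)),
            class = "precursor_spec")
}

separator_for <- function(regime, k) {
  switch(regime,
         KR = "KR", RR = "RR", R = "R",
         mixed = if (k %% 2L == 1L) "KR" else "R")
}

#' Generate a synthetic precursor with ground truth
#'
#' Builds the protein, a transcript (random UTRs plus uniformly sampled
#' synonymous codons, with an in-frame terminator closing the 5' UTR so
#' the coding sequence is recoverable as a clean ORF) and the full
#' expected annotation. The module contract — [annotate_precursor()] with
#' the default configuration reproduces the expected signal boundary,
#' sites and peptides exactly — is asserted at construction; a `BadSpec`
#' error means the requested architecture is not recoverable.
#'
#' @param spec A [precursor_spec].
#' @return Object of class `synthetic_truth`: `protein`, `record`,
#'   `transcript` (nt [seq_record]), `cds_start` (0-based forward-strand
#'   offset of the CDS), `signal_boundary`, `expected_sites`,
#'   `expected_peptides`, `spec`.
#' @export
generate_precursor <- function(spec) {
  if (!inherits(spec, "precursor_spec"))
    np_stop("npmine_bad_spec", "expected a precursor_spec")
  with_local_seed(spec$seed, build_truth(spec))
}

build_truth <- function(spec) {
  core <- c(sample(c("L", "A", "V", "I"), spec$signal_core_len - 1L,
                   replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15)), "L")
  signal <- paste0("M", paste(core, collapse = ""), "ASA")
  boundary <- nchar(signal)

  templates <- rep_len(spec$peptide_template, spec$n_copies)
  tail_seq <- spec$c_tail %||%
    paste(sample(c("S", "N", "A", "D", "E", "T", "P", "F"), 6L, replace = TRUE),
          collapse = "")

  # lay the pieces out left to right, tracking segment vs site coordinates
  pos <- boundary
  pieces <- character()
  seg_start <- integer(); seg_end <- integer(); seg_followed <- logical()
  site_start <- integer(); site_end <- integer(); site_motif <- character()
  sep_counter <- 0L
  add_site <- function(motif) {
    site_start[length(site_start) + 1L] <<- pos
    site_end[length(site_end) + 1L] <<- pos + nchar(motif)
    site_motif[length(site_motif) + 1L] <<- motif
    pieces[length(pieces) + 1L] <<- motif
    pos <<- pos + nchar(motif)
  }
  add_segment <- function(raw, is_last = FALSE) {
    seg_start[length(seg_start) + 1L] <<- pos
    seg_end[length(seg_end) + 1L] <<- pos + nchar(raw)
    seg_followed[length(seg_followed) + 1L] <<- !is_last
    pieces[length(pieces) + 1L] <<- raw
    pos <<- pos + nchar(raw)
  }

  for (i in seq_len(spec$n_copies)) {
    add_segment(paste0(templates[i], if (spec$amidation) "G" else ""))
    sep_counter <- sep_counter + 1L
    add_site(separator_for(spec$separator, sep_counter))
    if (!is.null(spec$spacer) && i < spec$n_copies) {
      add_segment(spec$spacer)
      sep_counter <- sep_counter + 1L
      add_site(separator_for(spec$separator, sep_counter))
    }
  }
  add_segment(tail_seq, is_last = TRUE)

  protein <- paste0(signal, paste(pieces, collapse = ""))
  expected_sites <- data.frame(
    start = site_start, end = site_end,
    kind = ifelse(nchar(site_motif) == 1L, "monobasic", "dibasic"),
    motif = site_motif, stringsAsFactors = FALSE)
  expected_peptides <- peptide_table(protein, seg_start, seg_end, seg_followed)

  tx <- encode_transcript(protein)
  truth <- structure(list(protein = protein,
                          record = seq_record(spec$id, protein),
                          transcript = seq_record(paste0(spec$id, "_tx"),
                                                  tx$nt, alphabet = "nt"),
                          cds_start = tx$cds_start,
                          signal_boundary = boundary,
                          expected_sites = expected_sites,
                          expected_peptides = expected_peptides,
                          spec = spec),
                     class = "synthetic_truth")
  assert_truth_contract(truth)
  truth
}

# Synonymous codons per residue under the standard code, computed once.
codon_choices <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

# Transcript layout: random 5' UTR closed by an in-frame terminator,
# uniformly sampled synonymous codons, a stop codon, random 3' UTR.
encode_transcript <- function(protein) {
  utr5_len <- 3L * sample(4:15, 1L)
  utr5 <- c(sample(c("A", "C", "G", "T"), utr5_len - 3L, replace = TRUE),
            strsplit(sample(c("TAA", "TGA", "TAG"), 1L), "")[[1]])
  chars <- strsplit(protein, "", fixed = TRUE)[[1]]
  choices <- codon_choices[chars]
  if (any(bad <- vapply(choices, is.null, logical(1))))
    np_stop("npmine_bad_spec",
            sprintf("cannot encode residue '%s'", chars[which(bad)[1]]))
  n_opt <- lengths(choices)
  picks <- ceiling(runif(length(chars)) * n_opt)
  codons <- mapply(`[[`, choices, picks)
  stop_codon <- sample(c("TAA", "TGA", "TAG"), 1L)
  utr3 <- sample(c("A", "C", "G", "T"), sample(10:40, 1L), replace = TRUE)
  nt <- paste0(paste(utr5, collapse = ""), paste(codons, collapse = ""),
               stop_codon, paste(utr3, collapse = ""))
  list(nt = nt, cds_start = utr5_len)
}

assert_truth_contract <- function(truth) {
  ann <- annotate_precursor(truth$record)
  ok <- isTRUE(ann$signal$present) &&
    identical(ann$signal$cleavage_pos, truth$signal_boundary) &&
    identical(ann$sites, truth$expected_sites) &&
    identical(ann$peptides, truth$expected_peptides)
  if (!ok)
    np_stop("npmine_bad_spec",
            "requested architecture is not recoverable by annotation (truth contract)")
  invisible(truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth %s: %d aa, %d copies, %d sites>\n",
              x$spec$id, nchar(x$protein), x$spec$n_copies,
              nrow(x$expected_sites)))
  invisible(x)
}

#' Default counting predicate for a synthetic family
#'
#' A family copy is a mature peptide carrying the family's diagnostic core
#' motif (the first residues of the template, which background mutation in
#' clade datasets never touches) and, for amidated families, the
#' C-terminal amide. This matches how multi-copy precursor repertoires
#' are counted in practice: a peptide fused across a destroyed cleavage
#' site is one (non-canonical) peptide, and a copy that lost its
#' amidation donor no longer counts as a deliverable family copy.
#'
#' @param spec A [precursor_spec].
#' @return Predicate string.
#' @export
spec_predicate <- function(spec) {
  core <- template_core(spec$peptide_template[1])
  p <- paste0("contains=", core)
  if (spec$amidation) p <- paste(p, "& amide")
  p
}

template_core <- function(template) {
  substr(template, 1L, min(5L, nchar(template)))
}

non_basic_pool <- strsplit("ACDEFHILMNPQSTVWY", "", fixed = TRUE)[[1]]

# Background-substitution pool: non-basic, no glycine (would create amide
# donors) and only mildly hydrophobic residues, so drifted orthologues can
# never grow a second signal-like stretch.
mutation_pool <- strsplit("ADEHMNPQSTWY", "", fixed = TRUE)[[1]]

#' Knock out a cleavage site or amidation donor
#'
#' Emulates the substitutions that drive copy-number loss: `basic_to_X`
#' replaces every K/R of the chosen site with random non-basic residues
#' (the two flanking peptides merge across the dead site); `glycine_to_X`
#' mutates the amidation donor glycine immediately before the chosen site
#' (same peptide count, one fewer amidated copy). Expected annotation and
#' transcript are recomputed, and the truth contract re-asserted.
#'
#' @param truth A `synthetic_truth`.
#' @param site_index 1-based index into `expected_sites`.
#' @param mode `"basic_to_X"` or `"glycine_to_X"`.
#' @param seed Seed for the replacement draws and transcript re-encoding.
#' @return A new `synthetic_truth` with a `knockout` field recording the
#'   planted substitutions (`pos`, `ref`, `obs`, `role`, `site_index`).
#' @export
knockout_cleavage <- function(truth, site_index, mode = c("basic_to_X",
                                                          "glycine_to_X"),
                              seed = 1L) {
  mode <- match.arg(mode)
  sites <- truth$expected_sites
  if (site_index < 1L || site_index > nrow(sites))
    np_stop("npmine_bad_index", sprintf("no cleavage site %d", site_index))
  with_local_seed(seed, knockout_apply(truth, as.integer(site_index), mode))
}

knockout_apply <- function(truth, site_index, mode) {
  chars <- strsplit(truth$protein, "", fixed = TRUE)[[1]]
  sites <- truth$expected_sites
  peps <- truth$expected_peptides
  site <- sites[site_index, ]
  planted <- list()

  if (mode == "basic_to_X") {
    for (p in seq.int(site$start, site$end - 1L)) {
      obs <- sample(non_basic_pool, 1L)
      planted[[length(planted) + 1L]] <- data.frame(
        pos = p, ref = chars[p + 1L], obs = obs, role = "cleavage_basic",
        site_index = site_index, stringsAsFactors = FALSE)
      chars[p + 1L] <- obs
    }
    protein <- paste(chars, collapse = "")
    ia <- which(peps$end == site$start)
    ib <- which(peps$start == site$end)
    if (length(ia) != 1L || length(ib) != 1L)
      np_stop("npmine_bad_index", "site is not flanked by two peptide segments")
    a <- peps[ia, ]; b <- peps[ib, ]
    raw <- substr(protein, a$start + 1L, b$end)
    amid <- b$amidated
    proc <- if (amid) substr(raw, 1L, nchar(raw) - 1L) else raw
    pyro <- startsWith(proc, "Q")
    merged <- data.frame(sequence = proc, start = a$start, end = b$end,
                         amidated = amid, pyroglutamated = pyro,
                         c_terminal_fragment = b$c_terminal_fragment,
                         notation = peptide_notation_string(proc, amid, pyro),
                         stringsAsFactors = FALSE)
    peps <- peps[-c(ia, ib), , drop = FALSE]
    peps <- rbind(peps, merged)
    peps <- peps[order(peps$start), , drop = FALSE]
    sites <- sites[-site_index, , drop = FALSE]
  } else {
    donor_pos <- site$start - 1L
    ia <- which(peps$end == site$start & peps$amidated)
    if (length(ia) != 1L || chars[donor_pos + 1L] != "G")
      np_stop("npmine_bad_index",
              "no amidation donor glycine before that site")
    obs <- sample(setdiff(non_basic_pool, "G"), 1L)
    planted[[1L]] <- data.frame(pos = donor_pos, ref = "G", obs = obs,
                                role = "amidation_glycine",
                                site_index = site_index,
                                stringsAsFactors = FALSE)
    chars[donor_pos + 1L] <- obs
    protein <- paste(chars, collapse = "")
    raw <- substr(protein, peps$start[ia] + 1L, peps$end[ia])
    pyro <- startsWith(raw, "Q")
    peps$sequence[ia] <- raw
    peps$amidated[ia] <- FALSE
    peps$pyroglutamated[ia] <- pyro
    peps$notation[ia] <- peptide_notation_string(raw, FALSE, pyro)
  }
  rownames(peps) <- NULL; rownames(sites) <- NULL

  tx <- encode_transcript(protein)
  out <- truth
  out$protein <- protein
  out$record <- seq_record(truth$spec$id, protein)
  out$transcript <- seq_record(paste0(truth$spec$id, "_tx"), tx$nt,
                               alphabet = "nt")
  out$cds_start <- tx$cds_start
  out$expected_sites <- sites
  out$expected_peptides <- peps
  out$knockout <- do.call(rbind, planted)
  assert_truth_contract(out)
  out
}
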