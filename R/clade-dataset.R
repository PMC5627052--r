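#' Specification of a cross-species clade dataset
#'
#' Describes a family of orthologous multi-copy precursors across several
#' clades: each clade has a characteristic copy number, individual species
#' can deviate (outliers), and cleavage-site / donor-glycine knockouts can
#' be planted. Orthologues share one master architecture — species with
#' fewer copies simply lack the trailing copy slots — so the alignment is
#' produced by construction and no aligner is needed.
#'
#' @param clades `data.frame` with columns `label`, `n_species`,
#'   `base_copies`.
#' @param base_spec A [precursor_spec] providing the family architecture
#'   (its `n_copies` is overridden per clade; no spacer; templates free of
#'   basic residues so knockouts stay local).
#' @param family Family label.
#' @param outliers Optional `data.frame` with columns `clade`, `delta`
#'   (copy-number deviation, counts stay >= 1) and optionally `species`
#'   (defaults to the clade's first species).
#' @param knockouts Optional `data.frame` with columns `clade`,
#'   `site_index`, `mode` (`basic_to_X`/`glycine_to_X`); planted in the
#'   first species of the clade not already an outlier.
#' @param mutation_rate Per-residue background substitution rate applied
#'   to template interiors and the tail (never to functional residues:
#'   signal, separators, donor glycines, N-terminal glutamines), so the
#'   truth stays recomputable. Substitutions never introduce K, R or G.
#' @param seed Integer seed.
#' @return Object of class `clade_dataset_spec`.
#' @export
clade_dataset_spec <- function(clades, base_spec, family = "family",
                               outliers = NULL, knockouts = NULL,
                               mutation_rate = 0.05, seed = 1L) {
  stopifnot(is.data.frame(clades),
            all(c("label", "n_species", "base_copies") %in% names(clades)))
  if (!inherits(base_spec, "precursor_spec"))
    np_stop("npmine_bad_spec", "base_spec must be a precursor_spec")
  if (!is.null(base_spec$spacer))
    np_stop("npmine_bad_spec", "clade datasets do not support spacers")
  if (any(grepl("[KR]", base_spec$peptide_template)))
    np_stop("npmine_bad_spec",
            "clade-dataset templates must be free of basic residues")
  if (length(base_spec$peptide_template) != 1L)
    np_stop("npmine_bad_spec",
            "clade datasets use a single template (one diagnostic core)")
  if (!is.null(outliers)) {
    stopifnot(all(c("clade", "delta") %in% names(outliers)))
    if (is.null(outliers$species)) outliers$species <- NA_character_
  }
  if (!is.null(knockouts))
    stopifnot(all(c("clade", "site_index", "mode") %in% names(knockouts)))
  structure(list(clades = clades, base_spec = base_spec, family = family,
                 outliers = outliers, knockouts = knockouts,
                 mutation_rate = mutation_rate, seed = as.integer(seed)),
            class = "clade_dataset_spec")
}

#' Generate a cross-species clade dataset with ground truth
#'
#' @param spec A [clade_dataset_spec].
#' @return List with elements `species` (data.frame: `species`, `clade`,
#'   `architectural_copies`, `expected_count`, `role`), `records` (named
#'   list of ungapped aa [seq_record]s), `matrix` (truth
#'   `copy_number_matrix`), `clades` (named vector), `alignment` (gapped
#'   [seq_record]s), `knockouts` (planted substitutions with 0-based
#'   `alignment_column`), `predicate`, `reference_species`, `family`.
#' @export
generate_clade_dataset <- function(spec) {
  if (!inherits(spec, "clade_dataset_spec"))
    np_stop("npmine_bad_spec", "expected a clade_dataset_spec")
  with_local_seed(spec$seed, build_clade_dataset(spec))
}

build_clade_dataset <- function(spec) {
  cl <- spec$clades
  sp_rows <- list()
  for (r in seq_len(nrow(cl))) {
    n <- cl$n_species[r]
    sp_rows[[r]] <- data.frame(
      species = sprintf("%s_sp%02d", cl$label[r], seq_len(n)),
      clade = cl$label[r],
      architectural_copies = rep(as.integer(cl$base_copies[r]), n),
      role = "typical", stringsAsFactors = FALSE)
  }
  sp <- do.call(rbind, sp_rows)

  # plant outliers
  if (!is.null(spec$outliers)) {
    for (r in seq_len(nrow(spec$outliers))) {
      o <- spec$outliers[r, ]
      cand <- which(sp$clade == o$clade & sp$role == "typical")
      if (!length(cand))
        np_stop("npmine_bad_spec",
                sprintf("no species left in clade %s for an outlier", o$clade))
      k <- cand[1]
      if (!is.na(o$species) && o$species %in% sp$species)
        k <- match(o$species, sp$species)
      sp$architectural_copies[k] <- sp$architectural_copies[k] + as.integer(o$delta)
      if (sp$architectural_copies[k] < 1L)
        np_stop("npmine_bad_spec", "outlier delta drives copy number below 1")
      sp$role[k] <- "outlier"
      if (!is.na(o$species)) sp$species[k] <- o$species
    }
  }
  ko_assign <- list()
  if (!is.null(spec$knockouts)) {
    for (r in seq_len(nrow(spec$knockouts))) {
      k <- spec$knockouts[r, ]
      cand <- which(sp$clade == k$clade & sp$role == "typical")
      if (!length(cand))
        np_stop("npmine_bad_spec",
                sprintf("no species left in clade %s for a knockout", k$clade))
      sp$role[cand[1]] <- "knockout"
      ko_assign[[sp$species[cand[1]]]] <- k
    }
  }

  M <- max(sp$architectural_copies)
  master_spec <- spec$base_spec
  master_spec$n_copies <- M
  master_spec$seed <- spec$seed
  master <- generate_precursor(master_spec)

  # master layout: signal | slot x M | tail; slot i = template_i (+G) + sep_i
  boundary <- master$signal_boundary
  slot_bounds <- slot_layout(master, M)
  tail_start <- slot_bounds$end[M]
  tail_len <- nchar(master$protein) - tail_start
  width <- nchar(master$protein)

  predicate <- spec_predicate(spec$base_spec)
  template_len <- nchar(spec$base_spec$peptide_template[1])

  records <- list(); aligned <- list(); planted <- list()
  counts <- integer(nrow(sp))
  for (i in seq_len(nrow(sp))) {
    n_i <- sp$architectural_copies[i]
    keep_end <- slot_bounds$end[n_i]
    body <- substr(master$protein, 1L, keep_end)
    tail_seq <- substr(master$protein, tail_start + 1L, width)
    chars <- strsplit(paste0(body, tail_seq), "", fixed = TRUE)[[1]]

    # mutable positions: template residues after the diagnostic core of
    # each copy, and the tail
    core_len <- nchar(template_core(spec$base_spec$peptide_template[1]))
    mutable <- integer()
    if (template_len > core_len)
      for (s in seq_len(n_i)) {
        tstart <- slot_bounds$start[s]
        mutable <- c(mutable, seq.int(tstart + core_len + 1L,
                                      tstart + template_len))
      }
    mutable <- c(mutable, seq.int(keep_end + 1L, keep_end + tail_len))
    hit <- mutable[runif(length(mutable)) < spec$mutation_rate]
    for (p in hit) {
      pool <- setdiff(mutation_pool, chars[p])
      chars[p] <- sample(pool, 1L)
    }

    expected <- n_i
    ko <- ko_assign[[sp$species[i]]]
    if (!is.null(ko)) {
      if (ko$site_index < 1L || ko$site_index > n_i)
        np_stop("npmine_bad_spec", "knockout site_index beyond this species")
      sep_start <- slot_bounds$sep_start[ko$site_index]
      sep_end <- slot_bounds$end[ko$site_index]
      if (ko$mode == "basic_to_X") {
        for (p in seq.int(sep_start, sep_end - 1L)) {
          obs <- sample(setdiff(non_basic_pool, "G"), 1L)
          planted[[length(planted) + 1L]] <- data.frame(
            species = sp$species[i], master_pos = p,
            reference_residue = substr(master$protein, p + 1L, p + 1L),
            observed_residue = obs, role = "cleavage_basic",
            site_index = as.integer(ko$site_index), stringsAsFactors = FALSE)
          chars[p + 1L] <- obs
        }
        expected <- expected - 1L
      } else {
        donor <- sep_start - 1L
        if (!spec$base_spec$amidation)
          np_stop("npmine_bad_spec", "glycine knockout needs an amidated family")
        obs <- sample(setdiff(non_basic_pool, "G"), 1L)
        planted[[length(planted) + 1L]] <- data.frame(
          species = sp$species[i], master_pos = donor,
          reference_residue = "G", observed_residue = obs,
          role = "amidation_glycine", site_index = as.integer(ko$site_index),
          stringsAsFactors = FALSE)
        chars[donor + 1L] <- obs
        # the copy keeps its length but loses the amide, so it leaves the
        # family count when the family predicate requires amidation
        expected <- expected - 1L
      }
    }

    prot <- paste(chars, collapse = "")
    records[[sp$species[i]]] <- seq_record(sp$species[i], prot)
    gap_block <- strrep("-", slot_bounds$end[M] - slot_bounds$end[n_i])
    aligned[[sp$species[i]]] <- seq_record(
      sp$species[i],
      paste0(substr(prot, 1L, keep_end), gap_block,
             substr(prot, keep_end + 1L, nchar(prot))),
      alphabet = "aa", allow_gaps = TRUE)
    counts[i] <- expected
  }
  sp$expected_count <- counts

  mat <- matrix(as.integer(counts), ncol = 1L,
                dimnames = list(sp$species, spec$family))
  mat <- structure(mat, class = c("copy_number_matrix", class(mat)))

  knock <- if (length(planted)) do.call(rbind, planted) else NULL
  if (!is.null(knock)) {
    # master positions are alignment columns: every row keeps coordinates
    # up to its own keep_end and knockouts never sit in the gap block
    knock$alignment_column <- knock$master_pos
    knock$master_pos <- NULL
  }

  ref_i <- which(sp$architectural_copies == M & sp$role == "typical")[1]
  if (is.na(ref_i)) ref_i <- which(sp$architectural_copies == M)[1]

  list(species = sp, records = records, matrix = mat,
       clades = setNames(sp$clade, sp$species), alignment = aligned,
       knockouts = knock, predicate = predicate,
       reference_species = sp$species[ref_i], family = spec$family)
}

# Copy-slot layout of a master synthetic precursor: for slot i, `start` is
# the 0-based start of the template, `sep_start` the start of its
# separator, `end` the end of the separator.
slot_layout <- function(master, M) {
  peps <- master$expected_peptides
  sites <- master$expected_sites
  copy_rows <- which(!peps$c_terminal_fragment)
  stopifnot(length(copy_rows) == M, nrow(sites) == M)
  list(start = peps$start[copy_rows],
       sep_start = sites$start,
       end = sites$end)
}
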