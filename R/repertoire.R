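#' Synthetic brittle-star precursor repertoire (stand-in)
#'
#' A fully synthetic stand-in repertoire whose architectures mirror the
#' published descriptions of multi-copy ophiuroid neuropeptide precursors
#' (copy numbers, peptide motifs, amidation and pyroglutamation): a
#' TRH-type precursor 1 with 21 pQXXXamide tetrapeptides; a TRH-type
#' precursor 2 with two pQGPRamide tetrapeptides plus two longer
#' GPRamide peptides lacking the N-terminal pyroglutamate; an np18-type
#' precursor with four LFWVD copies and a cysteine-rich C-terminal
#' region; np26-type precursors with seven (reference species) or eight
#' (two other species) amidated GW-motif peptides; a CCK-type precursor 1
#' with three peptides, a tachykinin-type precursor with four and a
#' kisspeptin-type precursor with two. The sequences themselves are
#' generated, not the deposited ones; only the annotated architecture is
#' modelled.
#'
#' @param seed Integer seed for the generated sequences.
#' @return Named list of `synthetic_truth` objects; element names are
#'   family labels (`trhp1`, `trhp2`, `np18`, `np26_ovic`, `np26_afil`,
#'   `np26_oara`, `cck1`, `tachykinin`, `kisspeptin`).
#' @export
synthetic_repertoire <- function(seed = 101L) {
  # 21 related pQXXXamide tetrapeptides (X variable, never basic)
  trh_x <- c("YPG", "FPA", "WPS", "YPA", "FPS", "WPG", "YPT", "FPG", "WPA",
             "YPS", "FPT", "WPT", "HPG", "HPA", "NPG", "YPN", "FPN", "WPN",
             "HPS", "NPA", "YPQ")
  trhp1 <- generate_precursor(precursor_spec(
    n_copies = 21L, peptide_template = paste0("Q", trh_x),
    separator = "KR", amidation = TRUE, id = "synthTRHP1", seed = seed))

  trhp2 <- generate_precursor(precursor_spec(
    n_copies = 4L,
    peptide_template = c("QGPR", "SSEANFDGPR", "QGPR", "TNELSADGPR"),
    separator = "KR", amidation = TRUE, id = "synthTRHP2", seed = seed + 1L))

  np18 <- generate_precursor(precursor_spec(
    n_copies = 4L, peptide_template = "LFWVD", separator = "KR",
    amidation = FALSE, c_tail = "SNECCTPACDLCA", id = "synthNP18",
    seed = seed + 2L))

  gw <- function(n, id, s)
    generate_precursor(precursor_spec(
      n_copies = n,
      peptide_template = paste0(c("NSAFD", "TSELD", "NSAMD", "SSAFE",
                                  "NTAFD", "TSALD", "NSSFD", "SSELD")[seq_len(n)],
                                "SGW"),
      separator = "KR", amidation = TRUE, id = id, seed = s))
  np26_ovic <- gw(7L, "synthNP26ov", seed + 3L)
  np26_afil <- gw(8L, "synthNP26af", seed + 4L)
  np26_oara <- gw(8L, "synthNP26oa", seed + 5L)

  cck1 <- generate_precursor(precursor_spec(
    n_copies = 3L, peptide_template = c("SGDYGHMGWMDF", "NGDYGHLGWMDF",
                                        "SADYGHMGWNDF"),
    separator = "KR", amidation = TRUE, id = "synthCCK1", seed = seed + 6L))

  tachykinin <- generate_precursor(precursor_spec(
    n_copies = 4L, peptide_template = c("GGGFTFHGMM", "SGGFSFHGMM",
                                        "GGGFTFHGLM", "AGGFSFHGMM"),
    separator = "KR", amidation = TRUE, id = "synthTK", seed = seed + 7L))

  kisspeptin <- generate_precursor(precursor_spec(
    n_copies = 2L, peptide_template = c("CCSDSNLAFHDWSNE", "DSNFNAWSE"),
    separator = "KR", amidation = TRUE, id = "synthKP", seed = seed + 8L))

  list(trhp1 = trhp1, trhp2 = trhp2, np18 = np18, np26_ovic = np26_ovic,
       np26_afil = np26_afil, np26_oara = np26_oara, cck1 = cck1,
       tachykinin = tachykinin, kisspeptin = kisspeptin)
}

#' Synthetic cross-species clade datasets (stand-ins)
#'
#' Three generated datasets emulating the published cross-species
#' copy-number patterns over the three primary ophiuroid clades:
#'
#' * `ftype_salmfamide` — clade-characteristic copy numbers 13 (clade A),
#'   12 (clade B) and 11 (clade C) with one mild exception per clade that
#'   leaves the medians untouched;
#' * `trh1` — clade C at 19 copies with one species reduced to 16;
#' * `kisspeptin` — four copies throughout with one clade-C species
#'   reduced to three.
#'
#' @param seed Integer seed.
#' @return Named list of clade datasets (see [generate_clade_dataset()]).
#' @export
synthetic_clade_datasets <- function(seed = 202L) {
  salm_spec <- precursor_spec(
    n_copies = 1L, peptide_template = "SAFDSLSGFNSGLTF", separator = "KR",
    amidation = TRUE, id = "synthSALMF", seed = seed)
  ftype <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = c("A", "B", "C"),
                        n_species = c(9L, 13L, 17L),
                        base_copies = c(13L, 12L, 11L)),
    base_spec = salm_spec, family = "F-SALMFamide",
    outliers = data.frame(clade = c("A", "B", "C"), delta = c(1L, -1L, 1L)),
    mutation_rate = 0.05, seed = seed))

  trh_spec <- precursor_spec(
    n_copies = 1L, peptide_template = "QWPA", separator = "KR",
    amidation = TRUE, id = "synthTRH1", seed = seed + 1L)
  trh1 <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = c("A", "B", "C"),
                        n_species = c(8L, 10L, 14L),
                        base_copies = c(18L, 20L, 19L)),
    base_spec = trh_spec, family = "TRH1",
    outliers = data.frame(clade = "C", delta = -3L, species = "Op_lame"),
    mutation_rate = 0.05, seed = seed + 1L))

  kp_spec <- precursor_spec(
    n_copies = 1L, peptide_template = "DSNFNAWSE", separator = "KR",
    amidation = TRUE, id = "synthKP52", seed = seed + 2L)
  kp <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = c("A", "B", "C"),
                        n_species = c(8L, 10L, 12L),
                        base_copies = c(4L, 4L, 4L)),
    base_spec = kp_spec, family = "kisspeptin",
    outliers = data.frame(clade = "C", delta = -1L, species = "Op_savi"),
    mutation_rate = 0.05, seed = seed + 2L))

  list(ftype_salmfamide = ftype, trh1 = trh1, kisspeptin = kp)
}
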