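test_that("signal prediction rejects hydrophilic N-termini and is window-local", {
  cfg <- annotation_config()
  # no hydrophobic core at all
  call <- predict_signal_peptide(strrep("E", 30), cfg)
  expect_false(call$present)
  expect_lt(call$score, cfg$signal_threshold)
  # score depends only on residues up to the candidate window
  base <- paste0("MKT", strrep("L", 10), "ASA", strrep("Q", 30))
  alt <- paste0(substr(base, 1, cfg$max_signal_cleavage + 1),
                strrep("W", 30))
  expect_equal(predict_signal_peptide(base, cfg)$score,
               predict_signal_peptide(alt, cfg)$score)
  # too-short input: absent, score 0
  short <- predict_signal_peptide("MKTLL", cfg)
  expect_false(short$present)
  expect_equal(short$score, 0)
})

test_that("signal cleavage lands within two residues of a designed boundary", {
  cfg <- annotation_config()
  set.seed(17)
  for (k in 1:50) {
    mature <- random_aa(sample(20:60, 1), setdiff(aa20, c("L", "V", "I")))
    prot <- paste0("MKT", strrep("L", 10), "ASA", mature)
    call <- predict_signal_peptide(prot, cfg)
    expect_true(call$present)
    expect_lte(abs(call$cleavage_pos - 16L), 2L)
  }
})

test_that("cleavage-site scanning merges runs and applies the monobasic context rule", {
  expect_equal(nrow(find_cleavage_sites("AAAA")), 0)
  s1 <- find_cleavage_sites("AAKRAA")
  expect_equal(s1$start, 2); expect_equal(s1$end, 4)
  expect_equal(s1$kind, "dibasic"); expect_equal(s1$motif, "KR")
  s2 <- find_cleavage_sites("AKRRA")
  expect_equal(nrow(s2), 1)
  expect_equal(s2$kind, "polybasic"); expect_equal(s2$motif, "KRR")
  # isolated monobasic R is a site; K is not unless enabled
  expect_equal(find_cleavage_sites("SSSRSSS")$kind, "monobasic")
  expect_equal(nrow(find_cleavage_sites("SSSKSSS")), 0)
  cfgK <- annotation_config(allow_monobasic_K = TRUE)
  expect_equal(find_cleavage_sites("SSSKSSS", config = cfgK)$motif, "K")
  # an R within two residues of another basic run is processing context,
  # not an independent site (the R of pQGPRamide)
  s3 <- find_cleavage_sites("QGPRGKR")
  expect_equal(nrow(s3), 1)
  expect_equal(s3$motif, "KR")
  # scanning starts at from_pos
  expect_equal(nrow(find_cleavage_sites("KRAAAKR", from_pos = 3)), 1)
})

test_that("mature peptides reproduce the published worked examples", {
  sig_absent <- npmine:::signal_call(FALSE, NA_integer_, 0)
  # one pQGPRamide copy
  p1 <- "QGPRGKR"
  peps1 <- derive_mature_peptides(p1, sig_absent, find_cleavage_sites(p1))
  expect_equal(nrow(peps1), 1)
  expect_equal(peps1$sequence, "QGPR")
  expect_true(peps1$amidated); expect_true(peps1$pyroglutamated)
  expect_equal(peps1$notation, "pQGPRamide")
  expect_equal(nchar(peps1$sequence), 4)  # pQ counts toward the length
  # four LFWVD copies, none amidated
  p2 <- strrep("LFWVDKR", 4)
  peps2 <- derive_mature_peptides(p2, sig_absent, find_cleavage_sites(p2))
  expect_equal(peps2$sequence, rep("LFWVD", 4))
  expect_false(any(peps2$amidated))
  expect_equal(unique(peps2$notation), "LFWVD")
  # no sites: single C-terminal fragment covering the propeptide
  p3 <- "QAWSTNDE"
  peps3 <- derive_mature_peptides(p3, sig_absent, find_cleavage_sites(p3))
  expect_equal(nrow(peps3), 1)
  expect_true(peps3$c_terminal_fragment)
  expect_false(peps3$amidated)
  # pQHPamide notation
  expect_equal(peptide_notation(list(sequence = "QHP", amidated = TRUE,
                                     pyroglutamated = TRUE)), "pQHPamide")
})

test_that("predicate language parses, evaluates and round-trips", {
  peps <- derive_mature_peptides("QGPRGKRLFWVDKRNSAFDSGWGKR",
                                 npmine:::signal_call(FALSE, NA, 0),
                                 find_cleavage_sites("QGPRGKRLFWVDKRNSAFDSGWGKR"))
  expect_equal(predicate_matches("len=4 & pyroQ & amide", peps),
               c(TRUE, FALSE, FALSE))
  expect_equal(predicate_matches("endswith=GW & amide", peps),
               c(FALSE, FALSE, TRUE))
  expect_equal(predicate_matches("contains=FWV", peps), c(FALSE, TRUE, FALSE))
  expect_equal(predicate_matches("!(amide | pyroQ)", peps),
               c(FALSE, TRUE, FALSE))
  expect_equal(predicate_matches("minres=F:1 & ! len=4", peps),
               c(FALSE, TRUE, TRUE))
  p <- parse_predicate("len=4 & pyroQ & amide")
  expect_identical(format(p), "len=4 & pyroQ & amide")
  expect_identical(predicate_matches(parse_predicate(format(p)), peps),
                   predicate_matches(p, peps))
  expect_error(parse_predicate("len=4 &"), class = "npmine_bad_predicate")
  expect_error(parse_predicate("frobnicate"), class = "npmine_bad_predicate")
})

test_that("copy counting excludes C-terminal fragments unless opted in", {
  truth <- generate_precursor(precursor_spec(3, "QWPSA", "KR", id = "t",
                                             seed = 2))
  ann <- annotate_precursor(truth$record)
  expect_equal(count_peptide_copies(ann, "true"), 3)
  expect_equal(count_peptide_copies(ann, "true | cterm"), 4)
  expect_equal(count_peptide_copies(ann, "false"), 0)
})

test_that("annotation is deterministic and reconstruction always holds", {
  set.seed(3)
  grid <- expand.grid(n = c(1, 4, 9), sep = c("KR", "R", "mixed"),
                      spacer = c(FALSE, TRUE), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    truth <- generate_precursor(precursor_spec(
      grid$n[r], "QWPSA", grid$sep[r], amidation = TRUE,
      spacer = if (grid$spacer[r]) "EEDSAE" else NULL,
      id = "g", seed = 100 + r))
    a1 <- annotate_precursor(truth$record)
    a2 <- annotate_precursor(truth$record)
    expect_identical(a1[names(a1) != "record"], a2[names(a2) != "record"])
    expect_identical(reconstruct_precursor(a1), truth$protein)
    expect_equal(count_peptide_copies(a1, "len=5 & pyroQ & amide"), grid$n[r])
  }
})

test_that("amidation flags always correspond to a glycine donor in the precursor", {
  set.seed(9)
  for (k in 1:10) {
    truth <- generate_precursor(precursor_spec(
      sample(1:8, 1), sample(c("QWPSA", "NSAFDSGW", "LFWVD"), 1),
      sample(c("KR", "RR", "mixed"), 1), amidation = sample(c(TRUE, FALSE), 1),
      id = "a", seed = 400 + k))
    ann <- annotate_precursor(truth$record)
    for (i in seq_len(nrow(ann$peptides))) {
      p <- ann$peptides[i, ]
      if (p$amidated) {
        expect_equal(substr(truth$protein, p$end, p$end), "G")
        expect_true(p$end %in% ann$sites$start)
      }
    }
  }
})

test_that("disabling monobasic R never increases counts and is neutral for dibasic-only precursors", {
  cfg_off <- annotation_config(allow_monobasic_R = FALSE)
  set.seed(4)
  for (k in 1:8) {
    sep <- sample(c("KR", "R", "mixed"), 1)
    truth <- generate_precursor(precursor_spec(sample(2:7, 1), "QWPSA", sep,
                                               id = "m", seed = 200 + k))
    on <- count_peptide_copies(annotate_precursor(truth$record),
                               "len=5 & pyroQ & amide")
    off <- count_peptide_copies(annotate_precursor(truth$record, cfg_off),
                                "len=5 & pyroQ & amide")
    expect_lte(off, on)
    if (sep == "KR") expect_equal(off, on)
  }
})

test_that("partial records are annotated but flagged", {
  # no plausible signal peptide: partial, sites still scanned from 0
  rec <- seq_record("frag", "EEQDWNDEEKREEQDWNDEEKREEQDWNDE")
  ann <- annotate_precursor(rec)
  expect_true(ann$partial)
  expect_equal(nrow(ann$sites), 2)
  expect_equal(count_peptide_copies(ann, "contains=QDWN"), 2)
  expect_identical(reconstruct_precursor(ann), rec$residues)
})

test_that("external signal calls override the built-in heuristic", {
  truth <- generate_precursor(precursor_spec(2, "QWPSA", "KR", id = "o",
                                             seed = 5))
  f <- withr::local_tempfile()
  writeLines(c("# SignalP-4.1 euk predictions",
               sprintf("%s 0.83 17 0.91 %d 0.95 13 0.87 0.812 Y 0.34 SignalP-noTM",
                       "o", truth$signal_boundary + 1L)), f)
  calls <- read_signalp(f)
  expect_true(calls$o$present)
  ann <- annotate_precursor(truth$record, signal_override = calls$o)
  expect_equal(ann$signal$score, 0.812)
  expect_identical(ann$peptides, truth$expected_peptides)
})
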