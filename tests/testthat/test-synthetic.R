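test_that("the generator is deterministic in its seed", {
  s <- precursor_spec(5, "QWPSA", "mixed", spacer = "EEDAE", id = "d", seed = 77)
  t1 <- generate_precursor(s)
  t2 <- generate_precursor(s)
  expect_identical(t1$protein, t2$protein)
  expect_identical(t1$transcript$residues, t2$transcript$residues)
  t3 <- generate_precursor(precursor_spec(5, "QWPSA", "mixed",
                                          spacer = "EEDAE", id = "d", seed = 78))
  expect_false(identical(t1$transcript$residues, t3$transcript$residues))
})

test_that("generated transcripts encode the protein in a clean ORF", {
  truth <- generate_precursor(precursor_spec(3, "NSAFDSGW", "RR", id = "t",
                                             seed = 12))
  cds <- substr(truth$transcript$residues, truth$cds_start + 1,
                truth$cds_start + 3 * nchar(truth$protein))
  expect_equal(as.character(Biostrings::translate(Biostrings::DNAString(cds))),
               truth$protein)
  # the codon immediately upstream of the CDS is a terminator
  up <- substr(truth$transcript$residues, truth$cds_start - 2, truth$cds_start)
  expect_true(up %in% c("TAA", "TGA", "TAG"))
})

test_that("generator truth equals pipeline annotation across architectures", {
  set.seed(6)
  for (k in 1:20) {
    spec <- precursor_spec(
      n_copies = sample(1:12, 1),
      peptide_template = sample(c("QWPSA", "LFWVD", "NSAFDSGW"), 1),
      separator = sample(c("KR", "RR", "R", "mixed"), 1),
      amidation = sample(c(TRUE, FALSE), 1),
      spacer = if (runif(1) < 0.4) "EEDSAE" else NULL,
      id = "c", seed = 500 + k)
    truth <- generate_precursor(spec)
    ann <- annotate_precursor(truth$record)
    expect_identical(ann$signal$cleavage_pos, truth$signal_boundary)
    expect_identical(ann$sites, truth$expected_sites)
    expect_identical(ann$peptides, truth$expected_peptides)
  }
})

test_that("over-hydrophobic templates are rejected as unrecoverable", {
  expect_error(precursor_spec(3, "VVVVVVVVVV", "KR"),
               class = "npmine_bad_spec")
})

test_that("templates with internal basics work only where context protects them", {
  # the R of pQGPRamide sits two residues before a dibasic site: recoverable
  t <- generate_precursor(precursor_spec(2, "QGPR", "KR", amidation = TRUE,
                                         id = "q", seed = 13))
  ann <- annotate_precursor(t$record)
  expect_equal(sum(ann$peptides$notation == "pQGPRamide"), 2)
  # with a monobasic separator the same template cannot be recovered and
  # the generator refuses to emit misleading truth
  expect_error(generate_precursor(precursor_spec(2, "QGPR", "R",
                                                 amidation = FALSE,
                                                 id = "q", seed = 13)),
               class = "npmine_bad_spec")
})

test_that("cleavage-site knockouts merge peptides and drop one copy", {
  truth <- generate_precursor(precursor_spec(3, "QWPSA", "KR", id = "k",
                                             seed = 31))
  ko <- knockout_cleavage(truth, 2L, "basic_to_X", seed = 1)
  expect_equal(nrow(ko$expected_sites), 2)
  expect_equal(nrow(ko$expected_peptides), nrow(truth$expected_peptides) - 1L)
  ann <- annotate_precursor(ko$record)
  expect_identical(ann$peptides, ko$expected_peptides)
  # one cleavage-site loss removes exactly one family copy: the two
  # flanking copies fuse into a single (still amidated) peptide
  expect_equal(count_peptide_copies(ann, spec_predicate(truth$spec)), 2)
  # the merged peptide spans the dead site and contains the replacements
  merged <- ann$peptides[nchar(ann$peptides$sequence) > 6 &
                           !ann$peptides$c_terminal_fragment, ]
  expect_equal(nrow(merged), 1)
  for (r in seq_len(nrow(ko$knockout)))
    expect_equal(substr(truth$protein, ko$knockout$pos[r] + 1,
                        ko$knockout$pos[r] + 1), ko$knockout$ref[r])
})

test_that("glycine knockouts keep the copy count but remove one amide", {
  truth <- generate_precursor(precursor_spec(4, "QWPSA", "KR", id = "g",
                                             seed = 32))
  ko <- knockout_cleavage(truth, 3L, "glycine_to_X", seed = 2)
  ann_before <- annotate_precursor(truth$record)
  ann_after <- annotate_precursor(ko$record)
  expect_equal(count_peptide_copies(ann_after, "contains=QWPSA"),
               count_peptide_copies(ann_before, "contains=QWPSA"))
  expect_equal(sum(ann_after$peptides$amidated),
               sum(ann_before$peptides$amidated) - 1L)
  expect_identical(ann_after$peptides, ko$expected_peptides)
  expect_equal(ko$knockout$role, "amidation_glycine")
})

test_that("knockout truth matches annotation across random specs", {
  set.seed(44)
  for (k in 1:15) {
    n <- sample(2:6, 1)
    truth <- generate_precursor(precursor_spec(
      n, sample(c("QWPSA", "NSAFDSGW"), 1), sample(c("KR", "RR"), 1),
      id = "r", seed = 700 + k))
    mode <- sample(c("basic_to_X", "glycine_to_X"), 1)
    ko <- knockout_cleavage(truth, sample(seq_len(n), 1), mode, seed = k)
    ann <- annotate_precursor(ko$record)
    expect_identical(ann$sites, ko$expected_sites)
    expect_identical(ann$peptides, ko$expected_peptides)
  }
})

test_that("clade datasets carry a consistent truth matrix and alignment", {
  ds <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = c("A", "B", "C"), n_species = c(4L, 4L, 4L),
                        base_copies = c(13L, 12L, 11L)),
    base_spec = precursor_spec(1, "SAFDSLSGF", "KR", id = "f", seed = 3),
    family = "fam", seed = 3))
  expect_equal(dim(ds$matrix), c(12L, 1L))
  expect_setequal(unique(as.integer(ds$matrix)), c(13L, 12L, 11L))
  # clade medians recover the design
  summ <- clade_summary(ds$matrix, ds$clades, "fam")
  expect_equal(summ$median, c(13L, 12L, 11L))
  # ungapping alignment rows recovers the per-species proteins
  for (s in names(ds$records))
    expect_identical(gsub("-", "", ds$alignment[[s]]$residues, fixed = TRUE),
                     ds$records[[s]]$residues)
  # alignment rows are equal length
  expect_length(unique(vapply(ds$alignment, function(r) nchar(r$residues),
                              integer(1))), 1L)
})
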