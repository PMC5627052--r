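make_entry <- function(species, family, truth) {
  list(species = species, family = family,
       annotation = annotate_precursor(truth$record, family = family))
}

test_that("copy matrices fill cells, respect the partial rule and catch conflicts", {
  t4 <- generate_precursor(precursor_spec(4, "QWPSA", "KR", id = "a", seed = 1))
  t6 <- generate_precursor(precursor_spec(6, "QWPSA", "KR", id = "b", seed = 2))
  t2 <- generate_precursor(precursor_spec(2, "LFWVD", "KR", amidation = FALSE,
                                          id = "c", seed = 3))
  preds <- c(famA = "len=5 & pyroQ & amide", famB = "contains=LFWVD")
  entries <- list(make_entry("sp1", "famA", t4), make_entry("sp2", "famA", t6),
                  make_entry("sp1", "famB", t2), make_entry("sp2", "famB", t2))
  m <- build_copy_matrix(entries, preds)
  expect_equal(unname(m["sp1", "famA"]), 4L)
  expect_equal(unname(m["sp2", "famA"]), 6L)
  expect_equal(unname(m["sp1", "famB"]), 2L)

  # a partial annotation leaves its cell missing, others untouched
  partial_ann <- annotate_precursor(seq_record("fragment",
                                               "EEQDWNDEEKREEQDWNDE"))
  expect_true(partial_ann$partial)
  entries2 <- c(entries, list(list(species = "sp3", family = "famA",
                                   annotation = partial_ann)))
  m2 <- build_copy_matrix(entries2, preds)
  expect_true(is.na(m2["sp3", "famA"]))
  expect_equal(unname(m2["sp1", "famA"]), 4L)
  # missing is NA, never zero
  expect_false(identical(m2["sp3", "famA"], 0L))

  # duplicate entries: identical counts tolerated, conflicts rejected
  expect_silent(build_copy_matrix(c(entries, entries[1]), preds))
  conflict <- c(entries, list(make_entry("sp1", "famA", t6)))
  expect_error(build_copy_matrix(conflict, preds),
               class = "npmine_ambiguous_input")
})

test_that("matrix TSV serialisation round-trips including missing cells", {
  m <- structure(matrix(c(3L, NA, 5L, 0L, 2L, 7L), nrow = 3,
                        dimnames = list(c("s1", "s2", "s3"), c("f1", "f2"))),
                 class = c("copy_number_matrix", "matrix", "array"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_copy_matrix(m, f)
  expect_identical(read_copy_matrix(f), m)
})

test_that("clade summaries match brute-force statistics and ignore species order", {
  m <- structure(matrix(c(13L, 13L, 14L, 12L, 12L, NA, 11L, 10L, 11L, 11L),
                        ncol = 1,
                        dimnames = list(paste0("s", 1:10), "fam")),
                 class = c("copy_number_matrix", "matrix", "array"))
  clades <- setNames(rep(c("A", "B", "C"), c(3, 3, 4)), paste0("s", 1:10))
  summ <- clade_summary(m, clades, "fam")
  # brute force per clade
  expect_equal(summ$mean, c(mean(c(13, 13, 14)), mean(c(12, 12)),
                            mean(c(11, 10, 11, 11))))
  expect_equal(summ$median, c(13L, 12L, 11L))
  expect_equal(summ$mode, c(13L, 12L, 11L))
  expect_equal(summ$n_missing, c(0L, 1L, 0L))
  # lower-middle median for even n; smallest mode among ties
  m2 <- structure(matrix(c(7L, 9L, 9L, 7L), ncol = 1,
                         dimnames = list(paste0("t", 1:4), "fam")),
                  class = c("copy_number_matrix", "matrix", "array"))
  s2 <- clade_summary(m2, setNames(rep("X", 4), paste0("t", 1:4)), "fam")
  expect_equal(s2$median, 7L)
  expect_equal(s2$mode, 7L)
  # invariance to row order
  perm <- sample(rownames(m))
  expect_equal(clade_summary(m[perm, , drop = FALSE], clades, "fam"), summ)
  # empty clade reports absent statistics
  s3 <- clade_summary(m, c(clades, z1 = "D"), "fam")
  expect_true(is.na(s3$mean[s3$clade == "D"]))
  expect_equal(s3$n_species[s3$clade == "D"], 0L)
})

test_that("outlier flagging reports deviations from the clade mode", {
  m <- structure(matrix(c(19L, 19L, 16L, 19L, 4L, 4L, 4L), ncol = 1,
                        dimnames = list(paste0("s", 1:7), "fam")),
                 class = c("copy_number_matrix", "matrix", "array"))
  clades <- setNames(rep(c("C", "A"), c(4, 3)), paste0("s", 1:7))
  out <- flag_outliers(m, clades, "fam")
  expect_equal(out$species, "s3")
  expect_equal(out$count, 16L)
  expect_equal(out$clade_mode, 19L)
  # all equal within clades: nothing flagged
  expect_equal(nrow(flag_outliers(m[5:7, , drop = FALSE],
                                  clades[5:7], "fam")), 0)
  # stable under clade relabelling
  relab <- setNames(c(Z = "Q", C = "Z", A = "P")[clades], names(clades))
  out2 <- flag_outliers(m, relab, "fam")
  expect_equal(out2$species, out$species)
  expect_equal(out2$count, out$count)
})

test_that("copy-loss scanning pinpoints planted substitutions", {
  truth <- generate_precursor(precursor_spec(3, "QWPSA", "KR", id = "ref",
                                             seed = 8))
  ann <- annotate_precursor(truth$record)
  # identical sequences: nothing to report
  msa_same <- list(seq_record("ref", truth$protein),
                   seq_record("other", truth$protein))
  expect_equal(nrow(explain_copy_loss(msa_same, "ref", ann)), 0)

  # destroy site 2 in an ortholog: both basics reported as cleavage knockouts
  ko <- knockout_cleavage(truth, 2L, "basic_to_X", seed = 5)
  msa <- list(seq_record("ref", truth$protein),
              seq_record("ortho", ko$protein))
  kn <- explain_copy_loss(msa, "ref", ann)
  expect_equal(nrow(kn), 2)
  expect_equal(unique(kn$role), "cleavage_basic")
  expect_equal(kn$alignment_column, ko$knockout$pos)
  expect_equal(kn$observed_residue, ko$knockout$obs)
  expect_true(all(kn$reference_residue %in% c("K", "R")))
  stat <- summarize_site_knockouts(kn, ann)
  expect_equal(stat$status, "destroyed")

  # single basic substitution: a weakened, not destroyed, site
  chars <- strsplit(truth$protein, "")[[1]]
  chars[ann$sites$start[1] + 1L] <- "N"
  weak <- paste(chars, collapse = "")
  kn2 <- explain_copy_loss(list(seq_record("ref", truth$protein),
                                seq_record("w", weak)), "ref", ann)
  expect_equal(summarize_site_knockouts(kn2, ann)$status, "weakened")

  # donor glycine substitution: amidation knockout plus one fewer amide
  kog <- knockout_cleavage(truth, 1L, "glycine_to_X", seed = 6)
  kn3 <- explain_copy_loss(list(seq_record("ref", truth$protein),
                                seq_record("g", kog$protein)), "ref", ann)
  expect_equal(kn3$role, "amidation_glycine")
  expect_equal(sum(annotate_precursor(kog$record)$peptides$amidated),
               sum(ann$peptides$amidated) - 1L)

  # gap columns are reported with observed '-'
  gapped <- sub("KR", "--", truth$protein)  # first site gapped out
  kn4 <- explain_copy_loss(list(seq_record("ref", truth$protein),
                                seq_record("gap", gapped, allow_gaps = TRUE)),
                           "ref", ann)
  expect_true(all(c("-") %in% kn4$observed_residue))

  expect_error(explain_copy_loss(msa, "absent", ann),
               class = "npmine_missing_reference")
  expect_error(explain_copy_loss(list(seq_record("ref", "MKWNDTE")), "ref", ann),
               class = "npmine_inconsistent")
})

test_that("clade dataset knockouts reconcile counts with reported site losses", {
  ds <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = c("A", "B"), n_species = c(3L, 3L),
                        base_copies = c(5L, 5L)),
    base_spec = precursor_spec(1, "QWPSA", "KR", id = "f", seed = 21),
    family = "fam",
    knockouts = data.frame(clade = "A", site_index = 2L, mode = "basic_to_X"),
    seed = 21))
  ref_ann <- annotate_precursor(ds$records[[ds$reference_species]])
  kn <- explain_copy_loss(ds$alignment, ds$reference_species, ref_ann)
  # exactly the planted substitutions are reported
  expect_equal(nrow(kn), nrow(ds$knockouts))
  expect_equal(sort(kn$alignment_column), sort(ds$knockouts$alignment_column))
  expect_equal(kn$observed_residue[order(kn$alignment_column)],
               ds$knockouts$observed_residue[order(ds$knockouts$alignment_column)])
  # knockout consistency: destroyed sites equal the copy-count deficit
  stat <- summarize_site_knockouts(kn, ref_ann)
  ko_species <- ds$species$species[ds$species$role == "knockout"]
  expect_equal(sum(stat$species == ko_species & stat$status == "destroyed"),
               5L - ds$species$expected_count[ds$species$species == ko_species])
})
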