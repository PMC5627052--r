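test_that("alignment readers parse FASTA and Clustal dialects", {
  f <- withr::local_tempfile()
  writeLines(c(">a", "MKW-ND", ">b", "MKWPN-"), f)
  aln <- read_alignment(f, "fasta")
  expect_length(aln, 2)
  expect_equal(aln$a$residues, "MKW-ND")

  writeLines(c(">a", "MKW-ND", ">b", "MKWPN"), f)
  expect_error(read_alignment(f, "fasta"), class = "npmine_ragged_alignment")

  # clustal with coordinate suffixes, a conservation line and a second block
  writeLines(c("CLUSTAL W (1.83) multiple sequence alignment", "",
               "seq1   MKW-ND 5", "seq2   MKWPN- 5", "       ***  .", "",
               "seq1   STY 8", "seq2   STY 8"), f)
  cl <- read_alignment(f, "clustal")
  expect_equal(cl$seq1$residues, "MKW-NDSTY")
  expect_equal(cl$seq2$residues, "MKWPN-STY")

  writeLines(c("not a clustal file", "seq1 MKW"), f)
  expect_error(read_alignment(f, "clustal"), class = "npmine_bad_format")
})

test_that("single-row alignments class exactly like direct annotation", {
  truth <- generate_precursor(precursor_spec(3, "QWPSA", "KR", id = "one",
                                             seed = 51))
  aln <- annotate_alignment(list(seq_record("one", truth$protein,
                                            allow_gaps = TRUE)))
  direct <- npmine:::residue_classes(annotate_precursor(truth$record))
  expect_equal(unname(aln$cell_classes[1, ]), direct)
  # signal cells blue, site cells green, donors pink
  expect_equal(sum(aln$cell_classes == "signal"), truth$signal_boundary)
  expect_equal(sum(aln$cell_classes == "cleavage"),
               sum(nchar(truth$expected_sites$motif)))
  expect_equal(sum(aln$cell_classes == "amide_glycine"),
               sum(truth$expected_peptides$amidated))
})

test_that("gap insertion shifts classes without changing their multiset", {
  ds <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = "A", n_species = 3L, base_copies = 4L),
    base_spec = precursor_spec(1, "QWPSA", "KR", id = "x", seed = 52),
    family = "x", seed = 52))
  aln <- annotate_alignment(ds$alignment)
  # insert a gap column at position 10 in every row
  shifted_rows <- lapply(ds$alignment, function(r)
    seq_record(r$id, paste0(substr(r$residues, 1, 9), "-",
                            substr(r$residues, 10, nchar(r$residues))),
               allow_gaps = TRUE))
  aln2 <- annotate_alignment(shifted_rows)
  expect_equal(aln2$cell_classes[, 10], setNames(rep("gap", 3),
                                                 rownames(aln2$cell_classes)))
  expect_equal(aln2$cell_classes[, 1:9], aln$cell_classes[, 1:9])
  expect_equal(aln2$cell_classes[, 11:ncol(aln2$cell_classes)],
               aln$cell_classes[, 10:ncol(aln$cell_classes)])
  # per-row class multisets are invariant under arbitrary gap patterns
  for (k in seq_along(ds$alignment)) {
    a <- table(aln$cell_classes[k, ][aln$cell_classes[k, ] != "gap"])
    b <- table(aln2$cell_classes[k, ][aln2$cell_classes[k, ] != "gap"])
    expect_equal(a, b)
  }
})

test_that("cleavage-class runs correspond one-to-one with cleavage sites", {
  ds <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = "A", n_species = 2L, base_copies = 5L),
    base_spec = precursor_spec(1, "NSAFDSGW", "mixed", id = "y", seed = 53),
    family = "y", seed = 53))
  aln <- annotate_alignment(ds$alignment)
  for (k in seq_along(ds$alignment)) {
    ann <- aln$annotations[[k]]
    runs <- rle(aln$cell_classes[k, ])
    expect_equal(sum(runs$values == "cleavage"), nrow(ann$sites))
  }
})

test_that("acidic spacers are classed for display without affecting counting", {
  truth <- generate_precursor(precursor_spec(3, "QWPSA", "KR",
                                             spacer = "EEDDEE", id = "sp",
                                             seed = 54))
  ann <- annotate_precursor(truth$record)
  cls <- npmine:::residue_classes(ann)
  spacer_rows <- ann$peptides[ann$peptides$sequence == "EEDDEE", ]
  expect_equal(nrow(spacer_rows), 2)
  expect_true(all(cls[(spacer_rows$start[1] + 1):spacer_rows$end[1]] == "spacer"))
  expect_equal(count_peptide_copies(ann, "len=5 & pyroQ & amide"), 3)
})

test_that("renderers preserve content across formats", {
  ds <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = "A", n_species = 2L, base_copies = 3L),
    base_spec = precursor_spec(1, "QWPSA", "KR", id = "r", seed = 55),
    family = "r", seed = 55))
  aln <- annotate_alignment(ds$alignment)

  txt <- render_annotated(aln, "tsv")
  expect_identical(parse_class_grid(txt), aln$cell_classes)

  html <- render_annotated(aln, "html")
  runs_total <- sum(vapply(seq_len(nrow(aln$cell_classes)), function(k)
    length(rle(aln$cell_classes[k, ])$lengths), integer(1)))
  expect_equal(lengths(regmatches(html, gregexpr("<span style=", html))),
               runs_total)

  ansi <- render_annotated(aln, "ansi")
  plain <- strip_ansi(ansi)
  for (r in aln$records)
    expect_true(grepl(r$residues, plain, fixed = TRUE))

  expect_error(render_annotated(aln, "pdf"), class = "npmine_bad_format")
})

test_that("curation overlays are explicit and validated", {
  ds <- generate_clade_dataset(clade_dataset_spec(
    clades = data.frame(label = "A", n_species = 2L, base_copies = 2L),
    base_spec = precursor_spec(1, "QWPSA", "KR", id = "o", seed = 56),
    family = "o", seed = 56))
  aln <- annotate_alignment(ds$alignment)
  id1 <- rownames(aln$cell_classes)[1]
  over <- data.frame(id = id1, column = 0L, class = "peptide")
  out <- apply_overlay(aln, over)
  expect_equal(unname(out$cell_classes[id1, 1]), "peptide")
  expect_error(apply_overlay(aln, data.frame(id = id1, column = 0L,
                                             class = "purple")),
               class = "npmine_bad_format")
  expect_error(apply_overlay(aln, data.frame(id = "nope", column = 0L,
                                             class = "signal")),
               class = "npmine_missing_reference")
  # overlays round-trip through TSV
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(over, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_overlay_tsv(f), over)
})
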