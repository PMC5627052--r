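#' Read a multiple alignment
#'
#' Aligned FASTA or Clustal. Clustal blocks may carry trailing cumulative
#' coordinates, which are stripped; conservation lines are ignored; `.`
#' gaps are normalised to `-`. All rows must have equal length.
#'
#' @param path Alignment file.
#' @param format `"fasta"` or `"clustal"`.
#' @param alphabet Residue alphabet of the rows.
#' @return List of gapped [seq_record]s.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal"),
                           alphabet = "aa") {
  format <- match.arg(format)
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
      np_stop("npmine_empty_input", sprintf("no records in %s", path))
    ids <- sub("\\s.*$", "", names(set))
    seqs <- toupper(as.character(set))
  } else {
    parsed <- parse_clustal(path)
    ids <- parsed$ids; seqs <- toupper(parsed$seqs)
  }
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(unique(nchar(seqs))) != 1L)
    np_stop("npmine_ragged_alignment",
            sprintf("alignment rows have unequal lengths: %s",
                    paste(unique(nchar(seqs)), collapse = ", ")))
  mapply(function(id, s) seq_record(id, s, alphabet = alphabet,
                                    allow_gaps = TRUE),
         ids, seqs, SIMPLIFY = FALSE)
}

parse_clustal <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^(CLUSTAL|MUSCLE)", lines[1], ignore.case = TRUE))
    np_stop("npmine_bad_format", "missing CLUSTAL header line")
  acc <- list()
  order <- character()
  for (ln in lines[-1]) {
    if (!nzchar(trimws(ln))) next
    if (grepl("^\\s", ln)) next                  # conservation line
    m <- regmatches(ln, regexec("^(\\S+)\\s+([A-Za-z.*-]+)(\\s+\\d+)?\\s*$", ln))[[1]]
    if (!length(m))
      np_stop("npmine_bad_format", sprintf("unparseable clustal line: '%s'", ln))
    id <- m[2]; chunk <- m[3]
    if (!id %in% order) order <- c(order, id)
    acc[[id]] <- paste0(acc[[id]] %||% "", chunk)
  }
  if (!length(order))
    np_stop("npmine_empty_input", sprintf("no sequences in %s", path))
  list(ids = order, seqs = unlist(acc[order], use.names = FALSE))
}

aln_classes <- c("signal", "peptide", "cleavage", "amide_glycine", "spacer", "gap")

#' Annotate a multiple alignment with precursor feature classes
#'
#' Every row is ungapped, annotated with [annotate_precursor()], and each
#' residue assigned one of the classes `signal`, `peptide`, `cleavage`,
#' `amide_glycine` or `spacer`; the classes are then projected back
#' through the row's gap structure (`gap` for gap cells). Classes are
#' per-sequence, not per-column consensus: each row is coloured by its own
#' features. A peptide segment whose acidic (D/E) fraction exceeds
#' `spacer_max_acid_fraction` is classed `spacer` for display; its
#' amidation donor glycine, if any, stays `amide_glycine`.
#'
#' @param aln List of gapped [seq_record]s (see [read_alignment()]).
#' @param config An [annotation_config].
#' @return Object of class `annotated_alignment`: `records`,
#'   `cell_classes` (rows x columns character matrix), `annotations`.
#' @export
annotate_alignment <- function(aln, config = annotation_config()) {
  widths <- vapply(aln, function(r) nchar(r$residues), integer(1))
  if (length(unique(widths)) != 1L)
    np_stop("npmine_ragged_alignment", "alignment rows have unequal lengths")
  ncol <- widths[1]
  ids <- unname(vapply(aln, `[[`, character(1), "id"))
  grid <- matrix("gap", nrow = length(aln), ncol = ncol,
                 dimnames = list(ids, NULL))
  anns <- vector("list", length(aln))
  for (k in seq_along(aln)) {
    row <- aln[[k]]$residues
    ungapped <- gsub("-", "", row, fixed = TRUE)
    ann <- annotate_precursor(seq_record(aln[[k]]$id, ungapped), config)
    anns[[k]] <- ann
    cls <- residue_classes(ann, config)
    chars <- strsplit(row, "", fixed = TRUE)[[1]]
    grid[k, chars != "-"] <- cls
  }
  structure(list(records = aln, cell_classes = grid, annotations = anns),
            class = "annotated_alignment")
}

# Per-residue class vector for an ungapped annotated precursor.
residue_classes <- function(ann, config = annotation_config()) {
  n <- nchar(ann$record$residues)
  cls <- rep("peptide", n)
  if (isTRUE(ann$signal$present) && ann$signal$cleavage_pos > 0L)
    cls[seq_len(ann$signal$cleavage_pos)] <- "signal"
  if (nrow(ann$sites))
    for (k in seq_len(nrow(ann$sites)))
      cls[seq.int(ann$sites$start[k] + 1L, ann$sites$end[k])] <- "cleavage"
  if (nrow(ann$peptides)) {
    for (k in seq_len(nrow(ann$peptides))) {
      p <- ann$peptides[k, ]
      idx <- seq.int(p$start + 1L, p$end)
      seqp <- p$sequence
      if (nzchar(seqp)) {
        acid <- sum(strsplit(seqp, "", fixed = TRUE)[[1]] %in% c("D", "E")) /
          nchar(seqp)
        if (acid > config$spacer_max_acid_fraction) cls[idx] <- "spacer"
      }
      if (p$amidated) cls[p$end] <- "amide_glycine"
    }
  }
  cls
}

#' Apply a manual curation overlay to an annotated alignment
#'
#' Curated colour adjustments are supported only as an explicit override
#' table — never silent edits — so the otherwise manual step stays
#' reproducible.
#'
#' @param aln An `annotated_alignment`.
#' @param overlay `data.frame` with columns `id`, `column` (0-based) and
#'   `class` (one of the alignment classes).
#' @return The modified `annotated_alignment`.
#' @export
apply_overlay <- function(aln, overlay) {
  stopifnot(all(c("id", "column", "class") %in% names(overlay)))
  if (!all(overlay$class %in% aln_classes))
    np_stop("npmine_bad_format",
            sprintf("unknown class in overlay: %s",
                    paste(setdiff(overlay$class, aln_classes), collapse = ", ")))
  for (k in seq_len(nrow(overlay))) {
    if (!overlay$id[k] %in% rownames(aln$cell_classes))
      np_stop("npmine_missing_reference",
              sprintf("overlay row id '%s' not in alignment", overlay$id[k]))
    aln$cell_classes[overlay$id[k], overlay$column[k] + 1L] <- overlay$class[k]
  }
  aln
}

#' Read a cell-class overlay TSV
#'
#' @param path TSV with columns `id`, `column`, `class`.
#' @return `data.frame` usable with [apply_overlay()].
#' @export
read_overlay_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

# Figure palette: signal blue, mature peptide red, cleavage green,
# amidation glycine pink.
aln_palette_html <- c(signal = "#2C5FD8", peptide = "#CC2222",
                      cleavage = "#1D9E44", amide_glycine = "#E8649C",
                      spacer = "#888888", gap = "#BBBBBB")
aln_palette_ansi <- c(signal = "34", peptide = "31", cleavage = "32",
                      amide_glycine = "35", spacer = "90", gap = "0")

#' Render an annotated alignment
#'
#' `"tsv"` emits the class grid verbatim (round-trips through
#' [parse_class_grid()]); `"html"` and `"ansi"` colour the residues with
#' the conventional palette (signal blue, peptide red, cleavage green,
#' amidation glycine pink), one styled span per contiguous same-class run.
#'
#' @param aln An `annotated_alignment`.
#' @param format `"html"`, `"ansi"` or `"tsv"`.
#' @return Character scalar (the document).
#' @export
render_annotated <- function(aln, format = c("tsv", "html", "ansi")) {
  if (length(format) == 1L && !format %in% c("tsv", "html", "ansi"))
    np_stop("npmine_bad_format", sprintf("unknown render format '%s'", format))
  format <- match.arg(format)
  grid <- aln$cell_classes
  ids <- rownames(grid)
  seqs <- vapply(aln$records, `[[`, character(1), "residues")
  switch(format,
    tsv = {
      lines <- vapply(seq_along(ids), function(k)
        paste(c(ids[k], grid[k, ]), collapse = "\t"), character(1))
      paste(lines, collapse = "\n")
    },
    html = {
      body <- vapply(seq_along(ids), function(k) {
        spans <- class_runs(grid[k, ], seqs[k])
        paste0("<div class=\"aln-row\"><span class=\"aln-id\">",
               ids[k], "</span> ",
               paste(sprintf("<span style=\"color:%s\">%s</span>",
                             aln_palette_html[spans$class], spans$text),
                     collapse = ""),
               "</div>")
      }, character(1))
      paste(c("<pre class=\"npmine-alignment\">", body, "</pre>"),
            collapse = "\n")
    },
    ansi = {
      body <- vapply(seq_along(ids), function(k) {
        spans <- class_runs(grid[k, ], seqs[k])
        paste0(format(ids[k], width = max(nchar(ids)) + 1L),
               paste(sprintf("\033[%sm%s\033[0m",
                             aln_palette_ansi[spans$class], spans$text),
                     collapse = ""))
      }, character(1))
      paste(body, collapse = "\n")
    })
}

class_runs <- function(classes, seq) {
  r <- rle(classes)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(class = r$values,
             text = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

#' @rdname render_annotated
#' @param text A TSV class grid produced by `render_annotated(format="tsv")`.
#' @return `parse_class_grid()`: the class-grid character matrix.
#' @export
parse_class_grid <- function(text) {
  rows <- strsplit(strsplit(text, "\n", fixed = TRUE)[[1]], "\t", fixed = TRUE)
  ids <- vapply(rows, `[[`, character(1), 1L)
  grid <- do.call(rbind, lapply(rows, function(r) r[-1]))
  rownames(grid) <- ids
  grid
}

#' Strip ANSI colour codes
#'
#' @param x Character vector.
#' @return `x` with escape sequences removed.
#' @export
strip_ansi <- function(x) gsub("\033\\[[0-9;]*m", "", x)
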