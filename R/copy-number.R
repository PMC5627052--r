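#' Build a species-by-family copy-number matrix
#'
#' One cell per (species, family): the number of mature peptides of the
#' family's precursor matching the family's predicate. A cell is `NA`
#' (missing — distinct from zero) when no annotation is available or the
#' annotation is partial: partial precursors may be truncated, so their
#' copy counts are not comparable.
#'
#' @param entries List of entries, each a list with `species`, `family` and
#'   `annotation` (a `precursor_annotation`).
#' @param predicates Named character vector or list of predicates, one per
#'   family (see [parse_predicate()]).
#' @return Integer matrix (species rows, family columns, `NA` = missing)
#'   of class `copy_number_matrix`.
#' @export
build_copy_matrix <- function(entries, predicates) {
  stopifnot(length(entries) > 0)
  species <- unique(vapply(entries, `[[`, character(1), "species"))
  fams_seen <- unique(vapply(entries, `[[`, character(1), "family"))
  families <- union(names(predicates)[names(predicates) %in% fams_seen],
                    fams_seen)
  m <- matrix(NA_integer_, nrow = length(species), ncol = length(families),
              dimnames = list(species, families))
  for (e in entries) {
    if (!e$family %in% names(predicates))
      np_stop("npmine_bad_config",
              sprintf("no predicate for family '%s'", e$family))
    val <- if (isTRUE(e$annotation$partial)) NA_integer_ else
      as.integer(count_peptide_copies(e$annotation, predicates[[e$family]]))
    prev <- m[e$species, e$family]
    if (!is.na(prev) && !is.na(val) && prev != val)
      np_stop("npmine_ambiguous_input",
              sprintf("conflicting counts for (%s, %s): %d vs %d",
                      e$species, e$family, prev, val))
    if (is.na(prev)) m[e$species, e$family] <- val
  }
  structure(m, class = c("copy_number_matrix", class(m)))
}

#' Write / read a copy-number matrix as TSV
#'
#' Species rows, family columns, explicit `NA` for missing cells; the
#' first column holds the species label. Round-trips exactly.
#'
#' @param matrix A `copy_number_matrix` (or plain integer matrix).
#' @param path File path.
#' @return The path / the matrix.
#' @export
write_copy_matrix <- function(matrix, path) {
  df <- data.frame(species = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_copy_matrix
#' @export
read_copy_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  structure(m, class = c("copy_number_matrix", class(m)))
}

normalize_clades <- function(clades) {
  if (is.data.frame(clades)) {
    stopifnot(ncol(clades) >= 2)
    setNames(as.character(clades[[2]]), as.character(clades[[1]]))
  } else {
    stopifnot(!is.null(names(clades)))
    setNames(as.character(clades), names(clades))
  }
}

#' Read a species-to-clade table (2-column TSV)
#'
#' @param path TSV with species and clade columns.
#' @return Named character vector species -> clade.
#' @export
read_clade_table <- function(path) {
  normalize_clades(utils::read.delim(path, stringsAsFactors = FALSE))
}

# Lower-middle median: for even n the lower of the two middle values, so
# statistics over small integer counts stay integers.
median_lower <- function(x) {
  x <- sort(x)
  x[floor((length(x) + 1) / 2)]
}

# Most frequent value; smallest among ties.
mode_smallest <- function(x) {
  tab <- table(x)
  as.integer(min(as.integer(names(tab)[tab == max(tab)])))
}

#' Per-clade summary of a family's copy numbers
#'
#' Mean, median (lower middle for even n, keeping integer counts integer),
#' mode (smallest among ties) over non-missing cells, plus the number of
#' species with and without counts. A clade with no non-missing cell gets
#' `NA` statistics (absent, not zero).
#'
#' @param matrix A `copy_number_matrix`.
#' @param clades Species-to-clade assignment: named vector or 2-column
#'   data frame.
#' @param family Family (column) label.
#' @return `data.frame` with one row per clade (clades sorted by label):
#'   `clade`, `mean`, `median`, `mode`, `n_species`, `n_missing`.
#' @export
clade_summary <- function(matrix, clades, family) {
  if (!family %in% colnames(matrix))
    np_stop("npmine_bad_index", sprintf("family '%s' not in matrix", family))
  clades <- normalize_clades(clades)
  labs <- sort(unique(clades))
  rows <- lapply(labs, function(cl) {
    sp <- intersect(names(clades)[clades == cl], rownames(matrix))
    vals <- matrix[sp, family]
    ok <- vals[!is.na(vals)]
    if (length(ok))
      data.frame(clade = cl, mean = mean(ok), median = median_lower(ok),
                 mode = mode_smallest(ok), n_species = length(ok),
                 n_missing = sum(is.na(vals)), stringsAsFactors = FALSE)
    else
      data.frame(clade = cl, mean = NA_real_, median = NA_integer_,
                 mode = NA_integer_, n_species = 0L,
                 n_missing = sum(is.na(vals)), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flag species deviating from their clade's modal copy number
#'
#' On near-constant small-integer counts the clade mode is the natural
#' reference; a species is an outlier when its (non-missing) count differs
#' from the mode of its clade.
#'
#' @inheritParams clade_summary
#' @return `data.frame` with columns `species`, `count`, `clade`,
#'   `clade_mode`; zero rows when every count equals its clade mode.
#' @export
flag_outliers <- function(matrix, clades, family) {
  if (!family %in% colnames(matrix))
    np_stop("npmine_bad_index", sprintf("family '%s' not in matrix", family))
  clades <- normalize_clades(clades)
  rows <- list()
  for (cl in sort(unique(clades))) {
    sp <- intersect(names(clades)[clades == cl], rownames(matrix))
    vals <- matrix[sp, family]
    ok <- !is.na(vals)
    if (!any(ok)) next
    md <- mode_smallest(vals[ok])
    dev <- sp[ok & vals != md]
    if (length(dev))
      rows[[length(rows) + 1L]] <- data.frame(
        species = dev, count = as.integer(matrix[dev, family]), clade = cl,
        clade_mode = md, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(), count = integer(), clade = character(),
               clade_mode = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Explain copy losses by cleavage-site / amidation-glycine substitutions
#'
#' Maps the reference precursor's functional residues — every basic
#' residue of every cleavage site, and the amidation donor glycine of
#' every amidated peptide — to alignment columns, then reports, for every
#' other sequence, the columns where the residue leaves the allowed set
#' ({K,R} for cleavage basics, {G} for donors). Gap columns are reported
#' with observed residue `-`.
#'
#' @param msa List of gapped [seq_record]s (an alignment).
#' @param reference_species Id of the reference row.
#' @param reference_annotation `precursor_annotation` of the ungapped
#'   reference sequence.
#' @return `data.frame` with columns `species`, `alignment_column`
#'   (0-based), `reference_residue`, `observed_residue`, `role`
#'   (`cleavage_basic` / `amidation_glycine`) and `site_index` (which
#'   cleavage site, or `NA` for donors).
#' @export
explain_copy_loss <- function(msa, reference_species, reference_annotation) {
  ids <- vapply(msa, `[[`, character(1), "id")
  ref_i <- match(reference_species, ids)
  if (is.na(ref_i))
    np_stop("npmine_missing_reference",
            sprintf("reference '%s' not in alignment", reference_species))
  ref_row <- msa[[ref_i]]$residues
  ungapped <- gsub("-", "", ref_row, fixed = TRUE)
  if (!identical(ungapped, reference_annotation$record$residues))
    np_stop("npmine_inconsistent",
            "reference annotation does not match the ungapped reference row")
  # ungapped position (0-based) -> alignment column (0-based)
  rc <- strsplit(ref_row, "", fixed = TRUE)[[1]]
  col_of <- which(rc != "-") - 1L
  fun <- functional_positions(reference_annotation)
  if (!nrow(fun))
    return(empty_knockouts())
  fun$alignment_column <- col_of[fun$pos + 1L]
  rows <- list()
  for (k in seq_along(msa)) {
    if (k == ref_i) next
    chars <- strsplit(msa[[k]]$residues, "", fixed = TRUE)[[1]]
    if (length(chars) != length(rc))
      np_stop("npmine_ragged_alignment", "alignment rows differ in length")
    for (r in seq_len(nrow(fun))) {
      obs <- chars[fun$alignment_column[r] + 1L]
      allowed <- if (fun$role[r] == "cleavage_basic") c("K", "R") else "G"
      if (!obs %in% allowed)
        rows[[length(rows) + 1L]] <- data.frame(
          species = ids[k], alignment_column = fun$alignment_column[r],
          reference_residue = fun$ref[r], observed_residue = obs,
          role = fun$role[r], site_index = fun$site_index[r],
          stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_knockouts()
  rownames(out) <- NULL
  out
}

empty_knockouts <- function() {
  data.frame(species = character(), alignment_column = integer(),
             reference_residue = character(), observed_residue = character(),
             role = character(), site_index = integer(),
             stringsAsFactors = FALSE)
}

functional_positions <- function(ann) {
  res <- ann$record$residues
  rows <- list()
  if (nrow(ann$sites)) {
    for (k in seq_len(nrow(ann$sites))) {
      ps <- seq.int(ann$sites$start[k], ann$sites$end[k] - 1L)
      rows[[length(rows) + 1L]] <- data.frame(
        pos = ps, ref = substring(res, ps + 1L, ps + 1L),
        role = "cleavage_basic", site_index = k, stringsAsFactors = FALSE)
    }
  }
  amid <- ann$peptides[ann$peptides$amidated, , drop = FALSE]
  if (nrow(amid))
    rows[[length(rows) + 1L]] <- data.frame(
      pos = amid$end - 1L, ref = "G", role = "amidation_glycine",
      site_index = NA_integer_, stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(pos = integer(), ref = character(), role = character(),
                      site_index = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$pos), , drop = FALSE]
}

#' Classify knockouts per site as destroyed or weakened
#'
#' A dibasic/polybasic site with every basic residue substituted in a
#' species is destroyed; with at least one basic left it is only weakened
#' (still cleavable when monobasic sites are enabled). The distinction
#' changes the biological conclusion, so it is made explicit.
#'
#' @param knockouts Output of [explain_copy_loss()].
#' @param reference_annotation The reference `precursor_annotation`.
#' @return `data.frame` with columns `species`, `site_index`, `n_hit`,
#'   `site_size`, `status` (`destroyed`/`weakened`).
#' @export
summarize_site_knockouts <- function(knockouts, reference_annotation) {
  kb <- knockouts[knockouts$role == "cleavage_basic", , drop = FALSE]
  if (!nrow(kb))
    return(data.frame(species = character(), site_index = integer(),
                      n_hit = integer(), site_size = integer(),
                      status = character(), stringsAsFactors = FALSE))
  sizes <- nchar(reference_annotation$sites$motif)
  agg <- stats::aggregate(list(n_hit = kb$alignment_column),
                          by = list(species = kb$species,
                                    site_index = kb$site_index),
                          FUN = length)
  agg$site_size <- sizes[agg$site_index]
  agg$status <- ifelse(agg$n_hit >= agg$site_size, "destroyed", "weakened")
  agg[order(agg$species, agg$site_index), , drop = FALSE]
}
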