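#' Scoring schemes for local protein alignment
#'
#' Bundles a substitution matrix with affine gap penalties and ungapped
#' Karlin-Altschul parameters. The first residue of a gap costs `gap_open`
#' and each further residue `gap_extend` (both negative, `gap_open <=
#' gap_extend`). The Karlin-Altschul pair `(ka_lambda, ka_k)` parameterises
#' the E-value `E = k * m * n * exp(-lambda * S)`; defaults are the
#' conventional ungapped constants for each matrix.
#'
#' @param matrix_name One of `"BLOSUM62"`, `"BLOSUM45"` (matrices shipped
#'   with Biostrings).
#' @param gap_open,gap_extend Negative integers.
#' @param ka_lambda,ka_k Positive reals; per-matrix defaults when `NULL`.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = c("BLOSUM62", "BLOSUM45"),
                           gap_open = -11L, gap_extend = -1L,
                           ka_lambda = NULL, ka_k = NULL) {
  matrix_name <- match.arg(matrix_name)
  defaults <- list(BLOSUM62 = c(lambda = 0.3176, k = 0.134),
                   BLOSUM45 = c(lambda = 0.2291, k = 0.0924))
  ka_lambda <- ka_lambda %||% unname(defaults[[matrix_name]]["lambda"])
  ka_k <- ka_k %||% unname(defaults[[matrix_name]]["k"])
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  if (!(gap_open <= gap_extend && gap_extend < 0L))
    np_stop("npmine_bad_scheme", "need gap_open <= gap_extend < 0")
  if (!(ka_lambda > 0 && ka_k > 0))
    np_stop("npmine_bad_scheme", "Karlin-Altschul parameters must be positive")
  structure(list(matrix_name = matrix_name,
                 matrix = substitution_matrix(matrix_name),
                 gap_open = gap_open, gap_extend = gap_extend,
                 ka_lambda = ka_lambda, ka_k = ka_k),
            class = "scoring_scheme")
}

substitution_matrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- get(name, envir = e)
  storage.mode(m) <- "integer"
  m
}

# Map residues absent from the substitution matrix (ambiguity codes the
# matrix lacks) onto 'X' so scoring stays defined.
matrix_safe <- function(s, mat) {
  known <- paste(rownames(mat), collapse = "")
  gsub(sprintf("[^%s]", gsub("([*])", "\\\\\\1", known)), "X", s)
}

#' Karlin-Altschul E-value
#'
#' `E = ka_k * m * n * exp(-ka_lambda * score)`: the expected number of
#' chance local alignments of at least `score` between a query of length
#' `m` and a database of length `n`. Strictly decreasing in `score`.
#'
#' @param score Non-negative alignment score.
#' @param query_len,db_len Positive lengths (aa).
#' @param scheme A [scoring_scheme].
#' @return Positive numeric E-value.
#' @export
evalue <- function(score, query_len, db_len, scheme) {
  stopifnot(score >= 0, query_len > 0, db_len > 0)
  scheme$ka_k * query_len * db_len * exp(-scheme$ka_lambda * score)
}

#' Best local alignment of two protein sequences
#'
#' Affine-gap Smith-Waterman optimum with a deterministic traceback:
#' on equal scores the move preference is diagonal > up > left, and the
#' traceback starts from the earliest maximal cell in row-major order.
#'
#' @param a,b Amino-acid strings (no gaps).
#' @param scheme A [scoring_scheme].
#' @return List with `score`, half-open 0-based `a_interval`/`b_interval`,
#'   and the gapped `a_aln`/`b_aln` strings.
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b))
    np_stop("npmine_empty_input", "smith_waterman needs two non-empty sequences")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    np_stop("npmine_bad_record", "gapped input to smith_waterman")
  mat <- scheme$matrix
  res <- sw_align_cpp(matrix_safe(a, mat), matrix_safe(b, mat), mat,
                      scheme$gap_open, scheme$gap_extend)
  # report alignment strings over the original residues
  res$a_aln <- regap(a, res$a_start, res$a_aln)
  res$b_aln <- regap(b, res$b_start, res$b_aln)
  list(score = res$score,
       a_interval = c(res$a_start, res$a_end),
       b_interval = c(res$b_start, res$b_end),
       a_aln = res$a_aln, b_aln = res$b_aln)
}

regap <- function(orig, start0, gapped) {
  chars <- strsplit(gapped, "", fixed = TRUE)[[1]]
  pos <- start0
  for (i in seq_along(chars)) {
    if (chars[i] != "-") {
      chars[i] <- substr(orig, pos + 1L, pos + 1L)
      pos <- pos + 1L
    }
  }
  paste(chars, collapse = "")
}

#' Rescore a gapped alignment pair column by column
#'
#' Independent of the DP: substitution scores on residue columns plus
#' affine penalties on gap runs. Used to verify that every reported
#' alignment reproduces its reported score.
#'
#' @param a_aln,b_aln Equal-length gapped strings.
#' @param scheme A [scoring_scheme].
#' @return Integer score.
#' @export
rescore_alignment <- function(a_aln, b_aln, scheme = scoring_scheme()) {
  ac <- strsplit(matrix_safe(a_aln, scheme$matrix), "", fixed = TRUE)[[1]]
  bc <- strsplit(matrix_safe(b_aln, scheme$matrix), "", fixed = TRUE)[[1]]
  stopifnot(length(ac) == length(bc))
  score <- 0L
  gap_a <- FALSE; gap_b <- FALSE  # track gap runs per string
  for (i in seq_along(ac)) {
    if (ac[i] == "-") {
      score <- score + if (gap_a) scheme$gap_extend else scheme$gap_open
      gap_a <- TRUE; gap_b <- FALSE
    } else if (bc[i] == "-") {
      score <- score + if (gap_b) scheme$gap_extend else scheme$gap_open
      gap_b <- TRUE; gap_a <- FALSE
    } else {
      score <- score + scheme$matrix[ac[i], bc[i]]
      gap_a <- FALSE; gap_b <- FALSE
    }
  }
  as.integer(score)
}
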