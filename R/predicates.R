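#' Peptide predicates
#'
#' A small composable language for classifying mature peptides, e.g.
#' `"len=4 & pyroQ & amide"` (TRH-like tetrapeptides) or
#' `"endswith=GW & amide"` (GW-motif peptides). Atoms:
#'
#' * `len=N` — processed sequence length equals `N` (the pQ residue counts;
#'   the removed amidation glycine does not);
#' * `startswith=S`, `endswith=S`, `contains=S` — literal matches on the
#'   processed sequence;
#' * `amide` — amidated; `pyroQ` — pyroglutamated;
#' * `minres=R:N` — at least `N` copies of residue `R`;
#' * `cterm` — matches C-terminal fragments; its presence anywhere in a
#'   predicate also opts fragments in to [count_peptide_copies()];
#' * `true` / `false` — constants.
#'
#' Combined with `&`/`AND`, `|`/`OR`, `!`/`NOT` and parentheses; `&` binds
#' tighter than `|`.
#'
#' @param text Predicate string.
#' @return An object of class `peptide_predicate`. `format()`/`as.character()`
#'   return the original text, so predicates round-trip through their
#'   serialisation.
#' @export
parse_predicate <- function(text) {
  toks <- predicate_tokens(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks; state$pos <- 1L; state$uses_cterm <- FALSE
  node <- parse_or(state)
  if (state$pos <= length(state$toks))
    np_stop("npmine_bad_predicate",
            sprintf("trailing input in predicate: '%s'",
                    paste(state$toks[state$pos:length(state$toks)], collapse = " ")))
  structure(node, class = "peptide_predicate", text = text,
            uses_cterm = state$uses_cterm)
}

as_peptide_predicate <- function(x) {
  if (inherits(x, "peptide_predicate")) x else parse_predicate(x)
}

#' @method format peptide_predicate
#' @export
format.peptide_predicate <- function(x, ...) attr(x, "text")

#' @method as.character peptide_predicate
#' @export
as.character.peptide_predicate <- function(x, ...) attr(x, "text")

#' @export
print.peptide_predicate <- function(x, ...) {
  cat(sprintf("<peptide_predicate: %s>\n", attr(x, "text")))
  invisible(x)
}

predicate_tokens <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  pat <- "\\(|\\)|&|\\||!|[A-Za-z]+=[A-Za-z0-9*:]+|[A-Za-z]+"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  leftover <- gsub(pat, "", text)
  if (grepl("\\S", leftover))
    np_stop("npmine_bad_predicate",
            sprintf("cannot tokenise predicate near '%s'", trimws(leftover)))
  toks
}

peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_
advance <- function(st) { st$pos <- st$pos + 1L; st$toks[st$pos - 1L] }

parse_or <- function(st) {
  left <- parse_and(st)
  while (!is.na(peek(st)) && peek(st) %in% c("|", "OR")) {
    advance(st)
    right <- parse_and(st)
    left <- list(op = "or", args = list(left, right))
  }
  left
}

parse_and <- function(st) {
  left <- parse_factor(st)
  while (!is.na(peek(st)) && peek(st) %in% c("&", "AND")) {
    advance(st)
    right <- parse_factor(st)
    left <- list(op = "and", args = list(left, right))
  }
  left
}

parse_factor <- function(st) {
  tok <- peek(st)
  if (is.na(tok))
    np_stop("npmine_bad_predicate", "predicate ended unexpectedly")
  if (tok %in% c("!", "NOT")) {
    advance(st)
    return(list(op = "not", args = list(parse_factor(st))))
  }
  if (tok == "(") {
    advance(st)
    node <- parse_or(st)
    if (!identical(peek(st), ")"))
      np_stop("npmine_bad_predicate", "unbalanced parentheses in predicate")
    advance(st)
    return(node)
  }
  advance(st)
  parse_atom(tok, st)
}

parse_atom <- function(tok, st) {
  if (grepl("=", tok, fixed = TRUE)) {
    key <- sub("=.*$", "", tok); val <- sub("^[^=]*=", "", tok)
    switch(key,
      len = list(op = "len", n = as.integer(val)),
      startswith = list(op = "startswith", s = toupper(val)),
      endswith = list(op = "endswith", s = toupper(val)),
      contains = list(op = "contains", s = toupper(val)),
      minres = {
        parts <- strsplit(val, ":", fixed = TRUE)[[1]]
        if (length(parts) != 2L)
          np_stop("npmine_bad_predicate", "minres needs the form minres=R:N")
        list(op = "minres", res = toupper(parts[1]), n = as.integer(parts[2]))
      },
      np_stop("npmine_bad_predicate", sprintf("unknown predicate atom '%s'", key)))
  } else {
    switch(toupper(tok),
      AMIDE = list(op = "amide"),
      PYROQ = list(op = "pyroq"),
      CTERM = { st$uses_cterm <- TRUE; list(op = "cterm") },
      "TRUE" = list(op = "true"),
      "FALSE" = list(op = "false"),
      np_stop("npmine_bad_predicate", sprintf("unknown predicate atom '%s'", tok)))
  }
}

#' Evaluate a predicate over a mature-peptide table
#'
#' @param predicate A `peptide_predicate` (or string).
#' @param peptides Mature-peptide `data.frame` as produced by
#'   [derive_mature_peptides()].
#' @return Logical vector, one element per peptide row.
#' @export
predicate_matches <- function(predicate, peptides) {
  predicate <- as_peptide_predicate(predicate)
  eval_node(unclass(predicate), peptides)
}

eval_node <- function(node, p) {
  switch(node$op,
    and = eval_node(node$args[[1]], p) & eval_node(node$args[[2]], p),
    or = eval_node(node$args[[1]], p) | eval_node(node$args[[2]], p),
    not = !eval_node(node$args[[1]], p),
    len = nchar(p$sequence) == node$n,
    startswith = startsWith(p$sequence, node$s),
    endswith = endsWith(p$sequence, node$s),
    contains = grepl(node$s, p$sequence, fixed = TRUE),
    amide = p$amidated,
    pyroq = p$pyroglutamated,
    cterm = p$c_terminal_fragment,
    minres = vapply(p$sequence, function(s)
      lengths(regmatches(s, gregexpr(node$res, s, fixed = TRUE))) >= node$n,
      logical(1), USE.NAMES = FALSE),
    true = rep(TRUE, nrow(p)),
    false = rep(FALSE, nrow(p)),
    np_stop("npmine_bad_predicate", sprintf("unknown node '%s'", node$op)))
}
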