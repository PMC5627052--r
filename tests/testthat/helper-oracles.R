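# Independent oracles and small generators used across the suite.

aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "", fixed = TRUE)[[1]]
nt4 <- c("A", "C", "G", "T")

random_aa <- function(n, alphabet = aa20) paste(sample(alphabet, n, TRUE), collapse = "")
random_nt <- function(n) paste(sample(nt4, n, TRUE), collapse = "")

# ---- exhaustive-path local alignment oracle ------------------------------
# Enumerates every monotone alignment path between every pair of substrings
# (no dynamic programming, no memoisation within a pair); affine costs with
# the first gap residue at `open`. A content-addressed cache makes repeated
# substring pairs cheap across test cases.
.oracle_cache <- new.env(parent = emptyenv())

oracle_global_score <- function(a, b, mat, open, ext) {
  key <- paste(a, b, sep = "\r")
  hit <- .oracle_cache[[key]]
  if (!is.null(hit)) return(hit)
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(ca); lb <- length(cb)
  rec <- function(i, j, last) {
    if (i == la && j == lb) return(0)
    best <- -Inf
    if (i < la && j < lb)
      best <- max(best, mat[ca[i + 1], cb[j + 1]] + rec(i + 1, j + 1, 0L))
    if (i < la)
      best <- max(best, (if (last == 1L) ext else open) + rec(i + 1, j, 1L))
    if (j < lb)
      best <- max(best, (if (last == 2L) ext else open) + rec(i, j + 1, 2L))
    best
  }
  val <- rec(0L, 0L, 0L)
  .oracle_cache[[key]] <- val
  val
}

oracle_local_score <- function(a, b, scheme = scoring_scheme()) {
  mat <- scheme$matrix
  la <- nchar(a); lb <- nchar(b)
  best <- 0
  for (i1 in seq_len(la)) for (i2 in i1:la) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(lb)) for (j2 in j1:lb) {
      sb <- substr(b, j1, j2)
      best <- max(best, oracle_global_score(sa, sb, mat,
                                            scheme$gap_open, scheme$gap_extend))
    }
  }
  as.integer(best)
}

# ---- brute-force ORF oracle ----------------------------------------------
# All maximal stop-free stretches of a frame translation; the unique one
# containing the hit interval.
oracle_orf <- function(aa, hit) {
  chars <- strsplit(aa, "", fixed = TRUE)[[1]]
  stops <- c(0L, which(chars == "*"), length(chars) + 1L)
  for (k in seq_len(length(stops) - 1L)) {
    s <- stops[k]; e <- stops[k + 1L] - 1L     # aa indices (s, e], 0-based [s, e)
    if (hit[1] >= s && hit[2] <= e)
      return(list(start = s, end = e,
                  protein = paste(chars[seq_len(e - s) + s], collapse = "")))
  }
  NULL
}

# ---- union-find component oracle -----------------------------------------
oracle_components <- function(edges, n) {
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_len(nrow(edges))) {
    ri <- find(edges$i[k]); rj <- find(edges$j[k])
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# ---- mutated-template families for clustering tests ----------------------
make_family <- function(n, prefix, len = 60L, rate = 0.1, seed = 1L) {
  set.seed(seed)
  template <- sample(aa20, len, TRUE)
  lapply(seq_len(n), function(k) {
    s <- template
    hit <- which(runif(len) < rate)
    for (p in hit) s[p] <- sample(setdiff(aa20, s[p]), 1L)
    seq_record(sprintf("%s_%02d", prefix, k), paste(s, collapse = ""))
  })
}

# flat annotation entries for a clade dataset
clade_entries <- function(ds, config = annotation_config()) {
  lapply(names(ds$records), function(s)
    list(species = s, family = ds$family,
         annotation = annotate_precursor(ds$records[[s]], config,
                                         family = ds$family)))
}
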