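#' All-vs-all similarity graph
#'
#' Smith-Waterman score and E-value-derived p-value for every unordered
#' pair of sequences. The p-value is `min(1, E)` with the pair's own
#' lengths as query/database size; it drives attraction in
#' [force_layout()] and thresholding in [components_at_cutoff()].
#' BLOSUM45 is the default matrix for clustering full precursors, which
#' are often highly divergent.
#'
#' @param seqs List of amino-acid [seq_record]s (>= 2).
#' @param scheme A [scoring_scheme]; default BLOSUM45.
#' @return `data.frame` with columns `i`, `j` (1-based node indices,
#'   `i < j`), `score`, `pvalue` — exactly `n(n-1)/2` rows.
#' @export
all_vs_all <- function(seqs, scheme = scoring_scheme("BLOSUM45")) {
  n <- length(seqs)
  if (n < 2L)
    np_stop("npmine_too_few", "all_vs_all needs at least two sequences")
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- smith_waterman(seqs[[i]]$residues, seqs[[j]]$residues, scheme)
      ev <- evalue(max(aln$score, 0L), nchar(seqs[[i]]$residues),
                   nchar(seqs[[j]]$residues), scheme)
      k <- k + 1L
      rows[[k]] <- data.frame(i = i, j = j, score = aln$score,
                              pvalue = min(1, ev))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Layout parameters for the force-directed embedding
#'
#' @param attract_weight,repulse_weight Force weights.
#' @param damping Velocity damping per iteration.
#' @param max_step Maximum per-node displacement per iteration.
#' @param pvalue_cutoff Only edges at or below this p-value attract.
#' @param eps Squared-distance floor in the repulsion term, preventing
#'   blow-up at coincident points.
#' @return Named list of parameters.
#' @export
layout_params <- function(attract_weight = 1, repulse_weight = 1,
                          damping = 0.9, max_step = 0.1,
                          pvalue_cutoff = 1e-3, eps = 1e-6) {
  list(attract_weight = attract_weight, repulse_weight = repulse_weight,
       damping = damping, max_step = max_step,
       pvalue_cutoff = pvalue_cutoff, eps = eps)
}

#' Seeded force-directed embedding of a similarity graph
#'
#' Nodes start uniformly in `[-1,1]^dims` from `seed`. Each iteration,
#' every node feels (i) attraction `a_ij * (x_j - x_i)` along each edge
#' with `pvalue <= pvalue_cutoff`, where `a_ij = min(-log10(pvalue), 20) *
#' attract_weight` (the cap prevents identical-pair singularities), and
#' (ii) repulsion `repulse_weight * (x_i - x_j) / max(||x_i - x_j||^2,
#' eps)` from every other node. Displacements are computed synchronously
#' from the current coordinates, damped, and clipped to `max_step`, so the
#' trajectory is a deterministic function of (edges, seed, params).
#'
#' @param edges Edge table from [all_vs_all()].
#' @param n_nodes Number of nodes.
#' @param dims 2 or 3.
#' @param seed Integer seed for the initial coordinates.
#' @param iterations Number of iterations (>= 1).
#' @param params See [layout_params()].
#' @return Object of class `layout_state`: `coordinates` (n x dims
#'   matrix), `iteration`, `seed`, `params`.
#' @export
force_layout <- function(edges, n_nodes, dims = 2L, seed = 1L,
                         iterations = 1000L, params = layout_params()) {
  stopifnot(iterations >= 1L, dims %in% c(2L, 3L), n_nodes >= 1L)
  X <- with_local_seed(seed, matrix(runif(n_nodes * dims, -1, 1),
                                    nrow = n_nodes, ncol = dims))
  force_layout_from(X, edges, iterations, params)
}

# Iterate the force model from given initial coordinates (used by tests
# for the translation-invariance property).
force_layout_from <- function(X, edges, iterations, params = layout_params()) {
  n_nodes <- nrow(X); dims <- ncol(X)
  act <- edges[edges$pvalue <= params$pvalue_cutoff, , drop = FALSE]
  A <- matrix(0, n_nodes, n_nodes)
  if (nrow(act)) {
    a <- pmin(-log10(act$pvalue), 20) * params$attract_weight
    a[is.infinite(a)] <- 20 * params$attract_weight
    A[cbind(act$i, act$j)] <- a
    A[cbind(act$j, act$i)] <- a
  }
  rsA <- rowSums(A)
  for (it in seq_len(iterations)) {
    d2 <- as.matrix(stats::dist(X))^2
    W <- params$repulse_weight / pmax(d2, params$eps)
    diag(W) <- 0
    disp <- (A %*% X - rsA * X) +            # attraction
            (rowSums(W) * X - W %*% X)       # repulsion
    disp <- params$damping * disp
    norms <- sqrt(rowSums(disp^2))
    over <- norms > params$max_step
    if (any(over))
      disp[over, ] <- disp[over, , drop = FALSE] * (params$max_step / norms[over])
    X <- X + disp
    dimnames(X) <- NULL
    if (!all(is.finite(X)))
      np_stop("npmine_layout_diverged",
              sprintf("layout diverged at iteration %d", it), iteration = it)
  }
  structure(list(coordinates = X, iteration = iterations,
                 seed = NA_integer_, params = params),
            class = "layout_state")
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Connected components of the similarity graph at a p-value cut-off
#'
#' Components of the subgraph restricted to edges with
#' `pvalue <= pvalue_cutoff`; nodes with no retained edge are singletons.
#' Labels are integers ordered by each component's smallest member index.
#'
#' @param edges Edge table from [all_vs_all()].
#' @param n_nodes Number of nodes.
#' @param pvalue_cutoff Positive cut-off.
#' @return Integer vector of component labels, one per node.
#' @export
components_at_cutoff <- function(edges, n_nodes, pvalue_cutoff) {
  stopifnot(pvalue_cutoff > 0)
  keep <- edges[edges$pvalue <= pvalue_cutoff, , drop = FALSE]
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(keep))
    g <- igraph::add_edges(g, rbind(keep$i, keep$j))
  memb <- igraph::components(g)$membership
  # relabel so component 1 contains node with the smallest index, etc.
  first <- tapply(seq_len(n_nodes), memb, min)
  relabel <- rank(first)
  as.integer(relabel[memb])
}

#' Write layout coordinates / edges / components as TSV
#'
#' @param layout A `layout_state`.
#' @param ids Node identifiers.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_layout_tsv <- function(layout, ids, path) {
  X <- layout$coordinates
  df <- data.frame(id = ids, X, stringsAsFactors = FALSE)
  names(df) <- c("id", c("x", "y", "z")[seq_len(ncol(X))])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
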