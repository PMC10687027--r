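#' Weighted shortest-path distance
#'
#' Distance between two nodes of a per-sample weighted graph: the minimum,
#' over paths, of the sum of edge lengths 1/sqrt(w) along the path. For an
#' adjacent pair this can undercut the direct edge length when a bypass is
#' shorter.
#'
#' @param g a `weighted_sample_graph`.
#' @param i,j distinct node names.
#' @return Positive distance.
#' @export
shortest_path_distance <- function(g, i, j) {
  if (identical(i, j)) stop("i and j must differ")
  D <- graph_distances(g, c(i, j))
  d <- D[i, j]
  if (!is.finite(d)) stop("nodes ", i, " and ", j, " are disconnected")
  d
}

# internal: full (or row-subset) weighted shortest-path matrix
graph_distances <- function(g, from = NULL, weighted = TRUE) {
  ig <- as_igraph_network(g$network)
  wts <- if (weighted) g$edges$length else NA
  v <- if (is.null(from)) igraph::V(ig) else from
  D <- igraph::distances(ig, v = v, weights = wts)
  D[, g$network$nodes, drop = FALSE][, , drop = FALSE]
}

#' Wasserstein-1 (earth mover's) distance between two discrete distributions
#'
#' Exact optimal-transport cost, computed by an exact min-cost-flow solve
#' (no entropic regularization). Symmetric in its arguments when the ground
#' matrix is a metric.
#'
#' @param mu_i,mu_j probability vectors (each summing to 1 within 1e-9).
#' @param ground matrix of ground distances, rows indexing the support of
#'   `mu_i` and columns the support of `mu_j`.
#' @return Nonnegative transport cost.
#' @export
wasserstein1 <- function(mu_i, mu_j, ground) {
  mu_i <- as.numeric(mu_i); mu_j <- as.numeric(mu_j)
  if (any(mu_i < 0) || any(mu_j < 0)) stop("probabilities must be nonnegative")
  if (abs(sum(mu_i) - 1) > 1e-9 || abs(sum(mu_j) - 1) > 1e-9)
    stop("mass mismatch: distributions must each sum to 1 within 1e-9")
  emd_cpp(mu_i, mu_j, as.matrix(ground))
}

#' Ollivier-Ricci curvature of one edge
#'
#' kappa(i,j) = 1 - W1(mu_i, mu_j) / d(i,j), where mu are the neighbor
#' distributions, W1 the exact transport cost under the weighted
#' shortest-path ground metric, and d the weighted shortest-path distance.
#' Positive curvature indicates well-connected, redundant neighborhoods
#' (robust edges); negative curvature indicates bottleneck, bridge-like
#' edges.
#'
#' @param g a `weighted_sample_graph`.
#' @param i,j endpoint node names of an edge of `g`.
#' @param config an [orc_config()]; `ground_metric` selects the W1 ground
#'   metric.
#' @return List of class `curvature_record` with `edge`, `W1`, `d`, `kappa`.
#' @export
orc_edge <- function(g, i, j, config = orc_config()) {
  hit <- (g$edges$from == i & g$edges$to == j) |
         (g$edges$from == j & g$edges$to == i)
  if (!any(hit)) stop("(", i, ",", j, ") is not an edge of the graph")
  mu_i <- neighbor_distribution(g, i)
  mu_j <- neighbor_distribution(g, j)
  Dw <- graph_distances(g)
  Dg <- if (config$ground_metric == "hop") graph_distances(g, weighted = FALSE) else Dw
  W1 <- wasserstein1(mu_i, mu_j, Dg[names(mu_i), names(mu_j), drop = FALSE])
  d <- Dw[i, j]
  structure(list(edge = c(i, j), W1 = W1, d = d, kappa = 1 - W1 / d),
            class = "curvature_record")
}

# internal: curvature of every edge of one weighted sample graph (fast path)
orc_all_edges <- function(g, config = orc_config()) {
  nodes <- g$network$nodes
  idx <- stats::setNames(seq_along(nodes) - 1L, nodes)
  adj0 <- lapply(g$adj, function(nb) unname(idx[nb]))
  Dw <- graph_distances(g)[nodes, nodes]
  Dg <- if (config$ground_metric == "hop")
    graph_distances(g, weighted = FALSE)[nodes, nodes] else Dw
  ei <- unname(idx[g$edges$from])
  ej <- unname(idx[g$edges$to])
  dvec <- Dw[cbind(ei + 1L, ej + 1L)]
  res <- orc_edges_cpp(ei, ej, unname(adj0), unname(g$r[nodes]), Dg, dvec)
  data.frame(from = g$edges$from, to = g$edges$to,
             W1 = res$W1, d = res$d, kappa = res$kappa,
             stringsAsFactors = FALSE)
}

#' Per-sample curvature matrix over a harmonized cohort
#'
#' Computes the Ollivier-Ricci curvature of every interaction edge in every
#' sample's weighted graph. Rows are edges (fixed lexicographic order
#' `"geneA|geneB"`), columns are samples.
#'
#' @param cohort a `cohort_tables` object from [harmonize()].
#' @param kind `"rna"` (node values from the `tpm` matrix) or `"cna"`.
#' @param config an [orc_config()].
#' @param verbose log per-sample progress.
#' @return Object of class `curvature_matrix`: `edges` (data frame
#'   `from`/`to`), `samples`, `kappa` (edges x samples), `kind`.
#' @export
curvature_matrix <- function(cohort, kind = c("rna", "cna"),
                             config = orc_config(), verbose = FALSE) {
  kind <- match.arg(kind)
  src <- if (kind == "rna") "tpm" else "cna"
  if (!src %in% names(cohort$matrices))
    stop("cohort has no ", src, " matrix")
  mat <- cohort$matrices[[src]]
  net <- cohort$network
  samples <- cohort$samples
  kap <- matrix(NA_real_, nrow = nrow(net$edges), ncol = length(samples),
                dimnames = list(paste(net$edges$from, net$edges$to, sep = "|"),
                                samples))
  for (s in samples) {
    r <- tryCatch(node_values(mat, s, config),
                  error = function(e) stop("sample ", s, ": ",
                                           conditionMessage(e), call. = FALSE))
    g <- build_weighted_graph(net, r)
    kap[, s] <- orc_all_edges(g, config)$kappa
    if (verbose) message("curvature: sample ", s, " done")
  }
  structure(list(edges = net$edges, samples = samples, kappa = kap,
                 kind = kind), class = "curvature_matrix")
}

#' @export
print.curvature_matrix <- function(x, ...) {
  cat(sprintf("curvature_matrix [%s]: %d edges x %d samples\n",
              x$kind, nrow(x$kappa), ncol(x$kappa)))
  invisible(x)
}

#' Read / write a curvature matrix as TSV
#'
#' Rows are edges keyed `"geneA|geneB"` in the first column (`edge`), one
#' column per sample.
#'
#' @param x a `curvature_matrix`.
#' @param path file path.
#' @param kind curvature source kind stored on read.
#' @return [write_curvature()]: the path, invisibly; [read_curvature()]: a
#'   `curvature_matrix`.
#' @export
write_curvature <- function(x, path) {
  df <- data.frame(edge = rownames(x$kappa), x$kappa, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curvature
#' @export
read_curvature <- function(path, kind = c("rna", "cna")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(colnames(df)[1] == "edge")
  kap <- as.matrix(df[, -1, drop = FALSE])
  rownames(kap) <- df$edge
  ends <- strsplit(df$edge, "|", fixed = TRUE)
  edges <- data.frame(from = vapply(ends, `[`, character(1), 1),
                      to = vapply(ends, `[`, character(1), 2),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, samples = colnames(kap), kappa = kap,
                 kind = kind), class = "curvature_matrix")
}
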