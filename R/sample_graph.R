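#' Configuration for per-sample graph weighting and curvature
#'
#' @param pseudocount_eps positive floor added to every node value after
#'   transformation, so that transition probabilities and edge lengths stay
#'   finite when a gene is unexpressed. Default 0.01.
#' @param rna_transform RNA-seq transform; only `"log2p1"` (log2(TPM+1)) is
#'   defined.
#' @param cna_encoding `"copy_number"` (values are absolute copy numbers,
#'   floored at 0) or `"log_ratio"` (log2 ratios, mapped to copy number as
#'   2^value * 2 before flooring).
#' @param ground_metric ground metric for the Wasserstein-1 distance:
#'   `"weighted"` (weighted shortest-path metric, the default) or `"hop"`
#'   (unweighted hop distance), exposed for sensitivity analysis.
#' @return A list of class `orc_config`.
#' @export
orc_config <- function(pseudocount_eps = 0.01,
                       rna_transform = c("log2p1"),
                       cna_encoding = c("copy_number", "log_ratio"),
                       ground_metric = c("weighted", "hop")) {
  if (!is.numeric(pseudocount_eps) || pseudocount_eps < 0)
    stop("pseudocount_eps must be a nonnegative number")
  structure(list(pseudocount_eps = pseudocount_eps,
                 rna_transform = match.arg(rna_transform),
                 cna_encoding = match.arg(cna_encoding),
                 ground_metric = match.arg(ground_metric)),
            class = "orc_config")
}

#' Per-sample node values from an omics matrix
#'
#' RNA-seq (`tpm`): r = log2(TPM + 1) + eps. Copy number (`cna`): r =
#' max(copy number, 0) + eps, with log-ratio inputs first mapped to copy
#' number as 2^value * 2. The floor eps keeps every value strictly positive
#' so neighbor distributions and edge lengths are well defined.
#'
#' @param matrix an `omics_matrix` of kind `tpm` or `cna`.
#' @param sample sample ID (must be a column of `matrix`).
#' @param config an [orc_config()].
#' @return Named numeric vector of node values (one per gene), with
#'   attribute `kind` set to `"rna"` or `"cna"`.
#' @export
node_values <- function(matrix, sample, config = orc_config()) {
  if (!inherits(matrix, "omics_matrix")) stop("matrix must be an omics_matrix")
  if (!sample %in% matrix$samples) stop("unknown sample: ", sample)
  v <- matrix$values[, sample]
  eps <- config$pseudocount_eps
  if (matrix$kind == "tpm") {
    if (any(v < 0)) stop("negative TPM values")
    r <- log2(v + 1) + eps
    kind <- "rna"
  } else if (matrix$kind == "cna") {
    if (config$cna_encoding == "log_ratio") v <- 2^v * 2
    r <- pmax(v, 0) + eps
    kind <- "cna"
  } else {
    stop("node values are defined for tpm or cna matrices, not ", matrix$kind)
  }
  names(r) <- matrix$genes
  attr(r, "kind") <- kind
  r
}

#' Build the weighted graph for one sample
#'
#' Node values r define directed transition probabilities
#' p_ij = r_j / sum over neighbors k of i of r_k (nonzero only across
#' interaction edges). The symmetric edge weight is the average of the two
#' directions, w_ij = (p_ij + p_ji)/2, and the edge length is
#' l_ij = 1/sqrt(w_ij). Probabilities are ratios of node values, so scaling
#' all r by a positive constant leaves the graph unchanged.
#'
#' @param net an `interaction_network` (connected; typically the harmonized
#'   LCC).
#' @param r named positive node-value vector covering every node of `net`.
#' @return An object of class `weighted_sample_graph`: the network, `r`, an
#'   adjacency list `adj`, and the edge table with columns `from`, `to`,
#'   `p_ij`, `p_ji`, `w`, `length`.
#' @export
build_weighted_graph <- function(net, r) {
  if (!all(net$nodes %in% names(r)))
    stop("node values must cover every network node")
  r <- r[net$nodes]
  if (any(!is.finite(r)) || any(r <= 0))
    stop("node values must be finite and strictly positive")
  adj <- adjacency_list(net)
  deg <- lengths(adj)
  if (any(deg == 0)) stop("network has isolated nodes; extract the LCC first")
  rsum <- vapply(adj, function(nb) sum(r[nb]), numeric(1))
  ed <- net$edges
  p_ij <- r[ed$to] / rsum[ed$from]   # from -> to
  p_ji <- r[ed$from] / rsum[ed$to]   # to -> from
  w <- (p_ij + p_ji) / 2
  stopifnot(all(w > 0))
  ed$p_ij <- unname(p_ij)
  ed$p_ji <- unname(p_ji)
  ed$w <- unname(w)
  ed$length <- 1 / sqrt(ed$w)
  structure(list(network = net, r = r, adj = adj, edges = ed),
            class = "weighted_sample_graph")
}

# internal: named adjacency list of an interaction_network
adjacency_list <- function(net) {
  adj <- lapply(stats::setNames(net$nodes, net$nodes), function(x) character(0))
  if (nrow(net$edges) > 0) {
    sp1 <- split(net$edges$to, net$edges$from)
    sp2 <- split(net$edges$from, net$edges$to)
    for (nm in names(sp1)) adj[[nm]] <- c(adj[[nm]], sp1[[nm]])
    for (nm in names(sp2)) adj[[nm]] <- c(adj[[nm]], sp2[[nm]])
    adj <- lapply(adj, sort)
  }
  adj
}

#' Neighbor probability distribution of a node
#'
#' mu_i places mass r_k / sum(r over neighbors of i) on each neighbor k of i
#' and zero mass elsewhere (no lazy/self mass).
#'
#' @param g a `weighted_sample_graph`.
#' @param i node name.
#' @return Named probability vector over the neighbors of `i`.
#' @export
neighbor_distribution <- function(g, i) {
  if (!i %in% g$network$nodes) stop("unknown node: ", i)
  nb <- g$adj[[i]]
  if (length(nb) == 0) stop("node ", i, " is isolated")
  mu <- g$r[nb] / sum(g$r[nb])
  mu
}

#' @export
print.weighted_sample_graph <- function(x, ...) {
  cat(sprintf("weighted_sample_graph: %d nodes, %d edges\n",
              length(x$network$nodes), nrow(x$edges)))
  invisible(x)
}
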