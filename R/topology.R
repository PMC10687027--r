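#' Degree-based gene classification: singleton / bridge / hub
#'
#' Hubs form more than twice the graph's mean number of connections
#' (strictly greater), singletons form exactly one connection, and bridge
#' genes fall in between (2 up to the hub threshold). With a mean degree of
#' 8.4 the hub rule reads "more than 16 connections".
#'
#' @param net an `interaction_network`.
#' @return Object of class `degree_classification`: `class` (named character
#'   vector gene -> singleton/bridge/hub), `degree`, `mean_degree`,
#'   `hub_threshold`.
#' @export
classify_degrees <- function(net) {
  deg <- degree_of(net)
  mean_deg <- 2 * nrow(net$edges) / length(net$nodes)
  thr <- 2 * mean_deg
  cls <- ifelse(deg == 1, "singleton", ifelse(deg > thr, "hub", "bridge"))
  structure(list(class = cls, degree = deg, mean_degree = mean_deg,
                 hub_threshold = thr), class = "degree_classification")
}

# internal: named degree vector
degree_of <- function(net) {
  deg <- stats::setNames(rep(0L, length(net$nodes)), net$nodes)
  tab <- table(c(net$edges$from, net$edges$to))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' k-hop neighborhood subgraph
#'
#' Induced subgraph on all nodes within unweighted hop distance `k` of the
#' focal gene: `k = 1` is the closed immediate neighborhood ("1-hop plot"),
#' `k = 2` additionally pulls in the neighbors' neighbors ("2-hop plot").
#'
#' @param net an `interaction_network`.
#' @param gene focal gene symbol.
#' @param k hop radius, 1 or 2.
#' @return The induced `interaction_network`.
#' @export
khop_subgraph <- function(net, gene, k = 1) {
  if (!gene %in% net$nodes) stop("unknown gene: ", gene)
  if (!k %in% c(1, 2)) stop("k must be 1 or 2")
  g <- as_igraph_network(net)
  nodes <- names(igraph::ego(g, order = k, nodes = gene)[[1]])
  induced_network(net, nodes)
}

#' Robust/fragile edge labels from median curvature differences
#'
#' For every edge, compares the median curvature across high-risk samples
#' with the median across low-risk samples. Edges with a positive difference
#' (delta = high - low > 0) are more robust in the high-risk group; negative
#' differences mark edges that are more fragile there.
#'
#' @param curv a `curvature_matrix`.
#' @param risk a `risk_grouping` (or named vector sample -> high/low).
#' @return Data frame of class `edge_delta_report`: `from`, `to`,
#'   `median_high`, `median_low`, `delta`, `label`
#'   (robust / fragile / unchanged).
#' @export
edge_robustness_delta <- function(curv, risk) {
  groups <- if (inherits(risk, "risk_grouping")) risk$groups else risk
  hi <- names(groups)[groups == "high"]
  lo <- names(groups)[groups == "low"]
  hi <- intersect(hi, curv$samples)
  lo <- intersect(lo, curv$samples)
  if (length(hi) == 0 || length(lo) == 0)
    stop("both risk groups must contain at least one sample")
  med_h <- apply(curv$kappa[, hi, drop = FALSE], 1, stats::median)
  med_l <- apply(curv$kappa[, lo, drop = FALSE], 1, stats::median)
  delta <- med_h - med_l
  out <- data.frame(from = curv$edges$from, to = curv$edges$to,
                    median_high = unname(med_h), median_low = unname(med_l),
                    delta = unname(delta),
                    label = ifelse(delta > 0, "robust",
                                   ifelse(delta < 0, "fragile", "unchanged")),
                    stringsAsFactors = FALSE)
  class(out) <- c("edge_delta_report", class(out))
  out
}

#' Annotated k-hop neighborhood report
#'
#' Extracts the k-hop subgraph around a gene and annotates its edges with
#' the robust/fragile labels from [edge_robustness_delta()] and its nodes
#' with their degree class in the full network. The result serializes to
#' node-link JSON.
#'
#' @param net the harmonized `interaction_network`.
#' @param curv a `curvature_matrix` over `net`.
#' @param risk a `risk_grouping`.
#' @param gene focal gene.
#' @param k hop radius (1 or 2).
#' @return List of class `neighborhood_report` with `gene`, `k`, `nodes`
#'   (data frame `id`, `degree_class`) and `links` (data frame `source`,
#'   `target`, `delta`, `label`).
#' @export
neighborhood_report <- function(net, curv, risk, gene, k = 1) {
  sub <- khop_subgraph(net, gene, k)
  deltas <- edge_robustness_delta(curv, risk)
  key <- paste(deltas$from, deltas$to, sep = "|")
  idx <- match(paste(sub$edges$from, sub$edges$to, sep = "|"), key)
  if (anyNA(idx)) stop("curvature matrix does not cover the neighborhood edges")
  cls <- classify_degrees(net)
  structure(list(
    gene = gene, k = k,
    nodes = data.frame(id = sub$nodes,
                       degree_class = unname(cls$class[sub$nodes]),
                       stringsAsFactors = FALSE),
    links = data.frame(source = sub$edges$from, target = sub$edges$to,
                       delta = deltas$delta[idx], label = deltas$label[idx],
                       stringsAsFactors = FALSE)),
    class = "neighborhood_report")
}

#' Write / read a neighborhood report as node-link JSON
#'
#' Format: `{gene, k, nodes: [{id, degree_class}], links: [{source, target,
#' delta, label}]}`.
#'
#' @param report a `neighborhood_report`.
#' @param path JSON path.
#' @return [write_neighborhood_json()]: the path, invisibly;
#'   [read_neighborhood_json()]: a `neighborhood_report`.
#' @export
write_neighborhood_json <- function(report, path) {
  jsonlite::write_json(list(gene = report$gene, k = report$k,
                            nodes = report$nodes, links = report$links),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_neighborhood_json
#' @export
read_neighborhood_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(gene = x$gene, k = x$k,
                 nodes = as.data.frame(x$nodes),
                 links = as.data.frame(x$links)),
            class = "neighborhood_report")
}
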