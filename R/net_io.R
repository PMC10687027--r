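#' Construct an interaction network
#'
#' An `interaction_network` is an undirected simple graph over gene symbols:
#' no self-loops, no duplicate edges, every edge endpoint present in `nodes`.
#' Gene symbols are case-sensitive character strings; no alias resolution is
#' attempted. Edges are stored in canonical order (alphabetically smaller
#' endpoint first) and sorted lexicographically, which fixes the edge ordering
#' used throughout the curvature pipeline.
#'
#' @param edges two-column character matrix or data frame of gene-symbol pairs.
#' @param nodes optional character vector of node names; defaults to the union
#'   of edge endpoints. Extra isolated nodes are allowed.
#' @return An object of class `interaction_network` with elements `nodes`
#'   (sorted character vector) and `edges` (data frame with columns `from`,
#'   `to`, `from < to`, sorted).
#' @export
interaction_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (ncol(edges) < 2) stop("edges must have two columns")
  edges <- matrix(as.character(edges[, 1:2]), ncol = 2)
  self <- edges[, 1] == edges[, 2]
  if (any(self)) {
    warning(sprintf("dropped %d self-loop(s)", sum(self)))
    edges <- edges[!self, , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    a <- pmin(edges[, 1], edges[, 2])
    b <- pmax(edges[, 1], edges[, 2])
    key <- paste(a, b, sep = "\t")
    keep <- !duplicated(key)
    ed <- data.frame(from = a[keep], to = b[keep], stringsAsFactors = FALSE)
    ed <- ed[order(ed$from, ed$to), , drop = FALSE]
    rownames(ed) <- NULL
  } else {
    ed <- data.frame(from = character(0), to = character(0),
                     stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) nodes <- unique(c(ed$from, ed$to))
  nodes <- sort(unique(as.character(nodes)))
  missing <- setdiff(c(ed$from, ed$to), nodes)
  if (length(missing) > 0)
    stop("edge endpoints missing from nodes: ", paste(missing, collapse = ", "))
  structure(list(nodes = nodes, edges = ed), class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("interaction_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes of an interaction network
#' @param net an `interaction_network`.
#' @return Integer count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

# internal: igraph view of the network (vertex name = gene symbol)
as_igraph_network <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Read a tab-separated gene-interaction edge list
#'
#' HPRD-style input: one interaction per line, first two tab-separated fields
#' are gene symbols (extra columns are ignored). Duplicate pairs in either
#' orientation are collapsed and self-loops are dropped with a warning.
#'
#' @param path path to the edge-list file.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty edge-list file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2)
  if (length(bad) > 0)
    stop(sprintf("malformed edge-list line %d in %s: fewer than 2 fields",
                 bad[1], path))
  m <- t(vapply(parts, function(p) trimws(p[1:2]), character(2)))
  interaction_network(m)
}

#' Write an interaction network as a two-column TSV edge list
#' @param net an `interaction_network`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Largest connected component
#'
#' Ties between equal-size components are broken deterministically by picking
#' the component that contains the lexicographically smallest gene symbol.
#'
#' @param net an `interaction_network`.
#' @return The induced `interaction_network` on the largest component.
#' @export
largest_connected_component <- function(net) {
  if (length(net$nodes) == 0) stop("empty network")
  g <- as_igraph_network(net)
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    firsts <- vapply(best, function(ci) {
      min(net$nodes[comp$membership == ci])
    }, character(1))
    best <- best[order(firsts)][1]
  }
  keep <- net$nodes[comp$membership == best]
  induced_network(net, keep)
}

#' Induced subgraph on a node subset
#' @param net an `interaction_network`.
#' @param genes character vector of node names to keep.
#' @return The induced `interaction_network`.
#' @export
induced_network <- function(net, genes) {
  genes <- intersect(net$nodes, genes)
  ed <- net$edges[net$edges$from %in% genes & net$edges$to %in% genes, ,
                  drop = FALSE]
  interaction_network(ed, nodes = genes)
}

#' Construct a gene-by-sample omics matrix
#'
#' @param values numeric matrix, genes in rows (rownames = gene symbols),
#'   samples in columns (colnames = sample IDs).
#' @param kind one of `"tpm"`, `"counts"`, `"cna"`. `tpm` and `counts` entries
#'   must be nonnegative; `counts` must be whole numbers.
#' @return An object of class `omics_matrix`.
#' @export
omics_matrix <- function(values, kind = c("tpm", "counts", "cna")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("omics matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values))) stop("duplicate gene symbols")
  if (anyDuplicated(colnames(values))) stop("duplicate sample IDs")
  if (!all(is.finite(values))) stop("omics values must be finite")
  if (kind %in% c("tpm", "counts") && any(values < 0))
    stop(kind, " values must be nonnegative")
  if (kind == "counts" && any(abs(values - round(values)) > 1e-8))
    stop("counts must be whole numbers")
  structure(list(genes = rownames(values), samples = colnames(values),
                 values = values, kind = kind), class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d genes x %d samples\n",
              x$kind, length(x$genes), length(x$samples)))
  invisible(x)
}

#' Read / write a gene-by-sample omics TSV
#'
#' Format: tab-separated, first column named `gene`, remaining columns one per
#' sample.
#'
#' @param path file path.
#' @param kind matrix kind, as in [omics_matrix()].
#' @return [read_omics()]: an `omics_matrix`; [write_omics()]: the path,
#'   invisibly.
#' @export
read_omics <- function(path, kind = c("tpm", "counts", "cna")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1] != "gene") stop("first column must be named 'gene'")
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df$gene
  omics_matrix(vals, kind)
}

#' @rdname read_omics
#' @param mat an `omics_matrix` to write.
#' @export
write_omics <- function(mat, path) {
  df <- data.frame(gene = mat$genes, mat$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate / read a clinical table
#'
#' One row per sample with columns `sample`, `pfs_time` (years, positive),
#' `event` (1 = progressed/died, 0 = censored), optional `iss` (I/II/III) and
#' any further numeric covariates.
#'
#' @param df data frame to validate.
#' @return The validated data frame with class `clinical_table` prepended.
#' @export
clinical_table <- function(df) {
  req <- c("sample", "pfs_time", "event")
  if (!all(req %in% colnames(df)))
    stop("clinical table must have columns: ", paste(req, collapse = ", "))
  df$sample <- as.character(df$sample)
  if (anyDuplicated(df$sample)) stop("duplicate sample IDs in clinical table")
  if (!all(is.finite(df$pfs_time)) || any(df$pfs_time <= 0))
    stop("pfs_time must be finite and positive")
  if (!all(df$event %in% c(0, 1))) stop("event must be 0 or 1")
  if ("iss" %in% colnames(df)) {
    ok <- is.na(df$iss) | df$iss %in% c("I", "II", "III")
    if (!all(ok)) stop("iss must be one of I, II, III (or NA)")
  }
  class(df) <- unique(c("clinical_table", class(df)))
  df
}

#' @rdname clinical_table
#' @param path TSV path with the columns described above.
#' @export
read_clinical <- function(path) {
  clinical_table(utils::read.delim(path, check.names = FALSE,
                                   stringsAsFactors = FALSE))
}

#' @rdname clinical_table
#' @param clin a `clinical_table` to write.
#' @export
write_clinical <- function(clin, path) {
  utils::write.table(clin, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: per line, a set name, a description (ignored), then the
#' member gene symbols, all tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad) > 0)
    stop(sprintf("malformed GMT line %d: fewer than 3 fields", bad[1]))
  nm <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(nm)) stop("duplicate gene-set name in GMT: ",
                              nm[duplicated(nm)][1])
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  structure(sets, class = "gene_set_collection")
}

#' Harmonize network, omics matrices and clinical table into a cohort
#'
#' Restricts genes to the intersection of the network nodes and every omics
#' matrix, re-extracts the largest connected component on that intersection,
#' restricts samples to those present in every matrix and in the clinical
#' table, and reorders all matrices identically (genes and samples sorted).
#' The operation is idempotent.
#'
#' @param net an `interaction_network`.
#' @param matrices list of `omics_matrix` objects (e.g. tpm, counts, cna);
#'   named by their `kind` in the result.
#' @param clinical a `clinical_table`.
#' @return An object of class `cohort_tables`: `network` (harmonized LCC),
#'   `matrices` (named list, aligned), `clinical` (aligned), `genes`,
#'   `samples`.
#' @export
harmonize <- function(net, matrices, clinical) {
  if (inherits(matrices, "omics_matrix")) matrices <- list(matrices)
  clinical <- clinical_table(as.data.frame(clinical))
  genes <- net$nodes
  for (m in matrices) genes <- intersect(genes, m$genes)
  if (length(genes) == 0) stop("no genes shared between network and matrices")
  sub <- induced_network(net, genes)
  if (nrow(sub$edges) == 0) stop("shared genes induce an edgeless network")
  lcc <- largest_connected_component(sub)
  genes <- lcc$nodes
  samples <- Reduce(intersect, lapply(matrices, `[[`, "samples"))
  samples <- intersect(samples, clinical$sample)
  if (length(samples) == 0) stop("no samples shared across matrices and clinical table")
  samples <- sort(samples)
  mats <- lapply(matrices, function(m) {
    omics_matrix(m$values[genes, samples, drop = FALSE], m$kind)
  })
  names(mats) <- vapply(mats, `[[`, character(1), "kind")
  clin <- clinical[match(samples, clinical$sample), , drop = FALSE]
  rownames(clin) <- NULL
  structure(list(network = lcc, matrices = mats, clinical = clin,
                 genes = genes, samples = samples), class = "cohort_tables")
}

#' @export
print.cohort_tables <- function(x, ...) {
  cat(sprintf("cohort_tables: %d genes (LCC), %d samples, matrices: %s\n",
              length(x$genes), length(x$samples),
              paste(names(x$matrices), collapse = ", ")))
  invisible(x)
}
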