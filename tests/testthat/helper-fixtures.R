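# shared in-code fixtures: tiny graphs and cohorts built at test time

uniform_r <- function(net) stats::setNames(rep(1, length(net$nodes)), net$nodes)

k3_network <- function() interaction_network(rbind(c("a", "b"), c("a", "c"),
                                                   c("b", "c")))

p3_network <- function() interaction_network(rbind(c("a", "b"), c("b", "c")))

complete_network <- function(nodes) interaction_network(t(utils::combn(nodes, 2)))

# two 4-cliques joined by a single bridge edge a1-b1
bridged_cliques_network <- function() {
  cl <- function(nodes) t(utils::combn(nodes, 2))
  interaction_network(rbind(cl(paste0("a", 1:4)), cl(paste0("b", 1:4)),
                            c("a1", "b1")))
}

# random connected simple graph on n <= 26 nodes (letters), edge prob p
random_connected_network <- function(n, p = 0.45) {
  repeat {
    m <- matrix(stats::runif(n * n) < p, n, n)
    m[lower.tri(m, diag = TRUE)] <- FALSE
    ed <- which(m, arr.ind = TRUE)
    if (nrow(ed) < n - 1) next
    nodes <- letters[seq_len(n)]
    net <- interaction_network(cbind(nodes[ed[, 1]], nodes[ed[, 2]]))
    if (length(net$nodes) == n &&
        igraph::is_connected(orcnet:::as_igraph_network(net)))
      return(net)
  }
}

# minimal harmonizable cohort: chain network, tpm/counts/cna over it
tiny_cohort <- function(n_samples = 4) {
  net <- interaction_network(rbind(c("A", "B"), c("B", "C"), c("C", "D")))
  samples <- paste0("s", seq_len(n_samples))
  set.seed(99)
  tpm <- matrix(stats::runif(4 * n_samples, 1, 100), 4, n_samples,
                dimnames = list(c("A", "B", "C", "D"), samples))
  counts <- matrix(stats::rpois(4 * n_samples, 50), 4, n_samples,
                   dimnames = list(c("A", "B", "C", "D"), samples))
  cna <- matrix(2, 4, n_samples,
                dimnames = list(c("A", "B", "C", "D"), samples))
  clin <- clinical_table(data.frame(
    sample = samples, pfs_time = seq_len(n_samples), event = 1,
    stringsAsFactors = FALSE))
  harmonize(net, list(omics_matrix(tpm, "tpm"), omics_matrix(counts, "counts"),
                      omics_matrix(cna, "cna")), clin)
}
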