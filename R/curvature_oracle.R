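#' Brute-force curvature oracles
#'
#' Independent reference implementations used to validate the fast curvature
#' path on small graphs: shortest paths by exhaustive simple-path
#' enumeration, and the transport problem by exhaustive enumeration of the
#' vertices of the transportation polytope (every spanning-tree basis of the
#' bipartite supply/demand graph, solved by leaf elimination) for small
#' supports, falling back to an independent simplex LP solve
#' (`pracma::linprog`) for larger ones. These share no code with the main
#' min-cost-flow implementation.
#'
#' @name curvature_oracles
NULL

#' Shortest-path distance by exhaustive simple-path enumeration
#'
#' @param g a `weighted_sample_graph` (small; intended for n <= 10 nodes).
#' @param i,j distinct node names.
#' @return Minimum total edge length over all simple i-j paths.
#' @export
shortest_path_oracle <- function(g, i, j) {
  if (identical(i, j)) stop("i and j must differ")
  len <- stats::setNames(g$edges$length,
                         paste(g$edges$from, g$edges$to, sep = "|"))
  elen <- function(a, b) {
    k <- paste(min(a, b), max(a, b), sep = "|")
    len[[k]]
  }
  best <- Inf
  walk <- function(node, visited, acc) {
    if (node == j) {
      if (acc < best) best <<- acc
      return(invisible(NULL))
    }
    for (nb in g$adj[[node]]) {
      if (!nb %in% visited)
        walk(nb, c(visited, nb), acc + elen(node, nb))
    }
  }
  walk(i, i, 0)
  if (!is.finite(best)) stop("no path between ", i, " and ", j)
  best
}

# internal: transport cost of the basic solution supported on a candidate
# basis (set of cells forming a spanning tree of the bipartite supply/demand
# graph), solved exactly by leaf elimination; NA when the basis is not a
# tree or yields a negative flow (infeasible vertex).
basis_cost <- function(a, b, C, rows, cols) {
  ns <- length(a); nd <- length(b)
  nv <- ns + nd
  verts <- c(rows, ns + cols)
  # union-find connectivity check (tree <=> nv-1 edges, connected)
  parent <- seq_len(nv)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in seq_along(rows)) {
    ra <- find(rows[k]); rb <- find(ns + cols[k])
    if (ra == rb) return(NA_real_)     # cycle
    parent[ra] <- rb
  }
  if (length(unique(vapply(seq_len(nv), find, 1L))) != 1L) return(NA_real_)
  # leaf elimination: a leaf vertex's requirement fixes its single incident
  # flow; every edge's flow counts toward both endpoint requirements
  req <- c(a, b)
  ei <- rows; ej <- ns + cols
  active <- rep(TRUE, length(rows))
  flow <- numeric(length(rows))
  deg <- tabulate(c(ei, ej), nbins = nv)
  for (pass in seq_len(length(rows))) {
    k <- NA_integer_
    for (kk in which(active)) {
      if (deg[ei[kk]] == 1L || deg[ej[kk]] == 1L) { k <- kk; break }
    }
    if (is.na(k)) return(NA_real_)      # cannot happen on a tree
    leaf <- if (deg[ei[k]] == 1L) ei[k] else ej[k]
    other <- if (leaf == ei[k]) ej[k] else ei[k]
    flow[k] <- req[leaf]
    req[other] <- req[other] - flow[k]
    req[leaf] <- 0
    deg[ei[k]] <- deg[ei[k]] - 1L
    deg[ej[k]] <- deg[ej[k]] - 1L
    active[k] <- FALSE
  }
  if (any(flow < -1e-10)) return(NA_real_)
  sum(pmax(flow, 0) * C[cbind(rows, cols)])
}

#' Exhaustive / independent-LP Wasserstein-1 oracle
#'
#' @param mu_i,mu_j probability vectors.
#' @param ground ground-distance matrix (support of `mu_i` x support of
#'   `mu_j`).
#' @param method `"enumeration"` forces exhaustive vertex enumeration (every
#'   basic feasible solution of the transportation polytope, i.e. every
#'   spanning-tree basis of the bipartite supply/demand graph; supports must
#'   be small), `"linprog"` forces the independent simplex solve, `"auto"`
#'   enumerates when `ns * nd` <= 12.
#' @return Optimal transport cost.
#' @export
wasserstein1_oracle <- function(mu_i, mu_j, ground,
                                method = c("auto", "enumeration", "linprog")) {
  method <- match.arg(method)
  a <- as.numeric(mu_i); b <- as.numeric(mu_j)
  C <- as.matrix(ground)
  ns <- length(a); nd <- length(b)
  stopifnot(nrow(C) == ns, ncol(C) == nd)
  if (method == "auto")
    method <- if (ns * nd <= 12) "enumeration" else "linprog"
  if (method == "enumeration") {
    if (ns == 1 || nd == 1)
      return(sum(outer(a, b) * C))      # single vertex: the product plan
    cells <- expand.grid(i = seq_len(ns), j = seq_len(nd))
    best <- Inf
    for (sel in utils::combn(ns * nd, ns + nd - 1L, simplify = FALSE)) {
      cost <- basis_cost(a, b, C, cells$i[sel], cells$j[sel])
      if (!is.na(cost) && cost < best) best <- cost
    }
    best
  } else {
    # one equality row is redundant (rank deficiency trips the simplex
    # code on degenerate instances); the Big-M phase is also sensitive to
    # the exact formulation, so equivalent variants are tried in turn
    scl <- max(C, 1e-12)
    attempts <- list(
      function() linprog_transport(a, b, C, drop_row = ns + nd),
      function() linprog_transport(a, b, C, drop_row = 1L),
      function() scl * linprog_transport(a, b, C / scl, drop_row = ns + nd),
      function() linprog_transport(b, a, t(C), drop_row = ns + nd),
      function() linprog_transport(b, a, t(C), drop_row = 1L))
    for (f in attempts) {
      val <- tryCatch(suppressWarnings(f()), error = function(e) NA_real_)
      if (!is.na(val)) return(val)
    }
    stop("independent LP oracle did not converge")
  }
}

# internal: one simplex solve of the transport LP with a chosen redundant
# equality row removed
linprog_transport <- function(a, b, C, drop_row) {
  ns <- length(a); nd <- length(b)
  Aeq <- matrix(0, ns + nd, ns * nd)
  for (i in seq_len(ns))
    for (j in seq_len(nd)) {
      k <- (j - 1) * ns + i          # column-major cell index
      Aeq[i, k] <- 1
      Aeq[ns + j, k] <- 1
    }
  pracma::linprog(cc = as.vector(C), Aeq = Aeq[-drop_row, , drop = FALSE],
                  beq = c(a, b)[-drop_row], maxiter = 5000)$fval
}

#' Brute-force Ollivier-Ricci curvature of one edge
#'
#' Composes [shortest_path_oracle()] (for the edge distance and all ground
#' distances between the two neighborhoods) with [wasserstein1_oracle()].
#'
#' @param g a small `weighted_sample_graph`.
#' @param i,j endpoints of an edge of `g`.
#' @param method transport oracle method, see [wasserstein1_oracle()].
#' @return List with `W1`, `d`, `kappa`.
#' @export
orc_edge_oracle <- function(g, i, j, method = "auto") {
  mu_i <- neighbor_distribution(g, i)
  mu_j <- neighbor_distribution(g, j)
  si <- names(mu_i); sj <- names(mu_j)
  C <- matrix(0, length(si), length(sj), dimnames = list(si, sj))
  for (a in si)
    for (b in sj)
      C[a, b] <- if (a == b) 0 else shortest_path_oracle(g, a, b)
  W1 <- wasserstein1_oracle(mu_i, mu_j, C, method = method)
  d <- shortest_path_oracle(g, i, j)
  list(W1 = W1, d = d, kappa = 1 - W1 / d)
}
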