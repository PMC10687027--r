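test_that("weighted shortest paths match hand values and the brute-force oracle", {
  g <- build_weighted_graph(p3_network(), uniform_r(p3_network()))
  expect_equal(shortest_path_distance(g, "a", "c"), 2 / sqrt(0.75),
               tolerance = 1e-12)
  # adjacent pair whose direct edge is the only path
  expect_equal(shortest_path_distance(g, "a", "b"), 1 / sqrt(0.75),
               tolerance = 1e-12)
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    net <- random_connected_network(n)
    r <- stats::setNames(stats::runif(n, 0.1, 10), net$nodes)
    gw <- build_weighted_graph(net, r)
    pair <- sample(net$nodes, 2)
    expect_equal(shortest_path_distance(gw, pair[1], pair[2]),
                 shortest_path_oracle(gw, pair[1], pair[2]),
                 tolerance = 1e-10)
  }
})

test_that("wasserstein1 handles identity, point masses, and validation", {
  C <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(wasserstein1(c(0.3, 0.7), c(0.3, 0.7), C), 0)
  expect_equal(wasserstein1(c(1, 0), c(0, 1), C), 2)   # point mass transport
  expect_error(wasserstein1(c(0.6, 0.3), c(0.5, 0.5), C), "mass mismatch")
  # symmetry
  set.seed(32)
  a <- stats::runif(4); a <- a / sum(a)
  b <- stats::runif(3); b <- b / sum(b)
  M <- matrix(stats::runif(12, 0.5, 3), 4, 3)
  expect_equal(wasserstein1(a, b, M), wasserstein1(b, a, t(M)),
               tolerance = 1e-12)
})

test_that("transport solver agrees with both independent oracle routes", {
  set.seed(33)
  for (rep in 1:25) {
    ns <- sample(2:4, 1); nd <- sample(2:3, 1)
    a <- stats::runif(ns); a <- a / sum(a)
    b <- stats::runif(nd); b <- b / sum(b)
    C <- matrix(stats::runif(ns * nd, 0.2, 4), ns, nd)
    main <- wasserstein1(a, b, C)
    expect_equal(main, wasserstein1_oracle(a, b, C, method = "enumeration"),
                 tolerance = 1e-8)
    expect_equal(main, wasserstein1_oracle(a, b, C, method = "linprog"),
                 tolerance = 1e-8)
  }
})

test_that("closed-form curvatures: K3 edges at 1/2, path edges at 0", {
  gk <- build_weighted_graph(k3_network(), uniform_r(k3_network()))
  for (e in 1:3) {
    rec <- orc_edge(gk, gk$edges$from[e], gk$edges$to[e])
    expect_equal(rec$kappa, 0.5, tolerance = 1e-12)
  }
  gp <- build_weighted_graph(p3_network(), uniform_r(p3_network()))
  expect_equal(orc_edge(gp, "a", "b")$kappa, 0, tolerance = 1e-12)
  expect_equal(orc_edge(gp, "b", "c")$kappa, 0, tolerance = 1e-12)
  expect_error(orc_edge(gp, "a", "c"), "not an edge")
})

test_that("curvature records are internally consistent and bounded", {
  set.seed(34)
  for (rep in 1:10) {
    n <- sample(5:8, 1)
    net <- random_connected_network(n)
    r <- stats::setNames(stats::runif(n, 0.1, 10), net$nodes)
    g <- build_weighted_graph(net, r)
    res <- orcnet:::orc_all_edges(g)
    expect_true(all(res$kappa <= 1 + 1e-12))
    expect_true(all(res$W1 >= -1e-12))
    expect_true(all(res$d > 0))
    expect_equal(res$kappa, 1 - res$W1 / res$d, tolerance = 1e-12)
  }
})

test_that("sign taxonomy: cliques positive, bridges the most negative", {
  k5 <- complete_network(letters[1:5])
  g5 <- build_weighted_graph(k5, uniform_r(k5))
  res5 <- orcnet:::orc_all_edges(g5)
  expect_true(all(res5$kappa > 0))
  # cross-check one K5 edge against the oracle
  o <- orc_edge_oracle(g5, "a", "b")
  expect_equal(res5$kappa[res5$from == "a" & res5$to == "b"], o$kappa,
               tolerance = 1e-8)

  bridged <- bridged_cliques_network()
  gb <- build_weighted_graph(bridged, uniform_r(bridged))
  resb <- orcnet:::orc_all_edges(gb)
  on_bridge <- resb$from == "a1" & resb$to == "b1"
  expect_lt(resb$kappa[on_bridge], 0)
  expect_equal(which.min(resb$kappa), which(on_bridge))
  ob <- orc_edge_oracle(gb, "a1", "b1")
  expect_equal(resb$kappa[on_bridge], ob$kappa, tolerance = 1e-8)
})

test_that("curvature matrices are deterministic and column-consistent", {
  co <- tiny_cohort(4)
  cm1 <- curvature_matrix(co, "rna")
  cm2 <- curvature_matrix(co, "rna")
  expect_identical(cm1$kappa, cm2$kappa)          # bit-identical reruns
  expect_true(all(cm1$kappa <= 1 + 1e-12))

  # duplicated omics columns give identical curvature columns
  tpm <- co$matrices$tpm$values
  tpm[, "s2"] <- tpm[, "s1"]
  co2 <- co
  co2$matrices$tpm <- omics_matrix(tpm, "tpm")
  cm3 <- curvature_matrix(co2, "rna")
  expect_equal(cm3$kappa[, "s1"], cm3$kappa[, "s2"])

  # permuting sample order permutes columns only
  co3 <- co
  perm <- rev(co$samples)
  co3$samples <- perm
  cm4 <- curvature_matrix(co3, "rna")
  expect_equal(cm4$kappa[, co$samples], cm1$kappa)
})

test_that("curvature TSV round-trips", {
  co <- tiny_cohort(3)
  cm <- curvature_matrix(co, "rna")
  f <- withr::local_tempfile()
  write_curvature(cm, f)
  back <- read_curvature(f, "rna")
  expect_equal(back$kappa, cm$kappa, tolerance = 1e-10)
  expect_identical(back$edges, cm$edges)
})

test_that("hop ground metric is a usable sensitivity switch", {
  co <- tiny_cohort(3)
  cm_hop <- curvature_matrix(co, "rna", orc_config(ground_metric = "hop"))
  expect_true(all(cm_hop$kappa <= 1 + 1e-12))
  expect_equal(dim(cm_hop$kappa), c(3, 3))
})
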