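test_that("size factors follow the median-of-ratios arithmetic", {
  cts <- matrix(c(2, 10, 4, 20), 2, 2,
                dimnames = list(c("g1", "g2"), c("s1", "s2")))
  sf <- size_factors(cts)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)

  # identical samples share a factor; scaling a sample scales its factor
  cts2 <- cbind(s1 = c(5, 9, 12), s2 = c(5, 9, 12))
  rownames(cts2) <- paste0("g", 1:3)
  expect_equal(unname(size_factors(cts2)), c(1, 1))
  cts3 <- cts2; cts3[, "s2"] <- cts3[, "s2"] * 3
  sf3 <- size_factors(cts3)
  expect_equal(unname(sf3["s2"] / sf3["s1"]), 3, tolerance = 1e-10)

  # invariant to gene order
  set.seed(61)
  m <- matrix(rpois(60, 40) + 1, 10, 6,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  expect_equal(size_factors(m), size_factors(m[sample(10), ]))

  zero <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(zero), "pseudocount")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(62)
  # odd gene count: the even-median convention (arithmetic vs geometric
  # midpoint) then cannot differ between the two implementations
  m <- matrix(rnbinom(201 * 8, mu = 80, size = 5) + 1, 201, 8,
              dimnames = list(paste0("g", 1:201), paste0("s", 1:8)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("NB two-group test is antisymmetric and recovers planted fold changes", {
  set.seed(63)
  # universe large enough that 25 strongly shifted genes stay a small
  # minority; median-of-ratios normalization assumes mostly-null genes
  n_genes <- 500; n <- 10
  mu <- exp(rnorm(n_genes, log(100), 1))
  planted <- 1:25
  shift <- rep(1, n_genes); shift[planted] <- 2^4      # log2FC 4
  cts <- cbind(
    matrix(rnbinom(n_genes * n, mu = mu * shift, size = 5), n_genes, n),
    matrix(rnbinom(n_genes * n, mu = mu, size = 5), n_genes, n))
  dimnames(cts) <- list(sprintf("g%03d", 1:n_genes), sprintf("s%02d", 1:(2 * n)))
  grp <- stats::setNames(rep(c("high", "low"), each = n), colnames(cts))
  de <- nb_two_group_test(cts, grp)
  hits <- de$gene[!is.na(de$q) & de$q < 0.05 & abs(de$log2FC) > 3.5]
  expect_gte(sum(sprintf("g%03d", planted) %in% hits), 20)

  # label swap flips every fold change
  grp_sw <- stats::setNames(ifelse(grp == "high", "low", "high"), names(grp))
  de_sw <- nb_two_group_test(cts, grp_sw)
  expect_equal(de_sw$log2FC, -de$log2FC, tolerance = 1e-10)
  expect_error(nb_two_group_test(cts[, 1:5],
                                 grp[1:5]), "at least 3")
})

test_that("all-zero genes are excluded and one-sided zeros get pseudocount LFC", {
  set.seed(64)
  cts <- matrix(rpois(8 * 10, 50), 8, 10,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  cts["g7", ] <- 0                                  # all-zero everywhere
  cts["g8", 1:5] <- 0                               # zero in the high group
  grp <- stats::setNames(rep(c("high", "low"), each = 5), colnames(cts))
  de <- nb_two_group_test(cts, grp)
  expect_false("g7" %in% de$gene)
  expect_true("g7" %in% attr(de, "excluded"))
  expect_equal(de$flag[de$gene == "g8"], "pseudocount_lfc")
  expect_lt(de$log2FC[de$gene == "g8"], 0)
})

test_that("significance filter applies strict inequalities exactly", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   baseMean = 1, log2FC = c(3.6, 3.6, -3.4, -4),
                   p = 0.001, q = c(0.049, 0.05, 0.01, 0.01),
                   direction = c("over", "over", "under", "under"),
                   flag = "ok")
  class(de) <- c("de_result", class(de))
  sel <- select_significant(de)
  expect_equal(sel$gene, c("a", "d"))               # q=0.05 and |LFC|<=3.5 out
  expect_equal(sel$direction, c("over", "under"))
})

test_that("hypergeometric enrichment reproduces exact tail probabilities", {
  universe <- paste0("g", 1:10)
  sets <- structure(list(S = paste0("g", 1:5)), class = "gene_set_collection")
  res <- hypergeom_enrichment(paste0("g", 1:5), sets, universe)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)   # 1/252

  # disjoint set: exact upper tail at overlap 0
  sets2 <- structure(list(S = paste0("g", 6:8)), class = "gene_set_collection")
  res2 <- hypergeom_enrichment(paste0("g", 1:2), sets2, universe)
  expect_equal(res2$p, stats::phyper(-1, 3, 7, 2, lower.tail = FALSE))
  expect_equal(res2$p, 1)

  # query = universe: every set fully overlaps, p = 1
  res3 <- hypergeom_enrichment(universe, sets, universe)
  expect_equal(res3$overlap, 5)
  expect_equal(res3$p, 1)
  expect_error(hypergeom_enrichment("g1", sets, character(0)), "empty universe")
  expect_error(hypergeom_enrichment("zz", sets, universe), "universe")
})
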