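test_that("feature matrix transposes and standardizes with degenerate-column rule", {
  kap <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
                dimnames = list(c("A|B", "B|C", "C|D"), c("s1", "s2")))
  X <- feature_matrix(kap)
  expect_equal(dim(X), c(2, 3))
  kap2 <- rbind(kap, `D|E` = c(7, 7))       # constant edge
  expect_warning(Xs <- feature_matrix(kap2, standardize = TRUE), "constant")
  expect_equal(ncol(Xs), 3)
  expect_equal(unname(colMeans(Xs)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(Xs, 2, sd)), rep(1, 3), tolerance = 1e-12)
})

test_that("hierarchical clustering splits separated clouds and handles edges", {
  set.seed(41)
  X <- rbind(matrix(rnorm(20, 0), 10, 2), matrix(rnorm(20, 100), 10, 2))
  rownames(X) <- paste0("s", 1:20)
  asg <- hierarchical_cluster(X, 2)
  expect_equal(length(unique(asg$labels[1:10])), 1)
  expect_equal(length(unique(asg$labels[11:20])), 1)
  expect_false(asg$labels[1] == asg$labels[11])

  singl <- hierarchical_cluster(X, nrow(X))
  expect_equal(sort(unique(singl$labels)), 1:20)   # all singletons
  expect_error(hierarchical_cluster(X, 21), "between")

  # duplicated rows always co-cluster
  X2 <- X; X2[2, ] <- X2[1, ]
  asg2 <- hierarchical_cluster(X2, 4)
  expect_equal(asg2$labels[[1]], asg2$labels[[2]])
})

test_that("silhouette model selection recovers planted blob counts", {
  blobs <- function(k, n = 30, sep = 10, seed = 42) {
    set.seed(seed)
    X <- do.call(rbind, lapply(seq_len(k), function(i)
      matrix(rnorm(n * 2, mean = i * sep), n, 2)))
    rownames(X) <- paste0("s", seq_len(k * n))
    X
  }
  expect_equal(select_k_silhouette(blobs(3), 2:8)$k, 3)
  expect_equal(select_k_silhouette(blobs(2), 2:8)$k, 2)
  expect_error(select_k_silhouette(blobs(2), 70:80), "empty k range")
})

test_that("cluster labels are stable under sample permutation", {
  skip_if_not_installed("mclust")
  set.seed(43)
  X <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 8), 20, 2))
  rownames(X) <- paste0("s", 1:40)
  a1 <- hierarchical_cluster(X, 2)
  perm <- sample(nrow(X))
  a2 <- hierarchical_cluster(X[perm, ], 2)
  ari <- mclust::adjustedRandIndex(a1$labels[rownames(X)],
                                   a2$labels[rownames(X)])
  expect_equal(ari, 1)
})

test_that("risk grouping applies manual maps and ranks by KM median in auto", {
  labels <- stats::setNames(rep(1:3, each = 10), paste0("s", 1:30))
  asg <- structure(list(labels = labels, k = 3, linkage = "ward.D2",
                        feature_kind = "orc_rna"),
                   class = "cluster_assignment")
  rg <- assign_risk_groups(asg, mode = "manual",
                           mapping = c(`1` = "low", `3` = "high"))
  expect_equal(unname(rg$groups[labels == 1]), rep("low", 10))
  expect_equal(unname(rg$groups[labels == 2]), rep("excluded", 10))
  expect_error(assign_risk_groups(asg, mode = "manual",
                                  mapping = c(`9` = "high")), "unknown")

  # auto: cluster with uniformly half the survival goes high
  clin <- clinical_table(data.frame(
    sample = paste0("s", 1:30),
    pfs_time = rep(c(1, 2, 4), each = 10), event = 1))
  rga <- assign_risk_groups(asg, clin, mode = "auto")
  expect_equal(unname(rga$groups[labels == 1]), rep("high", 10))
  expect_equal(unname(rga$groups[labels == 3]), rep("low", 10))
  expect_equal(unname(rga$groups[labels == 2]), rep("excluded", 10))

  one <- structure(list(labels = stats::setNames(rep(1, 5), paste0("s", 1:5))),
                   class = "cluster_assignment")
  expect_error(assign_risk_groups(one, clin, mode = "auto"), "at least 2")
})

test_that("hyperdiploidy annotation follows the >2 chromosomes x >60% gain rule", {
  seg <- function(s, chrom, frac, copy, L = 100) {
    rbind(data.frame(sample = s, chrom = chrom, start = 0, end = frac * L,
                     copy_state = copy),
          data.frame(sample = s, chrom = chrom, start = frac * L, end = L,
                     copy_state = 2))
  }
  segs <- rbind(
    seg("s1", "3", 0.7, 3), seg("s1", "5", 0.7, 3), seg("s1", "9", 0.7, 3),
    seg("s2", "3", 0.7, 3), seg("s2", "5", 0.7, 3),
    seg("s3", "1", 0.7, 3), seg("s3", "2", 0.7, 3), seg("s3", "4", 0.7, 3),
    seg("s4", "3", 0.5, 3), seg("s4", "5", 0.7, 3), seg("s4", "9", 0.7, 3))
  hd <- annotate_hyperdiploidy(segs)
  expect_true(hd[["s1"]])        # 3 listed chromosomes above 60%
  expect_false(hd[["s2"]])       # only 2 (">2" is strict)
  expect_false(hd[["s3"]])       # chromosomes not in the listed set
  expect_false(hd[["s4"]])       # 50% gain does not count

  bad <- rbind(segs, data.frame(sample = "s1", chrom = "weird", start = 0,
                                end = 10, copy_state = 3))
  expect_warning(annotate_hyperdiploidy(bad), "unknown chromosome")
})

test_that("cluster-feature association reproduces exact Fisher probabilities", {
  labels <- stats::setNames(rep(c(1, 2), each = 5), paste0("s", 1:10))
  asg <- structure(list(labels = labels), class = "cluster_assignment")
  feat <- stats::setNames(c(rep(TRUE, 5), rep(FALSE, 5)), names(labels))
  res <- cluster_feature_association(asg, feat, 1)
  expect_equal(res$p, 2 / choose(10, 5), tolerance = 1e-12)   # = 1/126

  balanced <- stats::setNames(rep(c(TRUE, FALSE), 4), paste0("s", 1:8))
  asg2 <- structure(list(labels = stats::setNames(rep(c(1, 2), each = 4),
                                                  paste0("s", 1:8))),
                    class = "cluster_assignment")
  expect_equal(cluster_feature_association(asg2, balanced, 1)$p, 1)

  allsame <- stats::setNames(rep(TRUE, 8), paste0("s", 1:8))
  deg <- cluster_feature_association(asg2, allsame, 1)
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
  expect_error(cluster_feature_association(asg2, balanced, 99), "no samples")
})
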