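#' Sample-by-feature matrix from a curvature matrix
#'
#' Transposes the edges-by-samples curvature matrix into the samples-by-edges
#' feature matrix consumed by clustering. Optional per-edge standardization
#' (mean 0, sd 1); constant edges are dropped with a warning when
#' standardizing, since they carry no contrast.
#'
#' @param curv a `curvature_matrix` (or a plain edges-by-samples matrix).
#' @param standardize standardize each feature column? Default `FALSE`.
#' @return Numeric matrix, samples in rows.
#' @export
feature_matrix <- function(curv, standardize = FALSE) {
  kap <- if (inherits(curv, "curvature_matrix")) curv$kappa else as.matrix(curv)
  if (length(kap) == 0) stop("empty curvature matrix")
  X <- t(kap)
  if (standardize) {
    sds <- apply(X, 2, stats::sd)
    const <- sds == 0 | !is.finite(sds)
    if (any(const)) {
      warning(sprintf("dropped %d constant feature(s) during standardization",
                      sum(const)))
      X <- X[, !const, drop = FALSE]
    }
    X <- scale(X)
    attr(X, "scaled:center") <- NULL
    attr(X, "scaled:scale") <- NULL
  }
  X
}

#' Hierarchical agglomerative clustering of samples
#'
#' Ward linkage on Euclidean distances by default (`hclust` method
#' `"ward.D2"`, i.e. Ward's criterion on unsquared distances). Deterministic
#' given the feature matrix and configuration.
#'
#' @param X samples-by-features numeric matrix (rownames = sample IDs).
#' @param k number of clusters, `2 <= k <= nrow(X)`.
#' @param linkage `hclust` agglomeration method.
#' @param feature_kind label recorded on the result (e.g. `"orc_rna"`).
#' @return Object of class `cluster_assignment`: `labels` (named integer
#'   vector, contiguous from 1), `k`, `linkage`, `feature_kind`.
#' @export
hierarchical_cluster <- function(X, k, linkage = "ward.D2",
                                 feature_kind = "orc_rna") {
  X <- as.matrix(X)
  if (k < 1 || k > nrow(X)) stop("k must be between 1 and the sample count")
  hc <- stats::hclust(stats::dist(X), method = linkage)
  labels <- stats::cutree(hc, k = k)
  if (is.null(names(labels))) names(labels) <- rownames(X)
  structure(list(labels = labels, k = k, linkage = linkage,
                 feature_kind = feature_kind), class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment [%s]: %d samples in %d clusters (%s)\n",
              x$feature_kind, length(x$labels), x$k, x$linkage))
  print(table(x$labels))
  invisible(x)
}

#' Select the number of clusters by mean silhouette score
#'
#' Clusters at every k in `k_range` and picks the k maximizing the mean
#' silhouette width (cohesion vs nearest-cluster separation); ties go to the
#' smallest k. Samples in singleton clusters contribute silhouette width 0
#' (the convention used by [cluster::silhouette()]).
#'
#' @param X samples-by-features matrix.
#' @param k_range candidate cluster counts, a subset of 2..(n-1). Default
#'   2:12, truncated to the sample count.
#' @param linkage `hclust` agglomeration method.
#' @return List with `k` (selected), `scores` (named mean silhouettes).
#' @export
select_k_silhouette <- function(X, k_range = 2:12, linkage = "ward.D2") {
  X <- as.matrix(X)
  n <- nrow(X)
  k_range <- k_range[k_range >= 2 & k_range <= n - 1]
  if (length(k_range) == 0) stop("empty k range after restricting to 2..(n-1)")
  d <- stats::dist(X)
  hc <- stats::hclust(d, method = linkage)
  scores <- vapply(k_range, function(k) {
    sil <- cluster::silhouette(stats::cutree(hc, k = k), d)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(scores) <- k_range
  k_best <- k_range[which.max(scores)]   # which.max takes the first maximum
  list(k = k_best, scores = scores)
}

#' Combine clusters into high/low-risk groups
#'
#' Manual mode applies a user mapping verbatim (the fidelity path: the study
#' design groups clusters by inspecting Kaplan-Meier curves). Auto mode ranks
#' clusters by median Kaplan-Meier survival and marks the bottom third of
#' clusters high-risk, the top third low-risk, and the middle excluded.
#'
#' @param assign a `cluster_assignment`.
#' @param clinical a `clinical_table` covering the assigned samples (needed
#'   for auto mode).
#' @param mode `"manual"` or `"auto"`.
#' @param mapping manual mode: named vector mapping cluster label ->
#'   `"high"`/`"low"`/`"excluded"`; clusters absent from the mapping are
#'   excluded.
#' @param quantile auto mode: fraction of clusters in each extreme group
#'   (default 1/3).
#' @param min_size_frac auto mode: clusters holding fewer than this
#'   fraction of the samples are never chosen as a risk extreme (their
#'   Kaplan-Meier medians are too unstable to anchor a group); they are
#'   marked excluded. Ignored if it would leave fewer than two eligible
#'   clusters. Default 0.05.
#' @return Object of class `risk_grouping`: `groups` (named character vector
#'   sample -> high/low/excluded), `provenance`, `cluster_of` (sample ->
#'   cluster).
#' @export
assign_risk_groups <- function(assign, clinical = NULL,
                               mode = c("auto", "manual"), mapping = NULL,
                               quantile = 1 / 3, min_size_frac = 0.05) {
  mode <- match.arg(mode)
  labels <- assign$labels
  clusters <- sort(unique(labels))
  if (length(clusters) < 2) stop("risk grouping needs at least 2 clusters")
  if (mode == "manual") {
    if (is.null(mapping)) stop("manual mode requires a mapping")
    unknown <- setdiff(names(mapping), as.character(clusters))
    if (length(unknown) > 0)
      stop("mapping names unknown cluster(s): ", paste(unknown, collapse = ", "))
    bad <- setdiff(mapping, c("high", "low", "excluded"))
    if (length(bad) > 0) stop("mapping values must be high/low/excluded")
    grp <- rep("excluded", length(labels))
    hit <- as.character(labels) %in% names(mapping)
    grp[hit] <- unname(mapping[as.character(labels)[hit]])
  } else {
    if (is.null(clinical)) stop("auto mode requires the clinical table")
    clinical <- clinical_table(as.data.frame(clinical))
    idx <- match(names(labels), clinical$sample)
    if (anyNA(idx)) stop("clinical table does not cover all samples")
    sizes <- table(labels)[as.character(clusters)]
    eligible <- clusters[sizes >= min_size_frac * length(labels)]
    if (length(eligible) >= 2) clusters <- eligible
    med <- vapply(clusters, function(cl) {
      sel <- labels == cl
      fit <- survival::survfit(
        survival::Surv(clinical$pfs_time[idx][sel],
                       clinical$event[idx][sel]) ~ 1)
      m <- unname(summary(fit)$table["median"])
      if (is.na(m)) Inf else m            # median never reached = best outcome
    }, numeric(1))
    ord <- order(med, clusters)           # worst survival first; label breaks ties
    n_ext <- max(1L, floor(length(clusters) * quantile))
    high_cl <- clusters[ord][seq_len(n_ext)]
    low_cl <- clusters[ord][length(clusters) - seq_len(n_ext) + 1L]
    grp <- rep("excluded", length(labels))
    grp[labels %in% high_cl] <- "high"
    grp[labels %in% low_cl] <- "low"
  }
  names(grp) <- names(labels)
  if (!any(grp == "high") || !any(grp == "low"))
    stop("risk grouping left the high or low group empty")
  structure(list(groups = grp, provenance = mode, cluster_of = labels),
            class = "risk_grouping")
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("risk_grouping (%s):\n", x$provenance))
  print(table(x$groups))
  invisible(x)
}

#' Annotate samples as hyperdiploid from copy-number segments
#'
#' Hyperdiploidy calls follow the odd-chromosome gain rule: a sample is
#' hyperdiploid when more than 2 of chromosomes 3, 5, 7, 9, 11, 15, 19, 21
#' each have copy-number gains (copy state > 2) covering more than 60% of the
#' chromosome.
#'
#' @param segments data frame with columns `sample`, `chrom`, `start`, `end`,
#'   `copy_state`. Chromosome names may carry a `chr` prefix.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximum segment end observed per chromosome.
#' @param gain_fraction,min_chroms rule parameters (defaults: >0.60 of the
#'   chromosome, on >2 i.e. at least 3 chromosomes).
#' @return Named logical vector, one entry per sample.
#' @export
annotate_hyperdiploidy <- function(segments, chrom_lengths = NULL,
                                   gain_fraction = 0.60, min_chroms = 3L) {
  req <- c("sample", "chrom", "start", "end", "copy_state")
  if (!all(req %in% colnames(segments)))
    stop("segments need columns: ", paste(req, collapse = ", "))
  hrd_chroms <- c("3", "5", "7", "9", "11", "15", "19", "21")
  chrom <- sub("^chr", "", as.character(segments$chrom))
  known <- chrom %in% c(as.character(1:22), "X", "Y")
  if (any(!known)) {
    warning("ignoring segments on unknown chromosome(s): ",
            paste(unique(chrom[!known]), collapse = ", "))
    segments <- segments[known, , drop = FALSE]
    chrom <- chrom[known]
  }
  segments$chrom <- chrom
  if (is.null(chrom_lengths)) {
    chrom_lengths <- tapply(segments$end, segments$chrom, max)
  } else {
    names(chrom_lengths) <- sub("^chr", "", names(chrom_lengths))
  }
  samples <- unique(segments$sample)
  out <- vapply(samples, function(s) {
    seg <- segments[segments$sample == s & segments$chrom %in% hrd_chroms &
                    segments$copy_state > 2, , drop = FALSE]
    if (nrow(seg) == 0) return(FALSE)
    gained <- tapply(pmax(seg$end - seg$start, 0), seg$chrom, sum)
    frac <- gained / chrom_lengths[names(gained)]
    sum(frac > gain_fraction) >= min_chroms
  }, logical(1))
  names(out) <- samples
  out
}

#' Cluster-feature association by Fisher's exact test
#'
#' Two-sided Fisher's exact test on the 2x2 table of cluster membership
#' (in the given cluster vs all remaining samples) against a binary sample
#' feature.
#'
#' @param assign a `cluster_assignment`.
#' @param feature named logical vector over the assigned samples.
#' @param cluster cluster label to contrast against the rest.
#' @return List with `odds_ratio` (conditional MLE; `NA` and `degenerate =
#'   TRUE` when the table has an empty margin), `p`, and the 2x2 `table`.
#' @export
cluster_feature_association <- function(assign, feature, cluster) {
  labels <- assign$labels
  if (!cluster %in% labels) stop("no samples in cluster ", cluster)
  if (all(labels == cluster)) stop("cluster covers all samples; no contrast")
  f <- feature[names(labels)]
  if (anyNA(f)) stop("feature must cover every assigned sample")
  tab <- table(factor(labels == cluster, levels = c(TRUE, FALSE)),
               factor(f, levels = c(TRUE, FALSE)),
               dnn = c("in_cluster", "feature"))
  if (length(unique(f)) == 1) {
    return(list(odds_ratio = NA_real_, p = 1, table = tab, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p = ft$p.value, table = tab,
       degenerate = FALSE)
}
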