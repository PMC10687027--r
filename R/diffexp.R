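#' Median-of-ratios size factors
#'
#' Per-sample normalization factors in the median-of-ratios style: for every
#' gene with all-positive counts, compute the per-sample ratio of its count
#' to the gene's geometric mean across samples; the size factor of a sample
#' is the median of these ratios.
#'
#' @param counts an `omics_matrix` of kind `counts`, or a genes-by-samples
#'   count matrix.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  m <- if (inherits(counts, "omics_matrix")) counts$values else as.matrix(counts)
  if (any(m < 0)) stop("counts must be nonnegative")
  allpos <- rowSums(m > 0) == ncol(m)
  if (!any(allpos))
    stop("no gene has positive counts in every sample; ",
         "consider adding a pseudocount upstream")
  ref <- m[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(ref)))
  sf <- apply(ref / geo, 2, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

#' Negative-binomial two-group differential expression test
#'
#' A self-contained NB Wald test between high- and low-risk groups:
#' counts are normalized by median-of-ratios size factors; a per-gene NB
#' dispersion is estimated by the method of moments on the normalized counts
#' (pooled within-group, floored at 1e-8); the group effect is fitted by an
#' NB log-linear model with a log size-factor offset and tested by a Wald z
#' on the group coefficient; p-values are BH-adjusted over the tested genes.
#' No shrinkage and no independent filtering are applied. The reported log2
#' fold change (high vs low) is the ratio of normalized group means, with a
#' 0.5 pseudocount on both means whenever either group mean is zero.
#' Genes with zero counts in all samples are excluded (reported in
#' `attr(, "excluded")`).
#'
#' @param counts an `omics_matrix` of kind `counts` (or genes-by-samples
#'   matrix).
#' @param groups named character vector sample -> `"high"`/`"low"`, or a
#'   `risk_grouping` (whose `"excluded"` samples are dropped). Each group
#'   needs at least 3 samples.
#' @return Object of class `de_result`: data frame `gene`, `baseMean`,
#'   `log2FC` (high vs low), `p`, `q`, `direction` (`over` iff log2FC > 0),
#'   `flag`.
#' @export
nb_two_group_test <- function(counts, groups) {
  m <- if (inherits(counts, "omics_matrix")) counts$values else as.matrix(counts)
  if (inherits(groups, "risk_grouping")) groups <- groups$groups
  groups <- groups[groups %in% c("high", "low")]
  keep <- intersect(colnames(m), names(groups))
  m <- m[, keep, drop = FALSE]
  groups <- groups[keep]
  n_h <- sum(groups == "high"); n_l <- sum(groups == "low")
  if (n_h < 3 || n_l < 3)
    stop("each group needs at least 3 samples (high=", n_h, ", low=", n_l, ")")

  sf <- size_factors(m)
  norm <- sweep(m, 2, sf, "/")
  allzero <- rowSums(m) == 0
  excluded <- rownames(m)[allzero]
  genes <- rownames(m)[!allzero]

  hi <- groups == "high"
  grp <- factor(ifelse(hi, "high", "low"), levels = c("low", "high"))
  res <- lapply(genes, function(g) {
    y <- m[g, ]
    ny <- norm[g, ]
    mu_h <- mean(ny[hi]); mu_l <- mean(ny[!hi])
    if (mu_h == 0 || mu_l == 0) {
      lfc <- log2((mu_h + 0.5) / (mu_l + 0.5))
      flag <- "pseudocount_lfc"
    } else {
      lfc <- log2(mu_h / mu_l)
      flag <- "ok"
    }
    # method-of-moments dispersion, pooled across the two groups
    vh <- stats::var(ny[hi]); vl <- stats::var(ny[!hi])
    disp_h <- if (mu_h > 0) (vh - mu_h) / mu_h^2 else 0
    disp_l <- if (mu_l > 0) (vl - mu_l) / mu_l^2 else 0
    disp <- max((disp_h * (n_h - 1) + disp_l * (n_l - 1)) / (n_h + n_l - 2),
                1e-8)
    p <- tryCatch({
      fit <- suppressWarnings(
        stats::glm(y ~ grp + offset(log(sf)),
                   family = MASS::negative.binomial(theta = 1 / disp)))
      co <- summary(fit, dispersion = 1)$coefficients
      if (!"grphigh" %in% rownames(co)) NA_real_ else co["grphigh", "Pr(>|z|)"]
    }, error = function(e) NA_real_)
    if (is.na(p)) flag <- "no_convergence"
    data.frame(gene = g, baseMean = mean(ny), log2FC = lfc, p = p,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- NA_real_
  tested <- !is.na(out$p)
  out$q[tested] <- bh_fdr(out$p[tested])
  out$direction <- ifelse(out$log2FC > 0, "over", "under")
  out <- out[, c("gene", "baseMean", "log2FC", "p", "q", "direction", "flag")]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  attr(out, "size_factors") <- sf
  class(out) <- c("de_result", class(out))
  out
}

#' Select significant genes by the strict q-value / fold-change filter
#'
#' A gene is selected when its BH-adjusted p-value is strictly below `q_max`
#' and its absolute log2 fold change is strictly above `lfc_min` (defaults:
#' q < 0.05 and |log2FC| > 3.5).
#'
#' @param de a `de_result`.
#' @param q_max,lfc_min strict thresholds.
#' @return Data frame of selected genes with their `log2FC`, `q` and
#'   `direction`, partitioned by the `direction` column.
#' @export
select_significant <- function(de, q_max = 0.05, lfc_min = 3.5) {
  if (nrow(de) == 0) stop("empty DE result")
  sel <- !is.na(de$q) & de$q < q_max & abs(de$log2FC) > lfc_min
  out <- de[sel, c("gene", "log2FC", "q", "direction"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation of gene sets
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set, against a gene universe; BH adjustment across sets.
#' Gene sets are intersected with the universe first.
#'
#' @param query character vector of genes (must be a subset of `universe`).
#' @param sets a `gene_set_collection` (named list of gene vectors).
#' @param universe character vector of background genes.
#' @return Data frame of class `enrichment_result`: `set`, `overlap`,
#'   `set_size`, `universe_size`, `p`, `q`, plus the overlap genes in
#'   `attr(, "overlap_genes")`.
#' @export
hypergeom_enrichment <- function(query, sets, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe)) stop("query genes must lie in the universe")
  N <- length(universe); n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, universe_size = N,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  attr(out, "overlap_genes") <-
    lapply(stats::setNames(names(sets), names(sets)),
           function(nm) intersect(intersect(sets[[nm]], universe), query))
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", class(out))
  out
}
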