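#' Simulation configuration for synthetic cohorts
#'
#' Defines the study conditions emulated by the generator: a scale-free
#' interactome with mean degree about 8, negative-binomial read counts with
#' planted subtype expression modules, copy-number aberrations with
#' gene-dosage coupling (including a planted hyperdiploid subtype), and
#' subtype- plus gene-linked exponential survival with uniform censoring.
#'
#' Module genes carry a centered expression contrast: a module gene of
#' subtype k is up-shifted by `module_shift` log2 units in samples of
#' subtype k and down-shifted by the same amount in all other samples, so
#' the realized between-subtype log2 fold change is `2 * module_shift`.
#'
#' @param n_genes number of genes (>= 10). Default 300.
#' @param n_samples cohort size. Default 200.
#' @param n_subtypes number of planted subtypes K. Default 3.
#' @param interactome list: `model` (`"barabasi_albert"` with parameter `m`,
#'   or `"configuration"` with `mean_degree`). Default BA with m = 4, giving
#'   mean degree near 8.
#' @param module_fraction fraction of genes in each subtype's expression
#'   module. Default 0.10.
#' @param module_shift half-amplitude (log2 units) of the centered module
#'   contrast. Default 2.0.
#' @param nb_dispersion NB dispersion of counts (variance = mu + disp*mu^2).
#'   Default 0.2, a typical bulk RNA-seq scale.
#' @param bio_sd per-gene, per-sample biological variability of the latent
#'   log2 expression (SD in log2 units, on top of the sequencing noise).
#'   Default 1.0 (about two-fold typical variation). This latent variation
#'   is what the planted prognostic signature lives in.
#' @param cna_profiles per-subtype list of data frames (`chrom`, `frac`,
#'   `copy`) describing arm-scale events; the default plants a hyperdiploid
#'   subtype 1 (70% gains of chromosomes 3, 5, 7, 9, 11, 15), a quiet
#'   subtype 2, and a subtype 3 with a chr1 gain plus chr13 loss.
#' @param cna_event_prob probability that each profile event is realized in
#'   a given sample. Default 0.9.
#' @param dosage_exponent exponent coupling copy number to expression mean,
#'   mu ~ (copy/2)^gamma. Default 1.
#' @param baseline_hazard baseline event rate (per year). Default 0.25.
#' @param subtype_loghr per-subtype log hazard ratios; by default all
#'   subtypes sit at the reference hazard except the last, which is the
#'   high-risk subtype at hazard ratio 3.
#' @param n_prognostic number of planted prognostic genes (drawn outside the
#'   modules and outside the CNA event regions). Default 8.
#' @param prognostic_beta log-hazard per SD of the latent prognostic
#'   signature (see `prognostic_factor_loading`). Default 0.8.
#' @param prognostic_factor_loading the planted prognostic genes behave as a
#'   co-regulated signature: each gene's latent expression loads on one
#'   shared per-sample factor with this loading (the remainder is
#'   gene-specific), and the survival hazard acts on the shared factor.
#'   Default 0.9.
#' @param censor_horizon censoring horizon in years (censoring times are
#'   uniform on (0, horizon)). Default 8.
#' @param seed mandatory RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_genes = 300, n_samples = 200, n_subtypes = 3,
                       interactome = list(model = "barabasi_albert", m = 4),
                       module_fraction = 0.10, module_shift = 2.0,
                       nb_dispersion = 0.2, bio_sd = 1.0,
                       cna_profiles = NULL, cna_event_prob = 0.9,
                       dosage_exponent = 1,
                       baseline_hazard = 0.25,
                       subtype_loghr = NULL,
                       n_prognostic = 8, prognostic_beta = 0.8,
                       prognostic_factor_loading = 0.9,
                       censor_horizon = 8, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_genes < 10) stop("n_genes must be at least 10")
  if (module_fraction * n_genes < 1)
    stop("module fraction times gene count must be at least 1")
  if (is.null(subtype_loghr)) {
    subtype_loghr <- rep(0, n_subtypes)
    subtype_loghr[n_subtypes] <- log(3)
  }
  if (length(subtype_loghr) != n_subtypes)
    stop("subtype_loghr must have one entry per subtype")
  if (is.null(cna_profiles)) {
    cna_profiles <- rep(list(NULL), n_subtypes)
    cna_profiles[[1]] <- data.frame(chrom = c(3, 5, 7, 9, 11, 15),
                                    frac = 0.7, copy = 3)
    if (n_subtypes >= 3)
      cna_profiles[[3]] <- data.frame(chrom = c(1, 13), frac = c(0.4, 0.7),
                                      copy = c(3, 1))
  }
  if (cna_event_prob < 0 || cna_event_prob > 1)
    stop("cna_event_prob must lie in [0, 1]")
  structure(list(n_genes = n_genes, n_samples = n_samples,
                 n_subtypes = n_subtypes, interactome = interactome,
                 module_fraction = module_fraction,
                 module_shift = module_shift, nb_dispersion = nb_dispersion,
                 bio_sd = bio_sd,
                 cna_profiles = cna_profiles, cna_event_prob = cna_event_prob,
                 dosage_exponent = dosage_exponent,
                 baseline_hazard = baseline_hazard,
                 subtype_loghr = subtype_loghr,
                 n_prognostic = n_prognostic,
                 prognostic_beta = prognostic_beta,
                 prognostic_factor_loading = prognostic_factor_loading,
                 censor_horizon = censor_horizon, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a scale-free interactome
#'
#' The default Barabasi-Albert model starts from `m` edgeless seed nodes;
#' the first newcomer links to all of them (so the graph is connected by
#' construction) and every later node attaches `m` edges preferentially
#' (weights degree + 1). The edge count is exactly `(n - m) * m` and the
#' mean degree approaches `2m` for large n. A configuration-model
#' alternative targets a given mean degree with Poisson degrees.
#'
#' @param cfg a [sim_config()] (only `n_genes`, `interactome` and `seed` are
#'   used).
#' @return A connected `interaction_network` over genes `G0001`, `G0002`,
#'   ...
#' @export
simulate_interactome <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_genes
  genes <- sprintf("G%04d", seq_len(n))
  model <- cfg$interactome$model
  if (identical(model, "barabasi_albert")) {
    m <- cfg$interactome$m
    if (is.null(m) || m < 1 || m >= n) stop("invalid BA parameter m")
    deg <- integer(n)
    from <- integer((n - m) * m)
    to <- integer((n - m) * m)
    k <- 0L
    for (t in (m + 1):n) {
      existing <- seq_len(t - 1L)
      targets <- sample(existing, m, prob = deg[existing] + 1)
      for (tg in targets) {
        k <- k + 1L
        from[k] <- t; to[k] <- tg
        deg[t] <- deg[t] + 1L
        deg[tg] <- deg[tg] + 1L
      }
    }
    net <- interaction_network(cbind(genes[from], genes[to]), nodes = genes)
  } else if (identical(model, "configuration")) {
    md <- cfg$interactome$mean_degree
    if (is.null(md) || md < 2) stop("configuration model needs mean_degree >= 2")
    degs <- pmax(1L, stats::rpois(n, md))
    if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1L
    g <- igraph::sample_degseq(degs, method = "configuration")
    g <- igraph::simplify(g)
    ed <- igraph::as_edgelist(g)
    net <- interaction_network(cbind(genes[ed[, 1]], genes[ed[, 2]]),
                               nodes = genes)
    net <- largest_connected_component(net)
  } else {
    stop("unknown interactome model: ", model)
  }
  net
}

#' Simulate a full synthetic cohort over an interactome
#'
#' Generates counts, TPM, gene-level copy number, a per-sample segment
#' table, a clinical table and a ground-truth manifest. Counts are NB with
#' mean = library size x gene baseline x 2^(module contrast) x
#' (copy/2)^gamma; TPM is the per-sample normalization of counts to one
#' million (gene lengths fixed at 1, so TPM coincides with CPM). Survival
#' times are exponential with log hazard = log(baseline) + subtype effect +
#' sum of planted gene effects on z-scored log2(TPM+1); censoring times are
#' uniform on (0, horizon).
#'
#' @param net a connected `interaction_network` (typically from
#'   [simulate_interactome()]).
#' @param cfg a [sim_config()].
#' @return List of class `synthetic_cohort`: `network`, `counts`, `tpm`,
#'   `cna` (all `omics_matrix`), `segments`, `clinical`, `ground_truth`.
#' @export
simulate_cohort <- function(net, cfg) {
  force(net)          # evaluate before seeding (the argument may use the RNG)
  set.seed(cfg$seed + 1L)
  genes <- net$nodes
  n <- length(genes)
  ns <- cfg$n_samples
  K <- cfg$n_subtypes
  samples <- sprintf("S%04d", seq_len(ns))

  subtype <- stats::setNames(sample(rep_len(seq_len(K), ns)), samples)

  # planted expression modules: disjoint random gene blocks, one per subtype
  msize <- max(1L, round(cfg$module_fraction * n))
  pool <- sample(genes)
  modules <- lapply(seq_len(K), function(k)
    sort(pool[((k - 1) * msize + 1):(k * msize)]))
  names(modules) <- paste0("subtype", seq_len(K))
  nonmodule <- setdiff(genes, unlist(modules))

  # gene -> chromosome map (round robin over 22 autosomes, 1 Mb per gene)
  chrom <- ((seq_len(n) - 1L) %% 22L) + 1L
  pos <- integer(n)
  for (c22 in 1:22) pos[chrom == c22] <- seq_len(sum(chrom == c22))
  chrom_len <- stats::setNames(tapply(pos, chrom, max) * 1e6,
                               as.character(1:22))

  # genes that any subtype's CNA profile can hit (kept out of the
  # prognostic set so planted hazards are not dosage-confounded)
  cna_hit <- rep(FALSE, n)
  for (prof in cfg$cna_profiles) {
    if (is.null(prof)) next
    for (k in seq_len(nrow(prof))) {
      L <- chrom_len[[as.character(prof$chrom[k])]]
      cna_hit <- cna_hit |
        (chrom == prof$chrom[k] & (pos - 0.5) * 1e6 <= prof$frac[k] * L)
    }
  }

  # planted prognostic genes: outside the modules and the CNA regions
  free <- setdiff(nonmodule, genes[cna_hit])
  prog <- sort(sample(free, min(cfg$n_prognostic, length(free))))

  # realized CNA events and segment table
  seg_list <- list()
  copy <- matrix(2, n, ns, dimnames = list(genes, samples))
  hyperdiploid <- stats::setNames(logical(ns), samples)
  hrd_set <- c(3, 5, 7, 9, 11, 15, 19, 21)
  for (s in samples) {
    prof <- cfg$cna_profiles[[subtype[s]]]
    events <- if (is.null(prof)) prof[0, ] else
      prof[stats::runif(nrow(prof)) < cfg$cna_event_prob, , drop = FALSE]
    n_hrd_gains <- 0L
    rows <- list()
    for (c22 in 1:22) {
      L <- chrom_len[[as.character(c22)]]
      ev <- if (!is.null(events) && nrow(events) > 0)
        events[events$chrom == c22, , drop = FALSE] else NULL
      if (!is.null(ev) && nrow(ev) > 0) {
        f <- ev$frac[1]; cp <- ev$copy[1]
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = as.character(c22),
          start = c(0, f * L), end = c(f * L, L),
          copy_state = c(cp, 2), stringsAsFactors = FALSE)
        hit <- chrom == c22 & (pos - 0.5) * 1e6 <= f * L
        copy[hit, s] <- cp
        if (cp > 2 && f > 0.6 && c22 %in% hrd_set)
          n_hrd_gains <- n_hrd_gains + 1L
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, chrom = as.character(c22), start = 0, end = L,
          copy_state = 2, stringsAsFactors = FALSE)
      }
    }
    hyperdiploid[s] <- n_hrd_gains >= 3L
    seg_list[[s]] <- do.call(rbind, rows)
  }
  segments <- do.call(rbind, seg_list)
  rownames(segments) <- NULL

  # NB counts with module contrast and dosage coupling
  baseline <- stats::setNames(stats::rlnorm(n, log(100), 1), genes)
  libsize <- stats::setNames(stats::rlnorm(ns, 0, 0.2), samples)
  shift <- matrix(0, n, ns, dimnames = list(genes, samples))
  for (k in seq_len(K)) {
    mg <- modules[[k]]
    own <- subtype == k
    shift[mg, own] <- cfg$module_shift
    shift[mg, !own] <- -cfg$module_shift
  }
  bio <- matrix(stats::rnorm(n * ns, 0, cfg$bio_sd), n, ns,
                dimnames = list(genes, samples))
  # prognostic genes form a co-regulated signature: shared latent factor
  # plus gene-specific remainder, at the same total biological variance
  lam <- cfg$prognostic_factor_loading
  factor_score <- stats::rnorm(ns)
  # the signature is independent of subtype by design; enforce exact
  # in-sample orthogonality so finite cohorts carry no spurious confounding
  factor_score <- factor_score -
    stats::ave(factor_score, subtype, FUN = mean)
  factor_score <- factor_score / stats::sd(factor_score)
  for (g in prog)
    bio[g, ] <- cfg$bio_sd *
      (lam * factor_score + sqrt(1 - lam^2) * stats::rnorm(ns))
  mu <- outer(baseline, libsize) * 2^(shift + bio) *
    (copy / 2)^cfg$dosage_exponent
  cts <- matrix(stats::rnbinom(n * ns, mu = mu, size = 1 / cfg$nb_dispersion),
                n, ns, dimnames = list(genes, samples))
  tpm <- sweep(cts, 2, colSums(cts), "/") * 1e6

  # survival: subtype hazard plus the prognostic-signature effect
  loghaz <- log(cfg$baseline_hazard) + cfg$subtype_loghr[subtype] +
    cfg$prognostic_beta * factor_score
  T_event <- stats::rexp(ns, rate = exp(loghaz))
  # staggered-entry censoring: everyone is followed to at least half the
  # horizon, censoring times spread uniformly up to the horizon
  C_cens <- stats::runif(ns, cfg$censor_horizon / 2, cfg$censor_horizon)
  pfs <- pmax(pmin(T_event, C_cens), 1e-3)
  clin <- clinical_table(data.frame(
    sample = samples, pfs_time = pfs,
    event = as.integer(T_event <= C_cens),
    iss = sample(c("I", "II", "III"), ns, replace = TRUE,
                 prob = c(0.35, 0.40, 0.25)),
    stringsAsFactors = FALSE))

  ground_truth <- list(
    subtype = subtype, modules = modules,
    module_shift = cfg$module_shift,
    de_contrast = 2 * cfg$module_shift,
    prognostic_genes = prog, prognostic_beta = cfg$prognostic_beta,
    prognostic_factor = stats::setNames(factor_score, samples),
    subtype_loghr = cfg$subtype_loghr,
    hyperdiploid = hyperdiploid)

  structure(list(network = net,
                 counts = omics_matrix(cts, "counts"),
                 tpm = omics_matrix(tpm, "tpm"),
                 cna = omics_matrix(copy, "cna"),
                 segments = segments, clinical = clin,
                 ground_truth = ground_truth, config = cfg),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d genes, %d samples, %d subtypes\n",
              length(x$network$nodes), length(x$clinical$sample),
              x$config$n_subtypes))
  invisible(x)
}

#' Write a synthetic cohort to a directory in the standard text formats
#'
#' Emits `network.tsv` (edge list), `counts.tsv`, `tpm.tsv`, `cna.tsv`,
#' `segments.tsv`, `clinical.tsv` and `ground_truth.json`.
#'
#' @param sim a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(network = file.path(dir, "network.tsv"),
             counts = file.path(dir, "counts.tsv"),
             tpm = file.path(dir, "tpm.tsv"),
             cna = file.path(dir, "cna.tsv"),
             segments = file.path(dir, "segments.tsv"),
             clinical = file.path(dir, "clinical.tsv"),
             ground_truth = file.path(dir, "ground_truth.json"))
  write_edge_list(sim$network, paths["network"])
  write_omics(sim$counts, paths["counts"])
  write_omics(sim$tpm, paths["tpm"])
  write_omics(sim$cna, paths["cna"])
  utils::write.table(sim$segments, paths["segments"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_clinical(sim$clinical, paths["clinical"])
  gt <- sim$ground_truth
  jsonlite::write_json(
    list(subtype = as.list(gt$subtype), modules = gt$modules,
         module_shift = gt$module_shift, de_contrast = gt$de_contrast,
         prognostic_genes = gt$prognostic_genes,
         prognostic_beta = gt$prognostic_beta,
         subtype_loghr = gt$subtype_loghr,
         hyperdiploid = as.list(gt$hyperdiploid)),
    paths["ground_truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
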