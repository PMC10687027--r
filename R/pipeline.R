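#' Run the full curvature analysis pipeline from one configuration
#'
#' Orchestrates simulate/ingest -> harmonize -> per-sample curvature ->
#' clustering (silhouette-selected k) -> risk grouping -> survival analysis
#' (Kaplan-Meier, log-rank, univariate Cox) -> differential expression with
#' the strict significance filter -> optional gene-set over-representation
#' -> network topology reports, writing every stage's outputs as plain-text
#' files plus a machine-readable run manifest.
#'
#' Stages are resumable: when a stage's output files already exist in the
#' output directory and the configuration hash matches the previous run's
#' manifest, the stage is skipped and its outputs are reused. Deleting a
#' stage's files forces only that stage (and nothing upstream) to recompute.
#'
#' The YAML configuration has the sections `seed` (integer, required),
#' `simulate` (generator settings, see [sim_config()]) or `inputs` (paths:
#' `edge_list`, `tpm`, `counts`, `cna`, `clinical`), and optional `curvature`
#' (`kind`, `pseudocount_eps`, `ground_metric`), `cluster` (`k` = "auto" or
#' an integer, `k_max`, `linkage`, `standardize`), `risk` (`mode`,
#' `quantile`, or a `mapping`), `diffexp` (`q_max`, `lfc_min`), `enrichment`
#' (`gmt` path), `topology` (`genes` = "auto" or a list, `k`).
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param out_dir output directory; defaults to `output_dir` from the config.
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  validate_pipeline_config(cfg)
  out_dir <- out_dir %||% cfg$output_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cfg_hash <- config_hash(cfg)
  prev <- file.path(out_dir, "manifest.json")
  prev_hash <- if (file.exists(prev))
    jsonlite::read_json(prev)$config_hash else NULL
  cache_ok <- identical(prev_hash, cfg_hash)

  manifest <- list(config_hash = cfg_hash, seed = cfg$seed,
                   version = as.character(utils::packageVersion("orcnet")),
                   stages = list(), inputs = list(), outputs = list())
  t_stage <- function(name, paths, compute) {
    t0 <- Sys.time()
    cached <- cache_ok && all(file.exists(paths))
    if (!cached) compute()
    manifest$stages[[name]] <<- list(
      cached = cached,
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    manifest$outputs[[name]] <<- as.list(unname(tools::md5sum(paths)))
    names(manifest$outputs[[name]]) <<- basename(paths)
    invisible(NULL)
  }

  # --- ingest -------------------------------------------------------------
  cohort_files <- file.path(out_dir, c("network.tsv", "tpm.tsv", "counts.tsv",
                                       "cna.tsv", "segments.tsv",
                                       "clinical.tsv"))
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    gt_file <- file.path(out_dir, "ground_truth.json")
    t_stage("ingest", c(cohort_files, gt_file), function() {
      net <- simulate_interactome(scfg)
      sim <- simulate_cohort(net, scfg)
      write_cohort(sim, out_dir)
    })
  } else {
    inp <- cfg$inputs
    manifest$inputs <- as.list(tools::md5sum(unlist(inp)))
    t_stage("ingest", cohort_files, function() {
      file.copy(inp$edge_list, cohort_files[1], overwrite = TRUE)
      file.copy(inp$tpm, cohort_files[2], overwrite = TRUE)
      file.copy(inp$counts, cohort_files[3], overwrite = TRUE)
      if (!is.null(inp$cna))
        file.copy(inp$cna, cohort_files[4], overwrite = TRUE)
      else write_omics(omics_matrix(matrix(2, 0, 0)[FALSE, , drop = FALSE],
                                    "cna"), cohort_files[4])
      if (!is.null(inp$segments))
        file.copy(inp$segments, cohort_files[5], overwrite = TRUE)
      else writeLines("sample\tchrom\tstart\tend\tcopy_state",
                      cohort_files[5])
      file.copy(inp$clinical, cohort_files[6], overwrite = TRUE)
    })
  }

  net <- read_edge_list(file.path(out_dir, "network.tsv"))
  tpm <- read_omics(file.path(out_dir, "tpm.tsv"), "tpm")
  counts <- read_omics(file.path(out_dir, "counts.tsv"), "counts")
  cna <- tryCatch(read_omics(file.path(out_dir, "cna.tsv"), "cna"),
                  error = function(e) NULL)
  clinical <- read_clinical(file.path(out_dir, "clinical.tsv"))
  mats <- Filter(Negate(is.null), list(tpm, counts, cna))
  cohort <- harmonize(net, mats, clinical)

  # --- curvature ----------------------------------------------------------
  ccfg <- cfg$curvature %||% list()
  kind <- ccfg$kind %||% "rna"
  oc <- orc_config(pseudocount_eps = ccfg$pseudocount_eps %||% 0.01,
                   ground_metric = ccfg$ground_metric %||% "weighted")
  curv_file <- file.path(out_dir, sprintf("curvature_%s.tsv", kind))
  t_stage("curvature", curv_file, function() {
    write_curvature(curvature_matrix(cohort, kind, oc), curv_file)
  })
  curv <- read_curvature(curv_file, kind)

  # --- clustering ---------------------------------------------------------
  kcfg <- cfg$cluster %||% list()
  clus_files <- file.path(out_dir, c("clusters.tsv", "silhouette.tsv"))
  t_stage("cluster", clus_files, function() {
    X <- feature_matrix(curv, standardize = isTRUE(kcfg$standardize))
    linkage <- kcfg$linkage %||% "ward.D2"
    if (is.null(kcfg$k) || identical(kcfg$k, "auto")) {
      sel <- select_k_silhouette(X, 2:(kcfg$k_max %||% 12), linkage)
      k <- sel$k
      sil <- data.frame(k = as.integer(names(sel$scores)),
                        mean_silhouette = unname(sel$scores))
    } else {
      k <- as.integer(kcfg$k)
      sil <- data.frame(k = k, mean_silhouette = NA_real_)
    }
    asg <- hierarchical_cluster(X, k, linkage,
                                feature_kind = paste0("orc_", kind))
    utils::write.table(data.frame(sample = names(asg$labels),
                                  cluster = unname(asg$labels)),
                       clus_files[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(sil, clus_files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  cl_df <- utils::read.delim(clus_files[1])
  assign <- structure(list(labels = stats::setNames(cl_df$cluster,
                                                    cl_df$sample),
                           k = length(unique(cl_df$cluster)),
                           linkage = kcfg$linkage %||% "ward.D2",
                           feature_kind = paste0("orc_", kind)),
                      class = "cluster_assignment")

  # --- risk groups --------------------------------------------------------
  rcfg <- cfg$risk %||% list()
  risk_file <- file.path(out_dir, "risk.tsv")
  t_stage("risk", risk_file, function() {
    risk <- if (!is.null(rcfg$mapping))
      assign_risk_groups(assign, cohort$clinical, mode = "manual",
                         mapping = unlist(rcfg$mapping))
    else
      assign_risk_groups(assign, cohort$clinical, mode = "auto",
                         quantile = rcfg$quantile %||% (1 / 3))
    utils::write.table(data.frame(sample = names(risk$groups),
                                  group = unname(risk$groups)),
                       risk_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })
  rk_df <- utils::read.delim(risk_file)
  risk <- structure(list(groups = stats::setNames(rk_df$group, rk_df$sample),
                         provenance = rcfg$mode %||% "auto",
                         cluster_of = assign$labels),
                    class = "risk_grouping")

  # --- survival -----------------------------------------------------------
  surv_files <- file.path(out_dir, c("logrank.tsv", "cox_univariate.tsv"))
  t_stage("survival", surv_files, function() {
    clin <- cohort$clinical
    lr_cl <- logrank_test(times = clin$pfs_time, events = clin$event,
                          labels = assign$labels[clin$sample])
    grp <- risk$groups[clin$sample]
    sel <- grp %in% c("high", "low")
    lr_rk <- logrank_test(times = clin$pfs_time[sel],
                          events = clin$event[sel], labels = grp[sel])
    utils::write.table(
      data.frame(contrast = c("clusters", "risk_groups"),
                 chisq = c(lr_cl$chisq, lr_rk$chisq),
                 df = c(lr_cl$df, lr_rk$df), p = c(lr_cl$p, lr_rk$p)),
      surv_files[1], sep = "\t", quote = FALSE, row.names = FALSE)
    expr <- t(log2(cohort$matrices$tpm$values + 1))
    cox <- cox_fit(expr, clin, mode = "univariate")
    utils::write.table(cox, surv_files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # --- differential expression -------------------------------------------
  dcfg <- cfg$diffexp %||% list()
  de_files <- file.path(out_dir, c("de.tsv", "significant_genes.tsv"))
  t_stage("diffexp", de_files, function() {
    de <- nb_two_group_test(cohort$matrices$counts, risk)
    utils::write.table(de, de_files[1], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    sig <- select_significant(de, dcfg$q_max %||% 0.05,
                              dcfg$lfc_min %||% 3.5)
    utils::write.table(sig, de_files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  })

  # --- enrichment (optional) ---------------------------------------------
  if (!is.null(cfg$enrichment$gmt)) {
    enr_file <- file.path(out_dir, "enrichment.tsv")
    t_stage("enrichment", enr_file, function() {
      sig <- utils::read.delim(de_files[2])
      sets <- read_gmt(cfg$enrichment$gmt)
      enr <- hypergeom_enrichment(intersect(sig$gene, cohort$genes), sets,
                                  cohort$genes)
      utils::write.table(enr, enr_file, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }

  # --- topology -----------------------------------------------------------
  tcfg <- cfg$topology %||% list()
  cls <- classify_degrees(cohort$network)
  topo_genes <- tcfg$genes
  if (is.null(topo_genes) || identical(topo_genes, "auto"))
    topo_genes <- names(which.max(cls$degree))
  topo_genes <- intersect(unlist(topo_genes), cohort$genes)
  topo_files <- file.path(out_dir,
                          c("degree_classes.tsv", "edge_deltas.tsv",
                            sprintf("neighborhood_%s.json", topo_genes)))
  t_stage("topology", topo_files, function() {
    utils::write.table(
      data.frame(gene = names(cls$class), degree = unname(cls$degree),
                 class = unname(cls$class)),
      topo_files[1], sep = "\t", quote = FALSE, row.names = FALSE)
    deltas <- edge_robustness_delta(curv, risk)
    utils::write.table(deltas, topo_files[2], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    for (i in seq_along(topo_genes)) {
      rep <- neighborhood_report(cohort$network, curv, risk, topo_genes[i],
                                 k = tcfg$k %||% 2)
      write_neighborhood_json(rep, topo_files[2 + i])
    }
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: md5 of the canonical JSON form of the config; the output
# location does not affect the analysis and is excluded
config_hash <- function(cfg) {
  cfg$output_dir <- NULL
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# internal: fail fast on malformed pipeline configs
validate_pipeline_config <- function(cfg) {
  if (!is.list(cfg)) stop("config must be a list / YAML mapping")
  known <- c("seed", "output_dir", "simulate", "inputs", "curvature",
             "cluster", "risk", "diffexp", "enrichment", "topology")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed) || !is.numeric(cfg$seed))
    stop("config needs an integer 'seed'")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("config needs either a 'simulate' or an 'inputs' section")
  if (!is.null(cfg$simulate) && !is.null(cfg$inputs))
    stop("'simulate' and 'inputs' are mutually exclusive")
  if (!is.null(cfg$inputs)) {
    req <- c("edge_list", "tpm", "counts", "clinical")
    miss <- setdiff(req, names(cfg$inputs))
    if (length(miss) > 0)
      stop("inputs section missing: ", paste(miss, collapse = ", "))
    for (f in unlist(cfg$inputs))
      if (!file.exists(f)) stop("input file not found: ", f)
  }
  if (!is.null(cfg$curvature$kind) &&
      !cfg$curvature$kind %in% c("rna", "cna"))
    stop("curvature kind must be rna or cna")
  invisible(TRUE)
}
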