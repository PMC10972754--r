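#' Run the full prioritization pipeline
#'
#' Orchestrates simulate (optional) -> TPM normalization -> bait
#' correlation -> cluster calling -> scoring -> ranking as one reproducible
#' run. Inputs come either from a `simulate:` block (the synthetic
#' generator) or from an `inputs:` block naming an annotation GFF3 and the
#' counts/lengths/samples TSVs. All scoring constants default to the
#' published calibration (PCC ramp 0.8--0.9, TPM ramp 1,000--3,000, cluster
#' bonuses 1/0.5, top 68 candidates) and are overridable.
#'
#' Configuration keys (YAML file or nested list): `simulate` (any
#' [sim_config()] argument) or `inputs` (`annotation`, `counts`, `lengths`,
#' `samples`); `bait_id` (defaults to the simulated truth's bait);
#' `scoring` (any [scoring_config()] argument); `clusters` (`external` TSV
#' path, or `max_gap_bp` / `min_classes` for the internal caller);
#' `options` (`log1p`, `tissue_means`, `whitelist_timing`); `seed`.
#'
#' Outputs written to `outdir`: `tpm.tsv`, `pcc.tsv`, `clusters.tsv`,
#' `ranked_all.tsv` (every scored gene, full precision),
#' `candidates_top.tsv` (whitelist/top-n applied, report-rounded),
#' `manifest.yaml`, `run.log`. All outputs are byte-deterministic for a
#' fixed config and seed.
#'
#' @param config Path to a YAML config or an equivalent nested list.
#' @param outdir Output directory, created if absent.
#' @param seed Optional seed overriding the config's.
#' @return Invisibly, a list with `ranked` (full ranked data.frame),
#'   `candidates` (filtered report), `clusters`, `manifest` and the output
#'   paths.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(simulate = list(n_genes = 300, n_scaffolds = 3),
#'                          seed = 7),
#'                     outdir = tempfile("run"))
#' head(out$candidates)
#' }
#' @export
run_pipeline <- function(config, outdir, seed = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("[config] config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("[config] config must be a list or YAML path",
                             call. = FALSE)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character()
  note <- function(stage, ...) {
    line <- paste0("[", stage, "] ", paste0(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }
  opt <- modifyList(list(log1p = FALSE, tissue_means = FALSE,
                         whitelist_timing = "before_top_n"),
                    config$options %||% list())
  if (!is.null(seed)) config$seed <- seed

  # ---- stage: inputs -------------------------------------------------------
  truth <- NULL
  input_paths <- character()
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_dataset(scfg)
    simdir <- file.path(outdir, "simulated")
    write_simulation(sim, simdir)
    genes <- sim$genes
    cm <- sim$counts
    truth <- sim$truth
    input_paths <- c(annotation = file.path(simdir, "genes.gff3"),
                     counts = file.path(simdir, "counts.tsv"),
                     lengths = file.path(simdir, "lengths.tsv"),
                     samples = file.path(simdir, "samples.tsv"))
    note("simulate", "generated ", nrow(genes), " genes, ",
         ncol(cm$counts), " samples (seed ", scfg$seed, ")")
  } else if (!is.null(config$inputs)) {
    ip <- config$inputs
    for (key in c("annotation", "counts", "lengths", "samples")) {
      if (is.null(ip[[key]]))
        stop("[inputs] config$inputs is missing '", key, "'", call. = FALSE)
      if (!file.exists(ip[[key]]))
        stop("[inputs] ", key, " file not found: ", ip[[key]], call. = FALSE)
    }
    genes <- read_gene_annotation(ip$annotation)
    cm <- read_counts_tsv(ip$counts, ip$lengths, ip$samples)
    input_paths <- unlist(ip[c("annotation", "counts", "lengths", "samples")])
    note("inputs", "read ", nrow(genes), " genes, ", ncol(cm$counts), " samples")
  } else {
    stop("[config] config needs either a 'simulate' or an 'inputs' block",
         call. = FALSE)
  }
  missing_ann <- setdiff(rownames(cm$counts), genes$gene_id)
  if (length(missing_ann) > 0)
    stop("[inputs] counts contain gene(s) absent from the annotation: ",
         paste(head(missing_ann, 3), collapse = ", "), call. = FALSE)

  bait_id <- config$bait_id %||% truth$bait_id
  if (is.null(bait_id)) stop("[config] no bait gene: set 'bait_id'", call. = FALSE)
  scoring_args <- config$scoring %||% list()
  cfg <- do.call(scoring_config, scoring_args)

  # ---- stage: normalize ----------------------------------------------------
  tpm <- compute_tpm(cm)
  write.table(data.frame(gene_id = rownames(tpm), tpm, check.names = FALSE),
              file.path(outdir, "tpm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("normalize", "TPM matrix ", nrow(tpm), " x ", ncol(tpm))

  # ---- stage: coexpress ----------------------------------------------------
  pcc_input <- tpm
  if (isTRUE(opt$tissue_means)) {
    tiss <- unique(cm$samples$tissue)
    pcc_input <- vapply(tiss, function(tt) tissue_mean_tpm(tpm, cm$samples, tt),
                        numeric(nrow(tpm)))
    colnames(pcc_input) <- tiss
  }
  pcc <- bait_pcc(pcc_input, bait_id, log1p = isTRUE(opt$log1p))
  write.table(data.frame(gene = pcc$gene_id, pcc = pcc$pcc,
                         defined = tolower(as.character(pcc$defined))),
              file.path(outdir, "pcc.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  note("coexpress", "bait ", bait_id, "; ", sum(!pcc$defined),
       " zero-variance gene(s) flagged undefined")

  # ---- stage: cluster ------------------------------------------------------
  clu_cfg <- config$clusters %||% list()
  if (!is.null(clu_cfg$external)) {
    clusters <- load_external_clusters(clu_cfg$external, genes)
    cluster_source <- paste0("external:", clu_cfg$external)
  } else {
    clusters <- call_clusters(genes,
                              max_gap_bp = clu_cfg$max_gap_bp %||% 20000,
                              min_classes = clu_cfg$min_classes %||% 2)
    cluster_source <- "internal_proximity_caller"
  }
  write_clusters_tsv(clusters, genes, file.path(outdir, "clusters.tsv"))
  note("cluster", nrow(clusters), " putative cluster(s) [", cluster_source, "]")

  # ---- stage: score + rank -------------------------------------------------
  prim_tpm <- tissue_mean_tpm(tpm, cm$samples, cfg$abundance_tissue)
  scores <- score_candidates(genes, pcc, prim_tpm, clusters, cfg)
  full_cfg <- cfg
  full_cfg$top_n <- NULL
  full_cfg$class_whitelist <- NULL
  ranked_all <- rank_candidates(scores, full_cfg)
  candidates <- format_candidate_report(
    rank_candidates(scores, cfg, whitelist_timing = opt$whitelist_timing))
  write.table(ranked_all, file.path(outdir, "ranked_all.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(candidates, file.path(outdir, "candidates_top.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  note("rank", nrow(ranked_all), " genes ranked; ", nrow(candidates),
       " in the candidate report")

  # ---- stage: manifest -----------------------------------------------------
  manifest <- list(
    tool = list(name = "bgcprior",
                version = as.character(packageVersion("bgcprior"))),
    seed = config$seed,
    bait_id = bait_id,
    inputs = lapply(as.list(input_paths), function(p) {
      # keep run-directory outputs relative so identical runs in different
      # directories produce identical manifests
      full <- normalizePath(p)
      root <- paste0(normalizePath(outdir), "/")
      shown <- if (startsWith(full, root)) substring(full, nchar(root) + 1) else p
      list(path = shown, md5 = unname(md5sum(p)))
    }),
    scoring = unclass(cfg),
    cluster_source = cluster_source,
    options = opt,
    simulate = config$simulate,
    stage_rows = list(genes = nrow(genes), samples = ncol(cm$counts),
                      clusters = nrow(clusters),
                      ranked = nrow(ranked_all),
                      candidates = nrow(candidates))
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  writeLines(log_lines, file.path(outdir, "run.log"))

  invisible(list(ranked = ranked_all, candidates = candidates,
                 clusters = clusters, truth = truth, manifest = manifest,
                 outdir = outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
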