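#' Generate a synthetic genome annotation with a planted pathway module
#'
#' Lays out `n_genes` non-overlapping genes (1-based, inclusive coordinates)
#' across scaffolds and plants a pathway module with the structure the
#' prioritization score assumes: most pathway genes sit in a few tight
#' genomic clusters (intra-cluster gaps at most `cluster_gap_bp`),
#' cluster-only decoys are interleaved inside those clusters, and
#' coexpression-only decoys plus any leftover pathway genes are placed as
#' isolated singletons. Planted loci are separated from their neighbours by
#' at least five times `cluster_gap_bp`, so they never chain with background
#' genes under any proximity threshold up to that distance.
#'
#' Ground truth (bait, pathway members, decoys, planted cluster membership,
#' characterized genes) is returned as a sidecar manifest and is never
#' encoded in gene identifiers, which are assigned in genome order.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (data.frame: `gene_id`, `scaffold`, `start`,
#'   `end`, `strand`, `length`, `enzyme_class`, `characterized`) and `truth`
#'   (list: `bait_id`, `pathway_ids`, `decoy_ids$coexpr`,
#'   `decoy_ids$clustered`, `planted_cluster_members`, `characterized_ids`,
#'   `config_echo`, `seed`).
#' @examples
#' sim <- simulate_genome(sim_config(n_genes = 300, n_scaffolds = 3))
#' head(sim$genes)
#' sim$truth$bait_id
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  k <- length(config$pathway_cluster_sizes)
  if (config$n_decoy_clustered > 0 && k == 0) {
    stop("simulate_genome: clustered decoys requested but no planted clusters",
         call. = FALSE)
  }

  set.seed(stage_seed(config$seed, "layout"))

  # ---- planted units -------------------------------------------------------
  # Roles: "pathway", "decoy_coexpr", "decoy_clustered", "background".
  n_unclustered_pw <- config$n_pathway_genes - sum(config$pathway_cluster_sizes)
  cluster_units <- list()
  if (k > 0) {
    decoys_per_cluster <- tabulate(
      rep(seq_len(k), length.out = config$n_decoy_clustered), nbins = k)
    for (i in seq_len(k)) {
      roles <- c(rep("pathway", config$pathway_cluster_sizes[i]),
                 rep("decoy_clustered", decoys_per_cluster[i]))
      # Interleave decoys among pathway members, but keep a pathway gene
      # first: it carries the cluster's characterized flag (the bait for
      # cluster 1).
      if (length(roles) > 2) {
        roles <- c("pathway", sample(roles[-1]))
      }
      cluster_units[[i]] <- roles
    }
  }
  singleton_roles <- c(rep("pathway", n_unclustered_pw),
                       rep("decoy_coexpr", config$n_decoy_coexpr))
  n_planted <- config$n_pathway_genes + config$n_decoy_coexpr +
    config$n_decoy_clustered
  n_background <- config$n_genes - n_planted

  # ---- assignment to scaffolds --------------------------------------------
  n_bg_per_scaf <- tabulate(
    rep(seq_len(config$n_scaffolds), length.out = n_background),
    nbins = config$n_scaffolds)
  units <- c(cluster_units, as.list(singleton_roles))
  unit_scaf <- if (length(units) > 0) {
    rep(seq_len(config$n_scaffolds), length.out = length(units))
  } else integer(0)

  # Per-scaffold ordered item list; each item is a character vector of roles
  # (length > 1 marks a planted cluster whose flanks get the isolation gap).
  scaffold_items <- vector("list", config$n_scaffolds)
  for (s in seq_len(config$n_scaffolds)) {
    items <- as.list(rep("background", n_bg_per_scaf[s]))
    for (u in which(unit_scaf == s)) {
      pos <- sample.int(length(items) + 1L, 1L)
      items <- append(items, units[u], after = pos - 1L)
    }
    scaffold_items[[s]] <- items
  }

  # ---- lengths and coordinates --------------------------------------------
  set.seed(stage_seed(config$seed, "lengths"))
  gene_len <- pmax(300L, as.integer(round(rlnorm(config$n_genes,
                                                 meanlog = log(1500),
                                                 sdlog = 0.35))))
  isolation_gap <- 5 * config$cluster_gap_bp
  rows <- vector("list", config$n_genes)
  gi <- 0L
  cluster_tag <- integer(config$n_genes)  # planted cluster index or 0
  next_cluster <- 0L
  for (s in seq_len(config$n_scaffolds)) {
    pos <- 0L
    prev_planted <- FALSE
    for (item in scaffold_items[[s]]) {
      planted_unit <- length(item) > 1L || item[1] != "background"
      if (length(item) > 1L) next_cluster <- next_cluster + 1L
      for (j in seq_along(item)) {
        gi <- gi + 1L
        gap <- if (j > 1L) {
          round(runif(1, 200, config$cluster_gap_bp))
        } else if (planted_unit || prev_planted) {
          isolation_gap + round(runif(1, 0, config$cluster_gap_bp))
        } else {
          round(rlnorm(1, meanlog = log(12000), sdlog = 0.6))
        }
        start <- pos + gap + 1L
        end <- start + gene_len[gi] - 1L
        if (end > config$scaffold_length_bp) {
          stop("simulate_genome: scaffold ", s, " exceeds scaffold_length_bp (",
               config$scaffold_length_bp, " bp); too many genes for the gap ",
               "model -- reduce n_genes or raise scaffold_length_bp",
               call. = FALSE)
        }
        rows[[gi]] <- list(scaffold = sprintf("scaffold_%02d", s),
                           start = as.integer(start), end = as.integer(end),
                           role = item[j])
        cluster_tag[gi] <- if (length(item) > 1L) next_cluster else 0L
        pos <- end
      }
      prev_planted <- planted_unit
    }
  }
  genes <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(config$n_genes)),
    scaffold = vapply(rows, `[[`, "", "scaffold"),
    start = vapply(rows, `[[`, 1L, "start"),
    end = vapply(rows, `[[`, 1L, "end"),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  genes$length <- genes$end - genes$start + 1L
  role <- vapply(rows, `[[`, "", "role")

  # ---- enzyme classes and characterized flags -----------------------------
  set.seed(stage_seed(config$seed, "classes"))
  ec <- rep("none", config$n_genes)
  bg <- which(role == "background")
  is_sig_bg <- runif(length(bg)) < config$background_signature_frac
  ec[bg[is_sig_bg]] <- sample(signature_classes, sum(is_sig_bg), replace = TRUE)
  whitelisted <- c("SDR-reductase", "BAHD-acyltransferase", "glycosyltransferase")
  ec[role == "decoy_coexpr"] <-
    rep(whitelisted, length.out = sum(role == "decoy_coexpr"))
  planted_cluster_members <- list()
  for (ci in seq_len(next_cluster)) {
    idx <- which(cluster_tag == ci)
    ec[idx] <- rep(signature_classes, length.out = length(idx))
    planted_cluster_members[[sprintf("cluster_%02d", ci)]] <- genes$gene_id[idx]
  }
  lone_pw <- which(role == "pathway" & cluster_tag == 0L)
  ec[lone_pw] <- rep(signature_classes, length.out = length(lone_pw))
  genes$enzyme_class <- ec

  pw_idx <- which(role == "pathway")
  bait_idx <- if (next_cluster > 0) which(cluster_tag == 1L & role == "pathway")[1] else pw_idx[1]
  genes$enzyme_class[bait_idx] <- "oxidosqualene-cyclase"
  characterized_idx <- bait_idx
  for (ci in seq_len(next_cluster)) {
    characterized_idx <- c(characterized_idx,
                           which(cluster_tag == ci & role == "pathway")[1])
  }
  characterized_idx <- sort(unique(characterized_idx))
  genes$characterized <- seq_len(config$n_genes) %in% characterized_idx

  truth <- list(
    bait_id = genes$gene_id[bait_idx],
    pathway_ids = genes$gene_id[pw_idx],
    decoy_ids = list(coexpr = genes$gene_id[role == "decoy_coexpr"],
                     clustered = genes$gene_id[role == "decoy_clustered"]),
    planted_cluster_members = planted_cluster_members,
    characterized_ids = genes$gene_id[characterized_idx],
    config_echo = unclass(config),
    seed = config$seed
  )
  list(genes = genes, truth = truth)
}

tissue_names <- function(n) {
  base <- c("primordia", "young_leaf", "old_leaf", "stem", "root",
            "flower", "bark", "seed")
  if (n <= length(base)) base[seq_len(n)] else c(base, sprintf("tissue_%02d", seq_len(n - length(base))))
}

#' Simulate a multi-tissue RNA-seq count matrix over a synthetic genome
#'
#' Pathway genes and coexpression decoys share one latent tissue profile
#' (primordia at `primordium_mean_tpm`, every other tissue at a tissue-
#' specific 1--10% of it), each scaled by a gene-specific lognormal factor.
#' Background genes and clustered decoys draw independent lognormal means
#' per tissue. Target TPM columns are renormalized to 1e6, converted to
#' expected fragment counts proportional to TPM times gene length at equal
#' library sizes, and counts drawn negative-binomial with dispersion
#' `nb_dispersion`. Recomputing TPM from the emitted counts therefore
#' recovers the target profile in expectation, keeping the scoring
#' thresholds (1,000 / 3,000 TPM) meaningful.
#'
#' @param config The [sim_config()] used for [simulate_genome()].
#' @param genes,truth The annotation and truth manifest from
#'   [simulate_genome()] under the same config.
#' @return A `count_matrix` list: `counts` (integer matrix, genes x
#'   samples), `lengths` (named bp vector), `samples` (data.frame `sample`,
#'   `tissue`).
#' @examples
#' cfg <- sim_config(n_genes = 200, n_scaffolds = 3)
#' sim <- simulate_genome(cfg)
#' cm <- simulate_counts(cfg, sim$genes, sim$truth)
#' dim(cm$counts)
#' @export
simulate_counts <- function(config, genes, truth) {
  validate_sim_config(config)
  if (!all(c(truth$pathway_ids, truth$decoy_ids$coexpr,
             truth$decoy_ids$clustered) %in% genes$gene_id) ||
      nrow(genes) != config$n_genes ||
      !identical(truth$config_echo$seed, config$seed)) {
    stop("simulate_counts: gene table / truth manifest does not match config",
         call. = FALSE)
  }

  n_g <- nrow(genes)
  tissues <- tissue_names(config$n_tissues)

  set.seed(stage_seed(config$seed, "profile"))
  latent <- c(config$primordium_mean_tpm,
              runif(config$n_tissues - 1, 0.01, 0.10) * config$primordium_mean_tpm)
  profiled <- genes$gene_id %in% c(truth$pathway_ids, truth$decoy_ids$coexpr)
  gene_factor <- rlnorm(n_g, meanlog = 0, sdlog = 0.25)
  target <- matrix(0, nrow = n_g, ncol = config$n_tissues,
                   dimnames = list(genes$gene_id, tissues))
  target[profiled, ] <- outer(gene_factor[profiled], latent)
  n_bgx <- sum(!profiled)
  target[!profiled, ] <- matrix(
    rlnorm(n_bgx * config$n_tissues,
           meanlog = config$background_tpm_logmean,
           sdlog = config$background_tpm_logsd),
    nrow = n_bgx)
  # exact TPM columns: each tissue's target sums to 1e6
  target <- sweep(target, 2, colSums(target), "/") * 1e6

  set.seed(stage_seed(config$seed, "counts"))
  len_kb <- genes$length / 1000
  samples <- data.frame(
    sample = paste0(rep(tissues, each = config$replicates_per_tissue), "_r",
                    rep(seq_len(config$replicates_per_tissue), config$n_tissues)),
    tissue = rep(tissues, each = config$replicates_per_tissue),
    stringsAsFactors = FALSE
  )
  counts <- matrix(0L, nrow = n_g, ncol = nrow(samples),
                   dimnames = list(genes$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- target[, samples$tissue[j]] * len_kb
    mu <- mu / sum(mu) * config$library_size
    counts[, j] <- rnbinom(n_g, mu = mu, size = 1 / config$nb_dispersion)
  }
  structure(list(counts = counts,
                 lengths = setNames(genes$length, genes$gene_id),
                 samples = samples),
            class = "count_matrix")
}

#' Simulate an annotation, truth manifest and count matrix in one call
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `truth` and `counts` (a `count_matrix`).
#' @export
simulate_dataset <- function(config = sim_config()) {
  g <- simulate_genome(config)
  cm <- simulate_counts(config, g$genes, g$truth)
  list(genes = g$genes, truth = g$truth, counts = cm)
}

#' Write a simulated dataset to disk
#'
#' Emits `genes.gff3` (attributes `enzyme_class`, `characterized`),
#' `counts.tsv` (gene id + one column per sample), `lengths.tsv`,
#' `samples.tsv` (`sample<TAB>tissue`) and `truth.yaml` (the ground-truth
#' manifest). All outputs are plain text and byte-deterministic for a fixed
#' config and seed.
#'
#' @param sim Result of [simulate_dataset()].
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_gene_annotation(sim$genes, file.path(outdir, "genes.gff3"))
  write_counts_tsv(sim$counts, outdir)
  truth <- sim$truth
  truth$decoy_ids <- lapply(truth$decoy_ids, as.list)
  yaml::write_yaml(truth, file.path(outdir, "truth.yaml"))
  invisible(outdir)
}
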