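#' Simulation configuration
#'
#' Parameters for the synthetic genome and multi-tissue count matrix. The
#' defaults describe the study conditions the package is validated under:
#' 2,000 genes on 10 scaffolds, 8 tissues with 3 replicates each (one tissue
#' designated `"primordia"`), a planted 12-gene pathway module (bait
#' included) laid out as three genomic clusters of 4, 4 and 3 genes with one
#' unclustered member, plus 4 coexpression-only and 4 cluster-only decoys.
#'
#' @param n_scaffolds Number of scaffolds.
#' @param n_genes Total number of genes (planted module included).
#' @param n_tissues Number of tissues; the first is always `"primordia"`.
#' @param replicates_per_tissue Biological replicates per tissue.
#' @param n_pathway_genes Planted pathway genes, bait included.
#' @param n_decoy_coexpr Decoys sharing the pathway expression profile but
#'   placed far from any planted cluster.
#' @param n_decoy_clustered Decoys placed inside planted clusters but given
#'   background expression.
#' @param pathway_cluster_sizes Integer vector: how many pathway genes sit in
#'   each planted genomic cluster; the remainder (`n_pathway_genes -
#'   sum(...)`) are placed as isolated singletons.
#' @param primordium_mean_tpm Latent pathway expression in primordia, in TPM
#'   before per-gene scaling. Other tissues receive 1--10% of this value.
#' @param background_tpm_logmean,background_tpm_logsd Lognormal parameters
#'   (natural-log scale) of background per-gene, per-tissue TPM. Defaults
#'   give a median of ~150 TPM with a heavy right tail, so background
#'   columns sum near 1e6 TPM for 2,000 genes.
#' @param nb_dispersion Negative-binomial dispersion phi (variance
#'   `m + phi * m^2`). Default 0.02, i.e. ~14% extra-Poisson CV, typical of
#'   biological replicates of highly expressed genes and consistent with the
#'   near-perfect (PCC > 0.98) coexpression observed among genes of one
#'   pathway.
#' @param cluster_gap_bp Maximum intergenic gap inside a planted cluster, bp.
#' @param scaffold_length_bp Maximum scaffold length; the generator errors if
#'   the requested genes and gaps do not fit.
#' @param background_signature_frac Fraction of background genes assigned a
#'   random signature enzyme class (the rest are labelled `"none"`).
#' @param library_size Expected fragments per sample; equal across samples.
#' @param seed RNG seed for the whole simulation.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_genes = 200, n_scaffolds = 4)
#' cfg$n_pathway_genes
#' @export
sim_config <- function(n_scaffolds = 10,
                       n_genes = 2000,
                       n_tissues = 8,
                       replicates_per_tissue = 3,
                       n_pathway_genes = 12,
                       n_decoy_coexpr = 4,
                       n_decoy_clustered = 4,
                       pathway_cluster_sizes = c(4, 4, 3),
                       primordium_mean_tpm = 8000,
                       background_tpm_logmean = 5.0,
                       background_tpm_logsd = 1.5,
                       nb_dispersion = 0.02,
                       cluster_gap_bp = 10000,
                       scaffold_length_bp = 2e7,
                       background_signature_frac = 0.10,
                       library_size = 5e6,
                       seed = 1) {
  cfg <- list(
    n_scaffolds = as.integer(n_scaffolds),
    n_genes = as.integer(n_genes),
    n_tissues = as.integer(n_tissues),
    replicates_per_tissue = as.integer(replicates_per_tissue),
    n_pathway_genes = as.integer(n_pathway_genes),
    n_decoy_coexpr = as.integer(n_decoy_coexpr),
    n_decoy_clustered = as.integer(n_decoy_clustered),
    pathway_cluster_sizes = as.integer(pathway_cluster_sizes),
    primordium_mean_tpm = primordium_mean_tpm,
    background_tpm_logmean = background_tpm_logmean,
    background_tpm_logsd = background_tpm_logsd,
    nb_dispersion = nb_dispersion,
    cluster_gap_bp = cluster_gap_bp,
    scaffold_length_bp = scaffold_length_bp,
    background_signature_frac = background_signature_frac,
    library_size = library_size,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  pos <- c("n_scaffolds", "n_genes", "n_tissues", "replicates_per_tissue",
           "n_pathway_genes", "primordium_mean_tpm", "nb_dispersion",
           "cluster_gap_bp", "scaffold_length_bp", "library_size")
  for (f in pos) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]) ||
        cfg[[f]] <= 0) {
      stop("sim_config: '", f, "' must be a single positive number", call. = FALSE)
    }
  }
  if (cfg$n_pathway_genes < 2)
    stop("sim_config: need at least 2 pathway genes (bait plus one)", call. = FALSE)
  if (cfg$n_decoy_coexpr < 0 || cfg$n_decoy_clustered < 0)
    stop("sim_config: decoy counts must be non-negative", call. = FALSE)
  if (any(cfg$pathway_cluster_sizes < 2))
    stop("sim_config: each planted cluster needs >= 2 pathway genes", call. = FALSE)
  if (sum(cfg$pathway_cluster_sizes) > cfg$n_pathway_genes)
    stop("sim_config: pathway_cluster_sizes sum exceeds n_pathway_genes", call. = FALSE)
  n_planted <- cfg$n_pathway_genes + cfg$n_decoy_coexpr + cfg$n_decoy_clustered
  if (n_planted > cfg$n_genes)
    stop("sim_config: planted genes (", n_planted, ") exceed n_genes", call. = FALSE)
  if (cfg$background_signature_frac < 0 || cfg$background_signature_frac > 1)
    stop("sim_config: background_signature_frac must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config:", x$n_genes, "genes /", x$n_scaffolds, "scaffolds;",
      x$n_tissues, "tissues x", x$replicates_per_tissue, "reps;",
      x$n_pathway_genes, "pathway genes (clusters:",
      paste(x$pathway_cluster_sizes, collapse = "+"), "),",
      x$n_decoy_coexpr, "+", x$n_decoy_clustered, "decoys; seed", x$seed, "\n")
  invisible(x)
}
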