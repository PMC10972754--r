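#' Scoring configuration
#'
#' Holds the constants of the composite prioritization score. The defaults
#' are the published calibration, ascertained from already characterized
#' saponin pathway genes: coexpression ramps linearly from 0 at bait PCC 0.8
#' to 1 at PCC 0.9; primordium abundance ramps from 0 at 1,000 TPM to 1 at
#' 3,000 TPM; cluster membership contributes 1 when the cluster contains an
#' already characterized pathway gene and 0.5 for any other putative
#' cluster. The composite is the plain sum, maximum 3.0.
#'
#' @param pcc_lo,pcc_hi Knots of the coexpression ramp.
#' @param tpm_lo,tpm_hi Knots of the abundance ramp, TPM.
#' @param bgc_char_bonus,bgc_other_bonus Cluster bonuses in `[0, 1]`.
#' @param abundance_tissue Tissue whose mean TPM feeds the abundance
#'   channel.
#' @param top_n Candidate list length after optional class filtering.
#' @param class_whitelist Optional character vector of enzyme classes to
#'   keep (e.g. reductases, acyl transferases and glycosyl transferases when
#'   hunting tailoring steps); `NULL` keeps all classes.
#' @return Object of class `scoring_config`.
#' @examples
#' scoring_config()
#' @export
scoring_config <- function(pcc_lo = 0.8, pcc_hi = 0.9,
                           tpm_lo = 1000, tpm_hi = 3000,
                           bgc_char_bonus = 1.0, bgc_other_bonus = 0.5,
                           abundance_tissue = "primordia",
                           top_n = 68, class_whitelist = NULL) {
  if (!(pcc_lo < pcc_hi)) stop("need pcc_lo < pcc_hi", call. = FALSE)
  if (!(tpm_lo < tpm_hi)) stop("need tpm_lo < tpm_hi", call. = FALSE)
  if (bgc_char_bonus < 0 || bgc_char_bonus > 1 ||
      bgc_other_bonus < 0 || bgc_other_bonus > 1)
    stop("cluster bonuses must lie in [0, 1]", call. = FALSE)
  structure(list(pcc_lo = pcc_lo, pcc_hi = pcc_hi,
                 tpm_lo = tpm_lo, tpm_hi = tpm_hi,
                 bgc_char_bonus = bgc_char_bonus,
                 bgc_other_bonus = bgc_other_bonus,
                 abundance_tissue = abundance_tissue,
                 top_n = if (is.null(top_n)) NULL else as.integer(top_n),
                 class_whitelist = class_whitelist),
            class = "scoring_config")
}

# shared piecewise-linear ramp: 0 at/below lo, 1 at/above hi, linear between
ramp01 <- function(x, lo, hi) pmin(1, pmax(0, (x - lo) / (hi - lo)))

#' Coexpression sub-score
#'
#' 1 for a bait PCC of `pcc_hi` (default 0.9) or greater; between 0 and 1 on
#' a linear scale for a PCC between `pcc_lo` and `pcc_hi`; 0 at or below
#' `pcc_lo` and for genes whose correlation is undefined (zero variance).
#'
#' @param pcc Numeric vector of Pearson coefficients in `[-1, 1]`; `NA`
#'   means undefined.
#' @param cfg A [scoring_config()].
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' coexpr_subscore(c(0.79, 0.85, 0.9, NA))
#' @export
coexpr_subscore <- function(pcc, cfg = scoring_config()) {
  bad <- !is.na(pcc) & (pcc < -1 | pcc > 1)
  if (any(bad))
    stop("PCC outside [-1, 1]: ", paste(pcc[bad], collapse = ", "),
         call. = FALSE)
  s <- ramp01(pcc, cfg$pcc_lo, cfg$pcc_hi)
  s[is.na(pcc)] <- 0
  s
}

#' Abundance sub-score
#'
#' 1 for a target-tissue TPM of `tpm_hi` (default 3,000) or greater; between
#' 0 and 1 on a linear scale between `tpm_lo` and `tpm_hi`; 0 at or below
#' `tpm_lo`.
#'
#' @param tpm Non-negative numeric vector of tissue-mean TPM values.
#' @inheritParams coexpr_subscore
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' abundance_subscore(c(0, 2000, 3000))
#' @export
abundance_subscore <- function(tpm, cfg = scoring_config()) {
  if (any(is.na(tpm)) || any(tpm < 0))
    stop("TPM values must be non-negative and non-missing", call. = FALSE)
  ramp01(tpm, cfg$tpm_lo, cfg$tpm_hi)
}

#' Cluster-membership sub-score
#'
#' `bgc_char_bonus` (default 1) for membership in a putative cluster
#' containing an already characterized pathway gene, `bgc_other_bonus`
#' (default 0.5) for membership in any other putative cluster, 0 otherwise.
#'
#' @param status Character vector over `in_characterized_cluster`,
#'   `in_other_cluster`, `unclustered` (see [gene_bgc_status()]).
#' @inheritParams coexpr_subscore
#' @return Numeric vector.
#' @export
bgc_subscore <- function(status, cfg = scoring_config()) {
  ok <- c("in_characterized_cluster", "in_other_cluster", "unclustered")
  if (!all(status %in% ok))
    stop("invalid BGC status: ", paste(setdiff(status, ok), collapse = ", "),
         call. = FALSE)
  unname(c(in_characterized_cluster = cfg$bgc_char_bonus,
           in_other_cluster = cfg$bgc_other_bonus,
           unclustered = 0)[status])
}

#' Composite candidate scores from the three evidence channels
#'
#' Assembles the per-gene evidence (bait PCC, target-tissue mean TPM, BGC
#' status), applies the three sub-scores and sums them into the composite
#' (maximum 3.0). The evidence values are echoed alongside the sub-scores
#' for audit; no rounding is applied here. The bait gene is scored like any
#' other gene.
#'
#' @param genes Gene annotation data.frame.
#' @param pcc Result of [bait_pcc()] (or a data.frame with `gene_id`,
#'   `pcc`).
#' @param tissue_tpm Named per-gene vector of target-tissue mean TPM (from
#'   [tissue_mean_tpm()]).
#' @param clusters Cluster data.frame.
#' @param cfg A [scoring_config()].
#' @return data.frame: `gene_id`, `enzyme_class`, `pcc`, `primordium_tpm`,
#'   `bgc_status`, `c_coexpr`, `c_abund`, `c_bgc`, `composite`.
#' @export
score_candidates <- function(genes, pcc, tissue_tpm, clusters,
                             cfg = scoring_config()) {
  validate_genes(genes)
  p <- pcc$pcc[match(genes$gene_id, pcc$gene_id)]
  tt <- tissue_tpm[genes$gene_id]
  if (anyNA(tt))
    stop("tissue TPM missing for gene(s): ",
         paste(genes$gene_id[is.na(tt)][1:3], collapse = ", "), call. = FALSE)
  status <- gene_bgc_status(genes$gene_id, clusters)
  res <- data.frame(
    gene_id = genes$gene_id,
    enzyme_class = genes$enzyme_class,
    pcc = p,
    primordium_tpm = unname(tt),
    bgc_status = status,
    c_coexpr = coexpr_subscore(p, cfg),
    c_abund = abundance_subscore(unname(tt), cfg),
    c_bgc = bgc_subscore(status, cfg),
    stringsAsFactors = FALSE
  )
  res$composite <- res$c_coexpr + res$c_abund + res$c_bgc
  res
}

#' Rank scored candidates and select the top of the list
#'
#' Sorts by composite score descending, breaking ties by PCC descending,
#' then target-tissue TPM descending, then gene id ascending; assigns ranks
#' 1..n. The optional enzyme-class whitelist can be applied either after
#' ranking the whole genome (`whitelist_timing = "before_top_n"`, the
#' default, mirroring a narrowing of an already ranked list) or before
#' ranks are assigned (`"before_ranking"`). `top_n` then truncates.
#'
#' @param scores Output of [score_candidates()].
#' @param cfg A [scoring_config()]; `cfg$top_n = NULL` keeps all rows.
#' @param whitelist_timing When to apply `cfg$class_whitelist`.
#' @return `scores` with a `rank` column, filtered and truncated.
#' @export
rank_candidates <- function(scores, cfg = scoring_config(),
                            whitelist_timing = c("before_top_n", "before_ranking")) {
  whitelist_timing <- match.arg(whitelist_timing)
  keep_whitelist <- function(df) {
    if (is.null(cfg$class_whitelist)) df
    else df[df$enzyme_class %in% cfg$class_whitelist, , drop = FALSE]
  }
  if (whitelist_timing == "before_ranking") scores <- keep_whitelist(scores)
  ord <- order(-scores$composite,
               ifelse(is.na(scores$pcc), Inf, -scores$pcc),
               -scores$primordium_tpm,
               scores$gene_id)
  ranked <- scores[ord, , drop = FALSE]
  ranked$rank <- seq_len(nrow(ranked))
  if (whitelist_timing == "before_top_n") ranked <- keep_whitelist(ranked)
  if (!is.null(cfg$top_n)) ranked <- head(ranked, cfg$top_n)
  rownames(ranked) <- NULL
  ranked[, c("rank", setdiff(names(ranked), "rank"))]
}

#' Round a ranked table for reporting
#'
#' Presentation helper: sub-scores and composite rounded to 2 decimals (so a
#' full-evidence gene prints `3.00`), PCC to 4 and TPM to 1. The machine
#' outputs keep full precision; only reports are rounded.
#'
#' @param ranked Output of [rank_candidates()].
#' @return data.frame with rounded numeric columns.
#' @export
format_candidate_report <- function(ranked) {
  ranked$pcc <- round(ranked$pcc, 4)
  ranked$primordium_tpm <- round(ranked$primordium_tpm, 1)
  for (col in c("c_coexpr", "c_abund", "c_bgc", "composite")) {
    ranked[[col]] <- round(ranked[[col]], 2)
  }
  ranked
}
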