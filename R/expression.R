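#' Normalize a count matrix to transcripts per million (TPM)
#'
#' `tpm[g, s] = (counts[g, s] / length[g]) / sum_g'(counts[g', s] /
#' length[g']) * 1e6`: fragment counts are first turned into length-
#' normalized transcript rates, then each sample column is scaled to sum to
#' one million. A sample with no counts at all yields an all-zero column
#' with a warning rather than an error.
#'
#' @param counts Non-negative integer matrix, genes x samples, or a
#'   `count_matrix` list (in which case `lengths` is taken from it).
#' @param lengths Positive per-gene lengths in bp, aligned with the rows.
#' @return Numeric matrix of TPM values with the input dimnames.
#' @examples
#' m <- matrix(c(10, 90), ncol = 1, dimnames = list(c("a", "b"), "s1"))
#' compute_tpm(m, lengths = c(a = 1000, b = 3000))
#' @export
compute_tpm <- function(counts, lengths = NULL) {
  if (inherits(counts, "count_matrix")) {
    lengths <- counts$lengths
    counts <- counts$counts
  }
  if (is.null(lengths)) stop("compute_tpm: gene lengths are required", call. = FALSE)
  validate_count_matrix(counts, lengths)
  rate <- counts / lengths
  denom <- colSums(rate)
  zero_cols <- denom == 0
  if (any(zero_cols)) {
    warning("all-zero sample column(s): ",
            paste(colnames(counts)[zero_cols], collapse = ", "),
            "; TPM set to 0 for these samples")
    denom[zero_cols] <- 1
  }
  sweep(rate, 2, denom, "/") * 1e6
}

#' Mean TPM per gene within one tissue
#'
#' Arithmetic mean of TPM across the replicate samples mapped to `tissue`.
#'
#' @param tpm TPM matrix (genes x samples).
#' @param samples data.frame with columns `sample` and `tissue`.
#' @param tissue Tissue label to aggregate.
#' @return Named numeric vector, one mean per gene.
#' @export
tissue_mean_tpm <- function(tpm, samples, tissue) {
  if (!tissue %in% samples$tissue)
    stop("unknown tissue label: '", tissue, "' (have: ",
         paste(unique(samples$tissue), collapse = ", "), ")", call. = FALSE)
  cols <- samples$sample[samples$tissue == tissue]
  cols <- intersect(colnames(tpm), cols)
  if (length(cols) == 0)
    stop("no samples of tissue '", tissue, "' present in the TPM matrix",
         call. = FALSE)
  rowMeans(tpm[, cols, drop = FALSE])
}

#' Pearson correlation of every gene with the bait gene
#'
#' Correlates each gene's expression vector with the bait's across all
#' samples (columns). By default the correlation is computed on raw TPM;
#' `log1p = TRUE` applies `log(1 + x)` to the whole matrix first. Genes with
#' zero variance across samples (including a zero-variance bait) cannot
#' carry a Pearson coefficient and are flagged undefined; downstream scoring
#' maps undefined to a coexpression sub-score of 0.
#'
#' @param tpm TPM matrix (genes x samples), at least 3 samples.
#' @param bait_id Row name of the bait gene.
#' @param log1p Correlate on `log1p(tpm)` instead of raw TPM.
#' @return data.frame with one row per gene: `gene_id`, `pcc` (NA when
#'   undefined), `defined`, `n_samples_used`; carries the bait id as
#'   attribute `bait_id`.
#' @examples
#' tpm <- rbind(bait = c(1, 2, 3, 4), g1 = c(1, 2, 3, 5))
#' bait_pcc(tpm, "bait")
#' @export
bait_pcc <- function(tpm, bait_id, log1p = FALSE) {
  if (!bait_id %in% rownames(tpm))
    stop("bait gene '", bait_id, "' not found in the expression matrix",
         call. = FALSE)
  if (ncol(tpm) < 3)
    stop("bait_pcc needs at least 3 samples, got ", ncol(tpm), call. = FALSE)
  if (anyNA(tpm))
    stop("missing values in the expression matrix are not supported", call. = FALSE)
  x <- if (log1p) log1p(tpm) else tpm
  # population-vs-sample scaling cancels in r; use sd > 0 as the defined flag
  sds <- apply(x, 1, stats::sd)
  bait_vec <- x[bait_id, ]
  if (sds[bait_id] == 0) {
    warning("bait gene '", bait_id,
            "' has zero variance across samples; all PCCs undefined")
    pcc <- rep(NA_real_, nrow(x))
    defined <- rep(FALSE, nrow(x))
  } else {
    pcc <- suppressWarnings(as.vector(cor(t(x), bait_vec)))
    defined <- sds > 0
    pcc[!defined] <- NA_real_
  }
  res <- data.frame(gene_id = rownames(x), pcc = pcc, defined = defined,
                    n_samples_used = ncol(x), stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(res, "bait_id") <- bait_id
  res
}
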