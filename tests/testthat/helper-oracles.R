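# Independent oracles and tiny fixture builders shared across the suite.

# Pearson correlation straight from the sum formula, no cor() call.
pcc_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# Minimal gene-table builder for cluster tests.
gene_row <- function(id, start, end, class = "none", scaffold = "s1",
                     characterized = FALSE) {
  data.frame(gene_id = id, scaffold = scaffold, start = start, end = end,
             strand = "+", length = end - start + 1, enzyme_class = class,
             characterized = characterized, stringsAsFactors = FALSE)
}

genes_table <- function(...) do.call(rbind, list(...))

# Brute-force cluster-chaining oracle: enumerate maximal chains of
# signature genes by explicit pairwise gap checks, then collect members by
# span containment. Returns a canonical list of clusters for comparison.
cluster_oracle <- function(genes, max_gap_bp, min_classes = 2,
                           classes = bgcprior::signature_classes) {
  out <- list()
  for (scaf in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == scaf, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    sig <- g[g$enzyme_class %in% classes, , drop = FALSE]
    n <- nrow(sig)
    if (n < 2) next
    # linked[i] says sig genes i and i+1 belong to the same chain
    linked <- logical(max(n - 1, 0))
    for (i in seq_len(n - 1)) {
      gap <- max(0, sig$start[i + 1] - sig$end[i] - 1)
      linked[i] <- gap <= max_gap_bp
    }
    chain_id <- cumsum(c(TRUE, !linked))
    for (ch in unique(chain_id)) {
      idx <- which(chain_id == ch)
      if (length(idx) < 2) next
      if (length(unique(sig$enzyme_class[idx])) < min_classes) next
      span <- c(min(sig$start[idx]), max(sig$end[idx]))
      members <- g$gene_id[g$start >= span[1] & g$end <= span[2]]
      out[[length(out) + 1]] <- list(
        scaffold = scaf, span = span,
        members = sort(members),
        characterized = any(g$characterized[g$gene_id %in% members]))
    }
  }
  out[order(vapply(out, function(x) paste(x$scaffold, x$span[1]), ""))]
}

canonical_clusters <- function(clusters) {
  if (nrow(clusters) == 0) return(list())
  out <- lapply(seq_len(nrow(clusters)), function(i) list(
    scaffold = clusters$scaffold[i],
    span = c(clusters$span_start[i], clusters$span_end[i]),
    members = sort(clusters$member_ids[[i]]),
    characterized = clusters$contains_characterized[i]))
  out[order(vapply(out, function(x) paste(x$scaffold, x$span[1]), ""))]
}

# Random single-scaffold instance for oracle equivalence tests; genes may
# overlap and classes mix signature and non-signature labels.
random_gene_instance <- function(n, classes = c("CYP", "glycosyltransferase",
                                                "SDR-reductase")) {
  start <- sort(sample.int(200000, n))
  len <- sample(300:4000, n, replace = TRUE)
  data.frame(gene_id = sprintf("g%03d", seq_len(n)), scaffold = "s1",
             start = start, end = start + len, strand = "+", length = len + 1,
             enzyme_class = sample(c(classes, "none"), n, replace = TRUE),
             characterized = runif(n) < 0.1, stringsAsFactors = FALSE)
}
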