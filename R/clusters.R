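#' Call putative biosynthetic gene clusters by genomic proximity
#'
#' A transparent proximity heuristic over annotated enzyme classes: on each
#' scaffold, signature-class genes sorted by start are chained while the
#' intergenic gap to the previous signature gene (`next.start - prev.end -
#' 1`; overlapping genes count as gap 0) is at most `max_gap_bp`. A chain
#' becomes a putative cluster when it holds at least two signature genes
#' spanning at least `min_classes` distinct classes. Every gene -- signature
#' or not -- lying inside the chain's genomic span is a member, and a
#' cluster is flagged `contains_characterized` when any member carries the
#' characterized flag. This approximates the "two or more enzyme families in
#' proximity" behaviour of cluster-detection tools such as plantiSMASH;
#' genuine tool output can be supplied instead via
#' [load_external_clusters()].
#'
#' @param genes Gene data.frame (see [read_gene_annotation()]).
#' @param max_gap_bp Maximum intergenic gap between chained signature genes,
#'   bp. Default 20,000.
#' @param min_classes Minimum number of distinct signature classes per
#'   cluster. Default 2.
#' @param classes Character vector of enzyme classes treated as signatures.
#' @return data.frame with one row per cluster: `cluster_id`, `scaffold`,
#'   `span_start`, `span_end`, `n_signature_classes`,
#'   `contains_characterized`, and a list-column `member_ids` (genes ordered
#'   by start).
#' @examples
#' g <- data.frame(gene_id = c("a", "b"), scaffold = "s1",
#'                 start = c(1, 7000), end = c(2000, 9000), strand = "+",
#'                 length = c(2000, 2001),
#'                 enzyme_class = c("CYP", "glycosyltransferase"),
#'                 characterized = c(TRUE, FALSE))
#' call_clusters(g, max_gap_bp = 20000)
#' @export
call_clusters <- function(genes, max_gap_bp = 20000, min_classes = 2,
                          classes = signature_classes) {
  validate_genes(genes)
  if (max_gap_bp <= 0) stop("max_gap_bp must be positive", call. = FALSE)
  if (min_classes < 2) stop("min_classes must be at least 2", call. = FALSE)
  if (!all(c("enzyme_class", "characterized") %in% names(genes)))
    stop("gene table needs enzyme_class and characterized columns", call. = FALSE)

  out <- list()
  cid <- 0L
  for (scaf in unique(genes$scaffold)) {
    g <- genes[genes$scaffold == scaf, , drop = FALSE]
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    sig <- g[g$enzyme_class %in% classes, , drop = FALSE]
    if (nrow(sig) < 2) next
    gap <- pmax(0, sig$start[-1] - sig$end[-nrow(sig)] - 1)
    chain <- cumsum(c(1L, as.integer(gap > max_gap_bp)))
    for (ch in split(seq_len(nrow(sig)), chain)) {
      if (length(ch) < 2) next
      n_cls <- length(unique(sig$enzyme_class[ch]))
      if (n_cls < min_classes) next
      span <- c(min(sig$start[ch]), max(sig$end[ch]))
      member <- g[g$start >= span[1] & g$end <= span[2], , drop = FALSE]
      cid <- cid + 1L
      out[[cid]] <- data.frame(
        cluster_id = sprintf("bgc_%03d", cid),
        scaffold = scaf,
        span_start = span[1],
        span_end = span[2],
        n_signature_classes = n_cls,
        contains_characterized = any(member$characterized),
        stringsAsFactors = FALSE
      )
      out[[cid]]$member_ids <- list(member$gene_id)
    }
  }
  if (length(out) == 0) {
    return(data.frame(cluster_id = character(), scaffold = character(),
                      span_start = integer(), span_end = integer(),
                      n_signature_classes = integer(),
                      contains_characterized = logical(),
                      member_ids = I(list()), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Load externally supplied cluster calls
#'
#' Ingests cluster membership produced by an external tool (for example
#' plantiSMASH) as a TSV with columns `cluster_id`, `scaffold` and
#' `member_id` (one row per member gene). Spans, signature-class counts and
#' characterized flags are recomputed from the gene annotation so the
#' downstream scoring sees the same structure as for [call_clusters()].
#'
#' @param path Path to the TSV.
#' @param genes Gene data.frame the member ids must resolve against.
#' @param classes Signature-class catalogue for `n_signature_classes`.
#' @return Same shape as [call_clusters()]; zero rows for an empty file.
#' @export
load_external_clusters <- function(path, genes, classes = signature_classes) {
  if (!file.exists(path)) stop("cluster file not found: ", path, call. = FALSE)
  validate_genes(genes)
  empty <- data.frame(cluster_id = character(), scaffold = character(),
                      span_start = integer(), span_end = integer(),
                      n_signature_classes = integer(),
                      contains_characterized = logical(),
                      member_ids = I(list()), stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) return(empty)
  if (!all(c("cluster_id", "member_id") %in% names(tab)))
    stop("cluster TSV needs columns cluster_id, scaffold, member_id: ", path,
         call. = FALSE)
  unknown <- setdiff(tab$member_id, genes$gene_id)
  if (length(unknown) > 0)
    stop("cluster member id(s) absent from the annotation: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rows <- lapply(split(tab, tab$cluster_id), function(cl) {
    member <- genes[match(cl$member_id, genes$gene_id), , drop = FALSE]
    member <- member[order(member$start, member$gene_id), , drop = FALSE]
    if (length(unique(member$scaffold)) > 1)
      stop("cluster ", cl$cluster_id[1], " spans multiple scaffolds",
           call. = FALSE)
    r <- data.frame(
      cluster_id = cl$cluster_id[1],
      scaffold = member$scaffold[1],
      span_start = min(member$start),
      span_end = max(member$end),
      n_signature_classes = length(unique(
        member$enzyme_class[member$enzyme_class %in% classes])),
      contains_characterized = any(member$characterized),
      stringsAsFactors = FALSE
    )
    r$member_ids <- list(member$gene_id)
    r
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$cluster_id), , drop = FALSE]
}

#' BGC membership status of genes
#'
#' Maps each gene onto the three-way status the scoring rule distinguishes:
#' member of at least one cluster that contains an already characterized
#' pathway gene (`in_characterized_cluster`), member of some other cluster
#' (`in_other_cluster`), or `unclustered`. A gene belonging to several
#' clusters takes the most favourable status.
#'
#' @param gene_id Character vector of gene ids (absent ids are
#'   `unclustered`).
#' @param clusters Cluster data.frame from [call_clusters()] or
#'   [load_external_clusters()].
#' @return Character vector aligned with `gene_id`.
#' @export
gene_bgc_status <- function(gene_id, clusters) {
  status <- rep("unclustered", length(gene_id))
  if (nrow(clusters) > 0) {
    char_members <- unique(unlist(clusters$member_ids[clusters$contains_characterized]))
    any_members <- unique(unlist(clusters$member_ids))
    status[gene_id %in% any_members] <- "in_other_cluster"
    status[gene_id %in% char_members] <- "in_characterized_cluster"
  }
  status
}

#' Write cluster calls as a long-format TSV
#'
#' One row per (cluster, member gene): `cluster_id`, `scaffold`,
#' `span_start`, `span_end`, `member_id`, `enzyme_class`, `characterized`.
#'
#' @param clusters Cluster data.frame.
#' @param genes Gene annotation used to annotate members.
#' @param path Output path.
#' @export
write_clusters_tsv <- function(clusters, genes, path) {
  if (nrow(clusters) == 0) {
    writeLines(paste(c("cluster_id", "scaffold", "span_start", "span_end",
                       "member_id", "enzyme_class", "characterized"),
                     collapse = "\t"), path)
    return(invisible(path))
  }
  long <- do.call(rbind, lapply(seq_len(nrow(clusters)), function(i) {
    ids <- clusters$member_ids[[i]]
    data.frame(cluster_id = clusters$cluster_id[i],
               scaffold = clusters$scaffold[i],
               span_start = clusters$span_start[i],
               span_end = clusters$span_end[i],
               member_id = ids,
               enzyme_class = genes$enzyme_class[match(ids, genes$gene_id)],
               characterized = genes$characterized[match(ids, genes$gene_id)],
               stringsAsFactors = FALSE)
  }))
  write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
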