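#' Read and write gene annotations and expression tables
#'
#' The annotation travels as GFF3 `gene` features whose attribute column
#' carries `ID`, `enzyme_class` and `characterized=true|false`; expression
#' data travels as plain TSV (counts with a leading `gene_id` column,
#' `lengths.tsv` with `gene_id<TAB>length`, `samples.tsv` with
#' `sample<TAB>tissue`). GFF3 parsing and serialization go through
#' `rtracklayer`.
#'
#' @param path File path.
#' @return `read_gene_annotation()` returns the gene data.frame used
#'   throughout the package (`gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `length`, `enzyme_class`, `characterized`).
#' @name annotation_io
NULL

#' @rdname annotation_io
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  genes <- data.frame(
    gene_id = as.character(mc$ID),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  genes$strand[genes$strand == "*"] <- "unknown"
  genes$length <- genes$end - genes$start + 1L
  genes$enzyme_class <- if ("enzyme_class" %in% names(mc))
    as.character(mc$enzyme_class) else "none"
  genes$enzyme_class[is.na(genes$enzyme_class)] <- "none"
  genes$characterized <- if ("characterized" %in% names(mc))
    tolower(as.character(mc$characterized)) == "true" else FALSE
  genes$characterized[is.na(genes$characterized)] <- FALSE
  validate_genes(genes)
  genes
}

#' @rdname annotation_io
#' @param genes Gene data.frame (see [read_gene_annotation()] for columns).
#' @export
write_gene_annotation <- function(genes, path) {
  validate_genes(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = ifelse(genes$strand %in% c("+", "-"), genes$strand, "*")
  )
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "bgcprior",
    type = "gene",
    ID = genes$gene_id,
    enzyme_class = genes$enzyme_class,
    characterized = ifelse(genes$characterized, "true", "false")
  )
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

validate_genes <- function(genes) {
  need <- c("gene_id", "scaffold", "start", "end")
  if (!all(need %in% names(genes)))
    stop("gene table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene ids in annotation: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:3],
               collapse = ", "), call. = FALSE)
  if (any(genes$start < 1) || any(genes$end < genes$start))
    stop("invalid gene coordinates (need 1 <= start <= end)", call. = FALSE)
  invisible(genes)
}

#' @rdname annotation_io
#' @param cm A `count_matrix` (see [simulate_counts()]).
#' @param outdir Directory for `counts.tsv`, `lengths.tsv`, `samples.tsv`.
#' @export
write_counts_tsv <- function(cm, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts_df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write.table(counts_df, file.path(outdir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = names(cm$lengths), length = cm$lengths),
              file.path(outdir, "lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cm$samples, file.path(outdir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' @rdname annotation_io
#' @param counts_path,lengths_path,samples_path Paths to the three TSVs.
#' @export
read_counts_tsv <- function(counts_path, lengths_path, samples_path) {
  for (p in c(counts_path, lengths_path, samples_path)) {
    if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
  }
  cdf <- read.delim(counts_path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(cdf) < 2) stop("malformed counts TSV (need gene_id + samples): ",
                          counts_path, call. = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf[[1]]
  storage.mode(counts) <- "integer"
  ldf <- read.delim(lengths_path, stringsAsFactors = FALSE)
  lengths <- setNames(ldf$length, ldf$gene_id)[rownames(counts)]
  if (anyNA(lengths))
    stop("lengths TSV is missing genes present in the counts: ",
         lengths_path, call. = FALSE)
  sdf <- read.delim(samples_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "tissue") %in% names(sdf)))
    stop("malformed samples TSV (need columns sample, tissue): ",
         samples_path, call. = FALSE)
  missing_s <- setdiff(colnames(counts), sdf$sample)
  if (length(missing_s) > 0)
    stop("samples TSV does not map sample(s): ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  sdf <- sdf[match(colnames(counts), sdf$sample), , drop = FALSE]
  rownames(sdf) <- NULL
  validate_count_matrix(counts, lengths)
  structure(list(counts = counts, lengths = lengths, samples = sdf),
            class = "count_matrix")
}

validate_count_matrix <- function(counts, lengths) {
  if (any(counts < 0, na.rm = TRUE)) stop("negative counts", call. = FALSE)
  if (anyNA(counts)) stop("missing values in counts are not supported", call. = FALSE)
  if (any(lengths <= 0) || anyNA(lengths))
    stop("gene lengths must be positive", call. = FALSE)
  invisible(NULL)
}
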