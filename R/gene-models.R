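#' Construct a gene-model table
#'
#' A gene model is one transcription unit: the union of its isoforms collapsed
#' to a single interval, with strand-aware TSS/TES. Coordinates are 0-based
#' half-open: `start < end`, the TSS base is `start` on `+` and `end - 1` on
#' `-`, and the TES is the opposite terminus.
#'
#' @param gene_id character vector of unique identifiers.
#' @param chrom contig name(s).
#' @param start,end 0-based half-open interval bounds, `start < end`.
#' @param strand `"+"` or `"-"`.
#' @param biotype gene biotype label (default `"protein_coding"`).
#' @return A `data.frame` of class `gene_models` with columns `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `biotype`, `tss`, `tes`, `length`.
#' @export
gene_models <- function(gene_id, chrom, start, end, strand,
                        biotype = "protein_coding") {
  gene_id <- as.character(gene_id)
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (any(start >= end)) stop("gene intervals must satisfy start < end")
  if (!all(strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  df <- data.frame(
    gene_id = gene_id,
    chrom   = as.character(chrom),
    start   = as.numeric(start),
    end     = as.numeric(end),
    strand  = as.character(strand),
    biotype = rep_len(as.character(biotype), length(gene_id)),
    stringsAsFactors = FALSE
  )
  df$tss    <- ifelse(df$strand == "+", df$start, df$end - 1)
  df$tes    <- ifelse(df$strand == "+", df$end - 1, df$start)
  df$length <- df$end - df$start
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from BED12 or GTF
#'
#' BED12 records are taken as one transcription unit each (chromStart to
#' chromEnd; block structure is ignored for the per-gene union). GTF mode
#' unions the exon spans sharing a `gene_id` into one interval per gene.
#'
#' @param path file path.
#' @param format `"bed12"` or `"gtf"`.
#' @return A [gene_models] table.
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "bed12") {
    gr <- tryCatch(
      rtracklayer::import(path, format = "bed"),
      error = function(e) stop("failed to parse BED: ", conditionMessage(e))
    )
    ids <- as.character(gr$name)
    if (any(is.na(ids)) || !length(ids))
      stop("BED records must carry a name (gene_id) column")
    if (anyDuplicated(ids))
      stop("duplicate gene_id in BED: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    strand <- as.character(BiocGenerics::strand(gr))
    if (any(strand == "*")) stop("unknown strand '*' in BED record")
    bt <- if (!is.null(gr$biotype)) as.character(gr$biotype) else "protein_coding"
    gene_models(
      gene_id = ids,
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      start   = BiocGenerics::start(gr) - 1L,  # GRanges is 1-based closed
      end     = BiocGenerics::end(gr),
      strand  = strand,
      biotype = bt
    )
  } else {
    gr <- tryCatch(
      rtracklayer::import(path, format = "gtf"),
      error = function(e) stop("failed to parse GTF: ", conditionMessage(e))
    )
    if (!is.null(gr$type)) {
      ex <- gr[gr$type == "exon"]
      if (!length(ex)) ex <- gr
    } else ex <- gr
    if (is.null(ex$gene_id)) stop("GTF records lack gene_id attributes")
    sp <- S4Vectors::split(ex, as.character(ex$gene_id))
    rg <- unlist(range(sp))
    strand <- as.character(BiocGenerics::strand(rg))
    if (any(strand == "*"))
      stop("gene(s) with exons on conflicting or unknown strands: ",
           paste(names(rg)[strand == "*"], collapse = ", "))
    bt <- vapply(sp, function(g) {
      b <- unique(as.character(g$gene_biotype))
      if (!length(b) || is.na(b[1])) "protein_coding" else b[1]
    }, character(1))
    gene_models(
      gene_id = names(rg),
      chrom   = as.character(GenomicRanges::seqnames(rg)),
      start   = BiocGenerics::start(rg) - 1L,
      end     = BiocGenerics::end(rg),
      strand  = strand,
      biotype = bt
    )
  }
}

#' Write gene models as BED12
#'
#' Each gene is written as a single-block BED12 record (0-based half-open).
#'
#' @param genes a [gene_models] table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(genes, path) {
  stopifnot(inherits(genes, "gene_models"))
  n <- nrow(genes)
  bed <- data.frame(
    chrom = genes$chrom,
    start = format(genes$start, scientific = FALSE, trim = TRUE),
    end = format(genes$end, scientific = FALSE, trim = TRUE),
    name = genes$gene_id,
    score = rep(0L, n),
    strand = genes$strand,
    thickStart = format(genes$start, scientific = FALSE, trim = TRUE),
    thickEnd = format(genes$end, scientific = FALSE, trim = TRUE),
    itemRgb = rep("0,0,0", n),
    blockCount = rep(1L, n),
    blockSizes = format(genes$end - genes$start, scientific = FALSE, trim = TRUE),
    blockStarts = rep(0L, n)
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Strand-aware offset to genomic position
#'
#' Offset 0 is the TSS base; positive offsets run in the direction of
#' transcription, negative offsets upstream. Returns 0-based positions.
#'
#' @param gene one row of a [gene_models] table.
#' @param offset integer offset(s) in bp.
#' @return 0-based genomic position(s).
#' @export
offset_to_position <- function(gene, offset) {
  if (gene$strand == "+") gene$tss + offset else gene$tss - offset
}
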