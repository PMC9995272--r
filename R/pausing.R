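#' Pausing index of one gene
#'
#' The pausing index is the ratio of mean per-base RNAPII density in a
#' promoter-proximal window (default offsets \[-50, 300) around the TSS) to
#' the mean density over the gene body (default offsets \[300, length)), both
#' strand-aware and spike-scaled. Higher values indicate a higher degree of
#' promoter-proximal pausing. Genes whose body density does not exceed
#' `body_floor` are flagged undefined and excluded from summaries; genes too
#' short to hold a body interval are flagged skipped.
#'
#' @param track an [occupancy_track] (ChIP-seq-style or mNET-seq-style; one
#'   code path — the assay label only selects the input).
#' @param gene one row of a [gene_models] table.
#' @param promoter_window length-2 offsets in bp, default `c(-50, 300)`.
#' @param body_offset body start offset in bp, default 300.
#' @param body_floor minimum body density for the index to be defined.
#' @return A one-row `data.frame`: `gene_id`, `sample`, `promoter_density`,
#'   `body_density`, `pausing_index`, `defined`.
#' @export
pausing_index <- function(track, gene, promoter_window = c(-50, 300),
                          body_offset = 300, body_floor = 0) {
  if (gene$length <= body_offset) {
    return(data.frame(gene_id = gene$gene_id, sample = track$sample_id,
                      promoter_density = NA_real_, body_density = NA_real_,
                      pausing_index = NA_real_, defined = FALSE))
  }
  prom <- window_density(track, gene, promoter_window[1], promoter_window[2])
  body <- window_density(track, gene, body_offset, gene$length)
  defined <- body > body_floor
  data.frame(
    gene_id = gene$gene_id, sample = track$sample_id,
    promoter_density = prom, body_density = body,
    pausing_index = if (defined) prom / body else NA_real_,
    defined = defined
  )
}

#' Pausing indices for a gene set, with the cumulative-index curve
#'
#' Computes one [pausing_index()] record per gene and the empirical CDF of
#' the log-index over defined records (the cumulative index plot).
#'
#' @param track an [occupancy_track].
#' @param genes a [gene_models] table.
#' @param ... passed to [pausing_index()].
#' @return A `data.frame` of records with attribute `"cumulative"`, a
#'   function: the ECDF of `log(pausing_index)` over defined genes. Window
#'   parameters are recorded in attribute `"params"`.
#' @export
pausing_index_table <- function(track, genes, ...) {
  records <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i)
    pausing_index(track, genes[i, ], ...)))
  ok <- records$defined & is.finite(records$pausing_index) &
    records$pausing_index > 0
  if (!any(ok)) warning("no gene has a defined pausing index")
  attr(records, "cumulative") <- if (any(ok))
    ecdf(log(records$pausing_index[ok])) else NULL
  attr(records, "params") <- list(...)
  records
}

#' Compare two pausing-index distributions
#'
#' Two-sided Wilcoxon rank-sum test on the log pausing indices of the genes
#' defined in both record sets (the paired gene universe; undefined genes are
#' dropped from both sides).
#'
#' @param records_a,records_b outputs of [pausing_index_table()] computed on
#'   the same gene universe.
#' @param exact passed to [stats::wilcox.test()]; default lets R choose
#'   (exact for small samples without ties).
#' @return The `htest` object, with `n` (shared genes) appended.
#' @export
compare_index_distributions <- function(records_a, records_b, exact = NULL) {
  ok_a <- records_a[records_a$defined & is.finite(records_a$pausing_index), ]
  ok_b <- records_b[records_b$defined & is.finite(records_b$pausing_index), ]
  shared <- intersect(ok_a$gene_id, ok_b$gene_id)
  if (!length(shared))
    stop("no shared genes with defined pausing indices between the two sets")
  a <- log(ok_a$pausing_index[match(shared, ok_a$gene_id)])
  b <- log(ok_b$pausing_index[match(shared, ok_b$gene_id)])
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact))
  # fully tied samples have zero rank variance; the statistic sits at the
  # null center and the two-sided p is 1
  if (is.nan(ht$p.value)) ht$p.value <- 1
  ht$n <- length(shared)
  ht
}
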