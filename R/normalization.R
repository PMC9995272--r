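#' Spike-in scale factors
#'
#' Computes per-sample multiplicative factors from exogenous spike-in read
#' totals, `factor(s) = spike_count(reference) / spike_count(s)`, so that
#' applying the factors equalizes spike totals across samples. The reference
#' sample gets factor 1; by convention the untreated / 0-min sample is used
#' as reference (the choice only rescales all samples jointly).
#'
#' @param tracks list of [occupancy_track] objects, or a sample-sheet
#'   `data.frame` with `sample` and `spike_count` columns.
#' @param reference sample_id of the reference sample; defaults to the first.
#' @return A named numeric vector of class `scale_factor_set` with attribute
#'   `reference`.
#' @export
spikein_scale_factors <- function(tracks, reference = NULL) {
  if (is.data.frame(tracks)) {
    ids <- as.character(tracks$sample)
    spikes <- as.numeric(tracks$spike_count)
  } else {
    ids <- vapply(tracks, `[[`, character(1), "sample_id")
    spikes <- vapply(tracks, `[[`, numeric(1), "spike_count")
  }
  names(spikes) <- ids
  bad <- ids[is.na(spikes) | spikes <= 0]
  if (length(bad))
    stop("missing or non-positive spike_count for sample(s): ",
         paste(bad, collapse = ", "))
  if (is.null(reference)) reference <- ids[1]
  if (!reference %in% ids) stop("reference sample not found: ", reference)
  factors <- spikes[[reference]] / spikes
  structure(factors, reference = reference,
            class = c("scale_factor_set", "numeric"))
}

#' @export
print.scale_factor_set <- function(x, ...) {
  cat("<scale_factor_set> reference =", attr(x, "reference"), "\n")
  print(setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Apply spike-in scale factors to tracks
#'
#' Sets each track's `scale` field; density accessors multiply by it.
#'
#' @param tracks list of [occupancy_track] objects.
#' @param factors a [spikein_scale_factors()] result.
#' @return the track list with scales set.
#' @export
apply_scale_factors <- function(tracks, factors) {
  lapply(tracks, function(tr) {
    if (!tr$sample_id %in% names(factors))
      stop("no scale factor for sample ", tr$sample_id)
    tr$scale <- as.numeric(factors[[tr$sample_id]])
    tr
  })
}

#' Signal density over a strand-aware TSS-offset window
#'
#' `per_base` is the spike-scaled mean per-base signal over the window;
#' `rpkm` is reads per kilobase per million mapped reads, computed from raw
#' (unscaled) counts against the sample's own library size, matching the
#' standard within-sample definition.
#'
#' @param track an [occupancy_track].
#' @param gene one row of a [gene_models] table.
#' @param offset_start,offset_end window in bp offsets from the TSS,
#'   `offset_start < offset_end` (offset 0 = the TSS base).
#' @param unit `"per_base"` or `"rpkm"`.
#' @return a single density value.
#' @export
window_density <- function(track, gene, offset_start, offset_end,
                           unit = c("per_base", "rpkm")) {
  unit <- match.arg(unit)
  v <- window_counts(track, gene, offset_start, offset_end)
  width <- offset_end - offset_start
  if (unit == "per_base") {
    track$scale * sum(v) / width
  } else {
    if (track$library_size <= 0) stop("library_size must be positive for rpkm")
    sum(v) / ((width / 1000) * (track$library_size / 1e6))
  }
}

#' Gene expression in reads per million
#'
#' Raw whole-gene signal total per million mapped reads of the sample.
#'
#' @inheritParams window_density
#' @return rpm value.
#' @export
gene_rpm <- function(track, gene) {
  v <- window_counts(track, gene, 0, gene$length)
  sum(v) / (track$library_size / 1e6)
}
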