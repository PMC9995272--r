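#' Select genes for wave-peak analysis
#'
#' Keeps protein-coding genes whose length lies strictly between `min_kb` and
#' `max_kb` (default 60-300 kb) and that do not overlap any other gene in the
#' input on either strand; both members of an overlapping pair are excluded.
#'
#' @param genes a [gene_models] table.
#' @param min_kb,max_kb exclusive length bounds in kb.
#' @return the filtered [gene_models] table (possibly empty).
#' @export
select_rate_genes <- function(genes, min_kb = 60, max_kb = 300) {
  if (!nrow(genes)) return(genes)
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end))
  hits <- GenomicRanges::countOverlaps(gr, gr, ignore.strand = TRUE)
  keep <- hits == 1 &                       # only itself
    genes$length > min_kb * 1000 &
    genes$length < max_kb * 1000 &
    genes$biotype == "protein_coding"
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# binned, spike-scaled, strand-projected coverage of one gene over
# offsets [0, nbins * grid_bp); replicate tracks pooled after scaling
binned_gene_coverage <- function(tracks, gene, nbins, grid_bp) {
  acc <- numeric(nbins)
  for (tr in tracks) {
    v <- window_counts(tr, gene, 0, nbins * grid_bp) * tr$scale
    acc <- acc + colMeans(matrix(v, nrow = grid_bp))
  }
  acc
}

#' Trimmed-mean metagene profile at one timepoint
#'
#' For each offset bin downstream of the TSS, takes the symmetric trimmed
#' mean over genes of spike-scaled, strand-projected coverage; replicate
#' tracks are pooled after scaling. Genes shorter than the profiled region
#' are dropped so that every gene contributes to every bin.
#'
#' @param tracks_at_t list of [occupancy_track] objects for one timepoint
#'   (replicates of one condition), scale factors applied.
#' @param genes a [gene_models] table (normally [select_rate_genes()]
#'   output).
#' @param region_kb profiled region downstream of the TSS, in kb.
#' @param trim_fraction fraction trimmed from each tail of the per-bin gene
#'   distribution (must be < 0.5); 0 gives the plain mean.
#' @param grid_bp offset bin width in bp.
#' @return An object of class `metagene_profile`: list with `offsets` (bin
#'   midpoints, bp), `raw`, `smooth` (`NULL` until [smooth_profile()]),
#'   `timepoint_min`, `n_genes`, `scope`, `grid_bp`.
#' @export
metagene <- function(tracks_at_t, genes, region_kb = 120,
                     trim_fraction = 0.1, grid_bp = 100) {
  if (trim_fraction >= 0.5) stop("trim_fraction must be < 0.5")
  if (!length(tracks_at_t)) stop("no tracks supplied")
  region <- round(region_kb * 1000)
  nbins <- region %/% grid_bp
  use <- genes[genes$length >= nbins * grid_bp, , drop = FALSE]
  if (!nrow(use)) stop("no gene is at least as long as the profiled region")
  mat <- t(vapply(seq_len(nrow(use)), function(i)
    binned_gene_coverage(tracks_at_t, use[i, ], nbins, grid_bp),
    numeric(nbins)))
  raw <- apply(mat, 2, mean, trim = trim_fraction)
  t0 <- unique(vapply(tracks_at_t, `[[`, numeric(1), "timepoint_min"))
  structure(
    list(offsets = (seq_len(nbins) - 0.5) * grid_bp, raw = raw,
         smooth = NULL, timepoint_min = if (length(t0) == 1) t0 else NA_real_,
         n_genes = nrow(use), scope = "metagene", grid_bp = grid_bp),
    class = "metagene_profile"
  )
}

#' Per-gene coverage profile at one timepoint
#'
#' Binned, spike-scaled coverage of a single gene (replicates pooled), in the
#' same container as [metagene()] so the peak-calling path is shared.
#'
#' @inheritParams metagene
#' @param gene one row of a [gene_models] table.
#' @return a `metagene_profile` with `scope = gene_id`, `n_genes = 1`.
#' @export
gene_profile <- function(tracks_at_t, gene, grid_bp = 100) {
  nbins <- gene$length %/% grid_bp
  raw <- binned_gene_coverage(tracks_at_t, gene, nbins, grid_bp)
  t0 <- unique(vapply(tracks_at_t, `[[`, numeric(1), "timepoint_min"))
  structure(
    list(offsets = (seq_len(nbins) - 0.5) * grid_bp, raw = raw,
         smooth = NULL, timepoint_min = if (length(t0) == 1) t0 else NA_real_,
         n_genes = 1L, scope = gene$gene_id, grid_bp = grid_bp),
    class = "metagene_profile"
  )
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf(
    "<metagene_profile> %s t=%g min, %d genes, %d bins of %d bp%s\n",
    x$scope, x$timepoint_min, x$n_genes, length(x$offsets), x$grid_bp,
    if (is.null(x$smooth)) "" else " (smoothed)"))
  invisible(x)
}

#' @export
plot.metagene_profile <- function(x, ...) {
  graphics::plot(x$offsets / 1000, x$raw, type = "l", col = "grey60",
                 xlab = "offset from TSS (kb)", ylab = "coverage",
                 main = sprintf("%s, t = %g min", x$scope, x$timepoint_min),
                 ...)
  if (!is.null(x$smooth))
    graphics::lines(x$offsets / 1000, x$smooth, col = "firebrick", lwd = 2)
  invisible(x)
}

#' Smooth a coverage profile with a cubic smoothing spline
#'
#' Fits [stats::smooth.spline()] to the raw values over the offset grid; the
#' smoothing penalty is chosen by generalized cross-validation unless `spar`
#' or `df` is given. The smoothing parameter used is recorded on the profile.
#' A degenerate (constant) profile is passed through unchanged.
#'
#' @param profile a `metagene_profile`.
#' @param spar,df optional smoothing overrides, passed to
#'   [stats::smooth.spline()].
#' @return the profile with `smooth` filled in on the same grid.
#' @export
smooth_profile <- function(profile, spar = NULL, df = NULL) {
  if (length(profile$offsets) < 10)
    stop("need at least 10 grid points to smooth")
  if (var(profile$raw) == 0) {
    profile$smooth <- profile$raw
    profile$spar <- NA_real_
    return(profile)
  }
  args <- list(x = profile$offsets, y = profile$raw)
  if (!is.null(spar)) args$spar <- spar
  if (!is.null(df)) args$df <- df
  ss <- do.call(smooth.spline, args)
  profile$smooth <- predict(ss, profile$offsets)$y
  profile$spar <- ss$spar
  profile
}

#' Call advancing wave peaks across a release time course
#'
#' For the first timepoint (t = 0) the peak is the spline maximum over the
#' full grid (the promoter pause peak). For each later timepoint the peak is
#' the spline maximum over offsets strictly greater than the previous
#' timepoint's peak plus `exclusion_kb` — the stipulation that the wave must
#' advance with time. A timepoint whose eligible region is empty or flat gets
#' a no-peak flag. The unconstrained (free) spline maximum is also recorded;
#' the series is accepted only when every constrained peak exists and the
#' free maxima themselves advance strictly with time.
#'
#' @param profiles list of smoothed `metagene_profile` objects sharing one
#'   grid, in ascending timepoint order (see [smooth_profile()]).
#' @param exclusion_kb minimum advance between consecutive peaks, in kb.
#' @return An object of class `wave_peak_series`: `data.frame` with columns
#'   `timepoint_min`, `peak_offset_kb` (constrained; `NA` if no peak),
#'   `free_peak_kb`; attributes `scope`, `accepted`, `advancing`.
#' @export
call_wave_peaks <- function(profiles, exclusion_kb = 2) {
  stopifnot(length(profiles) >= 1)
  times <- vapply(profiles, `[[`, numeric(1), "timepoint_min")
  if (is.unsorted(times, strictly = TRUE))
    stop("profiles must be in strictly ascending timepoint order")
  grids <- vapply(profiles, function(p) length(p$offsets), numeric(1))
  if (length(unique(grids)) != 1) stop("profiles must share one offset grid")
  for (p in profiles) if (is.null(p$smooth))
    stop("profiles must be smoothed first (smooth_profile)")
  offs <- profiles[[1]]$offsets
  peak <- rep(NA_real_, length(profiles))
  free <- rep(NA_real_, length(profiles))
  prev <- -Inf
  for (i in seq_along(profiles)) {
    s <- profiles[[i]]$smooth
    free[i] <- offs[which.max(s)]
    elig <- if (i == 1) rep(TRUE, length(offs))
            else offs > prev + exclusion_kb * 1000
    if (!any(elig) || var(s[elig]) == 0) {
      peak[i] <- NA_real_
    } else {
      peak[i] <- offs[elig][which.max(s[elig])]
      prev <- peak[i]
    }
  }
  out <- data.frame(timepoint_min = times, peak_offset_kb = peak / 1000,
                    free_peak_kb = free / 1000)
  attr(out, "scope") <- profiles[[1]]$scope
  attr(out, "advancing") <- !is.unsorted(free, strictly = TRUE)
  attr(out, "accepted") <- all(!is.na(peak)) && attr(out, "advancing")
  class(out) <- c("wave_peak_series", "data.frame")
  out
}

#' Fit an elongation rate to a wave-peak series
#'
#' Ordinary least squares of wave-peak position (kb) on time (min) over the
#' post-release (t > 0) points; the elongation rate is the slope in kb/min.
#' Per-timepoint rates (peak / time for each t > 0) are also reported - the
#' position-over-time variant used for per-gene rate tables.
#'
#' @param series a [call_wave_peaks()] result (or any `data.frame` with
#'   `timepoint_min` and `peak_offset_kb`).
#' @return An object of class `rate_fit`: list with `scope`, `rate_kb_min`,
#'   `intercept_kb`, `r2`, `n_points`, `per_timepoint_rates`, `series`.
#' @export
fit_rate <- function(series) {
  use <- series[series$timepoint_min > 0 & !is.na(series$peak_offset_kb), ]
  if (nrow(use) < 2)
    stop("need at least 2 post-release wave peaks to fit a rate")
  fit <- lm(peak_offset_kb ~ timepoint_min, data = use)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((use$peak_offset_kb - mean(use$peak_offset_kb))^2)
  structure(
    list(scope = attr(series, "scope"),
         rate_kb_min = coef(fit)[["timepoint_min"]],
         intercept_kb = coef(fit)[["(Intercept)"]],
         r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
         n_points = nrow(use),
         per_timepoint_rates = setNames(
           use$peak_offset_kb / use$timepoint_min,
           paste0("t", use$timepoint_min)),
         series = series),
    class = "rate_fit"
  )
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf(
    "<rate_fit> %s: %.3g kb/min (intercept %.3g kb, r2 = %.4g, n = %d)\n",
    if (is.null(x$scope)) "series" else x$scope,
    x$rate_kb_min, x$intercept_kb, x$r2, x$n_points))
  invisible(x)
}

#' @export
coef.rate_fit <- function(object, ...) {
  c(intercept_kb = object$intercept_kb, rate_kb_min = object$rate_kb_min)
}

#' @export
predict.rate_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$timepoint_min
       else if (is.list(newdata)) newdata$timepoint_min else as.numeric(newdata)
  object$intercept_kb + object$rate_kb_min * t
}

#' Per-gene eligibility filters for elongation-rate estimation
#'
#' Three flags, mirroring the rate-analysis filter cascade:
#' \describe{
#'   \item{expression}{the gene is expressed in the t = 0 control TT sample:
#'     whole-gene signal strictly above `rpm_min` reads per million
#'     (default 100).}
#'   \item{anchored}{the t = 0 wave peak falls within `anchor_kb` of the
#'     promoter pause region, i.e. peak offset <= `anchor_kb` (default
#'     10.3 kb = 10 kb + the 300-bp pause window).}
#'   \item{monotone}{the free (unconstrained) peaks strictly increase across
#'     all timepoints, 0 < 10 < 20 < 30 min.}
#' }
#'
#' @param gene one row of a [gene_models] table.
#' @param tracks_t0 t = 0 TT track(s) (replicates pooled over for rpm).
#' @param series the gene's [call_wave_peaks()] result.
#' @param rpm_min expression threshold in reads per million (strict).
#' @param anchor_kb anchoring threshold in kb.
#' @return list with `expression`, `anchored`, `monotone`, `eligible`, `rpm`.
#' @export
per_gene_rate_filters <- function(gene, tracks_t0, series, rpm_min = 100,
                                  anchor_kb = 10.3) {
  if (inherits(tracks_t0, "occupancy_track")) tracks_t0 <- list(tracks_t0)
  rpm <- mean(vapply(tracks_t0, gene_rpm, numeric(1), gene = gene))
  p0 <- series$peak_offset_kb[series$timepoint_min == 0]
  anchored <- length(p0) == 1 && !is.na(p0) && p0 <= anchor_kb
  free <- series$free_peak_kb
  monotone <- all(!is.na(free)) && !is.unsorted(free, strictly = TRUE)
  out <- list(expression = rpm > rpm_min, anchored = anchored,
              monotone = monotone, rpm = rpm)
  out$eligible <- out$expression && out$anchored && out$monotone
  out
}

#' Per-gene elongation rates for a cohort
#'
#' Runs the full per-gene wave analysis: binned profile per timepoint
#' (replicates pooled after scaling), spline smoothing, advancing wave-peak
#' calling, the eligibility filter cascade, and the linear rate fit.
#'
#' @param tracks all DRB-release tracks of one condition (scale factors
#'   applied); grouped by `timepoint_min` internally.
#' @param genes a [gene_models] table ([select_rate_genes()] output).
#' @param grid_bp profile bin width in bp.
#' @param exclusion_kb peak-advance exclusion, in kb.
#' @param rpm_min,anchor_kb see [per_gene_rate_filters()].
#' @param spar,df optional smoothing overrides (see [smooth_profile()]).
#' @return A `data.frame`, one row per gene: `gene_id`, `rate_kb_min`,
#'   `intercept_kb`, `r2`, `n_points`, `rate_ratio_mean` (mean of peak/time),
#'   `rpm`, `expression`, `anchored`, `monotone`, `accepted`, `eligible`.
#' @export
gene_wave_rates <- function(tracks, genes, grid_bp = 100, exclusion_kb = 2,
                            rpm_min = 100, anchor_kb = 10.3,
                            spar = NULL, df = NULL) {
  times <- sort(unique(vapply(tracks, `[[`, numeric(1), "timepoint_min")))
  by_t <- lapply(times, function(t)
    tracks[vapply(tracks, function(tr) tr$timepoint_min == t, logical(1))])
  t0_tracks <- by_t[[which(times == 0)]]
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    profiles <- lapply(by_t, function(trs)
      smooth_profile(gene_profile(trs, gene, grid_bp), spar = spar, df = df))
    series <- call_wave_peaks(profiles, exclusion_kb)
    flags <- per_gene_rate_filters(gene, t0_tracks, series, rpm_min,
                                   anchor_kb)
    fit <- tryCatch(fit_rate(series), error = function(e) NULL)
    data.frame(
      gene_id = gene$gene_id,
      rate_kb_min = if (is.null(fit)) NA_real_ else fit$rate_kb_min,
      intercept_kb = if (is.null(fit)) NA_real_ else fit$intercept_kb,
      r2 = if (is.null(fit)) NA_real_ else fit$r2,
      n_points = if (is.null(fit)) 0L else fit$n_points,
      rate_ratio_mean = if (is.null(fit)) NA_real_ else
        mean(fit$per_timepoint_rates),
      rpm = flags$rpm,
      expression = flags$expression, anchored = flags$anchored,
      monotone = flags$monotone, accepted = attr(series, "accepted"),
      eligible = flags$eligible && !is.null(fit)
    )
  })
  do.call(rbind, rows)
}

#' Metagene wave-peak series and rate across a release time course
#'
#' Convenience wrapper: builds one trimmed-mean metagene per timepoint,
#' smooths it, calls advancing wave peaks and fits the metagene rate.
#'
#' @inheritParams metagene
#' @inheritParams gene_wave_rates
#' @param tracks all DRB-release tracks of one condition, scale applied.
#' @return list with `profiles` (smoothed, by timepoint), `series`
#'   (a [call_wave_peaks()] result) and `fit` (a [fit_rate()] result, or
#'   `NULL` if fewer than 2 post-release peaks).
#' @export
metagene_rate <- function(tracks, genes, region_kb = 120,
                          trim_fraction = 0.1, grid_bp = 100,
                          exclusion_kb = 2, spar = NULL, df = NULL) {
  times <- sort(unique(vapply(tracks, `[[`, numeric(1), "timepoint_min")))
  profiles <- lapply(times, function(t) {
    trs <- tracks[vapply(tracks, function(tr) tr$timepoint_min == t,
                         logical(1))]
    smooth_profile(metagene(trs, genes, region_kb, trim_fraction, grid_bp),
                   spar = spar, df = df)
  })
  series <- call_wave_peaks(profiles, exclusion_kb)
  fit <- tryCatch(fit_rate(series), error = function(e) NULL)
  list(profiles = profiles, series = series, fit = fit)
}
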