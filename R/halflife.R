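#' Build a promoter-window time course for one gene
#'
#' Collects spike-scaled per-base densities over a TSS window (default
#' offsets \[0, 300)) from a triptolide time-course track set into a
#' timepoint x replicate matrix, plus the gene's whole-transcript RPKM at
#' t = 0 (mean of replicates) used by the detectability filter.
#'
#' @param tracks list of [occupancy_track] objects covering every
#'   timepoint x replicate of one condition (assay `"mnet"`); scale factors
#'   should already be applied (see [apply_scale_factors()]).
#' @param gene one row of a [gene_models] table.
#' @param window length-2 bp offsets from the TSS, default `c(0, 300)`.
#' @return An object of class `timecourse`: list with `gene_id`, `times`
#'   (sorted, starting at 0), `densities` (matrix, rows = timepoints,
#'   columns = replicates), `rpkm0`, `window`.
#' @export
build_timecourse <- function(tracks, gene, window = c(0, 300)) {
  times <- sort(unique(vapply(tracks, `[[`, numeric(1), "timepoint_min")))
  reps <- sort(unique(vapply(tracks, `[[`, integer(1), "replicate")))
  if (times[1] != 0) stop("time course must include t = 0")
  key <- function(tr) paste(tr$timepoint_min, tr$replicate)
  index <- setNames(seq_along(tracks), vapply(tracks, key, character(1)))
  wanted <- as.vector(outer(times, reps, paste))
  gaps <- setdiff(wanted, names(index))
  if (length(gaps))
    stop("missing timepoint x replicate combination(s): ",
         paste(gaps, collapse = "; "))
  dens <- matrix(NA_real_, nrow = length(times), ncol = length(reps),
                 dimnames = list(paste0("t", times), paste0("rep", reps)))
  for (i in seq_along(times)) for (j in seq_along(reps)) {
    tr <- tracks[[index[[paste(times[i], reps[j])]]]]
    dens[i, j] <- window_density(tr, gene, window[1], window[2])
  }
  rpkm0 <- mean(vapply(reps, function(r) {
    tr <- tracks[[index[[paste(0, r)]]]]
    window_density(tr, gene, 0, gene$length, unit = "rpkm")
  }, numeric(1)))
  structure(list(gene_id = gene$gene_id, times = times, densities = dens,
                 rpkm0 = rpkm0, window = window),
            class = "timecourse")
}

#' Replicate variability of a time course
#'
#' Mean over timepoints of the standard deviation across replicates of
#' densities normalized to the replicate-mean density at t = 0, so the
#' statistic is dimensionless and the threshold is depth-independent.
#'
#' @param tc a [build_timecourse()] object.
#' @return sigma, or `NA` with a single replicate.
#' @export
replicate_sigma <- function(tc) {
  if (ncol(tc$densities) < 2) return(NA_real_)
  d0 <- mean(tc$densities[1, ])
  if (d0 <= 0) return(NA_real_)
  mean(apply(tc$densities / d0, 1, sd))
}

#' Gene filters for half-life estimation
#'
#' The three selection criteria applied before half-life summaries, all as
#' strict inequalities:
#' \describe{
#'   \item{pass_rpkm}{detectable RNAPII: whole-transcript RPKM at t = 0
#'     strictly greater than `rpkm_min` (default 1).}
#'   \item{pass_max_at_zero}{the replicate-mean promoter density at 0 min is
#'     the strict maximum over timepoints (no initiation block should beat
#'     the untreated sample).}
#'   \item{pass_sigma}{replicate variability [replicate_sigma()] strictly
#'     below `sigma_max` (default 0.05). With a single replicate the
#'     criterion is passed with a warning (sigma undefined).}
#' }
#'
#' @param tc a [build_timecourse()] object.
#' @param rpkm_min,sigma_max filter thresholds.
#' @return list with the three logical flags, `replicate_sigma` and `pass`
#'   (all three hold).
#' @export
apply_gene_filters <- function(tc, rpkm_min = 1, sigma_max = 0.05) {
  means <- rowMeans(tc$densities)
  sig <- replicate_sigma(tc)
  pass_sigma <- if (is.na(sig) && ncol(tc$densities) < 2) {
    warning("single replicate: replicate sigma undefined, filter passed")
    TRUE
  } else !is.na(sig) && sig < sigma_max
  flags <- list(
    pass_rpkm = tc$rpkm0 > rpkm_min,
    pass_max_at_zero = all(means[1] > means[-1]),
    pass_sigma = pass_sigma,
    replicate_sigma = sig
  )
  flags$pass <- flags$pass_rpkm && flags$pass_max_at_zero && flags$pass_sigma
  flags
}

#' Fit an exponential-decay model to a promoter time course
#'
#' Fits `N(t) = n0 * exp(-k * t)` to the replicate-mean promoter densities,
#' normalized to 1 at t = 0, by nonlinear least squares (Levenberg-Marquardt)
#' with `n0` free near 1 and `k > 0`; the half-life is `ln(2) / k`.
#' Initialization is deterministic, from a log-linear pre-fit of
#' `log(N)` on `t`. When no post-zero density falls below the t = 0 level the
#' fit is degenerate (no measurable decay): `k` is reported at the lower
#' bound and the fit is flagged for exclusion from summaries.
#'
#' `fit_decay()` accepts either a [build_timecourse()] object or raw `times`
#' and `values` vectors.
#'
#' @param x a `timecourse`, or numeric vector of times (minutes, starting
#'   at 0).
#' @param values densities at `x` (single replicate vector or a
#'   timepoint x replicate matrix, averaged before fitting).
#' @param k_min lower bound for the decay rate (1/min).
#' @return An object of class `decay_fit`: list with `gene_id`, `times`,
#'   `data` (normalized replicate-mean densities), `n0`, `k`,
#'   `half_life_min`, `rmse`, `degenerate`, `scale` (the t = 0 level the data
#'   were normalized by).
#' @export
fit_decay <- function(x, values = NULL, k_min = 1e-4) {
  if (inherits(x, "timecourse")) {
    times <- x$times
    y <- rowMeans(x$densities)
    gene_id <- x$gene_id
  } else {
    times <- as.numeric(x)
    y <- if (is.matrix(values)) rowMeans(values) else as.numeric(values)
    gene_id <- NA_character_
  }
  if (length(times) != length(y)) stop("times and values differ in length")
  if (times[1] != 0) stop("time course must start at t = 0")
  if (y[1] <= 0) stop("density at t = 0 must be positive")
  scale <- y[1]
  yn <- y / scale
  degenerate <- all(yn[-1] >= yn[1])
  # deterministic init: log-linear pre-fit (guarding zeros)
  eps <- max(min(yn[yn > 0]) * 1e-3, 1e-12)
  pre <- lm(log(pmax(yn, eps)) ~ times)
  k0 <- max(-coef(pre)[[2]], k_min)
  n0_0 <- min(max(exp(coef(pre)[[1]]), 0.5), 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yn ~ n0 * exp(-k * t),
      data = list(yn = yn, t = times),
      start = list(n0 = n0_0, k = k0),
      lower = c(n0 = 0, k = k_min),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    n0 <- yn[1]; k <- k_min
    fitted <- n0 * exp(-k * times)
    degenerate <- TRUE
  } else {
    cf <- coef(fit)
    n0 <- cf[["n0"]]; k <- max(cf[["k"]], k_min)
    fitted <- n0 * exp(-k * times)
  }
  structure(
    list(gene_id = gene_id, times = times, data = yn, n0 = n0, k = k,
         half_life_min = log(2) / k,
         rmse = sqrt(mean((yn - fitted)^2)),
         degenerate = degenerate, scale = scale),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "<decay_fit>%s k = %.4g /min, half-life = %.3g min, n0 = %.3g, rmse = %.3g%s\n",
    if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
    x$k, x$half_life_min, x$n0, x$rmse,
    if (x$degenerate) " [degenerate: no measurable decay]" else ""))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  out <- data.frame(time_min = object$times, observed = object$data,
                    fitted = object$n0 * exp(-object$k * object$times))
  cat(sprintf("Exponential decay fit: N(t) = %.4g * exp(-%.4g t)\n",
              object$n0, object$k))
  cat(sprintf("Half-life %.4g min; rmse %.3g; degenerate: %s\n",
              object$half_life_min, object$rmse, object$degenerate))
  invisible(out)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(n0 = object$n0, k = object$k, half_life_min = object$half_life_min)
}

#' @export
predict.decay_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.list(newdata)) newdata$time else as.numeric(newdata)
  object$n0 * exp(-object$k * t)
}

#' @export
residuals.decay_fit <- function(object, ...) {
  object$data - predict(object)
}

#' Half-life fits for a gene cohort
#'
#' Builds the time course, applies the three gene filters and fits the decay
#' model for every gene.
#'
#' @param tracks triptolide time-course tracks (one condition), scale factors
#'   applied.
#' @param genes a [gene_models] table.
#' @param condition condition label recorded in the output.
#' @param window promoter window (bp offsets), default `c(0, 300)`.
#' @param rpkm_min,sigma_max filter thresholds (see [apply_gene_filters()]).
#' @return A `data.frame` with one row per gene: `gene_id`, `condition`, `k`,
#'   `half_life_min`, `n0`, `rmse`, `replicate_sigma`, `pass_rpkm`,
#'   `pass_max_at_zero`, `pass_sigma`, `degenerate`, `pass` (all filters and
#'   not degenerate).
#' @export
halflife_table <- function(tracks, genes, condition = "control",
                           window = c(0, 300), rpkm_min = 1,
                           sigma_max = 0.05) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    gene <- genes[i, ]
    tc <- build_timecourse(tracks, gene, window)
    if (mean(tc$densities[1, ]) <= 0) {
      return(data.frame(
        gene_id = gene$gene_id, condition = condition, k = NA_real_,
        half_life_min = NA_real_, n0 = NA_real_, rmse = NA_real_,
        replicate_sigma = NA_real_, pass_rpkm = FALSE,
        pass_max_at_zero = FALSE, pass_sigma = FALSE, degenerate = TRUE,
        pass = FALSE))
    }
    flags <- apply_gene_filters(tc, rpkm_min, sigma_max)
    fit <- fit_decay(tc)
    data.frame(
      gene_id = gene$gene_id, condition = condition, k = fit$k,
      half_life_min = fit$half_life_min, n0 = fit$n0, rmse = fit$rmse,
      replicate_sigma = flags$replicate_sigma,
      pass_rpkm = flags$pass_rpkm,
      pass_max_at_zero = flags$pass_max_at_zero,
      pass_sigma = flags$pass_sigma,
      degenerate = fit$degenerate,
      pass = flags$pass && !fit$degenerate
    )
  })
  do.call(rbind, rows)
}

#' Cohort summary of half-life fits
#'
#' Mean and median half-life over genes passing all filters, per condition,
#' with a kernel-density export for plotting and (for exactly two conditions)
#' a paired per-gene comparison table.
#'
#' @param fits a [halflife_table()] result, possibly row-bound over
#'   conditions.
#' @return list of class `halflife_summary`: `per_condition` (`data.frame`
#'   with `condition`, `n`, `mean_half_life_min`, `median_half_life_min`),
#'   `density` (list of [stats::density()] objects per condition), `paired`
#'   (per-gene wide table, or `NULL`).
#' @export
halflife_summary <- function(fits) {
  ok <- fits[fits$pass & is.finite(fits$half_life_min), ]
  if (!nrow(ok)) stop("no genes pass all filters")
  conds <- unique(ok$condition)
  per <- do.call(rbind, lapply(conds, function(cn) {
    h <- ok$half_life_min[ok$condition == cn]
    data.frame(condition = cn, n = length(h),
               mean_half_life_min = mean(h),
               median_half_life_min = median(h))
  }))
  dens <- lapply(setNames(conds, conds), function(cn)
    density(ok$half_life_min[ok$condition == cn]))
  paired <- NULL
  if (length(conds) == 2) {
    a <- ok[ok$condition == conds[1], c("gene_id", "half_life_min")]
    b <- ok[ok$condition == conds[2], c("gene_id", "half_life_min")]
    paired <- merge(a, b, by = "gene_id", suffixes = paste0("_", conds))
  }
  structure(list(per_condition = per, density = dens, paired = paired),
            class = "halflife_summary")
}

#' @export
print.halflife_summary <- function(x, ...) {
  cat("<halflife_summary>\n")
  print(x$per_condition, row.names = FALSE)
  invisible(x)
}
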