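test_that("rate-gene selection applies strict bounds and the non-overlap rule", {
  lens <- c(50, 60, 100, 300, 299) * 1000
  starts <- cumsum(c(10e3, head(lens, -1) + 10e3))
  g <- gene_models(paste0("g", 1:5), "chrS", starts, starts + lens,
                   rep(c("+", "-"), length.out = 5))
  keep <- select_rate_genes(g)
  expect_setequal(keep$gene_id, c("g3", "g5"))

  # an overlapping pair is excluded entirely, on either strand
  g2 <- gene_models(c("a", "b", "c"), "chrS",
                    c(10e3, 50e3, 500e3),
                    c(10e3 + 100e3, 50e3 + 10e3, 500e3 + 100e3),
                    c("+", "-", "+"))
  keep2 <- select_rate_genes(g2)
  expect_equal(keep2$gene_id, "c")

  # biotype matters and empty input passes through
  g3 <- gene_models("r1", "chrS", 1e4, 1.2e5, "+", biotype = "lincRNA")
  expect_equal(nrow(select_rate_genes(g3)), 0)
  expect_equal(nrow(select_rate_genes(g2[0, ])), 0)
})

test_that("the metagene is a per-bin trimmed mean over genes", {
  # five genes with constant coverage {0, 1, 2, 3, 100}
  vals <- c(0, 1, 2, 3, 100)
  len <- 3000; gap <- 500
  starts <- (seq_along(vals) - 1) * (len + gap) + gap
  g <- gene_models(paste0("g", seq_along(vals)), "chrS", starts,
                   starts + len, "+")
  plus <- numeric(max(starts) + len + gap)
  for (i in seq_along(vals))
    plus[(starts[i] + 1):(starts[i] + len)] <- vals[i]
  tr <- make_track(plus, assay = "ttseq")
  mg <- metagene(list(tr), g, region_kb = 2, trim_fraction = 0.2,
                 grid_bp = 100)
  expect_equal(unique(mg$raw), mean(c(1, 2, 3)))
  mg0 <- metagene(list(tr), g, region_kb = 2, trim_fraction = 0,
                  grid_bp = 100)
  expect_equal(unique(mg0$raw), mean(vals))
  expect_equal(mg$n_genes, 5)
  expect_error(metagene(list(tr), g, region_kb = 2, trim_fraction = 0.5),
               "trim_fraction")
})

test_that("identical shifted gene copies reproduce the single-gene profile", {
  shape <- rep(c(1, 4, 2, 0.5, 3), each = 100)  # 500 bp profile
  len <- 500; gap <- 300
  starts <- (0:3) * (len + gap) + gap
  g <- gene_models(paste0("g", 1:4), "chrS", starts, starts + len, "+")
  plus <- numeric(max(starts) + len + gap)
  for (s in starts) plus[(s + 1):(s + len)] <- shape
  mg <- metagene(list(make_track(plus, assay = "ttseq")), g,
                 region_kb = 0.5, trim_fraction = 0.1, grid_bp = 100)
  expect_equal(mg$raw, colMeans(matrix(shape, nrow = 100)))
})

test_that("spline smoothing preserves clean peaks and contracts noise", {
  offs <- seq(50, 40000, by = 100)
  bump <- exp(-(offs - 20050)^2 / (2 * 3000^2))
  prof <- structure(list(offsets = offs, raw = bump, smooth = NULL,
                         timepoint_min = 10, n_genes = 5L,
                         scope = "metagene", grid_bp = 100),
                    class = "metagene_profile")
  sm <- smooth_profile(prof)
  expect_equal(sm$offsets[which.max(sm$smooth)],
               offs[which.max(bump)], tolerance = 100)

  set.seed(4)
  noise <- prof; noise$raw <- rnorm(length(offs))
  smn <- smooth_profile(noise, spar = 1)
  expect_lt(var(smn$smooth), var(smn$raw))

  flat <- prof; flat$raw <- rep(2, length(offs))
  smf <- smooth_profile(flat)
  expect_equal(smf$smooth, flat$raw)
})

test_that("wave peaks advance under the exclusion constraint", {
  profs <- list(make_profile(50, 0, width_bp = 200),
                make_profile(22000, 10), make_profile(44000, 20),
                make_profile(66000, 30))
  series <- call_wave_peaks(profs, exclusion_kb = 2)
  expect_s3_class(series, "wave_peak_series")
  expect_true(attr(series, "accepted"))
  expect_equal(series$peak_offset_kb, c(0.05, 21.95, 43.95, 65.95),
               tolerance = 0.01)
  expect_true(all(diff(series$peak_offset_kb) > 0))

  # a wave that fails to advance is flagged
  profs_bad <- list(make_profile(50, 0, width_bp = 200),
                    make_profile(22000, 10), make_profile(21000, 20),
                    make_profile(66000, 30))
  bad <- call_wave_peaks(profs_bad, exclusion_kb = 2)
  expect_false(attr(bad, "advancing"))
  expect_false(attr(bad, "accepted"))

  # single timepoint: one entry, not rate-fittable
  one <- call_wave_peaks(profs[1])
  expect_equal(nrow(one), 1)
  expect_error(fit_rate(one), "at least 2")
})

test_that("the worked linear fit gives 2.2 kb/min with r2 = 1", {
  series <- data.frame(timepoint_min = c(0, 10, 20, 30),
                       peak_offset_kb = c(0.05, 22, 44, 66))
  fit <- fit_rate(series)
  expect_equal(fit$rate_kb_min, 2.2)
  expect_equal(fit$r2, 1)
  expect_equal(fit$n_points, 3)

  two <- data.frame(timepoint_min = c(10, 20), peak_offset_kb = c(20, 40))
  f2 <- fit_rate(two)
  expect_equal(f2$rate_kb_min, 2.0)
  expect_equal(unname(f2$per_timepoint_rates), c(2.0, 2.0))
  expect_named(coef(f2), c("intercept_kb", "rate_kb_min"))
  expect_equal(predict(f2, 30), 60)
})

test_that("per-gene eligibility flags follow the filter cascade", {
  g <- make_gene(1000, 120000, "+")
  len <- 130000
  tt0 <- make_track(c(numeric(1000), rep(1, 119000), numeric(len - 120000)),
                    assay = "ttseq")
  series_ok <- data.frame(timepoint_min = c(0, 10, 20, 30),
                          peak_offset_kb = c(0.05, 18, 39, 61),
                          free_peak_kb = c(0.05, 18, 39, 61))
  f <- per_gene_rate_filters(g, tt0, series_ok)
  expect_true(f$expression && f$anchored && f$monotone && f$eligible)

  # rpm boundary is strict
  tt_low <- tt0
  tt_low$library_size <- tt0$library_size * 1e4  # dilutes to 99 rpm
  rpm <- polwave::gene_rpm(tt_low, g)
  f_low <- per_gene_rate_filters(g, tt_low, series_ok, rpm_min = rpm)
  expect_false(f_low$expression)

  # t = 0 peak at 12 kb is not anchored to the pause region
  series_far <- series_ok; series_far$peak_offset_kb[1] <- 12
  expect_false(per_gene_rate_filters(g, tt0, series_far)$anchored)

  # non-advancing free peaks break monotonicity
  series_dec <- series_ok; series_dec$free_peak_kb[3] <- 17
  expect_false(per_gene_rate_filters(g, tt0, series_dec)$monotone)
})

test_that("noise-free homogeneous waves are recovered exactly by both routes", {
  cfg <- sim_config(n_genes = 12, gene_length_range = c(95e3, 130e3),
                    velocity_range = c(2, 2), dispersion = 0,
                    front_sd = 0.2, wave_broadening_cv = 0, seed = 5)
  sim <- simulate_genome(cfg)
  tts <- simulate_drb_release(sim$genes, sim$truth, cfg)
  rg <- select_rate_genes(sim$genes)
  mg <- metagene_rate(tts, rg, region_kb = 90)
  # one grid bin per timepoint tolerance: 0.1 kb / 10 min
  expect_equal(mg$fit$rate_kb_min, 2, tolerance = 0.01)
  expect_equal(mg$fit$r2, 1, tolerance = 1e-4)

  rates <- gene_wave_rates(tts, rg)
  expect_true(all(rates$eligible))
  expect_equal(rates$rate_kb_min, rep(2, nrow(rates)), tolerance = 0.01)
})

test_that("rate estimates are invariant to global rescaling of the tracks", {
  cfg <- sim_config(n_genes = 6, gene_length_range = c(95e3, 130e3),
                    velocity_range = c(1.5, 3), dispersion = 0,
                    seed = 16)
  sim <- simulate_genome(cfg)
  tts <- simulate_drb_release(sim$genes, sim$truth, cfg)
  rg <- select_rate_genes(sim$genes)
  r1 <- gene_wave_rates(tts, rg)
  scaled <- lapply(tts, function(tr) { tr$scale <- tr$scale * 7.3; tr })
  r2 <- gene_wave_rates(scaled, rg)
  expect_equal(r1$rate_kb_min, r2$rate_kb_min, tolerance = 1e-9)
  # eligible-gene count is monotone non-increasing in the rpm threshold
  n_at <- function(thr) sum(gene_wave_rates(tts, rg, rpm_min = thr)$eligible)
  thresholds <- c(0, 100, 1e4, 1e8)
  counts <- vapply(thresholds, n_at, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
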