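test_that("time courses assemble as timepoint x replicate density matrices", {
  cfg <- sim_config(n_genes = 4, gene_length_range = c(5e3, 9e3),
                    intergenic_gap = 2e3, dispersion = 0, seed = 14)
  sim <- simulate_genome(cfg)
  tracks <- simulate_triptolide_timecourse(sim$genes, sim$truth, cfg)
  tc <- build_timecourse(tracks, sim$genes[1, ])
  expect_s3_class(tc, "timecourse")
  expect_equal(dim(tc$densities), c(5, 2))
  expect_equal(tc$times, c(0, 5, 10, 20, 40))
  expect_true(tc$rpkm0 > 0)
  # strand symmetry: a minus-strand gene with the same truth gives the same
  # course (noise-free)
  g_minus <- sim$genes[2, ]
  truth_same <- sim$truth
  truth_same$half_life_min <- sim$truth$half_life_min[1]
  truth_same$pause_amplitude <- sim$truth$pause_amplitude[1]
  tr2 <- simulate_triptolide_timecourse(sim$genes, truth_same, cfg)
  tc_p <- build_timecourse(tr2, sim$genes[1, ])
  tc_m <- build_timecourse(tr2, g_minus)
  expect_equal(tc_p$densities, tc_m$densities, tolerance = 1e-12)
})

test_that("window sums translate to per-base densities", {
  # 300 counts then 150 counts over the 300-bp window -> densities 1.0, 0.5
  plus0 <- numeric(2000); plus0[501:800] <- 1
  plus5 <- numeric(2000); plus5[501:800] <- 0.5
  g <- make_gene(500, 1800, "+")
  tracks <- list(
    make_track(plus0, sample_id = "a", timepoint_min = 0, replicate = 1L),
    make_track(plus5, sample_id = "b", timepoint_min = 5, replicate = 1L)
  )
  tc <- build_timecourse(tracks, g)
  expect_equal(unname(tc$densities[, 1]), c(1.0, 0.5))
})

test_that("incomplete designs are completeness errors listing the gaps", {
  cfg <- sim_config(n_genes = 2, gene_length_range = c(5e3, 9e3),
                    dispersion = 0, seed = 15)
  sim <- simulate_genome(cfg)
  tracks <- simulate_triptolide_timecourse(sim$genes, sim$truth, cfg)
  tracks[["mnet_t10_r2"]] <- NULL
  expect_error(build_timecourse(tracks, sim$genes[1, ]), "10 2")
})

test_that("each filter trips independently, with strict boundaries", {
  clean <- function(rpkm0 = 10, rising = FALSE, delta = 0) {
    m <- exp(-log(2) * c(0, 5, 10, 20, 40) / 5)
    if (rising) m[2] <- m[1] * 1.2
    make_tc(c(0, 5, 10, 20, 40), cbind(m * (1 + delta), m * (1 - delta)),
            rpkm0 = rpkm0)
  }
  f0 <- apply_gene_filters(clean())
  expect_true(f0$pass_rpkm && f0$pass_max_at_zero && f0$pass_sigma && f0$pass)
  expect_equal(f0$replicate_sigma, 0)

  # (1) detectability only
  f1 <- apply_gene_filters(clean(rpkm0 = 0.5))
  expect_false(f1$pass_rpkm)
  expect_true(f1$pass_max_at_zero && f1$pass_sigma)
  # boundary: rpkm exactly at the threshold fails the strict inequality
  expect_false(apply_gene_filters(clean(rpkm0 = 1.0))$pass_rpkm)

  # (2) maximum at 0 min only
  f2 <- apply_gene_filters(clean(rising = TRUE))
  expect_false(f2$pass_max_at_zero)
  expect_true(f2$pass_rpkm && f2$pass_sigma)

  # (3) replicate variability only; with densities m * (1 +/- delta) the
  # statistic is delta * sqrt(2) * mean(m), so pick delta to hit a target
  m <- exp(-log(2) * c(0, 5, 10, 20, 40) / 5)
  delta_for <- function(target) target / (sqrt(2) * mean(m))
  f3 <- apply_gene_filters(clean(delta = delta_for(0.06)))
  expect_false(f3$pass_sigma)
  expect_true(f3$pass_rpkm && f3$pass_max_at_zero)
  expect_equal(f3$replicate_sigma, 0.06, tolerance = 1e-9)
  expect_true(apply_gene_filters(clean(delta = delta_for(0.04)))$pass_sigma)
})

test_that("a single replicate passes sigma with a warning", {
  m <- exp(-log(2) * c(0, 5, 10) / 4)
  tc <- make_tc(c(0, 5, 10), cbind(m))
  expect_warning(f <- apply_gene_filters(tc), "single replicate")
  expect_true(f$pass_sigma)
  expect_true(is.na(f$replicate_sigma))
})

test_that("noiseless exponential input is recovered to 1e-6 relative", {
  times <- c(0, 5, 10, 20, 40)
  for (hl in c(1, 2.3, 5.3, 12, 31, 60)) {
    fit <- fit_decay(times, exp(-log(2) * times / hl))
    expect_equal(fit$half_life_min, hl, tolerance = 1e-6)
    expect_false(fit$degenerate)
  }
  # two points: {1, 0.5} at t = {0, 1} -> half-life 1
  expect_equal(fit_decay(c(0, 1), c(1, 0.5))$half_life_min, 1,
               tolerance = 1e-6)
  # invariant half_life * k = ln 2 by construction
  f <- fit_decay(times, exp(-times / 3))
  expect_equal(f$half_life_min * f$k, log(2))
})

test_that("the decay fit is scale invariant and monotone in half-life", {
  times <- c(0, 5, 10, 20, 40)
  y <- 0.8 * exp(-log(2) * times / 7) + 0  # n0 != 1 via scaling below
  f1 <- fit_decay(times, y)
  f2 <- fit_decay(times, y * 137)
  expect_equal(f1$k, f2$k, tolerance = 1e-9)
  expect_equal(f2$scale, f1$scale * 137)

  fits <- vapply(c(2, 4, 8, 16, 32),
                 function(hl) fit_decay(times,
                                        exp(-log(2) * times / hl))$half_life_min,
                 numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("degenerate and invalid courses are flagged or rejected", {
  times <- c(0, 5, 10, 20, 40)
  up <- fit_decay(times, c(1, 1.1, 1.2, 1.3, 1.4))
  expect_true(up$degenerate)
  expect_error(fit_decay(times, c(0, 1, 1, 1, 1)), "positive")
  expect_error(fit_decay(c(5, 10), c(1, 0.5)), "t = 0")
})

test_that("decay_fit methods are coherent", {
  times <- c(0, 5, 10, 20, 40)
  f <- fit_decay(times, 2 * exp(-log(2) * times / 6))
  expect_named(coef(f), c("n0", "k", "half_life_min"))
  expect_equal(predict(f, 0), f$n0)
  expect_equal(predict(f, list(time = c(0, 6))),
               f$n0 * c(1, exp(-f$k * 6)))
  expect_equal(max(abs(residuals(f))), 0, tolerance = 1e-8)
  expect_output(print(f), "half-life")
  expect_output(s <- summary(f), "Exponential decay")
})

test_that("fits on noisy cohorts match a dense grid-search oracle", {
  co <- noisy_halflife_cohort(n_genes = 30, seed = 2)
  genes <- co$sim$genes
  hit <- 0
  for (i in seq_len(nrow(genes))) {
    tc <- build_timecourse(co$tracks, genes[i, ])
    if (mean(tc$densities[1, ]) <= 0) next
    fit <- fit_decay(tc)
    if (fit$degenerate) next
    # oracle: profile out n0 analytically on a 2000-point log grid of k
    y <- rowMeans(tc$densities) / mean(tc$densities[1, ])
    kgrid <- exp(seq(log(log(2) / 120), log(log(2) / 0.2), length.out = 2000))
    sse <- vapply(kgrid, function(k) {
      x <- exp(-k * tc$times)
      n0 <- sum(x * y) / sum(x * x)
      sum((y - n0 * x)^2)
    }, numeric(1))
    k_star <- kgrid[which.min(sse)]
    expect_equal(fit$k, k_star, tolerance = 0.02)
    hit <- hit + 1
  }
  expect_gt(hit, 20)
})

test_that("cohort tables carry flags and summaries aggregate passers", {
  co <- noisy_halflife_cohort(n_genes = 30, seed = 2)
  fits <- co$fits
  expect_equal(nrow(fits), 30)
  expect_true(all(c("pass_rpkm", "pass_max_at_zero", "pass_sigma",
                    "pass") %in% names(fits)))
  sm <- halflife_summary(fits)
  expect_equal(sm$per_condition$n, sum(fits$pass))
  expect_equal(sm$per_condition$mean_half_life_min,
               mean(fits$half_life_min[fits$pass]))
  none <- fits; none$pass <- FALSE
  expect_error(halflife_summary(none), "no genes pass")
})
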