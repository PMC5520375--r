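tp12 <- seq(0, 44, by = 4)

test_that("l2m centres profiles on their gene mean", {
  m <- rbind(g1 = c(4, 4, 4, 4), g2 = c(1, 2, 4, 8))
  out <- l2m_transform(m)
  expect_equal(unname(out["g1", ]), rep(0, 4))
  expect_equal(unname(out["g2", ]), log2(c(1, 2, 4, 8) / 3.75))
  # all-zero rows are dropped, zero entries trigger the offset rule
  m2 <- rbind(ok = c(1, 2, 3), zero = c(0, 0, 0))
  expect_warning(out2 <- l2m_transform(m2), "all-zero")
  expect_equal(rownames(out2), "ok")
  m3 <- rbind(g = c(0, 2, 4))
  expect_warning(out3 <- l2m_transform(m3), "offset")
  expect_equal(ncol(out3), 3)
})

test_that("replicate concatenation pools observations per gene", {
  t <- tp12
  y <- 1 + 0.5 * cos(2 * pi * (t - 6) / 24)
  a <- list(time = t, values = rbind(g1 = y))
  b <- list(time = t, values = rbind(g1 = y))
  cc <- concat_replicates(a, b)
  expect_equal(length(cc$time), 24)
  f1 <- harmonic_fit(a$time, a$values["g1", ])
  f2 <- harmonic_fit(cc$time, cc$values["g1", ])
  expect_equal(f1$phase, f2$phase, tolerance = 1e-9)

  # antiphasic replicates cancel: pooled amplitude below either alone
  anti <- list(time = t, values = rbind(g1 = 1 + 0.5 *
                                          cos(2 * pi * (t - 18) / 24)))
  cc2 <- concat_replicates(a, anti)
  f3 <- harmonic_fit(cc2$time, cc2$values["g1", ])
  expect_lt(f3$amplitude, f1$amplitude)
  expect_lt(f3$amplitude, 1e-9)  # exact cancellation for 12 h shift

  # one empty replicate returns the other unchanged
  expect_equal(concat_replicates(a, list(time = numeric(),
                                         values = a$values[0, ])), a)
  # differing gene universes intersect with a warning
  b2 <- list(time = t, values = rbind(g1 = y, g2 = y))
  expect_warning(cc3 <- concat_replicates(a, b2), "intersect")
  expect_equal(rownames(cc3$values), "g1")
})

test_that("Savitzky-Golay smoothing reproduces low-degree polynomials", {
  t <- 0:11
  m <- rbind(quad = 3 * t^2 - 2 * t + 1, lin = 2 * t + 5)
  sm <- sg_smooth(m, time = t)
  expect_equal(sm, m, tolerance = 1e-9)
})

test_that("interior smoothing matches the published (5,2) coefficients", {
  set.seed(41)
  y <- rnorm(12)
  sm <- as.numeric(sg_smooth(matrix(y, 1)))
  for (i in 3:10) {
    expect_equal(sm[i], sum(sg52_coef * y[(i - 2):(i + 2)]),
                 tolerance = 1e-10)
  }
  # a lone spike is attenuated to the central coefficient's share
  spike <- c(rep(0, 5), 1, rep(0, 6))
  sms <- as.numeric(sg_smooth(matrix(spike, 1)))
  expect_equal(sms[6], 17 / 35, tolerance = 1e-10)
})

test_that("smoothing validates window and sampling", {
  m <- matrix(rnorm(12), 1)
  expect_error(sg_smooth(m, window = 4), "odd")
  expect_error(sg_smooth(m, window = 3, polyorder = 4), "polyorder")
  expect_error(sg_smooth(matrix(1:3, 1), window = 5), "shorter")
  expect_error(sg_smooth(m, time = c(0, 1, 2, 4, 8, 16, 20, 24, 28, 30,
                                     31, 33)), "non-uniform")
})

test_that("harmonic regression recovers a noiseless sinusoid exactly", {
  y <- 2 + 3 * cos(2 * pi * (tp12 - 8) / 24)
  f <- harmonic_fit(tp12, y)
  expect_equal(f$amplitude, 3, tolerance = 1e-9)
  expect_equal(f$phase, 8, tolerance = 1e-9)
  expect_lt(f$p, 1e-10)
})

test_that("a constant series has zero amplitude and p = 1", {
  f <- harmonic_fit(tp12, rep(2.5, 12))
  expect_equal(f$fstat, 0)
  expect_equal(f$p, 1)
  expect_lt(f$amplitude, 1e-9)
})

test_that("degenerate designs are flagged rather than fitted", {
  f <- suppressWarnings(harmonic_fit(rep(3, 6), rnorm(6)))
  expect_false(f$ok)
  expect_true(is.na(f$p))
  expect_error(harmonic_fit(1:5, rnorm(5)), "at least 6")
  expect_warning(harmonic_fit(seq(0, 10, 2), rnorm(6)),
                 "less than one period")
})

test_that("phase estimation is shift-equivariant and amplitude
           scale-equivariant", {
  set.seed(43)
  y <- 0.3 * tp12 + 1.4 * cos(2 * pi * (tp12 - 5) / 24) + rnorm(12, 0, 0.2)
  f0 <- harmonic_fit(tp12, y)
  for (delta in c(3, 7.5, 26)) {
    fs <- harmonic_fit(tp12 + delta, y)
    expect_equal(fs$phase, (f0$phase + delta) %% 24, tolerance = 1e-8)
  }
  yc <- y - mean(y)
  f1 <- harmonic_fit(tp12, yc)
  f2 <- harmonic_fit(tp12, 3.7 * yc)
  expect_equal(f2$amplitude, 3.7 * f1$amplitude, tolerance = 1e-9)
})

test_that("the closed-form fit matches a fine grid-search oracle", {
  set.seed(47)
  for (i in 1:50) {
    phi <- runif(1, 0, 24)
    amp <- runif(1, 0.5, 2)
    y <- 0.02 * tp12 + amp * cos(2 * pi * (tp12 - phi) / 24) +
      rnorm(12, 0, 0.3)
    f <- harmonic_fit(tp12, y)
    g <- grid_phase_oracle(tp12, y)
    expect_lt(phase_diff(f$phase, g$phase), 0.011)
    expect_equal(f$amplitude, unname(g$amplitude), tolerance = 1e-3)
  }
})

test_that("oscillator calls control the FDR at high signal-to-noise", {
  sim <- simulate_expression(1000, frac_oscillating = 0.2,
                             noise_sd = 0.15, seed = 53)
  det <- rhythm_detect(sim$values, sim$time)
  tp <- sum(det$oscillating & sim$truth$oscillating)
  fp <- sum(det$oscillating & !sim$truth$oscillating)
  expect_gte(tp / sum(sim$truth$oscillating), 0.9)
  expect_lte(fp / max(tp + fp, 1), 0.1)
})

test_that("oscillator calling handles edge cases", {
  res <- data.frame(gene_id = c("a", "b"), p = c(1, 1),
                    phase = 0, amplitude = 0)
  out <- call_oscillators(res)
  expect_false(any(out$oscillating))
  one <- call_oscillators(data.frame(gene_id = "a", p = 0.04, phase = 1,
                                     amplitude = 1))
  expect_equal(one$q, 0.04)
  expect_true(one$oscillating)
})

test_that("circular correlation has the stated invariances", {
  a <- c(0, 6, 12, 20)
  expect_equal(circular_correlation(a, a)$rho_ccc, 1, tolerance = 1e-12)
  # common rotation leaves rho unchanged
  expect_equal(circular_correlation(a, (a + 3) %% 24)$rho_ccc, 1,
               tolerance = 1e-12)
  set.seed(59)
  x <- runif(20, 0, 24)
  y <- runif(20, 0, 24)
  r0 <- circular_correlation(x, y)$rho_ccc
  expect_equal(circular_correlation(x, (y + 7.3) %% 24)$rho_ccc, r0,
               tolerance = 1e-10)
  # reflection flips the sign
  expect_equal(circular_correlation(x, (-y) %% 24)$rho_ccc, -r0,
               tolerance = 1e-10)
})

test_that("circular correlation equals the direct-formula oracle", {
  a <- c(0, 6, 12, 20)
  b <- c(2, 4, 14, 18)
  expect_equal(circular_correlation(a, b)$rho_ccc, ccc_oracle(a, b),
               tolerance = 1e-12)
  set.seed(61)
  for (i in 1:20) {
    x <- runif(8, 0, 24)
    y <- runif(8, 0, 24)
    expect_equal(circular_correlation(x, y)$rho_ccc, ccc_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(out <- circular_correlation(rep(5, 4), c(1, 2, 3, 4)),
                 "zero circular variance")
  expect_true(is.na(out$rho_ccc))
  expect_error(circular_correlation(1:2, 1:2), "at least 3")
})

test_that("twin datasets with one phase program correlate strongly", {
  tw <- twin_datasets()
  ra <- rhythm_detect(tw$a, tw$time)
  rb <- rhythm_detect(tw$b, tw$time)
  cmp <- compare_datasets(ra, rb, names_ab = c("rep1", "rep2"))
  expect_gt(cmp$n_shared, 100)
  expect_gt(cmp$rho_ccc, 0.9)
  expect_lt(cmp$p_ccc, 0.01)
  expect_gt(cmp$rho_amp, 0.5)
})

test_that("a dataset compared with itself gives perfect correlations", {
  tw <- twin_datasets(n_genes = 60)
  ra <- rhythm_detect(tw$a, tw$time)
  cmp <- compare_datasets(ra, ra)
  expect_equal(cmp$rho_ccc, 1, tolerance = 1e-9)
  expect_equal(cmp$rho_amp, 1, tolerance = 1e-9)
})

test_that("comparisons with too few shared oscillators are skipped", {
  ra <- data.frame(gene_id = c("a", "b"), p = 0.001, q = 0.001,
                   phase = 1, amplitude = 1, oscillating = TRUE)
  rb <- data.frame(gene_id = c("x", "y"), p = 0.001, q = 0.001,
                   phase = 1, amplitude = 1, oscillating = TRUE)
  expect_warning(cmp <- compare_datasets(ra, rb), "skipped")
  expect_equal(cmp$n_shared, 0)
  expect_true(is.na(cmp$rho_ccc))
})

test_that("homolog maps link oscillators across gene namespaces", {
  tw <- twin_datasets(n_genes = 60)
  ra <- rhythm_detect(tw$a, tw$time)
  rb <- rhythm_detect(tw$b, tw$time)
  rb$gene_id <- sub("^g", "h", rb$gene_id)
  map <- data.frame(
    group_id = rep(sprintf("grp%03d", 1:60), 2),
    dataset = rep(c("a", "b"), each = 60),
    gene_id = c(sprintf("g%03d", 1:60), sprintf("h%03d", 1:60)))
  cmp <- compare_datasets(ra, rb, homolog_map = map,
                          names_ab = c("a", "b"))
  expect_gt(cmp$rho_ccc, 0.9)
  core <- core_diurnal_set(list(a = ra, b = rb), homolog_map = map)
  expect_true(all(grepl("^grp", core)))
  expect_gt(length(core), 40)
})

test_that("the core diurnal set is the intersection of oscillator sets", {
  mk_res <- function(genes, osc) {
    data.frame(gene_id = genes, p = 0.01, q = 0.01, phase = 1,
               amplitude = 1, oscillating = osc)
  }
  r1 <- mk_res(c("a", "b", "c"), c(TRUE, TRUE, FALSE))
  r2 <- mk_res(c("a", "b", "c"), c(TRUE, FALSE, TRUE))
  expect_equal(core_diurnal_set(list(d1 = r1)), c("a", "b"))
  expect_equal(core_diurnal_set(list(d1 = r1, d2 = r2)), "a")
  r3 <- mk_res(c("a", "b", "c"), c(FALSE, TRUE, FALSE))
  expect_equal(length(core_diurnal_set(list(d1 = r1, d2 = r2, d3 = r3))),
               0)
})

test_that("all-pairs comparison emits one row per dataset pair", {
  tw <- twin_datasets(n_genes = 50)
  ra <- rhythm_detect(tw$a, tw$time)
  rb <- rhythm_detect(tw$b, tw$time)
  out <- compare_all(list(x = ra, y = rb, z = ra))
  expect_equal(nrow(out), 3)
  expect_setequal(out$pair, c("x vs y", "x vs z", "y vs z"))
})
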