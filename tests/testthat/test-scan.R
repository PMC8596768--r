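grid33 <- grid_spec(fx_priors(), 33)

test_that("the neutral estimate is the arg-max of the product of densities", {
  po <- gaussian_posterior(grid33, center = c(10L, 22L))
  est <- estimate_neutral(list(po, po, po))
  expect_equal(est$cell, c(10L, 22L))
  expect_equal(unname(est$value),
               c(grid33$axis1[10], grid33$axis2[22]))

  # two equal-curvature log-densities centered at different cells: midpoint
  pa <- gaussian_posterior(grid33, center = c(11L, 17L), sigma = 1)
  pb <- gaussian_posterior(grid33, center = c(21L, 17L), sigma = 1)
  est2 <- estimate_neutral(list(pa, pb))
  expect_equal(est2$cell, c(16L, 17L))

  g15 <- grid_spec(fx_priors(), 15)
  expect_error(estimate_neutral(list(po, gaussian_posterior(g15, c(3L, 3L)))),
               "identical grids")
})

test_that("HPD p-values follow the strictly-greater tie rule", {
  # all mass in the estimate cell: h = 0, p = 1
  m0 <- matrix(0, 33, 33); m0[5, 5] <- 1
  hp <- hpd_pvalue(as_lsd_posterior(m0, grid33), c(5L, 5L))
  expect_equal(unname(hp["h"]), 0)
  expect_equal(unname(hp["p"]), 1)

  # perfectly flat posterior: no cell is strictly denser -> p = 1
  flat <- as_lsd_posterior(matrix(1, 33, 33), grid33)
  expect_equal(unname(hpd_pvalue(flat, c(1L, 1L))["p"]), 1)

  # p = 1 - h exactly on random posteriors
  set.seed(71)
  for (i in 1:10) {
    m <- matrix(rexp(33 * 33), 33, 33)
    po <- as_lsd_posterior(m, grid33)
    cell <- c(sample(33, 1), sample(33, 1))
    hp <- hpd_pvalue(po, cell)
    expect_identical(hp[["p"]], 1 - hp[["h"]])
    expect_true(hp[["p"]] >= 0 && hp[["p"]] <= 1)
  }
})

test_that("HPD mass approximates the continuous credible level", {
  # Gaussian posterior; estimate cell on (approximately) the 95% contour
  sigma <- 0.8
  po <- gaussian_posterior(grid33, center = c(17L, 17L), sigma = sigma)
  r95 <- sigma * sqrt(stats::qchisq(0.95, df = 2))
  cell1 <- which.min(abs(grid33$axis1 - (grid33$axis1[17] + r95)))
  hp <- hpd_pvalue(po, c(cell1, 17L))
  # continuum oracle: P(density > density at radius r) = exp(-r^2 / 2 sigma^2)
  r <- grid33$axis1[cell1] - grid33$axis1[17]
  expect_lt(abs(unname(hp["p"]) - exp(-r^2 / (2 * sigma^2))), 0.01)
  expect_lt(abs(unname(hp["p"]) - 0.05), 0.03)
})

test_that("the asymmetry mass obeys its symmetry anchors", {
  # exactly symmetric posterior about the neutral ratio line: sigma = 0.5
  po <- gaussian_posterior(grid33, center = c(17L, 17L), sigma = 0.7)
  sg <- asymmetry_sigma(po, c(17L, 17L))
  expect_equal(sg, 0.5, tolerance = 1e-12)

  # all mass strictly below the boundary: sigma = 1
  m1 <- matrix(0, 33, 33); m1[20, 3] <- 1  # M21 reduced far below M12
  expect_equal(asymmetry_sigma(as_lsd_posterior(m1, grid33), c(17L, 17L)), 1)

  # axis swap maps sigma -> 1 - sigma
  set.seed(72)
  m <- matrix(rexp(33 * 33), 33, 33)
  po_r <- as_lsd_posterior(m, grid33)
  po_t <- as_lsd_posterior(t(m), grid33)
  s1 <- asymmetry_sigma(po_r, c(12L, 20L))
  s2 <- asymmetry_sigma(po_t, c(20L, 12L))
  expect_equal(s1 + s2, 1, tolerance = 1e-12)
})

test_that("the asymmetry score is a clamped natural-log odds", {
  expect_equal(asymmetry_score(0.5), 0)
  expect_equal(asymmetry_score(0.9), log(9), tolerance = 1e-12)
  expect_equal(asymmetry_score(c(0.8, 1.0), mode = "aggregate"),
               log(0.9 / 0.1), tolerance = 1e-12)
  expect_equal(asymmetry_score(1), log((1 - 1e-6) / 1e-6))
  expect_true(is.finite(asymmetry_score(0)))
  expect_error(asymmetry_score(numeric(0)), "empty")
})

test_that("a scan is deterministic given its inputs and respects the neutral set", {
  tab <- fx_small_table()
  tr <- fx_small_transform()
  m <- fx_scaled_model()
  pg <- build_pseudogenome(m, list(M12 = 5, M21 = 5), NULL, n_n = 25, n_s = 0,
                           L = 5000, sample_config = fx_samples(), seed = 73)
  st <- locus_stats(pg$loci)
  s1 <- run_scan(st, tab, tr)
  s2 <- run_scan(st, tab, tr)
  expect_identical(s1$records, s2$records)

  # explicit full neutral list is equivalent to the default
  s3 <- run_scan(st, tab, tr, neutral = st$locus_id)
  expect_identical(s1$records$p, s3$records$p)
  expect_error(run_scan(st, tab, tr, neutral = "nope"), "unknown locus ids")

  # rescan with a different neutral subset reuses posteriors exactly
  s4 <- rescan(s1, st$locus_id[1:10])
  expect_length(s4$neutral_ids, 10)
  s5 <- run_scan(st, tab, tr, neutral = st$locus_id[1:10])
  expect_equal(s4$records, s5$records)
})

test_that("relabelling demes flips sigma and preserves p", {
  # swapping deme labels transposes every posterior and the estimate cell
  tab <- fx_small_table()
  tr <- fx_small_transform()
  pg <- build_pseudogenome(fx_scaled_model(), list(M12 = 5, M21 = 5), NULL,
                           n_n = 12, n_s = 0, L = 5000,
                           sample_config = fx_samples(), seed = 74)
  st <- locus_stats(pg$loci)
  sc <- run_scan(st, tab, tr)
  est <- sc$neutral_estimate
  for (id in st$locus_id[1:4]) {
    po <- sc$posteriors[[id]]
    po_sw <- as_lsd_posterior(t(po$mass), po$grid)
    cell_sw <- rev(est$cell)
    expect_equal(unname(hpd_pvalue(po_sw, cell_sw)["p"]),
                 unname(hpd_pvalue(po, est)["p"]), tolerance = 1e-12)
    expect_equal(asymmetry_sigma(po_sw, cell_sw),
                 1 - asymmetry_sigma(po, est), tolerance = 1e-12)
  }
})

test_that("tidiers expose scan results as tibbles", {
  tab <- fx_small_table()
  tr <- fx_small_transform()
  pg <- build_pseudogenome(fx_scaled_model(), list(M12 = 5, M21 = 5), NULL,
                           n_n = 6, n_s = 0, L = 5000,
                           sample_config = fx_samples(), seed = 75)
  sc <- run_scan(locus_stats(pg$loci), tab, tr)
  td <- tidy(sc)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("locus_id", "mode_M12", "mode_M21", "h", "p", "sigma", "a"))
  gl <- glance(sc)
  expect_equal(gl$n_loci, 6)
  expect_s3_class(tidy(sc$posteriors[[1]]), "tbl_df")
})
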