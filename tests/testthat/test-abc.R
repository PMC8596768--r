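test_that("reference tables are reproducible, prior-consistent and round-trip", {
  tab <- fx_small_table()
  expect_equal(nrow(tab), 3000)
  expect_gt(ks.test(tab$log10_M12, "punif", -4, 3)$p.value, 0.001)
  expect_gt(ks.test(tab$log10_M21, "punif", -4, 3)$p.value, 0.001)

  tab2 <- build_reference_table(fx_scaled_model(), fx_priors(), 100,
                                fx_samples(), 5000, seed = 99)
  tab3 <- build_reference_table(fx_scaled_model(), fx_priors(), 100,
                                fx_samples(), 5000, seed = 99)
  expect_identical(as.data.frame(tab2), as.data.frame(tab3))

  path <- tempfile(fileext = ".tsv")
  write_reftable(tab2, path)
  back <- read_reftable(path)
  expect_equal(as.data.frame(back), as.data.frame(tab2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(attr(back, "focal"), attr(tab2, "focal"))
  expect_equal(length(attr(back, "priors")), 2)
})

test_that("the PLS transform finds informative statistics", {
  # stat1 is exactly linear in M12 (log scale), the rest pure noise
  set.seed(61)
  n <- 2000
  th1 <- runif(n, -4, 3); th2 <- runif(n, -4, 3)
  stats <- tibble::tibble(
    s_info = th1 * 2 + 1,
    s_noise1 = rnorm(n), s_noise2 = rnorm(n), s_noise3 = rnorm(n))
  tab <- structure(
    dplyr::bind_cols(tibble::tibble(log10_M12 = th1, log10_M21 = th2), stats),
    class = c("lsd_reftable", "tbl_df", "tbl", "data.frame"),
    priors = fx_priors(), focal = c("M12", "M21"), L = 5000,
    stat_names = names(stats))
  tr <- fit_transform(tab, k = 2)
  w1 <- tr$W[, 1] / sqrt(sum(tr$W[, 1]^2))
  expect_gt(abs(w1["s_info"]), 0.9)

  # a duplicated statistic column must not break the transform
  tab2 <- tab
  tab2$s_dup <- tab2$s_info
  attr(tab2, "stat_names") <- c(names(stats), "s_dup")
  expect_s3_class(fit_transform(tab2, k = 2), "lsd_transform")

  expect_error(fit_transform(tab, k = 0), "k must be")
  # constant statistic dropped with a warning
  tab3 <- tab
  tab3$s_noise1 <- 1
  expect_warning(fit_transform(tab3, k = 2), "constant")
})

test_that("retention is a stable nearest-neighbour head", {
  tab <- fx_small_table()
  tr <- fx_small_transform()
  mm <- lsdscan:::reftable_matrices(tab)
  s_obs <- tab[17, attr(tab, "stat_names")]

  ret <- retain_closest(tab, tr, s_obs, 100)
  expect_equal(nrow(ret$theta), 100)
  expect_equal(ret$dist[1], 0, tolerance = 1e-9)  # own row at distance 0

  # full-sort oracle
  Tm <- project_stats(tr, mm$X)
  d <- sqrt(rowSums(sweep(Tm, 2, as.numeric(project_stats(tr, s_obs)))^2))
  expect_equal(sort(ret$index), sort(order(d)[1:100]))

  all_rows <- retain_closest(tab, tr, s_obs, nrow(Tm))
  expect_equal(nrow(all_rows$theta), nrow(Tm))
  expect_error(retain_closest(tab, tr, s_obs, nrow(Tm) + 1), "exceeds")

  # missing statistic is named in the error
  s_bad <- s_obs
  s_bad$pi_1 <- NA_real_
  expect_error(retain_closest(tab, tr, s_bad, 10), "pi_1")
})

test_that("distances are invariant to affine rescaling of raw statistics", {
  tab <- fx_small_table()
  tab2 <- tab
  tab2$pi_1 <- tab2$pi_1 * 1000 + 5
  tab2$S_tot <- tab2$S_tot / 77 - 3
  tr1 <- fit_transform(tab, k = 4)
  tr2 <- fit_transform(tab2, k = 4)
  s1 <- tab[3, attr(tab, "stat_names")]
  s2 <- tab2[3, attr(tab2, "stat_names")]
  r1 <- retain_closest(tab, tr1, s1, 50)
  r2 <- retain_closest(tab2, tr2, s2, 50)
  expect_equal(sort(r1$index), sort(r2$index))
})

test_that("the GLM recovers linear structure and regularizes the covariance", {
  set.seed(62)
  n <- 400
  Th <- cbind(runif(n, -4, 3), runif(n, -4, 3))
  colnames(Th) <- c("log10_M12", "log10_M21")
  B_true <- matrix(c(1.5, -0.5, 0.2, 2), 2, 2)
  Tm <- cbind(1, Th) %*% rbind(c(0.3, -1), t(B_true))

  g <- fit_glm(list(theta = Th, T = Tm))
  expect_equal(unname(g$B), unname(B_true), tolerance = 1e-6)
  expect_equal(unname(g$c0), c(0.3, -1), tolerance = 1e-6)
  expect_lt(sum(diag(g$Sigma)), 1e-6)

  # null data: B within noise of zero
  Tn <- matrix(rnorm(n * 2), n, 2)
  g0 <- fit_glm(list(theta = Th, T = Tn))
  expect_lt(max(abs(g0$B)), 0.1)
  expect_true(isSymmetric(g0$Sigma))
  expect_true(all(eigen(g0$Sigma, symmetric = TRUE)$values > 0))

  expect_error(fit_glm(list(theta = Th[1:3, ], T = Tm[1:3, ])), "at least")
})

test_that("posterior grids normalize, respect B = 0 and never underflow", {
  g <- grid_spec(fx_priors(), 33)
  expect_length(g$axis1, 33)
  expect_equal(g$axis1[1], -4 + 7 / 33 / 2)

  set.seed(63)
  Th <- cbind(runif(300, -4, 3), runif(300, -4, 3))
  Tn <- matrix(rnorm(600), 300, 2)
  glm0 <- fit_glm(list(theta = Th, T = Tn))
  po_u <- posterior_grid(glm0, g, c(0, 0), prior = "uniform")
  expect_equal(sum(po_u$mass), 1, tolerance = 1e-10)
  expect_lt(diff(range(po_u$mass)) / mean(po_u$mass), 0.15) # ~ flat

  # far-away observation: renormalized in log space, never all-zero
  glm1 <- fit_glm(list(theta = Th, T = Th %*% diag(2) + 1e-3 * Tn))
  po_far <- posterior_grid(glm1, g, c(1e4, -1e4), prior = "uniform")
  expect_equal(sum(po_far$mass), 1, tolerance = 1e-10)
  expect_true(all(is.finite(po_far$mass)))
})

test_that("the grid posterior matches the conjugate-normal closed form", {
  # 1 parameter, 1 statistic: s ~ N(b*theta, sig2), uniform prior on theta.
  # Build a 2-D problem whose second axis is uninformative so the first
  # marginal is exactly the 1-D conjugate posterior.
  b <- 1.2; sig <- 0.7; s_obs <- 0.4
  glm <- structure(list(
    c0 = c(0, 0),
    B = matrix(c(b, 0, 0, 0), 2, 2),   # stat2 carries no signal
    Sigma = diag(c(sig^2, 1)), chol = chol(diag(c(sig^2, 1))),
    n = 1000, param_names = c("log10_M12", "log10_M21")), class = "lsd_glm")
  g201 <- grid_spec(fx_priors(), 201)
  po <- posterior_grid(glm, g201, c(s_obs, 0), prior = "uniform")
  marg <- rowSums(po$mass)
  oracle <- stats::dnorm(s_obs, b * g201$axis1, sig)
  oracle <- oracle / sum(oracle)
  expect_lt(sum(abs(marg - oracle)) / 2, 0.01)  # total variation
})

test_that("shrinking the residual covariance concentrates the posterior", {
  set.seed(64)
  Th <- cbind(runif(500, -4, 3), runif(500, -4, 3))
  Tm <- Th + matrix(rnorm(1000, 0, 0.8), 500, 2)
  glm <- fit_glm(list(theta = Th, T = Tm))
  g <- grid_spec(fx_priors(), 33)
  entropy <- function(po) -sum(po$mass * log(po$mass))
  po1 <- posterior_grid(glm, g, c(0.3, -0.2), prior = "uniform")
  glm2 <- glm
  glm2$Sigma <- glm$Sigma / 16
  glm2$chol <- chol(glm2$Sigma)
  po2 <- posterior_grid(glm2, g, c(0.3, -0.2), prior = "uniform")
  expect_lt(entropy(po2), entropy(po1))
})
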