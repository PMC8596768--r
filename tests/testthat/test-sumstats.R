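test_that("within-population statistics match closed forms on toy data", {
  # two haplotypes differing at k = 3 sites: pi = theta_w = 3, D undefined tie
  H <- rbind(c(1, 1, 1), c(0, 0, 0))
  l <- make_locus(H, c("A", "A"))
  d <- diversity_stats(l, "A")
  expect_equal(d$S, 3)
  expect_equal(d$pi, 3)
  expect_equal(d$theta_w, 3)

  # n = 4, S = 5: theta_w = 5 / (1 + 1/2 + 1/3)
  set.seed(1)
  H4 <- matrix(0L, 4, 5)
  H4[cbind(c(1, 2, 3, 1, 2), 1:5)] <- 1L
  d4 <- diversity_stats(make_locus(H4, rep("A", 4)), "A")
  expect_equal(d4$theta_w, 5 / (1 + 1/2 + 1/3), tolerance = 1e-10)
  expect_equal(d4$theta_w, 2.72727, tolerance = 1e-5)

  # fewer than 2 haplotypes: missing sentinels
  d1 <- diversity_stats(make_locus(matrix(c(0L, 1L), 1, 2), "A", drop = FALSE), "A")
  expect_true(is.na(d1$pi) && is.na(d1$theta_w) && is.na(d1$tajima_d))

  # S = 0 within the population: Tajima's D is NA, never 0
  H0 <- rbind(c(1, 1), c(1, 1), c(0, 0))
  d0 <- diversity_stats(make_locus(H0, c("A", "A", "B")), "A")
  expect_equal(d0$S, 0)
  expect_true(is.na(d0$tajima_d))
})

test_that("pi and dxy equal the brute-force all-pairs counts", {
  set.seed(42)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1); S <- sample(1:12, 1)
    H <- matrix(rbinom((n1 + n2) * S, 1, runif(1, .2, .8)), n1 + n2, S)
    pops <- rep(c("A", "B"), c(n1, n2))
    l <- make_locus(H, pops, L = 1000, drop = TRUE)
    HA <- l$haplotypes[pops == "A", , drop = FALSE]
    HB <- l$haplotypes[pops == "B", , drop = FALSE]

    lc <- lsdscan:::locus_counts(l)
    st <- lsdscan:::stats_from_counts(lc$counts, lc$n, l$L)

    piA_bf <- bf_pi(HA)
    expect_equal(unname(st["pi_A"]), piA_bf, tolerance = 1e-12)
    expect_equal(unname(st["pi_tot"]), bf_pi(l$haplotypes), tolerance = 1e-12)

    dxy_bf <- bf_dxy_count(HA, HB)
    expect_equal(unname(st["dxy_A_B"]) * l$L, dxy_bf, tolerance = 1e-12)
    if (dxy_bf > 0) {
      fst_bf <- 1 - mean(c(piA_bf, bf_pi(HB))) / dxy_bf
      expect_equal(unname(st["fst_A_B"]), max(-1, min(1, fst_bf)),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(st["fst_A_B"]))
    }
  }
})

test_that("divergence statistics hit their anchors", {
  # panmictic pool split into two arbitrary "populations": E[F_ST] = 0
  m <- demographic_model(list(deme("A", 1000)), mutation_rate = 5e-7)
  set.seed(31)
  fst0 <- replicate(400, {
    l <- simulate_locus(m, NULL, c(A = 20), 5000)
    l$pop_labels <- rep(c("X", "Y"), 10)
    divergence_stats(l, "X", "Y")$fst
  })
  expect_lt(abs(mean(fst0)), 3 * sd(fst0) / sqrt(400))

  # one fixed difference, no within-pop variation: F_ST = 1, D_XY = 1/L
  Hf <- rbind(c(1L), c(1L), c(0L), c(0L))
  lf <- make_locus(Hf, c("A", "A", "B", "B"), L = 5000)
  df <- divergence_stats(lf, "A", "B")
  expect_equal(df$fst, 1)
  expect_equal(df$dxy, 1 / 5000)

  # label swap leaves F_ST and D_XY unchanged
  dr <- divergence_stats(lf, "B", "A")
  expect_equal(df$fst, dr$fst)
  expect_equal(df$dxy, dr$dxy)
})

test_that("private S and the binned SFS behave as defined", {
  # site 1 segregates only in A; site 2 segregates in both
  H <- rbind(c(1, 1), c(0, 0), c(0, 1), c(0, 0))
  l <- make_locus(H, c("A", "A", "B", "B"))
  dA <- diversity_stats(l, "A")
  expect_equal(dA$S, 2)
  expect_equal(dA$private_S, 1)

  # all singletons: all mass in the lowest bin
  Hs <- diag(1L, 8)
  s <- sfs_stats(make_locus(Hs, rep("A", 8)), "A", bins = 4)
  expect_equal(s, c(1, 0, 0, 0))

  # S = 0: zero vector; otherwise bins sum to 1
  expect_equal(sfs_stats(make_locus(matrix(0L, 4, 0), rep("A", 4),
                                    drop = FALSE), "A"), rep(0, 4))
  set.seed(7)
  Hr <- matrix(rbinom(60, 1, .4), 6, 10)
  lr <- make_locus(Hr, rep("A", 6), drop = TRUE)
  if (ncol(lr$haplotypes) > 0) expect_equal(sum(sfs_stats(lr, "A")), 1)
})

test_that("stats_vector has a stable ordering and propagates sentinels", {
  l <- simulate_locus(fx_scaled_model(), list(M12 = 5, M21 = 5),
                      fx_samples(), 5000, seed = 21)
  v1 <- stats_vector(l); v2 <- stats_vector(l)
  expect_identical(names(v1), names(v2))
  expect_identical(names(v1)[1:5], c("S_1", "privS_1", "pi_1", "thetaW_1", "tajD_1"))

  H0 <- rbind(c(1L, 1L), c(1L, 1L), c(0L, 0L), c(1L, 0L))
  v0 <- stats_vector(make_locus(H0, c("A", "A", "B", "B")))
  expect_true(is.na(v0$tajD_A))  # S_A = 0 -> NA, not 0
})

test_that("theta_w and pi agree in expectation under neutral equilibrium", {
  m <- demographic_model(list(deme("A", 1000)), mutation_rate = 5e-7)
  set.seed(22)
  diffs <- replicate(2000, {
    l <- simulate_locus(m, NULL, c(A = 10), 5000)
    d <- diversity_stats(l, "A")
    d$pi - d$theta_w
  })
  expect_lt(abs(mean(diffs)), 3 * sd(diffs) / sqrt(2000))
})

test_that("pooled-read emulation reproduces pool frequencies", {
  l <- simulate_locus(fx_scaled_model(), list(M12 = 5, M21 = 5),
                      fx_samples(), 5000, seed = 23)
  # effectively infinite fixed coverage: read frequencies = pool frequencies
  po <- emulate_pool_reads(l, c(`1` = 20, `2` = 20),
                           coverage = list(fixed = 20000), seed = 24)
  freq_pool <- colMeans(l$haplotypes[l$pop_labels == "1", ])
  freq_reads <- po$derived[, "1"] / po$depth[, "1"]
  expect_lt(max(abs(freq_pool - freq_reads)), 0.02)

  # a site fixed derived in the pool yields only derived reads
  fixed <- which(freq_pool == 1)
  if (length(fixed)) {
    expect_true(all(po$derived[fixed, "1"] == po$depth[fixed, "1"]))
  }

  # negative binomial depth: mean within 3 SE of the target
  po2 <- emulate_pool_reads(l, c(`1` = 20, `2` = 20),
                            coverage = list(mean = 30, dispersion = 5),
                            seed = 25)
  dp <- as.vector(po2$depth)
  expect_lt(abs(mean(dp) - 30), 3 * sd(dp) / sqrt(length(dp)))

  expect_error(emulate_pool_reads(l, c(`1` = 20, `2` = 20),
                                  coverage = list(mean = -3, dispersion = 1)),
               "invalid coverage")
  expect_error(emulate_pool_reads(l, c(`1` = 100, `2` = 20)), "needs")
})

test_that("pooled and haplotype paths agree in the no-noise limit", {
  l <- simulate_locus(fx_scaled_model(), list(M12 = 5, M21 = 5),
                      fx_samples(), 5000, seed = 26)
  po <- emulate_pool_reads(l, c(`1` = 20, `2` = 20),
                           coverage = list(fixed = 50000), seed = 27)
  sv_h <- stats_vector(l)
  sv_p <- stats_vector(po)
  expect_equal(sv_p$pi_1, sv_h$pi_1, tolerance = 0.06)
  expect_equal(sv_p$fst_1_2, sv_h$fst_1_2, tolerance = 0.05)
  expect_equal(sv_p$dxy_1_2, sv_h$dxy_1_2, tolerance = 0.02)
})
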