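test_that("rescaling preserves compound parameters and rejects bad factors", {
  m <- im_model()
  params <- list(M12 = 5, M21 = 5)
  reg <- selection_regime(0.01, 0.001, T_S = 40000)

  idf <- rescale_model(m, reg, 1, params)
  expect_equal(idf$model$demes[[1]]$initial_size, 10000)
  expect_equal(idf$regime$s1, 0.01)

  rs <- rescale_model(m, reg, 10, params)
  expect_equal(rs$model$demes[[1]]$initial_size, 1000)
  expect_equal(rs$model$mutation_rate, 5e-6)
  expect_equal(rs$regime$T_S, 4000)
  # N' * mu' and N' * s' invariant; M untouched (M = N m)
  expect_equal(rs$model$demes[[1]]$initial_size * rs$model$mutation_rate,
               10000 * 5e-7)
  expect_equal(rs$model$demes[[1]]$initial_size * rs$regime$s1, 10000 * 0.01)
  expect_equal(lsdscan:::forward_fractions(rs$model, params)[1, 2] * 1000, 5)

  expect_error(rescale_model(m, selection_regime(0.1, 0.1, T_S = 100), 20,
                             params),
               "leaves the diffusion regime")
  expect_equal(default_lambda(m, params), 10L)
})

test_that("the selection recursion matches its closed form", {
  # one deterministic step, p = 0.5, fitnesses (1.1, 1, 1)
  expect_equal(round(selection_step(0.5, c(1.1, 1, 1)), 5), 0.51220)

  # deterministic recursion drives a strongly favoured allele to fixation
  m <- im_model(N1 = 1000, N2 = 1000)
  reg <- selection_regime(0.5, 0, T_S = 2000, f1 = 0.1, f2 = 0)
  tr <- simulate_trajectory(m, list(M12 = 0, M21 = 0), reg,
                            deterministic = TRUE)
  expect_gt(tr$p[nrow(tr$p), 1], 0.999)
})

test_that("neutral unconditioned trajectories are a martingale", {
  m <- im_model(N1 = 500, N2 = 500)
  reg <- selection_regime(0, 0, T_S = 200, f1 = 0.3, f2 = 0.3)
  set.seed(41)
  ends <- replicate(600, {
    tr <- simulate_trajectory(m, list(M12 = 0, M21 = 0), reg,
                              conditioned = FALSE)
    mean(tr$p[nrow(tr$p), ])
  })
  expect_lt(abs(mean(ends) - 0.3), 3 * sd(ends) / sqrt(600))
})

test_that("loss regimes raise an explicit condition", {
  # de novo neutral variant: survival ~ 1/(2N); a modest cap flags loss
  m <- im_model(N1 = 5000, N2 = 5000)
  reg <- selection_regime(0, 0, T_S = 20000, origin = "de_novo")
  rs <- rescale_model(m, reg, 5, list(M12 = 5, M21 = 5))
  expect_error(
    simulate_selected_locus(rs$model, list(M12 = 5, M21 = 5), rs$regime,
                            5000, sample_config = fx_samples(),
                            resample_cap = 40, seed = 42),
    class = "lsd_loss_regime")
  expect_error(
    simulate_trajectory(rs$model, list(M12 = 5, M21 = 5), rs$regime,
                        resample_cap = 40, seed = 43),
    class = "lsd_loss_regime")
})

test_that("survival conditioning retains the derived allele", {
  m <- im_model()
  params <- list(M12 = 5, M21 = 5)
  reg <- selection_regime(0.01, 0.01, T_S = 40000)
  rs <- rescale_model(m, reg, 10, params)
  for (seed in 1:5) {
    l <- simulate_selected_locus(rs$model, params, rs$regime, 5000,
                                 sample_config = fx_samples(), seed = seed)
    expect_s3_class(l, "lsd_locus")
  }
})

test_that("forward-simulated selected loci are reproducible and differentiated", {
  m <- im_model()
  params <- list(M12 = 5, M21 = 5)
  reg <- selection_regime(0.1, 0.1, T_S = 40000)
  rs <- rescale_model(m, reg, 10, params)
  a <- simulate_selected_locus(rs$model, params, rs$regime, 5000,
                               sample_config = fx_samples(), seed = 51)
  b <- simulate_selected_locus(rs$model, params, rs$regime, 5000,
                               sample_config = fx_samples(), seed = 51)
  expect_identical(a$haplotypes, b$haplotypes)

  # strong symmetric divergent selection elevates F_ST above neutral
  set.seed(52)
  fst_sel <- replicate(6, {
    l <- simulate_selected_locus(rs$model, params, rs$regime, 5000,
                                 sample_config = fx_samples())
    divergence_stats(l, "1", "2")$fst
  })
  fst_neu <- replicate(20, {
    l <- simulate_locus(rs$model, params, fx_samples(), 5000)
    divergence_stats(l, "1", "2")$fst
  })
  expect_gt(mean(fst_sel), mean(fst_neu))
})

test_that("neutral forward simulation matches the coalescent distribution", {
  # identical model simulated forward (after burn-in) and backward
  m <- demographic_model(
    list(deme("1", 200), deme("2", 200)),
    migration = matrix(c(0, "M12", "M21", 0), 2, 2, byrow = TRUE),
    mutation_rate = 2.5e-5)
  params <- list(M12 = 5, M21 = 5)
  set.seed(53)
  S_fwd <- replicate(300, {
    l <- simulate_selected_locus(m, params, NULL, 1000,
                                 sample_config = c(`1` = 20, `2` = 20))
    ncol(l$haplotypes)
  })
  S_coa <- replicate(300, {
    l <- simulate_locus(m, params, c(`1` = 20, `2` = 20), 1000)
    ncol(l$haplotypes)
  })
  expect_gt(suppressWarnings(ks.test(S_fwd, S_coa))$p.value, 0.001)
})

test_that("rescaled models leave summary-statistic distributions invariant", {
  # coalescent invariance under lambda (compound-parameter identity)
  m <- im_model(N1 = 2000, N2 = 2000, mutation_rate = 2.5e-6)
  params <- list(M12 = 5, M21 = 5)
  rs <- rescale_model(m, NULL, 5, params)
  set.seed(54)
  S1 <- replicate(500, ncol(simulate_locus(m, params, fx_samples(), 5000)$haplotypes))
  S5 <- replicate(500, ncol(simulate_locus(rs$model, params, fx_samples(), 5000)$haplotypes))
  expect_gt(suppressWarnings(ks.test(S1, S5))$p.value, 0.001)

  # forward-simulator invariance at small scale
  base <- demographic_model(
    list(deme("1", 400), deme("2", 400)),
    migration = matrix(c(0, "M12", "M21", 0), 2, 2, byrow = TRUE),
    mutation_rate = 5e-6)
  rs2 <- rescale_model(base, NULL, 2, params)
  set.seed(55)
  F1 <- replicate(150, ncol(simulate_selected_locus(base, params, NULL, 1000,
                   sample_config = c(`1` = 20, `2` = 20))$haplotypes))
  F2 <- replicate(150, ncol(simulate_selected_locus(rs2$model, params, NULL, 1000,
                   sample_config = c(`1` = 20, `2` = 20))$haplotypes))
  expect_gt(suppressWarnings(ks.test(F1, F2))$p.value, 0.001)
})

test_that("pseudogenomes have the declared composition", {
  m <- im_model()
  params <- list(M12 = 5, M21 = 5)
  reg <- selection_regime(0.1, 0.1, T_S = 40000)
  rs <- rescale_model(m, reg, 10, params)
  pg <- build_pseudogenome(rs$model, params, rs$regime, n_n = 8, n_s = 3,
                           L = 5000, sample_config = fx_samples(), seed = 56)
  expect_equal(sum(pg$manifest$label == "selected"), 3)
  expect_equal(sum(pg$manifest$label == "neutral"), 8)
  expect_equal(length(pg$loci) * pg$L, 11 * 5000)
  expect_true(all(vapply(pg$loci, function(l) nrow(l$haplotypes), 0L) == 80))

  # pure neutral pseudogenome
  pg0 <- build_pseudogenome(rs$model, params, NULL, n_n = 4, n_s = 0,
                            L = 5000, sample_config = fx_samples(), seed = 57)
  expect_equal(nrow(pg0$manifest), 4)
  expect_true(all(pg0$manifest$label == "neutral"))
})

test_that("the printed fitness table is the default and dominance is optional", {
  w <- fitness_table(0.1, 0.01)
  expect_equal(unname(w[1, ]), c(1.1, 1, 1))
  expect_equal(unname(w[2, ]), c(1, 1, 1.01))
  wd <- fitness_table(0.1, 0.01, dominance = TRUE)
  expect_equal(unname(wd[1, ]), c(1.1, 1.1, 1))
  expect_error(fitness_table(-0.1, 0))
})
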