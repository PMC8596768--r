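# Shared fixtures, memoized so expensive simulations run once per session.
.fx <- new.env(parent = emptyenv())

fx_samples <- function() c(`1` = 40L, `2` = 40L)

fx_priors <- function() {
  list(parameter_prior("M12", "log10", -4, 3),
       parameter_prior("M21", "log10", -4, 3))
}

# model M1 at desk scale (rescaled from N = 10,000 by lambda = 10)
fx_scaled_model <- function() {
  rescale_model(im_model(), NULL, 10, list(M12 = 5, M21 = 5))$model
}

# small reference table for mechanics tests
fx_small_table <- function() {
  if (is.null(.fx$small_tab)) {
    .fx$small_tab <- build_reference_table(
      fx_scaled_model(), fx_priors(), 3000, fx_samples(), 5000, seed = 4242)
  }
  .fx$small_tab
}

fx_small_transform <- function() {
  if (is.null(.fx$small_tr)) .fx$small_tr <- fit_transform(fx_small_table())
  .fx$small_tr
}

# full-size reference table used by the acceptance suite
fx_acc_table <- function() {
  if (is.null(.fx$acc_tab)) {
    .fx$acc_tab <- build_reference_table(
      fx_scaled_model(), fx_priors(), 50000, fx_samples(), 5000, seed = 424242)
  }
  .fx$acc_tab
}

fx_acc_transform <- function() {
  if (is.null(.fx$acc_tr)) .fx$acc_tr <- fit_transform(fx_acc_table())
  .fx$acc_tr
}

# scan of the strong-selection pseudogenome (model M1, M = 5, s1 = s2 = 0.1,
# T_S = 40,000, standing f = 0.1), shared between the power and the
# mis-specification checks
fx_power_scan <- function() {
  if (is.null(.fx$power)) {
    m <- im_model()
    params <- list(M12 = 5, M21 = 5)
    regime <- selection_regime(0.1, 0.1, T_S = 40000)
    rs <- rescale_model(m, regime, default_lambda(m, params), params)
    pg <- build_pseudogenome(rs$model, params, rs$regime, n_n = 200, n_s = 50,
                             L = 5000, sample_config = fx_samples(),
                             seed = 20240101)
    st <- locus_stats(pg$loci)
    scan <- run_scan(st, fx_acc_table(), fx_acc_transform(),
                     neutral = pg$manifest$locus_id[pg$manifest$label == "neutral"])
    .fx$power <- list(pg = pg, scan = scan)
  }
  .fx$power
}

# hand-rolled pairwise-difference oracles
bf_pi <- function(H) {
  n <- nrow(H)
  if (n < 2) return(NA_real_)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    tot <- tot + sum(H[i, ] != H[j, ])
  }
  tot / (n * (n - 1) / 2)
}

bf_dxy_count <- function(HA, HB) {
  tot <- 0
  for (i in seq_len(nrow(HA))) for (j in seq_len(nrow(HB))) {
    tot <- tot + sum(HA[i, ] != HB[j, ])
  }
  tot / (nrow(HA) * nrow(HB))
}

make_locus <- function(H, pops, L = 5000, drop = FALSE) {
  locus_data(H, seq_len(ncol(H)) / (ncol(H) + 1), L, pops,
             drop_monomorphic = drop)
}

# isotropic Gaussian posterior centered at a grid cell
gaussian_posterior <- function(grid, center = c(17L, 17L), sigma = 0.5) {
  m <- outer(grid$axis1, grid$axis2, function(x, y) {
    exp(-((x - grid$axis1[center[1]])^2 + (y - grid$axis2[center[2]])^2) /
          (2 * sigma^2))
  })
  as_lsd_posterior(m, grid)
}
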