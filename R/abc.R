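#' Build an ABC reference table of single-locus simulations
#'
#' Draws `n_sims` parameter sets from the priors, simulates one neutral
#' coalescent locus per draw under the model, and computes the summary-
#' statistics vector for each. Focal parameters (the reciprocal migration
#' rates) are stored on the log10 scale alongside the statistics. Rows with
#' undefined statistics are flagged and excluded downstream.
#'
#' @param model An `lsd_model`.
#' @param priors List of [parameter_prior()] objects covering the model's
#'   free parameters; focal parameters are those named in `focal`
#'   (default `M12`, `M21`).
#' @param n_sims Number of simulations (`>= 100`).
#' @param sample_config Named haploid sample counts per deme.
#' @param L Locus length (bp).
#' @param focal Names of the focal parameters.
#' @param seed Optional integer seed.
#' @return A tibble of class `lsd_reftable`: columns `log10_<focal>` then
#'   one column per statistic, plus attributes `priors`, `focal`, `n`,
#'   `L`, `seed`.
#' @export
build_reference_table <- function(model, priors, n_sims, sample_config, L,
                                  focal = c("M12", "M21"), seed = NULL) {
  stopifnot(n_sims >= 100)
  run <- function() {
    params <- sample_parameters(priors, n = n_sims)
    re0 <- resolve_epochs(model, params[1, ])
    n <- check_sample_config(model, sample_config)
    sample_demes0 <- rep(seq_along(re0$deme_ids) - 1L, times = n)
    pnames <- names(params)
    single_epoch <- length(model$events) == 0L

    rows <- vector("list", n_sims)
    for (i in seq_len(n_sims)) {
      pi_ <- as.list(params[i, ])
      if (single_epoch && i > 1L) {
        # fast path: only migration entries change between draws
        re <- re0
        re$epochs[[1]]$M <- resolve_migration(model, pi_)
      } else {
        re <- resolve_epochs(model, pi_)
      }
      sim <- simulate_locus_counts(re, sample_demes0, n, re$mu, L)
      rows[[i]] <- stats_from_counts(sim$counts, n, L)
    }
    stats <- do.call(rbind, rows)
    tab <- dplyr::bind_cols(
      as_tibble(setNames(lapply(focal, function(f) log10(params[[f]])),
                         paste0("log10_", focal))),
      as_tibble(stats)
    )
    structure(tab,
              class = c("lsd_reftable", class(tab)),
              priors = priors, focal = focal, L = L,
              sample_config = n, stat_names = colnames(stats))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

resolve_migration <- function(model, params) {
  D <- length(model$demes)
  M <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    if (i != j) M[i, j] <- resolve_value(model$migration[i, j], params)
  }
  M
}

#' @export
print.lsd_reftable <- function(x, ...) {
  cat("<lsd_reftable> ", nrow(x), " simulations, ",
      length(attr(x, "stat_names")), " statistics, focal: ",
      paste(attr(x, "focal"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

reftable_matrices <- function(table) {
  focal <- attr(table, "focal")
  pcols <- paste0("log10_", focal)
  scols <- attr(table, "stat_names")
  X <- as.matrix(table[, scols, drop = FALSE])
  Y <- as.matrix(table[, pcols, drop = FALSE])
  ok <- stats::complete.cases(X)
  if (mean(ok) < 0.5) {
    stop("more than 50% of reference rows have undefined statistics",
         call. = FALSE)
  }
  list(X = X[ok, , drop = FALSE], Y = Y[ok, , drop = FALSE], ok = ok)
}

#' Fit the summary-statistic transformation (standardize + PLS)
#'
#' Statistics are standardized (constant statistics are dropped with a
#' warning) and reduced by a partial least squares regression of the focal
#' parameters on the standardized statistics; the first `k` latent
#' directions are kept as a linear rotation.
#'
#' @param table An `lsd_reftable`.
#' @param k Number of PLS components (`1 <= k <=` number of retained
#'   statistics). Default `min(p, 4 * number of focal parameters)`: with
#'   two focal migration rates, eight components are needed to resolve the
#'   direction (not just the magnitude) of migration from the asymmetric
#'   diversity statistics; see the methods vignette.
#' @return Object of class `lsd_transform`: per-statistic `center`/`scale`,
#'   rotation matrix `W` (statistics x k) applied after standardization.
#' @export
fit_transform <- function(table, k = NULL) {
  m <- reftable_matrices(table)
  X <- m$X
  sds <- apply(X, 2, sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const)) {
    warning("dropping constant statistics: ",
            paste(colnames(X)[const], collapse = ", "))
    X <- X[, !const, drop = FALSE]
    sds <- sds[!const]
  }
  p <- ncol(X)
  k <- k %||% min(p, 4L * ncol(m$Y))
  if (k < 1L || k > p) stop("PLS component count k must be in [1, ", p, "]",
                            call. = FALSE)
  ctr <- colMeans(X)
  Xs <- sweep(sweep(X, 2, ctr), 2, sds, "/")
  fit <- mixOmics::pls(Xs, m$Y, ncomp = k, mode = "regression", scale = FALSE)
  # rotation mapping (standardized) statistics to scores: W* = W (P'W)^{-1},
  # the standard PLS projection for new data
  Wm <- fit$loadings$X
  Tm <- fit$variates$X
  P <- crossprod(Xs, Tm) %*% diag(1 / colSums(Tm^2), k, k)
  W <- Wm %*% solve(t(P) %*% Wm)
  colnames(W) <- paste0("comp", seq_len(k))
  structure(
    list(center = ctr, scale = sds, W = W, k = k,
         stat_names = colnames(X)),
    class = "lsd_transform"
  )
}

#' Project summary statistics into PLS space
#'
#' @param transform An `lsd_transform`.
#' @param stats A tibble/data frame of statistics (reference table or
#'   observed rows), or a named numeric vector.
#' @return Numeric matrix (rows x k).
#' @export
project_stats <- function(transform, stats) {
  if (is.numeric(stats) && !is.matrix(stats)) stats <- t(as.matrix(stats))
  X <- as.matrix(as.data.frame(stats)[, transform$stat_names, drop = FALSE])
  if (anyNA(X)) {
    bad <- transform$stat_names[apply(X, 2, anyNA)]
    stop("missing statistic in observed data: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  Xs <- sweep(sweep(X, 2, transform$center), 2, transform$scale, "/")
  Xs %*% transform$W
}

#' Retain the simulations closest to an observed statistics vector
#'
#' Euclidean distance in PLS space; exactly `n_ret` rows are kept, ties at
#' the cutoff broken by row index (stable).
#'
#' @param table An `lsd_reftable`.
#' @param transform An `lsd_transform` fitted on `table`.
#' @param s_obs Observed statistics (one-row tibble or named vector).
#' @param n_ret Number of rows to retain.
#' @return List: `theta` (retained focal parameters, log10 scale), `T`
#'   (retained projected statistics), `s_proj` (projected observation),
#'   `index` (row indices into the complete-case table).
#' @export
retain_closest <- function(table, transform, s_obs, n_ret) {
  m <- reftable_matrices(table)
  Tm <- project_stats(transform, m$X)
  s_proj <- project_stats(transform, s_obs)
  if (n_ret > nrow(Tm)) stop("n_ret exceeds usable reference rows", call. = FALSE)
  d2 <- rowSums(sweep(Tm, 2, as.numeric(s_proj))^2)
  idx <- order(d2)[seq_len(n_ret)] # order() is stable: ties break by row index
  list(theta = m$Y[idx, , drop = FALSE], T = Tm[idx, , drop = FALSE],
       s_proj = s_proj, index = idx, dist = sqrt(d2[idx]))
}

#' Fit the ABC-GLM likelihood model on retained simulations
#'
#' Ordinary least squares of the transformed statistics on the focal
#' parameters among the retained simulations, `s = c0 + B theta + eps`,
#' with residual covariance `Sigma` ridge-regularized to positive
#' definiteness (`delta = 1e-8 * mean diagonal`). The fitted linear-
#' Gaussian model approximates the likelihood function of `theta` locally,
#' in the region selected by the retention step. Following the ABC-GLM
#' algorithm, the retention-truncated prior is approximated by a Gaussian
#' over the retained parameter values (`mt`, `St`), which
#' [posterior_grid()] multiplies into the posterior by default.
#'
#' @param retained Result of [retain_closest()] (or a list with `theta`
#'   and `T`).
#' @return Object of class `lsd_glm` with `c0`, `B`, `Sigma` (and its
#'   Cholesky factor) plus the truncated-prior moments `mt`, `St`.
#' @export
fit_glm <- function(retained) {
  Th <- retained$theta
  Tm <- retained$T
  n <- nrow(Tm)
  if (n < ncol(Th) + 2L) stop("need at least #parameters + 2 retained rows",
                              call. = FALSE)
  X <- cbind(1, Th)
  fit <- stats::lm.fit(X, Tm)
  coefs <- fit$coefficients
  if (anyNA(coefs)) stop("rank-deficient GLM design", call. = FALSE)
  c0 <- coefs[1L, ]
  B <- t(coefs[-1L, , drop = FALSE]) # k x q
  res <- as.matrix(fit$residuals)
  Sigma <- crossprod(res) / max(1L, n - ncol(X))
  delta <- 1e-8 * mean(diag(Sigma))
  if (!is.finite(delta) || delta <= 0) delta <- 1e-12
  Sigma <- Sigma + diag(delta, ncol(Sigma))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  tries <- 0L
  while (is.null(ch) && tries < 10L) {
    delta <- delta * 100
    Sigma <- Sigma + diag(delta, ncol(Sigma))
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    tries <- tries + 1L
  }
  if (is.null(ch)) stop("residual covariance not positive definite", call. = FALSE)
  mt <- colMeans(Th)
  St <- stats::cov(Th)
  St <- St + diag(1e-8 * max(mean(diag(St)), 1e-8), ncol(St))
  structure(list(c0 = c0, B = B, Sigma = Sigma, chol = ch, n = n,
                 mt = mt, St = St, chol_St = chol(St),
                 param_names = colnames(Th)),
            class = "lsd_glm")
}

#' Grid specification for posterior evaluation
#'
#' Regular grids of cell centers over the prior box on the log10 scale:
#' `n` cells per axis, centers at the midpoints of equal-width cells.
#'
#' @param priors List of priors for the two focal parameters (log10 scale).
#' @param n Cells per axis.
#' @return Object of class `lsd_grid` with `axis1`, `axis2` (cell centers),
#'   cell width `w`, and axis names.
#' @export
grid_spec <- function(priors, n = 33L) {
  stopifnot(length(priors) == 2L)
  ax <- lapply(priors, function(pr) {
    if (pr$scale != "log10") stop("grid axes require log10-scale priors", call. = FALSE)
    w <- (pr$upper - pr$lower) / n
    list(centers = seq(pr$lower + w / 2, pr$upper - w / 2, length.out = n), w = w)
  })
  structure(list(axis1 = ax[[1]]$centers, axis2 = ax[[2]]$centers,
                 w1 = ax[[1]]$w, w2 = ax[[2]]$w,
                 names = vapply(priors, function(p) p$name, character(1))),
            class = "lsd_grid")
}

#' Evaluate the ABC-GLM posterior on a grid
#'
#' Cell mass is proportional to `prior(theta) * N(s_obs; c0 + B theta,
#' Sigma)` at cell centers. With `prior = "truncated"` (the default, per
#' the ABC-GLM algorithm) the retention-truncated prior is approximated by
#' the Gaussian fitted to the retained parameter values, so the posterior
#' combines the local linear likelihood with the nonparametric information
#' carried by the retained set; with `prior = "uniform"` the flat prior on
#' the log10 scale is used. Arithmetic is in log space so heavy underflow
#' cannot produce an all-zero grid; densities are floored at `1e-300`
#' before normalization.
#'
#' @param glm An `lsd_glm`.
#' @param grid An `lsd_grid`.
#' @param s_proj Projected observed statistics (from [project_stats()] or
#'   [retain_closest()]).
#' @param prior `"truncated"` or `"uniform"`.
#' @param mix_eps Weight of the uniform component in the defensive mixture
#'   used with `prior = "truncated"`: the truncated-prior factor is
#'   `(1 - mix_eps) * N(theta; mt, St) + mix_eps * uniform`. The uniform
#'   floor keeps tail coverage honest where the statistics carry little
#'   information (weakly identified directions), while the Gaussian
#'   carries the geometry of the retained set.
#' @return Object of class `lsd_posterior`: matrix `mass` (axis1 x axis2)
#'   summing to 1, plus the grid.
#' @export
posterior_grid <- function(glm, grid, s_proj,
                           prior = c("truncated", "uniform"),
                           mix_eps = 0.25) {
  prior <- match.arg(prior)
  th <- as.matrix(expand.grid(a1 = grid$axis1, a2 = grid$axis2))
  mu <- matrix(glm$c0, nrow(th), length(glm$c0), byrow = TRUE) + th %*% t(glm$B)
  R <- sweep(-mu, 2, as.numeric(s_proj), "+")
  # log N(s; mu, Sigma) up to a constant shared by all cells
  z <- backsolve(glm$chol, t(R), transpose = TRUE)
  logd <- -0.5 * colSums(z^2)
  if (prior == "truncated" && !is.null(glm$mt)) {
    zt <- backsolve(glm$chol_St, t(sweep(th, 2, glm$mt)), transpose = TRUE)
    ldet <- -sum(log(diag(glm$chol_St))) - log(2 * pi)
    gdens <- exp(ldet - 0.5 * colSums(zt^2))
    box <- diff(range(grid$axis1)) + grid$w1
    box <- box * (diff(range(grid$axis2)) + grid$w2)
    logd <- logd + log((1 - mix_eps) * gdens + mix_eps / box)
  }
  logd <- logd - max(logd)
  mass <- pmax(exp(logd), 1e-300)
  mass <- mass / sum(mass)
  structure(list(mass = matrix(mass, length(grid$axis1), length(grid$axis2)),
                 grid = grid),
            class = "lsd_posterior")
}

#' Construct a posterior-grid object from a mass matrix
#'
#' Mainly useful for constructing reference posteriors in analyses and
#' tests (e.g. exactly symmetric posteriors for asymmetry anchors).
#'
#' @param mass Non-negative matrix (`length(grid$axis1)` x
#'   `length(grid$axis2)`); normalized to sum to 1.
#' @param grid An `lsd_grid`.
#' @return An `lsd_posterior`.
#' @export
as_lsd_posterior <- function(mass, grid) {
  mass <- as.matrix(mass)
  stopifnot(all(mass >= 0), nrow(mass) == length(grid$axis1),
            ncol(mass) == length(grid$axis2))
  structure(list(mass = mass / sum(mass), grid = grid),
            class = "lsd_posterior")
}

#' @export
print.lsd_posterior <- function(x, ...) {
  ij <- arrayInd(which.max(x$mass), dim(x$mass))
  cat("<lsd_posterior> ", nrow(x$mass), " x ", ncol(x$mass),
      " grid; mode at (", x$grid$names[1], " = ",
      signif(x$grid$axis1[ij[1]], 3), ", ", x$grid$names[2], " = ",
      signif(x$grid$axis2[ij[2]], 3), ")\n", sep = "")
  invisible(x)
}

# Pipeline: posterior for one observed statistics row.
locus_posterior <- function(table, transform, s_obs, grid, n_ret,
                            cache = NULL, prior = "truncated") {
  if (is.null(cache)) {
    ret <- retain_closest(table, transform, s_obs, n_ret)
  } else {
    s_proj <- project_stats(transform, s_obs)
    d2 <- rowSums(sweep(cache$Tm, 2, as.numeric(s_proj))^2)
    idx <- order(d2)[seq_len(n_ret)]
    ret <- list(theta = cache$Y[idx, , drop = FALSE],
                T = cache$Tm[idx, , drop = FALSE], s_proj = s_proj)
  }
  glm <- fit_glm(ret)
  posterior_grid(glm, grid, ret$s_proj, prior = prior)
}
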