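#' Neutral point estimate from per-locus posteriors
#'
#' Multiplies the per-locus posterior densities of the putatively neutral
#' loci (sums their log cell masses) and takes the arg-max grid cell as the
#' neutral parameter estimate. Cell masses are floored at `1e-300` before
#' taking logs; ties break toward the smallest (column-major) cell index.
#'
#' @param posteriors List of `lsd_posterior` objects on identical grids.
#' @return Object of class `lsd_neutral_estimate`: grid cell indices
#'   `cell`, parameter values `value` (log10 scale, named by the grid
#'   axes), and the per-cell summed log density `log_density`.
#' @export
estimate_neutral <- function(posteriors) {
  stopifnot(length(posteriors) >= 1L)
  g0 <- posteriors[[1]]$grid
  for (p in posteriors) {
    if (!isTRUE(all.equal(p$grid$axis1, g0$axis1)) ||
        !isTRUE(all.equal(p$grid$axis2, g0$axis2))) {
      stop("posteriors are not on identical grids", call. = FALSE)
    }
  }
  logsum <- Reduce(`+`, lapply(posteriors, function(p) log(pmax(p$mass, 1e-300))))
  ij <- arrayInd(which.max(logsum), dim(logsum)) # which.max: first max, smallest index
  structure(
    list(cell = as.integer(ij),
         value = setNames(c(g0$axis1[ij[1]], g0$axis2[ij[2]]), g0$names),
         log_density = logsum, grid = g0, n_loci = length(posteriors)),
    class = "lsd_neutral_estimate"
  )
}

#' @export
print.lsd_neutral_estimate <- function(x, ...) {
  cat("<lsd_neutral_estimate> from ", x$n_loci, " loci: log10 ",
      x$grid$names[1], " = ", signif(x$value[1], 4), ", log10 ",
      x$grid$names[2], " = ", signif(x$value[2], 4), "\n", sep = "")
  invisible(x)
}

#' Highest-posterior-density p-value of a locus against the neutral estimate
#'
#' `h` is the mass of the smallest highest-posterior-density region that
#' contains the neutral estimate: the summed mass of all cells with density
#' strictly greater than the density at the neutral-estimate cell. The
#' outlier metric is `p = 1 - h`; under the null (locus generated at the
#' neutral parameters) `p` is, conservatively, stochastically at least
#' uniform, so it is interpreted as a p-value. The strictly-greater tie
#' rule makes a perfectly flat posterior give `h = 0`, `p = 1`.
#'
#' @param posterior An `lsd_posterior`.
#' @param estimate An `lsd_neutral_estimate` (or integer cell index pair).
#' @return Named numeric vector `c(h =, p =)`.
#' @export
hpd_pvalue <- function(posterior, estimate) {
  cell <- if (inherits(estimate, "lsd_neutral_estimate")) estimate$cell else as.integer(estimate)
  d0 <- posterior$mass[cell[1], cell[2]]
  h <- sum(posterior$mass[posterior$mass > d0])
  c(h = h, p = 1 - h)
}

#' Posterior asymmetry mass of a locus
#'
#' The posterior mass on the side of the neutral ratio line where `M21` has
#' been reduced more than `M12`:
#' `sigma = P[ log10 M21 - log10 M12 < log10 Mhat21 - log10 Mhat12 ]`.
#' Grid cells lying exactly on the boundary contribute half their mass
#' (the continuum integral puts zero measure there; the grid needs a rule).
#' A posterior symmetric under exchanging the two deviation axes has
#' `sigma = 0.5`.
#'
#' @param posterior An `lsd_posterior` (axis 1 = log10 M12, axis 2 =
#'   log10 M21).
#' @param estimate An `lsd_neutral_estimate` (or cell index pair).
#' @return `sigma` in `[0, 1]`.
#' @export
asymmetry_sigma <- function(posterior, estimate) {
  cell <- if (inherits(estimate, "lsd_neutral_estimate")) estimate$cell else as.integer(estimate)
  g <- posterior$grid
  dvals <- outer(-g$axis1, g$axis2, `+`) # [i, j] = axis2[j] - axis1[i]
  ref <- g$axis2[cell[2]] - g$axis1[cell[1]]
  tol <- 1e-9 * (abs(g$w1) + abs(g$w2))
  below <- dvals < ref - tol
  onb <- abs(dvals - ref) <= tol
  sum(posterior$mass[below]) + 0.5 * sum(posterior$mass[onb])
}

#' Asymmetry score
#'
#' The log-odds of the asymmetry mass, `a = ln(sigma / (1 - sigma))`
#' (natural log), with `sigma` clamped to `[eps, 1 - eps]` before the
#' logit. `a = 0` reflects perfect symmetry of the joint posterior about
#' the neutral ratio line. In aggregate mode, `sigma` values are averaged
#' over the designated (selected or candidate) loci first.
#'
#' @param sigma Numeric vector of asymmetry masses in `[0, 1]`.
#' @param mode `"per_locus"` (a value per sigma) or `"aggregate"` (one
#'   value from the mean sigma).
#' @param eps Clamping bound.
#' @return Numeric vector (per-locus) or scalar (aggregate).
#' @export
asymmetry_score <- function(sigma, mode = c("per_locus", "aggregate"),
                            eps = 1e-6) {
  mode <- match.arg(mode)
  if (!length(sigma)) stop("empty sigma input", call. = FALSE)
  stopifnot(all(sigma >= 0 & sigma <= 1))
  if (mode == "aggregate") sigma <- mean(sigma)
  s <- pmin(1 - eps, pmax(eps, sigma))
  log(s / (1 - s))
}

#' Run an LSD genome scan
#'
#' The full two-step scan: (1) an ABC-GLM posterior of the reciprocal
#' migration rates is computed for every locus from the reference table;
#' the neutral point estimate is the arg-max of the product of the
#' posterior densities of the designated neutral subset. (2) Each locus is
#' scored by the HPD p-value `p = 1 - h` of its posterior against the
#' neutral estimate, plus the asymmetry mass `sigma` and score `a`.
#'
#' @param stats Tibble of observed per-locus statistics with a `locus_id`
#'   column (e.g. from [locus_stats()]).
#' @param table An `lsd_reftable`.
#' @param transform An `lsd_transform` (default: fitted on `table`).
#' @param neutral Character vector of locus ids forming the putatively
#'   neutral subset (default: all loci).
#' @param n_ret Retained simulations per locus (default 1% of the table
#'   with a floor of 1000).
#' @param grid_n Grid cells per axis.
#' @param keep_posteriors Keep per-locus posterior grids in the result
#'   (needed by [rescan()] and [misspecification_experiment()]).
#' @param prior Posterior prior handling, passed to [posterior_grid()].
#' @return Object of class `lsd_scan`: `records` tibble (locus_id,
#'   mode_<axes>, h, p, sigma, a), the `neutral_estimate`, and optionally
#'   `posteriors`.
#' @export
run_scan <- function(stats, table, transform = NULL, neutral = NULL,
                     n_ret = NULL, grid_n = 33L, keep_posteriors = TRUE,
                     prior = "truncated") {
  stopifnot("locus_id" %in% names(stats))
  transform <- transform %||% fit_transform(table)
  n_ret <- n_ret %||% max(1000L, ceiling(0.01 * nrow(table)))
  focal <- attr(table, "focal")
  priors <- attr(table, "priors")
  prior_focal <- priors[vapply(priors, function(p) p$name %in% focal, logical(1))]
  grid <- grid_spec(prior_focal[match(focal, vapply(prior_focal, `[[`, "", "name"))],
                    n = grid_n)

  m <- reftable_matrices(table)
  cache <- list(Tm = project_stats(transform, m$X), Y = m$Y)
  n_ret <- min(n_ret, nrow(cache$Tm))

  ids <- as.character(stats$locus_id)
  posteriors <- vector("list", nrow(stats))
  names(posteriors) <- ids
  for (i in seq_len(nrow(stats))) {
    posteriors[[i]] <- locus_posterior(table, transform, stats[i, , drop = FALSE],
                                       grid, n_ret, cache = cache, prior = prior)
  }

  neutral <- neutral %||% ids
  if (!all(neutral %in% ids)) stop("unknown locus ids in `neutral`", call. = FALSE)
  est <- estimate_neutral(posteriors[neutral])

  records <- scan_records(posteriors, est, ids)
  structure(
    list(records = records, neutral_estimate = est, neutral_ids = neutral,
         posteriors = if (keep_posteriors) posteriors else NULL,
         grid = grid, n_ret = n_ret),
    class = "lsd_scan"
  )
}

scan_records <- function(posteriors, est, ids) {
  g <- est$grid
  rows <- purrr::map2(posteriors, ids, function(po, id) {
    hp <- hpd_pvalue(po, est)
    sg <- asymmetry_sigma(po, est)
    ij <- arrayInd(which.max(po$mass), dim(po$mass))
    tibble(locus_id = id,
           mode1 = g$axis1[ij[1]], mode2 = g$axis2[ij[2]],
           h = unname(hp["h"]), p = unname(hp["p"]),
           sigma = sg, a = asymmetry_score(sg))
  })
  out <- dplyr::bind_rows(rows)
  names(out)[2:3] <- paste0("mode_", g$names)
  out
}

#' Re-evaluate a scan under a different neutral subset
#'
#' Reuses the stored per-locus posteriors, recomputing only the neutral
#' estimate and the per-locus records. The posteriors themselves do not
#' depend on the neutral subset, so this is exact, not an approximation.
#'
#' @param scan An `lsd_scan` with kept posteriors.
#' @param neutral Character vector of locus ids.
#' @return A new `lsd_scan`.
#' @export
rescan <- function(scan, neutral) {
  if (is.null(scan$posteriors)) stop("scan was run with keep_posteriors = FALSE",
                                     call. = FALSE)
  ids <- names(scan$posteriors)
  if (!all(neutral %in% ids)) stop("unknown locus ids in `neutral`", call. = FALSE)
  est <- estimate_neutral(scan$posteriors[neutral])
  structure(
    list(records = scan_records(scan$posteriors, est, ids),
         neutral_estimate = est, neutral_ids = neutral,
         posteriors = scan$posteriors, grid = scan$grid, n_ret = scan$n_ret),
    class = "lsd_scan"
  )
}

#' @export
print.lsd_scan <- function(x, ...) {
  cat("<lsd_scan> ", nrow(x$records), " loci; neutral subset: ",
      length(x$neutral_ids), " loci\n", sep = "")
  print(x$neutral_estimate)
  invisible(x)
}

#' @export
tidy.lsd_scan <- function(x, ...) x$records

#' @export
glance.lsd_scan <- function(x, ...) {
  v <- x$neutral_estimate$value
  tibble(n_loci = nrow(x$records), n_neutral = length(x$neutral_ids),
         !!paste0("log10_", names(v)[1]) := unname(v[1]),
         !!paste0("log10_", names(v)[2]) := unname(v[2]),
         n_ret = x$n_ret)
}
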