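#' Genotype fitness table
#'
#' Per-environment relative fitnesses of genotypes `(AA, Aa, aa)` for the
#' biallelic selected site (ancestral `a`, derived `A`). The default scheme
#' is the reciprocal two-environment table `(1 + s1, 1, 1)` in environment 1
#' and `(1, 1, 1 + s2)` in environment 2: the derived allele is favoured in
#' environment 1 and the ancestral allele in environment 2, each advantage
#' expressed in homozygotes. With `dominance = TRUE` the heterozygote takes
#' the full benefit (`(1 + s, 1 + s, 1)` and `(1, 1, 1 + s)` respectively).
#'
#' @param s1,s2 Selection coefficients in environments 1 and 2 (`>= 0`).
#' @param dominance If `TRUE` the favoured allele is dominant.
#' @return Matrix with one row per environment, columns `wAA`, `wAa`, `waa`.
#' @export
fitness_table <- function(s1, s2, dominance = FALSE) {
  stopifnot(s1 >= 0, s2 >= 0)
  w <- rbind(
    c(1 + s1, if (dominance) 1 + s1 else 1, 1),
    c(1, if (dominance) 1 + s2 else 1, 1 + s2)
  )
  colnames(w) <- c("wAA", "wAa", "waa")
  if (any(w <= 0)) stop("fitnesses must be positive", call. = FALSE)
  w
}

#' Selection regime
#'
#' Describes divergent selection on a biallelic site: coefficients `s1`,
#' `s2` in the two contrasting environments, the onset time `T_S`
#' (generations before present) and initial derived-allele frequencies at
#' the onset. `origin = "de_novo"` forces `f1 = 1/(2 N1)`, `f2 = 0` (a
#' single new copy in deme 1); `origin = "standing"` uses the supplied
#' frequencies (default 0.1 in both demes).
#'
#' @param s1,s2 Selection coefficients (`>= 0`).
#' @param T_S Onset of selection, generations before present (`> 0`).
#' @param f1,f2 Initial derived-allele frequencies at `T_S`.
#' @param origin `"standing"` or `"de_novo"`.
#' @param dominance Passed to [fitness_table()].
#' @return An object of class `lsd_regime`.
#' @export
selection_regime <- function(s1, s2, T_S, f1 = 0.1, f2 = 0.1,
                             origin = c("standing", "de_novo"),
                             dominance = FALSE) {
  origin <- match.arg(origin)
  stopifnot(s1 >= 0, s2 >= 0, T_S > 0, f1 >= 0, f1 <= 1, f2 >= 0, f2 <= 1)
  structure(
    list(s1 = s1, s2 = s2, T_S = T_S, f1 = f1, f2 = f2, origin = origin,
         dominance = dominance),
    class = "lsd_regime"
  )
}

#' Rescale a model and regime for desk-scale forward simulation
#'
#' Standard population-genetic rescaling by a factor `lambda`: sizes and
#' times shrink (`N -> N/lambda`, `t -> t/lambda`) while selection,
#' migration fractions and mutation intensify (`s -> s*lambda`,
#' `m -> m*lambda`, `mu -> mu*lambda`). The compound parameters `4*N*mu`,
#' `N*m` (= `M`, so migrant numbers are untouched), `N*s` and `t/N` are
#' invariant, so summary-statistic distributions are preserved within the
#' diffusion regime. Rescaling is rejected when it leaves that regime
#' (`s*lambda > 1` or any forward migration fraction `> 1`).
#'
#' @param model An `lsd_model` with literal (or resolvable) sizes.
#' @param regime An `lsd_regime` (or `NULL`).
#' @param lambda Rescaling factor (`>= 1`).
#' @param params Optional parameter set used to resolve sizes/migration.
#' @return List with elements `model`, `regime`, `lambda`.
#' @export
rescale_model <- function(model, regime = NULL, lambda, params = NULL) {
  stopifnot(lambda >= 1)
  params <- as_params(params)
  if (!is.null(regime)) {
    for (s in c(regime$s1, regime$s2)) {
      if (s * lambda > 1) {
        stop("rescaled selection coefficient s*lambda = ", s * lambda,
             " > 1: model leaves the diffusion regime", call. = FALSE)
      }
    }
  }
  demes2 <- lapply(model$demes, function(d) {
    deme(d$id, resolve_value(d$initial_size, params) / lambda,
         resolve_value(d$growth_rate, params) * lambda)
  })
  # migration entries are migrants/generation (M = N m): invariant, but check
  # the implied forward fractions in the rescaled model
  D <- length(demes2)
  mig2 <- model$migration
  for (i in seq_len(D)) {
    Ni <- demes2[[i]]$initial_size
    mrow <- 0
    for (j in seq_len(D)) {
      if (i == j) next
      Mij <- model$migration[i, j]
      if (!is.character(Mij) || !is.na(suppressWarnings(as.numeric(Mij)))) {
        mrow <- mrow + resolve_value(Mij, params) / Ni
      }
    }
    if (mrow > 1) {
      stop("rescaled migration fraction exceeds 1 in deme ", demes2[[i]]$id,
           call. = FALSE)
    }
  }
  events2 <- lapply(model$events, function(ev) {
    ev$time <- ev$time / lambda
    if (ev$kind == "size_change") ev$size <- resolve_value(ev$size, params) / lambda
    if (ev$kind == "growth_change") ev$rate <- resolve_value(ev$rate, params) * lambda
    ev
  })
  model2 <- demographic_model(
    demes = demes2, migration = mig2, events = events2,
    mutation_rate = resolve_value(model$mutation_rate, params) * lambda,
    free_parameters = model$free_parameters
  )
  regime2 <- regime
  if (!is.null(regime2)) {
    regime2$s1 <- regime$s1 * lambda
    regime2$s2 <- regime$s2 * lambda
    regime2$T_S <- regime$T_S / lambda
    if (regime2$origin == "de_novo") {
      regime2$f1 <- 1 / (2 * demes2[[1]]$initial_size)
      regime2$f2 <- 0
    }
  }
  list(model = model2, regime = regime2, lambda = lambda)
}

#' Default rescaling factor
#'
#' Chooses the smallest integer `lambda` such that all rescaled diploid
#' sizes are at most `N_max`.
#'
#' @param model An `lsd_model`.
#' @param params Optional parameter set.
#' @param N_max Largest allowed rescaled size (default 1000 diploids).
#' @return Integer `lambda >= 1`.
#' @export
default_lambda <- function(model, params = NULL, N_max = 1000) {
  params <- as_params(params)
  N <- vapply(model$demes, function(d) resolve_value(d$initial_size, params),
              numeric(1))
  max(1L, as.integer(ceiling(max(N) / N_max)))
}

# Forward migration fractions matching the backward convention used by the
# coalescent engine: each backward lineage in deme i migrates at rate
# m_ij = M_ij / N_i per generation, so forward each gamete of deme i is
# drawn from deme j's pool with probability mt[i, j] = M_ij / N_i (the two
# conventions coincide to first order for conservative migration).
forward_fractions <- function(model, params = NULL) {
  rs <- resolve_at_time(model, params, 0)
  D <- length(rs$size)
  mt <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    if (i != j) mt[i, j] <- rs$M[i, j] / rs$size[i]
  }
  if (any(rowSums(mt) >= 1)) {
    stop("forward migration fractions sum to >= 1; rescale less aggressively",
         call. = FALSE)
  }
  mt
}

#' Simulate a selected-allele frequency trajectory
#'
#' Forward per-generation recursion from the onset of selection `T_S` to the
#' present, for each deme: (1) selection,
#' `p* = (p^2 wAA + p(1-p) wAa) / wbar`; (2) migration,
#' `p_i <- (1 - sum_j mt_ij) p_i* + sum_j mt_ij p_j*` with forward fractions
#' `mt` derived from the model's migrant numbers; (3) binomial drift over
#' `2 N_i` gametes. With `conditioned = TRUE` the trajectory is
#' rejection-resampled until the derived allele survives (the retention
#' rule), up to `resample_cap` attempts.
#'
#' @param model An `lsd_model` (resolvable at all `t <= T_S`).
#' @param params Parameter set.
#' @param regime An `lsd_regime`.
#' @param conditioned Resample until the derived allele is retained?
#' @param retention `"not_lost"` (segregating or fixed somewhere at `t = 0`)
#'   or `"segregating"`.
#' @param resample_cap Maximum conditioning attempts before declaring a
#'   loss regime.
#' @param deterministic If `TRUE`, skip drift (infinite-population
#'   recursion).
#' @param seed Optional integer seed.
#' @return Object of class `lsd_trajectory`: matrix `p` of per-deme
#'   frequencies for `t = T_S ... 0` (rows), flag `survived`, attempt count.
#' @export
simulate_trajectory <- function(model, params, regime, conditioned = TRUE,
                                retention = c("not_lost", "segregating"),
                                resample_cap = 1e4, deterministic = FALSE,
                                seed = NULL) {
  retention <- match.arg(retention)
  run <- function() {
    rs0 <- resolve_at_time(model, params, 0)
    D <- length(rs0$size)
    if (D < 2 && regime$origin == "standing") D <- max(D, 1L)
    w <- fitness_table(regime$s1, regime$s2, regime$dominance)
    if (nrow(w) < D) w <- w[rep(seq_len(nrow(w)), length.out = D), , drop = FALSE]
    mt <- forward_fractions(model, params)
    Tn <- as.integer(round(regime$T_S))
    f0 <- c(regime$f1, regime$f2)[seq_len(D)]
    if (regime$origin == "de_novo") f0 <- c(1 / (2 * rs0$size[1]), rep(0, D - 1))
    twoN <- 2 * rs0$size

    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      p <- matrix(NA_real_, Tn + 1L, D)
      p[1L, ] <- f0
      cur <- f0
      for (g in seq_len(Tn)) {
        ps <- numeric(D)
        for (d in seq_len(D)) {
          pd <- cur[d]
          wbar <- pd^2 * w[d, 1] + 2 * pd * (1 - pd) * w[d, 2] + (1 - pd)^2 * w[d, 3]
          ps[d] <- (pd^2 * w[d, 1] + pd * (1 - pd) * w[d, 2]) / wbar
        }
        pm <- numeric(D)
        for (d in seq_len(D)) {
          pm[d] <- (1 - sum(mt[d, -d])) * ps[d] + sum(mt[d, -d] * ps[-d])
        }
        if (deterministic) {
          cur <- pm
        } else {
          cur <- rbinom(D, twoN, pm) / twoN
        }
        p[g + 1L, ] <- cur
      }
      tot <- sum(cur * rs0$size) # proportional to copy number
      ok <- if (retention == "segregating") tot > 0 && any(cur < 1) else tot > 0
      if (!conditioned || deterministic || ok) {
        return(structure(list(p = p, survived = tot > 0, attempts = attempt,
                              deme_ids = model$deme_ids[seq_len(D)]),
                         class = "lsd_trajectory"))
      }
      if (attempt >= resample_cap) {
        stop(loss_regime_condition(regime))
      }
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

loss_regime_condition <- function(regime) {
  structure(
    class = c("lsd_loss_regime", "error", "condition"),
    list(message = sprintf(
      "loss regime: derived allele lost in every attempt (s1=%g, s2=%g, T_S=%g, origin=%s)",
      regime$s1, regime$s2, regime$T_S, regime$origin),
      call = NULL, regime = regime)
  )
}

#' One deterministic selection step
#'
#' The infinite-population recursion `p* = (p^2 wAA + p(1-p) wAa) / wbar`
#' used by the forward simulators; exported for transparency.
#'
#' @param p Current derived-allele frequency.
#' @param w Length-3 fitness vector `(wAA, wAa, waa)`.
#' @return Post-selection frequency.
#' @export
selection_step <- function(p, w) {
  wbar <- p^2 * w[1] + 2 * p * (1 - p) * w[2] + (1 - p)^2 * w[3]
  (p^2 * w[1] + p * (1 - p) * w[2]) / wbar
}

#' Simulate a selected locus by individual-based forward simulation
#'
#' Simulates all `2 N_i` haplotypes of each deme for one non-recombining
#' `L`-bp locus: infinite-sites neutral mutation at rate `mu` per bp per
#' generation, selection through a selected site fully linked to the locus,
#' and migration as whole-haplotype exchange. The population is burned in
#' neutrally for `burnin_factor * max(N)` generations, the selected variant
#' is introduced per the regime at `T_S`, and the simulation is
#' rejection-resampled (from the post-burn-in state) until the derived
#' allele is retained. Haplotypes are sampled at the present.
#'
#' The model must have constant demography (no events); apply
#' [rescale_model()] first so sizes are desk-scale.
#'
#' @param model Constant-demography `lsd_model` (typically rescaled).
#' @param params Parameter set.
#' @param regime An `lsd_regime` (already rescaled if the model is).
#' @param L Locus length (bp).
#' @param mu Mutation rate per bp per generation (default: model's).
#' @param sample_config Named haploid sample counts per deme.
#' @param burnin_factor Burn-in length in units of the largest diploid size.
#' @param retention Survival-conditioning rule (see
#'   [simulate_trajectory()]).
#' @param resample_cap Conditioning attempts before signalling a loss
#'   regime.
#' @param seed Optional integer seed.
#' @return An `lsd_locus`; the selected site (if segregating in the sample)
#'   is included as a column at a uniform position.
#' @export
simulate_selected_locus <- function(model, params, regime, L, mu = NULL,
                                    sample_config, burnin_factor = 20,
                                    retention = c("not_lost", "segregating"),
                                    resample_cap = 1e4, seed = NULL) {
  retention <- match.arg(retention)
  if (length(model$events)) {
    stop("the forward haplotype simulator supports constant demography only",
         call. = FALSE)
  }
  params <- as_params(params)
  run <- function() {
    rs <- resolve_at_time(model, params, 0)
    D <- length(rs$size)
    N <- as.integer(round(rs$size))
    mu <- mu %||% resolve_value(model$mutation_rate, params)
    mt <- forward_fractions(model, params)
    n <- check_sample_config(model, sample_config)
    w <- if (is.null(regime)) matrix(1, D, 3) else {
      ft <- fitness_table(regime$s1, regime$s2, regime$dominance)
      ft[rep(seq_len(nrow(ft)), length.out = D), , drop = FALSE]
    }
    origin <- if (is.null(regime)) "none" else regime$origin
    f_init <- if (is.null(regime)) rep(0, D) else {
      c(regime$f1, regime$f2)[seq_len(D)]
    }
    t_burn <- as.integer(round(burnin_factor * max(N)))
    t_sel <- if (is.null(regime)) 0L else as.integer(round(regime$T_S))

    sim <- .cpp_forward_locus(N, mt, mu * L, w, t_burn, t_sel, f_init,
                              origin, as.integer(n), retention,
                              as.integer(resample_cap))
    if (!sim$survived) stop(loss_regime_condition(regime))

    H <- sim$haplotypes
    S <- ncol(H)
    pos <- runif(S)
    sel_col <- NULL
    if (origin != "none") {
      sel <- as.integer(sim$sel)
      if (sum(sel) > 0L && sum(sel) < length(sel)) {
        H <- cbind(H, sel)
        pos <- c(pos, runif(1))
      }
    }
    o <- order(pos)
    locus_data(H[, o, drop = FALSE], pos[o], L,
               rep(model$deme_ids, times = n), drop_monomorphic = TRUE)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Build a validation pseudogenome
#'
#' A pseudogenome is a collection of independent loci (free recombination
#' between loci): `n_n` neutral loci simulated under the structured
#' coalescent and `n_s` selected loci simulated forward under the given
#' regime, all sharing the sample configuration.
#'
#' @param model Constant-demography `lsd_model` (typically rescaled).
#' @param params Parameter set (must include the migration parameters).
#' @param regime An `lsd_regime` (rescaled consistently with the model), or
#'   `NULL` when `n_s = 0`.
#' @param n_n,n_s Numbers of neutral and selected loci (defaults: 1000
#'   neutral + 50 selected).
#' @param L Per-locus length in bp (default 5 kb, for a 5.25 Mb default
#'   pseudogenome).
#' @param sample_config Named haploid sample counts per deme.
#' @param seed Optional integer seed.
#' @param ... Passed to [simulate_selected_locus()].
#' @return Object of class `lsd_pseudogenome`: list of `lsd_locus` in
#'   `loci`, a `manifest` tibble (locus_id, label, regime fields), and the
#'   per-locus length `L`.
#' @export
build_pseudogenome <- function(model, params, regime, n_n = 1000, n_s = 50,
                               L = 5000, sample_config, seed = NULL, ...) {
  stopifnot(n_n >= 0, n_s >= 0)
  params <- as_params(params)
  run <- function() {
    re <- resolve_epochs(model, params)
    n <- check_sample_config(model, sample_config)
    sample_demes0 <- rep(seq_along(re$deme_ids) - 1L, times = n)
    labels <- rep(model$deme_ids, times = n)
    loci <- vector("list", n_n + n_s)
    for (i in seq_len(n_n)) {
      g <- .cpp_sim_genealogy(re$epochs, sample_demes0, re$n_demes, 1e9)
      mut <- .cpp_drop_mutations(g$parent, g$node_time, g$n_samples,
                                 sample_demes0, re$n_demes, re$mu, L, TRUE)
      loci[[i]] <- locus_data(mut$haplotypes, mut$positions, L, labels,
                              locus_id = sprintf("neutral_%04d", i),
                              drop_monomorphic = FALSE)
    }
    for (i in seq_len(n_s)) {
      l <- simulate_selected_locus(model, params, regime, L,
                                   sample_config = sample_config, ...)
      l$locus_id <- sprintf("selected_%04d", i)
      loci[[n_n + i]] <- l
    }
    manifest <- tibble(
      locus_id = vapply(loci, function(l) l$locus_id, character(1)),
      label = rep(c("neutral", "selected"), c(n_n, n_s)),
      s1 = if (is.null(regime)) NA_real_ else
        ifelse(seq_along(loci) > n_n, regime$s1, NA_real_),
      s2 = if (is.null(regime)) NA_real_ else
        ifelse(seq_along(loci) > n_n, regime$s2, NA_real_),
      T_S = if (is.null(regime)) NA_real_ else
        ifelse(seq_along(loci) > n_n, regime$T_S, NA_real_)
    )
    structure(list(loci = loci, manifest = manifest, n_n = n_n, n_s = n_s,
                   L = L),
              class = "lsd_pseudogenome")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.lsd_pseudogenome <- function(x, ...) {
  cat("<lsd_pseudogenome> ", x$n_n, " neutral + ", x$n_s, " selected loci x ",
      x$L, " bp = ", (x$n_n + x$n_s) * x$L, " bp total\n", sep = "")
  invisible(x)
}
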