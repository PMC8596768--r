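#' Per-locus haplotype data
#'
#' Container for a single non-recombining locus: a binary haplotype matrix
#' (0 = ancestral, 1 = derived), relative positions in `[0, 1)`, the locus
#' length in bp and a population label per haplotype.
#'
#' @param haplotypes `n x S` 0/1 matrix.
#' @param positions Strictly increasing numeric vector of length `S` in
#'   `[0, 1)`.
#' @param L Locus length in bp.
#' @param pop_labels Character vector of deme ids, one per haplotype row.
#' @param locus_id Optional identifier.
#' @param drop_monomorphic Drop columns that are invariant across all
#'   haplotypes (the container's invariant; default `TRUE`).
#' @return An object of class `lsd_locus`.
#' @export
locus_data <- function(haplotypes, positions, L, pop_labels,
                       locus_id = NULL, drop_monomorphic = TRUE) {
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) < 1L) stop("need at least one haplotype", call. = FALSE)
  if (length(pop_labels) != nrow(haplotypes)) {
    stop("`pop_labels` must match haplotype rows", call. = FALSE)
  }
  if (length(positions) != ncol(haplotypes)) {
    stop("`positions` must match haplotype columns", call. = FALSE)
  }
  if (drop_monomorphic && ncol(haplotypes)) {
    cs <- colSums(haplotypes)
    keep <- cs > 0L & cs < nrow(haplotypes)
    haplotypes <- haplotypes[, keep, drop = FALSE]
    positions <- positions[keep]
  }
  if (is.unsorted(positions, strictly = TRUE)) {
    o <- order(positions)
    positions <- positions[o]
    haplotypes <- haplotypes[, o, drop = FALSE]
  }
  structure(
    list(haplotypes = haplotypes, positions = as.numeric(positions),
         L = L, pop_labels = as.character(pop_labels), locus_id = locus_id),
    class = "lsd_locus"
  )
}

#' @export
print.lsd_locus <- function(x, ...) {
  cat("<lsd_locus> ", nrow(x$haplotypes), " haplotypes, ",
      ncol(x$haplotypes), " segregating sites, L = ", x$L, " bp\n", sep = "")
  invisible(x)
}

check_sample_config <- function(model, sample_config) {
  if (is.null(names(sample_config)) || !all(names(sample_config) %in% model$deme_ids)) {
    stop("`sample_config` must be a named vector of haploid counts keyed by deme id",
         call. = FALSE)
  }
  n <- setNames(integer(length(model$deme_ids)), model$deme_ids)
  n[names(sample_config)] <- as.integer(sample_config)
  if (sum(n) < 1L) stop("need at least one sampled lineage", call. = FALSE)
  n
}

#' Simulate a neutral genealogy under the structured coalescent
#'
#' Simulates the genealogy of a sample of lineages under an arbitrary
#' [demographic_model()]: within deme `i` at time `t` each lineage pair
#' coalesces at rate `1/(2 N_i(t))` per generation and each lineage
#' migrates (backward) to deme `j` at rate `m_ij(t) = M_ij / N_i(t)`.
#' Event times are drawn exactly (continuous-time exponential races with
#' thinning under exponential growth).
#'
#' @param model An `lsd_model`.
#' @param params Named parameter set or one-row tibble.
#' @param sample_config Named vector of haploid sample counts per deme id.
#' @param seed Optional integer seed.
#' @param time_ceiling Error if the coalescent has not completed by this
#'   many generations (guards non-coalescing models).
#' @return An object of class `lsd_genealogy` with 1-based `parent`
#'   pointers (root parent = `NA`), `node_time` in generations, and the
#'   sampled lineages' deme labels.
#' @export
simulate_genealogy <- function(model, params, sample_config, seed = NULL,
                               time_ceiling = 1e9) {
  n <- check_sample_config(model, sample_config)
  re <- resolve_epochs(model, params)
  sample_demes <- rep(seq_along(re$deme_ids) - 1L, times = n)
  run <- function() {
    .cpp_sim_genealogy(re$epochs, as.integer(sample_demes), re$n_demes,
                       time_ceiling)
  }
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(
    list(parent = ifelse(sim$parent < 0L, NA_integer_, sim$parent + 1L),
         node_time = sim$node_time, n_samples = sim$n_samples,
         sample_demes = rep(re$deme_ids, times = n)),
    class = "lsd_genealogy"
  )
}

#' Total branch length of a genealogy (in generations)
#' @param genealogy An `lsd_genealogy`.
#' @return Sum of branch lengths over all non-root nodes.
#' @export
total_branch_length <- function(genealogy) {
  p <- genealogy$parent
  sum(genealogy$node_time[p[!is.na(p)]] - genealogy$node_time[!is.na(p)])
}

#' Drop infinite-sites mutations on a genealogy
#'
#' The number of mutations is Poisson with mean `mu * L * T` where `T` is
#' the total branch length; each mutation is placed uniformly on branches
#' and assigned a unique uniform position (infinite-sites model). Haplotypes
#' below the mutated branch carry the derived state.
#'
#' @param genealogy An `lsd_genealogy`.
#' @param mu Mutation rate per bp per generation (`>= 0`).
#' @param L Locus length in bp (`> 0`).
#' @param seed Optional integer seed.
#' @return An `lsd_locus`.
#' @export
drop_mutations <- function(genealogy, mu, L, seed = NULL) {
  stopifnot(mu >= 0, L > 0)
  parent0 <- ifelse(is.na(genealogy$parent), -1L, genealogy$parent - 1L)
  demes <- match(genealogy$sample_demes, unique(genealogy$sample_demes)) - 1L
  run <- function() {
    .cpp_drop_mutations(as.integer(parent0), genealogy$node_time,
                        genealogy$n_samples, as.integer(demes),
                        max(demes) + 1L, mu, L, TRUE)
  }
  sim <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  locus_data(sim$haplotypes, sim$positions, L, genealogy$sample_demes,
             drop_monomorphic = FALSE)
}

#' Simulate a neutral locus (genealogy + mutations)
#'
#' @inheritParams simulate_genealogy
#' @param L Locus length in bp.
#' @param mu Mutation rate per bp per generation; defaults to the model's.
#' @return An `lsd_locus`.
#' @export
simulate_locus <- function(model, params, sample_config, L, mu = NULL,
                           seed = NULL, time_ceiling = 1e9) {
  run <- function() {
    g <- simulate_genealogy(model, params, sample_config,
                            time_ceiling = time_ceiling)
    mu <- mu %||% resolve_value(model$mutation_rate, as_params(params))
    drop_mutations(g, mu, L)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Fast path used by the reference-table builder: simulate a locus and return
# only per-site derived-allele counts per deme (all implemented summary
# statistics are functions of these counts).
simulate_locus_counts <- function(re, sample_demes0, n_per_pop, mu, L,
                                  time_ceiling = 1e9) {
  g <- .cpp_sim_genealogy(re$epochs, sample_demes0, re$n_demes, time_ceiling)
  .cpp_drop_mutations(g$parent, g$node_time, g$n_samples, sample_demes0,
                      re$n_demes, mu, L, FALSE)
}
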