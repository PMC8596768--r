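#' @title Per-locus summary statistics
#' @description
#' Statistics are computed from derived-allele counts per population.
#' Within-population statistics `S`, `pi` and `theta_w` are reported
#' per-locus (window totals); `D_XY` is reported per site. Undefined
#' statistics (e.g. Tajima's D when `S = 0`, F_ST when there is no between-
#' population diversity) are reported as `NA`, never as 0.
#' @name sumstats
NULL

tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

# counts: S x P matrix of derived counts per population; n: haploids per pop
stats_from_counts <- function(counts, n, L, sfs_bins = 4L) {
  P <- length(n)
  pops <- names(n) %||% as.character(seq_len(P))
  out <- list()

  piw <- numeric(P)
  for (p in seq_len(P)) {
    cp <- counts[, p]
    np <- n[p]
    seg <- cp > 0L & cp < np
    Sp <- sum(seg)
    others_mono <- if (P > 1L) {
      oc <- counts[, -p, drop = FALSE]
      on <- n[-p]
      rowSums(sweep(oc, 2, on, function(c, nn) c > 0 & c < nn)) == 0
    } else rep(TRUE, nrow(counts))
    privSp <- sum(seg & others_mono)

    if (np >= 2L) {
      pi_p <- sum(2 * cp[seg] * (np - cp[seg])) / (np * (np - 1))
      tc <- tajima_constants(np)
      thetaW <- Sp / tc$a1
      tajD <- if (Sp > 0) {
        (pi_p - thetaW) / sqrt(tc$e1 * Sp + tc$e2 * Sp * (Sp - 1))
      } else NA_real_
    } else {
      pi_p <- thetaW <- tajD <- NA_real_
    }
    piw[p] <- pi_p

    sfs <- rep(0, sfs_bins)
    if (Sp > 0) {
      fr <- cp[seg] / np
      bin <- pmin(sfs_bins, ceiling(fr * sfs_bins))
      tb <- tabulate(bin, nbins = sfs_bins)
      sfs <- tb / Sp
    }

    out[[paste0("S_", pops[p])]] <- as.numeric(Sp)
    out[[paste0("privS_", pops[p])]] <- as.numeric(privSp)
    out[[paste0("pi_", pops[p])]] <- pi_p
    out[[paste0("thetaW_", pops[p])]] <- thetaW
    out[[paste0("tajD_", pops[p])]] <- tajD
    for (b in seq_len(sfs_bins)) {
      out[[paste0("sfs", b, "_", pops[p])]] <- sfs[b]
    }
  }

  if (P > 1L) {
    for (a in seq_len(P - 1L)) {
      for (b in seq(a + 1L, P)) {
        ca <- counts[, a]; cb <- counts[, b]
        na <- n[a]; nb <- n[b]
        pib <- sum(ca * (nb - cb) + (na - ca) * cb) / (na * nb)
        dxy <- pib / L
        fst <- if (pib > 0) {
          max(-1, min(1, 1 - mean(c(piw[a], piw[b])) / pib))
        } else NA_real_
        out[[paste0("fst_", pops[a], "_", pops[b])]] <- fst
        out[[paste0("dxy_", pops[a], "_", pops[b])]] <- dxy
      }
    }
  }

  ntot <- sum(n)
  ctot <- rowSums(counts)
  segt <- ctot > 0L & ctot < ntot
  out[["S_tot"]] <- as.numeric(sum(segt))
  out[["pi_tot"]] <- if (ntot >= 2L) {
    sum(2 * ctot[segt] * (ntot - ctot[segt])) / (ntot * (ntot - 1))
  } else NA_real_
  v <- as.numeric(unlist(out, use.names = FALSE))
  names(v) <- names(out)
  v
}

locus_counts <- function(locus, pops = NULL) {
  labs <- locus$pop_labels
  pops <- pops %||% unique(labs)
  n <- vapply(pops, function(p) sum(labs == p), integer(1))
  counts <- vapply(pops, function(p) {
    if (n[[p]] == 0L) rep(0, ncol(locus$haplotypes))
    else colSums(locus$haplotypes[labs == p, , drop = FALSE])
  }, numeric(ncol(locus$haplotypes)))
  if (ncol(locus$haplotypes) == 0L) {
    counts <- matrix(0L, 0L, length(pops))
  }
  counts <- matrix(as.integer(counts), ncol = length(pops))
  colnames(counts) <- pops
  list(counts = counts, n = setNames(as.integer(n), pops))
}

#' Within-population diversity statistics
#'
#' Computes the number of segregating sites `S`, private `S` (segregating in
#' `pop`, monomorphic in all other populations), nucleotide diversity `pi`
#' (mean pairwise difference count per locus), Watterson's estimator
#' `theta_w = S / a_{n-1}` and Tajima's D for one population.
#'
#' @param locus An `lsd_locus`.
#' @param pop Deme id.
#' @return One-row tibble with columns `S`, `private_S`, `pi`, `theta_w`,
#'   `tajima_d` (`NA` where fewer than 2 haplotypes, or `D` when `S = 0`).
#' @export
diversity_stats <- function(locus, pop) {
  lc <- locus_counts(locus)
  if (!pop %in% names(lc$n)) stop("unknown population: ", pop, call. = FALSE)
  st <- stats_from_counts(lc$counts, lc$n, locus$L)
  tibble(
    S = st[[paste0("S_", pop)]],
    private_S = st[[paste0("privS_", pop)]],
    pi = st[[paste0("pi_", pop)]],
    theta_w = st[[paste0("thetaW_", pop)]],
    tajima_d = st[[paste0("tajD_", pop)]]
  )
}

#' Between-population divergence statistics
#'
#' `D_XY` is the mean pairwise difference count between populations divided
#' by the locus length (per site). `F_ST` is Hudson's estimator
#' `1 - mean(pi_A, pi_B) / pi_between` (per locus), clamped to `[-1, 1]`;
#' it is `NA` when `pi_between = 0`.
#'
#' @param locus An `lsd_locus`.
#' @param popA,popB Deme ids.
#' @return One-row tibble with columns `fst`, `dxy`.
#' @export
divergence_stats <- function(locus, popA, popB) {
  lc <- locus_counts(locus, pops = c(popA, popB))
  if (any(lc$n < 1L)) stop("need at least one haplotype per population", call. = FALSE)
  st <- stats_from_counts(lc$counts, lc$n, locus$L)
  tibble(
    fst = st[[paste0("fst_", popA, "_", popB)]],
    dxy = st[[paste0("dxy_", popA, "_", popB)]]
  )
}

#' Binned unfolded site-frequency spectrum
#'
#' Derived-allele frequencies of sites segregating within `pop` are
#' aggregated into `bins` equal-width classes over `(0, 1)` and normalized
#' to sum to 1 (all-zero when `S = 0`).
#'
#' @param locus An `lsd_locus`.
#' @param pop Deme id.
#' @param bins Number of frequency bins.
#' @return Numeric vector of length `bins`.
#' @export
sfs_stats <- function(locus, pop, bins = 4L) {
  lc <- locus_counts(locus)
  st <- stats_from_counts(lc$counts, lc$n, locus$L, sfs_bins = bins)
  unname(st[paste0("sfs", seq_len(bins), "_", pop)])
}

#' Summary-statistics vector for a locus
#'
#' Aggregates all implemented statistics in a fixed, documented column
#' order: per population `S`, private `S`, `pi`, `theta_w`, Tajima's D and
#' `sfs_bins` SFS bins; per population pair Hudson's `F_ST` and per-site
#' `D_XY`; then total `S` and total `pi`. The ordering is identical for
#' observed and simulated data, and `NA` sentinels propagate.
#'
#' @param x An `lsd_locus` or `lsd_pooled` object.
#' @param pops Populations to include (default: all, in order of first
#'   appearance for haplotype data; pool order for pooled data).
#' @param sfs_bins Number of SFS bins per population.
#' @param ... Passed to methods.
#' @return A one-row tibble.
#' @export
stats_vector <- function(x, ...) UseMethod("stats_vector")

#' @rdname stats_vector
#' @export
stats_vector.lsd_locus <- function(x, pops = NULL, sfs_bins = 4L, ...) {
  lc <- locus_counts(x, pops = pops)
  as_tibble(as.list(stats_from_counts(lc$counts, lc$n, x$L, sfs_bins = sfs_bins)))
}

#' Summary statistics for a set of loci
#'
#' @param loci List of `lsd_locus` (or `lsd_pooled`) objects.
#' @param ... Passed to [stats_vector()].
#' @return A tibble with one row per locus and a `locus_id` column.
#' @export
locus_stats <- function(loci, ...) {
  rows <- purrr::imap(loci, function(l, i) {
    id <- l$locus_id %||% paste0("locus_", i)
    dplyr::bind_cols(tibble(locus_id = as.character(id)), stats_vector(l, ...))
  })
  dplyr::bind_rows(rows)
}

#' Emulate pooled sequencing of a locus
#'
#' Mimics pool-seq data: for each segregating site and pool, a read depth is
#' drawn from a negative binomial coverage model (or held fixed) and derived
#' read counts are binomial in the pool's derived-allele frequency. Pools
#' take `2 * pools[i]` haplotypes to represent `pools[i]` diploid
#' individuals. Sites with zero depth are marked missing.
#'
#' @param locus An `lsd_locus`.
#' @param pools Named vector: diploid individuals pooled per deme.
#' @param coverage List: either `list(mean =, dispersion =)` for negative
#'   binomial depths (`dispersion` is the NB size parameter) or
#'   `list(fixed =)` for constant depth.
#' @param seed Optional integer seed.
#' @return An object of class `lsd_pooled` with per-site, per-pool `depth`
#'   and `derived` matrices.
#' @export
emulate_pool_reads <- function(locus, pools, coverage = list(mean = 30, dispersion = 5),
                               seed = NULL) {
  labs <- locus$pop_labels
  pops <- names(pools)
  if (is.null(pops)) stop("`pools` must be named by deme id", call. = FALSE)
  run <- function() {
    S <- ncol(locus$haplotypes)
    depth <- derived <- matrix(0L, S, length(pops), dimnames = list(NULL, pops))
    for (p in seq_along(pops)) {
      avail <- which(labs == pops[p])
      need <- 2L * pools[[p]]
      if (length(avail) < need) {
        stop("pool for deme ", pops[p], " needs ", need,
             " haplotypes but only ", length(avail), " available", call. = FALSE)
      }
      take <- avail[seq_len(need)]
      freq <- colMeans(locus$haplotypes[take, , drop = FALSE])
      dp <- if (!is.null(coverage$fixed)) {
        rep(as.integer(coverage$fixed), S)
      } else {
        if (is.null(coverage$mean) || is.null(coverage$dispersion) ||
            coverage$mean <= 0 || coverage$dispersion <= 0) {
          stop("invalid coverage parameters", call. = FALSE)
        }
        rnbinom(S, mu = coverage$mean, size = coverage$dispersion)
      }
      depth[, p] <- dp
      derived[, p] <- rbinom(S, dp, freq)
    }
    structure(
      list(depth = depth, derived = derived, positions = locus$positions,
           L = locus$L, pools = pools, locus_id = locus$locus_id),
      class = "lsd_pooled"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @rdname stats_vector
#' @param min_count Minimum reads of an allele for a site to count as
#'   polymorphic in the pooled path (anti-singleton-noise rule).
#' @export
stats_vector.lsd_pooled <- function(x, pops = NULL, sfs_bins = 4L,
                                    min_count = 2L, ...) {
  pops <- pops %||% colnames(x$depth)
  P <- length(pops)
  nhap <- setNames(2L * unlist(x$pools)[pops], pops) # haploid pool sizes
  out <- list()
  pihat <- numeric(P)
  fhat <- matrix(NA_real_, nrow(x$depth), P)
  poly <- matrix(FALSE, nrow(x$depth), P)
  for (p in seq_len(P)) {
    dp <- x$depth[, pops[p]]
    dr <- x$derived[, pops[p]]
    ok <- dp > 0L
    fhat[ok, p] <- dr[ok] / dp[ok]
    poly[, p] <- ok & dr >= min_count & (dp - dr) >= min_count
  }
  for (p in seq_len(P)) {
    ok <- !is.na(fhat[, p])
    Leff <- x$L # relative missingness is per-site; window L retained
    Sp <- sum(poly[, p])
    others_mono <- rowSums(poly[, -p, drop = FALSE]) == 0
    privSp <- sum(poly[, p] & others_mono)
    n <- nhap[p]
    f <- fhat[poly[, p], p]
    pi_p <- sum(2 * f * (1 - f)) * n / (n - 1)
    tc <- tajima_constants(n)
    thetaW <- Sp / tc$a1
    tajD <- if (Sp > 0) {
      (pi_p - thetaW) / sqrt(tc$e1 * Sp + tc$e2 * Sp * (Sp - 1))
    } else NA_real_
    pihat[p] <- pi_p
    sfs <- rep(0, sfs_bins)
    if (Sp > 0) {
      bin <- pmin(sfs_bins, ceiling(f * sfs_bins))
      sfs <- tabulate(bin, nbins = sfs_bins) / Sp
    }
    out[[paste0("S_", pops[p])]] <- as.numeric(Sp)
    out[[paste0("privS_", pops[p])]] <- as.numeric(privSp)
    out[[paste0("pi_", pops[p])]] <- pi_p
    out[[paste0("thetaW_", pops[p])]] <- thetaW
    out[[paste0("tajD_", pops[p])]] <- tajD
    for (b in seq_len(sfs_bins)) out[[paste0("sfs", b, "_", pops[p])]] <- sfs[b]
  }
  if (P > 1L) {
    for (a in seq_len(P - 1L)) for (b in seq(a + 1L, P)) {
      ok <- !is.na(fhat[, a]) & !is.na(fhat[, b])
      fa <- fhat[ok, a]; fb <- fhat[ok, b]
      pib <- sum(fa * (1 - fb) + fb * (1 - fa))
      fst <- if (pib > 0) max(-1, min(1, 1 - mean(c(pihat[a], pihat[b])) / pib)) else NA_real_
      out[[paste0("fst_", pops[a], "_", pops[b])]] <- fst
      out[[paste0("dxy_", pops[a], "_", pops[b])]] <- pib / x$L
    }
  }
  anypoly <- rowSums(poly) > 0
  out[["S_tot"]] <- as.numeric(sum(anypoly))
  fbar_n <- rowSums(x$derived); fbar_d <- rowSums(x$depth)
  okt <- fbar_d > 0
  ft <- fbar_n[okt & anypoly] / fbar_d[okt & anypoly]
  ntot <- sum(nhap)
  out[["pi_tot"]] <- sum(2 * ft * (1 - ft)) * ntot / (ntot - 1)
  as_tibble(lapply(out, function(v) as.numeric(unname(v))))
}
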