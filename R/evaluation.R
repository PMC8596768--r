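#' ROC curve for discriminating selected from neutral loci
#'
#' Loci are scored by `1 - p` (low HPD p-values mark outliers). Thresholds
#' sweep all distinct scores plus the endpoints, giving a monotone
#' non-decreasing staircase from (0, 0) to (1, 1).
#'
#' @param score Numeric scores in `[0, 1]` (higher = more outlier-like).
#' @param label Character/factor vector: `"selected"` (positive class) or
#'   `"neutral"`.
#' @return Tibble of class `lsd_roc` with columns `threshold`, `fpr`,
#'   `tpr`, ordered by increasing `fpr`.
#' @export
roc_curve <- function(score, label) {
  label <- as.character(label)
  if (length(unique(label)) < 2L) stop("both classes must be present", call. = FALSE)
  sel <- label == "selected"
  th <- sort(unique(score), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(score[sel] >= t), numeric(1))
  fpr <- vapply(th, function(t) mean(score[!sel] >= t), numeric(1))
  out <- tibble(threshold = c(Inf, th), fpr = c(0, fpr), tpr = c(0, tpr))
  if (utils::tail(out$fpr, 1) < 1 || utils::tail(out$tpr, 1) < 1) {
    out <- dplyr::bind_rows(out, tibble(threshold = -Inf, fpr = 1, tpr = 1))
  }
  class(out) <- c("lsd_roc", class(out))
  out
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' `AUC = U / (n_s * n_n)` with midrank tie handling: the probability that
#' a random selected locus outscores a random neutral locus (ties counted
#' half). Equals the trapezoidal area under [roc_curve()]. 0.5 reflects
#' random assignment; 1 reflects perfect classification.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(score, label) {
  label <- as.character(label)
  sel <- label == "selected"
  ns <- sum(sel); nn <- sum(!sel)
  if (ns == 0L || nn == 0L) stop("both classes must be present", call. = FALSE)
  r <- rank(score) # midranks
  (sum(r[sel]) - ns * (ns + 1) / 2) / (ns * nn)
}

#' Trapezoidal area under an ROC staircase
#' @param roc An `lsd_roc` tibble.
#' @return Numeric area.
#' @export
roc_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

#' Scan-level labeled scores
#'
#' @param scan An `lsd_scan`.
#' @param labels Tibble with `locus_id` and `label` columns (e.g. a
#'   pseudogenome manifest).
#' @return Tibble with `locus_id`, `score` (`1 - p`), `label`.
#' @export
scan_scores <- function(scan, labels) {
  dplyr::inner_join(
    dplyr::transmute(scan$records, locus_id = .data$locus_id,
                     score = 1 - .data$p),
    dplyr::select(labels, "locus_id", "label"),
    by = "locus_id"
  )
}

#' Neutral-set mis-specification experiment
#'
#' Re-runs the scan with a neutral subset contaminated by truly selected
#' loci: `floor(f * n)` of the `n` designated neutral slots are replaced by
#' selected loci drawn without replacement, the neutral estimate is
#' re-derived, and the AUC against the true labels is returned. Because the
#' per-locus posteriors do not depend on the neutral subset, the stored
#' posteriors are reused exactly.
#'
#' @param scan An `lsd_scan` of a labeled pseudogenome (posteriors kept).
#' @param labels Manifest tibble with `locus_id`, `label`.
#' @param f Contamination fraction in `[0, 0.5]`.
#' @param seed Optional integer seed for the contamination draw.
#' @return List: `auc`, the contaminated `neutral_ids`, and the rescanned
#'   `lsd_scan`.
#' @export
misspecification_experiment <- function(scan, labels, f, seed = NULL) {
  stopifnot(f >= 0, f <= 0.5)
  neutral_ids <- labels$locus_id[labels$label == "neutral"]
  selected_ids <- labels$locus_id[labels$label == "selected"]
  n <- length(neutral_ids)
  k <- floor(f * n)
  if (k > length(selected_ids)) {
    stop("insufficient selected loci to contaminate at f = ", f, call. = FALSE)
  }
  draw <- function() {
    sub_out <- if (k > 0) sample(neutral_ids, k) else character(0)
    sub_in <- if (k > 0) sample(selected_ids, k) else character(0)
    c(setdiff(neutral_ids, sub_out), sub_in)
  }
  contaminated <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  s2 <- rescan(scan, contaminated)
  sc <- scan_scores(s2, labels)
  list(auc = auc(sc$score, sc$label), neutral_ids = contaminated, scan = s2)
}

#' Power evaluation over a grid of selection regimes
#'
#' For each regime (neutral migration rate `M`, selection coefficients
#' `s1`, `s2`, onset `T_S`), simulates a labeled pseudogenome under the
#' (rescaled) model, runs the scan against the shared reference table, and
#' reports the AUC and the aggregate asymmetry score over the selected
#' loci. Regimes where the derived allele is always lost are reported as
#' loss regimes, never silently skipped.
#'
#' @param model Unrescaled `lsd_model` (sizes literal).
#' @param regimes Tibble with columns `M`, `s1`, `s2`, `T_S` (and
#'   optionally `origin`, `f1`, `f2`).
#' @param table Reference table (`lsd_reftable`) shared across regimes.
#' @param transform Matching `lsd_transform`.
#' @param n_n,n_s Neutral/selected locus counts per pseudogenome.
#' @param L Locus length (bp).
#' @param sample_config Named haploid counts per deme.
#' @param lambda Rescaling factor (default via [default_lambda()]).
#' @param seed Optional integer seed.
#' @param resample_cap Survival-conditioning attempts per selected locus
#'   before a regime is declared a loss regime; the default marks regimes
#'   whose conditional survival probability is below roughly 1/2000 as
#'   loss regimes (the desk-scale analogue of "the derived allele is always
#'   lost").
#' @param ... Passed to [run_scan()].
#' @return Tibble: one row per regime with `auc`, aggregate `a`,
#'   `sigma_bar`, `loss` flag.
#' @export
regime_grid <- function(model, regimes, table, transform, n_n = 200, n_s = 50,
                        L = 5000, sample_config, lambda = NULL, seed = NULL,
                        resample_cap = 2000, ...) {
  stopifnot(nrow(regimes) >= 1L)
  run <- function() {
    rows <- vector("list", nrow(regimes))
    for (i in seq_len(nrow(regimes))) {
      rg <- regimes[i, ]
      params <- list(M12 = rg$M, M21 = rg$M)
      lam <- lambda %||% default_lambda(model, params)
      regime <- selection_regime(
        s1 = rg$s1, s2 = rg$s2, T_S = rg$T_S,
        f1 = if ("f1" %in% names(rg)) rg$f1 else 0.1,
        f2 = if ("f2" %in% names(rg)) rg$f2 else 0.1,
        origin = if ("origin" %in% names(rg)) rg$origin else "standing"
      )
      rs <- rescale_model(model, regime, lam, params)
      res <- tryCatch({
        pg <- build_pseudogenome(rs$model, params, rs$regime, n_n, n_s, L,
                                 sample_config, resample_cap = resample_cap)
        st <- locus_stats(pg$loci)
        sc <- run_scan(st, table, transform,
                       neutral = pg$manifest$locus_id[pg$manifest$label == "neutral"],
                       keep_posteriors = FALSE, ...)
        scores <- scan_scores(sc, pg$manifest)
        sel <- sc$records$locus_id %in%
          pg$manifest$locus_id[pg$manifest$label == "selected"]
        sig <- sc$records$sigma[sel]
        tibble(M = rg$M, s1 = rg$s1, s2 = rg$s2, T_S = rg$T_S,
               auc = auc(scores$score, scores$label),
               sigma_bar = mean(sig),
               a = asymmetry_score(sig, mode = "aggregate"),
               loss = FALSE)
      }, lsd_loss_regime = function(e) {
        tibble(M = rg$M, s1 = rg$s1, s2 = rg$s2, T_S = rg$T_S,
               auc = NA_real_, sigma_bar = NA_real_, a = NA_real_,
               loss = TRUE)
      })
      rows[[i]] <- res
    }
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
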