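#' Tidy an ABC-GLM fit
#'
#' One row per (statistic, parameter) coefficient of the linear-Gaussian
#' likelihood model `s = c0 + B theta + eps`.
#'
#' @param x An `lsd_glm`.
#' @param ... Ignored.
#' @return Tibble with `statistic`, `term`, `estimate`.
#' @export
tidy.lsd_glm <- function(x, ...) {
  k <- length(x$c0)
  stat <- rownames(x$B) %||% paste0("comp", seq_len(k))
  out <- tibble(
    statistic = rep(stat, times = ncol(x$B) + 1L),
    term = rep(c("(Intercept)", x$param_names %||%
                   paste0("theta", seq_len(ncol(x$B)))), each = k),
    estimate = c(x$c0, as.vector(x$B))
  )
  out
}

#' @export
glance.lsd_glm <- function(x, ...) {
  tibble(n_retained = x$n, k = length(x$c0),
         sigma_trace = sum(diag(x$Sigma)))
}

#' @export
glance.lsd_reftable <- function(x, ...) {
  pr <- attr(x, "priors")
  tibble(n_sims = nrow(x),
         n_stats = length(attr(x, "stat_names")),
         focal = paste(attr(x, "focal"), collapse = ","),
         L = attr(x, "L"),
         priors = paste(vapply(pr, function(p) {
           paste0(p$name, "~", p$scale, "U[", p$lower, ",", p$upper, "]")
         }, character(1)), collapse = "; "))
}

#' Tidy a posterior grid into long format
#'
#' @param x An `lsd_posterior`.
#' @param ... Ignored.
#' @return Tibble with the two axis values and the cell mass.
#' @export
tidy.lsd_posterior <- function(x, ...) {
  g <- x$grid
  out <- tidyr::expand_grid(a2 = g$axis2, a1 = g$axis1)
  out <- dplyr::arrange(out, .data$a2, .data$a1)
  out$mass <- as.vector(x$mass)
  names(out)[1:2] <- paste0("log10_", rev(g$names))
  out[, c(2, 1, 3)]
}
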