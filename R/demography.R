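#' Define a deme
#'
#' A deme is a randomly mating population of constant or exponentially
#' changing diploid effective size. Sizes may be given as literal values or
#' as names of free parameters resolved at simulation time.
#'
#' @param id Unique deme label (character scalar).
#' @param initial_size Diploid effective size at the present (t = 0), or a
#'   parameter name.
#' @param growth_rate Exponential growth rate per generation (forward in
#'   time); 0 keeps the size constant. Backward in time the size at `t`
#'   generations before present is `initial_size * exp(-growth_rate * t)`.
#' @return An object of class `lsd_deme`.
#' @export
deme <- function(id, initial_size, growth_rate = 0) {
  stopifnot(is.character(id), length(id) == 1L)
  if (is.numeric(initial_size) && initial_size <= 0) {
    stop("deme `initial_size` must be positive", call. = FALSE)
  }
  structure(
    list(id = id, initial_size = initial_size, growth_rate = growth_rate),
    class = "lsd_deme"
  )
}

#' Define a demographic event
#'
#' Events modify the model backward in time. An event at time `t` applies to
#' all times `>= t` (half-open convention `[t, next event)`).
#'
#' @param time Generations before present (`>= 0`).
#' @param kind One of `"size_change"`, `"growth_change"`,
#'   `"migration_change"`, `"join"`.
#' @param ... Kind-specific payload: `size_change` takes `deme`, `size`;
#'   `growth_change` takes `deme`, `rate`; `migration_change` takes `from`,
#'   `to`, `rate` (migrants per generation, backward convention); `join`
#'   takes `from`, `to` and merges deme `from` into `to` (backward merge,
#'   i.e. a forward-in-time population split).
#' @return An object of class `lsd_event`.
#' @export
dem_event <- function(time, kind = c("size_change", "growth_change",
                                     "migration_change", "join"), ...) {
  kind <- match.arg(kind)
  if (!is.numeric(time) || time < 0) stop("event `time` must be >= 0", call. = FALSE)
  payload <- list(...)
  needed <- switch(kind,
    size_change = c("deme", "size"),
    growth_change = c("deme", "rate"),
    migration_change = c("from", "to", "rate"),
    join = c("from", "to")
  )
  missing <- setdiff(needed, names(payload))
  if (length(missing)) {
    stop("event `", kind, "` needs fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  structure(c(list(time = time, kind = kind), payload), class = "lsd_event")
}

#' Define a discrete-deme demographic model
#'
#' Represents a coalescent demographic model with time-varying sizes,
#' migration and divergence events. Migration uses the backward (ms-style)
#' convention: entry `M[i, j]` is the expected number of lineages currently
#' in deme `i` per generation whose parent lineage is in deme `j`, i.e.
#' `M[i, j] = N_i * m_ij` where `m_ij` is the per-lineage backward migration
#' rate. This is the `M = N m` scaling customary for island models; note
#' that the forward-in-time interpretation (individuals moving `j -> i`)
#' coincides to first order for conservative migration.
#'
#' Any size, rate or migration entry may be a parameter name (character);
#' such names are resolved against a parameter set at simulation time and
#' must be listed in `free_parameters` (names referenced anywhere are added
#' automatically).
#'
#' @param demes List of [deme()] objects with unique ids.
#' @param migration `D x D` matrix of migration rates in migrants per
#'   generation (numeric, or character parameter names). The diagonal is
#'   ignored.
#' @param events List of [dem_event()] objects.
#' @param mutation_rate Mutation rate per bp per generation (or parameter
#'   name).
#' @param free_parameters Character vector of free parameter names; inferred
#'   from character entries when omitted.
#' @return An object of class `lsd_model`.
#' @export
demographic_model <- function(demes, migration = NULL, events = list(),
                              mutation_rate = 5e-7, free_parameters = NULL) {
  stopifnot(is.list(demes), length(demes) >= 1L)
  ids <- vapply(demes, function(d) d$id, character(1))
  if (anyDuplicated(ids)) stop("deme ids must be unique", call. = FALSE)
  D <- length(demes)
  if (is.null(migration)) migration <- matrix(0, D, D)
  migration <- as.matrix(migration)
  if (!all(dim(migration) == c(D, D))) {
    stop("`migration` must be a ", D, " x ", D, " matrix", call. = FALSE)
  }
  dimnames(migration) <- list(ids, ids)

  referenced <- character(0)
  grab <- function(x) {
    if (is.character(x) && suppressWarnings(is.na(as.numeric(x)))) x else character(0)
  }
  for (d in demes) {
    referenced <- c(referenced, grab(d$initial_size), grab(d$growth_rate))
  }
  referenced <- c(referenced, unlist(lapply(as.vector(migration), grab)))
  for (ev in events) {
    for (fld in intersect(names(ev), c("size", "rate"))) {
      referenced <- c(referenced, grab(ev[[fld]]))
    }
  }
  referenced <- c(referenced, grab(mutation_rate))
  free_parameters <- union(free_parameters %||% character(0), unique(referenced))

  structure(
    list(demes = demes, deme_ids = ids, migration = migration,
         events = events[order(vapply(events, function(e) e$time, numeric(1)))],
         mutation_rate = mutation_rate, free_parameters = free_parameters),
    class = "lsd_model"
  )
}

#' @export
print.lsd_model <- function(x, ...) {
  cat("<lsd_model> ", length(x$demes), " deme(s): ",
      paste(x$deme_ids, collapse = ", "), "\n", sep = "")
  cat("  events: ", length(x$events),
      "; free parameters: ",
      if (length(x$free_parameters)) paste(x$free_parameters, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Two-deme isolation-with-migration model
#'
#' Convenience constructor for the canonical two-deme IM model with
#' reciprocal migration rates `M12` and `M21` (migrants per generation) left
#' as free parameters.
#'
#' @param N1,N2 Diploid effective sizes of demes "1" and "2".
#' @param mutation_rate Mutation rate per bp per generation.
#' @return An `lsd_model` with free parameters `M12` and `M21`.
#' @export
im_model <- function(N1 = 10000, N2 = 10000, mutation_rate = 5e-7) {
  demographic_model(
    demes = list(deme("1", N1), deme("2", N2)),
    migration = matrix(c(0, "M12", "M21", 0), 2, 2, byrow = TRUE),
    mutation_rate = mutation_rate
  )
}

#' Define a parameter prior
#'
#' @param name Parameter name.
#' @param scale `"log10"` (uniform on the log10 scale, values returned on
#'   the natural scale) or `"linear"`.
#' @param lower,upper Bounds on the stated scale (`lower < upper`).
#' @return An object of class `lsd_prior`.
#' @export
parameter_prior <- function(name, scale = c("log10", "linear"), lower, upper) {
  scale <- match.arg(scale)
  if (!is.numeric(lower) || !is.numeric(upper) || lower >= upper) {
    stop("prior bounds must satisfy lower < upper", call. = FALSE)
  }
  structure(list(name = name, scale = scale, lower = lower, upper = upper),
            class = "lsd_prior")
}

#' Sample parameter sets from priors
#'
#' Each draw is uniform on the prior's stated scale; log10-scale priors
#' return `10^u` on the natural scale.
#'
#' @param priors List of [parameter_prior()] objects.
#' @param n Number of parameter sets to draw.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble with `n` rows and one column per parameter (natural
#'   scale).
#' @export
sample_parameters <- function(priors, n = 1, seed = NULL) {
  stopifnot(length(priors) >= 1L)
  draw <- function() {
    vals <- lapply(priors, function(pr) {
      u <- runif(n, pr$lower, pr$upper)
      switch(pr$scale, log10 = 10^u, linear = u,
             stop("unknown prior scale: ", pr$scale, call. = FALSE))
    })
    names(vals) <- vapply(priors, function(pr) pr$name, character(1))
    as_tibble(vals)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# resolve a literal-or-parameter-name value against a parameter set
resolve_value <- function(x, params) {
  if (is.numeric(x)) return(x)
  num <- suppressWarnings(as.numeric(x))
  if (!is.na(num)) return(num)
  if (!is.null(params) && x %in% names(params)) return(as.numeric(params[[x]]))
  stop("unresolved parameter: `", x, "`", call. = FALSE)
}

as_params <- function(params) {
  if (is.data.frame(params)) {
    stopifnot(nrow(params) == 1L)
    params <- as.list(params)
  }
  params
}

#' Validate a demographic model
#'
#' Checks that all parameter references resolve (when `params` is given)
#' and that the backward process guarantees a common ancestor: a single
#' deme, or a migration graph connecting all demes (entries that are free
#' parameters are treated as potentially positive), or join events merging
#' all demes into one.
#'
#' @param model An `lsd_model`.
#' @param params Optional named parameter set (or one-row tibble) used to
#'   resolve free parameters; without it, free entries are assumed
#'   potentially positive.
#' @return Character vector of diagnostics; empty if the model is valid.
#' @export
validate_model <- function(model, params = NULL) {
  params <- as_params(params)
  diags <- character(0)
  D <- length(model$demes)

  if (!is.null(params)) {
    for (nm in model$free_parameters) {
      if (!nm %in% names(params)) {
        diags <- c(diags, paste0("free parameter `", nm, "` missing from parameter set"))
      }
    }
    if (length(diags)) return(diags)
    for (d in model$demes) {
      sz <- resolve_value(d$initial_size, params)
      if (!is.finite(sz) || sz <= 0) {
        diags <- c(diags, paste0("deme `", d$id, "` has non-positive size"))
      }
    }
    mu <- resolve_value(model$mutation_rate, params)
    if (!is.finite(mu) || mu < 0) diags <- c(diags, "negative mutation rate")
  }

  # connectivity: union demes via joins and (potentially) positive migration
  if (D > 1L) {
    pos <- matrix(FALSE, D, D)
    entry_positive <- function(x) {
      if (is.null(params)) {
        is.character(x) || (is.numeric(x) && x > 0) ||
          (!is.na(suppressWarnings(as.numeric(x))) && as.numeric(x) > 0)
      } else {
        resolve_value(x, params) > 0
      }
    }
    for (i in seq_len(D)) {
      for (j in seq_len(D)) {
        if (i != j && entry_positive(model$migration[i, j])) pos[i, j] <- TRUE
      }
    }
    for (ev in model$events) {
      if (ev$kind == "migration_change" && entry_positive(ev$rate)) {
        i <- match(ev$from, model$deme_ids)
        j <- match(ev$to, model$deme_ids)
        pos[i, j] <- TRUE
      }
    }
    parent <- seq_len(D)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    link <- function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <<- ri
      invisible(NULL)
    }
    for (i in seq_len(D)) for (j in seq_len(D)) {
      if (pos[i, j] || pos[j, i]) link(i, j)
    }
    for (ev in model$events) {
      if (ev$kind == "join") {
        link(match(ev$from, model$deme_ids), match(ev$to, model$deme_ids))
      }
    }
    roots <- unique(vapply(seq_len(D), find, integer(1)))
    if (length(roots) > 1L) {
      diags <- c(diags, "no common ancestor reachable: demes are not connected by migration or join events")
    }
  }
  diags
}

# Flatten model + params into epochs for the C++ engine.
# Returns list(epochs = <list for C++>, n_demes, deme_ids, mu)
resolve_epochs <- function(model, params = NULL) {
  params <- as_params(params)
  D <- length(model$demes)
  ids <- model$deme_ids

  N <- vapply(model$demes, function(d) resolve_value(d$initial_size, params), numeric(1))
  g <- vapply(model$demes, function(d) resolve_value(d$growth_rate, params), numeric(1))
  M <- matrix(0, D, D)
  for (i in seq_len(D)) for (j in seq_len(D)) {
    if (i != j) M[i, j] <- resolve_value(model$migration[i, j], params)
  }
  if (any(M < 0)) stop("negative migration rate", call. = FALSE)

  ev_times <- vapply(model$events, function(e) e$time, numeric(1))
  breaks <- sort(unique(c(0, ev_times)))
  epochs <- vector("list", length(breaks))
  t_prev <- 0
  alive <- rep(TRUE, D)

  for (b in seq_along(breaks)) {
    tb <- breaks[b]
    # sizes decay within the preceding epoch
    if (b > 1L) N <- N * exp(-g * (tb - t_prev))
    join_from <- integer(0); join_to <- integer(0)
    if (tb > 0 || b == 1L) {
      for (ev in model$events) {
        if (ev$time != tb) next
        if (ev$kind == "size_change") {
          i <- match(ev$deme, ids)
          N[i] <- resolve_value(ev$size, params)
        } else if (ev$kind == "growth_change") {
          i <- match(ev$deme, ids)
          g[i] <- resolve_value(ev$rate, params)
        } else if (ev$kind == "migration_change") {
          i <- match(ev$from, ids); j <- match(ev$to, ids)
          M[i, j] <- resolve_value(ev$rate, params)
        } else if (ev$kind == "join") {
          i <- match(ev$from, ids); j <- match(ev$to, ids)
          join_from <- c(join_from, i - 1L); join_to <- c(join_to, j - 1L)
          alive[i] <- FALSE
          M[i, ] <- 0; M[, i] <- 0
          g[i] <- 0
        }
      }
    }
    if (any(!is.finite(N)) || any(N <= 0)) {
      stop("negative or zero resolved population size at time ", tb, call. = FALSE)
    }
    epochs[[b]] <- list(start = tb, N0 = N, growth = g, M = M,
                        join_from = as.integer(join_from),
                        join_to = as.integer(join_to))
    t_prev <- tb
  }
  list(epochs = epochs, n_demes = D, deme_ids = ids,
       mu = resolve_value(model$mutation_rate, params))
}

#' Resolve instantaneous demographic rates at a time point
#'
#' Applies all events with time `<= t` (events are half-open backward:
#' an event at time `t0` applies to all `t >= t0`) and resolves exponential
#' growth, returning per-deme sizes and migration rates at `t`.
#'
#' @param model An `lsd_model`.
#' @param params Named parameter set (or one-row tibble).
#' @param t Time in generations before present.
#' @return A list with elements `size` (named diploid sizes `N_i(t)`), `M`
#'   (migrants per generation `M_ij`), `m` (per-lineage backward rates
#'   `m_ij = M_ij / N_i(t)`), and `alive` (logical; demes not yet merged).
#' @export
resolve_at_time <- function(model, params = NULL, t = 0) {
  stopifnot(t >= 0)
  re <- resolve_epochs(model, params)
  starts <- vapply(re$epochs, function(e) e$start, numeric(1))
  b <- findInterval(t, starts)
  ep <- re$epochs[[b]]
  N <- ep$N0 * exp(-ep$growth * (t - ep$start))
  if (any(N <= 0)) stop("negative resolved size", call. = FALSE)
  alive <- rep(TRUE, re$n_demes)
  for (bb in seq_len(b)) alive[re$epochs[[bb]]$join_from + 1L] <- FALSE
  m <- ep$M / N # row i divided by N_i
  dimnames(ep$M) <- dimnames(m) <- list(re$deme_ids, re$deme_ids)
  list(size = setNames(N, re$deme_ids), growth = setNames(ep$growth, re$deme_ids),
       M = ep$M, m = m, alive = setNames(alive, re$deme_ids))
}
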