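#' Write loci in Hudson ms format
#'
#' One `//` block per locus with `segsites:` and `positions:` lines
#' (positions to 6 decimals) followed by one 0/1 row per haplotype.
#' Population membership goes to a sidecar TSV via [write_pop_map()].
#'
#' @param loci List of `lsd_locus` objects (or an `lsd_pseudogenome`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_ms <- function(loci, path) {
  if (inherits(loci, "lsd_pseudogenome")) loci <- loci$loci
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("ms-format multi-locus output", con)
  writeLines("", con)
  for (l in loci) {
    writeLines("//", con)
    S <- ncol(l$haplotypes)
    writeLines(paste0("segsites: ", S), con)
    if (S > 0) {
      writeLines(paste0("positions: ",
                        paste(sprintf("%.6f", l$positions), collapse = " ")), con)
      apply(l$haplotypes, 1, function(r) writeLines(paste(r, collapse = ""), con))
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Read loci from Hudson ms format
#'
#' @param path ms-format file (`//`, `segsites:`, `positions:`, 0/1 rows).
#' @param pop_labels Character vector of deme ids per haplotype (e.g. from
#'   [read_pop_map()]); recycled across loci.
#' @param L Locus length in bp to attach to each locus.
#' @return List of `lsd_locus` objects.
#' @export
read_ms <- function(path, pop_labels, L) {
  lines <- readLines(path)
  loci <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "//")) { i <- i + 1L; next }
    i <- i + 1L
    if (i > length(lines) || !startsWith(lines[i], "segsites:")) {
      stop("malformed ms block at line ", i, ": expected `segsites:`", call. = FALSE)
    }
    S <- suppressWarnings(as.integer(sub("segsites:\\s*", "", lines[i])))
    if (is.na(S)) stop("malformed segsites count at line ", i, call. = FALSE)
    i <- i + 1L
    if (S == 0L) {
      loci[[length(loci) + 1L]] <- locus_data(
        matrix(0L, length(pop_labels), 0L), numeric(0), L, pop_labels,
        locus_id = sprintf("locus_%04d", length(loci) + 1L),
        drop_monomorphic = FALSE)
      next
    }
    if (i > length(lines) || !startsWith(lines[i], "positions:")) {
      stop("malformed ms block at line ", i, ": expected `positions:`", call. = FALSE)
    }
    pos <- as.numeric(strsplit(trimws(sub("positions:\\s*", "", lines[i])),
                               "\\s+")[[1]])
    if (length(pos) != S || anyNA(pos)) {
      stop("malformed positions at line ", i, call. = FALSE)
    }
    i <- i + 1L
    rows <- list()
    while (i <= length(lines) && grepl("^[01]+$", lines[i])) {
      r <- as.integer(strsplit(lines[i], "")[[1]])
      if (length(r) != S) {
        stop("haplotype width mismatch at line ", i, ": expected ", S,
             " sites, found ", length(r), call. = FALSE)
      }
      rows[[length(rows) + 1L]] <- r
      i <- i + 1L
    }
    if (!length(rows)) stop("ms block with no haplotype rows at line ", i, call. = FALSE)
    H <- do.call(rbind, rows)
    if (nrow(H) != length(pop_labels)) {
      stop("haplotype count (", nrow(H), ") does not match population map (",
           length(pop_labels), ")", call. = FALSE)
    }
    loci[[length(loci) + 1L]] <- locus_data(
      H, pos, L, pop_labels,
      locus_id = sprintf("locus_%04d", length(loci) + 1L),
      drop_monomorphic = FALSE)
  }
  loci
}

#' Write / read a sample-to-deme population map (sidecar TSV)
#'
#' @param pop_labels Character vector of deme ids, in haplotype order.
#' @param path TSV path with columns `sample_id`, `deme`.
#' @return `write_pop_map()`: the path; `read_pop_map()`: character vector
#'   of deme ids in sample order.
#' @export
write_pop_map <- function(pop_labels, path) {
  utils::write.table(
    data.frame(sample_id = sprintf("hap_%04d", seq_along(pop_labels)),
               deme = pop_labels),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pop_map
#' @export
read_pop_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  df$deme
}

#' Read a model + priors configuration (YAML)
#'
#' The configuration declares demes, migration entries (literals or bare
#' parameter names), events, the mutation rate and parameter priors. See
#' `inst/extdata/model_m1.yaml` for the layout.
#'
#' @param path YAML file.
#' @return List with `model` (an `lsd_model`) and `priors` (list of
#'   [parameter_prior()]).
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  demes <- lapply(cfg$demes, function(d) {
    deme(as.character(d$id), d$size, d$growth %||% 0)
  })
  ids <- vapply(demes, function(d) d$id, character(1))
  D <- length(demes)
  M <- matrix(0, D, D, dimnames = list(ids, ids))
  if (!is.null(cfg$migration)) {
    M <- matrix("0", D, D, dimnames = list(ids, ids))
    for (e in cfg$migration) {
      M[as.character(e$from), as.character(e$to)] <- as.character(e$rate)
    }
  }
  events <- lapply(cfg$events %||% list(), function(e) {
    do.call(dem_event, c(list(time = e$time, kind = e$kind),
                         e[setdiff(names(e), c("time", "kind"))]))
  })
  model <- demographic_model(demes, M, events,
                             mutation_rate = cfg$mutation_rate %||% 5e-7)
  priors <- lapply(cfg$priors %||% list(), function(p) {
    parameter_prior(p$name, p$scale %||% "log10", p$lower, p$upper)
  })
  list(model = model, priors = priors)
}

#' Write scan records as a results TSV
#'
#' Tab-separated with `#`-prefixed header metadata lines (neutral estimate,
#' retained count), Manhattan-plot ready.
#'
#' @param scan An `lsd_scan`.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_scan_tsv <- function(scan, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- scan$neutral_estimate$value
  writeLines(c(
    paste0("# lsdscan results"),
    paste0("# neutral_estimate: log10_", names(v)[1], "=", v[1],
           " log10_", names(v)[2], "=", v[2]),
    paste0("# n_ret: ", scan$n_ret)
  ), con)
  utils::write.table(scan$records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a reference table TSV with a `#` header block
#'
#' @param table An `lsd_reftable`.
#' @param path TSV path.
#' @return `write_reftable()`: the path; `read_reftable()`: the table with
#'   priors and focal attributes restored.
#' @export
write_reftable <- function(table, path) {
  con <- file(path, "w")
  on.exit(close(con))
  priors <- attr(table, "priors")
  hdr <- vapply(priors, function(p) {
    paste0("# prior: ", p$name, " ", p$scale, " ", p$lower, " ", p$upper)
  }, character(1))
  writeLines(c("# lsdscan reference table",
               paste0("# focal: ", paste(attr(table, "focal"), collapse = " ")),
               paste0("# L: ", attr(table, "L")),
               hdr), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_reftable
#' @export
read_reftable <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  focal <- strsplit(sub("# focal: ", "", hdr[startsWith(hdr, "# focal:")]), " ")[[1]]
  L <- as.numeric(sub("# L: ", "", hdr[startsWith(hdr, "# L:")]))
  priors <- lapply(hdr[startsWith(hdr, "# prior:")], function(h) {
    f <- strsplit(sub("# prior: ", "", h), " ")[[1]]
    parameter_prior(f[1], f[2], as.numeric(f[3]), as.numeric(f[4]))
  })
  tab <- as_tibble(utils::read.table(text = lines[!startsWith(lines, "#")],
                                     header = TRUE, sep = "\t"))
  structure(tab, class = c("lsd_reftable", class(tab)),
            priors = priors, focal = focal, L = L,
            stat_names = setdiff(colnames(tab), paste0("log10_", focal)))
}
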