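#' Pipeline orchestration
#'
#' Batch drivers behind the command-line subcommands: each takes plain
#' inputs (manifest tables, structure files), runs one analysis stage over
#' every row, and returns a tidy data.frame. When an output directory is
#' given, results are written as TSV together with a key=value run log
#' carrying the configuration hash and seeds, so identical configurations
#' give bit-identical outputs on deterministic paths.
#'
#' @name cli_pipeline
NULL

# Tiny polynomial hash of a deparse()d object (31-bit, exact in doubles);
# enough to fingerprint a config in the run log.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) {
    h <- (h * 131 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

write_run_log <- function(out_dir, stage, config) {
  path <- file.path(out_dir, paste0(stage, ".log"))
  keys <- vapply(names(config), function(nm) {
    sprintf("%s=%s", nm, paste(format(config[[nm]]), collapse = ","))
  }, character(1))
  writeLines(c(sprintf("stage=%s", stage),
               sprintf("config_hash=%s", config_hash(config)),
               keys), path)
  invisible(path)
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) {
      acd_error(sprintf("manifest not found: %s", manifest),
                "format_error")
    }
    manifest <- utils::read.table(manifest, header = TRUE, sep = "\t",
                                  stringsAsFactors = FALSE)
  }
  need <- c("construct_id", "condition", "replicate", "role", "path")
  if (!all(need %in% names(manifest))) {
    acd_error(paste("manifest needs columns:",
                    paste(need, collapse = ", ")), "format_error")
  }
  manifest
}

#' Run the Ratio A analysis over a manifest
#'
#' The manifest (data.frame or TSV path) maps each spectrum file to a
#' `construct_id`, `condition`, `replicate` and `role`. Roles `f280`,
#' `f370`, `f280_notag` define one sample; roles `free_acd_280` /
#' `free_acd_370` define the free-acceptor reference, from which a single
#' Ratio A0 (mean over its replicates) is applied to all samples.
#'
#' @param manifest Manifest data.frame or path to a TSV.
#' @param window Ratio A averaging window (default 410-480 nm).
#' @param donor_window Donor scaling window (default 300-360 nm).
#' @param rule Donor scaling rule, `"integral"` or `"peak"`.
#' @param out_dir Optional directory for `spectral_fret.tsv` plus run log.
#' @return data.frame: construct_id, condition, replicate, ratio_a,
#'   ratio_a0, relative_fret, flatness.
#' @export
run_spectral_fret <- function(manifest, window = default_acceptor_window,
                              donor_window = default_donor_window,
                              rule = "integral", out_dir = NULL) {
  manifest <- read_manifest(manifest)
  free <- manifest[startsWith(manifest$role, "free_acd"), , drop = FALSE]
  samp <- manifest[!startsWith(manifest$role, "free_acd"), , drop = FALSE]

  a0 <- NA_real_
  if (nrow(free)) {
    reps <- unique(free$replicate)
    vals <- vapply(reps, function(r) {
      p280 <- free$path[free$replicate == r & free$role == "free_acd_280"]
      p370 <- free$path[free$replicate == r & free$role == "free_acd_370"]
      if (length(p280) != 1L || length(p370) != 1L) {
        acd_error(sprintf("free_acd replicate %s needs one 280 and one 370 spectrum", r),
                  "format_error")
      }
      ratio_a0(read_spectrum(p280, "emission", excitation_nm = 280),
               read_spectrum(p370, "emission", excitation_nm = 370),
               window = window)
    }, numeric(1))
    a0 <- mean(vals)
  }

  key <- unique(samp[, c("construct_id", "condition", "replicate")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    k <- key[i, ]
    check_condition(k$condition)
    sub <- samp[samp$construct_id == k$construct_id &
                samp$condition == k$condition &
                samp$replicate == k$replicate, ]
    pick <- function(role) {
      p <- sub$path[sub$role == role]
      if (length(p) != 1L) {
        acd_error(sprintf("%s/%s/rep %s: need exactly one '%s' spectrum",
                          k$construct_id, k$condition, k$replicate, role),
                  "format_error")
      }
      p
    }
    res <- spectral_fret_analysis(
      read_spectrum(pick("f280"), "emission", excitation_nm = 280),
      read_spectrum(pick("f370"), "emission", excitation_nm = 370),
      read_spectrum(pick("f280_notag"), "emission", excitation_nm = 280),
      ratio_a0 = a0, donor_window = donor_window, window = window,
      rule = rule)
    data.frame(construct_id = k$construct_id, condition = k$condition,
               replicate = k$replicate, ratio_a = res$ratio_a,
               ratio_a0 = a0, relative_fret = res$relative_fret,
               flatness = res$flatness, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(out_dir, "spectral_fret.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_run_log(out_dir, "spectral_fret",
                  list(window = window, donor_window = donor_window,
                       rule = rule))
  }
  out
}

#' Paired condition comparison over a results table
#'
#' Runs [compare_conditions()] per construct on the output of
#' [run_spectral_fret()], pairing replicates by number.
#'
#' @param results Output of [run_spectral_fret()].
#' @param reference,treated,reversal Condition labels; `reversal` optional.
#' @param p_adjust Method for [stats::p.adjust()] across constructs
#'   (default `"none"`, matching per-construct annotation).
#' @return data.frame: construct_id, n, mean_delta, p_value,
#'   p_adjusted, reversibility.
#' @export
run_condition_comparison <- function(results, reference = "apo",
                                     treated = "zinc", reversal = NULL,
                                     p_adjust = "none") {
  pick <- function(cid, cond) {
    sub <- results[results$construct_id == cid &
                   results$condition == cond, ]
    sub <- sub[order(sub$replicate), ]
    stats::setNames(sub$relative_fret, sub$replicate)
  }
  constructs <- unique(results$construct_id[
    results$condition == treated])
  rows <- lapply(constructs, function(cid) {
    a <- pick(cid, reference)
    b <- pick(cid, treated)
    common <- intersect(names(a), names(b))
    r <- NULL
    if (!is.null(reversal)) {
      r3 <- pick(cid, reversal)
      common <- intersect(common, names(r3))
      r <- r3[common]
    }
    cmp <- compare_conditions(a[common], b[common], reversal = r,
                              construct_id = cid)
    data.frame(construct_id = cid, n = length(cmp$deltas),
               mean_delta = cmp$mean_delta, p_value = cmp$p_value,
               reversibility = cmp$reversibility,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Predict FRET efficiencies for a list of acceptor sites
#'
#' @param structure A `structure_model` or path to a PDB/mmCIF file.
#' @param sites Integer vector of acceptor residue numbers.
#' @param mode `"all_donors"`, `"intrasubunit"`, or `"both"`.
#' @param seed Integer seed recorded in the output and used for any Monte
#'   Carlo path.
#' @param ... Passed to [construct_prediction()].
#' @param out_dir Optional directory for `predictions.tsv` plus run log.
#' @return data.frame: construct_id, site, mode, efficiency, n_donors,
#'   seed.
#' @export
run_predict <- function(structure, sites,
                        mode = c("all_donors", "intrasubunit", "both"),
                        seed = 1L, ..., out_dir = NULL) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("all_donors", "intrasubunit") else mode
  model <- if (inherits(structure, "structure_model")) structure
           else load_structure(structure)
  rows <- list()
  for (s in sites) {
    for (m in modes) {
      p <- construct_prediction(model, s, mode = m, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        construct_id = p$construct_id, site = s, mode = m,
        efficiency = p$efficiency, n_donors = nrow(p$per_donor),
        seed = seed, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(out_dir, "predictions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    write_run_log(out_dir, "predict",
                  list(sites = sites, mode = mode, seed = seed))
  }
  out
}

#' Compare measured relative FRET with predictions
#'
#' Joins a measured table (columns `construct_id`, `relative_fret`;
#' replicates are averaged) with a predicted table (columns
#' `construct_id`, `efficiency`) and fits the through-origin line.
#'
#' @param measured,predicted data.frames as above.
#' @return An `origin_fit` with the joined table in attribute `"data"`.
#' @export
run_compare <- function(measured, predicted) {
  m <- stats::aggregate(relative_fret ~ construct_id, data = measured,
                        FUN = mean)
  j <- merge(m, predicted[, c("construct_id", "efficiency")],
             by = "construct_id")
  if (nrow(j) < 3L) {
    acd_error("fewer than 3 constructs after joining", "statistics_error")
  }
  fit <- correlate_and_fit(j$relative_fret, j$efficiency)
  attr(fit, "data") <- j
  fit
}

#' Command-line entry point
#'
#' Dispatches `spectra`, `fret-ratio`, `zinc-compare`, `predict`,
#' `compare`, `lifetime`, `flux` and `simulate` subcommands. Arguments are
#' `--key value` pairs. Returns (invisibly) exit code 0 on success, 1 on
#' input errors, 2 on computation errors; wrap in [base::quit()] from a
#' script.
#'
#' @param args Character vector, default [base::commandArgs()] trailing
#'   arguments.
#' @return Integer exit code, invisibly.
#' @export
acd_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: acdfret <spectra|fret-ratio|zinc-compare|predict|compare|lifetime|flux|simulate> [--key value ...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  code <- tryCatch({
    switch(cmd,
      "spectra" = cli_spectra(opts),
      "fret-ratio" = cli_fret_ratio(opts),
      "zinc-compare" = cli_zinc_compare(opts),
      "predict" = cli_predict(opts),
      "compare" = cli_compare(opts),
      "lifetime" = cli_lifetime(opts),
      "flux" = cli_flux(opts),
      "simulate" = cli_simulate(opts),
      {
        message("unknown subcommand: ", cmd)
        1L
      })
  },
  acdfret_error = function(e) {
    message("error: ", conditionMessage(e))
    if (inherits(e, c("format_error", "annotation_error", "range_error",
                      "grid_error", "argument_error"))) 1L else 2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(as.integer(code))
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) {
      acd_error(sprintf("unexpected argument '%s'", args[i]),
                "argument_error")
    }
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

opt_or <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else opts[[key]]
}

req_opt <- function(opts, key) {
  if (is.null(opts[[key]])) {
    acd_error(sprintf("missing required option --%s", key),
              "argument_error")
  }
  opts[[key]]
}

emit_table <- function(tab, opts) {
  out <- opt_or(opts, "out", NULL)
  if (is.null(out)) {
    utils::write.table(tab, stdout(), sep = "\t", row.names = FALSE,
                       quote = FALSE)
  } else {
    utils::write.table(tab, out, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  0L
}

cli_spectra <- function(opts) {
  s <- read_spectrum(req_opt(opts, "in"),
                     kind = opt_or(opts, "kind", "emission"),
                     excitation_nm = as.numeric(opt_or(opts, "excitation",
                                                       280)))
  peak <- locate_maximum(s,
    smooth_window = if (!is.null(opts$smooth))
      as.integer(opts$smooth) else NULL)
  emit_table(data.frame(file = req_opt(opts, "in"), n = length(s),
                        maximum_at = peak,
                        peak_intensity = max(s$intensity)), opts)
}

cli_fret_ratio <- function(opts) {
  res <- run_spectral_fret(req_opt(opts, "manifest"),
                           out_dir = opt_or(opts, "out-dir", NULL))
  emit_table(res, opts)
}

cli_zinc_compare <- function(opts) {
  res <- run_spectral_fret(req_opt(opts, "manifest"))
  cmp <- run_condition_comparison(
    res, treated = opt_or(opts, "treated", "zinc"),
    reversal = opt_or(opts, "reversal", NULL))
  emit_table(cmp, opts)
}

cli_predict <- function(opts) {
  sites <- as.integer(strsplit(req_opt(opts, "sites"), ",")[[1]])
  res <- run_predict(req_opt(opts, "structure"), sites,
                     mode = opt_or(opts, "mode", "all_donors"),
                     seed = as.integer(opt_or(opts, "seed", 1)),
                     out_dir = opt_or(opts, "out-dir", NULL))
  emit_table(res, opts)
}

cli_compare <- function(opts) {
  measured <- utils::read.table(req_opt(opts, "measured"), header = TRUE,
                                sep = "\t", stringsAsFactors = FALSE)
  predicted <- utils::read.table(req_opt(opts, "predicted"), header = TRUE,
                                 sep = "\t", stringsAsFactors = FALSE)
  fit <- run_compare(measured, predicted)
  emit_table(data.frame(slope_m = fit$slope_m, pearson_r = fit$pearson_r,
                        n = fit$n), opts)
}

cli_lifetime <- function(opts) {
  d <- read_decay(req_opt(opts, "in"), opt_or(opts, "irf", NULL))
  fit <- fit_decay(d, n_components = as.integer(opt_or(opts,
                                                       "components", 1)))
  emit_table(data.frame(component = seq_along(fit$lifetimes),
                        lifetime_ns = fit$lifetimes,
                        amplitude = fit$amplitudes,
                        mean_lifetime_ns = mean_lifetime(fit),
                        chi2_reduced = fit$goodness), opts)
}

cli_flux <- function(opts) {
  tr <- read_flux_trace(req_opt(opts, "in"), opt_or(opts, "events", NULL))
  tr <- normalize_flux(tr)
  qm <- quench_metrics(tr)
  emit_table(data.frame(f_max = tr$f_max, f_min = tr$f_min,
                        extent = qm$extent, rate_per_s = qm$rate,
                        rate_censored = qm$rate_censored), opts)
}

cli_simulate <- function(opts) {
  what <- opt_or(opts, "what", "fret")
  seed <- as.integer(opt_or(opts, "seed", 1))
  dir <- opt_or(opts, "dir", ".")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (what == "fret") {
    sc <- spectra_scenario(
      true_efficiency = as.numeric(opt_or(opts, "efficiency", 0.3)),
      noise_sd = as.numeric(opt_or(opts, "noise", 0)), seed = seed)
    mp <- write_fret_dataset(make_fret_dataset(sc), dir)
    cat(mp, "\n")
  } else if (what == "structure") {
    path <- file.path(dir, "toy_dimer.pdb")
    make_helix_bundle(toy_structure_scenario(seed = seed), path = path)
    cat(path, "\n")
  } else if (what == "decay") {
    d <- make_decay(c(3, 16), c(0.4, 0.6), seed = seed)
    write_spectrum(spectrum(d$time_bins, d$counts, kind = "chromatogram"),
                   file.path(dir, "decay.csv"))
    write_spectrum(spectrum(d$time_bins, d$irf_counts,
                            kind = "chromatogram"),
                   file.path(dir, "irf.csv"))
    cat(file.path(dir, "decay.csv"), "\n")
  } else if (what == "flux") {
    tr <- make_flux_trace(seed = seed)
    write_spectrum(spectrum(tr$time, tr$fluorescence,
                            kind = "chromatogram"),
                   file.path(dir, "flux.csv"))
    utils::write.table(tr$events, file.path(dir, "flux_events.csv"),
                       sep = ",", row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    cat(file.path(dir, "flux.csv"), "\n")
  } else {
    acd_error(sprintf("unknown simulation '%s'", what), "argument_error")
  }
  0L
}
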