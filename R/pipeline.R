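#' Configuration for an end-to-end niche breadth analysis
#'
#' Either supply paths to an occurrence CSV and a Newick tree, or leave
#' both NULL to simulate inputs with [simulate_occurrences()] /
#' [simulate_yule_tree()] under `sim_params`.
#'
#' @param occurrences Path to an occurrence CSV, or NULL to simulate.
#' @param tree Path to a Newick tree, or NULL to simulate.
#' @param sim_params A [climate_field_params()] object (used when input
#'   paths are NULL).
#' @param outdir Output directory (created; refuses to overwrite an
#'   existing analysis unless `force`).
#' @param seed Integer master seed recorded in the manifest; simulation
#'   seeds derive from it.
#' @param force Overwrite an existing output directory.
#' @param temp_scale Divisor for temperature columns on read (10 for
#'   WorldClim v1 degC x 10 rasters).
#' @param qc List of QC options: `variables`, `threshold_n`, `method`,
#'   `precision` (see [apply_qc()], [deduplicate_occurrences()]).
#' @param metrics List of metric options: `by_region`,
#'   `ratio_denominator`, `midpoint_variance`, `pnb_index` (`"wetdry"`
#'   or `"annual"`; which precipitation breadth feeds the regressions).
#' @param min_stratum_n Minimum species per stratum for a PGLS fit;
#'   smaller strata are skipped with a warning.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(occurrences = NULL, tree = NULL,
                            sim_params = climate_field_params(),
                            outdir = "niche_analysis",
                            seed = 1L, force = FALSE, temp_scale = 1,
                            qc = list(), metrics = list(),
                            min_stratum_n = 4L) {
  qc_def <- list(variables = c("bio1", "bio5", "bio6",
                               "bio12", "bio16", "bio17"),
                 threshold_n = 20L, method = "auto", precision = 4L)
  met_def <- list(by_region = TRUE, ratio_denominator = "region",
                  midpoint_variance = "locality", pnb_index = "wetdry")
  qc <- utils::modifyList(qc_def, qc)
  metrics <- utils::modifyList(met_def, metrics)
  structure(list(occurrences = occurrences, tree = tree,
                 sim_params = sim_params, outdir = outdir,
                 seed = as.integer(seed), force = isTRUE(force),
                 temp_scale = temp_scale, qc = qc, metrics = metrics,
                 min_stratum_n = as.integer(min_stratum_n)),
            class = "analysis_config")
}

#' Read an analysis configuration from JSON
#'
#' JSON fields mirror the arguments of [analysis_config()]; `sim_params`
#' is a nested object of [climate_field_params()] overrides.
#'
#' @param path Path to a JSON file.
#' @param ... Overrides applied after reading (e.g. `outdir`, `seed`).
#' @return An `analysis_config` object.
#' @export
read_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  over <- list(...)
  js[names(over)] <- over
  sp <- js$sim_params
  js$sim_params <- if (is.null(sp)) climate_field_params()
                   else do.call(climate_field_params, sp)
  do.call(analysis_config, js)
}

# stratum -> summary rows: regional strata use the per-region rows,
# the global stratum uses the pooled species-level rows
.stratum_rows <- function(summaries, stratum) {
  if (stratum == "Global") summaries[summaries$region == "global", , drop = FALSE]
  else summaries[summaries$region == stratum, , drop = FALSE]
}

.fit_one <- function(rows, yvar, xvar, tree, model, stratum, pnb_index) {
  y <- stats::setNames(rows[[yvar]], rows$species)
  x <- stats::setNames(rows[[xvar]], rows$species)
  na_row <- data.frame(model = model, region = stratum, n = nrow(rows),
                       lambda = NA_real_, r2 = NA_real_, p = NA_real_,
                       slope = NA_real_, intercept = NA_real_,
                       degenerate = NA, pnb_index = pnb_index,
                       stringsAsFactors = FALSE)
  if (stats::var(x) < 1e-12) {
    warning("degenerate predictor '", xvar, "' in stratum ", stratum,
            " (zero variance); fit skipped")
    na_row$degenerate <- TRUE
    return(na_row)
  }
  fit <- fit_pgls_lambda(y, x, tree)
  data.frame(model = model, region = stratum, n = fit$n,
             lambda = fit$lambda, r2 = fit$r2, p = fit$p_slope,
             slope = unname(fit$beta["slope"]),
             intercept = unname(fit$beta["intercept"]),
             degenerate = fit$degenerate, pnb_index = pnb_index,
             stringsAsFactors = FALSE)
}

.run_suite <- function(summaries, tree, models, min_stratum_n, pnb_index) {
  strata <- c(sort(unique(summaries$region[summaries$region != "global"])),
              "Global")
  out <- list()
  for (m in seq_len(nrow(models))) {
    for (s in strata) {
      rows <- .stratum_rows(summaries, s)
      if (nrow(rows) < min_stratum_n) {
        warning("stratum ", s, " has only ", nrow(rows),
                " species (< ", min_stratum_n, "); skipped")
        next
      }
      out[[length(out) + 1L]] <-
        .fit_one(rows, models$y[m], models$x[m], tree,
                 models$label[m], s, pnb_index)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Niche breadth vs niche position regression suite
#'
#' Fits three PGLS models -- temperature breadth on temperature
#' position, precipitation breadth on precipitation position, and
#' temperature breadth on precipitation breadth -- in every regional
#' stratum with enough species and globally. Regional strata use each
#' species' regional summary; the global stratum uses the pooled
#' species-level summaries, so a multi-region species contributes one
#' row per occupied region regionally and one row globally.
#'
#' @param summaries Output of [summarize_niches()].
#' @param tree A `phylo` object covering the species.
#' @param pnb_index Which precipitation breadth column feeds the models:
#'   `"wetdry"` (max Bio16 - min Bio17, default) or `"annual"`
#'   (range of Bio12).
#' @param min_stratum_n Minimum species per stratum (default 4).
#' @return Data frame with columns `model, region, n, lambda, r2, p,
#'   slope, intercept, degenerate, pnb_index`.
#' @export
run_breadth_position_suite <- function(summaries, tree,
                                       pnb_index = c("wetdry", "annual"),
                                       min_stratum_n = 4L) {
  pnb_index <- match.arg(pnb_index)
  pnb_col <- if (pnb_index == "wetdry") "pnb_wetdry" else "pnb_annual"
  models <- data.frame(
    label = c("TNB ~ temp_position", "PNB ~ precip_position", "TNB ~ PNB"),
    y = c("tnb", pnb_col, "tnb"),
    x = c("temp_position", "precip_position", pnb_col),
    stringsAsFactors = FALSE)
  .run_suite(summaries, tree, models, min_stratum_n, pnb_index)
}

#' Within-locality breadth ratio summary
#'
#' Mean and range of the within/species breadth ratios per regional
#' stratum and globally. Regional rows count every species occurring in
#' the region (with its regional ratio); the global row counts each
#' species once (with its cross-region mean ratio).
#'
#' @param summaries Output of [summarize_niches()].
#' @return Data frame with columns `region, n, tnbr_mean, tnbr_min,
#'   tnbr_max, pnbr_mean, pnbr_min, pnbr_max`.
#' @export
run_ratio_summary <- function(summaries) {
  strata <- c(sort(unique(summaries$region[summaries$region != "global"])),
              "Global")
  rows <- lapply(strata, function(s) {
    d <- .stratum_rows(summaries, s)
    data.frame(region = s, n = nrow(d),
               tnbr_mean = mean(d$tnbr_wl_s),
               tnbr_min = min(d$tnbr_wl_s), tnbr_max = max(d$tnbr_wl_s),
               pnbr_mean = mean(d$pnbr_wl_s),
               pnbr_min = min(d$pnbr_wl_s), pnbr_max = max(d$pnbr_wl_s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Breadth decomposition regression suite
#'
#' Fits six PGLS models relating species niche breadth to the three
#' decomposition metrics, for temperature and precipitation: breadth on
#' mean within-locality breadth, breadth on the within/species breadth
#' ratio, and breadth on the midpoint position variance.
#'
#' @inheritParams run_breadth_position_suite
#' @return Data frame as in [run_breadth_position_suite()].
#' @export
run_decomposition_suite <- function(summaries, tree,
                                    pnb_index = c("wetdry", "annual"),
                                    min_stratum_n = 4L) {
  pnb_index <- match.arg(pnb_index)
  pnb_col <- if (pnb_index == "wetdry") "pnb_wetdry" else "pnb_annual"
  models <- data.frame(
    label = c("TNB ~ TNB_WL", "PNB ~ PNB_WL",
              "TNB ~ TNBR_WL_S", "PNB ~ PNBR_WL_S",
              "TNB ~ TNPV", "PNB ~ PNPV"),
    y = c("tnb", pnb_col, "tnb", pnb_col, "tnb", pnb_col),
    x = c("tnb_wl", "pnb_wl", "tnbr_wl_s", "pnbr_wl_s", "tnpv", "pnpv"),
    stringsAsFactors = FALSE)
  .run_suite(summaries, tree, models, min_stratum_n, pnb_index)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, quality control, niche summaries, and
#' the three result tables, writing everything plus a JSON manifest and
#' a log to `config$outdir`:
#' `inputs/occurrences.csv`, `inputs/tree.nwk`
#' (and `inputs/sim_truth.json` when simulating), `qc_report.csv`,
#' `occurrences_clean.csv`, `niche_summaries.csv`,
#' `table1_breadth_position.csv`, `table2_ratio_summary.csv`,
#' `table3_decomposition.csv`, `manifest.json`, `log.txt`.
#' Reruns with the same config and seed produce identical tables.
#'
#' @param config An [analysis_config()] object.
#' @return The output directory path, invisibly.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  outdir <- config$outdir
  if (dir.exists(outdir) && length(list.files(outdir)) > 0 && !config$force) {
    stop("output directory ", outdir,
         " already exists and is non-empty; use force = TRUE to overwrite")
  }
  dir.create(file.path(outdir, "inputs"), recursive = TRUE,
             showWarnings = FALSE)
  log_path <- file.path(outdir, "log.txt")
  cat("", file = log_path)
  warnings_seen <- character(0)
  logmsg <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(name, ": ", conditionMessage(w)))
        logmsg("WARNING [", name, "] ", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  set.seed(config$seed)
  simulated <- is.null(config$occurrences) || is.null(config$tree)

  records <- stage("ingest", {
    if (simulated) {
      sp <- config$sim_params
      sp$seed <- config$seed
      sim <- simulate_occurrences(sp)
      jsonlite::write_json(sim$truth,
                           file.path(outdir, "inputs", "sim_truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write_occurrences(sim$records,
                        file.path(outdir, "inputs", "occurrences.csv"))
      logmsg("simulated ", nrow(sim$records), " records for ",
             sp$n_species, " species (seed ", config$seed, ")")
      sim$records
    } else {
      if (!file.exists(config$occurrences)) {
        stop("occurrence file not found: ", config$occurrences)
      }
      r <- read_occurrences(config$occurrences,
                            temp_scale = config$temp_scale)
      logmsg("read ", nrow(r), " records from ", config$occurrences)
      r
    }
  })

  tree <- stage("tree", {
    if (simulated) {
      tr <- simulate_yule_tree(config$sim_params$n_species,
                               seed = config$seed)
      cat(write_newick(tr), "\n", sep = "",
          file = file.path(outdir, "inputs", "tree.nwk"))
      logmsg("simulated Yule tree with ", length(tr$tip.label), " tips")
      tr
    } else {
      if (!file.exists(config$tree)) {
        stop("tree file not found: ", config$tree)
      }
      txt <- paste(readLines(config$tree, warn = FALSE), collapse = "")
      tr <- parse_newick(txt)
      tr$tip.label <- normalize_species_labels(tr$tip.label)
      logmsg("read tree with ", length(tr$tip.label), " tips from ",
             config$tree)
      tr
    }
  })

  qc_out <- stage("qc", {
    dd <- deduplicate_occurrences(records,
                                  precision = config$qc$precision)
    sc <- apply_qc(dd$kept, variables = config$qc$variables,
                   threshold_n = config$qc$threshold_n,
                   by_region = config$metrics$by_region,
                   method = config$qc$method)
    # unified per-record report: duplicates from pass 1, then outcome of
    # the outlier screen; row ids refer back to the input table
    kept_orig <- dd$report$row[dd$report$status == "kept"]
    sc$report$row <- kept_orig[sc$report$row]
    dup_rows <- dd$report[dd$report$status == "duplicate", ]
    dup_rows$region <- records$region[dup_rows$row]
    report <- rbind(sc$report,
                    dup_rows[, names(sc$report)])
    report <- report[order(report$row), ]
    rownames(report) <- NULL
    utils::write.csv(report, file.path(outdir, "qc_report.csv"),
                     row.names = FALSE)
    write_occurrences(sc$kept, file.path(outdir, "occurrences_clean.csv"))
    logmsg("QC: ", nrow(records), " in, ",
           sum(report$status == "duplicate"), " duplicates, ",
           length(unique(report$row[report$status == "outlier"])),
           " outliers, ", nrow(sc$kept), " kept")
    list(kept = sc$kept, report = report)
  })

  summaries <- stage("metrics", {
    s <- summarize_niches(qc_out$kept,
                          by_region = config$metrics$by_region,
                          ratio_denominator = config$metrics$ratio_denominator,
                          midpoint_variance = config$metrics$midpoint_variance)
    utils::write.csv(s, file.path(outdir, "niche_summaries.csv"),
                     row.names = FALSE)
    logmsg("summaries: ", sum(s$region == "global"), " species, ",
           sum(s$region != "global"), " species-region rows")
    s
  })

  t1 <- stage("breadth_position_suite", {
    tab <- run_breadth_position_suite(summaries, tree,
                                      pnb_index = config$metrics$pnb_index,
                                      min_stratum_n = config$min_stratum_n)
    utils::write.csv(tab, file.path(outdir, "table1_breadth_position.csv"),
                     row.names = FALSE)
    tab
  })
  t2 <- stage("ratio_summary", {
    tab <- run_ratio_summary(summaries)
    utils::write.csv(tab, file.path(outdir, "table2_ratio_summary.csv"),
                     row.names = FALSE)
    tab
  })
  t3 <- stage("decomposition_suite", {
    tab <- run_decomposition_suite(summaries, tree,
                                   pnb_index = config$metrics$pnb_index,
                                   min_stratum_n = config$min_stratum_n)
    utils::write.csv(tab, file.path(outdir, "table3_decomposition.csv"),
                     row.names = FALSE)
    tab
  })

  stage("manifest", {
    manifest <- list(
      seed = config$seed,
      simulated_inputs = simulated,
      r_version = as.character(getRversion()),
      package_version = as.character(utils::packageVersion("nichebreadth")),
      config = list(temp_scale = config$temp_scale, qc = config$qc,
                    metrics = config$metrics,
                    min_stratum_n = config$min_stratum_n,
                    sim_params = if (simulated)
                      unclass(config$sim_params) else NULL,
                    occurrences = config$occurrences, tree = config$tree),
      counts = list(records_in = nrow(records),
                    records_kept = nrow(qc_out$kept),
                    species = sum(summaries$region == "global"),
                    table1_rows = nrow(t1), table2_rows = nrow(t2),
                    table3_rows = nrow(t3)),
      warnings = warnings_seen)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })
  logmsg("done: ", outdir)
  invisible(outdir)
}
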