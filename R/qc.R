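#' Remove duplicate occurrence points
#'
#' Records of the same species whose coordinates agree after rounding to
#' `precision` decimal places collapse to one; the first occurrence is
#' kept. Different species at the same coordinates are never collapsed.
#'
#' @param records Occurrence data frame (see [read_occurrences()]).
#' @param precision Grid resolution in decimal places: coordinates are
#'   snapped to a 10^-precision degree grid (default 4, roughly 11 m at
#'   the equator) and compared by cell.
#' @return List with `kept` (deduplicated data frame) and `report`
#'   (one row per input record: `row`, `species`, `status` of
#'   `"kept"`/`"duplicate"`).
#' @export
deduplicate_occurrences <- function(records, precision = 4L) {
  cell <- function(x) floor(x * 10^precision)
  key <- paste(records$species, cell(records$lon), cell(records$lat),
               sep = "\r")
  dup <- duplicated(key)
  report <- data.frame(row = seq_len(nrow(records)),
                       species = records$species,
                       status = ifelse(dup, "duplicate", "kept"),
                       method = "dedup",
                       variable = NA_character_,
                       value = NA_real_,
                       threshold = NA_real_,
                       stringsAsFactors = FALSE)
  list(kept = records[!dup, , drop = FALSE], report = report)
}

#' Flag outliers by the 1.5 x interquartile-range rule
#'
#' Values outside \[Q1 - k IQR, Q3 + k IQR\] are flagged. Intended for
#' small samples (the usual recommendation is N < 20), where the
#' gap-based jackknife screen is unreliable. Quartiles use linear
#' interpolation between order statistics (`stats::quantile` type 7 by
#' default); the convention is configurable because legacy GIS tools do
#' not document theirs.
#'
#' @param values Numeric vector (length >= 4 for any flagging).
#' @param k Fence multiplier (default 1.5).
#' @param type Quantile type passed to [stats::quantile()].
#' @return Integer indices of flagged values, with the fences attached
#'   as attributes `lower` and `upper`.
#' @export
iqr_outliers <- function(values, k = 1.5, type = 7L) {
  values <- as.numeric(values)
  if (length(values) < 4L) {
    warning("fewer than 4 values; IQR screen not applied")
    return(structure(integer(0), lower = -Inf, upper = Inf))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE,
                       type = type, na.rm = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  structure(which(values < lower | values > upper),
            lower = lower, upper = upper)
}

#' Flag outliers by the reverse jackknife gap test
#'
#' Chapman-style screen for climatic values at occurrence points,
#' suitable for large samples: values are sorted and the gap between
#' consecutive order statistics is compared with the critical value
#' `C = (0.95 * sqrt(n) + 0.2) * (max - min) / 50`. Walking inward from
#' each end over the outer decile of the sorted vector (at least one
#' gap per end), a gap exceeding C cuts off everything outside it
#' (toward the extreme); the innermost violating gap in each tail wins,
#' so a cluster of aberrant values separated from the body by one large
#' gap is flagged as a whole. The walk depth is capped at the outer
#' decile because an outlier screen presumes outliers are a minority:
#' on continuous data the critical value is small enough at n of a few
#' dozen that gaps near the median would otherwise amputate the body of
#' the sample.
#'
#' @param values Numeric vector (length >= 5 with positive range for any
#'   flagging).
#' @return Integer indices (into `values`, original order) of flagged
#'   values, with the critical value attached as attribute `threshold`.
#' @export
reverse_jackknife_outliers <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  rng <- if (n > 0) max(values) - min(values) else 0
  if (n < 5L || rng == 0) {
    warning("fewer than 5 values or zero range; jackknife screen not applied")
    return(structure(integer(0), threshold = Inf))
  }
  crit <- (0.95 * sqrt(n) + 0.2) * rng / 50
  ord <- order(values)
  s <- values[ord]
  gaps <- diff(s)                      # gaps[j] between s[j] and s[j+1]
  depth <- min(max(1L, as.integer(ceiling(n / 10))), (n - 1L) %/% 2L)
  flag_sorted <- logical(n)
  low <- which(gaps[seq_len(depth)] > crit)
  if (length(low) > 0) flag_sorted[seq_len(max(low))] <- TRUE
  hi_range <- seq.int(n - depth, n - 1L)
  hi <- hi_range[gaps[hi_range] > crit]
  if (length(hi) > 0) flag_sorted[seq.int(min(hi) + 1L, n)] <- TRUE
  structure(ord[flag_sorted], threshold = crit)
}

#' Screen occurrence records for climatic outliers per species
#'
#' For each species (or species-by-region group when `by_region = TRUE`
#' and a region column is present) and each listed bioclim variable, the
#' screen is chosen by sample size: groups with fewer than `threshold_n`
#' localities use the 1.5 IQR rule, larger groups the reverse jackknife.
#' A record flagged on any variable is removed.
#'
#' @param records Occurrence data frame.
#' @param variables Bioclim columns to screen (default all six).
#' @param threshold_n Sample-size cutoff between the two methods
#'   (default 20).
#' @param by_region Group per species x region rather than per species.
#' @param method `"auto"` (select by sample size, the default) or force
#'   `"iqr"` / `"jackknife"` for every group.
#' @param k,type Passed to [iqr_outliers()].
#' @return List with `kept` (cleaned data frame) and `report` (one row
#'   per input record and flagged variable: `row`, `species`, `region`,
#'   `status` of `"kept"`/`"outlier"`, `method`, `variable`, `value`,
#'   `threshold`). Every input record appears at least once; unflagged
#'   records appear exactly once with status `"kept"`.
#' @export
apply_qc <- function(records,
                     variables = c("bio1", "bio5", "bio6",
                                   "bio12", "bio16", "bio17"),
                     threshold_n = 20L,
                     by_region = TRUE,
                     method = c("auto", "iqr", "jackknife"),
                     k = 1.5, type = 7L) {
  method <- match.arg(method)
  unknown <- setdiff(variables, names(records))
  if (length(unknown) > 0) {
    stop("unknown variable name(s): ", paste(unknown, collapse = ", "))
  }
  has_region <- by_region && "region" %in% names(records)
  grp <- if (has_region) paste(records$species, records$region, sep = "\r")
         else records$species
  idx_by_grp <- split(seq_len(nrow(records)), grp)

  out_rows <- vector("list", length(idx_by_grp) * length(variables))
  ii <- 0L
  for (idx in idx_by_grp) {
    n <- length(idx)
    use_iqr <- switch(method,
                      auto = n < threshold_n,
                      iqr = TRUE,
                      jackknife = FALSE)
    for (v in variables) {
      vals <- records[[v]][idx]
      if (use_iqr) {
        fl <- suppressWarnings(iqr_outliers(vals, k = k, type = type))
        thr_lo <- attr(fl, "lower"); thr_hi <- attr(fl, "upper")
        thr <- ifelse(vals[fl] < thr_lo, thr_lo, thr_hi)
        meth <- "iqr"
      } else {
        fl <- suppressWarnings(reverse_jackknife_outliers(vals))
        thr <- rep(attr(fl, "threshold"), length(fl))
        meth <- "jackknife"
      }
      ii <- ii + 1L
      out_rows[[ii]] <- data.frame(
        row = idx[fl],
        variable = rep(v, length(fl)),
        value = vals[fl],
        threshold = as.numeric(thr),
        method = rep(meth, length(fl)),
        stringsAsFactors = FALSE)
    }
  }
  flagged <- do.call(rbind, out_rows[seq_len(ii)])
  flagged <- flagged[order(flagged$row), , drop = FALSE]

  is_out <- logical(nrow(records))
  is_out[flagged$row] <- TRUE
  kept_report <- data.frame(row = which(!is_out),
                            variable = NA_character_, value = NA_real_,
                            threshold = NA_real_, method = NA_character_,
                            stringsAsFactors = FALSE)
  kept_report$status <- rep("kept", nrow(kept_report))
  flagged$status <- rep("outlier", nrow(flagged))
  report <- rbind(kept_report, flagged)
  report <- report[order(report$row), c("row", "status", "method",
                                        "variable", "value", "threshold")]
  report$species <- records$species[report$row]
  report$region <- if ("region" %in% names(records))
    records$region[report$row] else NA_character_
  rownames(report) <- NULL
  list(kept = records[!is_out, , drop = FALSE], report = report)
}
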