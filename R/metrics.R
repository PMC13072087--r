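#' Species-level climatic niche breadth and position statistics
#'
#' Scalar statistics over the occurrence records of one species (or one
#' species-by-region group). Each georeferenced point is one "locality".
#'
#' * `tnb()`: temperature niche breadth, `max(bio5) - min(bio6)` (degC).
#' * `pnb_annual()`: precipitation breadth as the range of annual
#'   precipitation, `max(bio12) - min(bio12)` (mm).
#' * `pnb_wetdry()`: precipitation breadth spanning seasonal extremes,
#'   `max(bio16) - min(bio17)` (mm).
#' * `niche_positions()`: mean `bio1` and mean `bio12` across localities.
#' * `within_locality_breadths()`: means across localities of the
#'   per-locality seasonal ranges `bio5 - bio6` and `bio16 - bio17`.
#' * `position_variances()`: sample variances (n-1 denominator; 0 when
#'   n = 1) across localities of the per-locality climatic midpoints
#'   `(bio5 + bio6)/2` and `(bio16 + bio17)/2` -- an among-locality
#'   (spatial) variability measure.
#'
#' @param records Occurrence data frame with at least one row.
#' @return `tnb`, `pnb_annual`, `pnb_wetdry`: a single number.
#'   `niche_positions`: named vector `c(temp_position, precip_position)`.
#'   `within_locality_breadths`: named vector `c(tnb_wl, pnb_wl)`.
#'   `position_variances`: named vector `c(tnpv, pnpv)`.
#' @name niche_statistics
NULL

.assert_records <- function(records) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no occurrence records supplied")
  }
}

#' @rdname niche_statistics
#' @export
tnb <- function(records) {
  .assert_records(records)
  max(records$bio5) - min(records$bio6)
}

#' @rdname niche_statistics
#' @export
pnb_annual <- function(records) {
  .assert_records(records)
  max(records$bio12) - min(records$bio12)
}

#' @rdname niche_statistics
#' @export
pnb_wetdry <- function(records) {
  .assert_records(records)
  max(records$bio16) - min(records$bio17)
}

#' @rdname niche_statistics
#' @export
niche_positions <- function(records) {
  .assert_records(records)
  c(temp_position = mean(records$bio1),
    precip_position = mean(records$bio12))
}

#' @rdname niche_statistics
#' @export
within_locality_breadths <- function(records) {
  .assert_records(records)
  c(tnb_wl = mean(records$bio5 - records$bio6),
    pnb_wl = mean(records$bio16 - records$bio17))
}

#' @rdname niche_statistics
#' @export
position_variances <- function(records) {
  .assert_records(records)
  if (nrow(records) == 1L) return(c(tnpv = 0, pnpv = 0))
  c(tnpv = stats::var((records$bio5 + records$bio6) / 2),
    pnpv = stats::var((records$bio16 + records$bio17) / 2))
}

# within/species breadth ratio with the degenerate zero-breadth case
# pinned to 1 (a single climatically uniform locality IS its own breadth)
.breadth_ratio <- function(wl, total, label) {
  if (total <= 0) {
    if (wl > 0) warning("zero ", label,
                        " breadth with positive within-locality breadth")
    else warning("zero ", label, " breadth; ratio defined as 1")
    return(1)
  }
  wl / total
}

.summarize_group <- function(records, midpoint_variance = "locality") {
  wl <- within_locality_breadths(records)
  pos <- niche_positions(records)
  pv <- if (midpoint_variance == "locality") position_variances(records) else NULL
  data.frame(n_localities = nrow(records),
             temp_position = unname(pos[1]),
             precip_position = unname(pos[2]),
             tnb = tnb(records),
             pnb_annual = pnb_annual(records),
             pnb_wetdry = pnb_wetdry(records),
             tnb_wl = unname(wl[1]),
             pnb_wl = unname(wl[2]),
             tnpv = if (is.null(pv)) NA_real_ else unname(pv[1]),
             pnpv = if (is.null(pv)) NA_real_ else unname(pv[2]),
             stringsAsFactors = FALSE)
}

#' Per-species and per-region niche summaries
#'
#' Computes the full set of niche statistics for every species-by-region
#' group and for every species pooled over all of its points (rows with
#' `region = "global"`). Within/species breadth ratios (`tnbr_wl_s`,
#' `pnbr_wl_s`) are formed per region and averaged (unweighted) over a
#' species' occupied regions; the species-level row carries that mean.
#'
#' @param records QC'd occurrence data frame.
#' @param by_region Split multi-region species by their region label
#'   (default TRUE). With FALSE, each species forms a single group.
#' @param ratio_denominator `"region"` (default): the ratio in region r
#'   divides by that region's breadth; `"species"`: divide by the
#'   species-level (all-points) breadth instead, for sensitivity checks.
#' @param midpoint_variance `"locality"` (default): `tnpv`/`pnpv` are
#'   variances of per-locality midpoints; `"region"`: variances of the
#'   per-region mean midpoints (degenerate to 0 for single-region
#'   species).
#' @return Data frame with one row per species x region plus one
#'   species-level row (`region == "global"`), and columns
#'   `species, region, n_localities, temp_position, precip_position,
#'   tnb, pnb_annual, pnb_wetdry, tnb_wl, pnb_wl, tnbr_wl_s, pnbr_wl_s,
#'   tnpv, pnpv`.
#' @export
summarize_niches <- function(records, by_region = TRUE,
                             ratio_denominator = c("region", "species"),
                             midpoint_variance = c("locality", "region")) {
  ratio_denominator <- match.arg(ratio_denominator)
  midpoint_variance <- match.arg(midpoint_variance)
  .assert_records(records)
  if (!"region" %in% names(records) || !by_region) records$region <- "all"
  if (any(records$region == "global")) {
    stop("region label 'global' is reserved for the species-level rows")
  }

  out <- vector("list", 0L)
  sp_idx <- split(seq_len(nrow(records)), records$species)
  for (sp in unique(records$species)) {
    rs <- records[sp_idx[[sp]], , drop = FALSE]
    regions <- unique(rs$region)
    reg_rows <- vector("list", length(regions))
    for (i in seq_along(regions)) {
      rr <- rs[rs$region == regions[i], , drop = FALSE]
      g <- .summarize_group(rr, midpoint_variance)
      if (midpoint_variance == "region") { g$tnpv <- NA_real_; g$pnpv <- NA_real_ }
      reg_rows[[i]] <- cbind(data.frame(species = sp, region = regions[i],
                                        stringsAsFactors = FALSE), g)
    }
    reg <- do.call(rbind, reg_rows)

    sp_row <- cbind(data.frame(species = sp, region = "global",
                               stringsAsFactors = FALSE),
                    .summarize_group(rs, midpoint_variance))

    denom_t <- if (ratio_denominator == "region") reg$tnb else sp_row$tnb
    denom_p <- if (ratio_denominator == "region") reg$pnb_wetdry else sp_row$pnb_wetdry
    reg$tnbr_wl_s <- mapply(.breadth_ratio, reg$tnb_wl, denom_t,
                            MoreArgs = list(label = "temperature"))
    reg$pnbr_wl_s <- mapply(.breadth_ratio, reg$pnb_wl, denom_p,
                            MoreArgs = list(label = "precipitation"))
    sp_row$tnbr_wl_s <- mean(reg$tnbr_wl_s)
    sp_row$pnbr_wl_s <- mean(reg$pnbr_wl_s)

    if (midpoint_variance == "region") {
      mids <- lapply(seq_len(nrow(reg)), function(i) {
        rr <- rs[rs$region == reg$region[i], , drop = FALSE]
        c(mean((rr$bio5 + rr$bio6) / 2), mean((rr$bio16 + rr$bio17) / 2))
      })
      mt <- vapply(mids, `[`, numeric(1), 1L)
      mp <- vapply(mids, `[`, numeric(1), 2L)
      reg$tnpv <- 0; reg$pnpv <- 0
      sp_row$tnpv <- if (length(mt) > 1) stats::var(mt) else 0
      sp_row$pnpv <- if (length(mp) > 1) stats::var(mp) else 0
    }
    out[[length(out) + 1L]] <- rbind(reg[, names(sp_row)], sp_row)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  cols <- c("species", "region", "n_localities", "temp_position",
            "precip_position", "tnb", "pnb_annual", "pnb_wetdry",
            "tnb_wl", "pnb_wl", "tnbr_wl_s", "pnbr_wl_s", "tnpv", "pnpv")
  res[, cols]
}

#' Within/species breadth ratios for one species
#'
#' Convenience wrapper returning the two breadth ratios for a single
#' species, averaging per-region ratios over occupied regions (see
#' [summarize_niches()] for the full table).
#'
#' @param records Occurrence records of one species.
#' @inheritParams summarize_niches
#' @return Named vector `c(tnbr_wl_s, pnbr_wl_s)`.
#' @export
breadth_ratios <- function(records, by_region = TRUE,
                           ratio_denominator = c("region", "species")) {
  ratio_denominator <- match.arg(ratio_denominator)
  .assert_records(records)
  if (length(unique(records$species)) != 1L) {
    stop("breadth_ratios expects records of a single species")
  }
  s <- summarize_niches(records, by_region = by_region,
                        ratio_denominator = ratio_denominator)
  s <- s[s$region == "global", ]
  c(tnbr_wl_s = s$tnbr_wl_s, pnbr_wl_s = s$pnbr_wl_s)
}
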