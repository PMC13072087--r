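#' Simulate a pure-birth (Yule) phylogeny
#'
#' Stand-in for an empirical time-calibrated tree in recovery experiments:
#' a rooted bifurcating tree with exponential waiting times between
#' speciation events (unit birth rate), conditioned on the number of tips.
#' Tips are labelled `sp0001`, `sp0002`, ... to match the occurrence
#' generator.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed; the same seed always yields the same tree.
#' @return A `phylo` object.
#' @export
simulate_yule_tree <- function(n_tips, seed = 1L) {
  if (!is.numeric(n_tips) || n_tips < 2) stop("n_tips must be >= 2")
  n_tips <- as.integer(n_tips)
  set.seed(as.integer(seed))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  tree$tip.label <- sprintf("sp%04d", seq_len(n_tips))
  tree
}

#' Simulate tip trait values under Brownian motion with Pagel's lambda
#'
#' Draws one trait vector from a multivariate normal with mean
#' `root_value` and covariance `sigma2 * lambda_transform(phylo_vcv(tree), lam)`.
#' With `lam = 1` this is plain Brownian motion; with `lam = 0` tip values
#' are independent normals with variance `sigma2` times each tip's
#' root-to-tip distance.
#'
#' @param tree A `phylo` object.
#' @param lam Pagel's lambda in \[0, 1\].
#' @param sigma2 Brownian rate (trait variance per unit branch length), >= 0.
#' @param root_value Trait value at the root (the common mean).
#' @param seed Integer seed.
#' @return Named numeric vector of tip values, ordered as `tree$tip.label`.
#' @export
simulate_bm_traits <- function(tree, lam = 1, sigma2 = 1, root_value = 0,
                               seed = 1L) {
  stopifnot(sigma2 >= 0)
  V <- lambda_transform(phylo_vcv(tree), lam)
  n <- nrow(V)
  set.seed(as.integer(seed))
  z <- stats::rnorm(n)
  if (sigma2 == 0) {
    x <- rep(root_value, n)
  } else {
    U <- tryCatch(chol(sigma2 * V), error = function(e)
      stop("covariance matrix not positive definite: ", conditionMessage(e)))
    x <- root_value + drop(crossprod(U, z))
  }
  names(x) <- rownames(V)
  x
}

#' Simulate a regression dataset with phylogenetic residuals
#'
#' Generates a predictor `x` by Brownian motion (lambda = 1, unit rate)
#' and a response `y = intercept + slope * x + eps`, where `eps` is
#' phylogenetically structured noise with parameters (`lam`, `sigma2`).
#' The predictor and noise use independent seed streams derived from
#' `seed`, so the same seed reproduces the full dataset.
#'
#' @inheritParams simulate_bm_traits
#' @param slope,intercept True regression coefficients.
#' @return List with named vectors `x`, `y`, and `truth` (a list of the
#'   generating parameters).
#' @export
simulate_regression_dataset <- function(tree, slope, intercept = 0, lam = 1,
                                        sigma2 = 1, seed = 1L) {
  seed <- as.integer(seed)
  x <- simulate_bm_traits(tree, lam = 1, sigma2 = 1, root_value = 0,
                          seed = seed)
  eps <- simulate_bm_traits(tree, lam = lam, sigma2 = sigma2, root_value = 0,
                            seed = seed + 1000003L)
  y <- intercept + slope * x + eps
  list(x = x, y = y,
       truth = list(slope = slope, intercept = intercept, lambda = lam,
                    sigma2 = sigma2, seed = seed))
}

#' Parameters for the synthetic occurrence/climate generator
#'
#' Bundles the knobs controlling the simulated occurrence compilation:
#' how many species, how many localities each, the spatial temperature
#' gradient (the among-locality component), the seasonal amplitude (the
#' within-locality component), and the precipitation field. Defaults
#' emulate a global compilation for a warm-adapted lizard clade: locality
#' counts log-uniform over 2-3082 per species, a ~0.6 degC drop in mean
#' annual temperature per degree latitude, and per-locality seasonal
#' half-ranges of 5-18 degC.
#'
#' @param n_species Number of species.
#' @param locality_range Length-2 integer range; per-species locality
#'   counts are log-uniform over this interval.
#' @param regions Data frame with columns `name`, `lon_min`, `lon_max`
#'   giving disjoint longitude bands; default mimics an
#'   Africa/Asia/Oceania partition.
#' @param region_prob Sampling probabilities for species range centres
#'   across regions (default roughly 0.17/0.52/0.31).
#' @param lat_range Latitude band for species range centres (degrees).
#' @param species_range_sd SD (degrees) of locality scatter around the
#'   species range centre, for both longitude and latitude.
#' @param temp_at_equator Mean annual temperature at latitude 0 (degC).
#' @param spatial_gradient_temp Cooling rate with absolute latitude
#'   (degC per degree latitude); this drives among-locality variance.
#' @param seasonal_amplitude_range Range (degC) for the per-species
#'   baseline seasonal half-amplitude a = (Bio5 - Bio6)/2; drives
#'   within-locality breadth.
#' @param amplitude_lat_gradient Increase of the seasonal half-amplitude
#'   with absolute latitude (degC per degree). The default 0.15 encodes
#'   the real-world rise of temperature seasonality toward the poles and
#'   induces the negative breadth-position relationship typical of
#'   terrestrial ectotherm compilations; set 0 for latitude-independent
#'   seasonality.
#' @param amplitude_jitter Relative per-locality jitter on the amplitude.
#' @param precip_base_range Range (mm) for the per-species annual
#'   precipitation level (log-uniform).
#' @param precip_spatial_sd SD of the log-normal among-locality
#'   multiplier on annual precipitation.
#' @param wet_dry_fraction_range Range for the fraction of Bio12 falling
#'   in the wettest quarter (Bio16).
#' @param dry_fraction_range Range for Bio17 as a fraction of
#'   `min(Bio16, Bio12 - Bio16)`, which guarantees
#'   0 <= Bio17 <= Bio16 and Bio16 + Bio17 <= Bio12.
#' @param noise_sd_temp SD (degC) of locality-level temperature noise.
#' @param noise_sd_precip SD (mm) of locality-level precipitation noise.
#' @param outlier_fraction Fraction of records perturbed into climatic
#'   outliers (10 species-level SDs by default), for QC testing.
#' @param outlier_sd Outlier displacement in species-level SD units.
#' @param duplicate_fraction Fraction of records duplicated exactly, for
#'   dedup testing.
#' @param seed Integer seed.
#' @return A list of class `climate_field_params`.
#' @seealso [simulate_occurrences()], [high_seasonality_params()],
#'   [high_gradient_params()]
#' @export
climate_field_params <- function(n_species = 100L,
                                 locality_range = c(2L, 3082L),
                                 regions = data.frame(
                                   name = c("Africa", "Asia", "Oceania"),
                                   lon_min = c(-20, 60, 130),
                                   lon_max = c(60, 130, 180)),
                                 region_prob = c(0.17, 0.52, 0.31),
                                 lat_range = c(-40, 40),
                                 species_range_sd = 3,
                                 temp_at_equator = 28,
                                 spatial_gradient_temp = 0.6,
                                 seasonal_amplitude_range = c(5, 18),
                                 amplitude_lat_gradient = 0.15,
                                 amplitude_jitter = 0.1,
                                 precip_base_range = c(150, 2500),
                                 precip_spatial_sd = 0.3,
                                 wet_dry_fraction_range = c(0.3, 0.6),
                                 dry_fraction_range = c(0.05, 0.6),
                                 noise_sd_temp = 0.5,
                                 noise_sd_precip = 20,
                                 outlier_fraction = 0,
                                 outlier_sd = 10,
                                 duplicate_fraction = 0,
                                 seed = 1L) {
  p <- list(n_species = as.integer(n_species),
            locality_range = as.integer(locality_range),
            regions = regions, region_prob = region_prob,
            lat_range = lat_range, species_range_sd = species_range_sd,
            temp_at_equator = temp_at_equator,
            spatial_gradient_temp = spatial_gradient_temp,
            seasonal_amplitude_range = seasonal_amplitude_range,
            amplitude_lat_gradient = amplitude_lat_gradient,
            amplitude_jitter = amplitude_jitter,
            precip_base_range = precip_base_range,
            precip_spatial_sd = precip_spatial_sd,
            wet_dry_fraction_range = wet_dry_fraction_range,
            dry_fraction_range = dry_fraction_range,
            noise_sd_temp = noise_sd_temp,
            noise_sd_precip = noise_sd_precip,
            outlier_fraction = outlier_fraction, outlier_sd = outlier_sd,
            duplicate_fraction = duplicate_fraction,
            seed = as.integer(seed))
  validate_climate_field_params(p)
  class(p) <- "climate_field_params"
  p
}

validate_climate_field_params <- function(p) {
  chk_range <- function(r, nm, lo = -Inf, hi = Inf) {
    if (length(r) != 2L || any(!is.finite(r)) || r[1] > r[2] ||
        r[1] < lo || r[2] > hi) {
      stop("invalid parameter '", nm, "': need min <= max within [",
           lo, ", ", hi, "]")
    }
  }
  if (p$n_species < 1L) stop("invalid parameter 'n_species': need >= 1")
  chk_range(p$locality_range, "locality_range", lo = 1)
  chk_range(p$lat_range, "lat_range", lo = -90, hi = 90)
  chk_range(p$seasonal_amplitude_range, "seasonal_amplitude_range", lo = 0)
  chk_range(p$precip_base_range, "precip_base_range", lo = 0)
  chk_range(p$wet_dry_fraction_range, "wet_dry_fraction_range",
            lo = 1e-6, hi = 1 - 1e-6)
  chk_range(p$dry_fraction_range, "dry_fraction_range", lo = 0, hi = 1)
  if (!is.data.frame(p$regions) ||
      !all(c("name", "lon_min", "lon_max") %in% names(p$regions))) {
    stop("invalid parameter 'regions': need columns name, lon_min, lon_max")
  }
  if (any(p$regions$lon_min >= p$regions$lon_max)) {
    stop("invalid parameter 'regions': lon_min must be < lon_max")
  }
  o <- order(p$regions$lon_min)
  if (any(p$regions$lon_max[o][-nrow(p$regions)] !=
          p$regions$lon_min[o][-1])) {
    stop("invalid parameter 'regions': longitude bands must be contiguous")
  }
  if (length(p$region_prob) != nrow(p$regions) || any(p$region_prob < 0)) {
    stop("invalid parameter 'region_prob': one non-negative weight per region")
  }
  if (p$spatial_gradient_temp < 0) stop("invalid parameter 'spatial_gradient_temp': need >= 0")
  if (p$amplitude_lat_gradient < 0) stop("invalid parameter 'amplitude_lat_gradient': need >= 0")
  if (p$outlier_fraction < 0 || p$outlier_fraction >= 1) {
    stop("invalid parameter 'outlier_fraction': need in [0, 1)")
  }
  if (p$duplicate_fraction < 0 || p$duplicate_fraction >= 1) {
    stop("invalid parameter 'duplicate_fraction': need in [0, 1)")
  }
  invisible(p)
}

#' Preset generator configurations for the breadth decomposition
#'
#' `high_seasonality_params()` makes within-locality (seasonal) variation
#' dominate: large seasonal amplitudes, an almost flat spatial
#' temperature field, and near-constant amplitude across a species'
#' localities (amplitude spread is itself an among-locality component,
#' so it is switched almost off), so species-level breadth is generated
#' locally and the within/species breadth ratio approaches 1.
#' `high_gradient_params()` does the opposite: a steep latitudinal
#' gradient dwarfs the seasonal amplitudes (which still vary across
#' species, keeping the within-locality breadth identifiable), so
#' breadth is generated by geography and the ratio falls well below one
#' half.
#'
#' @param ... Overrides passed on to [climate_field_params()].
#' @return A `climate_field_params` object.
#' @rdname generator_presets
#' @export
high_seasonality_params <- function(...) {
  climate_field_params(spatial_gradient_temp = 0.05,
                       seasonal_amplitude_range = c(12, 18),
                       amplitude_lat_gradient = 0,
                       amplitude_jitter = 0.02,
                       wet_dry_fraction_range = c(0.55, 0.65),
                       dry_fraction_range = c(0.02, 0.08),
                       precip_spatial_sd = 0.05,
                       noise_sd_temp = 0.2, ...)
}

#' @rdname generator_presets
#' @export
high_gradient_params <- function(...) {
  climate_field_params(spatial_gradient_temp = 1.2,
                       species_range_sd = 6,
                       seasonal_amplitude_range = c(1, 6),
                       amplitude_lat_gradient = 0,
                       precip_spatial_sd = 0.8,
                       noise_sd_temp = 0.2, ...)
}

#' Simulate an occurrence table with known climatic structure
#'
#' Generates one row per occurrence point (species, lon, lat, region,
#' Bio1/5/6 in degC, Bio12/16/17 in mm) with a controlled split between
#' within-locality (seasonal amplitude) and among-locality (latitudinal
#' gradient, spatial precipitation field) climatic variance, so that the
#' downstream breadth decomposition has a known ground truth. Every
#' record satisfies Bio6 <= Bio1 <= Bio5 and
#' 0 <= Bio17 <= Bio16, Bio16 + Bio17 <= Bio12.
#'
#' @param params A [climate_field_params()] object.
#' @return List with `records` (data frame) and `truth` (list with
#'   per-species generating values plus the row indices of injected
#'   outliers and duplicates).
#' @export
simulate_occurrences <- function(params = climate_field_params()) {
  p <- validate_climate_field_params(params)
  o <- order(p$regions$lon_min)
  p$region_prob <- p$region_prob[o]
  p$regions <- p$regions[o, , drop = FALSE]
  set.seed(p$seed)
  ns <- p$n_species
  species <- sprintf("sp%04d", seq_len(ns))
  lr <- log(as.numeric(p$locality_range))
  n_loc <- pmax(p$locality_range[1],
                pmin(p$locality_range[2],
                     round(exp(stats::runif(ns, lr[1], lr[2])))))

  reg_idx <- sample.int(nrow(p$regions), ns, replace = TRUE,
                        prob = p$region_prob)
  center_lon <- stats::runif(ns, p$regions$lon_min[reg_idx],
                             p$regions$lon_max[reg_idx])
  center_lat <- stats::runif(ns, p$lat_range[1], p$lat_range[2])
  amp_sp <- stats::runif(ns, p$seasonal_amplitude_range[1],
                         p$seasonal_amplitude_range[2])
  precip_sp <- exp(stats::runif(ns, log(p$precip_base_range[1]),
                                log(p$precip_base_range[2])))

  N <- sum(n_loc)
  sp_of <- rep.int(seq_len(ns), n_loc)
  lon <- stats::rnorm(N, center_lon[sp_of], p$species_range_sd)
  lat <- stats::rnorm(N, center_lat[sp_of], p$species_range_sd)
  lon <- pmin(pmax(lon, min(p$regions$lon_min)), max(p$regions$lon_max) - 1e-9)
  lat <- pmin(pmax(lat, -89.9), 89.9)
  region <- cut(lon, breaks = c(p$regions$lon_min[1], p$regions$lon_max),
                labels = p$regions$name, include.lowest = TRUE)
  region <- as.character(region)

  tmean <- p$temp_at_equator - p$spatial_gradient_temp * abs(lat) +
    stats::rnorm(N, 0, p$noise_sd_temp)
  amp <- (amp_sp[sp_of] + p$amplitude_lat_gradient * abs(lat)) *
    stats::runif(N, 1 - p$amplitude_jitter, 1 + p$amplitude_jitter)
  bio5 <- tmean + amp
  bio6 <- tmean - amp
  bio1 <- pmin(pmax(tmean + stats::rnorm(N, 0, p$noise_sd_temp), bio6), bio5)

  bio12 <- precip_sp[sp_of] * exp(stats::rnorm(N, 0, p$precip_spatial_sd)) +
    stats::rnorm(N, 0, p$noise_sd_precip)
  bio12 <- pmax(bio12, 1)
  wet_f <- stats::runif(N, p$wet_dry_fraction_range[1],
                        p$wet_dry_fraction_range[2])
  bio16 <- wet_f * bio12
  dry_f <- stats::runif(N, p$dry_fraction_range[1], p$dry_fraction_range[2])
  bio17 <- dry_f * pmin(bio16, bio12 - bio16)

  rec <- data.frame(species = species[sp_of],
                    lon = lon, lat = lat, region = region,
                    bio1 = bio1, bio5 = bio5, bio6 = bio6,
                    bio12 = bio12, bio16 = bio16, bio17 = bio17,
                    stringsAsFactors = FALSE)

  # inject climatic outliers: shift the temperature block additively and
  # scale the precipitation block multiplicatively, both by `outlier_sd`
  # species-level standard deviations, so all record-level orderings hold
  outlier_rows <- integer(0)
  if (p$outlier_fraction > 0) {
    eligible <- which(n_loc[sp_of] >= 20L)
    k <- min(length(eligible), max(1L, round(p$outlier_fraction * N)))
    outlier_rows <- sort(sample(eligible, k))
    sd1 <- stats::ave(rec$bio1, rec$species, FUN = stats::sd)
    sd12 <- stats::ave(rec$bio12, rec$species, FUN = stats::sd)
    shift <- sample(c(-1, 1), k, replace = TRUE) *
      p$outlier_sd * pmax(sd1[outlier_rows], 0.5)
    rec$bio1[outlier_rows] <- rec$bio1[outlier_rows] + shift
    rec$bio5[outlier_rows] <- rec$bio5[outlier_rows] + shift
    rec$bio6[outlier_rows] <- rec$bio6[outlier_rows] + shift
    fac <- 1 + p$outlier_sd * pmax(sd12[outlier_rows], 10) /
      rec$bio12[outlier_rows]
    rec$bio12[outlier_rows] <- rec$bio12[outlier_rows] * fac
    rec$bio16[outlier_rows] <- rec$bio16[outlier_rows] * fac
    rec$bio17[outlier_rows] <- rec$bio17[outlier_rows] * fac
  }

  dup_rows <- integer(0)
  if (p$duplicate_fraction > 0) {
    k <- max(1L, round(p$duplicate_fraction * nrow(rec)))
    src <- sort(sample.int(nrow(rec), k))
    dup <- rec[src, , drop = FALSE]
    dup_rows <- nrow(rec) + seq_len(k)
    rec <- rbind(rec, dup)
    rownames(rec) <- NULL
  }

  per_species <- data.frame(
    species = species,
    region = p$regions$name[reg_idx],
    n_localities = n_loc,
    center_lon = center_lon,
    center_lat = center_lat,
    seasonal_amplitude = amp_sp,
    precip_level = precip_sp,
    mean_amplitude = as.numeric(tapply(amp, sp_of, mean)),
    among_locality_temp_var = as.numeric(tapply(tmean, sp_of,
                                                function(v) if (length(v) > 1) stats::var(v) else 0)),
    stringsAsFactors = FALSE)

  list(records = rec,
       truth = list(per_species = per_species,
                    spatial_gradient_temp = p$spatial_gradient_temp,
                    amplitude_lat_gradient = p$amplitude_lat_gradient,
                    outlier_rows = outlier_rows,
                    duplicate_rows = dup_rows,
                    seed = p$seed))
}

#' Read and write occurrence tables
#'
#' Occurrence CSVs have one row per point with columns
#' `species, lon, lat, region, bio1, bio5, bio6, bio12, bio16, bio17`
#' (temperatures degC, precipitation mm). WorldClim v1 rasters store
#' temperatures as degC x 10; pass `temp_scale = 10` to divide the three
#' temperature columns on read.
#'
#' @param path File path.
#' @param temp_scale Divisor applied to bio1/bio5/bio6 on read (default 1).
#' @return `read_occurrences`: a data frame; `write_occurrences`: the
#'   path, invisibly.
#' @rdname occurrence_io
#' @export
read_occurrences <- function(path, temp_scale = 1) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "lon", "lat", "bio1", "bio5", "bio6",
            "bio12", "bio16", "bio17")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("occurrence file missing column(s): ",
                             paste(miss, collapse = ", "))
  if (!"region" %in% names(df)) df$region <- "all"
  df$species <- normalize_species_labels(df$species)
  if (temp_scale != 1) {
    for (v in c("bio1", "bio5", "bio6")) df[[v]] <- df[[v]] / temp_scale
  }
  validate_occurrences(df)
  df
}

#' @param records Occurrence data frame.
#' @rdname occurrence_io
#' @export
write_occurrences <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Check occurrence-record invariants
#'
#' Verifies coordinate bounds and the bioclim orderings
#' Bio6 <= Bio1 <= Bio5 and 0 <= Bio17 <= Bio16 <= Bio12.
#'
#' @param records Occurrence data frame.
#' @param tol Numeric slack for the orderings.
#' @return The records, invisibly, or an error naming the violated rule.
#' @export
validate_occurrences <- function(records, tol = 1e-8) {
  bad <- function(cond, what) {
    if (any(cond, na.rm = TRUE)) {
      stop("invalid occurrence record(s) [", what, "] at row(s): ",
           paste(utils::head(which(cond), 5L), collapse = ", "))
    }
  }
  bad(records$lat < -90 | records$lat > 90, "lat outside [-90, 90]")
  bad(records$lon < -180 | records$lon > 180, "lon outside [-180, 180]")
  bad(records$bio1 > records$bio5 + tol, "bio1 > bio5")
  bad(records$bio6 > records$bio1 + tol, "bio6 > bio1")
  bad(records$bio17 < -tol, "bio17 < 0")
  bad(records$bio16 < records$bio17 - tol, "bio17 > bio16")
  bad(records$bio12 < records$bio16 - tol, "bio16 > bio12")
  invisible(records)
}

#' Normalise species labels to Newick tip convention
#'
#' Trims surrounding whitespace and replaces internal spaces with
#' underscores, so occurrence tables match tree tip labels exactly.
#'
#' @param x Character vector of species names.
#' @return Character vector of normalised names.
#' @export
normalize_species_labels <- function(x) {
  gsub(" ", "_", trimws(as.character(x)))
}
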