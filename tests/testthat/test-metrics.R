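test_that("breadth and position statistics match hand-computed values", {
  one <- make_records("spA", bio5 = 30, bio6 = 10, bio16 = 400, bio17 = 20)
  expect_equal(tnb(one), 20)
  expect_equal(pnb_annual(one), 0)
  expect_equal(pnb_wetdry(one), 380)

  two <- make_records("spA", bio5 = c(35, 30), bio6 = c(5, -4),
                      bio1 = c(20, 13), bio12 = c(200, 950))
  expect_equal(tnb(two), 39)
  expect_equal(pnb_annual(two), 750)
  expect_equal(unname(niche_positions(two)), c(16.5, 575))
  expect_equal(unname(within_locality_breadths(two)[1]), 32)  # (30+34)/2

  three <- make_records("spA", bio5 = c(35, 30, 31), bio6 = c(5, -4, 2),
                        bio12 = c(200, 950, 600))
  expect_equal(pnb_annual(three), 750)
  # permutation invariance
  expect_equal(tnb(three[c(3, 1, 2), ]), tnb(three))
  expect_equal(position_variances(three[3:1, ]), position_variances(three))

  # midpoints {10, 20} -> sample variance 50
  mid <- make_records("spA", bio5 = c(15, 25), bio6 = c(5, 15))
  expect_equal(unname(position_variances(mid)[1]), 50)
  expect_equal(unname(position_variances(mid[1, ])), c(0, 0))

  expect_error(tnb(one[0, ]), "no occurrence")
  expect_error(niche_positions(one[0, ]), "no occurrence")
})

test_that("breadth ratios divide within-locality by species breadth", {
  r <- make_records("spA", bio5 = c(35, 30), bio6 = c(5, -4))
  br <- breadth_ratios(r)
  expect_equal(unname(br["tnbr_wl_s"]), 32 / 39, tolerance = 1e-12)

  single <- make_records("spA", bio5 = 30, bio6 = 10)
  expect_equal(unname(breadth_ratios(single)), c(1, 1))

  # climatically identical single locality: zero breadth, ratio pinned to 1
  degen <- make_records("spA", bio5 = 20, bio6 = 20,
                        bio16 = 100, bio17 = 100)
  # both the temperature and the precipitation ratio warn
  expect_warning(expect_warning(bd <- breadth_ratios(degen),
                                "ratio defined as 1"))
  expect_equal(unname(bd), c(1, 1))
})

test_that("summarize_niches splits regions and pools the species row", {
  rec <- rbind(
    make_records("spA", bio5 = c(35, 30), bio6 = c(5, -4), region = "Asia",
                 bio16 = c(300, 350), bio17 = c(30, 40)),
    make_records("spA", bio5 = c(28, 26), bio6 = c(12, 10), region = "Africa",
                 bio16 = c(500, 450), bio17 = c(60, 50)),
    make_records("spB", bio5 = c(33, 31), bio6 = c(3, 1), region = "Asia",
                 bio16 = c(200, 250), bio17 = c(10, 20)))
  s <- summarize_niches(rec)
  expect_equal(nrow(s), 5L)  # 3 region rows + 2 species rows

  gA <- s[s$species == "spA" & s$region == "global", ]
  rA <- s[s$species == "spA" & s$region != "global", ]
  expect_true(all(gA$tnb >= rA$tnb))
  expect_true(all(gA$pnb_wetdry >= rA$pnb_wetdry))
  # species ratio is the unweighted mean of the regional ratios
  expect_equal(gA$tnbr_wl_s, mean(rA$tnbr_wl_s), tolerance = 1e-12)

  # single-region species: region row equals the species row
  gB <- s[s$species == "spB" & s$region == "global", ]
  rB <- s[s$species == "spB" & s$region == "Asia", ]
  for (col in c("tnb", "pnb_wetdry", "tnb_wl", "tnpv", "tnbr_wl_s")) {
    expect_equal(gB[[col]], rB[[col]], tolerance = 1e-12)
  }

  # species-level denominator option gives smaller regional ratios
  s2 <- summarize_niches(rec, ratio_denominator = "species")
  r2A <- s2[s2$species == "spA" & s2$region != "global", ]
  expect_true(all(r2A$tnbr_wl_s <= rA$tnbr_wl_s + 1e-12))

  # regional midpoint-variance reading: variance across region means
  s3 <- summarize_niches(rec, midpoint_variance = "region")
  g3A <- s3[s3$species == "spA" & s3$region == "global", ]
  expect_gt(g3A$tnpv, 0)
  g3B <- s3[s3$species == "spB" & s3$region == "global", ]
  expect_equal(g3B$tnpv, 0)
})

test_that("metric identities hold across random synthetic species", {
  sim <- simulate_occurrences(climate_field_params(
    n_species = 120, locality_range = c(1, 80), seed = 17))
  s <- summarize_niches(sim$records)
  expect_true(all(s$tnb >= s$tnb_wl - 1e-9))
  expect_true(all(s$pnb_wetdry >= s$pnb_wl - 1e-9))
  expect_true(all(s$tnbr_wl_s > 0 & s$tnbr_wl_s <= 1 + 1e-12))
  expect_true(all(s$pnbr_wl_s > 0 & s$pnbr_wl_s <= 1 + 1e-12))
  expect_true(all(s$tnpv >= 0 & s$pnpv >= 0))
  expect_true(all(s$n_localities >= 1))
  one_loc <- s$n_localities == 1
  expect_true(all(s$tnbr_wl_s[one_loc] == 1))
  expect_true(all(s$tnpv[one_loc] == 0))

  # dominance: species breadth >= breadth of any subset of its points
  rec <- sim$records
  sp <- names(sort(table(rec$species), decreasing = TRUE))[1]
  rs <- rec[rec$species == sp, ]
  set.seed(17)
  for (i in 1:10) {
    sub <- rs[sample(nrow(rs), sample(nrow(rs), 1)), ]
    expect_lte(tnb(sub), tnb(rs) + 1e-12)
    expect_lte(pnb_annual(sub), pnb_annual(rs) + 1e-12)
    expect_lte(pnb_wetdry(sub), pnb_wetdry(rs) + 1e-12)
  }
})

test_that("breadths and variances are invariant under constant climate shifts", {
  sim <- simulate_occurrences(climate_field_params(
    n_species = 10, locality_range = c(3, 30), seed = 23))
  rec <- sim$records
  shifted <- rec
  shifted[c("bio1", "bio5", "bio6")] <- shifted[c("bio1", "bio5", "bio6")] + 7.3
  shifted[c("bio12", "bio16", "bio17")] <-
    shifted[c("bio12", "bio16", "bio17")] + 250
  a <- summarize_niches(rec)
  b <- summarize_niches(shifted)
  for (col in c("tnb", "pnb_annual", "pnb_wetdry", "tnb_wl", "pnb_wl",
                "tnbr_wl_s", "pnbr_wl_s", "tnpv", "pnpv")) {
    expect_equal(b[[col]], a[[col]], tolerance = 1e-9)
  }
})

test_that("the breadth ratio falls monotonically as spatial gradient grows", {
  grads <- c(0, 0.3, 0.6, 1.2, 2.4)
  mean_ratio <- numeric(length(grads))
  mean_tnpv <- numeric(length(grads))
  for (i in seq_along(grads)) {
    # amplitude jitter off: varying seasonality across localities is
    # itself an among-locality component and would cap the ratio below 1
    sim <- simulate_occurrences(climate_field_params(
      n_species = 40, locality_range = c(10, 60),
      spatial_gradient_temp = grads[i], noise_sd_temp = 0.1,
      amplitude_jitter = 0, amplitude_lat_gradient = 0, seed = 33))
    g <- summarize_niches(sim$records)
    g <- g[g$region == "global", ]
    mean_ratio[i] <- mean(g$tnbr_wl_s)
    mean_tnpv[i] <- mean(g$tnpv)
  }
  expect_true(all(diff(mean_ratio) < 0))
  expect_true(all(diff(mean_tnpv) > 0))
  expect_gt(mean_ratio[1], 0.95)  # no gradient: breadth is all seasonal
})
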