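# shared fixtures: tiny trees and occurrence tables built in code

three_tip_tree <- function() parse_newick("((A:1,B:1):1,C:2);")

# occurrence table from a compact locality spec: one row per locality
make_records <- function(species, bio5, bio6, bio1 = (bio5 + bio6) / 2,
                         bio12 = 1000, bio16 = 400, bio17 = 50,
                         lon = seq_along(bio5), lat = seq_along(bio5),
                         region = "all") {
  data.frame(species = species, lon = lon, lat = lat, region = region,
             bio1 = bio1, bio5 = bio5, bio6 = bio6,
             bio12 = bio12, bio16 = bio16, bio17 = bio17,
             stringsAsFactors = FALSE)
}

random_yule <- function(n, seed) simulate_yule_tree(n, seed = seed)

expect_psd <- function(V, tol = 1e-9) {
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -tol)
}
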