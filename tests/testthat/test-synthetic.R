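test_that("planting a signature round-trips through digestion", {
  withr::with_seed(7, {
    for (i in 1:40) {
      tgt <- random_feasible_signature(1450)
      seq <- plant_signature(tgt, 1450, seed = i)$sequence
      expect_equal(unname(trf_signature(seq)), unname(tgt))
    }
  })
})

test_that("plant_signature rejects geometrically impossible targets", {
  # one numeric and one no-cut end of the same (palindromic) enzyme
  expect_error(
    plant_signature(as_signature(60, NA, NA, NA, NA, NA), 500, seed = 1),
    class = "fetrflp_infeasible")
  # overlapping sites that would write contradictory bases: MspI and
  # HaeIII first sites at 210/210 demand C and G at one position
  expect_error(
    plant_signature(as_signature(210, NA, 210, 126, NA, 125), 1450, seed = 1),
    class = "fetrflp_infeasible")
  # fragment placing a site inside the forward primer
  expect_error(
    plant_signature(as_signature(5, NA, NA, 100, NA, NA), 500, seed = 1),
    class = "fetrflp_infeasible")
})

test_that("community draws live on the simplex and obey the seed", {
  one <- generate_community(1, seed = 3)
  expect_equal(one$abundance, 1)
  a <- generate_community(5, seed = 11)
  b <- generate_community(5, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a, generate_community(5, seed = 12)))
  expect_equal(sum(a$abundance), 1, tolerance = 1e-9)
  expect_true(all(a$abundance >= 0))
  expect_error(generate_community(0), "at least one taxon")
})

test_that("Dirichlet component means match the moment oracle", {
  # symmetric Dirichlet(1) over 4 taxa: component mean 1/4, variance
  # 3/80; the mean over n draws must sit within 3 standard errors
  n <- 2000
  draws <- vapply(seq_len(n), function(s) {
    generate_community(4, concentration = 1, seed = s)$abundance
  }, numeric(4))
  se <- sqrt(3 / 80 / n)
  expect_true(all(abs(rowMeans(draws) - 0.25) < 3 * se))
})

test_that("noiseless profiles reproduce the planted community exactly", {
  comm <- generate_community(c("x", "y", "z"), seed = 2)
  sig <- tibble::tibble(taxon = c("x", "y", "z"),
                        mspi_fwd = c(100, 200, 300))
  quiet <- noise_spec(0, 0, 0, 0)
  prof <- synthesize_profiles(comm, sig, "MspI", "forward", quiet,
                              n_replicates = 1, seed = 5)
  expect_equal(sort(prof$size_bp), c(100, 200, 300))
  expect_equal(prof$area[order(prof$size_bp)], comm$abundance)

  # full dropout leaves only noise peaks
  noisy <- noise_spec(10, 0.01, 0, dropout_prob = 1)
  prof2 <- synthesize_profiles(comm, sig, "MspI", "forward", noisy,
                               n_replicates = 1, seed = 5)
  expect_equal(nrow(prof2), 10)
  expect_true(all(prof2$size_bp >= 30 & prof2$size_bp <= 600))

  # empty community gives empty profiles
  empty <- synthesize_profiles(comm[0, ], sig, "MspI", "forward", quiet,
                               n_replicates = 1, seed = 5)
  expect_equal(nrow(empty), 0)

  # determinism of the noisy generator
  n1 <- synthesize_profiles(comm, sig, "MspI", "forward", noise_spec(),
                            seed = 9)
  n2 <- synthesize_profiles(comm, sig, "MspI", "forward", noise_spec(),
                            seed = 9)
  expect_identical(n1, n2)
})

test_that("uncut taxa contribute a full-length peak outside the window", {
  comm <- generate_community(c("cutter", "noncutter"), seed = 4)
  sig <- tibble::tibble(taxon = c("cutter", "noncutter"),
                        haeiii_fwd = c(150, NA))
  prof <- synthesize_profiles(comm, sig, "HaeIII", "forward",
                              noise_spec(0, 0, 0, 0), n_replicates = 1,
                              seed = 1, amplicon_length = 1450)
  expect_setequal(prof$size_bp, c(150, 1450))
  expect_equal(nrow(export_window(prof)), 1)
})

test_that("the Fe grid honours its shape tags and amplitude contracts", {
  grid <- generate_fe_grid(seed = 31)
  expect_equal(nrow(grid), 120)  # 3 minerals x 4 carbons x 5 dilutions x 2

  series <- grid |>
    dplyr::group_by(mineral, carbon, dilution_exponent) |>
    dplyr::summarise(pct = mean(percent_reduced), .groups = "drop")

  # ferrihydrite responses decrease with dilution for every carbon
  ferri <- series[series$mineral == "ferrihydrite", ]
  for (cb in unique(ferri$carbon)) {
    s <- ferri$pct[ferri$carbon == cb][order(ferri$dilution_exponent[ferri$carbon == cb])]
    expect_true(all(diff(s) <= 0))
  }

  # crystalline oxides with fermentable carbon peak in the third dilution
  uni <- series[series$mineral != "ferrihydrite" & series$carbon != "acetate", ]
  for (key in split(uni, paste(uni$mineral, uni$carbon))) {
    expect_equal(key$dilution_exponent[which.max(key$pct)], 3)
  }

  # acetate on goethite/hematite stays at or below its 6% ceiling
  flat <- grid[grid$carbon == "acetate" & grid$mineral != "ferrihydrite", ]
  expect_true(all(flat$percent_reduced <= 6))

  # noise-free amplitudes: ferrihydrite/acetate starts in the 84-88% band
  clean <- generate_fe_grid(seed = 31, noise_sd = 0)
  fa1 <- clean[clean$mineral == "ferrihydrite" & clean$carbon == "acetate" &
                 clean$dilution_exponent == 1, ]
  expect_true(all(fa1$percent_reduced >= 84 & fa1$percent_reduced <= 88))

  # derived chemistry is self-consistent
  expect_equal(grid$percent_reduced,
               100 * grid$fe2_mM / grid$fetot_mM, tolerance = 1e-9)
  expect_true(all(grid$fetot_mM == 25))

  # determinism
  expect_identical(grid, generate_fe_grid(seed = 31))
})

test_that("a zeroed amplitude grid selects nothing", {
  spec <- fe_grid_spec()
  spec$amp_lo <- 0
  spec$amp_hi <- 0
  grid <- generate_fe_grid(spec, seed = 1, noise_sd = 0)
  expect_true(all(grid$percent_reduced == 0))
  expect_equal(nrow(select_reduced(grid)$selected), 0)
})

test_that("an incomplete grid specification is rejected by name", {
  spec <- fe_grid_spec()
  spec <- spec[!(spec$mineral == "goethite" & spec$carbon == "lactate"), ]
  expect_error(generate_fe_grid(spec, seed = 1), "goethite x lactate")
})

test_that("the simulated study is reproducible and structured by carbon", {
  st1 <- simulate_study(seed = 8)
  st2 <- simulate_study(seed = 8)
  expect_identical(st1$profiles, st2$profiles)
  expect_identical(st1$truth, st2$truth)
  expect_equal(nrow(st1$metadata), 45)
  # each planted phylotype reproduces its target slots exactly
  pool <- study_phylotypes()
  expect_equal(st1$signatures[slot_names6],
               pool[slot_names6])
  # pools are disjoint at group level
  pools <- split(st1$signatures$group, st1$signatures$carbon_pool)
  expect_equal(length(Reduce(intersect, pools)), 0)
})
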