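mk_profile <- function(sizes, areas, replicate = 1L, sample_id = "S",
                       enzyme = "MspI", label = "forward") {
  tibble::tibble(sample_id = sample_id, enzyme = enzyme, label = label,
                 replicate = replicate, size_bp = sizes, area = areas)
}

test_that("export_window keeps inclusive bounds and passes clean profiles", {
  prof <- mk_profile(c(49.9, 50, 550, 550.1), rep(1, 4))
  kept <- export_window(prof)
  expect_equal(kept$size_bp, c(50, 550))
  expect_equal(nrow(export_window(prof[0, ])), 0)
  inside <- mk_profile(c(100, 200), c(1, 2))
  expect_equal(export_window(inside), inside)
  expect_error(export_window(prof, 500, 100), "low bound")
})

test_that("the iterative threshold isolates a dominant peak from a noise floor", {
  # 100 against twelve unit-area noise peaks: first pass sigma ~ 27.7, the
  # dominant peak exceeds 3 sigma, nothing else ever does
  prof <- mk_profile(seq(60, 180, by = 10), c(100, rep(1, 12)))
  out <- denoise_peaks(prof, k = 3)
  expect_equal(out$area, 100)

  # the six-peak variant needs the laxer threshold to separate
  prof6 <- mk_profile(seq(60, 110, by = 10), c(100, rep(1, 5)))
  expect_equal(denoise_peaks(prof6, k = 2)$area, 100)
})

test_that("profiles with no super-threshold peak are retained whole", {
  flat <- mk_profile(seq(60, 150, by = 10), rep(2, 10))
  expect_message(out <- denoise_peaks(flat), class = "fetrflp_denoise_note")
  expect_equal(suppressMessages(denoise_peaks(flat)), flat)
})

test_that("tiny and empty profiles pass through the denoiser unchanged", {
  two <- mk_profile(c(100, 200), c(5, 1))
  expect_equal(denoise_peaks(two), two)
  expect_equal(nrow(denoise_peaks(two[0, ])), 0)
})

test_that("denoising is idempotent on generated noisy profiles", {
  for (s in 1:10) {
    comm <- generate_community(4, seed = s)
    sig <- tibble::tibble(taxon = comm$taxon,
                          mspi_fwd = c(100, 180, 260, 340))
    prof <- synthesize_profiles(comm, sig, noise = noise_spec(),
                                n_replicates = 1, seed = s)
    once <- suppressMessages(denoise_peaks(prof))
    twice <- suppressMessages(denoise_peaks(once))
    expect_equal(twice, once)
  }
})

test_that("duplicate consensus averages relative areas of matched peaks only", {
  a <- mk_profile(c(100, 150), c(5, 3), replicate = 1L)
  b <- mk_profile(100, 7, replicate = 2L)
  out <- consensus_duplicates(dplyr::bind_rows(a, b), tol = 0.5)
  # 150 bp unmatched and discarded; the survivor re-relativizes to 1
  expect_equal(out$size_bp, 100)
  expect_equal(out$area, 1)

  # before re-relativization the matched area is the mean of 5/8 and 7/7;
  # visible when two peaks survive
  a2 <- mk_profile(c(100, 200), c(1, 3), replicate = 1L)
  b2 <- mk_profile(c(100, 200), c(3, 1), replicate = 2L)
  out2 <- consensus_duplicates(dplyr::bind_rows(a2, b2), tol = 0.5)
  expect_equal(out2$area, c(0.5, 0.5))
})

test_that("consensus is empty for disjoint replicates and stable for identical ones", {
  a <- mk_profile(c(100, 150), c(5, 3), replicate = 1L)
  b <- mk_profile(c(300, 400), c(2, 2), replicate = 2L)
  expect_equal(nrow(consensus_duplicates(dplyr::bind_rows(a, b))), 0)

  same <- dplyr::bind_rows(a, dplyr::mutate(a, replicate = 2L))
  out <- consensus_duplicates(same)
  expect_equal(out$size_bp, a$size_bp)
  expect_equal(out$area, a$area / sum(a$area))
})

test_that("consensus is commutative in its replicates and wants exactly two", {
  a <- random_profile(8, seed = 1, replicate = 1L)
  b <- random_profile(6, seed = 2, replicate = 2L)
  ab <- consensus_duplicates(dplyr::bind_rows(a, b))
  ba <- consensus_duplicates(dplyr::bind_rows(
    dplyr::mutate(a, replicate = 2L), dplyr::mutate(b, replicate = 1L)))
  expect_equal(ab, ba)
  expect_error(consensus_duplicates(a), "two replicates")
})

test_that("binning chains peaks by single linkage with the gap rule", {
  cons <- tibble::tibble(
    sample_id = c("A", "B"), enzyme = "MspI", label = "forward",
    size_bp = c(100.1, 100.4), area = c(1, 1))
  bins <- bin_peaks(cons, gap = 1)
  expect_equal(unique(bins$bin_center), 100.25)

  two <- dplyr::mutate(cons, size_bp = c(100, 102))
  expect_equal(dplyr::n_distinct(bin_peaks(two, gap = 1)$bin), 2)

  chain <- tibble::tibble(
    sample_id = c("A", "B", "C"), enzyme = "MspI", label = "forward",
    size_bp = c(100, 100.8, 101.6), area = 1)
  chained <- bin_peaks(chain, gap = 1)
  expect_equal(dplyr::n_distinct(chained$bin), 1)
  expect_equal(unique(chained$bin_center), 100.8)
})

test_that("per-sample relative areas sum to one through the whole chain", {
  withr::with_seed(77, {
    raw <- dplyr::bind_rows(purrr::map(1:4, function(i) {
      dplyr::bind_rows(
        random_profile(12, seed = i, sample_id = paste0("S", i), replicate = 1L),
        random_profile(12, seed = i + 50, sample_id = paste0("S", i), replicate = 2L))
    }))
  })
  cons <- suppressMessages(
    raw |> export_window() |> denoise_peaks() |> consensus_duplicates(tol = 5))
  sums <- cons |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(area))
  expect_true(all(abs(sums$s - 1) < 1e-9))

  bins <- bin_peaks(cons)
  bsums <- bins |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(rel_area))
  expect_true(all(abs(bsums$s - 1) < 1e-9))
})
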