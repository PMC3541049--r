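#' Default Fe-reduction response-surface specification
#'
#' One row per mineral x carbon combination giving the dilution-response
#' shape and the amplitude range (percent of total Fe reduced). Defaults
#' emulate the qualitative behaviour of sediment enrichment grids:
#' ferrihydrite, the most bioavailable oxide, is reduced under every
#' carbon source with activity decreasing monotonically with sediment
#' dilution (acetate amplitude 84-88%); the crystalline oxides goethite
#' and hematite are reduced by the fermentable substrates
#' (lactate/glucose/mixed) with a maximum in the third decimal dilution
#' (amplitudes 56-67% on goethite, lower on hematite except lactate), and
#' essentially not at all with acetate (<= 6%).
#'
#' @return Tibble `mineral`, `carbon`, `shape`, `amp_lo`, `amp_hi`.
#' @export
fe_grid_spec <- function() {
  dplyr::bind_rows(
    tibble(mineral = "ferrihydrite",
           carbon = c("acetate", "lactate", "glucose", "mixed"),
           shape = "decreasing",
           amp_lo = c(84, 75, 70, 70), amp_hi = c(88, 88, 88, 88)),
    tibble(mineral = "goethite",
           carbon = c("acetate", "lactate", "glucose", "mixed"),
           shape = c("flat_low", "unimodal_at_third", "unimodal_at_third",
                     "unimodal_at_third"),
           amp_lo = c(0, 56, 56, 56), amp_hi = c(6, 67, 67, 67)),
    tibble(mineral = "hematite",
           carbon = c("acetate", "lactate", "glucose", "mixed"),
           shape = c("flat_low", "unimodal_at_third", "unimodal_at_third",
                     "unimodal_at_third"),
           amp_lo = c(0, 56, 8, 8), amp_hi = c(6, 67, 15, 15))
  )
}

# Dilution-response multipliers of the three shape tags over the decimal
# dilutions 10^-1 .. 10^-5. Gaps between adjacent dilutions are kept large
# relative to the measurement noise so the shape survives it.
shape_multipliers <- function(shape, n_dilutions = 5) {
  base <- switch(shape,
    decreasing        = c(1, 0.75, 0.45, 0.2, 0.02),
    unimodal_at_third = c(0.3, 0.33, 1, 0.1, 0.02),
    flat_low          = rep(1, 5),
    abort(paste0("unknown shape tag: ", shape))
  )
  base[seq_len(n_dilutions)]
}

#' Generate a synthetic mineral x carbon x dilution Fe-reduction grid
#'
#' For each mineral x carbon combination an amplitude is drawn uniformly
#' from its range, shaped over the five decimal dilutions according to the
#' shape tag, measured in duplicate with additive Gaussian noise (sd 2
#' percentage points, truncated to \[0, 100\]), and converted to Fe(II)
#' concentrations against a fixed total Fe pool. `flat_low` series are
#' additionally capped at their amplitude ceiling, which that tag defines
#' as an upper bound on observable reduction.
#'
#' @param spec Specification tibble from [fe_grid_spec()]; must cover all
#'   mineral x carbon combinations it declares minerals and carbons for.
#' @param seed Integer seed.
#' @param n_replicates Duplicate enrichments per condition (default 2; 12
#'   combinations x 5 dilutions x 2 gives the canonical 120-enrichment
#'   grid).
#' @param n_dilutions Number of decimal dilutions (default 5).
#' @param fe_tot Total Fe per enrichment in mM (default 25).
#' @param noise_sd Measurement noise sd in percentage points.
#' @return Enrichment tibble: `sample_id`, `mineral`, `carbon`,
#'   `dilution_exponent`, `replicate`, `fe2_mM`, `fetot_mM`,
#'   `percent_reduced`.
#' @export
generate_fe_grid <- function(spec = fe_grid_spec(), seed = 1,
                             n_replicates = 2, n_dilutions = 5,
                             fe_tot = 25, noise_sd = 2) {
  full <- tidyr::expand_grid(mineral = unique(spec$mineral),
                             carbon = unique(spec$carbon))
  gap <- dplyr::anti_join(full, spec, by = c("mineral", "carbon"))
  if (nrow(gap) > 0) {
    abort(paste0("spec lacks combination(s): ",
                 paste(paste(gap$mineral, gap$carbon, sep = " x "),
                       collapse = "; ")))
  }
  if (any(spec$amp_lo < 0 | spec$amp_hi > 100 | spec$amp_lo > spec$amp_hi)) {
    abort("amplitude ranges must satisfy 0 <= lo <= hi <= 100")
  }

  withr::with_seed(seed, {
    rows <- purrr::pmap(spec, function(mineral, carbon, shape, amp_lo, amp_hi) {
      amp <- stats::runif(1, amp_lo, amp_hi)
      mult <- shape_multipliers(shape, n_dilutions)
      out <- tidyr::expand_grid(dilution_exponent = seq_len(n_dilutions),
                                replicate = seq_len(n_replicates))
      pct <- amp * mult[out$dilution_exponent] +
        stats::rnorm(nrow(out), 0, noise_sd)
      pct <- pmin(pmax(pct, 0), 100)
      if (shape == "flat_low") pct <- pmin(pct, amp_hi)
      out |>
        dplyr::mutate(mineral = mineral, carbon = carbon,
                      percent_reduced = pct)
    })
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_d%d_r%d",
                          substr(.data$mineral, 1, 1), substr(.data$carbon, 1, 1),
                          .data$dilution_exponent, .data$replicate),
      fetot_mM = fe_tot,
      fe2_mM = .data$percent_reduced / 100 * fe_tot
    ) |>
    dplyr::select("sample_id", "mineral", "carbon", "dilution_exponent",
                  "replicate", "fe2_mM", "fetot_mM", "percent_reduced")
}

#' Read or write the delimited enrichment table
#'
#' @param path File path (TSV).
#' @return A tibble of enrichment records.
#' @export
read_enrichment_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    mineral = readr::col_character(),
    carbon = readr::col_character(),
    dilution_exponent = readr::col_integer(),
    replicate = readr::col_integer(),
    fe2_mM = readr::col_double(),
    fetot_mM = readr::col_double(),
    percent_reduced = readr::col_double()
  ))
}

#' @rdname read_enrichment_table
#' @param records Enrichment tibble.
#' @export
write_enrichment_table <- function(records, path) {
  readr::write_tsv(records, path)
  invisible(path)
}
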