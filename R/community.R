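#' Draw a synthetic community composition
#'
#' Relative abundances are drawn from a symmetric Dirichlet distribution
#' (via normalised gamma variates), the standard neutral model for
#' compositional community data; they are non-negative and sum to 1.
#'
#' @param taxa Character vector of unique taxon labels, or a single count
#'   (labels are then generated).
#' @param concentration Dirichlet concentration parameter; 1 gives a
#'   uniform distribution on the simplex, larger values give more even
#'   communities.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @return Tibble `taxon`, `abundance`.
#' @export
generate_community <- function(taxa, concentration = 1, seed = 1) {
  if (is.numeric(taxa) && length(taxa) == 1) {
    if (taxa < 1) abort("community must contain at least one taxon")
    taxa <- sprintf("taxon%02d", seq_len(taxa))
  }
  if (length(taxa) == 0) abort("community must contain at least one taxon")
  if (anyDuplicated(taxa)) abort("taxon labels must be unique")
  if (concentration <= 0) abort("concentration must be positive")
  ab <- withr::with_seed(seed, stats::rgamma(length(taxa), shape = concentration))
  if (sum(ab) == 0) ab <- rep(1, length(taxa))
  tibble(taxon = taxa, abundance = ab / sum(ab))
}

#' Electropherogram noise model
#'
#' Parameters of the synthetic noise applied to each replicate digest:
#' `n_noise_peaks` spurious peaks with sizes uniform on \[30, 600\] bp
#' (deliberately wider than the 50-550 bp export window) and
#' exponentially distributed areas of mean `noise_area_scale` (in units
#' of total true signal area), Gaussian size jitter with standard
#' deviation `size_jitter_sd` bp, and an independent per-peak dropout
#' probability per replicate.
#'
#' @param n_noise_peaks Number of noise peaks per profile.
#' @param noise_area_scale Mean noise-peak area (relative units).
#' @param size_jitter_sd Size jitter SD in bp.
#' @param dropout_prob Per-peak, per-replicate dropout probability.
#' @return A list of class `trf_noise`.
#' @export
noise_spec <- function(n_noise_peaks = 30, noise_area_scale = 0.005,
                       size_jitter_sd = 0.1, dropout_prob = 0.001) {
  if (n_noise_peaks < 0 || noise_area_scale < 0 || size_jitter_sd < 0 ||
      dropout_prob < 0 || dropout_prob > 1) {
    abort("noise parameters must be non-negative (dropout_prob <= 1)")
  }
  structure(list(n_noise_peaks = as.integer(n_noise_peaks),
                 noise_area_scale = noise_area_scale,
                 size_jitter_sd = size_jitter_sd,
                 dropout_prob = dropout_prob),
            class = "trf_noise")
}

#' Simulate replicate electropherograms for a known community
#'
#' True peaks are placed at each taxon's terminal-fragment size for the
#' requested digest with areas proportional to abundance; taxa whose
#' sequence the enzyme does not cut contribute a peak at the uncut
#' amplicon length (which falls outside the export window downstream).
#' Each replicate is independently jittered, thinned by dropout and
#' contaminated with noise peaks according to the [noise_spec()].
#'
#' @param community Tibble `taxon`, `abundance` (see
#'   [generate_community()]).
#' @param signatures Tibble with a `taxon` column and the six signature
#'   slot columns giving each taxon's true fragment sizes (`NA` = no
#'   cut).
#' @param enzyme,label The digest to simulate.
#' @param noise A [noise_spec()].
#' @param n_replicates Number of replicate digests (default 2, duplicate
#'   digests).
#' @param seed Integer seed.
#' @param sample_id Sample identifier stamped on the profiles.
#' @param amplicon_length Uncut amplicon length in bp.
#' @return Peak table (`sample_id`, `enzyme`, `label`, `replicate`,
#'   `size_bp`, `area`).
#' @export
synthesize_profiles <- function(community, signatures, enzyme = "MspI",
                                label = "forward", noise = noise_spec(),
                                n_replicates = 2, seed = 1,
                                sample_id = "S1", amplicon_length = 1450) {
  if (nrow(community) == 0) {
    return(tibble(sample_id = character(0), enzyme = character(0),
                  label = character(0), replicate = integer(0),
                  size_bp = numeric(0), area = numeric(0)))
  }
  slot <- slot_name(enzyme, label)
  if (!slot %in% names(signatures)) abort(paste0("signatures lack slot ", slot))
  truth <- community |>
    dplyr::left_join(dplyr::select(signatures, "taxon", size = dplyr::all_of(slot)),
                     by = "taxon") |>
    dplyr::mutate(size = ifelse(is.na(.data$size), amplicon_length, .data$size))

  withr::with_seed(seed, {
    reps <- purrr::map(seq_len(n_replicates), function(r) {
      keep <- stats::runif(nrow(truth)) >= noise$dropout_prob
      true_peaks <- tibble(
        size_bp = truth$size[keep] +
          stats::rnorm(sum(keep), 0, noise$size_jitter_sd),
        area = truth$abundance[keep]
      )
      noise_peaks <- tibble(
        size_bp = stats::runif(noise$n_noise_peaks, 30, 600),
        area = if (noise$noise_area_scale > 0)
          stats::rexp(noise$n_noise_peaks, rate = 1 / noise$noise_area_scale)
        else rep(0, noise$n_noise_peaks)
      ) |>
        dplyr::filter(.data$area > 0)
      dplyr::bind_rows(true_peaks, noise_peaks) |>
        dplyr::filter(.data$size_bp > 0) |>
        dplyr::mutate(replicate = r)
    })
  })
  dplyr::bind_rows(reps) |>
    dplyr::mutate(sample_id = sample_id, enzyme = enzyme, label = label) |>
    dplyr::select("sample_id", "enzyme", "label", "replicate", "size_bp", "area") |>
    dplyr::arrange(.data$replicate, .data$size_bp)
}

#' Simulate all six digests of one sample
#'
#' Convenience wrapper running [synthesize_profiles()] for the three
#' enzymes at both labelled ends with per-digest derived seeds.
#'
#' @inheritParams synthesize_profiles
#' @return Combined peak table over the six digests.
#' @export
synthesize_sample <- function(community, signatures, noise = noise_spec(),
                              n_replicates = 2, seed = 1, sample_id = "S1",
                              amplicon_length = 1450) {
  enz <- trf_enzymes()
  combos <- tidyr::expand_grid(enzyme = enz$enzyme,
                               label = c("forward", "reverse"))
  purrr::pmap(combos, function(enzyme, label) {
    k <- which(combos$enzyme == enzyme & combos$label == label)
    synthesize_profiles(community, signatures, enzyme, label, noise,
                        n_replicates, derive_seed(seed, k),
                        sample_id, amplicon_length)
  }) |>
    dplyr::bind_rows()
}
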