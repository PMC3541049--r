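#' Restrict peaks to the reliable sizing window
#'
#' Capillary size calling is reliable only within the size-standard range;
#' peaks outside `[low, high]` bp (bounds inclusive) are dropped.
#'
#' @param peaks Peak table: one row per peak with columns `sample_id`,
#'   `enzyme`, `label`, `replicate`, `size_bp`, `area`.
#' @param low,high Window bounds in bp (defaults 50 and 550).
#' @return The filtered peak table.
#' @export
export_window <- function(peaks, low = 50, high = 550) {
  if (low > high) abort("window low bound exceeds high bound")
  assert_peak_table(peaks, need_replicate = FALSE)
  dplyr::filter(peaks, .data$size_bp >= low, .data$size_bp <= high)
}

#' Iterative signal/noise discrimination
#'
#' Within each electropherogram, areas are relativized and the standard
#' deviation of the not-yet-flagged areas about zero is computed; peaks
#' whose area exceeds `k` times that deviation are flagged as signal and
#' removed from the noise pool, and the statistic is recomputed until no
#' new peak is flagged. Flagged peaks are returned with their original
#' areas.
#'
#' Two guards apply: profiles with fewer than three peaks are returned
#' unchanged (the deviation is not meaningful), and when no peak exceeds
#' the threshold on the first pass the whole profile is retained rather
#' than discarded, so low-diversity profiles of near-equal true peaks are
#' not annihilated (a note is emitted).
#'
#' @param peaks Peak table (see [export_window()]).
#' @param k Threshold multiplier (default 3).
#' @return Peak table restricted to signal peaks.
#' @export
denoise_peaks <- function(peaks, k = 3) {
  if (k <= 0) abort("k must be positive")
  assert_peak_table(peaks, need_replicate = FALSE)
  grp <- intersect(c("sample_id", "enzyme", "label", "replicate"), names(peaks))
  peaks |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::group_modify(function(df, key) denoise_one(df, k)) |>
    dplyr::ungroup()
}

denoise_one <- function(df, k) {
  n <- nrow(df)
  if (n < 3) return(df)
  rel <- relativize(df$area)
  signal <- rep(FALSE, n)
  first_pass <- TRUE
  repeat {
    pool <- rel[!signal]
    if (length(pool) == 0) break
    sigma <- sqrt(mean(pool^2))  # deviation about zero
    newly <- !signal & rel > k * sigma
    if (!any(newly)) {
      if (first_pass) {
        inform("no peak exceeded the signal threshold; profile retained as-is",
               class = "fetrflp_denoise_note")
        return(df)
      }
      break
    }
    signal <- signal | newly
    first_pass <- FALSE
  }
  df[signal, , drop = FALSE]
}

#' Consensus of duplicate digests
#'
#' Duplicate T-RF profiles of the same sample/enzyme/label are reconciled:
#' each replicate is relativized (correcting for differences in injected
#' DNA), peaks are matched greedily nearest-first across replicates within
#' `tol` bp (each peak matches at most once), unmatched peaks are
#' discarded, matched peaks keep the mean size and mean relative area, and
#' the consensus profile is re-relativized.
#'
#' @param peaks Peak table containing exactly two replicates per
#'   (`sample_id`, `enzyme`, `label`) profile.
#' @param tol Replicate matching tolerance in bp (default 0.5).
#' @return Consensus peak table without a `replicate` column; `area` holds
#'   relative areas summing to 1 per profile.
#' @export
consensus_duplicates <- function(peaks, tol = 0.5) {
  if (tol < 0) abort("tol must be non-negative")
  assert_peak_table(peaks)
  peaks |>
    dplyr::group_by(.data$sample_id, .data$enzyme, .data$label) |>
    dplyr::group_modify(function(df, key) consensus_one(df, tol)) |>
    dplyr::ungroup()
}

consensus_one <- function(df, tol) {
  reps <- sort(unique(df$replicate))
  if (length(reps) != 2) {
    abort(paste0("consensus needs exactly two replicates per profile, got ",
                 length(reps)))
  }
  a <- df[df$replicate == reps[1], ]
  b <- df[df$replicate == reps[2], ]
  a$rel <- relativize(a$area)
  b$rel <- relativize(b$area)
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(tibble(size_bp = numeric(0), area = numeric(0)))
  }
  cand <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b))) |>
    dplyr::mutate(d = abs(a$size_bp[.data$i] - b$size_bp[.data$j])) |>
    dplyr::filter(.data$d <= tol) |>
    dplyr::arrange(.data$d, .data$i, .data$j)
  used_i <- logical(nrow(a)); used_j <- logical(nrow(b))
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    i <- cand$i[r]; j <- cand$j[r]
    if (!used_i[i] && !used_j[j]) {
      used_i[i] <- TRUE; used_j[j] <- TRUE
      keep <- c(keep, r)
    }
  }
  cand <- cand[keep, , drop = FALSE]
  out <- tibble(
    size_bp = (a$size_bp[cand$i] + b$size_bp[cand$j]) / 2,
    area = (a$rel[cand$i] + b$rel[cand$j]) / 2
  )
  out$area <- relativize(out$area)
  dplyr::arrange(out, .data$size_bp)
}

#' Align consensus peaks into cross-sample bins
#'
#' Within each digest (enzyme x label), peak sizes pooled over samples are
#' clustered by single linkage: sizes processed in ascending order chain
#' into one bin while consecutive gaps are `<= gap` bp, and a gap `> gap`
#' starts a new bin. The bin centre is the mean member size. Because this
#' is single-linkage, a chain of closely spaced peaks can form one wide
#' bin even when its extremes differ by more than `gap`.
#'
#' @param consensus Consensus peak table (see [consensus_duplicates()]).
#' @param gap Maximum chaining gap in bp (default 1.0).
#' @return Long bin table: `enzyme`, `label`, `bin`, `bin_center`
#'   (mean size over all member peaks), `sample_id`, `sample_size_bp`
#'   (mean size of this sample's own member peaks, used for signature
#'   matching because chained bins can be wider than the match
#'   tolerance), `rel_area` (a sample's relative areas within one digest
#'   sum to 1).
#' @export
bin_peaks <- function(consensus, gap = 1.0) {
  if (gap < 0) abort("gap must be non-negative")
  assert_peak_table(consensus, need_replicate = FALSE)
  consensus |>
    dplyr::group_by(.data$enzyme, .data$label) |>
    dplyr::group_modify(function(df, key) bin_one_digest(df, gap)) |>
    dplyr::ungroup()
}

bin_one_digest <- function(df, gap) {
  df <- dplyr::arrange(df, .data$size_bp)
  brk <- c(0, cumsum(diff(df$size_bp) > gap))
  df$bin <- brk + 1L
  df |>
    dplyr::group_by(.data$bin) |>
    dplyr::mutate(bin_center = mean(.data$size_bp)) |>
    dplyr::group_by(.data$bin, .data$bin_center, .data$sample_id) |>
    dplyr::summarise(sample_size_bp = stats::weighted.mean(.data$size_bp, .data$area),
                     rel_area = sum(.data$area), .groups = "drop")
}

#' Pivot a bin table to a samples-by-bins matrix
#'
#' @param bins Long bin table from [bin_peaks()].
#' @param enzyme,label Digest to extract (defaults: MspI forward, the
#'   fingerprinting digest).
#' @return Wide tibble: `sample_id` plus one numeric column per bin centre.
#' @export
bin_table_wide <- function(bins, enzyme = "MspI", label = "forward") {
  bins |>
    dplyr::filter(.data$enzyme == !!enzyme, .data$label == !!label) |>
    dplyr::mutate(bin_name = sprintf("trf_%.2f", .data$bin_center)) |>
    dplyr::select("sample_id", "bin_name", "rel_area") |>
    tidyr::pivot_wider(names_from = "bin_name", values_from = "rel_area",
                       values_fill = 0)
}

#' Read or write a delimited peak table
#'
#' @param path File path (TSV).
#' @return A peak table tibble.
#' @export
read_peak_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    enzyme = readr::col_character(),
    label = readr::col_character(),
    replicate = readr::col_integer(),
    size_bp = readr::col_double(),
    area = readr::col_double()
  ))
}

#' @rdname read_peak_table
#' @param peaks Peak table tibble.
#' @export
write_peak_table <- function(peaks, path) {
  readr::write_tsv(peaks, path)
  invisible(path)
}
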