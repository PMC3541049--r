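#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join bind_rows n across all_of row_number desc
#' @importFrom tibble tibble as_tibble
NULL

# Derive a reproducible sub-stream seed from a master seed. Kept below 2^31
# so it is always a valid R integer.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 2654435761 + k * 40503) %% 2147483647)
}

# Relative areas within one electropherogram (profile). Profiles with zero
# total area are left at zero rather than producing NaN.
relativize <- function(area) {
  tot <- sum(area)
  if (tot <= 0) return(area * 0)
  area / tot
}

assert_peak_table <- function(peaks, need_replicate = TRUE) {
  needed <- c("sample_id", "enzyme", "label", "size_bp", "area")
  if (need_replicate) needed <- c(needed, "replicate")
  missing <- setdiff(needed, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("peak table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(peaks$size_bp <= 0)) abort("peak sizes must be strictly positive")
  if (any(peaks$area < 0)) abort("peak areas must be non-negative")
  invisible(peaks)
}
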