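#' Match an observed six-slot signature against a phylotype library
#'
#' A library entry matches only if all six slots agree ("six of six"):
#' numeric slots inside the detection window must agree within `tol` bp,
#' while slots that cannot produce an in-window peak (no cut, or a
#' fragment outside the window, however the library spells it) must agree
#' categorically. When several entries match, the nearest by summed
#' absolute slot deviation wins; an exact tie across different group
#' labels is ambiguous and returns unassigned with a warning, whereas a
#' tie among entries of one group (indistinguishable phylotypes of the
#' same bin, which real clone tables do contain) resolves to the first of
#' them.
#'
#' @param observed Named numeric vector over the six signature slots;
#'   `NA` marks a slot with no in-window peak.
#' @param library Signature library tibble
#'   (see [read_signature_library()]).
#' @param tol Match tolerance in bp (default 1.0, the capillary sizing
#'   error scale).
#' @param window Detection window in bp.
#' @return The matching `phylotype_id`, or `NA_character_` when no entry
#'   (or no unambiguous entry) matches.
#' @export
match_signature <- function(observed, library, tol = 1.0,
                            window = c(50, 550)) {
  if (tol < 0) abort("tol must be non-negative")
  slots <- signature_slots()
  if (!all(slots %in% names(observed))) abort("observed must name all six slots")
  obs <- as.numeric(observed[slots])
  obs_cat <- is.na(obs) | obs < window[1] | obs > window[2]

  dev <- rep(NA_real_, nrow(library))
  for (r in seq_len(nrow(library))) {
    lib <- as.numeric(library[r, slots])
    lib_cat <- is.na(lib) | lib < window[1] | lib > window[2]
    if (any(lib_cat != obs_cat)) next
    num <- !lib_cat
    if (any(abs(obs[num] - lib[num]) > tol)) next
    dev[r] <- sum(abs(obs[num] - lib[num]))
  }
  if (all(is.na(dev))) return(NA_character_)
  best <- which(dev == min(dev, na.rm = TRUE))
  if (length(best) > 1) {
    groups <- unique(library$group[best])
    if (length(groups) > 1) {
      warn(paste0("ambiguous signature match among groups ",
                  paste(groups, collapse = ", "), "; left unassigned"),
           class = "fetrflp_ambiguous_match")
      return(NA_character_)
    }
  }
  library$phylotype_id[best[1]]
}

#' Assign binned T-RFs to phylotypes by presence-based six-of-six matching
#'
#' Community fingerprints are read from one digest (by default MspI,
#' forward label); the five companion digests of each sample supply the
#' evidence for the remaining signature slots. For a candidate library
#' entry to explain a bin, every in-window numeric slot of the entry must
#' have a peak within `tol` bp in the sample's corresponding digest; slots
#' the instrument cannot observe (no cut or out-of-window fragments)
#' impose no requirement. This pairing across the six electropherograms of
#' a sample is a reconstruction of manual practice; it is conservative in
#' that one missing companion peak vetoes the assignment.
#'
#' @param bins Long bin table from [bin_peaks()] covering all six digests.
#' @param library Signature library tibble.
#' @param consensus Optional consensus peak table (see
#'   [consensus_duplicates()]); when supplied, companion-slot evidence is
#'   taken from each sample's own consensus peak sizes, which is robust
#'   to cross-sample bin chaining (a single-linkage bin can span several
#'   distinct fragments and its aggregated size then misrepresents each
#'   one). Without it, per-sample bin sizes are used.
#' @param tol Match tolerance in bp.
#' @param window Detection window in bp.
#' @param enzyme,label The fingerprinting digest.
#' @return Long assignment table: `sample_id`, `bin_center`, `rel_area`,
#'   `phylotype_id`, `taxon`, `group` (`NA`s mark unassigned bins).
#' @export
assign_bins <- function(bins, library, consensus = NULL, tol = 1.0,
                        window = c(50, 550),
                        enzyme = "MspI", label = "forward") {
  slots <- signature_slots()
  bins <- dplyr::mutate(
    bins,
    obs_size = if ("sample_size_bp" %in% names(bins)) .data$sample_size_bp
               else .data$bin_center)
  fp <- bins |>
    dplyr::filter(.data$enzyme == !!enzyme, .data$label == !!label,
                  .data$rel_area > 0)
  # per sample, the observed peak positions of every digest
  digest_peaks <- if (!is.null(consensus)) {
    consensus |>
      dplyr::mutate(slot = purrr::map2_chr(.data$enzyme, .data$label, slot_name),
                    obs_size = .data$size_bp) |>
      dplyr::select("sample_id", "slot", "obs_size")
  } else {
    bins |>
      dplyr::filter(.data$rel_area > 0) |>
      dplyr::mutate(slot = purrr::map2_chr(.data$enzyme, .data$label, slot_name)) |>
      dplyr::select("sample_id", "slot", "obs_size")
  }
  fp_slot <- slot_name(enzyme, label)

  assign_one <- function(sample_id, center) {
    dev <- rep(NA_real_, nrow(library))
    sp <- digest_peaks[digest_peaks$sample_id == sample_id, ]
    for (r in seq_len(nrow(library))) {
      lib <- as.numeric(library[r, slots])
      names(lib) <- slots
      lib_cat <- is.na(lib) | lib < window[1] | lib > window[2]
      names(lib_cat) <- slots
      if (lib_cat[[fp_slot]]) next           # cannot explain an observed bin
      if (abs(lib[[fp_slot]] - center) > tol) next
      total <- abs(lib[[fp_slot]] - center)
      ok <- TRUE
      for (s in setdiff(slots, fp_slot)) {
        if (lib_cat[[s]]) next
        cand <- sp$obs_size[sp$slot == s]
        if (length(cand) == 0) { ok <- FALSE; break }
        d <- min(abs(cand - lib[[s]]))
        if (d > tol) { ok <- FALSE; break }
        total <- total + d
      }
      if (ok) dev[r] <- total
    }
    if (all(is.na(dev))) return(NA_integer_)
    best <- which(dev == min(dev, na.rm = TRUE))
    if (length(best) > 1 && length(unique(library$group[best])) > 1) {
      warn(paste0("ambiguous bin assignment at ", round(center, 2),
                  " bp in sample ", sample_id, "; left unassigned"),
           class = "fetrflp_ambiguous_match")
      return(NA_integer_)
    }
    best[1]
  }

  idx <- purrr::map2_int(fp$sample_id, fp$obs_size, assign_one)
  tibble(
    sample_id = fp$sample_id,
    bin_center = fp$bin_center,
    rel_area = fp$rel_area,
    phylotype_id = ifelse(is.na(idx), NA_character_, library$phylotype_id[idx]),
    taxon = ifelse(is.na(idx), NA_character_, library$taxon[idx]),
    group = ifelse(is.na(idx), NA_character_, library$group[idx])
  )
}

#' Collapse phylotype assignments into taxon-group bins
#'
#' Phylotypes sharing a group label (for instance several *Desulfovibrio*
#' species) are combined into a single bin per sample by summing their
#' relative areas; unassigned area is collected into the `unknown` group.
#' Total area is conserved.
#'
#' @param assignments Assignment table from [assign_bins()].
#' @return Long tibble `sample_id`, `group`, `rel_area`.
#' @export
collapse_groups <- function(assignments) {
  assignments |>
    dplyr::mutate(group = ifelse(is.na(.data$group), "unknown", .data$group)) |>
    dplyr::group_by(.data$sample_id, .data$group) |>
    dplyr::summarise(rel_area = sum(.data$rel_area), .groups = "drop")
}

#' Build the samples-by-groups community matrix
#'
#' Convenience composition of [assign_bins()] and [collapse_groups()]
#' returning a wide relative-abundance matrix with an explicit `unknown`
#' column; each row (assigned + unknown) sums to 1.
#'
#' @inheritParams assign_bins
#' @return Wide tibble of class `trf_community`: `sample_id`, one column
#'   per taxon group, and `unknown`. The bin-level assignment table is
#'   attached as attribute `"assignments"`.
#' @export
build_community_matrix <- function(bins, library, consensus = NULL,
                                   tol = 1.0, window = c(50, 550),
                                   enzyme = "MspI", label = "forward") {
  assignments <- assign_bins(bins, library, consensus, tol, window,
                             enzyme, label)
  long <- collapse_groups(assignments)
  wide <- long |>
    tidyr::pivot_wider(names_from = "group", values_from = "rel_area",
                       values_fill = 0)
  if (!"unknown" %in% names(wide)) wide$unknown <- 0
  wide <- dplyr::relocate(wide, "unknown", .after = dplyr::last_col())
  attr(wide, "assignments") <- assignments
  class(wide) <- c("trf_community", class(wide))
  wide
}
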