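#' Restriction enzymes used for community fingerprinting
#'
#' The three tetrameric-recognition enzymes used to digest dual-end-labelled
#' 16S rRNA amplicons. Each enzyme has a palindromic recognition sequence and
#' a cut offset, the number of bases from the recognition-site start to the
#' cut position on the labelled strand: MspI cuts C^CGG (offset 1), HaeIII
#' GG^CC (offset 2) and HhaI GCG^C (offset 3).
#'
#' @param names Optional character vector restricting the returned set.
#' @return A tibble with columns `enzyme`, `recognition` and `cut_offset`.
#' @examples
#' trf_enzymes()
#' @export
trf_enzymes <- function(names = NULL) {
  tbl <- tibble(
    enzyme      = c("MspI", "HhaI", "HaeIII"),
    recognition = c("CCGG", "GCGC", "GGCC"),
    cut_offset  = c(1L, 3L, 2L)
  )
  if (!is.null(names)) {
    unknown <- setdiff(names, tbl$enzyme)
    if (length(unknown) > 0) {
      abort(paste0("unknown enzyme(s): ", paste(unknown, collapse = ", ")))
    }
    tbl <- tbl[match(names, tbl$enzyme), ]
  }
  tbl
}

#' Amplification primer pair
#'
#' Default near-full-length 16S primers: 8F (labelled HEX on the forward
#' fragment end) and 1492R (labelled FAM). The reverse primer is written
#' 5'->3' on the reverse strand; it is matched as its reverse complement on
#' the forward strand. Primers may contain IUPAC degeneracy codes.
#'
#' @param forward,reverse Primer sequences, 5'->3'.
#' @param max_mismatches Number of mismatches tolerated when locating a
#'   primer binding site. Defaults to 0, appropriate for synthetic work.
#' @return A list of class `trf_primers`.
#' @examples
#' trf_primers()
#' @export
trf_primers <- function(forward = "AGAGTTTGATCCTGGCTCAG",
                        reverse = "GGTTACCTTGTTACGACTT",
                        max_mismatches = 0L) {
  if (!nzchar(forward) || !nzchar(reverse)) abort("primers must be non-empty")
  ok <- grepl("^[ACGTRYSWKMBDHVN]+$", c(forward, reverse))
  if (!all(ok)) abort("primers must use IUPAC nucleotide codes")
  if (max_mismatches < 0) abort("max_mismatches must be >= 0")
  structure(
    list(forward = forward, reverse = reverse,
         max_mismatches = as.integer(max_mismatches)),
    class = "trf_primers"
  )
}

# The six signature slots, in the column order of the clone-library table:
# forward (HEX) fragments for MspI, HhaI, HaeIII, then reverse (FAM).
signature_slots <- function() {
  c("mspi_fwd", "hhai_fwd", "haeiii_fwd", "mspi_rev", "hhai_rev", "haeiii_rev")
}

slot_name <- function(enzyme, label) {
  paste0(c(MspI = "mspi", HhaI = "hhai", HaeIII = "haeiii")[[enzyme]],
         ifelse(label == "forward", "_fwd", "_rev"))
}
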