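#' Locate the amplified region of a sequence
#'
#' Finds the forward primer and the reverse-complemented reverse primer on
#' the forward strand (IUPAC-aware, allowing up to `max_mismatches`
#' substitutions) and returns the spanned amplicon: from the start of the
#' forward primer through the end of the reverse-primer binding site.
#'
#' @param sequence A single nucleotide string.
#' @param primers A [trf_primers()] object.
#' @return A one-row tibble with `amplicon`, and 0-based half-open
#'   coordinates `start` and `end` on the input sequence.
#' @examples
#' p <- trf_primers()
#' seq <- paste0(p$forward, strrep("A", 60),
#'               as.character(Biostrings::reverseComplement(Biostrings::DNAString(p$reverse))))
#' locate_amplicon(seq, p)
#' @export
locate_amplicon <- function(sequence, primers = trf_primers()) {
  if (!is.character(sequence) || length(sequence) != 1 || !nzchar(sequence)) {
    abort("sequence must be a single non-empty string")
  }
  subject <- Biostrings::DNAString(sequence)
  fwd <- Biostrings::DNAString(primers$forward)
  rev <- Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse))

  hit_f <- Biostrings::matchPattern(
    fwd, subject, max.mismatch = primers$max_mismatches,
    fixed = c(pattern = FALSE, subject = TRUE))
  if (length(hit_f) == 0) {
    abort("sequence is not amplifiable: no forward-primer binding site found",
          class = "fetrflp_not_amplifiable")
  }
  f_start <- Biostrings::start(hit_f)[1]

  hit_r <- Biostrings::matchPattern(
    rev, subject, max.mismatch = primers$max_mismatches,
    fixed = c(pattern = FALSE, subject = TRUE))
  hit_r <- hit_r[Biostrings::start(hit_r) > f_start + length(fwd) - 1]
  if (length(hit_r) == 0) {
    abort("sequence is not amplifiable: no reverse-primer binding site found",
          class = "fetrflp_not_amplifiable")
  }
  r_end <- Biostrings::end(hit_r)[length(hit_r)]

  tibble(
    amplicon = as.character(Biostrings::subseq(subject, f_start, r_end)),
    start = f_start - 1L,
    end = r_end
  )
}

#' Terminal restriction fragment length of an amplicon
#'
#' The labelled terminal fragment produced by a restriction digest: the
#' distance from the labelled amplicon end to the first cut site. For
#' `label = "forward"` this is the 0-based start of the first recognition
#' site plus the enzyme's cut offset; for `label = "reverse"` the same
#' computation is performed on the reverse complement of the amplicon.
#'
#' @param amplicon Amplicon sequence in forward orientation.
#' @param enzyme An enzyme name (`"MspI"`, `"HhaI"`, `"HaeIII"`) or a
#'   one-row tibble as returned by [trf_enzymes()].
#' @param label `"forward"` or `"reverse"`: which labelled end is measured.
#' @return Fragment length in bp, or `NA` when the recognition sequence is
#'   absent (no cut).
#' @examples
#' terminal_fragment("CCGGAAAA", "MspI", "forward")  # 1
#' terminal_fragment("AAAAACCGGTTTT", "MspI", "forward")  # 6
#' @export
terminal_fragment <- function(amplicon, enzyme, label = c("forward", "reverse")) {
  label <- match.arg(label)
  if (!is.character(amplicon) || length(amplicon) != 1 || !nzchar(amplicon)) {
    abort("amplicon must be a single non-empty string")
  }
  if (is.character(enzyme)) enzyme <- trf_enzymes(enzyme)
  subject <- Biostrings::DNAString(amplicon)
  if (label == "reverse") subject <- Biostrings::reverseComplement(subject)
  hits <- Biostrings::matchPattern(enzyme$recognition, subject)
  if (length(hits) == 0) return(NA_real_)
  (Biostrings::start(hits)[1] - 1) + enzyme$cut_offset
}

#' Six-slot digest signature of a phylotype
#'
#' Runs [locate_amplicon()] then [terminal_fragment()] for the three default
#' enzymes at both labelled ends, producing the six fragment lengths that
#' identify a phylotype (`NA` marks a missing cut).
#'
#' @param sequence A nucleotide string containing the amplifiable region.
#' @param primers A [trf_primers()] object.
#' @param enzymes Enzyme tibble; defaults to [trf_enzymes()].
#' @return A named numeric vector over the six slots
#'   (`mspi_fwd`, `hhai_fwd`, `haeiii_fwd`, `mspi_rev`, `hhai_rev`,
#'   `haeiii_rev`), lengths in bp or `NA` for no cut.
#' @export
trf_signature <- function(sequence, primers = trf_primers(),
                          enzymes = trf_enzymes()) {
  amp <- locate_amplicon(sequence, primers)$amplicon
  out <- numeric(0)
  for (lab in c("forward", "reverse")) {
    for (i in seq_len(nrow(enzymes))) {
      out[slot_name(enzymes$enzyme[i], lab)] <-
        terminal_fragment(amp, enzymes[i, ], lab)
    }
  }
  out[signature_slots()]
}

#' In silico digestion of a phylotype library
#'
#' @param phylotypes A tibble with columns `phylotype_id` and `sequence`
#'   (additional columns such as `taxon` and `group` are carried through),
#'   or a path to a FASTA file.
#' @param primers A [trf_primers()] object.
#' @return The input annotation joined with the six signature columns.
#' @export
digest_phylotypes <- function(phylotypes, primers = trf_primers()) {
  if (is.character(phylotypes)) phylotypes <- read_phylotypes(phylotypes)
  if (!all(c("phylotype_id", "sequence") %in% names(phylotypes))) {
    abort("phylotypes needs columns phylotype_id and sequence")
  }
  sig <- purrr::map(phylotypes$sequence, trf_signature, primers = primers)
  sig <- as_tibble(do.call(rbind, sig))
  dplyr::bind_cols(dplyr::select(phylotypes, -"sequence"), sig)
}

#' Read or write a phylotype FASTA file
#'
#' @param path File path.
#' @return `read_phylotypes()` returns a tibble with `phylotype_id` and
#'   `sequence`.
#' @export
read_phylotypes <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  tibble(phylotype_id = names(set), sequence = as.character(set))
}

#' @rdname read_phylotypes
#' @param phylotypes Tibble with `phylotype_id` and `sequence`.
#' @export
write_phylotypes <- function(phylotypes, path) {
  set <- Biostrings::DNAStringSet(phylotypes$sequence)
  names(set) <- phylotypes$phylotype_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read or write a signature library TSV
#'
#' The library format mirrors the clone table of a study: one row per
#' phylotype with `phylotype_id`, `taxon`, `group` and the six fragment
#' columns. Tokens `NC` (no cut) and `<50` (below the detection window) are
#' both read as `NA`; numeric values outside the export window are kept as
#' printed and handled categorically at match time.
#'
#' @param path File path.
#' @return A signature library tibble.
#' @export
read_signature_library <- function(path) {
  lib <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  for (s in signature_slots()) {
    if (!s %in% names(lib)) abort(paste0("library lacks slot column ", s))
    v <- lib[[s]]
    v[v %in% c("NC", "<50")] <- NA
    lib[[s]] <- suppressWarnings(as.numeric(v))
  }
  if (anyDuplicated(lib$phylotype_id)) abort("phylotype_ids must be unique")
  lib
}

#' @rdname read_signature_library
#' @param library A signature library tibble.
#' @export
write_signature_library <- function(library, path) {
  out <- library
  for (s in signature_slots()) {
    v <- as.character(out[[s]])
    v[is.na(v)] <- "NC"
    out[[s]] <- v
  }
  readr::write_tsv(out, path)
  invisible(path)
}
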