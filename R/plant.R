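#' Construct an amplicon sequence with a planted digest signature
#'
#' Builds a synthetic amplicon whose in silico digestion reproduces a
#' requested six-slot signature exactly. The sequence begins with the
#' forward primer and ends with the reverse complement of the reverse
#' primer; background bases are drawn uniformly over A/C/G/T with rejection
#' of any accidental recognition site, so the planted sites are guaranteed
#' to be the first (and last) site of their enzyme.
#'
#' Because all three recognition sequences are palindromic, any cut site
#' produces a terminal fragment at *both* labelled ends: a target that
#' requests a numeric fragment for one end of an enzyme and no-cut for the
#' other is geometrically impossible and raises an infeasibility error
#' naming the offending slots, as does any pair of planted sites that would
#' have to write contradictory bases at a shared position.
#'
#' @param target Named numeric vector over the six signature slots (see
#'   [trf_signature()]); `NA` requests no cut for that enzyme (both slots).
#' @param amplicon_length Total amplicon length in bp (default 1450,
#'   approximately the 8F-1492R span).
#' @param seed Integer seed; the construction is deterministic given
#'   `target` and `seed`.
#' @param primers A [trf_primers()] object.
#' @param max_tries Fresh background fills attempted before giving up.
#' @return A one-row tibble with `sequence` (and `length`).
#' @examples
#' tgt <- c(mspi_fwd = 164, hhai_fwd = 93, haeiii_fwd = 217,
#'          mspi_rev = 126, hhai_rev = 405, haeiii_rev = 124)
#' seq <- plant_signature(tgt, 1450, seed = 1)$sequence
#' stopifnot(identical(unname(trf_signature(seq)), unname(tgt)))
#' @export
plant_signature <- function(target, amplicon_length = 1450, seed = 1,
                            primers = trf_primers(), max_tries = 50) {
  L <- as.integer(amplicon_length)
  enz <- trf_enzymes()
  slots <- signature_slots()
  if (!all(slots %in% names(target))) {
    abort(paste0("target must name all six slots: ", paste(slots, collapse = ", ")))
  }
  target <- target[slots]

  fwd <- primers$forward
  rev_rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(primers$reverse)))
  n_fwd <- nchar(fwd)
  n_rev <- nchar(rev_rc)
  if (L < n_fwd + n_rev + 8) abort("amplicon_length too short for the primer pair")

  # Resolve each enzyme's first/last site positions (0-based starts).
  sites <- list()
  for (i in seq_len(nrow(enz))) {
    e <- enz$enzyme[i]; off <- enz$cut_offset[i]; w <- nchar(enz$recognition[i])
    f <- target[[slot_name(e, "forward")]]
    r <- target[[slot_name(e, "reverse")]]
    if (is.na(f) && is.na(r)) next
    if (is.na(f) || is.na(r)) {
      abort(paste0("infeasible target: ", e, " recognition is palindromic, so ",
                   "slots ", slot_name(e, "forward"), " and ", slot_name(e, "reverse"),
                   " must be both numeric or both no-cut"),
            class = "fetrflp_infeasible")
    }
    if (f != round(f) || r != round(r)) {
      abort("fragment lengths must be whole base pairs", class = "fetrflp_infeasible")
    }
    p1 <- as.integer(f) - off            # first site start, 0-based
    p2 <- L - w - (as.integer(r) - off)  # last site start, 0-based
    if (p1 < n_fwd || p2 + w > L - n_rev || p1 > p2) {
      abort(paste0("infeasible target: ", e, " fragments ", f, "/", r,
                   " place sites outside the fillable region or out of order"),
            class = "fetrflp_infeasible")
    }
    starts <- unique(c(p1, p2))
    sites[[e]] <- tibble(enzyme = e, start = starts,
                         recognition = enz$recognition[i])
  }
  sites <- if (length(sites) > 0) dplyr::bind_rows(sites) else
    tibble(enzyme = character(), start = integer(), recognition = character())

  # Write fixed bases: primers, then planted recognition sites; detect
  # contradictory overlaps.
  chars <- rep(NA_character_, L)
  fixed <- rep(FALSE, L)
  chars[1:n_fwd] <- strsplit(fwd, "")[[1]];           fixed[1:n_fwd] <- TRUE
  chars[(L - n_rev + 1):L] <- strsplit(rev_rc, "")[[1]]
  fixed[(L - n_rev + 1):L] <- TRUE
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      pos <- sites$start[i] + seq_len(nchar(sites$recognition[i]))  # 1-based
      bases <- strsplit(sites$recognition[i], "")[[1]]
      clash <- fixed[pos] & !is.na(chars[pos]) & chars[pos] != bases
      if (any(clash)) {
        abort(paste0("infeasible target: planted ", sites$enzyme[i],
                     " site at position ", sites$start[i],
                     " conflicts with previously fixed bases"),
              class = "fetrflp_infeasible")
      }
      chars[pos] <- bases
      fixed[pos] <- TRUE
    }
  }
  # Occurrences between an enzyme's first and last planted site are
  # harmless (they change neither terminal fragment); only sites outside
  # that span are spurious.
  allowed <- lapply(split(sites$start, sites$enzyme), range)

  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      s <- chars
      free <- !fixed
      s[free] <- sample(c("A", "C", "G", "T"), sum(free), replace = TRUE)
      if (scrub_sites(s, free, enz, allowed, environment())) {
        seq <- paste(s, collapse = "")
        got <- trf_signature(seq, primers)
        if (isTRUE(all.equal(unname(got), unname(target)))) {
          return(tibble(sequence = seq, length = L))
        }
      }
    }
  })
  abort("could not realise the requested signature; try another seed",
        class = "fetrflp_infeasible")
}

# Remove accidental recognition sites from the candidate sequence by
# re-drawing free bases inside spurious windows; mutates `s` in `env`.
scrub_sites <- function(s, free, enz, allowed, env) {
  for (pass in 1:200) {
    dirty <- FALSE
    for (i in seq_len(nrow(enz))) {
      pat <- strsplit(enz$recognition[i], "")[[1]]
      w <- length(pat)
      L <- length(s)
      hit <- rep(TRUE, L - w + 1)
      for (j in seq_len(w)) hit <- hit & s[j:(L - w + j)] == pat[j]
      starts0 <- which(hit) - 1L  # 0-based
      span <- allowed[[enz$enzyme[i]]]
      spurious <- if (is.null(span)) starts0 else
        starts0[starts0 < span[1] | starts0 > span[2]]
      for (p in spurious) {
        idx <- p + seq_len(w)  # 1-based window
        mut <- idx[free[idx]]
        if (length(mut) == 0) return(FALSE)  # fully fixed spurious site
        s[mut[1]] <- sample(setdiff(c("A", "C", "G", "T"), s[mut[1]]), 1)
        dirty <- TRUE
      }
    }
    if (!dirty) {
      assign("s", s, envir = env)
      return(TRUE)
    }
  }
  FALSE
}

#' Draw a random feasible digest signature
#'
#' Generates a six-slot target that [plant_signature()] can realise: for
#' each enzyme either both slots are no-cut, or a first and last site are
#' placed in the fillable region (possibly coinciding) and converted to the
#' corresponding forward/reverse fragment lengths. Cross-enzyme base
#' conflicts are avoided by rejection.
#'
#' @param amplicon_length Amplicon length in bp.
#' @param p_nocut Probability that an enzyme has no site at all.
#' @param primers A [trf_primers()] object.
#' @return Named numeric vector over the six slots.
#' @export
random_feasible_signature <- function(amplicon_length = 1450, p_nocut = 0.25,
                                      primers = trf_primers()) {
  L <- as.integer(amplicon_length)
  enz <- trf_enzymes()
  n_fwd <- nchar(primers$forward)
  n_rev <- nchar(primers$reverse)
  pick <- function(x) x[sample.int(length(x), 1)]
  for (try in 1:200) {
    tgt <- stats::setNames(rep(NA_real_, 6), signature_slots())
    occupied <- integer(0)
    ok <- TRUE
    for (i in seq_len(nrow(enz))) {
      if (stats::runif(1) < p_nocut) next
      w <- nchar(enz$recognition[i]); off <- enz$cut_offset[i]
      lo <- n_fwd; hi <- L - n_rev - w
      # keep planted windows at least three free bases apart: two fixed
      # windows closer than that can embed a spurious, unscrubbable site
      # of another enzyme (e.g. GGCCGGCC contains CCGG)
      clear <- function(p) length(intersect((p - 3):(p + w + 2), occupied)) == 0
      p1 <- pick(lo:hi)
      if (!clear(p1)) { ok <- FALSE; break }
      occupied <- c(occupied, p1 + 0:(w - 1))
      cand2 <- c(p1, Filter(clear, if (p1 + w + 3 <= hi) (p1 + w + 3):hi else integer(0)))
      p2 <- pick(cand2)
      if (p2 != p1) occupied <- c(occupied, p2 + 0:(w - 1))
      tgt[slot_name(enz$enzyme[i], "forward")] <- p1 + off
      tgt[slot_name(enz$enzyme[i], "reverse")] <- L - w - p2 + off
    }
    if (ok) return(tgt)
  }
  abort("failed to draw a feasible signature")
}
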