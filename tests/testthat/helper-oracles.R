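# Independent oracles used to cross-check the implementation. These are
# deliberately naive (string scans, explicit member enumeration) and share
# no code with the package internals.

# Enumerate every recognition-site occurrence by a sliding substring scan
# and derive the terminal fragment from the first one.
oracle_terminal_fragment <- function(amplicon, recognition, cut_offset,
                                     label = "forward") {
  revcomp <- function(s) {
    map <- c(A = "T", C = "G", G = "C", T = "A")
    paste(rev(unname(map[strsplit(s, "")[[1]]])), collapse = "")
  }
  if (label == "reverse") amplicon <- revcomp(amplicon)
  w <- nchar(recognition)
  n <- nchar(amplicon)
  if (n < w) return(NA_real_)
  starts <- which(vapply(seq_len(n - w + 1), function(i) {
    substr(amplicon, i, i + w - 1) == recognition
  }, logical(1)))
  if (length(starts) == 0) return(NA_real_)
  (starts[1] - 1) + cut_offset
}

# Brute-force UPGMA: merge the closest pair, recomputing inter-cluster
# distances as plain means over all member pairs of the ORIGINAL matrix.
# Returns the cophenetic matrix of merge heights.
oracle_upgma_cophenetic <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        dij <- mean(D[clusters[[i]], clusters[[j]]])
        if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Kruskal-Wallis H by direct evaluation of the rank formula with midrank
# ties and the tie correction.
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)  # midranks
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) sum(x)^2 / length(x))) - 3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

# A quick random profile generator for property-style tests.
random_profile <- function(n, seed, sample_id = "S", enzyme = "MspI",
                           label = "forward", replicate = 1L) {
  withr::with_seed(seed, tibble::tibble(
    sample_id = sample_id, enzyme = enzyme, label = label,
    replicate = replicate,
    size_bp = sort(runif(n, 40, 560)),
    area = rexp(n)
  ))
}

slot_names6 <- c("mspi_fwd", "hhai_fwd", "haeiii_fwd",
                 "mspi_rev", "hhai_rev", "haeiii_rev")

as_signature <- function(...) {
  v <- c(...)
  stats::setNames(as.numeric(v), slot_names6)
}

geobacter_signature <- function() as_signature(164, 93, 217, 126, 405, 124)
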