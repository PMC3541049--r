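#' Bray-Curtis dissimilarity between samples
#'
#' BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over the feature columns of
#' a samples-by-features relative-abundance table, computed with
#' `vegan::vegdist()`. A pair of all-zero samples is defined to have
#' dissimilarity 0.
#'
#' @param comm Wide tibble (e.g. from [build_community_matrix()] or
#'   [bin_table_wide()]): one row per sample, a `sample_id` column and
#'   numeric feature columns.
#' @param sample_col Name of the sample identifier column.
#' @return A `dist` object labelled by sample.
#' @examples
#' m <- tibble::tibble(sample_id = c("a", "b"), x = c(1, 3), y = c(3, 1))
#' bray_curtis(m)  # 0.5
#' @export
bray_curtis <- function(comm, sample_col = "sample_id") {
  x <- as.matrix(comm[setdiff(names(comm), sample_col)])
  if (!is.numeric(x)) abort("feature columns must be numeric")
  if (any(x < 0)) abort("abundances must be non-negative")
  rownames(x) <- comm[[sample_col]]
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  d[is.nan(d)] <- 0  # pairs of empty samples
  d
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering in which the distance between clusters is the
#' unweighted mean of member pairwise dissimilarities, yielding an
#' ultrametric merge tree whose node heights are cophenetic
#' dissimilarities.
#'
#' @param d A `dist` object, n >= 2.
#' @return An object of class `trf_upgma` (an `hclust` with the input
#'   dissimilarities attached), usable with [cut_dendrogram()],
#'   [cophenetic_correlation()], [export_newick()], [generics::tidy()] and
#'   [ggplot2::autoplot()].
#' @export
upgma <- function(d) {
  if (!inherits(d, "dist")) abort("d must be a dist object")
  if (attr(d, "Size") < 2) abort("clustering needs at least two samples")
  hc <- stats::hclust(d, method = "average")
  attr(hc, "dissimilarity") <- d
  class(hc) <- c("trf_upgma", "hclust")
  hc
}

#' Cophenetic correlation of a dendrogram
#'
#' Pearson correlation between the input pairwise dissimilarities and the
#' cophenetic dissimilarities (the merge height at which each leaf pair
#' first joins). Values near 1 indicate the tree faithfully represents
#' the dissimilarity structure; an ultrametric input gives exactly 1.
#'
#' @param d A `dist` object, n >= 3.
#' @param tree A tree from [upgma()] built over the same labels.
#' @return Correlation in \[-1, 1\].
#' @export
cophenetic_correlation <- function(d, tree) {
  if (attr(d, "Size") < 3) abort("cophenetic correlation needs at least three samples")
  dm <- as.matrix(d)
  cm <- as.matrix(stats::cophenetic(tree))
  if (!setequal(rownames(dm), rownames(cm))) abort("tree labels do not match d")
  cm <- cm[rownames(dm), rownames(dm)]
  ut <- upper.tri(dm)
  stats::cor(dm[ut], cm[ut])
}

#' Cut a dendrogram at a dissimilarity height
#'
#' Removes merges higher than `h` and returns the connected components:
#' samples joined at cophenetic dissimilarity <= `h` share a cluster.
#'
#' @param tree A tree from [upgma()].
#' @param h Cut height (e.g. 0.7 on the Bray-Curtis scale).
#' @return Tibble `sample_id`, `cluster`.
#' @export
cut_dendrogram <- function(tree, h) {
  if (h < 0) abort("cut height must be non-negative")
  cl <- stats::cutree(stats::as.hclust(tree), h = h)
  tibble(sample_id = names(cl), cluster = unname(cl))
}

#' Kruskal-Wallis rank-sum test
#'
#' Non-parametric one-way analysis over a grouping factor, with midrank
#' ties and the standard tie correction; the p-value uses the chi-square
#' approximation on k - 1 degrees of freedom. A thin tibble-in/tibble-out
#' wrapper around `stats::kruskal.test()`.
#'
#' @param data Data frame holding the response and grouping columns.
#' @param value,group Column names (tidyselect) of the response values and
#'   group labels.
#' @return One-row tibble: `statistic` (H), `df`, `p_value`.
#' @examples
#' d <- tibble::tibble(y = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
#' kruskal_wallis(d, y, g)  # H = 3.857, p = 0.0495
#' @export
kruskal_wallis <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- as.factor(dplyr::pull(data, {{ group }}))
  if (nlevels(droplevels(g)) < 2) abort("kruskal_wallis needs at least two groups")
  ht <- stats::kruskal.test(v, g)
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value)
}

#' Export a dendrogram as Newick
#'
#' Writes the merge tree with heights encoded as branch lengths, readable
#' by any phylogenetics tool.
#'
#' @param tree A tree from [upgma()].
#' @param path Output file path.
#' @export
export_newick <- function(tree, path) {
  ape::write.tree(ape::as.phylo(stats::as.hclust(tree)), file = path)
  invisible(path)
}

#' @export
tidy.trf_upgma <- function(x, ...) {
  tibble(
    merge = seq_along(x$height),
    height = x$height,
    left = x$merge[, 1],
    right = x$merge[, 2]
  )
}

#' @export
glance.trf_upgma <- function(x, ...) {
  d <- attr(x, "dissimilarity")
  tibble(
    n_samples = length(x$labels),
    max_height = max(x$height),
    cophenetic_correlation =
      if (!is.null(d) && attr(d, "Size") >= 3) cophenetic_correlation(d, x)
      else NA_real_
  )
}
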