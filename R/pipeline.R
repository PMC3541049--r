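#' Configuration for an end-to-end pipeline run
#'
#' Collects the master seed and every stage parameter in one flat list.
#' All randomness flows from `seed` through per-stage derived seeds, so a
#' config determines every numeric output exactly.
#'
#' @param seed Master integer seed.
#' @param out_dir Output directory (created if needed).
#' @param window Export window in bp.
#' @param k Signal/noise threshold multiplier.
#' @param consensus_tol Replicate matching tolerance in bp.
#' @param gap Binning gap in bp.
#' @param match_tol Signature match tolerance in bp.
#' @param cut_height Dendrogram cut height (Bray-Curtis scale).
#' @param fe_threshold Selection threshold in percent Fe reduced.
#' @param concentration Dirichlet concentration for community draws.
#' @param noise A [noise_spec()].
#' @return A list of class `trflp_config`.
#' @export
trflp_config <- function(seed = 1, out_dir = tempfile("trflp_run_"),
                         window = c(50, 550), k = 3, consensus_tol = 0.5,
                         gap = 1.0, match_tol = 1.0, cut_height = 0.7,
                         fe_threshold = 10, concentration = 1,
                         noise = noise_spec()) {
  stopifnot(length(window) == 2, window[1] <= window[2], k > 0,
            consensus_tol >= 0, gap >= 0, match_tol >= 0, cut_height >= 0)
  structure(list(seed = as.integer(seed), out_dir = out_dir, window = window,
                 k = k, consensus_tol = consensus_tol, gap = gap,
                 match_tol = match_tol, cut_height = cut_height,
                 fe_threshold = fe_threshold, concentration = concentration,
                 noise = noise),
            class = "trflp_config")
}

#' Run the full fingerprinting-and-geochemistry pipeline
#'
#' Executes the stage sequence simulate -> digest -> process -> assign ->
#' cluster -> stats -> geochem, writing every intermediate to
#' `config$out_dir` in plain-text formats (FASTA, TSV, Newick, YAML) and
#' returning the in-memory results. Identical configs produce
#' byte-identical numeric outputs.
#'
#' @param config A [trflp_config()].
#' @return Invisibly, a list with the stage results and `manifest` (also
#'   written as `manifest.yml`).
#' @export
run_trflp_pipeline <- function(config = trflp_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  note <- function(stage, f) { files[stage] <<- f; f }

  # simulate
  st <- simulate_study(seed = config$seed,
                       concentration = config$concentration,
                       noise = config$noise)
  write_phylotypes(st$phylotypes, note("phylotypes", path("phylotypes.fasta")))
  write_peak_table(st$profiles, note("peaks", path("peaks.tsv")))
  readr::write_tsv(st$metadata, note("metadata", path("metadata.tsv")))
  grid <- generate_fe_grid(seed = derive_seed(config$seed, 77))
  write_enrichment_table(grid, note("enrichments", path("enrichments.tsv")))

  # digest
  library_tbl <- clone_signatures()
  write_signature_library(
    digest_phylotypes(dplyr::select(st$phylotypes, "phylotype_id", "taxon",
                                    "group", "sequence")),
    note("signatures", path("signatures.tsv")))

  # process
  consensus <- st$profiles |>
    export_window(config$window[1], config$window[2]) |>
    denoise_peaks(config$k) |>
    consensus_duplicates(config$consensus_tol)
  bins <- bin_peaks(consensus, config$gap)
  readr::write_tsv(bins, note("bins", path("bins.tsv")))

  # assign
  comm <- build_community_matrix(bins, library_tbl, consensus,
                                 tol = config$match_tol,
                                 window = config$window)
  readr::write_tsv(comm, note("community", path("community_matrix.tsv")))

  # cluster
  fingerprints <- bin_table_wide(bins)
  d <- bray_curtis(fingerprints)
  tree <- upgma(d)
  export_newick(tree, note("dendrogram", path("dendrogram.nwk")))
  clusters <- cut_dendrogram(tree, config$cut_height) |>
    dplyr::left_join(st$metadata, by = "sample_id")
  readr::write_tsv(clusters, note("clusters", path("clusters.tsv")))

  # stats
  groups <- setdiff(names(comm), c("sample_id", "unknown"))
  kw <- purrr::map(groups, function(g) {
    df <- dplyr::left_join(comm[, c("sample_id", g)], st$metadata,
                           by = "sample_id")
    dplyr::mutate(kruskal_wallis(df, !!rlang::sym(g), "carbon"), group = g,
                  .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(kw, note("kruskal", path("kruskal_carbon.tsv")))

  # geochem
  sel <- select_reduced(grid, config$fe_threshold)
  readr::write_tsv(sel$by_mineral, note("selection", path("selection_by_mineral.tsv")))
  readr::write_tsv(sel$by_carbon, path("selection_by_carbon.tsv"))
  yields <- free_energy_yields()
  readr::write_tsv(yields, note("thermo", path("free_energy_yields.tsv")))

  manifest <- list(
    package = "fetrflp",
    version = as.character(utils::packageVersion("fetrflp")),
    seed = config$seed,
    parameters = list(window = config$window, k = config$k,
                      consensus_tol = config$consensus_tol, gap = config$gap,
                      match_tol = config$match_tol,
                      cut_height = config$cut_height,
                      fe_threshold = config$fe_threshold,
                      concentration = config$concentration,
                      noise = unclass(config$noise)),
    outputs = as.list(files)
  )
  yaml::write_yaml(manifest, path("manifest.yml"))

  invisible(list(study = st, grid = grid, consensus = consensus, bins = bins,
                 community = comm, dissimilarity = d, tree = tree,
                 clusters = clusters, kruskal = kw, selection = sel,
                 yields = yields, manifest = manifest))
}
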