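#' Bundled clone-library signature table
#'
#' Six-slot digest signatures of 16S rRNA clones sequenced from
#' Fe(III)-reducing sediment enrichments, with genus/family-level taxon
#' and group labels. Tokens `NC` and `<50` in the shipped TSV are read as
#' unobservable slots.
#'
#' @return A signature library tibble (see [read_signature_library()]).
#' @export
clone_signatures <- function() {
  read_signature_library(
    system.file("extdata", "clone_signatures.tsv", package = "fetrflp"))
}

#' Synthetic study phylotypes with carbon-source-specific pools
#'
#' Nine phylotypes drawn from the clone library, three per carbon pool
#' (acetate: Geobacter, Desulfobacter, Firmicutes; lactate:
#' Desulfovibrio, Actinobacteria, Geothrix; glucose: Enterobacteriaceae,
#' Bacteroidetes, Chloroflexi), chosen so that (i) every six-slot
#' signature is exactly plantable (the Spirochaetes clone, whose 210/210
#' MspI+HaeIII forward pair would require two recognition sites to write
#' contradictory bases at a shared position, is excluded), (ii) groups
#' are disjoint across pools, and (iii) fingerprint (MspI forward)
#' fragments of different pools differ by more than the binning gap, so
#' carbon pools do not share fingerprint bins. The Bacteroidetes
#' below-window HaeIII forward fragment is planted at a concrete 40 bp.
#'
#' @return Tibble `phylotype_id`, `taxon`, `group`, `carbon_pool` and the
#'   six planted slot values (`NA` = no cut).
#' @export
study_phylotypes <- function() {
  tibble::tribble(
    ~phylotype_id, ~group, ~carbon_pool,
    ~mspi_fwd, ~hhai_fwd, ~haeiii_fwd, ~mspi_rev, ~hhai_rev, ~haeiii_rev,
    "AP-FeEnrich17", "Geobacter",          "acetate", 164, 93, 217, 126, 405, 124,
    "AP-FeEnrich12", "Desulfobacter",      "acetate", 515, 95, 209, 127, 405, 125,
    "AP-FeEnrich9",  "Firmicutes",         "acetate", 216, 371, NA, 127, 401, NA,
    "AP-FeEnrich14", "Desulfovibrio",      "lactate", 457, 95, 201, 127, 142, 123,
    "AP-FeEnrich2",  "Actinobacteria",     "lactate", 172, 284, 229, 128, 45, 69,
    "AP-FeEnrich1",  "Geothrix",           "lactate", 278, 359, 201, 92, 380, 125,
    "AP-FeEnrich21", "Enterobacteriaceae", "glucose", 493, 373, 206, 127, 49, 123,
    "AP-FeEnrich6",  "Bacteroidetes",      "glucose", 95, 100, 40, 120, 135, 116,
    "AP-FeEnrich7",  "Chloroflexi",        "glucose", 159, 536, 220, 76, 390, 125
  ) |>
    dplyr::mutate(taxon = .data$group, .after = "phylotype_id")
}

#' Simulate a complete enrichment fingerprinting study
#'
#' Generates the full synthetic dataset of a carbon x mineral x dilution
#' enrichment campaign: phylotype sequences with planted signatures,
#' Dirichlet community compositions for 3 carbons x 3 minerals x
#' `n_dilutions` samples where each carbon source selects its own
#' three-taxon pool, and duplicate six-digest electropherograms per
#' sample under the given noise model. Everything derives from one master
#' seed.
#'
#' @param seed Master integer seed.
#' @param n_dilutions Decimal dilutions per carbon x mineral series
#'   (default 5, giving 45 samples).
#' @param concentration Dirichlet concentration for community draws.
#' @param noise A [noise_spec()].
#' @param amplicon_length Planted amplicon length in bp.
#' @return List with `phylotypes` (tibble incl. `sequence`), `signatures`
#'   (in silico digest of the planted sequences), `metadata` (`sample_id`,
#'   `carbon`, `mineral`, `dilution_exponent`), `truth` (planted
#'   abundances per sample) and `profiles` (raw peak table).
#' @export
simulate_study <- function(seed = 1, n_dilutions = 5, concentration = 1,
                           noise = noise_spec(), amplicon_length = 1450) {
  pool <- study_phylotypes()
  seqs <- purrr::map_chr(seq_len(nrow(pool)), function(i) {
    tgt <- as.numeric(pool[i, signature_slots()])
    names(tgt) <- signature_slots()
    plant_signature(tgt, amplicon_length, seed = derive_seed(seed, 100 + i))$sequence
  })
  phylotypes <- dplyr::mutate(pool, sequence = seqs)
  signatures <- digest_phylotypes(
    dplyr::select(phylotypes, "phylotype_id", "taxon", "group",
                  "carbon_pool", "sequence")
  )

  metadata <- tidyr::expand_grid(
    carbon = c("acetate", "lactate", "glucose"),
    mineral = c("ferrihydrite", "goethite", "hematite"),
    dilution_exponent = seq_len(n_dilutions)
  ) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_d%d", substr(.data$carbon, 1, 2),
                                      substr(.data$mineral, 1, 2),
                                      .data$dilution_exponent))

  sim <- purrr::map(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    taxa <- signatures$taxon[signatures$carbon_pool == md$carbon]
    comm <- generate_community(taxa, concentration,
                               seed = derive_seed(seed, 1000 + i))
    profiles <- synthesize_sample(comm, signatures, noise,
                                  n_replicates = 2,
                                  seed = derive_seed(seed, 2000 + i),
                                  sample_id = md$sample_id,
                                  amplicon_length = amplicon_length)
    truth <- dplyr::mutate(comm, sample_id = md$sample_id,
                           group = signatures$group[match(.data$taxon, signatures$taxon)])
    list(profiles = profiles, truth = truth)
  })

  list(
    phylotypes = phylotypes,
    signatures = signatures,
    metadata = metadata,
    truth = dplyr::bind_rows(purrr::map(sim, "truth")),
    profiles = dplyr::bind_rows(purrr::map(sim, "profiles"))
  )
}
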