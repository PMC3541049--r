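# Elemental composition and charge of the built-in species, used for
# reaction balance checking.
species_composition <- function() {
  tibble(
    species = c("acetate", "lactate", "bicarbonate", "Fe2+", "goethite",
                "H+", "H2O", "sulfate", "HS-", "H2S"),
    C  = c(2, 3, 1, 0, 0, 0, 0, 0, 0, 0),
    H  = c(3, 5, 1, 0, 1, 1, 2, 0, 1, 2),
    O  = c(2, 3, 3, 0, 2, 0, 1, 4, 0, 0),
    Fe = c(0, 0, 0, 1, 1, 0, 0, 0, 0, 0),
    S  = c(0, 0, 0, 0, 0, 0, 0, 1, 1, 1),
    charge = c(-1, -1, -1, 2, 0, 1, 0, -2, -1, 0)
  )
}

#' Standard Gibbs free energies of formation
#'
#' Loads the species table of standard free energies of formation (25 C,
#' kJ/mol) from the shipped YAML compilation, or from a user-edited copy.
#' Solids and liquid water are tagged with a phase and held at unit
#' activity in [delta_g_prime()].
#'
#' @param path Optional path to an alternative YAML compilation with the
#'   same layout as `system.file("extdata", "thermo_gibbs.yml", package =
#'   "fetrflp")`.
#' @return Tibble `species`, `dg0f_kj`, `phase`, `provenance`.
#' @export
thermo_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "thermo_gibbs.yml", package = "fetrflp")
  raw <- yaml::read_yaml(path)$species
  tibble(
    species = names(raw),
    dg0f_kj = unname(purrr::map_dbl(raw, "dg0f")),
    phase = unname(purrr::map_chr(raw, "phase")),
    provenance = unname(purrr::map_chr(raw, "provenance"))
  )
}

#' Define a redox reaction
#'
#' @param name Reaction label.
#' @param coefficients Named numeric vector of stoichiometric coefficients
#'   over species identifiers: products positive, reactants negative.
#' @param basis The electron-donor species per mole of which energy yields
#'   are reported.
#' @return A list of class `trf_reaction`.
#' @export
trf_reaction <- function(name, coefficients, basis) {
  if (is.null(names(coefficients)) || any(!nzchar(names(coefficients)))) {
    abort("coefficients must be a named vector of species")
  }
  if (!basis %in% names(coefficients)) abort("basis species must appear in the reaction")
  structure(list(name = name, coefficients = coefficients, basis = basis),
            class = "trf_reaction")
}

#' @export
print.trf_reaction <- function(x, ...) {
  co <- x$coefficients
  side <- function(v) paste(sprintf("%s %s", abs(v), names(v)), collapse = " + ")
  cat(x$name, ":", side(co[co < 0]), "->", side(co[co > 0]),
      sprintf("(per mol %s)\n", x$basis))
  invisible(x)
}

#' Built-in enrichment redox couples
#'
#' The three reactions relevant to carbon-source selection in
#' iron-reducing enrichments: acetate oxidation coupled to goethite
#' reduction, incomplete lactate oxidation coupled to goethite reduction,
#' and incomplete lactate oxidation coupled to sulfate reduction.
#'
#' @return Named list of [trf_reaction()] objects.
#' @export
iron_reactions <- function() {
  list(
    acetate_goethite = trf_reaction(
      "acetate_goethite",
      c(acetate = -1, goethite = -8, "H+" = -15,
        bicarbonate = 2, "Fe2+" = 8, H2O = 12),
      basis = "acetate"),
    lactate_goethite = trf_reaction(
      "lactate_goethite",
      c(lactate = -1, goethite = -4, "H+" = -7,
        acetate = 1, bicarbonate = 1, "Fe2+" = 4, H2O = 6),
      basis = "lactate"),
    lactate_sulfate = trf_reaction(
      "lactate_sulfate",
      c(lactate = -1, sulfate = -0.5,
        acetate = 1, bicarbonate = 1, "HS-" = 0.5, "H+" = 0.5),
      basis = "lactate")
  )
}

#' Check the mass and charge balance of a reaction
#'
#' @param rxn A [trf_reaction()].
#' @return Tibble of element (and charge) residuals: products minus
#'   reactants; all zero for a balanced reaction. An empty reaction is
#'   trivially balanced and flagged `degenerate`.
#' @export
validate_reaction <- function(rxn) {
  comp <- species_composition()
  unknown <- setdiff(names(rxn$coefficients), comp$species)
  if (length(unknown) > 0) {
    abort(paste0("unknown species: ", paste(unknown, collapse = ", ")))
  }
  cols <- c("C", "H", "O", "Fe", "S", "charge")
  resid <- vapply(cols, function(el) {
    sum(rxn$coefficients *
          comp[[el]][match(names(rxn$coefficients), comp$species)])
  }, numeric(1))
  tibble(quantity = cols, residual = unname(resid),
         balanced = abs(unname(resid)) < 1e-9,
         degenerate = length(rxn$coefficients) == 0)
}

#' Reaction conditions for free-energy corrections
#'
#' @param pH Solution pH (H+ activity is taken as `10^-pH`).
#' @param temperature Temperature in K (default 298.15).
#' @param ... Named aqueous concentrations in mol/L, e.g. `acetate = 0.01`.
#' @return A list of class `trf_conditions`.
#' @export
enrichment_conditions <- function(pH = 7.3, temperature = 298.15, ...) {
  conc <- c(...)
  if (pH < 0 || pH > 14) abort("pH must lie in [0, 14]")
  if (length(conc) > 0 && any(conc <= 0)) abort("concentrations must be positive")
  structure(list(pH = pH, temperature = temperature, concentrations = conc),
            class = "trf_conditions")
}

#' @rdname enrichment_conditions
#' @details `acetate_conditions()` and `lactate_conditions()` are the two
#'   preset condition sets of the enrichment experiments: pH 7.3 with
#'   acetate 10 mM, Fe2+ 5 uM and bicarbonate 10 mM for the acetate-fed
#'   couples; and lactate 10 mM, acetate 1 uM, Fe2+ 5 uM, bicarbonate
#'   10 mM, sulfate 200 uM, sulfide 1 uM for the lactate-fed couples.
#' @export
acetate_conditions <- function() {
  enrichment_conditions(pH = 7.3, acetate = 10e-3, "Fe2+" = 5e-6,
                        bicarbonate = 10e-3)
}

#' @rdname enrichment_conditions
#' @export
lactate_conditions <- function() {
  enrichment_conditions(pH = 7.3, lactate = 10e-3, acetate = 1e-6,
                        "Fe2+" = 5e-6, bicarbonate = 10e-3,
                        sulfate = 200e-6, "HS-" = 1e-6)
}

#' Activity-corrected reaction energy yield
#'
#' Computes `-(dG0 + RT ln Q)` per mole of the reaction's basis species,
#' where `dG0` comes from standard formation energies and the reaction
#' quotient `Q` uses molar concentrations as activities (no ionic-strength
#' correction), `10^-pH` for H+, and unit activity for solids and water.
#' The sign convention reports thermodynamically favorable reactions as
#' positive energy yields in kJ per mole of electron donor.
#'
#' @param rxn A [trf_reaction()].
#' @param conditions A [enrichment_conditions()] object.
#' @param table Formation-energy table from [thermo_table()].
#' @return Energy yield in kJ per mole of basis species.
#' @examples
#' delta_g_prime(iron_reactions()$lactate_goethite, lactate_conditions())
#' @export
delta_g_prime <- function(rxn, conditions, table = thermo_table()) {
  bal <- validate_reaction(rxn)
  if (!all(bal$balanced)) {
    bad <- bal[!bal$balanced, ]
    abort(paste0("reaction is not balanced; residuals: ",
                 paste(sprintf("%s=%+g", bad$quantity, bad$residual),
                       collapse = ", ")))
  }
  co <- rxn$coefficients
  missing <- setdiff(names(co), table$species)
  if (length(missing) > 0) {
    abort(paste0("species absent from the thermo table: ",
                 paste(missing, collapse = ", ")))
  }
  idx <- match(names(co), table$species)
  dg0 <- sum(co * table$dg0f_kj[idx])

  activity <- vapply(seq_along(co), function(i) {
    sp <- names(co)[i]
    ph <- table$phase[idx[i]]
    if (sp == "H+") return(10^(-conditions$pH))
    if (ph %in% c("s", "l")) return(1)
    a <- conditions$concentrations[[sp]]
    if (is.null(a) || is.na(a)) {
      abort(paste0("no concentration given for aqueous species ", sp))
    }
    a
  }, numeric(1))
  RT <- 0.0083145 * conditions$temperature  # kJ/mol
  lnQ <- sum(co * log(activity))
  -(dg0 + RT * lnQ) / abs(co[[rxn$basis]])
}

#' Energy yields of the built-in couples at enrichment conditions
#'
#' Evaluates [delta_g_prime()] for the three built-in reactions, each
#' under its matching condition preset.
#'
#' @param table Formation-energy table from [thermo_table()].
#' @return Tibble `reaction`, `basis`, `yield_kj_per_mol`.
#' @export
free_energy_yields <- function(table = thermo_table()) {
  rxns <- iron_reactions()
  conds <- list(acetate_goethite = acetate_conditions(),
                lactate_goethite = lactate_conditions(),
                lactate_sulfate = lactate_conditions())
  tibble(
    reaction = names(rxns),
    basis = purrr::map_chr(rxns, "basis"),
    yield_kj_per_mol = purrr::map_dbl(names(rxns), function(n) {
      delta_g_prime(rxns[[n]], conds[[n]], table)
    })
  )
}

#' Percent of total Fe(III) reduced
#'
#' `100 * fe2 / fetot`, the fraction of total iron present as ferrous
#' iron, the study-level readout of enrichment activity.
#'
#' @param fe2 Fe(II) concentration (mM).
#' @param fetot Total Fe concentration (mM); must satisfy
#'   `0 <= fe2 <= fetot`, `fetot > 0`.
#' @return Percent reduced, vectorised.
#' @export
percent_reduced <- function(fe2, fetot) {
  if (any(fetot <= 0)) abort("fetot must be positive")
  if (any(fe2 < 0 | fe2 > fetot)) abort("fe2 must lie in [0, fetot]")
  100 * fe2 / fetot
}

#' Select actively iron-reducing enrichments
#'
#' Applies the strict `> threshold` rule on percent Fe(III) reduced and
#' tallies the selected enrichments by mineral and by carbon source; a
#' record at exactly the threshold is excluded.
#'
#' @param records Enrichment table with columns `mineral`, `carbon` and
#'   either `percent_reduced` or both `fe2_mM` and `fetot_mM`.
#' @param threshold Selection threshold in percent (default 10).
#' @return List with `selected` (subset tibble), `by_mineral` and
#'   `by_carbon` tallies (`n_selected`, `n_total`, `fraction` of all
#'   selected records).
#' @export
select_reduced <- function(records, threshold = 10) {
  if (!"percent_reduced" %in% names(records)) {
    records <- dplyr::mutate(records,
      percent_reduced = percent_reduced(.data$fe2_mM, .data$fetot_mM))
  }
  selected <- dplyr::filter(records, .data$percent_reduced > threshold)
  tally_by <- function(col) {
    tot <- dplyr::count(records, .data[[col]], name = "n_total")
    sel <- dplyr::count(selected, .data[[col]], name = "n_selected")
    dplyr::left_join(tot, sel, by = col) |>
      dplyr::mutate(
        n_selected = dplyr::coalesce(.data$n_selected, 0L),
        fraction = if (nrow(selected) > 0) .data$n_selected / nrow(selected) else 0
      )
  }
  list(selected = selected,
       by_mineral = tally_by("mineral"),
       by_carbon = tally_by("carbon"))
}
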