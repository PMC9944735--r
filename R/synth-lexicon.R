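# Seeded RNG scope: evaluates `code` under `seed` and restores the caller's
# RNG state afterwards, so no hidden global randomness leaks.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-document sub-seed: stable under changes of n_docs so that
# document i is identical no matter how many documents are generated.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 747796405 + as.numeric(index) * 2654435761) %%
               2147483647)
}

#' Canonical entity types
#'
#' The default label set used throughout the package: the five types of the
#' worked examples (bioactivity, genus, species epithet, sample type, sample
#' source) plus molecular formula and compound name. `full = TRUE` returns
#' the extended inventory covering physicochemical and bibliographic
#' attribute types as well.
#'
#' @param full Return the extended type inventory.
#' @return Character vector of type identifiers.
#' @export
mnp_types <- function(full = FALSE) {
  core <- c("Bioactivity", "Generic_name", "Specific_name", "Sample_types",
            "Sample_source", "Formula", "Compound_name")
  if (!full) return(core)
  c(core,
    "Species", "Active_data", "Periodical_information",
    "Relative_molecular_mass", "Name_in_notebook", "Smiles",
    "Molecular_weight", "Name", "Number_of_heavy_atoms",
    "Number_of_rotatable_bonds", "donorHB", "PSA", "AlogP", "accptHB",
    "Species_and_origin", "Action", "PercentHumanOralAbsorption",
    "PMDCK", "Pcaco", "logS", "logHERG", "logBB", "logKp", "logKhsa")
}

# Hand-curated seed surfaces per type: canonical examples of each entity
# type in marine natural product records.
seed_surfaces <- function() {
  list(
    Formula = c("C_60_H_94_O_34_S_2_Na_2_", "C_35_H_42_O_11_"),
    Sample_source = c("The coast of Key Largo", "off Ulleung Island, Korea",
                      "at the coast of Yantai, China",
                      "Sanya Bay, Hainan province"),
    Species = c("Theonella", "moluccensis"),
    Generic_name = c("Siliquariaspongia sp.", "Xylocarpus", "Culcita",
                     "Hippasteria", "Callophycus", "Laurencia",
                     "Polysiphonia"),
    Specific_name = c("novaeguineae", "kurilensis", "serratus", "similis",
                      "urceolata"),
    Active_data = c("MIC80", "<50.0"),
    Periodical_information = c("Molecules 2009, 14, 414-422",
                               "J. Nat. Prod. 2009, 72, 1657-1662"),
    Compound_name = c("Lepirudin", "S-sulfocysteine", "Prosurugatoxin",
                      "surugatoxin", "bromophycolide"),
    Relative_molecular_mass = c("201.221", "156.850"),
    Name_in_notebook = c("1987-2", "1987-3"),
    Molecular_weight = c("684.4210", "320.3040"),
    Bioactivity = c("cytotoxic", "antibacterial", "antifungal", "antiviral",
                    "antitumor", "antioxidant", "anti-inflammatory",
                    "antiproliferative", "antimalarial", "antifouling"),
    Sample_types = c("red alga", "brown alga", "green alga", "sponge",
                     "starfish", "soft coral", "sea cucumber", "tunicate",
                     "sea hare", "bryozoan")
  )
}

.latin_genus_prefix <- c("Callo", "Poly", "Sipho", "Theo", "Halo", "Aplys",
                         "Dysi", "Spiro", "Lepto", "Chondro", "Phyco",
                         "Steno", "Amphi", "Myco")
.latin_genus_suffix <- c("phycus", "siphonia", "nella", "spongia", "clona",
                         "dictyon", "coccus", "thrix", "phyllum", "ceras")
.latin_species_stem <- c("marin", "pacific", "orient", "austral", "japon",
                         "sinens", "coreens", "littoral", "profund", "rubr",
                         "virid", "gracil")
.latin_species_suffix <- c("us", "a", "um", "ensis", "icus", "alis")
.compound_stem <- c("halo", "theo", "spiro", "lauren", "poly", "callo",
                    "marino", "ulva", "cysto", "sarco", "bryo", "phorbo")
.compound_suffix <- c("lide", "mide", "toxin", "statin", "sterol", "quinone",
                      "mycin", "zole", "peptin", "phenol")
.place_names <- c("Weizhou Island", "Jeju Island", "Okinawa", "Palau",
                  "Madagascar", "the Great Barrier Reef", "Paracel Islands",
                  "Bohai Bay", "Amami Oshima", "the Gulf of Mannar")
.place_countries <- c("China", "Korea", "Japan", "Australia", "India",
                      "Indonesia", "Fiji", "the Philippines")

random_formula <- function(n) {
  x <- sample(10:80, n, replace = TRUE)
  y <- sample(12:120, n, replace = TRUE)
  extra <- vapply(seq_len(n), function(i) {
    els <- sample(c("O", "N", "S", "Na"), sample(1:2, 1))
    paste0(vapply(els, function(e) {
      paste0(e, "_", sample(1:34, 1), "_")
    }, character(1)), collapse = "")
  }, character(1))
  paste0("C_", x, "_H_", y, "_", extra)
}

#' Build the entity lexicon for the synthetic corpus generator
#'
#' Combines the hand-curated seed surfaces of [seed_surfaces()] with seeded
#' programmatic expansions: random molecular formulas, latinate genus names
#' and species epithets, compound names, and collection-site phrases. Also
#' creates a pool of deliberately ambiguous surfaces, each usable as either a
#' compound name or a genus name, which the generator reserves for ambiguity
#' documents. Deterministic under the config seed.
#'
#' @param config A [generator_config()].
#' @return Object of class `mnp_lexicon`: list with `types` (named list of
#'   surface vectors), `ambiguous` (data.frame `surface`, `types`), and
#'   `filler` (non-entity vocabulary).
#' @export
build_lexicon <- function(config = generator_config()) {
  stopifnot(inherits(config, "mnp_generator_config"))
  seeds <- seed_surfaces()
  lex <- with_seed(derive_seed(config$seed, 0L), {
    genus <- unique(paste0(
      sample(.latin_genus_prefix, 40, replace = TRUE),
      sample(.latin_genus_suffix, 40, replace = TRUE)))
    species <- unique(paste0(
      sample(.latin_species_stem, 40, replace = TRUE),
      sample(.latin_species_suffix, 40, replace = TRUE)))
    compounds <- unique(paste0(
      sample(.compound_stem, 40, replace = TRUE),
      sample(.compound_suffix, 40, replace = TRUE)))
    sources <- unique(c(
      paste0("off the coast of ", sample(.place_names, 15, replace = TRUE),
             ", ", sample(.place_countries, 15, replace = TRUE)),
      paste0("at a depth of ", sample(5:60, 8) , " m near ",
             sample(.place_names, 8, replace = TRUE))))
    amb <- unique(paste0(
      toupper(substr(.compound_stem, 1, 1)),
      substr(sample(.compound_stem, 12, replace = TRUE), 2, 99),
      sample(c("ion", "aria", "ina", "osia"), 12, replace = TRUE)))
    list(genus = genus, species = species, compounds = compounds,
         sources = sources, amb = amb)
  })
  types <- seeds
  types$Formula <- unique(c(seeds$Formula,
                            with_seed(derive_seed(config$seed, 1L),
                                      random_formula(25L))))
  types$Generic_name <- unique(c(seeds$Generic_name, lex$genus))
  types$Specific_name <- unique(c(seeds$Specific_name, lex$species))
  types$Compound_name <- unique(c(seeds$Compound_name, lex$compounds))
  types$Sample_source <- unique(c(seeds$Sample_source, lex$sources))
  if (!config$full_types) {
    types <- types[intersect(names(types), config$types)]
  }
  filler <- c("asterosaponins", "steroid glycosides", "macrolides",
              "alkaloids", "terpenoids", "sesquiterpenes", "diterpenes",
              "polyketides", "depsipeptides", "bromophenols")
  # reserve ambiguous surfaces: never part of the per-type sampling pools
  ambiguous <- data.frame(surface = setdiff(lex$amb, unlist(types)),
                          stringsAsFactors = FALSE)
  ambiguous$types <- rep(list(c("Compound_name", "Generic_name")),
                         nrow(ambiguous))
  # a surface form must never coincide with a template literal / filler word
  types <- lapply(types, function(v) setdiff(v, filler))
  structure(list(types = types, ambiguous = ambiguous, filler = filler),
            class = "mnp_lexicon")
}

#' @export
print.mnp_lexicon <- function(x, ...) {
  cat(sprintf("<mnp_lexicon> %d types (%s), %d ambiguous surfaces\n",
              length(x$types),
              paste0(names(x$types)[seq_len(min(4, length(x$types)))],
                     collapse = ", "),
              nrow(x$ambiguous)))
  invisible(x)
}
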