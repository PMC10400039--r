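## Orthogroup categorization by phylogenetic breadth and copy number, and
## per-species single-copy (SC) status.

OG_CATEGORIES <- c("core:multicopy", "core:single-copy", "cross-family",
                   "family-specific", "species/lineage-specific")

#' Core-orthogroup species cutoff
#'
#' The minimum number of species an orthogroup must be present in to be
#' called "core", expressed as a fraction of the panel so panels of any
#' size reproduce the same cutoff logic (0.879 of a 58-species panel
#' gives 51).
#'
#' @param n_species Panel size.
#' @param core_frac Fraction of species required (default 0.879).
#' @return Integer cutoff, `ceiling(core_frac * n_species)`.
#' @export
core_min_species <- function(n_species, core_frac = 0.879) {
  as.integer(ceiling(core_frac * n_species))
}

## Long membership table (og_id, species, gene_id) from an
## Orthofinder-style wide table.
og_long <- function(og) {
  og <- as.data.table(og)
  species <- setdiff(names(og), "og_id")
  long <- melt(og, id.vars = "og_id", variable.name = "species",
               value.name = "genes", variable.factor = FALSE)
  long <- long[!is.na(genes) & genes != ""]
  long <- long[, .(gene_id = trimws(strsplit(genes, ",", fixed = TRUE)[[1L]])),
               by = .(og_id, species)]
  long[gene_id != ""]
}

#' Categorize orthogroups
#'
#' Orthogroups present in at least `core_min_species` species are "core
#' angiosperm" groups, split into `core:single-copy` (duplication
#' resistant) when the fraction of species carrying exactly one copy is
#' at least `sc_frac`, else `core:multicopy`. Remaining orthogroups are
#' classified by increasing lineage specificity: `cross-family` (at
#' least two plant families), `family-specific` (at least two species of
#' one family), or `species/lineage-specific` (a single species). Genes
#' in no orthogroup, when a gene universe is supplied, become
#' species-specific singleton pseudo-orthogroups.
#'
#' @param og Orthogroup table as from [read_orthogroups()].
#' @param species_families Named character vector species -> family, as
#'   from [read_species_families()]. Every species column must be mapped.
#' @param core_min_species Absolute core cutoff; defaults to
#'   [core_min_species()] of the panel size at `core_frac`.
#' @param core_frac Fractional core cutoff used when `core_min_species`
#'   is not given (default 0.879).
#' @param sc_frac Single-copy fraction threshold (default 0.70).
#' @param sc_denominator `"present"` (default) computes the single-copy
#'   fraction over species in which the orthogroup occurs; `"all"` over
#'   the whole panel.
#' @param gene_universe Optional data frame (`species`, `gene_id`) of all
#'   genes; genes absent from every orthogroup are added as singleton
#'   pseudo-orthogroups (`og_id` prefixed `SOG:`).
#' @return Data frame: `og_id`, `n_species_present`, `n_families_present`,
#'   `frac_single_copy`, `category`.
#' @export
categorize_orthogroups <- function(og, species_families,
                                   core_min_species = NULL, core_frac = 0.879,
                                   sc_frac = 0.70,
                                   sc_denominator = c("present", "all"),
                                   gene_universe = NULL) {
  sc_denominator <- match.arg(sc_denominator)
  og <- as.data.table(og)
  species <- setdiff(names(og), "og_id")
  unmapped <- setdiff(species, names(species_families))
  if (length(unmapped))
    stop_("species '%s' missing from the family map", unmapped[1L])
  n_panel <- length(species)
  cutoff <- core_min_species %||% core_min_species(n_panel, core_frac)

  long <- og_long(og)
  if (!is.null(gene_universe)) {
    gu <- as.data.table(gene_universe)
    orphan <- gu[!gene_id %in% long$gene_id]
    if (nrow(orphan)) {
      long <- rbind(long, orphan[, .(og_id = paste0("SOG:", gene_id),
                                     species, gene_id)])
    }
  }

  counts <- long[, .(n_copies = .N), by = .(og_id, species)]
  counts[, family := species_families[species]]
  stats <- counts[, .(
    n_species_present = .N,
    n_families_present = length(unique(family)),
    n_single = sum(n_copies == 1L)
  ), by = og_id]
  denom <- if (sc_denominator == "present") stats$n_species_present else n_panel
  stats[, frac_single_copy := n_single / denom]

  category <- with(stats, ifelse(
    n_species_present >= cutoff,
    ifelse(frac_single_copy >= sc_frac, "core:single-copy", "core:multicopy"),
    ifelse(n_families_present >= 2L, "cross-family",
           ifelse(n_species_present >= 2L, "family-specific",
                  "species/lineage-specific"))
  ))
  stats[, category := factor(category, levels = OG_CATEGORIES)]
  stats[, n_single := NULL]
  as.data.frame(stats)
}

#' Single-copy status of genes in core:single-copy orthogroups
#'
#' Within each species, genes of a `core:single-copy` orthogroup are
#' `SC-singleton` when the species carries exactly one copy and
#' `SC-intermediate` when it still retains two or more copies. Genes of
#' other orthogroup categories are not applicable and are not returned.
#'
#' @param og Orthogroup table as from [read_orthogroups()].
#' @param categories Output of [categorize_orthogroups()].
#' @return Data frame: `gene_id`, `species`, `og_id`, `status` in
#'   `{"SC-singleton", "SC-intermediate"}`.
#' @export
sc_status <- function(og, categories) {
  sc_ogs <- categories$og_id[categories$category == "core:single-copy"]
  long <- og_long(og)
  long <- long[og_id %in% sc_ogs]
  if (!nrow(long)) {
    return(data.frame(gene_id = character(), species = character(),
                      og_id = character(), status = character()))
  }
  long[, n_copies := .N, by = .(og_id, species)]
  long[, status := ifelse(n_copies == 1L, "SC-singleton", "SC-intermediate")]
  as.data.frame(long[, .(gene_id, species, og_id, status)])
}
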