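## End-to-end orchestration: run every stage in dependency order from
## input files, write per-stage tables and a combined gene-level master
## table.

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order -- methylome classification,
#' duplicate classification, orthogroup categorization, Ka/Ks,
#' expression specificity, TE association and enrichment scans -- from a
#' named list of input file paths. Optional inputs are skipped with
#' their columns absent from the master table.
#'
#' @param inputs Named list of paths. Required: `gff`, `allc`, `hits`.
#'   Optional: `outgroup_hits` + `outgroup_genes`, `orthogroups` +
#'   `species_families`, `expression`, `tes`, `alignments` (TSV with
#'   `gene1,gene2,seq1,seq2`), `kaks_table` (external import),
#'   `population_labels`, `coverage`.
#' @param out_dir Output directory for the per-stage TSVs; created if
#'   needed. `NULL` skips writing.
#' @param alpha FDR threshold for methylation classification.
#' @param max_evalue Hit retention cutoff.
#' @param max_gap,min_anchors Collinearity parameters.
#' @param max_intervening Proximal-pair ceiling.
#' @param te_margin TE-association flank (bp).
#' @param pav_threshold PAV coverage cutoff.
#' @return A list: `summaries` (with labels), `background`, `pairs`
#'   (typed, with pair methylation classes), `blocks`, `og_categories`,
#'   `sc_status`, `kaks`, `expression` (tau table), `te_associated`,
#'   `population`, `master` (combined gene-level table), `divergence`
#'   (from [report_divergence()]).
#' @export
run_all <- function(inputs, out_dir = NULL, alpha = 0.05,
                    max_evalue = 1e-5, max_gap = 25L, min_anchors = 5L,
                    max_intervening = 10L, te_margin = 1000L,
                    pav_threshold = 0.2) {
  for (need in c("gff", "allc", "hits")) {
    if (is.null(inputs[[need]]) || !file.exists(inputs[[need]]))
      stop_("stage '%s': input file missing", need)
  }
  res <- list()

  ## --- methylome
  gm <- read_gff(inputs$gff)
  sites <- read_allc(inputs$allc)
  summaries <- summarize_genes(sites, gm$genes, gm$cds)
  background <- compute_background(summaries)
  summaries <- classify_genes(summaries, background, alpha = alpha)
  labels <- setNames(as.character(summaries$label), summaries$gene_id)
  res$summaries <- summaries
  res$background <- background

  ## --- duplicates
  hits <- read_hits(inputs$hits, max_evalue = max_evalue)
  intra <- detect_collinear_blocks(hits, gm$genes, max_gap = max_gap,
                                   min_anchors = min_anchors)
  syntenic <- unique(c(intra$anchors$gene_a, intra$anchors$gene_b))
  if (!is.null(inputs$outgroup_hits)) {
    og_hits <- read_hits(inputs$outgroup_hits, max_evalue = max_evalue)
    og_genes <- as.data.frame(fread(inputs$outgroup_genes))
    ranks2 <- rbind(gm$genes[, c("gene_id", "chrom", "rank")],
                    og_genes[, c("gene_id", "chrom", "rank")])
    out_blocks <- detect_collinear_blocks(og_hits, ranks2, max_gap = max_gap,
                                          min_anchors = min_anchors)
    syntenic <- unique(c(syntenic, out_blocks$anchors$gene_a,
                         out_blocks$anchors$gene_b))
    syntenic <- intersect(syntenic, gm$genes$gene_id)
  }
  pairs <- select_unique_pairs(hits)
  pairs <- classify_pairs(pairs, gm$genes, intra$anchors, syntenic,
                          max_intervening = max_intervening)
  pairs <- pair_meth_class(pairs, labels)
  tl <- pairs$dup_type == "translocated"
  pairs$switch_direction <- NA_character_
  if (any(tl)) {
    pairs$switch_direction[tl] <-
      switch_direction(pairs[tl, ], labels)$switch_direction
  }
  res$pairs <- pairs
  res$blocks <- intra

  ## --- orthogroups
  if (!is.null(inputs$orthogroups)) {
    og <- read_orthogroups(inputs$orthogroups)
    fam <- read_species_families(inputs$species_families)
    res$og_categories <- categorize_orthogroups(og, fam)
    res$sc_status <- sc_status(og, res$og_categories)
  }

  ## --- sequence evolution
  if (!is.null(inputs$kaks_table)) {
    res$kaks <- read_kaks_table(inputs$kaks_table)
  } else if (!is.null(inputs$alignments)) {
    aln <- as.data.frame(fread(inputs$alignments))
    res$kaks <- compute_kaks_table(aln)
  }

  ## --- expression
  if (!is.null(inputs$expression)) {
    mat <- read_expression_matrix(inputs$expression)
    res$expression <- expression_summary(mat)
    res$pair_expression <- pair_expression(pairs, mat)
  }

  ## --- TE association
  if (!is.null(inputs$tes)) {
    tes <- read_te_bed(inputs$tes)
    res$te_associated <- te_association(gm$genes, tes, margin = te_margin)
  }

  ## --- PAV
  if (!is.null(inputs$coverage)) {
    cov <- read_expression_matrix(inputs$coverage)  # same layout
    res$pav <- call_pav(cov, threshold = pav_threshold)
  }

  ## --- population epialleles
  if (!is.null(inputs$population_labels)) {
    labs <- as.data.frame(fread(inputs$population_labels))
    m <- as.matrix(labs[, -1L, drop = FALSE])
    rownames(m) <- labs[[1L]]
    res$population <- population_frequency(m)
  }

  ## --- enrichment scans and divergence report
  dup_of_gene <- c(setNames(as.character(pairs$dup_type), pairs$gene1),
                  setNames(as.character(pairs$dup_type), pairs$gene2))
  dup_of_gene <- dup_of_gene[!duplicated(names(dup_of_gene))]
  res$enrichment_dup <- enrichment_scan(labels, dup_of_gene)
  res$divergence <- report_divergence(pairs)

  ## --- master table
  master <- data.frame(gene_id = gm$genes$gene_id,
                       chrom = gm$genes$chrom, rank = gm$genes$rank)
  master$label <- labels[master$gene_id]
  master$dup_type <- dup_of_gene[master$gene_id]
  if (!is.null(res$expression))
    master$tau <- res$expression$tau[match(master$gene_id, res$expression$gene_id)]
  if (!is.null(res$te_associated))
    master$te_associated <- res$te_associated[master$gene_id]
  if (!is.null(res$pav))
    master$pav <- res$pav[master$gene_id]
  res$master <- master

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fwrite(as.data.table(summaries), file.path(out_dir, "gene_methylation.tsv"),
           sep = "\t")
    fwrite(as.data.table(pairs), file.path(out_dir, "duplicate_pairs.tsv"),
           sep = "\t")
    fwrite(as.data.table(intra$blocks), file.path(out_dir, "blocks.tsv"),
           sep = "\t")
    if (!is.null(res$kaks))
      fwrite(as.data.table(res$kaks), file.path(out_dir, "kaks.tsv"), sep = "\t")
    if (!is.null(res$og_categories))
      fwrite(as.data.table(res$og_categories),
             file.path(out_dir, "orthogroup_categories.tsv"), sep = "\t")
    fwrite(as.data.table(master), file.path(out_dir, "master.tsv"), sep = "\t")
  }
  res
}

#' Methylation-divergence report for duplicate pairs
#'
#' Per duplication type: the proportion of pairs whose two paralogs have
#' the same versus different genic methylation (pairs excluded for
#' missing/unclassified labels are reported separately, and the three
#' proportions sum to one). When translocated pairs carry a
#' `switch_direction` column, its per-direction counts are also
#' returned.
#'
#' @param pairs Typed pair table with `dup_type`, `same_class`,
#'   `excluded` (e.g. from [run_all()] or [pair_meth_class()]).
#' @return A list: `by_type` (data frame `dup_type`, `n`, `prop_same`,
#'   `prop_different`, `prop_excluded`) and `switches` (data frame
#'   `direction`, `n`; `NULL` when unavailable).
#' @export
report_divergence <- function(pairs) {
  dt <- as.data.table(pairs)
  by_type <- dt[, .(
    n = .N,
    prop_same = sum(same_class %in% TRUE) / .N,
    prop_different = sum(same_class %in% FALSE) / .N,
    prop_excluded = sum(excluded) / .N
  ), by = dup_type]
  setorder(by_type, dup_type)
  switches <- NULL
  if ("switch_direction" %in% names(dt)) {
    sw <- dt[dup_type == "translocated" & !is.na(switch_direction)]
    if (nrow(sw)) {
      switches <- as.data.frame(sw[, .(n = .N), by = .(direction = switch_direction)])
    }
  }
  list(by_type = as.data.frame(by_type), switches = switches)
}
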