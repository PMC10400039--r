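## Synthetic-data generator: toy genomes with planted duplication events,
## methylomes, codon alignments, expression matrices, TE annotations,
## orthogroup tables and accession populations -- all with ground truth,
## so every pipeline stage is testable without downloads.
##
## All stochastic draws flow from a single seed through named substreams
## (one per output type), so adding one output never perturbs another.

#' Simulation configuration
#'
#' Builds the configuration list consumed by the `simulate_*` functions,
#' with defaults defining the reference study conditions: a 3-chromosome
#' genome with a 10-gene whole-genome-duplication block and 20 events
#' each of tandem, proximal, translocated and dispersed duplication;
#' class-specific methylation emission rates (gbM genes methylated in CG
#' only, teM in CG and non-CG, unM unmethylated) at 20x coverage;
#' class-dependent Ks/omega targets per duplicate-pair methylation
#' class; class-dependent expression-specificity targets; and a
#' 928-accession population with per-class epiallele switch rates.
#'
#' @param seed Integer seed; all substreams derive from it.
#' @param ... Named overrides of any default listed below.
#' @return A list of class `methyldup_sim_config`.
#' @export
sim_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    ## genome layout
    n_chromosomes = 3L,
    genes_per_chromosome = 700L,
    gene_length = 1900L,
    gene_spacing = 3000L,
    ## planted duplication events
    wgd_blocks = 1L,
    wgd_block_genes = 10L,
    n_tandem = 20L,
    n_proximal = 20L,
    n_translocated = 20L,
    n_dispersed = 20L,
    n_outgroup_epochs = 3L,
    max_gap = 25L,
    planted_evalue = 1e-180,
    outgroup_evalue = 1e-150,
    spurious_hit_rate = 0,
    ## methylome emission
    class_mix = c(gbM = 0.3, teM = 0.2, unM = 0.5),
    meth_rates = list(gbM = c(CG = 0.85, CHG = 0.01, CHH = 0.01),
                      teM = c(CG = 0.90, CHG = 0.65, CHH = 0.10),
                      unM = c(CG = 0.005, CHG = 0.005, CHH = 0.005)),
    sites_mean = c(CG = 30, CHG = 25, CHH = 60),
    coverage_lambda = 20,
    error_rate = 0.005,
    call_p_cut = 0.01,
    ## probability that a planted duplicate copy switches methylation
    ## class relative to its source gene
    pair_switch_prob = 0.2,
    ## sequence evolution targets per pair methylation class
    kaks_targets = data.frame(
      pair_meth_class = c("gbM-gbM", "gbM-unM", "unM-unM",
                          "gbM-teM", "unM-teM", "teM-teM"),
      ks = c(0.60, 0.55, 0.50, 0.30, 0.25, 0.20),
      omega = c(0.10, 0.20, 0.30, 0.50, 0.60, 0.80)
    ),
    codons_per_gene = 200L,
    ## expression
    n_conditions = 10L,
    tau_targets = c(gbM = 0.15, unM = 0.35),
    tau_tem_base = 0.40,
    tau_tem_span = 0.55,
    dirichlet_conc = 3000,
    expr_meanlog = 3,
    expr_sdlog = 0.5,
    ## transposable elements
    te_prob = c(gbM = 0.10, teM = 0.80, unM = 0.10),
    te_length = 500L,
    background_tes_per_chrom = 40L,
    ## population of accessions
    n_accessions = 928L,
    switch_rates = list(gbM = c(unM = 0.05), unM = c(gbM = 0.03, teM = 0.02)),
    tem_retention_strata = c(0.10, 0.375, 0.625, 0.875),
    missing_rate = 0.02,
    ## orthogroup panel (58 pseudo-species, 8 pseudo-families)
    og_n_species = 58L,
    og_n_families = 8L,
    og_counts = c(`core:single-copy` = 40L, `core:multicopy` = 60L,
                  `cross-family` = 50L, `family-specific` = 30L,
                  `species/lineage-specific` = 20L),
    core_frac = 0.879,
    sc_frac = 0.70
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop_("unknown config field '%s'", unknown[1L])
  cfg[names(dots)] <- dots
  class(cfg) <- "methyldup_sim_config"
  cfg
}

## ---------------------------------------------------------------------
## Genome with planted duplication events
## ---------------------------------------------------------------------

## Region allocator over base-gene index space. Allocations on a
## chromosome are separated by guard = max_gap + 1 base genes, so planted
## single-gene duplicates can never chain into spurious collinear blocks.
new_allocator <- function(n_chrom, cap, guard) {
  env <- new.env(parent = emptyenv())
  env$cursor <- rep(2L, n_chrom)
  env$cap <- cap
  env$guard <- guard
  env
}

alloc_region <- function(al, span, chrom = NULL) {
  order_ <- if (is.null(chrom)) order(al$cursor) else chrom
  for (ch in order_) {
    if (al$cursor[ch] + span <= al$cap - 2L) {
      at <- al$cursor[ch]
      al$cursor[ch] <- at + span + al$guard
      return(list(chrom = ch, at = at))
    }
  }
  stop_("planted events exceed genome capacity; increase genes_per_chromosome")
}

#' Simulate a genome with planted duplication events
#'
#' Lays out base genes with fixed spacing, then plants: WGD events as
#' duplicated collinear segments, tandem events as rank-adjacent copies,
#' proximal events with 2-9 intervening genes, translocated events with
#' the parental copy inside a segment collinear with a small outgroup
#' gene set, and dispersed events at distant isolated positions. A hit
#' table is emitted with planted pairs far below the e-value cutoff and,
#' optionally, spurious hits at a configured rate.
#'
#' Single-gene insertions are spaced more than `max_gap` base genes
#' apart and tandem/proximal events grouped in clusters of at most four,
#' so planted single-gene duplicates cannot form spurious collinear
#' chains of `min_anchors` length.
#'
#' @param config A [sim_config()] list.
#' @return A list: `genes`, `cds` (as from [read_gff()]), `hits`,
#'   `outgroup_genes`, `outgroup_hits`, `truth_pairs` (`gene1`, `gene2`,
#'   `dup_type`, `parent_id`, `daughter_id`, `epoch`), `epoch_flags`
#'   (logical matrix daughters x outgroup ladder).
#' @export
simulate_genome <- function(config = sim_config()) {
  set_substream(config$seed, "genome")
  nC <- config$n_chromosomes
  nG <- config$genes_per_chromosome
  chroms <- paste0("chr", seq_len(nC))
  guard <- config$max_gap + 1L

  base_ids <- lapply(seq_len(nC), function(c) sprintf("g%d_%04d", c, seq_len(nG)))
  ## inserted[[c]] maps base index -> character vector of genes inserted
  ## immediately after that base gene (in order)
  inserted <- lapply(seq_len(nC), function(c) vector("list", nG))

  al <- new_allocator(nC, nG, guard)
  truth <- list()
  copy_counter <- 0L
  new_id <- function(tag) {
    copy_counter <<- copy_counter + 1L
    sprintf("%s_%04d", tag, copy_counter)
  }
  insert_after <- function(ch, at, id) {
    inserted[[ch]][[at]] <<- c(inserted[[ch]][[at]], id)
  }

  ## --- WGD: duplicated collinear segments
  for (w in seq_len(config$wgd_blocks)) {
    src <- alloc_region(al, config$wgd_block_genes, chrom = 1L)
    tgt <- alloc_region(al, 1L, chrom = if (nC >= 2L) 2L else 1L)
    for (k in seq_len(config$wgd_block_genes)) {
      g1 <- base_ids[[src$chrom]][src$at + k - 1L]
      g2 <- new_id("wgd")
      insert_after(tgt$chrom, tgt$at, g2)
      truth[[length(truth) + 1L]] <- data.table(
        gene1 = g1, gene2 = g2, dup_type = "WGD",
        parent_id = NA_character_, daughter_id = NA_character_, epoch = NA_integer_)
    }
  }

  ## --- translocated parents: segment collinear with the outgroup
  outgroup_genes <- data.frame(gene_id = character(), chrom = character(),
                               rank = integer())
  outgroup_hits <- data.frame(gene1 = character(), gene2 = character(),
                              evalue = numeric())
  parents <- character()
  if (config$n_translocated > 0L) {
    seg <- alloc_region(al, config$n_translocated)
    parents <- base_ids[[seg$chrom]][seg$at + seq_len(config$n_translocated) - 1L]
    og_ids <- sprintf("og_%04d", seq_len(config$n_translocated))
    outgroup_genes <- data.frame(gene_id = og_ids, chrom = "og_chr1",
                                 rank = seq_along(og_ids) - 1L)
    outgroup_hits <- data.frame(gene1 = pmin(parents, og_ids),
                                gene2 = pmax(parents, og_ids),
                                evalue = config$outgroup_evalue)
  }

  ## --- tandem and proximal events, in mixed clusters of <= 4
  ## interleave types so clusters mix tandem and proximal
  events <- c(rep("tandem", config$n_tandem), rep("proximal", config$n_proximal))
  events <- events[order(c(seq_len(config$n_tandem), seq_len(config$n_proximal)),
                         events)]
  clusters <- split(events, ceiling(seq_along(events) / 4L))
  for (cl in clusters) {
    ks <- ifelse(cl == "tandem", 0L, sample(2:9, length(cl), replace = TRUE))
    span <- sum(1L + ks)
    reg <- alloc_region(al, span)
    off <- 0L
    for (i in seq_along(cl)) {
      s_at <- reg$at + off
      src_gene <- base_ids[[reg$chrom]][s_at]
      cp <- new_id(if (cl[i] == "tandem") "tan" else "prox")
      insert_after(reg$chrom, s_at + ks[i], cp)
      truth[[length(truth) + 1L]] <- data.table(
        gene1 = src_gene, gene2 = cp, dup_type = cl[i],
        parent_id = NA_character_, daughter_id = NA_character_, epoch = NA_integer_)
      off <- off + 1L + ks[i]
    }
  }

  ## --- dispersed sources (compact run) and isolated copy slots
  disp_sources <- character()
  if (config$n_dispersed > 0L) {
    reg <- alloc_region(al, config$n_dispersed)
    disp_sources <- base_ids[[reg$chrom]][reg$at + seq_len(config$n_dispersed) - 1L]
  }
  for (g in sample(disp_sources)) {
    slot <- alloc_region(al, 1L)
    cp <- new_id("disp")
    insert_after(slot$chrom, slot$at, cp)
    truth[[length(truth) + 1L]] <- data.table(
      gene1 = g, gene2 = cp, dup_type = "dispersed",
      parent_id = NA_character_, daughter_id = NA_character_, epoch = NA_integer_)
  }

  ## --- translocated daughters at isolated slots + epoch ladder
  epoch_flags <- NULL
  if (config$n_translocated > 0L) {
    epochs <- sample(0:config$n_outgroup_epochs, config$n_translocated,
                     replace = TRUE)
    flags <- matrix(FALSE, nrow = config$n_translocated,
                    ncol = config$n_outgroup_epochs)
    daughters <- character(config$n_translocated)
    for (i in seq_len(config$n_translocated)) {
      slot <- alloc_region(al, 1L)
      d <- new_id("trans")
      insert_after(slot$chrom, slot$at, d)
      daughters[i] <- d
      if (epochs[i] > 0L) flags[i, epochs[i]:config$n_outgroup_epochs] <- TRUE
      truth[[length(truth) + 1L]] <- data.table(
        gene1 = parents[i], gene2 = d, dup_type = "translocated",
        parent_id = parents[i], daughter_id = d, epoch = epochs[i])
    }
    rownames(flags) <- daughters
    epoch_flags <- flags
  }

  ## --- assemble final gene order, ranks and coordinates
  rows <- list()
  for (ch in seq_len(nC)) {
    order_ids <- unlist(lapply(seq_len(nG), function(i) {
      c(base_ids[[ch]][i], inserted[[ch]][[i]])
    }), use.names = FALSE)
    rows[[ch]] <- data.table(gene_id = order_ids, chrom = chroms[ch],
                             rank = seq_along(order_ids) - 1L)
  }
  genes <- rbindlist(rows)
  genes[, start := rank * config$gene_spacing + 200L]
  genes[, end := start + config$gene_length]
  genes[, strand := "+"]
  setcolorder(genes, c("gene_id", "chrom", "start", "end", "strand", "rank"))
  ## two CDS intervals per gene
  cds <- rbind(
    genes[, .(gene_id, start = start, end = start + 900L)],
    genes[, .(gene_id, start = start + 960L, end = end)]
  )
  setorder(cds, gene_id, start)

  truth_pairs <- as.data.frame(rbindlist(truth))
  set_substream(config$seed, "hits")
  hits <- data.table(gene1 = pmin(truth_pairs$gene1, truth_pairs$gene2),
                     gene2 = pmax(truth_pairs$gene1, truth_pairs$gene2),
                     evalue = config$planted_evalue)
  if (config$spurious_hit_rate > 0 && nrow(hits)) {
    n_sp <- round(config$spurious_hit_rate * nrow(hits))
    if (n_sp > 0) {
      g <- genes$gene_id
      sp <- data.table(gene1 = sample(g, n_sp, replace = TRUE),
                       gene2 = sample(g, n_sp, replace = TRUE),
                       evalue = 10^runif(n_sp, -20, -6))
      sp <- sp[gene1 != gene2]
      sp[, `:=`(gene1 = pmin(gene1, gene2), gene2 = pmax(gene1, gene2))]
      hits <- rbind(hits, sp)
      hits <- hits[, .(evalue = min(evalue)), by = .(gene1, gene2)]
    }
  }
  setorder(hits, gene1, gene2)

  list(genes = as.data.frame(genes), cds = as.data.frame(cds),
       hits = as.data.frame(hits),
       outgroup_genes = outgroup_genes, outgroup_hits = outgroup_hits,
       truth_pairs = truth_pairs, epoch_flags = epoch_flags)
}

## ---------------------------------------------------------------------
## Methylome
## ---------------------------------------------------------------------

#' Simulate a per-cytosine methylome (allc table)
#'
#' For each gene, cytosine positions are drawn inside its CDS intervals
#' with per-context site counts around the configured means; coverage is
#' Poisson; methylated read counts are binomial with class-specific
#' per-context rates; the per-site methylation call applies the binomial
#' error-rate test of [call_site_methylation()].
#'
#' @param genes,cds Gene models (as from [read_gff()] or
#'   [simulate_genome()]).
#' @param classes Named vector gene -> true methylation class
#'   (gbM/teM/unM).
#' @param config A [sim_config()] list.
#' @return Data frame in the layout of [read_allc()].
#' @export
simulate_methylome <- function(genes, cds, classes, config = sim_config()) {
  set_substream(config$seed, "methylome")
  genes <- as.data.table(genes)
  cdsdt <- as.data.table(cds)
  ctx_strings <- c(CG = "CGA", CHG = "CAG", CHH = "CTT")

  cds_by_gene <- split(cdsdt, by = "gene_id", keep.by = FALSE)
  pos_l <- ctx_l <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    gi <- cds_by_gene[[genes$gene_id[i]]]
    cds_pos <- unlist(Map(function(s, e) seq.int(s + 1L, e), gi$start, gi$end),
                      use.names = FALSE)  # 1-based positions
    n_per_ctx <- pmax(1L, rpois(3L, config$sites_mean))
    total <- sum(n_per_ctx)
    if (total > length(cds_pos)) {
      n_per_ctx <- pmax(1L, floor(n_per_ctx * length(cds_pos) / total))
      total <- sum(n_per_ctx)
    }
    pos_l[[i]] <- sort(sample(cds_pos, total))
    ctx_l[[i]] <- rep(names(ctx_strings), n_per_ctx)
  }
  n_per_gene <- lengths(pos_l)
  ctx <- unlist(ctx_l, use.names = FALSE)
  cls <- rep(as.character(classes[genes$gene_id]), n_per_gene)
  rate_tab <- do.call(rbind, config$meth_rates)
  rates <- rate_tab[cbind(match(cls, rownames(rate_tab)),
                          match(ctx, colnames(rate_tab)))]
  cov <- rpois(length(ctx), config$coverage_lambda)
  out <- data.table(
    chrom = rep(genes$chrom, n_per_gene),
    pos = unlist(pos_l, use.names = FALSE),
    strand = "+",
    context = unname(ctx_strings[ctx]),
    mc_reads = rbinom(length(ctx), cov, rates),
    total_reads = cov
  )
  out[, is_methylated := call_site_methylation(mc_reads, total_reads,
                                               config$error_rate,
                                               config$call_p_cut)]
  out[, `:=`(context_class = context_class(context), covered = total_reads > 0L)]
  setorder(out, chrom, pos)
  setcolorder(out, c("chrom", "pos", "strand", "context", "context_class",
                     "mc_reads", "total_reads", "is_methylated", "covered"))
  as.data.frame(out)
}

## ---------------------------------------------------------------------
## Codon sequence evolution
## ---------------------------------------------------------------------

## Evolve one codon sequence (character vector of codons) for time t
## under per-change rates: 1 for synonymous, omega for nonsynonymous,
## 0 into stops.
evolve_codons <- function(codons, t, omega) {
  cd <- codon_data()
  for (i in seq_along(codons)) {
    remaining <- t
    repeat {
      nb <- cd$neighbors[[codons[i]]]
      rates <- ifelse(nb$syn, 1, omega)
      total <- sum(rates)
      if (total <= 0) break
      dt <- rexp(1L, total)
      if (dt > remaining) break
      remaining <- remaining - dt
      codons[i] <- sample(nb$to, 1L, prob = rates)
    }
  }
  codons
}

#' Simulate codon-aligned duplicate pairs at target Ks and omega
#'
#' Draws an ancestral sequence uniformly over sense codons per pair and
#' evolves both branches under a codon substitution process in which
#' every single-base change has rate 1 when synonymous and `omega` when
#' nonsynonymous (changes into stop codons are forbidden). Branch
#' lengths are set so the expected pairwise synonymous divergence equals
#' the target Ks.
#'
#' @param pairs Data frame with `gene1`, `gene2`, `target_ks`,
#'   `target_omega`.
#' @param config A [sim_config()] list (`codons_per_gene`, seed).
#' @return `pairs` with added `seq1`, `seq2` columns (aligned nucleotide
#'   strings).
#' @export
simulate_sequences <- function(pairs, config = sim_config()) {
  set_substream(config$seed, "sequences")
  cd <- codon_data()
  pairs <- as.data.frame(pairs)
  n <- nrow(pairs)
  seq1 <- seq2 <- character(n)
  for (i in seq_len(n)) {
    anc <- sample(cd$sense, config$codons_per_gene, replace = TRUE)
    ## per-unit-time Ks accrual is 3 (see vignette); each branch gets
    ## half the pair divergence
    tb <- pairs$target_ks[i] / 3 / 2
    s1 <- evolve_codons(anc, tb, pairs$target_omega[i])
    s2 <- evolve_codons(anc, tb, pairs$target_omega[i])
    seq1[i] <- paste(s1, collapse = "")
    seq2[i] <- paste(s2, collapse = "")
  }
  pairs$seq1 <- seq1
  pairs$seq2 <- seq2
  pairs
}

## ---------------------------------------------------------------------
## Expression
## ---------------------------------------------------------------------

#' Simulate an expression matrix with target tau per gene
#'
#' Per gene, a profile shape with specificity exactly `tau` (one
#' dominant condition, the rest at `1 - tau` of the maximum) is
#' perturbed by a Dirichlet draw at the configured concentration and
#' scaled by a lognormal magnitude.
#'
#' @param tau_targets Named numeric vector gene -> target tau.
#' @param config A [sim_config()] list.
#' @return Numeric matrix genes x conditions with gene rownames.
#' @export
simulate_expression <- function(tau_targets, config = sim_config()) {
  set_substream(config$seed, "expression")
  nc <- config$n_conditions
  genes <- names(tau_targets)
  mat <- matrix(0, nrow = length(genes), ncol = nc,
                dimnames = list(genes, paste0("cond", seq_len(nc))))
  dominant <- sample.int(nc, length(genes), replace = TRUE)
  for (i in seq_along(genes)) {
    shape <- rep(1 - tau_targets[i], nc)
    shape[dominant[i]] <- 1
    alpha <- config$dirichlet_conc * shape / sum(shape)
    x <- rgamma(nc, shape = alpha)
    if (sum(x) == 0) x[dominant[i]] <- 1
    mat[i, ] <- x / sum(x) * rlnorm(1L, config$expr_meanlog, config$expr_sdlog)
  }
  mat
}

## ---------------------------------------------------------------------
## Transposable elements
## ---------------------------------------------------------------------

#' Simulate TE annotations associated with teM genes
#'
#' Places a TE immediately upstream (within the 1-kb association margin)
#' of each gene with class-dependent probability, plus uniform
#' background TEs along each chromosome.
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param classes Named vector gene -> methylation class.
#' @param config A [sim_config()] list.
#' @return TE data frame (`chrom`, `start`, `end`, `family`).
#' @export
simulate_tes <- function(genes, classes, config = sim_config()) {
  set_substream(config$seed, "tes")
  genes <- as.data.frame(genes)
  p <- config$te_prob[as.character(classes[genes$gene_id])]
  p[is.na(p)] <- 0
  hit <- runif(nrow(genes)) < p
  te_len <- config$te_length
  assoc <- data.frame(chrom = genes$chrom[hit],
                      start = pmax(0L, genes$start[hit] - 300L - te_len),
                      end = pmax(te_len, genes$start[hit] - 300L),
                      family = "planted")
  bg <- do.call(rbind, lapply(unique(genes$chrom), function(ch) {
    len <- max(genes$end[genes$chrom == ch])
    s <- sort(sample.int(max(1L, len - te_len), config$background_tes_per_chrom))
    data.frame(chrom = ch, start = s, end = s + te_len, family = "background")
  }))
  out <- rbind(assoc, bg)
  out[order(out$chrom, out$start), ]
}

## ---------------------------------------------------------------------
## Accession population
## ---------------------------------------------------------------------

#' Simulate per-accession methylation labels
#'
#' Each gene keeps its base class or switches per the configured
#' per-class switch rates in every accession, independently; teM genes
#' instead retain teM with a per-gene planted retention probability
#' (switching to unM otherwise), which creates population-frequency
#' strata. A missing-data mask is applied at the configured rate.
#'
#' @param classes Named vector gene -> base class.
#' @param config A [sim_config()] list.
#' @param tem_retention Optional named vector of per-teM-gene retention
#'   probabilities; defaults to sampling the configured strata.
#' @return A list: `labels` (character matrix genes x accessions, `NA`
#'   = missing), `freq_target` (data frame of planted per-gene class
#'   frequencies), `tem_retention` (named vector as used).
#' @export
simulate_population <- function(classes, config = sim_config(),
                                tem_retention = NULL) {
  set_substream(config$seed, "population")
  genes <- names(classes)
  nA <- config$n_accessions
  cls <- as.character(classes)
  all_classes <- c("gbM", "teM", "unM")

  for (r in config$switch_rates) {
    if (sum(r) > 1) stop_("switch-rate rows must sum to at most 1")
  }

  if (is.null(tem_retention)) {
    tem_genes <- genes[cls == "teM"]
    tem_retention <- setNames(
      sample(config$tem_retention_strata, length(tem_genes), replace = TRUE),
      tem_genes)
  }

  ## planted per-gene class distribution
  probs <- matrix(0, nrow = length(genes), ncol = length(all_classes),
                  dimnames = list(genes, all_classes))
  for (i in seq_along(genes)) {
    base <- cls[i]
    if (base == "teM") {
      keep <- tem_retention[[genes[i]]]
      probs[i, "teM"] <- keep
      probs[i, "unM"] <- 1 - keep
    } else {
      sw <- config$switch_rates[[base]] %||% numeric()
      probs[i, names(sw)] <- sw
      probs[i, base] <- 1 - sum(sw)
    }
  }

  labels <- matrix(NA_character_, nrow = length(genes), ncol = nA,
                   dimnames = list(genes, sprintf("acc%04d", seq_len(nA))))
  for (i in seq_along(genes)) {
    labels[i, ] <- sample(all_classes, nA, replace = TRUE, prob = probs[i, ])
  }
  if (config$missing_rate > 0) {
    miss <- matrix(runif(length(labels)) < config$missing_rate,
                   nrow = nrow(labels))
    labels[miss] <- NA_character_
  }
  list(labels = labels,
       freq_target = data.frame(gene_id = genes, base_class = cls,
                                probs, check.names = FALSE, row.names = NULL),
       tem_retention = tem_retention)
}

## ---------------------------------------------------------------------
## Orthogroup panel
## ---------------------------------------------------------------------

#' Simulate an orthogroup table with planted categories
#'
#' Builds an Orthofinder-style membership table over a pseudo-species
#' panel (default 58 species in 8 families, so the 51-species core
#' cutoff is exercised literally) with planted counts per category.
#'
#' @param config A [sim_config()] list.
#' @return A list: `og` (wide membership table), `species_families`
#'   (named vector), `truth` (data frame `og_id`, `category`).
#' @export
simulate_orthogroups <- function(config = sim_config()) {
  set_substream(config$seed, "orthogroups")
  nS <- config$og_n_species
  species <- sprintf("sp%02d", seq_len(nS))
  families <- sprintf("fam%d", rep_len(seq_len(config$og_n_families), nS))
  fam_map <- setNames(families, species)
  core_cut <- core_min_species(nS, config$core_frac)

  og_rows <- list(); truth <- list(); og_i <- 0L
  add_og <- function(copies, category) {
    og_i <<- og_i + 1L
    id <- sprintf("OG%06d", og_i)
    genes <- vapply(seq_len(nS), function(s) {
      if (copies[s] == 0L) "" else
        paste(sprintf("%s_%s_g%d", species[s], id, seq_len(copies[s])),
              collapse = ", ")
    }, "")
    og_rows[[og_i]] <<- c(og_id = id, setNames(genes, species))
    truth[[og_i]] <<- data.frame(og_id = id, category = category)
  }

  counts <- config$og_counts
  for (j in seq_len(counts[["core:single-copy"]])) {
    n_present <- sample(core_cut:nS, 1L)
    n_single <- ceiling(config$sc_frac * n_present) +
      sample(0:(n_present - ceiling(config$sc_frac * n_present)), 1L)
    present <- sample(nS, n_present)
    copies <- integer(nS)
    copies[present] <- c(rep(1L, n_single), rep(2L, n_present - n_single))
    add_og(copies, "core:single-copy")
  }
  for (j in seq_len(counts[["core:multicopy"]])) {
    n_present <- sample(core_cut:nS, 1L)
    ## keep the single-copy fraction well below the threshold
    n_single <- floor(0.4 * n_present)
    present <- sample(nS, n_present)
    copies <- integer(nS)
    copies[present] <- c(rep(1L, n_single),
                         sample(2:4, n_present - n_single, replace = TRUE))
    add_og(copies, "core:multicopy")
  }
  for (j in seq_len(counts[["cross-family"]])) {
    repeat {
      n_present <- sample(2:min(20L, core_cut - 1L), 1L)
      present <- sample(nS, n_present)
      if (length(unique(families[present])) >= 2L) break
    }
    copies <- integer(nS)
    copies[present] <- sample(1:3, n_present, replace = TRUE)
    add_og(copies, "cross-family")
  }
  for (j in seq_len(counts[["family-specific"]])) {
    fam <- sample(unique(families), 1L)
    members <- which(families == fam)
    n_present <- sample(2:length(members), 1L)
    present <- sample(members, n_present)
    copies <- integer(nS)
    copies[present] <- sample(1:3, n_present, replace = TRUE)
    add_og(copies, "family-specific")
  }
  for (j in seq_len(counts[["species/lineage-specific"]])) {
    copies <- integer(nS)
    copies[sample(nS, 1L)] <- sample(1:3, 1L)
    add_og(copies, "species/lineage-specific")
  }

  og <- as.data.frame(do.call(rbind, og_rows), stringsAsFactors = FALSE)
  list(og = og, species_families = fam_map,
       truth = do.call(rbind, truth))
}

## ---------------------------------------------------------------------
## Full dataset
## ---------------------------------------------------------------------

#' Simulate a complete dataset with ground truth
#'
#' Runs every generator under one seed: genome and planted duplications,
#' per-gene methylation classes and allc methylome, codon alignments at
#' class-dependent Ks/omega targets, expression with class-dependent
#' tau targets (teM genes' tau rises with their planted population
#' retention), TE annotations, an accession population, and an
#' orthogroup panel. Optionally writes all outputs as plain-text files.
#'
#' @param config A [sim_config()] list.
#' @param out_dir Optional directory; when given, writes `genome.gff3`,
#'   `allc.tsv`, `hits.tsv`, `outgroup_hits.tsv`, `tes.bed`,
#'   `orthogroups.tsv`, `species_families.tsv`, `expression.tsv`,
#'   `alignments.tsv`, `population_labels.tsv` and `truth_*.tsv`.
#' @return A list with all simulated components and a `truth` list
#'   (`classes`, `pairs`, `og`, `tau`, `population_freq`).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  genome <- simulate_genome(config)

  set_substream(config$seed, "classes")
  gene_ids <- genome$genes$gene_id
  classes <- setNames(sample(names(config$class_mix), length(gene_ids),
                             replace = TRUE, prob = config$class_mix),
                      gene_ids)
  ## planted duplicate copies inherit the source class, switching with
  ## probability pair_switch_prob
  tp <- genome$truth_pairs
  for (i in seq_len(nrow(tp))) {
    if (runif(1L) >= config$pair_switch_prob) {
      classes[tp$gene2[i]] <- classes[tp$gene1[i]]
    } else {
      classes[tp$gene2[i]] <- sample(setdiff(names(config$class_mix),
                                             classes[tp$gene1[i]]), 1L)
    }
  }
  allc <- simulate_methylome(genome$genes, genome$cds, classes, config)

  ## pair-level targets from realized pair methylation classes
  pairs <- pair_meth_class(genome$truth_pairs, classes)
  pairs <- merge(pairs, config$kaks_targets, by = "pair_meth_class",
                 all.x = TRUE, sort = FALSE)
  pairs$target_ks <- pairs$ks
  pairs$target_omega <- pairs$omega
  pairs$ks <- pairs$omega <- NULL
  alignments <- simulate_sequences(pairs, config)

  population <- simulate_population(classes, config)

  tau_targets <- numeric(length(gene_ids))
  names(tau_targets) <- gene_ids
  for (cl in names(config$tau_targets)) {
    tau_targets[classes == cl] <- config$tau_targets[[cl]]
  }
  tem <- names(population$tem_retention)
  tau_targets[tem] <- config$tau_tem_base +
    config$tau_tem_span * population$tem_retention
  expression <- simulate_expression(tau_targets, config)

  tes <- simulate_tes(genome$genes, classes, config)
  ogs <- simulate_orthogroups(config)

  out <- c(genome, list(
    classes = classes, allc = allc, alignments = alignments,
    expression = expression, tes = tes,
    population = population, orthogroups = ogs,
    truth = list(classes = classes, pairs = genome$truth_pairs,
                 og = ogs$truth, tau = tau_targets,
                 population_freq = population$freq_target),
    config = config
  ))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(out_dir, f)
    write_gff3(genome$genes, genome$cds, fp("genome.gff3"))
    write_allc(allc, fp("allc.tsv"))
    write_hits(genome$hits, fp("hits.tsv"))
    if (nrow(genome$outgroup_hits)) {
      write_hits(genome$outgroup_hits, fp("outgroup_hits.tsv"))
      fwrite(as.data.table(genome$outgroup_genes), fp("outgroup_genes.tsv"),
             sep = "\t")
    }
    write_te_bed(tes, fp("tes.bed"))
    write_orthogroups(ogs$og, fp("orthogroups.tsv"))
    fwrite(data.table(species = names(ogs$species_families),
                      family = unname(ogs$species_families)),
           fp("species_families.tsv"), sep = "\t")
    write_expression_matrix(expression, fp("expression.tsv"))
    fwrite(as.data.table(alignments), fp("alignments.tsv"), sep = "\t")
    labs <- population$labels
    fwrite(cbind(data.table(gene_id = rownames(labs)), as.data.table(labs)),
           fp("population_labels.tsv"), sep = "\t")
    fwrite(data.table(gene_id = names(classes), class = unname(classes)),
           fp("truth_classes.tsv"), sep = "\t")
    fwrite(as.data.table(genome$truth_pairs), fp("truth_pairs.tsv"), sep = "\t")
    fwrite(as.data.table(ogs$truth), fp("truth_orthogroups.tsv"), sep = "\t")
  }
  out
}
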