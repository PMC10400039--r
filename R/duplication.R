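## Duplicate-pair classification: collinear (syntenic) block detection by
## dynamic programming over gene-rank anchor chains, then a priority
## hierarchy WGD > tandem > proximal > translocated > dispersed.

DUP_TYPES <- c("WGD", "tandem", "proximal", "translocated", "dispersed")
PAIR_LABEL_ORDER <- c("gbM", "unM", "teM")

#' Detect collinear blocks from filtered hits
#'
#' Builds anchor chains over gene-rank space for every chromosome pair by
#' dynamic programming: a match extends a chain when the rank gap on both
#' axes is in `[1, max_gap]` and the orientation (both ranks increasing,
#' or one increasing and one decreasing) is consistent. Overlapping
#' chains are resolved greedily by anchor count: the best chain is
#' extracted, its matches removed, and the search repeated until no chain
#' reaches `min_anchors`.
#'
#' @param hits Data frame with `gene1`, `gene2` (as from [read_hits()]).
#' @param genes Data frame with `gene_id`, `chrom`, `rank`; may combine
#'   gene sets from two genomes (e.g. species + outgroup).
#' @param max_gap Maximum rank gap between consecutive anchors
#'   (default 25).
#' @param min_anchors Minimum anchors per reported block (default 5).
#' @return A list with `blocks` (one row per block: `block_id`,
#'   `chrom_a`, `chrom_b`, `orientation`, `n_anchors`) and `anchors`
#'   (one row per anchor pair: `block_id`, `gene_a`, `gene_b`).
#' @export
detect_collinear_blocks <- function(hits, genes, max_gap = 25L,
                                    min_anchors = 5L) {
  genes <- as.data.table(genes)
  hits <- as.data.table(hits)
  empty <- list(
    blocks = data.frame(block_id = integer(), chrom_a = character(),
                        chrom_b = character(), orientation = character(),
                        n_anchors = integer()),
    anchors = data.frame(block_id = integer(), gene_a = character(),
                         gene_b = character())
  )
  if (!nrow(hits)) return(empty)

  idx <- match(hits$gene1, genes$gene_id)
  idx2 <- match(hits$gene2, genes$gene_id)
  keep <- !is.na(idx) & !is.na(idx2)
  hits <- hits[keep]; idx <- idx[keep]; idx2 <- idx2[keep]
  if (!nrow(hits)) return(empty)

  m <- data.table(
    ga = hits$gene1, gb = hits$gene2,
    ca = genes$chrom[idx], cb = genes$chrom[idx2],
    ra = genes$rank[idx], rb = genes$rank[idx2]
  )
  ## canonical axis order: chrom_a <= chrom_b; within a chromosome,
  ## axis a carries the smaller rank
  swap <- m$ca > m$cb | (m$ca == m$cb & m$ra > m$rb)
  m[swap, `:=`(ga = gb, gb = ga, ca = cb, cb = ca, ra = rb, rb = ra)]
  m <- unique(m)

  blocks <- list(); anchors <- list(); bid <- 0L
  for (grp in split(m, paste(m$ca, m$cb, sep = "\r"))) {
    avail <- grp
    repeat {
      ch_same <- best_chain(avail$ra, avail$rb, max_gap, inverted = FALSE)
      ch_inv <- best_chain(avail$ra, -avail$rb, max_gap, inverted = TRUE)
      if (length(ch_same) >= length(ch_inv)) {
        ch <- ch_same; orient <- "same"
      } else {
        ch <- ch_inv; orient <- "inverted"
      }
      if (length(ch) < min_anchors) break
      bid <- bid + 1L
      blocks[[bid]] <- data.table(block_id = bid, chrom_a = avail$ca[1L],
                                  chrom_b = avail$cb[1L], orientation = orient,
                                  n_anchors = length(ch))
      anchors[[bid]] <- data.table(block_id = bid, gene_a = avail$ga[ch],
                                   gene_b = avail$gb[ch])
      avail <- avail[-ch]
      if (!nrow(avail)) break
    }
  }
  if (!bid) return(empty)
  list(blocks = as.data.frame(rbindlist(blocks)),
       anchors = as.data.frame(rbindlist(anchors)))
}

## Longest chain over matches (ra, rb) with both gaps in [1, max_gap];
## pass rb negated for inverted orientation. Returns row indices in
## input order along the chain.
best_chain <- function(ra, rb, max_gap, inverted = FALSE) {
  n <- length(ra)
  if (!n) return(integer())
  ord <- order(ra, rb)
  a <- ra[ord]; b <- rb[ord]
  dp <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    da <- a[i] - a
    db <- b[i] - b
    cand <- which(da >= 1L & da <= max_gap & db >= 1L & db <= max_gap)
    if (length(cand)) {
      j <- cand[which.max(dp[cand])]
      dp[i] <- dp[j] + 1L
      prev[i] <- j
    }
  }
  i <- which.max(dp)
  chain <- integer(dp[i])
  k <- dp[i]
  while (i > 0L) {
    chain[k] <- i
    k <- k - 1L
    i <- prev[i]
  }
  ord[chain]
}

#' Retain one paralog pair per gene
#'
#' To avoid overcounting genes with more than one potential paralog,
#' pairs are retained by greedy matching on e-value: hits are visited in
#' increasing e-value order and a pair is kept only when neither of its
#' genes is already part of a retained pair, so each gene appears in at
#' most one pair. Exact e-value ties resolve toward the
#' lexicographically smaller pair (and are reported via `message()`).
#'
#' @param hits Data frame with `gene1`, `gene2`, `evalue`.
#' @return Subset of `hits` rows forming the retained pair set.
#' @export
select_unique_pairs <- function(hits) {
  hits <- as.data.table(hits)
  if (!nrow(hits)) return(as.data.frame(hits))
  setorder(hits, evalue, gene1, gene2)
  long <- rbind(hits[, .(gene = gene1, evalue)], hits[, .(gene = gene2, evalue)])
  setorder(long, gene, evalue)
  n_tied <- long[, .(tie = .N > 1L && evalue[1L] == evalue[2L]), by = gene][, sum(tie)]
  if (n_tied > 0L) {
    message(n_tied, " gene(s) had tied lowest e-values; ",
            "kept the lexicographically smaller pair")
  }
  all_genes <- unique(c(hits$gene1, hits$gene2))
  used <- logical(length(all_genes))
  i1 <- match(hits$gene1, all_genes)
  i2 <- match(hits$gene2, all_genes)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    if (!used[i1[i]] && !used[i2[i]]) {
      keep[i] <- TRUE
      used[i1[i]] <- used[i2[i]] <- TRUE
    }
  }
  out <- hits[keep]
  setorder(out, gene1, gene2)
  as.data.frame(out)
}

#' Classify duplicate pairs by mechanism
#'
#' Applies the priority hierarchy WGD > tandem > proximal > translocated
#' > dispersed: a pair is WGD if it is an anchor pair of an intra-species
#' collinear block; tandem if on the same chromosome with adjacent ranks;
#' proximal if on the same chromosome with at most `max_intervening`
#' intervening genes; translocated if exactly one gene is syntenic (that
#' gene is the parent, the other the daughter); dispersed otherwise.
#'
#' @param pairs Data frame with `gene1`, `gene2` (and optionally
#'   `evalue`), e.g. from [select_unique_pairs()].
#' @param genes Data frame with `gene_id`, `chrom`, `rank` for this
#'   species.
#' @param anchors Anchor table of intra-species blocks
#'   (from [detect_collinear_blocks()]`$anchors`); used for the WGD rule.
#' @param syntenic_genes Character vector of genes flagged syntenic:
#'   anchors of any collinear block, intra-species or versus an outgroup.
#' @param max_intervening Proximal-pair ceiling on intervening gene count
#'   (default 10).
#' @return `pairs` with added columns `dup_type`, `parent_id`,
#'   `daughter_id` (non-`NA` for translocated pairs only).
#' @export
classify_pairs <- function(pairs, genes, anchors, syntenic_genes,
                           max_intervening = 10L) {
  pairs <- as.data.table(pairs)
  genes <- as.data.table(genes)
  miss <- setdiff(unique(c(pairs$gene1, pairs$gene2)), genes$gene_id)
  if (length(miss)) stop_("gene '%s' absent from the rank table", miss[1L])

  key <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2), sep = "\r")
  anchor_keys <- if (NROW(anchors)) key(anchors$gene_a, anchors$gene_b) else character()

  i1 <- match(pairs$gene1, genes$gene_id)
  i2 <- match(pairs$gene2, genes$gene_id)
  same_chrom <- genes$chrom[i1] == genes$chrom[i2]
  rdiff <- abs(genes$rank[i1] - genes$rank[i2])
  syn1 <- pairs$gene1 %in% syntenic_genes
  syn2 <- pairs$gene2 %in% syntenic_genes

  dup_type <- rep("dispersed", nrow(pairs))
  parent <- daughter <- rep(NA_character_, nrow(pairs))

  is_transloc <- xor(syn1, syn2)
  dup_type[is_transloc] <- "translocated"
  parent[is_transloc] <- ifelse(syn1[is_transloc],
                                pairs$gene1[is_transloc], pairs$gene2[is_transloc])
  daughter[is_transloc] <- ifelse(syn1[is_transloc],
                                  pairs$gene2[is_transloc], pairs$gene1[is_transloc])

  is_prox <- same_chrom & rdiff >= 2L & rdiff <= max_intervening + 1L
  is_tand <- same_chrom & rdiff == 1L
  dup_type[is_prox] <- "proximal"
  dup_type[is_tand] <- "tandem"
  parent[is_prox | is_tand] <- NA_character_
  daughter[is_prox | is_tand] <- NA_character_

  is_wgd <- key(pairs$gene1, pairs$gene2) %in% anchor_keys
  dup_type[is_wgd] <- "WGD"
  parent[is_wgd] <- NA_character_
  daughter[is_wgd] <- NA_character_

  pairs[, `:=`(dup_type = factor(dup_type, levels = DUP_TYPES),
               parent_id = parent, daughter_id = daughter)]
  as.data.frame(pairs)
}

#' Assign a translocation epoch from an outgroup ladder
#'
#' Given, for one translocated pair, an ordered vector of flags (closest
#' outgroup first) saying whether the daughter locus is syntenic versus
#' each outgroup, the epoch is the smallest 1-based index with a `TRUE`
#' flag (the duplication predates that divergence node), or 0 when the
#' daughter is syntenic versus no outgroup (the youngest, lineage-specific
#' class).
#'
#' @param outgroup_synteny Logical vector, closest outgroup first.
#' @return Integer epoch, or `NA` for an empty ladder.
#' @export
assign_epoch <- function(outgroup_synteny) {
  if (!length(outgroup_synteny)) return(NA_integer_)
  hit <- which(as.logical(outgroup_synteny))
  if (!length(hit)) 0L else hit[1L]
}

#' Methylation class of a duplicate pair
#'
#' Combines the two paralogs' genic methylation labels into an unordered
#' pair class (`gbM-gbM`, `gbM-unM`, `gbM-teM`, `unM-unM`, `unM-teM`,
#' `teM-teM`). Pairs where either gene is `missing` or `unclassified`
#' are excluded (`NA` class).
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param labels Named character (or factor) vector mapping gene id to
#'   its methylation label.
#' @return `pairs` with added `pair_meth_class`, `same_class` (logical;
#'   `NA` when excluded) and `excluded` columns.
#' @export
pair_meth_class <- function(pairs, labels) {
  pairs <- as.data.table(pairs)
  labels <- setNames(as.character(labels), names(labels))
  l1 <- labels[pairs$gene1]
  l2 <- labels[pairs$gene2]
  ok <- !is.na(l1) & !is.na(l2) & l1 %in% PAIR_LABEL_ORDER & l2 %in% PAIR_LABEL_ORDER
  o1 <- factor(l1, levels = PAIR_LABEL_ORDER)
  o2 <- factor(l2, levels = PAIR_LABEL_ORDER)
  lo <- pmin(as.integer(o1), as.integer(o2))
  hi <- pmax(as.integer(o1), as.integer(o2))
  cls <- ifelse(ok, paste(PAIR_LABEL_ORDER[lo], PAIR_LABEL_ORDER[hi], sep = "-"),
                NA_character_)
  pairs[, `:=`(pair_meth_class = cls,
               same_class = ifelse(ok, l1 == l2, NA),
               excluded = !ok)]
  as.data.frame(pairs)
}

#' Direction of methylation switching in translocated pairs
#'
#' Takes the parental (syntenic) locus methylation label as the ancestral
#' state; when the daughter label differs the direction is
#' `to-<daughter label>`, otherwise `same`.
#'
#' @param pairs Data frame with `parent_id` and `daughter_id` set (e.g.
#'   translocated rows from [classify_pairs()]).
#' @param labels Named label vector as in [pair_meth_class()]; both genes
#'   of a pair must be labelled gbM, teM or unM (others give `NA`).
#' @return `pairs` with an added `switch_direction` column in
#'   `{"same", "to-gbM", "to-unM", "to-teM"}`.
#' @export
switch_direction <- function(pairs, labels) {
  pairs <- as.data.table(pairs)
  if (any(is.na(pairs$parent_id) | is.na(pairs$daughter_id)))
    stop_("parent/daughter roles missing; run classify_pairs first")
  labels <- setNames(as.character(labels), names(labels))
  lp <- labels[pairs$parent_id]
  ld <- labels[pairs$daughter_id]
  ok <- !is.na(lp) & !is.na(ld) & lp %in% PAIR_LABEL_ORDER & ld %in% PAIR_LABEL_ORDER
  dir <- ifelse(!ok, NA_character_,
                ifelse(lp == ld, "same", paste0("to-", ld)))
  pairs[, switch_direction := dir]
  as.data.frame(pairs)
}
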