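rank_table <- function(...) {
  ## rank_table(chr1 = c("a1","a2"), chr2 = ...) -> gene/chrom/rank table
  chroms <- list(...)
  do.call(rbind, lapply(names(chroms), function(ch) {
    data.frame(gene_id = chroms[[ch]], chrom = ch,
               rank = seq_along(chroms[[ch]]) - 1L)
  }))
}

test_that("a perfect diagonal of 10 anchors forms one same-orientation block", {
  genes <- rank_table(chrA = paste0("a", 1:10), chrB = paste0("b", 1:10))
  hits <- data.frame(gene1 = paste0("a", 1:10), gene2 = paste0("b", 1:10),
                     evalue = 1e-50)
  res <- detect_collinear_blocks(hits, genes)
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$n_anchors, 10L)
  expect_equal(res$blocks$orientation, "same")
  expect_setequal(res$anchors$gene_a, paste0("a", 1:10))
})

test_that("four anchors do not reach the collinearity minimum", {
  genes <- rank_table(chrA = paste0("a", 1:4), chrB = paste0("b", 1:4))
  hits <- data.frame(gene1 = paste0("a", 1:4), gene2 = paste0("b", 1:4),
                     evalue = 1e-50)
  res <- detect_collinear_blocks(hits, genes)
  expect_equal(nrow(res$blocks), 0L)
})

test_that("a reversed segment is reported as an inverted block", {
  genes <- rank_table(chrA = paste0("a", 1:10), chrB = paste0("b", 1:10))
  hits <- data.frame(gene1 = paste0("a", 1:10), gene2 = paste0("b", 10:1),
                     evalue = 1e-50)
  res <- detect_collinear_blocks(hits, genes)
  expect_equal(nrow(res$blocks), 1L)
  expect_equal(res$blocks$orientation, "inverted")
  expect_equal(res$blocks$n_anchors, 10L)
})

test_that("rank gaps beyond max_gap break chains", {
  genes <- rank_table(chrA = sprintf("a%03d", 1:100),
                      chrB = sprintf("b%03d", 1:100))
  ## two runs of 4 anchors separated by a 30-rank gap: no block at min 5
  ia <- c(1:4, 35:38)
  hits <- data.frame(gene1 = sprintf("a%03d", ia),
                     gene2 = sprintf("b%03d", ia), evalue = 1e-50)
  res <- detect_collinear_blocks(hits, genes, max_gap = 25L, min_anchors = 5L)
  expect_equal(nrow(res$blocks), 0L)
  ## with a permissive gap the same matches chain into one block of 8
  res2 <- detect_collinear_blocks(hits, genes, max_gap = 40L, min_anchors = 5L)
  expect_equal(res2$blocks$n_anchors, 8L)
})

test_that("dynamic-programming chains equal exhaustive search on random match sets", {
  set.seed(77)
  for (case in 1:40) {
    n_matches <- sample(6:16, 1L)
    ra <- sample.int(200L, n_matches)
    rb <- sample.int(200L, n_matches)
    max_gap <- sample(c(5L, 15L, 25L), 1L)
    best_dp <- max(length(methyldup:::best_chain(ra, rb, max_gap)),
                   length(methyldup:::best_chain(ra, -rb, max_gap)))
    expect_equal(best_dp, oracle_best_chain_size(ra, rb, max_gap),
                 info = sprintf("case %d", case))
  }
  ## plus structured near-diagonal cases where chains actually grow
  for (case in 1:10) {
    n <- sample(8:14, 1L)
    ra <- cumsum(sample(1:6, n, replace = TRUE))
    rb <- cumsum(sample(1:6, n, replace = TRUE))
    jitter <- sample(n, 3L)
    rb[jitter] <- rb[jitter] + sample(c(-40L, 40L), 3L, replace = TRUE)
    best_dp <- max(length(methyldup:::best_chain(ra, rb, 25L)),
                   length(methyldup:::best_chain(ra, -rb, 25L)))
    expect_equal(best_dp, oracle_best_chain_size(ra, rb, 25L),
                 info = sprintf("diag case %d", case))
  }
})

test_that("greedy matching keeps each gene's lowest-e-value pair at most once", {
  hits <- data.frame(gene1 = c("A", "A", "B"), gene2 = c("B", "C", "C"),
                     evalue = c(1e-50, 1e-20, 1e-30))
  out <- select_unique_pairs(hits)
  ## A-B wins (lowest e-value); A and B are then spoken for, so no pair
  ## involving them survives and each gene appears at most once
  expect_equal(pair_key(out$gene1, out$gene2), "A|B")
  expect_lte(max(table(c(out$gene1, out$gene2))), 1L)
  ## disjoint pairs are all retained
  hits2 <- data.frame(gene1 = c("A", "C"), gene2 = c("B", "D"),
                      evalue = c(1e-50, 1e-20))
  expect_equal(nrow(select_unique_pairs(hits2)), 2L)
  ## a single hit is kept unchanged
  one <- data.frame(gene1 = "A", gene2 = "B", evalue = 1e-10)
  expect_equal(select_unique_pairs(one), one)
})

test_that("e-value ties resolve to the lexicographically smaller partner, independent of input order", {
  base <- data.frame(gene1 = c("A", "A"), gene2 = c("B", "C"),
                     evalue = c(1e-50, 1e-50))
  for (ord in list(1:2, 2:1)) {
    expect_message(out <- select_unique_pairs(base[ord, ]), "tied")
    expect_true("A|B" %in% pair_key(out$gene1, out$gene2))
    expect_false("A|C" %in% pair_key(out$gene1, out$gene2))
  }
})

test_that("pair typing follows the WGD > tandem > proximal > translocated > dispersed priority", {
  genes <- rank_table(chr1 = paste0("g", 1:30), chr2 = paste0("h", 1:5))
  anchors <- data.frame(block_id = 1L, gene_a = c("g1", "g2"),
                        gene_b = c("h1", "h2"))
  syntenic <- c("g1", "g2", "h1", "h2", "g25")
  pairs <- data.frame(
    gene1 = c("g1", "g3", "g8", "g8", "g25", "g5"),
    gene2 = c("h1", "g4", "g14", "g20", "h4", "h5"),
    evalue = 1e-60
  )
  out <- classify_pairs(pairs, genes, anchors, syntenic)
  expect_equal(as.character(out$dup_type),
               c("WGD",          # anchor pair (and one gene syntenic)
                 "tandem",       # adjacent ranks
                 "proximal",     # ranks 7 and 13: 5 intervening
                 "dispersed",    # ranks 7 and 19: 11 intervening, no synteny
                 "translocated", # exactly one syntenic
                 "dispersed"))
  expect_equal(out$parent_id[5], "g25")
  expect_equal(out$daughter_id[5], "h4")
  ## an adjacent pair that is also a block anchor is WGD by priority
  genes2 <- rank_table(chr1 = c("x1", "x2"))
  anch2 <- data.frame(block_id = 1L, gene_a = "x1", gene_b = "x2")
  out2 <- classify_pairs(data.frame(gene1 = "x1", gene2 = "x2", evalue = 0),
                         genes2, anch2, c("x1", "x2"))
  expect_equal(as.character(out2$dup_type), "WGD")
  ## unknown gene errors by name
  expect_error(classify_pairs(data.frame(gene1 = "zz", gene2 = "g1", evalue = 0),
                              genes, anchors, syntenic), "zz")
})

test_that("pair typing is invariant under swapping gene1 and gene2", {
  genes <- rank_table(chr1 = paste0("g", 1:30), chr2 = paste0("h", 1:5))
  anchors <- data.frame(block_id = 1L, gene_a = c("g1", "g2"),
                        gene_b = c("h1", "h2"))
  syntenic <- c("g1", "g2", "h1", "h2", "g25")
  pairs <- data.frame(gene1 = c("g1", "g3", "g8", "g25"),
                      gene2 = c("h1", "g4", "g14", "h4"), evalue = 0)
  swapped <- data.frame(gene1 = pairs$gene2, gene2 = pairs$gene1, evalue = 0)
  t1 <- classify_pairs(pairs, genes, anchors, syntenic)
  t2 <- classify_pairs(swapped, genes, anchors, syntenic)
  expect_equal(as.character(t1$dup_type), as.character(t2$dup_type))
  expect_equal(t1$parent_id, t2$parent_id)
})

test_that("epoch assignment matches the ladder rule exhaustively for k = 3", {
  expect_equal(assign_epoch(c(FALSE, FALSE, FALSE)), 0L)
  expect_equal(assign_epoch(c(FALSE, TRUE, TRUE)), 2L)
  expect_equal(assign_epoch(c(TRUE, FALSE, TRUE)), 1L)
  expect_true(is.na(assign_epoch(logical(0))))
  for (f1 in c(TRUE, FALSE)) for (f2 in c(TRUE, FALSE)) for (f3 in c(TRUE, FALSE)) {
    flags <- c(f1, f2, f3)
    expected <- if (!any(flags)) 0L else min(which(flags))
    expect_equal(assign_epoch(flags), expected)
  }
})

test_that("pair methylation classes are unordered and exclude unscored genes", {
  labels <- c(a = "gbM", b = "teM", c = "unM", d = "unM", e = "unclassified",
              f = "missing")
  pairs <- data.frame(gene1 = c("a", "b", "c", "a", "a"),
                      gene2 = c("b", "a", "d", "e", "f"))
  out <- pair_meth_class(pairs, labels)
  expect_equal(out$pair_meth_class[1:3], c("gbM-teM", "gbM-teM", "unM-unM"))
  expect_equal(out$same_class[1:3], c(FALSE, FALSE, TRUE))
  expect_true(all(out$excluded[4:5]))
  expect_true(all(is.na(out$pair_meth_class[4:5])))
})

test_that("switch direction treats the parental label as ancestral", {
  labels <- c(p1 = "gbM", d1 = "teM", p2 = "unM", d2 = "unM",
              p3 = "teM", d3 = "gbM")
  pairs <- data.frame(gene1 = c("p1", "p2", "p3"), gene2 = c("d1", "d2", "d3"),
                      parent_id = c("p1", "p2", "p3"),
                      daughter_id = c("d1", "d2", "d3"))
  out <- switch_direction(pairs, labels)
  expect_equal(out$switch_direction, c("to-teM", "same", "to-gbM"))
  expect_error(switch_direction(data.frame(gene1 = "x", gene2 = "y",
                                           parent_id = NA, daughter_id = "y"),
                                labels), "roles missing")
})

test_that("planted duplication types are fully recovered on a noise-free genome", {
  cfg <- sim_config(seed = 31, genes_per_chromosome = 400L,
                    n_tandem = 8L, n_proximal = 8L, n_translocated = 8L,
                    n_dispersed = 8L)
  g <- simulate_genome(cfg)
  blocks <- detect_collinear_blocks(g$hits, g$genes)
  syn <- unique(c(blocks$anchors$gene_a, blocks$anchors$gene_b))
  ranks2 <- rbind(g$genes[, c("gene_id", "chrom", "rank")], g$outgroup_genes)
  ob <- detect_collinear_blocks(g$outgroup_hits, ranks2)
  syn <- intersect(unique(c(syn, ob$anchors$gene_a, ob$anchors$gene_b)),
                   g$genes$gene_id)
  pairs <- classify_pairs(select_unique_pairs(g$hits), g$genes,
                          blocks$anchors, syn)
  called <- setNames(as.character(pairs$dup_type),
                     pair_key(pairs$gene1, pairs$gene2))
  truth <- setNames(as.character(g$truth_pairs$dup_type),
                    pair_key(g$truth_pairs$gene1, g$truth_pairs$gene2))
  expect_equal(unname(called[names(truth)]), unname(truth))
  ## epochs recovered from the emitted ladder flags
  tr <- g$truth_pairs[g$truth_pairs$dup_type == "translocated", ]
  rec <- vapply(tr$daughter_id,
                function(d) assign_epoch(g$epoch_flags[d, ]), 0L)
  expect_equal(unname(rec), tr$epoch)
})
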