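make_summary_row <- function(gene_id, n_sites, n_meth, mc, cov) {
  ## n_sites etc. are named vectors over CG/CHG/CHH; nonCG is derived
  row <- list(gene_id = gene_id)
  for (ctx in c("CG", "CHG", "CHH")) {
    row[[paste0("n_sites_", ctx)]] <- n_sites[[ctx]]
    row[[paste0("n_meth_", ctx)]] <- n_meth[[ctx]]
    row[[paste0("mc_", ctx)]] <- mc[[ctx]]
    row[[paste0("cov_", ctx)]] <- cov[[ctx]]
    row[[paste0("wm_", ctx)]] <- if (cov[[ctx]] > 0) mc[[ctx]] / cov[[ctx]] else NA_real_
  }
  row$n_sites_nonCG <- n_sites[["CHG"]] + n_sites[["CHH"]]
  row$n_meth_nonCG <- n_meth[["CHG"]] + n_meth[["CHH"]]
  row$mc_nonCG <- mc[["CHG"]] + mc[["CHH"]]
  row$cov_nonCG <- cov[["CHG"]] + cov[["CHH"]]
  row$wm_nonCG <- if (row$cov_nonCG > 0) row$mc_nonCG / row$cov_nonCG else NA_real_
  as.data.frame(row)
}

test_that("weighted methylation is the read-sum ratio with an undefined flag", {
  expect_equal(weighted_methylation(5, 20), 0.25)
  expect_equal(weighted_methylation(0, 50), 0)
  expect_true(is.na(weighted_methylation(0, 0)))
  expect_error(weighted_methylation(5, 4), "exceeds")
})

test_that("gene summaries count covered CDS sites per context", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 0L, end = 40L,
                      strand = "+", rank = 0L)
  cds <- data.frame(gene_id = "g1", start = 0L, end = 10L)
  sites <- data.frame(
    chrom = "chr1",
    pos = c(3L, 5L, 7L, 9L, 8L, 25L),
    strand = "+",
    context = c("CGA", "CGA", "CAG", "CTT", "CGA", "CGA"),
    mc_reads = c(5L, 0L, 2L, 1L, 0L, 9L),
    total_reads = c(5L, 6L, 10L, 10L, 0L, 9L),
    is_methylated = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
    covered = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  sites$context_class <- context_class(sites$context)
  s <- summarize_genes(sites, genes, cds)
  expect_equal(s$n_sites_CG, 2L)       # uncovered CG site and site at pos 25 excluded
  expect_equal(s$n_meth_CG, 1L)
  expect_equal(s$wm_CG, 5 / 11)
  ## CHG (2/10) + CHH (1/10) combine into nonCG
  expect_equal(s$n_sites_nonCG, 2L)
  expect_equal(s$wm_nonCG, 3 / 20)
})

test_that("a gene with no covered CDS sites is eligible only for missing", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                      start = c(0L, 100L), end = c(40L, 140L),
                      strand = "+", rank = 0:1)
  cds <- data.frame(gene_id = c("g1", "g2"), start = c(0L, 100L),
                    end = c(10L, 140L))
  sites <- data.frame(chrom = "chr1", pos = 105L, strand = "+",
                      context = "CGA", context_class = "CG",
                      mc_reads = 8L, total_reads = 10L,
                      is_methylated = TRUE, covered = TRUE)
  s <- summarize_genes(sites, genes, cds)
  cl <- classify_genes(s, list(b_CG = 0.2, b_CHG = 0.05, b_CHH = 0.05,
                               b_nonCG = 0.05))
  expect_equal(as.character(cl$label[cl$gene_id == "g1"]), "missing")
})

test_that("background is the unweighted per-gene mean of methylated-site fractions", {
  s <- rbind(
    make_summary_row("g1", c(CG = 10, CHG = 5, CHH = 5), c(CG = 2, CHG = 0, CHH = 0),
                     c(CG = 20, CHG = 0, CHH = 0), c(CG = 100, CHG = 50, CHH = 50)),
    make_summary_row("g2", c(CG = 20, CHG = 5, CHH = 5), c(CG = 8, CHG = 1, CHH = 0),
                     c(CG = 40, CHG = 5, CHH = 0), c(CG = 100, CHG = 50, CHH = 50))
  )
  b <- compute_background(s)
  expect_equal(b$b_CG, mean(c(0.2, 0.4)))
  expect_equal(b$b_CHG, mean(c(0, 0.2)))
  ## a gene without sites in a context is excluded from that context
  s$n_sites_CHH[1] <- 0
  s$n_meth_CHH[1] <- 0
  b2 <- compute_background(s)
  expect_equal(b2$b_CHH, 0 / 5)
  expect_equal(unname(b2$n_genes_used["CHH"]), 1L)
})

test_that("background estimate matches a Beta-distributed simulation mean", {
  set.seed(421)
  n_genes <- 1000L
  frac <- rbeta(n_genes, 2, 8)  # mean 0.2
  n_sites <- rep(50L, n_genes)
  n_meth <- rbinom(n_genes, n_sites, frac)
  rows <- lapply(seq_len(n_genes), function(i) {
    make_summary_row(paste0("g", i),
                     c(CG = n_sites[i], CHG = 1, CHH = 1),
                     c(CG = n_meth[i], CHG = 0, CHH = 0),
                     c(CG = n_meth[i], CHG = 0, CHH = 0),
                     c(CG = n_sites[i], CHG = 10, CHH = 10))
  })
  b <- compute_background(do.call(rbind, rows))
  se <- sqrt(0.2 * 0.8 / n_genes * (1 + 1 / 10))  # beta + binomial noise, loose
  expect_lt(abs(b$b_CG - 0.2), 3 * se)
})

test_that("enrichment p-values match closed forms and direct summation", {
  s <- make_summary_row("g", c(CG = 10, CHG = 20, CHH = 1),
                        c(CG = 10, CHG = 8, CHH = 0),
                        c(CG = 100, CHG = 80, CHH = 0),
                        c(CG = 100, CHG = 200, CHH = 10))
  bg <- list(b_CG = 0.5, b_CHG = 0.1, b_CHH = 0.1, b_nonCG = 0.1)
  p <- test_enrichment(s, bg)
  expect_equal(p$p_CG, 2^-10)
  expect_equal(p$p_CHG, oracle_binom_upper(8, 20, 0.1))
  expect_equal(p$p_CHH, 1)  # zero methylated -> upper tail is 1
  ## undefined where no covered sites
  s0 <- make_summary_row("g0", c(CG = 0, CHG = 3, CHH = 3),
                         c(CG = 0, CHG = 0, CHH = 0),
                         c(CG = 0, CHG = 0, CHH = 0),
                         c(CG = 0, CHG = 30, CHH = 30))
  expect_true(is.na(test_enrichment(s0, bg)$p_CG))
})

test_that("the classification decision tree follows the stated precedence", {
  bg <- list(b_CG = 0.1, b_CHG = 0.1, b_CHH = 0.1, b_nonCG = 0.1)
  s <- rbind(
    ## gbM: CG enriched with >= 10 sites, CHG/CHH at background
    make_summary_row("gbm", c(CG = 15, CHG = 20, CHH = 20),
                     c(CG = 15, CHG = 2, CHH = 2),
                     c(CG = 150, CHG = 20, CHH = 20),
                     c(CG = 150, CHG = 200, CHH = 200)),
    ## teM: CHG enriched with >= 10 sites, regardless of CG enrichment
    make_summary_row("tem", c(CG = 15, CHG = 12, CHH = 20),
                     c(CG = 15, CHG = 12, CHH = 2),
                     c(CG = 150, CHG = 120, CHH = 20),
                     c(CG = 150, CHG = 120, CHH = 200)),
    ## unM: CG enriched but only 9 sites; low weighted methylation
    make_summary_row("unm_sites", c(CG = 9, CHG = 20, CHH = 20),
                     c(CG = 9, CHG = 0, CHH = 0),
                     c(CG = 3, CHG = 0, CHH = 0),
                     c(CG = 200, CHG = 200, CHH = 200)),
    ## unM: a single methylated site, nothing significant
    make_summary_row("unm_one", c(CG = 15, CHG = 20, CHH = 20),
                     c(CG = 1, CHG = 0, CHH = 0),
                     c(CG = 30, CHG = 10, CHH = 10),
                     c(CG = 150, CHG = 200, CHH = 200)),
    ## unclassified: several methylated sites, 5% weighted CG, no enrichment
    make_summary_row("uncl", c(CG = 30, CHG = 20, CHH = 20),
                     c(CG = 3, CHG = 1, CHH = 1),
                     c(CG = 15, CHG = 6, CHH = 6),
                     c(CG = 300, CHG = 200, CHH = 200))
  )
  cl <- classify_genes(s, bg)
  labels <- setNames(as.character(cl$label), cl$gene_id)
  expect_equal(unname(labels["gbm"]), "gbM")
  expect_equal(unname(labels["tem"]), "teM")
  expect_equal(unname(labels["unm_sites"]), "unM")
  expect_equal(unname(labels["unm_one"]), "unM")
  expect_equal(unname(labels["uncl"]), "unclassified")
  ## exactly one label per gene, drawn from the closed label set
  expect_true(all(labels %in% c("gbM", "teM", "unM", "unclassified", "missing")))
})

test_that("enrichment p-values are monotone in the methylated-site count", {
  bg <- list(b_CG = 0.3, b_CHG = 0.3, b_CHH = 0.3, b_nonCG = 0.3)
  p_prev <- 1
  for (k in 0:20) {
    s <- make_summary_row("g", c(CG = 20, CHG = 1, CHH = 1),
                          c(CG = k, CHG = 0, CHH = 0),
                          c(CG = k, CHG = 0, CHH = 0),
                          c(CG = 20, CHG = 10, CHH = 10))
    p <- test_enrichment(s, bg)$p_CG
    expect_lte(p, p_prev + 1e-12)
    p_prev <- p
  }
})

test_that("classifier recovery is seed-stable", {
  accs <- vapply(1:3, function(seed) {
    cfg <- sim_config(seed = seed, genes_per_chromosome = 150L,
                      n_chromosomes = 2L, wgd_blocks = 0L, n_tandem = 0L,
                      n_proximal = 0L, n_translocated = 0L, n_dispersed = 0L)
    g <- simulate_genome(cfg)
    set.seed(seed + 1000L)
    classes <- setNames(sample(names(cfg$class_mix), nrow(g$genes), TRUE,
                               cfg$class_mix), g$genes$gene_id)
    allc <- simulate_methylome(g$genes, g$cds, classes, cfg)
    s <- summarize_genes(allc, g$genes, g$cds)
    cl <- classify_genes(s, compute_background(s))
    mean(as.character(cl$label) == classes[cl$gene_id])
  }, 0)
  expect_true(all(accs >= 0.95))
  expect_lt(max(accs) - min(accs), 0.02)
})

test_that("the per-site re-caller applies the error-rate binomial test", {
  ## at 20x and epsilon 0.005, two methylated reads are needed for a call
  expect_false(call_site_methylation(1L, 20L))
  expect_true(call_site_methylation(2L, 20L))
  expect_false(call_site_methylation(0L, 0L))
  p2 <- oracle_binom_upper(2, 20, 0.005)
  expect_lt(p2, 0.01)
  expect_gt(oracle_binom_upper(1, 20, 0.005), 0.01)
})
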