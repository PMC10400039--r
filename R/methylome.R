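## Genic methylation classification: gbM / teM / unM / unclassified /
## missing, from per-cytosine calls summarized over primary-transcript CDS.

CONTEXTS <- c("CG", "CHG", "CHH", "nonCG")
METH_LABELS <- c("gbM", "teM", "unM", "unclassified", "missing")

#' Weighted methylation level
#'
#' The ratio of methylated reads to total reads summed over sites,
#' `sum_mc / sum_cov`. Returns `NA` (undefined) when there is no coverage.
#'
#' @param sum_mc Summed methylated read counts (vectorized).
#' @param sum_cov Summed total read counts.
#' @return Numeric vector of proportions in `[0, 1]`, `NA` where
#'   `sum_cov == 0`.
#' @export
weighted_methylation <- function(sum_mc, sum_cov) {
  if (any(sum_mc > sum_cov)) stop_("sum_mc exceeds sum_cov")
  if (any(sum_mc < 0) || any(sum_cov < 0)) stop_("negative read counts")
  ifelse(sum_cov > 0, sum_mc / sum_cov, NA_real_)
}

#' Summarize per-cytosine calls over gene CDS intervals
#'
#' Restricts methylation sites to positions inside the CDS intervals of
#' each gene and accumulates, per context class (CG, CHG, CHH, and the
#' combined nonCG), the number of covered sites, the number of methylated
#' sites, read sums, and the weighted methylation level. Sites on both
#' strands are counted regardless of gene strand; sites with zero
#' coverage are excluded from site counts.
#'
#' @param sites Data frame of methylation sites as from [read_allc()].
#' @param genes,cds Gene models as from [read_gff()].
#' @return Data frame with one row per gene: `gene_id` and, for each
#'   context `c` in `CG, CHG, CHH, nonCG`, columns `n_sites_c`,
#'   `n_meth_c`, `mc_c`, `cov_c`, `wm_c`. Genes whose CDS contains no
#'   covered site have all-zero counts (eligible only for the `missing`
#'   label downstream).
#' @export
summarize_genes <- function(sites, genes, cds) {
  genes <- as.data.table(genes)
  cdsdt <- as.data.table(cds)
  sites <- as.data.table(sites)

  base <- CJ(gene_id = genes$gene_id, context_class = c("CG", "CHG", "CHH"))
  if (nrow(cdsdt) && nrow(sites)) {
    ## assign covered sites to CDS intervals via IRanges overlap
    s <- sites[covered == TRUE]
    if (nrow(s)) {
      q <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$pos, width = 1L))
      cds_chrom <- genes$chrom[match(cdsdt$gene_id, genes$gene_id)]
      subj <- GenomicRanges::GRanges(cds_chrom,
                                     IRanges::IRanges(cdsdt$start + 1L, cdsdt$end))
      ov <- GenomicRanges::findOverlaps(q, subj, ignore.strand = TRUE)
      hit <- data.table(
        gene_id = cdsdt$gene_id[S4Vectors::subjectHits(ov)],
        context_class = s$context_class[S4Vectors::queryHits(ov)],
        mc_reads = s$mc_reads[S4Vectors::queryHits(ov)],
        total_reads = s$total_reads[S4Vectors::queryHits(ov)],
        is_methylated = s$is_methylated[S4Vectors::queryHits(ov)]
      )
      agg <- hit[, .(n_sites = .N, n_meth = sum(is_methylated),
                     mc = sum(mc_reads), cov = sum(total_reads)),
                 by = .(gene_id, context_class)]
    } else {
      agg <- NULL
    }
  } else agg <- NULL
  if (is.null(agg) || !nrow(agg)) {
    agg <- data.table(gene_id = character(), context_class = character(),
                      n_sites = integer(), n_meth = integer(),
                      mc = integer(), cov = integer())
  }

  long <- merge(base, agg, by = c("gene_id", "context_class"), all.x = TRUE)
  for (col in c("n_sites", "n_meth", "mc", "cov")) {
    long[is.na(get(col)), (col) := 0L]
  }
  noncg <- long[context_class %in% c("CHG", "CHH"),
                .(context_class = "nonCG", n_sites = sum(n_sites),
                  n_meth = sum(n_meth), mc = sum(mc), cov = sum(cov)),
                by = gene_id]
  long <- rbind(long, noncg)
  long[, wm := weighted_methylation(mc, cov)]

  wide <- dcast(long, gene_id ~ context_class,
                value.var = c("n_sites", "n_meth", "mc", "cov", "wm"), sep = "_")
  setcolorder(wide, c("gene_id",
                      as.vector(t(outer(c("n_sites", "n_meth", "mc", "cov", "wm"),
                                        CONTEXTS, paste, sep = "_")))))
  ## preserve input gene order
  wide <- wide[match(genes$gene_id, gene_id)]
  as.data.frame(wide)
}

#' Per-context background methylation rates
#'
#' The background rate for each context is the unweighted mean over genes
#' of the fraction of methylated sites in that context; genes with no
#' covered site in a context are excluded from that context's mean.
#'
#' @param summaries Gene summaries from [summarize_genes()]. Pass
#'   summaries from a single species for a per-species background, or
#'   row-bind several species for a pooled background.
#' @return A list with elements `b_CG`, `b_CHG`, `b_CHH`, `b_nonCG` and
#'   `n_genes_used` (named integer vector per context).
#' @export
compute_background <- function(summaries) {
  s <- as.data.table(summaries)
  rates <- lapply(CONTEXTS, function(ctx) {
    n <- s[[paste0("n_sites_", ctx)]]
    m <- s[[paste0("n_meth_", ctx)]]
    use <- n > 0
    if (!any(use)) stop_("no genes with covered %s sites; cannot estimate background", ctx)
    list(b = mean(m[use] / n[use]), n_used = sum(use))
  })
  names(rates) <- CONTEXTS
  out <- list(b_CG = rates$CG$b, b_CHG = rates$CHG$b,
              b_CHH = rates$CHH$b, b_nonCG = rates$nonCG$b,
              n_genes_used = vapply(rates, `[[`, integer(1), "n_used"))
  out
}

#' One-tailed binomial enrichment test per context
#'
#' For each gene and context, tests whether the number of methylated
#' sites exceeds the background expectation: the upper-tail binomial
#' probability `P(X >= n_meth)` with `X ~ Binomial(n_sites, b)`. The
#' p-value is undefined (`NA`) for genes with no covered site in that
#' context. A zero background with observed methylation gives p = 0; a
#' zero background with no methylation gives p = 1.
#'
#' @param summaries Gene summaries from [summarize_genes()].
#' @param background Background rates from [compute_background()].
#' @return `summaries` with added columns `p_CG`, `p_CHG`, `p_CHH`,
#'   `p_nonCG`.
#' @export
test_enrichment <- function(summaries, background) {
  s <- as.data.table(summaries)
  for (ctx in CONTEXTS) {
    n <- s[[paste0("n_sites_", ctx)]]
    k <- s[[paste0("n_meth_", ctx)]]
    b <- background[[paste0("b_", ctx)]]
    p <- binom_upper_tail(k, n, b)
    p[n == 0] <- NA_real_
    s[, (paste0("p_", ctx)) := p]
  }
  as.data.frame(s)
}

## P(X >= k), X ~ Binomial(n, b); handles the degenerate b = 0 edge.
binom_upper_tail <- function(k, n, b) {
  if (b < 0 || b > 1) stop_("background rate outside [0, 1]")
  if (b == 0) return(ifelse(k > 0, 0, 1))
  stats::pbinom(k - 1L, n, b, lower.tail = FALSE)
}

#' Classify genes as gbM, teM, unM, unclassified or missing
#'
#' Applies, per context, Benjamini-Hochberg correction across genes with
#' a defined p-value (via [bh_adjust()]), then the decision tree, in
#' order:
#' \enumerate{
#'   \item \strong{missing} -- no covered CDS site in any context;
#'   \item \strong{teM} -- enrichment (`q < alpha`) for CHG, CHH or
#'     non-CG with at least `min_sites` covered sites in that context;
#'   \item \strong{gbM} -- enrichment for CG with at least `min_sites` CG
#'     sites and no significant CHG or CHH enrichment;
#'   \item \strong{unM} -- at most `unm_max_meth_sites` methylated sites
#'     across CG+CHG+CHH (option `unm_rule = "per_context"` instead
#'     requires it in every context), or weighted methylation at most
#'     `unm_max_wm` in all of CG, CHG and CHH (contexts without coverage
#'     count as unmethylated);
#'   \item \strong{unclassified} -- anything else.
#' }
#'
#' @param summaries Gene summaries from [summarize_genes()], one species.
#' @param background Background rates from [compute_background()].
#' @param alpha FDR threshold on BH-adjusted q-values (default 0.05).
#' @param min_sites Minimum covered sites in the enriched context
#'   (default 10).
#' @param unm_max_meth_sites Methylated-site ceiling for unM (default 1).
#' @param unm_max_wm Weighted-methylation ceiling for unM (default 0.02).
#' @param unm_rule `"total"` (default) applies the methylated-site
#'   ceiling to the CG+CHG+CHH total; `"per_context"` to each context.
#' @return `summaries` with added `p_*`, `q_*` columns and a `label`
#'   column taking exactly one of `gbM`, `teM`, `unM`, `unclassified`,
#'   `missing` per gene.
#' @export
classify_genes <- function(summaries, background, alpha = 0.05,
                           min_sites = 10L, unm_max_meth_sites = 1L,
                           unm_max_wm = 0.02,
                           unm_rule = c("total", "per_context")) {
  unm_rule <- match.arg(unm_rule)
  s <- as.data.table(test_enrichment(summaries, background))
  for (ctx in CONTEXTS) {
    s[, (paste0("q_", ctx)) := bh_adjust(get(paste0("p_", ctx)))]
  }

  sig <- function(ctx) {
    q <- s[[paste0("q_", ctx)]]
    !is.na(q) & q < alpha
  }
  nsite <- function(ctx) s[[paste0("n_sites_", ctx)]]

  is_missing <- nsite("CG") + nsite("CHG") + nsite("CHH") == 0L
  is_tem <- (sig("CHG") & nsite("CHG") >= min_sites) |
    (sig("CHH") & nsite("CHH") >= min_sites) |
    (sig("nonCG") & nsite("nonCG") >= min_sites)
  is_gbm <- sig("CG") & nsite("CG") >= min_sites & !sig("CHG") & !sig("CHH")

  meth_per_ctx <- cbind(s$n_meth_CG, s$n_meth_CHG, s$n_meth_CHH)
  few_meth <- if (unm_rule == "total") {
    rowSums(meth_per_ctx) <= unm_max_meth_sites
  } else {
    apply(meth_per_ctx <= unm_max_meth_sites, 1L, all)
  }
  wm <- cbind(s$wm_CG, s$wm_CHG, s$wm_CHH)
  wm[is.na(wm)] <- 0  # no coverage in a context counts as unmethylated
  low_wm <- rowSums(wm <= unm_max_wm) == 3L
  is_unm <- few_meth | low_wm

  label <- rep("unclassified", nrow(s))
  label[is_unm] <- "unM"
  label[is_gbm] <- "gbM"
  label[is_tem] <- "teM"
  label[is_missing] <- "missing"
  s[, label := factor(label, levels = METH_LABELS)]
  as.data.frame(s)
}

#' Re-call per-site methylation status
#'
#' For allc inputs that lack the methylated-site call column: a site is
#' called methylated when the one-tailed binomial p-value of its
#' methylated read count against a sequencing/conversion error rate
#' `epsilon` falls below `p_cut`.
#'
#' @param mc_reads,total_reads Integer vectors of read counts.
#' @param epsilon Per-read error rate (default 0.005).
#' @param p_cut Call threshold on the binomial p-value (default 0.01).
#' @return Logical vector; `FALSE` for uncovered sites.
#' @export
call_site_methylation <- function(mc_reads, total_reads, epsilon = 0.005,
                                  p_cut = 0.01) {
  p <- stats::pbinom(mc_reads - 1L, total_reads, epsilon, lower.tail = FALSE)
  total_reads > 0L & p < p_cut
}
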