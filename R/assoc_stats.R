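## Shared statistical layer: Fisher enrichment, BH correction,
## two-proportion contrasts, TE association, genomic sliding windows,
## PAV calling, population epiallele frequencies, grouped summaries.

FREQ_BINS <- c("0%", "<25%", "25-50%", "50-75%", ">75%")

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' The two-sided p-value follows the minimum-likelihood convention (the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins that are no more probable than the observed table). The odds
#' ratio reported is the sample odds ratio `(a*d)/(b*c)` with
#' `Inf`/`0` sentinels for zero cells, plus a Haldane-Anscombe (+0.5)
#' version for plotting.
#'
#' @param a,b,c,d Nonnegative integer cell counts: `a` = in both sets,
#'   `b` = label only, `c` = category only, `d` = neither.
#' @return A list: `a,b,c,d`, `odds_ratio`, `odds_ratio_h` (+0.5
#'   smoothed), `p`, `direction` (`"enriched"`, `"depleted"`, `"none"`).
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (!is_count(cells)) stop_("cell counts must be nonnegative integers")
  if (sum(cells) == 0) stop_("all-zero contingency table")
  p <- stats::fisher.test(matrix(cells, nrow = 2L, byrow = TRUE))$p.value
  or <- if (b * c > 0) (a * d) / (b * c) else if (a * d > 0) Inf else NA_real_
  if (!is.na(or) && or == 0 && a * d == 0 && b * c > 0) or <- 0
  or_h <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  direction <- if (is.na(or) || or == 1) "none" else if (or > 1) "enriched" else "depleted"
  list(a = a, b = b, c = c, d = d, odds_ratio = or, odds_ratio_h = or_h,
       p = min(p, 1), direction = direction)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment preserving input order;
#' `q_i = min over p_(j) >= p_(i) of p_(j) * m / rank(j)`, capped at 1.
#' `NA` p-values are excluded from the family and returned as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]`; NA allowed.
#' @return q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_("p-values outside [0, 1]")
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

#' Enrichment scan of a label partition against a category partition
#'
#' For every (label, category) combination, tests the 2x2 table
#' `a = |L intersect C|`, `b = |L \\ C|`, `c = |C \\ L|`, `d = rest` with
#' [fisher_exact()] and applies BH correction across all tests of the
#' scan. By default the universe excludes genes labelled `missing` or
#' `unclassified` (the three informative methylation classes are
#' tested); pass `universe = "all"` to keep every gene.
#'
#' @param labels Named character vector gene -> label (e.g. methylation
#'   class).
#' @param categories Named character vector gene -> category (e.g.
#'   duplication type or orthogroup category).
#' @param universe `"classified"` (default; drops `missing` and
#'   `unclassified` labels) or `"all"`.
#' @return Long data frame: `label`, `category`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `odds_ratio_h`, `p`, `q`, `direction`.
#' @export
enrichment_scan <- function(labels, categories,
                            universe = c("classified", "all")) {
  universe <- match.arg(universe)
  genes <- intersect(names(labels), names(categories))
  lab <- as.character(labels[genes])
  cat_ <- as.character(categories[genes])
  keep <- !is.na(lab) & !is.na(cat_)
  if (universe == "classified") keep <- keep & !lab %in% c("missing", "unclassified")
  lab <- lab[keep]; cat_ <- cat_[keep]
  n <- length(lab)
  rows <- list()
  for (L in sort(unique(lab))) {
    for (C in sort(unique(cat_))) {
      inC <- cat_ == C
      if (!any(inC)) {
        warn_("empty category '%s'; skipped", C)
        next
      }
      a <- sum(lab == L & inC)
      b <- sum(lab == L & !inC)
      cc <- sum(lab != L & inC)
      d <- n - a - b - cc
      f <- fisher_exact(a, b, cc, d)
      rows[[length(rows) + 1L]] <- data.frame(
        label = L, category = C, a = a, b = b, c = cc, d = d,
        odds_ratio = f$odds_ratio, odds_ratio_h = f$odds_ratio_h,
        p = f$p, direction = f$direction
      )
    }
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

#' Two-proportion Z-test
#'
#' Pooled-variance Z-test of `x1/n1` versus `x2/n2` with a two-sided
#' normal p-value and no continuity correction. A pooled proportion of
#' exactly 0 or 1 carries no information and returns `z = 0`, `p = 1`
#' with `degenerate = TRUE`.
#'
#' @param x1,n1,x2,n2 Successes and totals of the two groups.
#' @return A list: `z`, `p`, `p1`, `p2`, `degenerate`.
#' @export
two_proportion_z <- function(x1, n1, x2, n2) {
  if (!is_count(c(x1, n1, x2, n2)) || x1 > n1 || x2 > n2 || n1 == 0 || n2 == 0)
    stop_("need 0 <= x <= n with n > 0 for both groups")
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp == 0 || pp == 1) {
    return(list(z = 0, p = 1, p1 = p1, p2 = p2, degenerate = TRUE))
  }
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), p1 = p1, p2 = p2,
       degenerate = FALSE)
}

#' Transposable-element association of genes
#'
#' A gene is TE-associated when any TE interval overlaps the gene body
#' extended by `margin` base pairs on both sides
#' (`[start - margin, end + margin)`, same chromosome).
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param tes Data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [read_te_bed()].
#' @param margin Flank size in base pairs (default 1000).
#' @return Named logical vector over `genes$gene_id`.
#' @export
te_association <- function(genes, tes, margin = 1000L) {
  genes <- as.data.frame(genes)
  tes <- as.data.frame(tes)
  out <- setNames(rep(FALSE, nrow(genes)), genes$gene_id)
  if (!nrow(tes) || !nrow(genes)) return(out)
  ## 0-based half-open -> 1-based closed for IRanges
  q <- GenomicRanges::GRanges(genes$chrom,
                              IRanges::IRanges(genes$start - margin + 1L,
                                               genes$end + margin))
  s <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start + 1L, tes$end))
  hit <- GenomicRanges::countOverlaps(q, s, ignore.strand = TRUE) > 0
  out[] <- hit
  out
}

#' Sliding-window genomic profiles and class-density correlations
#'
#' Tiles each chromosome with windows of `window` bp starting at 0 and
#' stepping by `step` bp while the window start is inside the
#' chromosome (the last window is truncated). A gene is counted in a
#' window when its midpoint lies in the window; TEs are counted by
#' overlap and by overlapping base pairs. Pearson correlations (with
#' t-based two-sided p and BH correction across the correlation family)
#' are computed between each methylation-class count and total gene
#' count, TE count, and TE base pairs across all windows.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `start`, `end`.
#' @param labels Named vector gene -> methylation class.
#' @param tes TE data frame (`chrom`, `start`, `end`).
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window,step Window and step sizes in bp (defaults 100 kb /
#'   50 kb).
#' @return A list with `windows` (per window: `chrom`, `start`, `end`,
#'   `n_genes`, one `n_<class>` column per class, `n_TEs`, `te_bp`) and
#'   `correlations` (`class`, `against`, `r`, `p`, `q`).
#' @export
sliding_windows <- function(genes, labels, tes, chrom_lengths,
                            window = 100000L, step = 50000L) {
  genes <- as.data.frame(genes)
  tes <- as.data.frame(tes)
  classes <- sort(unique(as.character(labels)))
  wins <- rbindlist(lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    starts <- seq(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    data.table(chrom = ch, start = starts, end = pmin(starts + window, len))
  }))

  mid <- genes$start + (genes$end - genes$start) %/% 2L
  lab <- as.character(labels[genes$gene_id])
  counts <- matrix(0L, nrow = nrow(wins), ncol = 1L + length(classes),
                   dimnames = list(NULL, c("n_genes", paste0("n_", classes))))
  for (i in seq_len(nrow(wins))) {
    inw <- genes$chrom == wins$chrom[i] & mid >= wins$start[i] & mid < wins$end[i]
    counts[i, "n_genes"] <- sum(inw)
    for (cl in classes) counts[i, paste0("n_", cl)] <- sum(inw & !is.na(lab) & lab == cl)
  }
  n_te <- integer(nrow(wins))
  te_bp <- numeric(nrow(wins))
  if (nrow(tes)) {
    wq <- GenomicRanges::GRanges(wins$chrom,
                                 IRanges::IRanges(wins$start + 1L, wins$end))
    ts <- GenomicRanges::GRanges(tes$chrom, IRanges::IRanges(tes$start + 1L, tes$end))
    ov <- GenomicRanges::findOverlaps(wq, ts, ignore.strand = TRUE)
    if (length(ov)) {
      inter <- IRanges::pintersect(wq[S4Vectors::queryHits(ov)],
                                   ts[S4Vectors::subjectHits(ov)])
      widths <- GenomicRanges::width(inter)
      agg <- data.table(w = S4Vectors::queryHits(ov), bp = widths)[
        , .(n = .N, bp = sum(bp)), by = w]
      n_te[agg$w] <- agg$n
      te_bp[agg$w] <- agg$bp
    }
  }
  windows <- cbind(as.data.frame(wins), as.data.frame(counts),
                   n_TEs = n_te, te_bp = te_bp)

  targets <- c("n_genes", "n_TEs", "te_bp")
  cors <- list()
  for (cl in classes) {
    for (tg in targets) {
      x <- windows[[paste0("n_", cl)]]
      y <- windows[[tg]]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x, y, method = "pearson")
        r <- unname(ct$estimate); p <- ct$p.value
      }
      cors[[length(cors) + 1L]] <- data.frame(class = cl, against = tg,
                                              r = r, p = p)
    }
  }
  correlations <- do.call(rbind, cors)
  correlations$q <- bh_adjust(correlations$p)
  list(windows = windows, correlations = correlations)
}

#' Call presence-absence variable (PAV) genes
#'
#' A gene is PAV when its average read coverage is strictly below
#' `threshold` in at least one accession.
#'
#' @param coverage Numeric matrix genes x accessions with gene rownames.
#' @param threshold Coverage cutoff (default 0.2).
#' @return Named logical vector over genes.
#' @export
call_pav <- function(coverage, threshold = 0.2) {
  if (any(coverage < 0, na.rm = TRUE)) stop_("negative coverage values")
  setNames(apply(coverage, 1L, function(x) any(x < threshold, na.rm = TRUE)),
           rownames(coverage))
}

#' Bin a class frequency into population-frequency strata
#'
#' Bins on the percent scale: exactly 0 -> `"0%"`; `(0, 25)` ->
#' `"<25%"`; `[25, 50)` -> `"25-50%"`; `[50, 75)` -> `"50-75%"`;
#' `[75, 100]` -> `">75%"` (bins above zero are left-closed).
#'
#' @param freq Frequencies in `[0, 1]`.
#' @return Factor with levels `0%`, `<25%`, `25-50%`, `50-75%`, `>75%`.
#' @export
bin_frequency <- function(freq) {
  pct <- freq * 100
  bin <- ifelse(is.na(pct), NA_character_,
         ifelse(pct == 0, "0%",
         ifelse(pct < 25, "<25%",
         ifelse(pct < 50, "25-50%",
         ifelse(pct < 75, "50-75%", ">75%")))))
  factor(bin, levels = FREQ_BINS)
}

#' Population epiallele frequencies per gene
#'
#' From a genes x accessions matrix of per-accession methylation labels,
#' computes, per gene, the frequency of each class among accessions with
#' an informative (non-missing) label, and the frequency bin per class
#' via [bin_frequency()]. Genes informative in no accession are excluded.
#'
#' @param labels Character matrix or data frame (genes x accessions);
#'   `NA` or `"missing"` marks accessions without data.
#' @param classes Classes to report (default gbM, teM, unM,
#'   unclassified).
#' @return Data frame: `gene_id`, `n_accessions_with_data`, then
#'   `freq_<class>` and `bin_<class>` per class.
#' @export
population_frequency <- function(labels,
                                 classes = c("gbM", "teM", "unM", "unclassified")) {
  m <- as.matrix(labels)
  m[m == "missing"] <- NA
  informative <- rowSums(!is.na(m))
  if (any(informative == 0)) {
    message(sum(informative == 0), " gene(s) with no informative accession excluded")
  }
  keep <- informative > 0
  m <- m[keep, , drop = FALSE]
  out <- data.frame(gene_id = rownames(m) %||% as.character(seq_len(nrow(m))),
                    n_accessions_with_data = informative[keep],
                    row.names = NULL)
  for (cl in classes) {
    f <- rowSums(m == cl, na.rm = TRUE) / out$n_accessions_with_data
    out[[paste0("freq_", cl)]] <- f
    out[[paste0("bin_", cl)]] <- bin_frequency(f)
  }
  out
}

#' Grouped distribution summaries ranked by median
#'
#' Summarizes a numeric quantity (Ks, Ka/Ks, tau, ...) per group:
#' counts, median and quartiles, with undefined values excluded and
#' counted, and groups ranked by median.
#'
#' @param values Numeric vector (NA allowed).
#' @param groups Grouping vector of the same length.
#' @return Data frame ordered by median: `group`, `n`, `n_undefined`,
#'   `median`, `q1`, `q3`, `rank` (1 = smallest median; empty groups get
#'   `n = 0` and no rank).
#' @export
summarize_by_group <- function(values, groups) {
  dt <- data.table(value = values, group = as.character(groups))
  out <- dt[, .(
    n = sum(!is.na(value)),
    n_undefined = sum(is.na(value)),
    median = stats::median(value, na.rm = TRUE),
    q1 = if (any(!is.na(value))) unname(stats::quantile(value, 0.25, na.rm = TRUE)) else NA_real_,
    q3 = if (any(!is.na(value))) unname(stats::quantile(value, 0.75, na.rm = TRUE)) else NA_real_
  ), by = group]
  out[n == 0, median := NA_real_]
  setorder(out, median, na.last = TRUE)
  out[, rank := ifelse(n > 0, cumsum(n > 0), NA_integer_)]
  as.data.frame(out)
}
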