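## Expression specificity (tau) and per-pair expression divergence.

#' Tissue-specificity index tau
#'
#' For a nonnegative expression vector `x` over `n >= 2` conditions,
#' `tau = sum(1 - x/max(x)) / (n - 1)`: 0 for uniformly (broadly)
#' expressed genes, 1 for expression confined to a single condition.
#' Genes not expressed in any condition have no defined tau (`NA`).
#'
#' @param x Nonnegative numeric vector of normalized expression values.
#' @param log2 Apply a `log2(x + 1)` transform before computing tau
#'   (default `FALSE`; tau is computed on linear values).
#' @return Scalar tau in `[0, 1]`, or `NA` when `max(x) == 0`.
#' @export
compute_tau <- function(x, log2 = FALSE) {
  if (length(x) < 2L) stop_("tau needs at least 2 conditions")
  if (any(is.na(x))) stop_("missing expression values")
  if (any(x < 0)) stop_("expression values must be nonnegative")
  if (log2) x <- base::log2(x + 1)
  mx <- max(x)
  if (mx == 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1L)
}

#' Per-gene expression summaries
#'
#' @param mat Expression matrix (genes x conditions) with gene rownames.
#' @param log2 Passed to [compute_tau()].
#' @return Data frame: `gene_id`, `tau`, `n_conditions`, `max_expression`.
#' @export
expression_summary <- function(mat, log2 = FALSE) {
  data.frame(
    gene_id = rownames(mat),
    tau = apply(mat, 1L, compute_tau, log2 = log2),
    n_conditions = ncol(mat),
    max_expression = apply(mat, 1L, max),
    row.names = NULL
  )
}

#' Expression divergence of duplicate pairs
#'
#' For each pair, the Pearson correlation of the two genes' expression
#' profiles across conditions and the absolute difference in tau.
#' Correlation is undefined (`NA`, flagged) when either profile has zero
#' variance; `abs_delta_tau` is undefined when either tau is (gene not
#' expressed in any condition).
#'
#' @param pairs Data frame with `gene1`, `gene2`.
#' @param mat Expression matrix with gene rownames; both genes of a pair
#'   must be present (others get `NA` with `in_matrix = FALSE`).
#' @param log2 Passed to [compute_tau()].
#' @return `pairs` with added `pearson_r`, `abs_delta_tau`, `in_matrix`,
#'   `zero_variance` columns.
#' @export
pair_expression <- function(pairs, mat, log2 = FALSE) {
  pairs <- as.data.frame(pairs)
  tau <- setNames(apply(mat, 1L, compute_tau, log2 = log2), rownames(mat))
  n <- nrow(pairs)
  r <- dt <- rep(NA_real_, n)
  zv <- rep(NA, n)
  present <- pairs$gene1 %in% rownames(mat) & pairs$gene2 %in% rownames(mat)
  for (i in which(present)) {
    x <- mat[pairs$gene1[i], ]
    y <- mat[pairs$gene2[i], ]
    zv[i] <- stats::sd(x) == 0 || stats::sd(y) == 0
    if (!zv[i]) r[i] <- stats::cor(x, y)
    t1 <- tau[[pairs$gene1[i]]]
    t2 <- tau[[pairs$gene2[i]]]
    dt[i] <- abs(t1 - t2)
  }
  pairs$pearson_r <- r
  pairs$abs_delta_tau <- dt
  pairs$in_matrix <- present
  pairs$zero_variance <- zv
  pairs
}
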