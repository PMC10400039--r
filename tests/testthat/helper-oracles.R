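## Independent brute-force oracles. These deliberately re-derive each
## quantity from first principles, by direct enumeration or summation,
## so they share no code path with the package implementations.

## Upper binomial tail by direct summation of the mass function.
oracle_binom_upper <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  j <- k:n
  sum(exp(lchoose(n, j) + j * log(p) + (n - j) * log1p(-p)))
}

## Textbook BH step-up: q_(i) = min_{j >= i} p_(j) * m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

## Two-sided Fisher p by exhaustive enumeration of all tables with the
## observed margins, summing probabilities of tables no more probable
## than the observed one (relative tolerance for float comparison).
oracle_fisher_p <- function(a, b, c, d, rel_tol = 1e-7) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(a_range, function(x) {
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1))
  }, 0)
  p_obs <- probs[a_range == a]
  sum(probs[probs <= p_obs * (1 + rel_tol)])
}

## ---------------------------------------------------------------------
## Independent Nei-Gojobori implementation: loop-based site counting and
## recursive (depth-first) pathway enumeration.
## ---------------------------------------------------------------------

.oracle_gc <- as.list(Biostrings::GENETIC_CODE)

oracle_codon_sites <- function(codon) {
  s <- 0
  for (i in 1:3) {
    for (base in setdiff(c("A", "C", "G", "T"), substr(codon, i, i))) {
      alt <- codon
      substr(alt, i, i) <- base
      if (.oracle_gc[[alt]] != "*" && .oracle_gc[[alt]] == .oracle_gc[[codon]])
        s <- s + 1 / 3
    }
  }
  s
}

## All pathways between two codons by recursive DFS over the remaining
## differing positions; returns a data.frame of per-path (sd, nd, blocked).
oracle_paths <- function(c1, c2) {
  acc <- list()
  walk <- function(cur, remaining, sd, nd, blocked) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- data.frame(sd = sd, nd = nd, blocked = blocked)
      return(invisible(NULL))
    }
    for (pos in remaining) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      step_syn <- .oracle_gc[[nxt]] != "*" && .oracle_gc[[cur]] != "*" &&
        .oracle_gc[[nxt]] == .oracle_gc[[cur]]
      walk(nxt, setdiff(remaining, pos),
           sd + step_syn, nd + !step_syn,
           blocked || (.oracle_gc[[nxt]] == "*" && nxt != c2))
    }
  }
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diff_pos)) return(data.frame(sd = 0, nd = 0, blocked = FALSE))
  walk(c1, diff_pos, 0, 0, FALSE)
  do.call(rbind, acc)
}

oracle_ng86 <- function(seq1, seq2) {
  n <- nchar(seq1) %/% 3L
  starts <- 3L * seq_len(n) - 2L
  co1 <- substring(seq1, starts, starts + 2L)
  co2 <- substring(seq2, starts, starts + 2L)
  keep <- logical(n)
  for (i in seq_len(n)) {
    keep[i] <- grepl("^[ACGT]{3}$", co1[i]) && grepl("^[ACGT]{3}$", co2[i]) &&
      .oracle_gc[[co1[i]]] != "*" && .oracle_gc[[co2[i]]] != "*"
  }
  co1 <- co1[keep]; co2 <- co2[keep]
  S <- (sum(vapply(co1, oracle_codon_sites, 0)) +
          sum(vapply(co2, oracle_codon_sites, 0))) / 2
  N <- 3 * length(co1) - S
  Sd <- Nd <- 0
  for (i in seq_along(co1)) {
    paths <- oracle_paths(co1[i], co2[i])
    use <- if (all(paths$blocked)) rep(TRUE, nrow(paths)) else !paths$blocked
    Sd <- Sd + mean(paths$sd[use])
    Nd <- Nd + mean(paths$nd[use])
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, Ks = jc(Sd / S), Ka = jc(Nd / N))
}

## ---------------------------------------------------------------------
## Exhaustive longest-chain search over anchor matches: plain recursion
## over every extension, no dynamic programming.
## ---------------------------------------------------------------------

oracle_best_chain_size <- function(ra, rb, max_gap) {
  extend <- function(i) {
    da <- ra - ra[i]
    db <- rb - rb[i]
    nxt <- which(da >= 1 & da <= max_gap & db >= 1 & db <= max_gap)
    if (!length(nxt)) return(1L)
    1L + max(vapply(nxt, extend, 0L))
  }
  one_dir <- function(rb_dir) {
    rb <<- rb_dir
    if (!length(ra)) return(0L)
    max(vapply(seq_along(ra), extend, 0L))
  }
  rb_orig <- rb
  max(one_dir(rb_orig), one_dir(-rb_orig))
}

## Random expression profile with known tau is not needed: tau has a
## closed form. Random pair-table helper for property tests:
random_hits <- function(n, genes, seed) {
  set.seed(seed)
  g1 <- sample(genes, n, replace = TRUE)
  g2 <- sample(genes, n, replace = TRUE)
  keep <- g1 != g2
  data.frame(gene1 = pmin(g1[keep], g2[keep]),
             gene2 = pmax(g1[keep], g2[keep]),
             evalue = 10^runif(sum(keep), -50, -6))
}

## Canonical unordered-pair key for comparing pair tables.
pair_key <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2), sep = "|")
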