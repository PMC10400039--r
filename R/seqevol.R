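## Nei-Gojobori (1986) Ka/Ks estimation on pairwise codon alignments:
## synonymous site fractions from the standard genetic code, differences
## averaged over minimal mutational pathways with equal weights, and
## Jukes-Cantor distance correction.

.seqevol_cache <- new.env(parent = emptyenv())

## Standard-code codon machinery, computed once per session.
codon_data <- function() {
  if (!is.null(.seqevol_cache$codon_data)) return(.seqevol_cache$codon_data)
  gc_ <- Biostrings::GENETIC_CODE
  codons <- names(gc_)
  aa <- unname(gc_)
  bases <- c("A", "C", "G", "T")
  is_stop <- aa == "*"
  sense <- codons[!is_stop]

  ## synonymous fraction per position: of the 3 possible changes, the
  ## share preserving the amino acid (changes to stops are nonsynonymous)
  syn_frac <- matrix(0, nrow = length(codons), ncol = 3L,
                     dimnames = list(codons, NULL))
  neighbors <- vector("list", length(codons))
  names(neighbors) <- codons
  for (cd in codons) {
    nb <- character(0); nb_syn <- logical(0)
    for (i in 1:3) {
      cur <- substr(cd, i, i)
      syn <- 0L
      for (b in setdiff(bases, cur)) {
        alt <- cd
        substr(alt, i, i) <- b
        alt_aa <- gc_[[alt]]
        if (alt_aa != "*") {
          nb <- c(nb, alt)
          nb_syn <- c(nb_syn, alt_aa == gc_[[cd]])
        }
        if (alt_aa == gc_[[cd]] && alt_aa != "*") syn <- syn + 1L
      }
      syn_frac[cd, i] <- syn / 3
    }
    neighbors[[cd]] <- list(to = nb, syn = nb_syn)
  }
  out <- list(codons = codons, aa = setNames(aa, codons), sense = sense,
              is_stop = setNames(is_stop, codons),
              syn_frac = syn_frac, S_codon = setNames(rowSums(syn_frac), codons),
              neighbors = neighbors,
              perms = list(`1` = matrix(1L, 1, 1),
                           `2` = rbind(c(1L, 2L), c(2L, 1L)),
                           `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L),
                                       c(2L, 1L, 3L), c(2L, 3L, 1L),
                                       c(3L, 1L, 2L), c(3L, 2L, 1L))))
  .seqevol_cache$codon_data <- out
  out
}

## Average (Sd, Nd) between two codons over minimal mutational pathways
## (permutations of the differing positions), equal weights, pathways
## through stop codons excluded; if all pathways are blocked they are all
## used (steps involving a stop count as nonsynonymous). Memoized.
codon_path_counts <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .seqevol_cache[[key]]
  if (!is.null(hit)) return(hit)
  cd <- codon_data()
  diff_pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  d <- length(diff_pos)
  if (d == 0L) {
    res <- c(sd = 0, nd = 0)
  } else {
    perms <- cd$perms[[as.character(d)]]
    path_sd <- path_nd <- numeric(nrow(perms))
    blocked <- logical(nrow(perms))
    for (p in seq_len(nrow(perms))) {
      cur <- c1
      sd <- nd <- 0
      for (step in diff_pos[perms[p, ]]) {
        nxt <- cur
        substr(nxt, step, step) <- substr(c2, step, step)
        if (cd$aa[[nxt]] == "*" && nxt != c2) blocked[p] <- TRUE
        if (cd$aa[[nxt]] == cd$aa[[cur]] && cd$aa[[nxt]] != "*" &&
            cd$aa[[cur]] != "*") {
          sd <- sd + 1
        } else {
          nd <- nd + 1
        }
        cur <- nxt
      }
      path_sd[p] <- sd
      path_nd[p] <- nd
    }
    use <- if (all(blocked)) rep(TRUE, length(blocked)) else !blocked
    res <- c(sd = mean(path_sd[use]), nd = mean(path_nd[use]))
  }
  assign(key, res, envir = .seqevol_cache)
  res
}

#' Nei-Gojobori Ka/Ks for one codon-aligned pair
#'
#' Computes synonymous (S) and nonsynonymous (N) site counts averaged
#' over the two sequences, synonymous (Sd) and nonsynonymous (Nd)
#' differences averaged over all minimal mutational pathways (pathways
#' through stop codons excluded, equal weights), the proportions
#' `pS = Sd/S` and `pN = Nd/N`, Jukes-Cantor corrected distances
#' `Ks`/`Ka` (`d = -3/4 * log(1 - 4p/3)`), and `omega = Ka/Ks`.
#'
#' Codons containing gaps or ambiguity codes, and observed stop codons,
#' are dropped pairwise before counting. A proportion at or beyond the
#' Jukes-Cantor saturation point (`p >= 0.75`) gives an undefined (`NA`)
#' distance, flagged via `saturated`. `omega` is undefined when `Ks` is
#' undefined or zero.
#'
#' @param seq1,seq2 Equal-length nucleotide strings over `A,C,G,T,-`,
#'   length divisible by 3.
#' @return A list with `n_codons` (compared codons), `S`, `N`, `Sd`,
#'   `Nd`, `pS`, `pN`, `Ks`, `Ka`, `omega`, `saturated`.
#' @export
compute_kaks <- function(seq1, seq2) {
  seq1 <- toupper(seq1); seq2 <- toupper(seq2)
  if (nchar(seq1) != nchar(seq2)) stop_("sequences differ in length")
  if (nchar(seq1) %% 3L != 0L) stop_("alignment length not divisible by 3")
  cd <- codon_data()
  n <- nchar(seq1) %/% 3L
  starts <- 3L * seq_len(n) - 2L
  co1 <- substring(seq1, starts, starts + 2L)
  co2 <- substring(seq2, starts, starts + 2L)
  clean <- grepl("^[ACGT]{3}$", co1) & grepl("^[ACGT]{3}$", co2)
  clean <- clean & !ifelse(clean, cd$is_stop[co1], TRUE) &
    !ifelse(clean, cd$is_stop[co2], TRUE)
  co1 <- co1[clean]; co2 <- co2[clean]
  if (!length(co1)) stop_("no comparable codons after filtering")

  S <- (sum(cd$S_codon[co1]) + sum(cd$S_codon[co2])) / 2
  N <- 3 * length(co1) - S
  counts <- vapply(seq_along(co1),
                   function(i) codon_path_counts(co1[i], co2[i]),
                   numeric(2))
  Sd <- sum(counts["sd", ])
  Nd <- sum(counts["nd", ])
  pS <- Sd / S
  pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  Ks <- jc(pS)
  Ka <- jc(pN)
  omega <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  list(n_codons = length(co1), S = S, N = N, Sd = Sd, Nd = Nd,
       pS = pS, pN = pN, Ks = Ks, Ka = Ka, omega = omega,
       saturated = pS >= 0.75 || pN >= 0.75)
}

#' Ka/Ks for a table of aligned pairs
#'
#' Applies [compute_kaks()] to each row of a pair manifest with aligned
#' sequences.
#'
#' @param alignments Data frame with columns `gene1`, `gene2`, `seq1`,
#'   `seq2`.
#' @return Data frame with `gene1`, `gene2`, `S`, `N`, `Sd`, `Nd`, `Ks`,
#'   `Ka`, `omega`, `regime`.
#' @export
compute_kaks_table <- function(alignments) {
  alignments <- as.data.frame(alignments)
  res <- lapply(seq_len(nrow(alignments)), function(i) {
    k <- compute_kaks(alignments$seq1[i], alignments$seq2[i])
    data.frame(gene1 = alignments$gene1[i], gene2 = alignments$gene2[i],
               S = k$S, N = k$N, Sd = k$Sd, Nd = k$Nd,
               Ks = k$Ks, Ka = k$Ka, omega = k$omega,
               regime = selection_regime(k$omega))
  })
  do.call(rbind, res)
}

#' Selection regime from a Ka/Ks ratio
#'
#' `omega < 1` indicates purifying selection, `omega > 1` diversifying
#' selection, `omega = 1` (within `tol`) neutrality; an undefined omega
#' gives `"undefined"`.
#'
#' @param omega Numeric vector of Ka/Ks ratios (NA allowed).
#' @param tol Equality tolerance for the neutral call (default 1e-9).
#' @return Character vector in
#'   `{"purifying","neutral","diversifying","undefined"}`.
#' @export
selection_regime <- function(omega, tol = 1e-9) {
  ifelse(is.na(omega), "undefined",
         ifelse(abs(omega - 1) <= tol, "neutral",
                ifelse(omega < 1, "purifying", "diversifying")))
}

#' Import an externally computed Ka/Ks table
#'
#' Fidelity path for reruns with an external codon-model calculator:
#' reads a TSV with header columns `gene1`, `gene2`, `Ka`, `Ks` and
#' optionally `omega` (recomputed as `Ka/Ks` when absent).
#'
#' @param path Path to the TSV.
#' @return Data frame with `gene1`, `gene2`, `Ka`, `Ks`, `omega`,
#'   `regime`.
#' @export
read_kaks_table <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  need <- c("gene1", "gene2", "Ka", "Ks")
  if (!all(need %in% names(dt)))
    stop_("Ka/Ks table must have columns %s", paste(need, collapse = ", "))
  if (!"omega" %in% names(dt)) {
    dt[, omega := ifelse(Ks > 0, Ka / Ks, NA_real_)]
  }
  dt[, regime := selection_regime(omega)]
  as.data.frame(dt)
}
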