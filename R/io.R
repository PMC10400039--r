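## Readers and writers for the external formats plus the shared coordinate
## model. All intervals are 0-based half-open internally; GFF3 (1-based
## inclusive) and allc positions (1-based) are converted on read and
## reconverted on write.

#' Cytosine sequence context class
#'
#' Maps a trinucleotide context string (first base is the cytosine) to its
#' context class: `CG` if the second base is G, `CHG` if the third base is
#' G, otherwise `CHH`.
#'
#' @param context Character vector of trinucleotide contexts (e.g. `"CGA"`,
#'   `"CAG"`, `"CTT"`).
#' @return Character vector in `{"CG","CHG","CHH"}`.
#' @examples
#' context_class(c("CGA", "CAG", "CTT"))
#' @export
context_class <- function(context) {
  second <- substr(context, 2L, 2L)
  third <- substr(context, 3L, 3L)
  ifelse(second == "G", "CG", ifelse(third == "G", "CHG", "CHH"))
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features and returns one gene model per gene based
#' on its primary transcript, defined as the transcript with the longest
#' total CDS (ties broken by lexicographic transcript id). GFF3 1-based
#' inclusive coordinates are converted to 0-based half-open. Genes are
#' ranked 0-based along each chromosome by start position.
#'
#' @param path Path to a GFF3 file.
#' @return A list with two data frames:
#' \describe{
#'   \item{genes}{`gene_id`, `chrom`, `start`, `end`, `strand`, `rank`.}
#'   \item{cds}{`gene_id`, `start`, `end` -- the CDS intervals of the
#'     primary transcript, sorted and non-overlapping.}
#' }
#' Genes without any CDS are kept with zero CDS intervals and a warning.
#' @export
read_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  ids <- as.character(meta$ID)
  parents <- meta$Parent  # CharacterList

  is_gene <- type == "gene"
  if (!any(is_gene)) {
    return(list(
      genes = data.frame(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), rank = integer()),
      cds = data.frame(gene_id = character(), start = integer(),
                       end = integer())
    ))
  }
  genes <- data.table(
    gene_id = ids[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene] - 1L,
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene]
  )
  genes[strand == "*", strand := "+"]

  is_tx <- type %in% c("mRNA", "transcript")
  tx <- data.table(
    tx_id = ids[is_tx],
    gene_id = vapply(parents[is_tx], function(p) if (length(p)) p[[1]] else NA_character_, "")
  )

  is_cds <- type == "CDS"
  cds_parent <- parents[is_cds]
  cds <- data.table(
    tx_id = rep(vapply(cds_parent, function(p) if (length(p)) p[[1]] else NA_character_, ""),
                1L),
    start = GenomicRanges::start(gr)[is_cds] - 1L,
    end = GenomicRanges::end(gr)[is_cds]
  )
  cds <- merge(cds, tx, by = "tx_id", all.x = TRUE)
  ## CDS attached directly to a gene (no transcript layer)
  cds[is.na(gene_id) & tx_id %in% genes$gene_id, gene_id := tx_id]
  cds <- cds[!is.na(gene_id)]

  ## primary transcript: longest total CDS, ties by lexicographic tx id
  if (nrow(cds)) {
    tx_len <- cds[, .(cds_len = sum(end - start)), by = .(gene_id, tx_id)]
    setorder(tx_len, gene_id, -cds_len, tx_id)
    primary <- tx_len[, .SD[1L], by = gene_id]
    cds <- cds[paste(gene_id, tx_id) %in% paste(primary$gene_id, primary$tx_id)]
    cds <- cds[, .(gene_id, start, end)]
    setorder(cds, gene_id, start)
  } else {
    cds <- data.table(gene_id = character(), start = integer(), end = integer())
  }

  no_cds <- setdiff(genes$gene_id, unique(cds$gene_id))
  if (length(no_cds)) {
    warn_("%d gene(s) have no CDS feature (e.g. %s); emitted with empty CDS",
          length(no_cds), no_cds[1L])
  }

  setorder(genes, chrom, start, gene_id)
  genes[, rank := seq_len(.N) - 1L, by = chrom]
  list(genes = as.data.frame(genes), cds = as.data.frame(cds))
}

#' Write gene models to a GFF3 file
#'
#' Inverse of [read_gff()]: emits gene, mRNA and CDS features, converting
#' internal 0-based half-open coordinates back to GFF3 1-based inclusive.
#' One mRNA (`<gene_id>.t1`) is written per gene.
#'
#' @param genes,cds Data frames as returned by [read_gff()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, cds, path) {
  genes <- as.data.table(genes)
  cdsdt <- as.data.table(cds)
  lines <- character(0)
  setorder(genes, chrom, start, gene_id)
  gl <- genes[, sprintf("%s\tmethyldup\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                        chrom, start + 1L, end, strand, gene_id)]
  tl <- genes[, sprintf("%s\tmethyldup\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                        chrom, start + 1L, end, strand, gene_id, gene_id)]
  cdsdt <- merge(cdsdt, genes[, .(gene_id, chrom, strand)], by = "gene_id")
  setorder(cdsdt, chrom, start)
  cl <- cdsdt[, sprintf("%s\tmethyldup\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s.t1",
                        chrom, start + 1L, end, strand, gene_id, gene_id)]
  ## interleave per gene so parents precede children
  ord <- order(c(genes$start, genes$start, cdsdt$start),
               c(rep(0L, nrow(genes)), rep(1L, nrow(genes)), rep(2L, nrow(cdsdt))))
  body <- c(gl, tl, cl)[ord]
  writeLines(c("##gff-version 3", body), path)
  invisible(path)
}

#' Read per-cytosine methylation calls (allc format)
#'
#' Reads the 7-column tab-delimited allc dialect: chromosome, 1-based
#' position, strand, trinucleotide context, methylated read count, total
#' read count, methylated-site flag (0/1). Sites with zero coverage are
#' retained but flagged uncovered.
#'
#' @param path Path to an allc TSV (no header).
#' @return Data frame with columns `chrom`, `pos` (1-based), `strand`,
#'   `context`, `context_class`, `mc_reads`, `total_reads`,
#'   `is_methylated` (logical), `covered` (logical).
#' @export
read_allc <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "pos", "strand", "context",
                            "mc_reads", "total_reads", "is_methylated"))
  for (col in c("pos", "mc_reads", "total_reads")) {
    v <- dt[[col]]
    if (!is.numeric(v) || any(v != floor(v)))
      stop_("non-integer values in allc column '%s'", col)
  }
  bad <- which(dt$mc_reads > dt$total_reads)
  if (length(bad))
    stop_("mc_reads > total_reads at allc row %d (%s:%d)",
          bad[1L], dt$chrom[bad[1L]], dt$pos[bad[1L]])
  dt[, `:=`(
    context_class = context_class(context),
    is_methylated = as.logical(is_methylated),
    covered = total_reads > 0L
  )]
  setcolorder(dt, c("chrom", "pos", "strand", "context", "context_class",
                    "mc_reads", "total_reads", "is_methylated", "covered"))
  as.data.frame(dt)
}

#' Write methylation calls in allc format
#'
#' @param sites Data frame as returned by [read_allc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_allc <- function(sites, path) {
  dt <- as.data.table(sites)[, .(chrom, pos, strand, context, mc_reads,
                                 total_reads, is_methylated = as.integer(is_methylated))]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read and filter all-vs-all protein similarity hits
#'
#' Reads a BLAST outfmt-6-like tab-delimited file (columns 1 = query,
#' 2 = subject; the e-value is taken from column 11 when at least 11
#' columns are present, otherwise from column 3). Filtering follows the
#' paralog-calling conventions: self-hits are removed, hits at or above
#' `max_evalue` are removed, hits whose genes belong to different
#' orthogroups are removed when `og_map` is given, and reciprocal
#' duplicates (A,B)/(B,A) are collapsed keeping the smaller e-value.
#'
#' @param path Path to a hits TSV (no header).
#' @param max_evalue Retain hits with e-value strictly below this
#'   (default `1e-5`).
#' @param og_map Optional named character vector mapping gene id to
#'   orthogroup id. Hits are kept only when both genes map to the same
#'   orthogroup.
#' @return Data frame with columns `gene1`, `gene2` (lexicographically
#'   ordered within each pair), `evalue`.
#' @export
read_hits <- function(path, max_evalue = 1e-5, og_map = NULL) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop_("hits file needs at least 3 columns: %s", path)
  ecol <- if (ncol(dt) >= 11L) 11L else 3L
  hits <- data.table(query_id = as.character(dt[[1L]]),
                     subject_id = as.character(dt[[2L]]),
                     evalue = as.numeric(dt[[ecol]]))
  if (anyNA(hits$evalue)) stop_("malformed e-value at hits row %d", which(is.na(hits$evalue))[1L])
  filter_hits(hits, max_evalue = max_evalue, og_map = og_map)
}

## Shared hit-filtering logic; `hits` has query_id/subject_id/evalue.
filter_hits <- function(hits, max_evalue = 1e-5, og_map = NULL) {
  hits <- as.data.table(hits)
  hits <- hits[query_id != subject_id]
  hits <- hits[evalue < max_evalue]
  if (!is.null(og_map)) {
    og1 <- og_map[hits$query_id]
    og2 <- og_map[hits$subject_id]
    hits <- hits[!is.na(og1) & !is.na(og2) & og1 == og2]
  }
  if (!nrow(hits)) {
    return(data.frame(gene1 = character(), gene2 = character(), evalue = numeric()))
  }
  hits[, `:=`(gene1 = pmin(query_id, subject_id), gene2 = pmax(query_id, subject_id))]
  out <- hits[, .(evalue = min(evalue)), by = .(gene1, gene2)]
  setorder(out, gene1, gene2)
  as.data.frame(out)
}

#' Write a pair table in outfmt-6-like form
#'
#' Emits 11 tab-separated columns with the e-value in column 11 (unused
#' columns are written as `.`/0), so [read_hits()] round-trips it.
#'
#' @param hits Data frame with `gene1`, `gene2`, `evalue`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path) {
  dt <- as.data.table(hits)
  lines <- dt[, sprintf("%s\t%s\t100.0\t0\t0\t0\t0\t0\t0\t0\t%g\t0",
                        gene1, gene2, evalue)]
  writeLines(lines, path)
  invisible(path)
}

#' Read an Orthofinder-style orthogroup membership table
#'
#' First column is the orthogroup id; one column per species containing
#' comma-separated gene ids (empty when absent).
#'
#' @param path Path to the orthogroups TSV (with header).
#' @return Data frame, first column named `og_id`.
#' @export
read_orthogroups <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", colClasses = "character")
  setnames(dt, 1L, "og_id")
  as.data.frame(dt)
}

#' Write an orthogroup membership table
#' @param og Data frame as returned by [read_orthogroups()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_orthogroups <- function(og, path) {
  fwrite(as.data.table(og), path, sep = "\t")
  invisible(path)
}

#' Read a normalized expression matrix
#'
#' Tab-delimited with a header of condition names; the first column holds
#' gene ids.
#'
#' @param path Path to the expression TSV.
#' @return Numeric matrix (genes x conditions) with gene ids as rownames.
#' @export
read_expression_matrix <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1L, with = FALSE])
  mode(m) <- "double"
  rownames(m) <- as.character(dt[[1L]])
  m
}

#' Write a normalized expression matrix
#' @param mat Numeric matrix with gene ids as rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  dt <- data.table(gene_id = rownames(mat))
  dt <- cbind(dt, as.data.table(mat))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read transposable-element annotations from BED
#'
#' BED intervals are already 0-based half-open; they are passed through
#' unchanged. The 4th BED column, when present, is kept as the TE family.
#'
#' @param path Path to a BED file.
#' @return Data frame with `chrom`, `start`, `end`, `family`.
#' @export
read_te_bed <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  out <- data.table(chrom = as.character(dt[[1L]]),
                    start = as.integer(dt[[2L]]),
                    end = as.integer(dt[[3L]]),
                    family = if (ncol(dt) >= 4L) as.character(dt[[4L]]) else NA_character_)
  if (any(out$start >= out$end)) stop_("BED interval with start >= end in %s", path)
  as.data.frame(out)
}

#' Write transposable-element annotations to BED
#' @param tes Data frame with `chrom`, `start`, `end` and optionally `family`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(tes, path) {
  dt <- as.data.table(tes)
  fam <- if ("family" %in% names(dt)) dt$family else NA_character_
  fam[is.na(fam)] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s", dt$chrom, dt$start, dt$end, fam)
  writeLines(lines, path)
  invisible(path)
}

#' Read a species-to-family map
#' @param path Two-column TSV (species, family) with header.
#' @return Named character vector mapping species to family.
#' @export
read_species_families <- function(path) {
  dt <- fread(path, header = TRUE, sep = "\t", colClasses = "character")
  setNames(dt[[2L]], dt[[1L]])
}
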