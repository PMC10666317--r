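#' @name transfer
#' @title Homologous fragments between genomes (plastid-to-mitochondrion
#'   transfer)
#'
#' @description
#' Plastid-derived sequence in a mitochondrial genome (MTPT) is detected
#' as inter-genome homologous fragments: exact seed words shared by the
#' two genomes are clustered by diagonal on both strands and the
#' candidate regions are locally aligned; fragments passing the identity
#' and length thresholds (defaults 70% and 30 bp, the usual screening
#' criteria) are reported with mismatch and gap-opening counts,
#' Table-style 1-based inclusive coordinates (a minus-strand subject
#' interval has start > end), and sorted by length descending.
#'
#' Instead of a database e-value, fragments carry `evalue_proxy`, a
#' Karlin-Altschul-style quantity computed from the alignment score and
#' the product of genome lengths; it is used only for filtering parity
#' and reported for reference.
NULL

# cluster seed matches between two code tables by diagonal; returns a
# data.frame of candidate regions (q0, q1, t0, t1) in target-frame coords
.seedClusters <- function(codes_q, codes_t, word, band = 25L,
                          max_gap = 100L) {
  dq <- data.table::data.table(code = codes_q, qpos = seq_along(codes_q))
  dtt <- data.table::data.table(code = codes_t, tpos = seq_along(codes_t))
  dq <- dq[!is.na(dq$code)]
  dtt <- dtt[!is.na(dtt$code)]
  mm <- merge(dq, dtt, by = "code", allow.cartesian = TRUE)
  if (nrow(mm) == 0L) return(NULL)
  mm$diag <- mm$qpos - mm$tpos
  mm <- mm[order(mm$diag, mm$qpos), ]
  # single-linkage along the diagonal axis, then along the query axis
  new_band <- c(TRUE, diff(mm$diag) > band)
  bd <- cumsum(new_band)
  out <- list()
  for (ix in split(seq_len(nrow(mm)), bd)) {
    sub <- mm[ix, ][order(mm$qpos[ix]), ]
    brk <- c(0L, which(diff(sub$qpos) > max_gap), nrow(sub))
    for (g in seq_len(length(brk) - 1L)) {
      rows <- (brk[g] + 1L):brk[g + 1L]
      out[[length(out) + 1L]] <- data.frame(
        q0 = min(sub$qpos[rows]), q1 = max(sub$qpos[rows]) + word - 1L,
        t0 = min(sub$tpos[rows]), t1 = max(sub$tpos[rows]) + word - 1L,
        n_seeds = length(rows))
    }
  }
  do.call(rbind, out)
}

# merge candidate regions that overlap on the query
.mergeRegions <- function(reg, slack = 30L) {
  reg <- reg[order(reg$q0), , drop = FALSE]
  keep <- list(reg[1, ])
  if (nrow(reg) > 1L) for (i in 2:nrow(reg)) {
    last <- keep[[length(keep)]]
    if (reg$q0[i] <= last$q1 + slack && reg$t0[i] <= last$t1 + slack &&
        reg$t1[i] >= last$t0 - slack) {
      last$q1 <- max(last$q1, reg$q1[i]); last$q0 <- min(last$q0, reg$q0[i])
      last$t1 <- max(last$t1, reg$t1[i]); last$t0 <- min(last$t0, reg$t0[i])
      last$n_seeds <- last$n_seeds + reg$n_seeds[i]
      keep[[length(keep)]] <- last
    } else keep[[length(keep) + 1L]] <- reg[i, ]
  }
  do.call(rbind, keep)
}

#' Find homologous fragments between two genomes
#'
#' @param genome_a,genome_b [GenomeRecord-class] objects (query and
#'   subject; for MTPT quantification, mitochondrial and plastid).
#' @param min_identity minimum block identity (default 0.70).
#' @param min_length minimum alignment length in columns (default 30).
#' @param word exact seed length (default 12).
#' @return data.frame sorted by length descending with `a_start`,
#'   `a_end`, `b_start`, `b_end` (1-based inclusive; minus-strand subject
#'   has start > end), `length`, `mismatches`, `gap_openings`,
#'   `identity`, `evalue_proxy`.
#' @export
findHomologs <- function(genome_a, genome_b, min_identity = 0.70,
                         min_length = 30, word = 12L) {
  stopifnot(is(genome_a, "GenomeRecord"), is(genome_b, "GenomeRecord"))
  sa <- genomeSeq(genome_a)
  sb <- genomeSeq(genome_b)
  La <- nchar(sa); Lb <- nchar(sb)
  codes_a <- .kmerCodes(sa, word)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  rows <- list()
  for (strand in c("+", "-")) {
    st <- if (strand == "+") sb else revComp(sb)
    reg <- .seedClusters(codes_a, .kmerCodes(st, word), word)
    if (is.null(reg)) next
    reg <- .mergeRegions(reg)
    for (i in seq_len(nrow(reg))) {
      margin <- 25L
      q0 <- max(1L, reg$q0[i] - margin); q1 <- min(La, reg$q1[i] + margin)
      t0 <- max(1L, reg$t0[i] - margin); t1 <- min(Lb, reg$t1[i] + margin)
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(substr(sa, q0, q1)),
        Biostrings::DNAString(substr(st, t0, t1)),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      cols <- Biostrings::nchar(al)
      if (cols < min_length) next
      nmatch <- Biostrings::nmatch(al)
      nmis <- Biostrings::nmismatch(al)
      identity <- nmatch / cols
      if (identity < min_identity) next
      pq <- al@pattern@range
      ps <- al@subject@range
      a_iv <- c(q0 + IRanges::start(pq) - 1L, q0 + IRanges::end(pq) - 1L)
      t_iv <- c(t0 + IRanges::start(ps) - 1L, t0 + IRanges::end(ps) - 1L)
      b_iv <- if (strand == "+") t_iv else
        c(Lb - t_iv[1] + 1L, Lb - t_iv[2] + 1L)
      gaps <- .gapOpenings(al)
      score <- Biostrings::score(al)
      rows[[length(rows) + 1L]] <- data.frame(
        a_start = a_iv[1], a_end = a_iv[2],
        b_start = b_iv[1], b_end = b_iv[2],
        length = cols, mismatches = nmis, gap_openings = gaps,
        identity = identity,
        evalue_proxy = as.numeric(La) * Lb * 2^(-0.5 * score))
    }
  }
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      length = integer(0), mismatches = integer(0),
                      gap_openings = integer(0), identity = numeric(0),
                      evalue_proxy = numeric(0))
  if (!length(rows)) return(empty)
  res <- do.call(rbind, rows)
  # duplicate candidates from adjacent clusters: keep the longest per
  # overlapping query interval
  res <- res[order(-res$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  if (nrow(res) > 1L) for (i in 2:nrow(res)) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      ov <- min(res$a_end[i], res$a_end[j]) -
        max(res$a_start[i], res$a_start[j]) + 1L
      bi <- sort(c(res$b_start[i], res$b_end[i]))
      bj <- sort(c(res$b_start[j], res$b_end[j]))
      ovb <- min(bi[2], bj[2]) - max(bi[1], bj[1]) + 1L
      if (ov > 0.8 * res$length[i] && ovb > 0.8 * res$length[i]) {
        keep[i] <- FALSE; break
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

.gapOpenings <- function(al) {
  ip <- Biostrings::indel(al@pattern)
  is <- Biostrings::indel(al@subject)
  length(ip[[1]]) + length(is[[1]])
}

#' Annotate subject-genome genes covered by homologous fragments
#'
#' For every gene intersecting a fragment, the covered fraction of the
#' gene length after merging fragment overlaps; genes covered end to end
#' are flagged complete (a complete transfer).
#'
#' @param fragments result of [findHomologs()] (subject coordinates in
#'   `b_start`/`b_end`) or any data.frame with those columns.
#' @param genes_on_b data.frame with `gene`, `start`, `end` (subject
#'   coordinates), or a list of [GeneModel-class] whose exons lie on the
#'   subject genome.
#' @return data.frame `gene`, `fraction_covered` (percentage, 2 dp),
#'   `complete`.
#' @export
annotateGeneCoverage <- function(fragments, genes_on_b) {
  if (is.list(genes_on_b) && !is.data.frame(genes_on_b)) {
    genes_on_b <- do.call(rbind, lapply(genes_on_b, function(g)
      data.frame(gene = geneName(g),
                 start = min(IRanges::start(g@exons)),
                 end = max(IRanges::end(g@exons)))))
  }
  if (nrow(fragments) == 0L || nrow(genes_on_b) == 0L)
    return(data.frame(gene = character(0), fraction_covered = numeric(0),
                      complete = logical(0)))
  b0 <- pmin(fragments$b_start, fragments$b_end)
  b1 <- pmax(fragments$b_start, fragments$b_end)
  cov <- IRanges::reduce(IRanges::IRanges(b0, b1))
  rows <- lapply(seq_len(nrow(genes_on_b)), function(i) {
    g_iv <- IRanges::IRanges(genes_on_b$start[i], genes_on_b$end[i])
    inter <- IRanges::intersect(cov, g_iv)
    covered <- sum(IRanges::width(inter))
    if (covered == 0L) return(NULL)
    frac <- 100 * covered / IRanges::width(g_iv)
    data.frame(gene = genes_on_b$gene[i],
               fraction_covered = round(frac, 2),
               complete = covered == IRanges::width(g_iv))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(gene = character(0), fraction_covered = numeric(0),
                      complete = logical(0)))
  out
}

#' Summarize homologous fragments against the query genome
#'
#' @param fragments result of [findHomologs()] (or a data.frame with
#'   `length`, `a_start`, `a_end`).
#' @param genome_a_length query genome length in bases.
#' @param use_union if `TRUE` the genome fraction uses the overlap-merged
#'   union of query intervals; default `FALSE` uses the plain sum of
#'   fragment lengths.
#' @return list with `n_fragments`, `total_bp`, `union_bp`,
#'   `fraction_of_genome` (percentage, 2 dp), `longest`, `shortest`.
#' @export
transferSummary <- function(fragments, genome_a_length,
                            use_union = FALSE) {
  if (genome_a_length <= 0) stop("genome length must be positive")
  n <- nrow(fragments)
  if (n == 0L)
    return(list(n_fragments = 0L, total_bp = 0L, union_bp = 0L,
                fraction_of_genome = 0, longest = 0L, shortest = 0L))
  total <- sum(fragments$length)
  union_bp <- sum(IRanges::width(IRanges::reduce(
    IRanges::IRanges(pmin(fragments$a_start, fragments$a_end),
                     pmax(fragments$a_start, fragments$a_end)))))
  used <- if (use_union) union_bp else total
  list(n_fragments = n, total_bp = total, union_bp = union_bp,
       fraction_of_genome = round(100 * used / genome_a_length, 2),
       longest = max(fragments$length), shortest = min(fragments$length))
}
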