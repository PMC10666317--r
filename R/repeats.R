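#' @name repeats
#' @title Repeat mining: microsatellites, tandem and dispersed repeats
#'
#' @description
#' Three repeat classes are mined from a genome: perfect microsatellites
#' (SSRs) with MISA-style per-unit-length minimum copy numbers
#' (1-10, 2-5, 3-4, 4-3, 5-3, 6-3), tandem repeats scored by consensus
#' alignment with tandem-finder weights (match 2, mismatch 7, indel 7,
#' min score 50, max period 2000), and dispersed repeats in the four
#' orientation classes (forward, palindromic, reverse, complement) found
#' by seeded ungapped extension of the genome against itself on both
#' strands.
NULL

.isNonPrimitive <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(FALSE)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L &&
        strrep(substr(motif, 1L, d), u %/% d) == motif) return(TRUE)
  }
  FALSE
}

.minRotation <- function(motif) {
  u <- nchar(motif)
  if (u == 1L) return(motif)
  dbl <- paste0(motif, motif)
  min(vapply(seq_len(u), function(i) substr(dbl, i, i + u - 1L),
             character(1)))
}

# 2-bit k-mer codes along a string; NA where the window contains non-ACGT
.kmerCodes <- function(s, k) {
  v <- c(A = 0, C = 1, G = 2, T = 3)[.chars(s)]
  n <- length(v)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  code <- numeric(m)
  for (j in 0:(k - 1L)) code <- code * 4 + v[(1L + j):(m + j)]
  code
}

#' Find perfect microsatellites (SSRs)
#'
#' Maximal perfect runs of a 1-6 bp unit meeting the per-unit-length
#' minimum copy number. Runs whose motif is a repetition of a shorter
#' motif are reported at the shorter unit only; circular genomes are
#' scanned across the origin (a hit may have `end > length`, wrapping).
#' Lengths are truncated to whole copies. The reported motif is the
#' lexicographically minimal rotation of the repeat unit; `start` anchors
#' the run on the genome.
#'
#' @param genome a [GenomeRecord-class].
#' @param thresholds named vector of minimum copies per unit length
#'   (defaults to the MISA convention `1-10 2-5 3-4 4-3 5-3 6-3`).
#' @return data.frame with `motif`, `unit_length`, `copies`, `start`,
#'   `end`, `length`, sorted by `start`.
#' @export
findSsrs <- function(genome,
                     thresholds = c("1" = 10, "2" = 5, "3" = 4,
                                    "4" = 3, "5" = 3, "6" = 3)) {
  stopifnot(is(genome, "GenomeRecord"))
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  s <- genomeSeq(genome)
  L <- nchar(s)
  circ <- isCircular(genome)
  s2 <- if (circ) paste0(s, s) else s
  ch <- .chars(s2)
  n2 <- length(ch)
  out <- list()
  for (u in 1:6) {
    thr <- as.integer(thresholds[[as.character(u)]])
    if (n2 <= u) next
    m <- ch[seq_len(n2 - u)] == ch[(u + 1L):n2]
    r <- rle(m)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    for (j in which(r$values)) {
      i <- run_start[j]
      copies <- (r$lengths[j] + u) %/% u
      if (copies < thr || i > L) next
      # a run at position 1 of a circular genome that continues from the
      # sequence end is the tail of a wrapping run reported elsewhere
      if (circ && i == 1L && ch[L] == ch[u]) next
      copies <- min(copies, L %/% u)
      if (copies < thr) next
      motif <- substr(s2, i, i + u - 1L)
      if (grepl("[^ACGT]", motif) || .isNonPrimitive(motif)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = .minRotation(motif), unit_length = u, copies = copies,
        start = i, end = i + u * copies - 1L, length = u * copies)
    }
  }
  if (!length(out))
    return(data.frame(motif = character(0), unit_length = integer(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_length), , drop = FALSE]
}

# score one tandem candidate region against its period-p consensus
.scoreTandem <- function(region, p, match, mismatch, indel) {
  len <- nchar(region)
  ncop <- len %/% p
  if (ncop < 2L) return(NULL)
  chunks <- substring(region, seq(1L, by = p, length.out = ncop),
                      seq(p, by = p, length.out = ncop))
  tail_len <- len - ncop * p
  tail_chunk <- if (tail_len > 0) substr(region, ncop * p + 1L, len) else NULL
  cm <- do.call(rbind, strsplit(chunks, "", fixed = TRUE))
  consensus <- apply(cm, 2, function(col) names(sort(table(col),
                                                     decreasing = TRUE))[1])
  nmatch <- sum(cm == matrix(consensus, nrow(cm), ncol(cm), byrow = TRUE))
  ncols <- length(chunks) * p
  if (!is.null(tail_chunk)) {
    tc <- .chars(tail_chunk)
    nmatch <- nmatch + sum(tc == consensus[seq_along(tc)])
    ncols <- ncols + tail_len
  }
  nmis <- ncols - nmatch
  score <- match * nmatch - mismatch * nmis
  list(consensus = paste(consensus, collapse = ""), score = score,
       percent_match = 100 * nmatch / ncols,
       copies = round(len / p, 1))
}

#' Find tandem repeats by k-mer recurrence and consensus alignment
#'
#' Candidate periods are proposed from exact k-mer recurrences at a fixed
#' distance; each candidate region is scored against its majority-rule
#' consensus with the given weights. Candidates below `min_score` are
#' dropped; overlapping candidates keep the best score (ties to the
#' smaller period).
#'
#' @param genome a [GenomeRecord-class].
#' @param match,mismatch,indel alignment weights (mismatch/indel are
#'   penalties, entered positive).
#' @param min_score minimum reported alignment score.
#' @param max_period maximum repeat period considered.
#' @param kmer seed length for period proposal (default 7).
#' @return data.frame with `period`, `copies`, `consensus`,
#'   `percent_match`, `score`, `start`, `end`.
#' @export
findTandems <- function(genome, match = 2, mismatch = 7, indel = 7,
                        min_score = 50, max_period = 2000, kmer = 7L) {
  stopifnot(is(genome, "GenomeRecord"), match > 0, mismatch > 0, indel > 0)
  s <- genomeSeq(genome)
  L <- nchar(s)
  ext <- if (isCircular(genome)) min(L, 2L * max_period) else 0L
  s2 <- paste0(s, substr(s, 1L, ext))
  codes <- .kmerCodes(s2, kmer)
  dt <- data.table::data.table(pos = seq_along(codes), code = codes)
  dt <- dt[!is.na(dt$code)]
  pos <- NULL; code <- NULL  # appease R CMD check NSE
  pairs <- dt[, if (.N > 1L) list(pos1 = pos[-.N], pos2 = pos[-1L]),
              by = code]
  empty <- data.frame(period = integer(0), copies = numeric(0),
                      consensus = character(0), percent_match = numeric(0),
                      score = numeric(0), start = integer(0),
                      end = integer(0))
  if (nrow(pairs) == 0L) return(empty)
  pairs$d <- pairs$pos2 - pairs$pos1
  pairs <- pairs[pairs$d <= max_period, ]
  if (nrow(pairs) == 0L) return(empty)
  cand <- list()
  for (d in sort(unique(pairs$d))) {
    pp <- sort(pairs$pos1[pairs$d == d])
    gap_thr <- max(2L * kmer + 10L, d)
    brk <- c(0L, which(diff(pp) > gap_thr), length(pp))
    for (g in seq_len(length(brk) - 1L)) {
      idx <- (brk[g] + 1L):brk[g + 1L]
      i0 <- pp[idx[1]]; i1 <- pp[idx[length(idx)]]
      if (i0 > L) next
      reg_len <- (i1 + d + kmer - 1L) - i0 + 1L
      if (reg_len < 2L * d) next
      cand[[length(cand) + 1L]] <- c(start = i0, d = d, len = reg_len)
    }
  }
  if (!length(cand)) return(empty)
  hits <- list()
  for (cc in cand) {
    region <- substr(s2, cc["start"], cc["start"] + cc["len"] - 1L)
    sc <- .scoreTandem(region, cc["d"], match, mismatch, indel)
    if (is.null(sc) || sc$score < min_score) next
    hits[[length(hits) + 1L]] <- data.frame(
      period = as.integer(cc["d"]), copies = sc$copies,
      consensus = sc$consensus, percent_match = round(sc$percent_match, 2),
      score = sc$score, start = as.integer(cc["start"]),
      end = as.integer(cc["start"] + cc["len"] - 1L))
  }
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  res <- res[order(-res$score, res$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    if (i < nrow(res)) for (j in (i + 1L):nrow(res)) {
      if (!keep[j]) next
      ov <- min(res$end[i], res$end[j]) - max(res$start[i], res$start[j]) + 1L
      if (ov > 0 && (ov >= 0.5 * (res$end[j] - res$start[j] + 1L) ||
                     ov >= 0.5 * (res$end[i] - res$start[i] + 1L)))
        keep[j] <- FALSE
    }
  }
  res <- res[keep, , drop = FALSE]
  res[order(res$start), , drop = FALSE]
}

# ungapped X-drop extension of an exact seed block; returns the maximal
# scoring block (match +1, mismatch -2, x-drop 6) and its identity
.extendUngapped <- function(qa, qb, qs, ts, len, nq, nt, xdrop = 6) {
  # qa, qb: character vectors of the two sequences
  best_l <- 0L; sc <- 0; best_sc <- 0
  i <- qs - 1L; j <- ts - 1L
  while (i >= 1L && j >= 1L) {
    sc <- sc + if (qa[i] == qb[j]) 1 else -2
    if (sc > best_sc) { best_sc <- sc; best_l <- qs - i }
    if (sc < best_sc - xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  best_r <- 0L; sc <- 0; best_sc <- 0
  i <- qs + len; j <- ts + len
  while (i <= nq && j <= nt) {
    sc <- sc + if (qa[i] == qb[j]) 1 else -2
    if (sc > best_sc) { best_sc <- sc; best_r <- i - (qs + len) + 1L }
    if (sc < best_sc - xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  a0 <- qs - best_l; b0 <- ts - best_l
  blk <- len + best_l + best_r
  nmatch <- sum(qa[a0:(a0 + blk - 1L)] == qb[b0:(b0 + blk - 1L)])
  list(q_start = a0, t_start = b0, length = blk, identity = nmatch / blk)
}

#' Find dispersed repeats with orientation classes
#'
#' The genome is compared against itself in the four orientations:
#' unchanged (forward repeats), reverse complement (palindromic), reversed
#' without complement (reverse) and complemented without reversal
#' (complement). Exact seed words are clustered by diagonal and extended
#' ungapped; pairs overlapping a reported SSR or tandem interval by more
#' than half of a copy are removed, as are symmetric duplicates.
#'
#' @param genome a [GenomeRecord-class].
#' @param min_length minimum copy length (default 30).
#' @param min_identity minimum identity over the block (default 0.80).
#' @param word exact seed length (default 11).
#' @param ssrs,tandems hit tables used for the overlap filter; computed
#'   with default parameters when `NULL`. Pass data.frames with zero rows
#'   to disable the filter.
#' @return data.frame with `class`, `a_start`, `a_end`, `b_start`,
#'   `b_end`, `length`, `identity`.
#' @export
findDispersed <- function(genome, min_length = 30, min_identity = 0.80,
                          word = 11L, ssrs = NULL, tandems = NULL) {
  stopifnot(is(genome, "GenomeRecord"))
  s <- genomeSeq(genome)
  L <- nchar(s)
  qa <- .chars(s)
  codes_q <- .kmerCodes(s, word)
  orientations <- list(
    forward = s, palindromic = revComp(s), reverse = .rev(s),
    complement = .comp(s))
  hits <- list()
  for (orient in names(orientations)) {
    t <- orientations[[orient]]
    tb <- .chars(t)
    codes_t <- if (orient == "forward") codes_q else .kmerCodes(t, word)
    dq <- data.table::data.table(code = codes_q,
                                 qpos = seq_along(codes_q))
    dtt <- data.table::data.table(code = codes_t,
                                  tpos = seq_along(codes_t))
    dq <- dq[!is.na(dq$code)]; dtt <- dtt[!is.na(dtt$code)]
    mm <- merge(dq, dtt, by = "code", allow.cartesian = TRUE)
    if (orient == "forward") mm <- mm[mm$qpos < mm$tpos, ]
    if (nrow(mm) == 0L) next
    mm$diag <- mm$qpos - mm$tpos
    mm <- mm[order(mm$diag, mm$qpos), ]
    new_clust <- c(TRUE, diff(mm$diag) != 0 |
                           diff(mm$qpos) > word + 20L)
    cl <- cumsum(new_clust)
    for (ix in split(seq_len(nrow(mm)), cl)) {
      q0 <- mm$qpos[ix[1]]; t0 <- mm$tpos[ix[1]]
      seed_len <- mm$qpos[ix[length(ix)]] + word - 1L - q0 + 1L
      ext <- .extendUngapped(qa, tb, q0, t0, seed_len, L, L)
      if (ext$length < min_length || ext$identity < min_identity) next
      a_iv <- c(ext$q_start, ext$q_start + ext$length - 1L)
      t_iv <- c(ext$t_start, ext$t_start + ext$length - 1L)
      b_iv <- switch(orient,
        forward = t_iv,
        complement = t_iv,
        palindromic = c(L - t_iv[2] + 1L, L - t_iv[1] + 1L),
        reverse = c(L - t_iv[2] + 1L, L - t_iv[1] + 1L))
      if (a_iv[1] == b_iv[1] && a_iv[2] == b_iv[2]) next
      hits[[length(hits) + 1L]] <- data.frame(
        class = orient, a_start = a_iv[1], a_end = a_iv[2],
        b_start = b_iv[1], b_end = b_iv[2], length = ext$length,
        identity = ext$identity)
    }
  }
  empty <- data.frame(class = character(0), a_start = integer(0),
                      a_end = integer(0), b_start = integer(0),
                      b_end = integer(0), length = integer(0),
                      identity = numeric(0))
  if (!length(hits)) return(empty)
  res <- do.call(rbind, hits)
  # canonical order within a pair, then drop symmetric duplicates
  swap <- res$b_start < res$a_start
  tmp <- res[swap, c("a_start", "a_end")]
  res[swap, c("a_start", "a_end")] <- res[swap, c("b_start", "b_end")]
  res[swap, c("b_start", "b_end")] <- tmp
  res <- res[!duplicated(res[, c("class", "a_start", "a_end",
                                 "b_start", "b_end")]), , drop = FALSE]
  # contained duplicates from multiple seeds of one repeat
  res <- res[order(-res$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  if (nrow(res) > 1L) for (i in 2:nrow(res)) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      if (res$class[i] == res$class[j] &&
          res$a_start[i] >= res$a_start[j] - 5L &&
          res$a_end[i] <= res$a_end[j] + 5L &&
          res$b_start[i] >= res$b_start[j] - 5L &&
          res$b_end[i] <= res$b_end[j] + 5L) { keep[i] <- FALSE; break }
    }
  }
  res <- res[keep, , drop = FALSE]
  # remove pairs sitting on SSR/tandem intervals
  if (is.null(ssrs)) ssrs <- findSsrs(genome)
  if (is.null(tandems)) tandems <- findTandems(genome)
  masks <- rbind(
    if (nrow(ssrs)) data.frame(start = ssrs$start, end = ssrs$end),
    if (nrow(tandems)) data.frame(start = tandems$start, end = tandems$end))
  if (!is.null(masks) && nrow(masks)) {
    mr <- IRanges::reduce(IRanges::IRanges(masks$start, masks$end))
    covered <- function(st, en) {
      iv <- IRanges::IRanges(st, en)
      sum(IRanges::width(IRanges::intersect(mr, iv))) / (en - st + 1)
    }
    drop <- vapply(seq_len(nrow(res)), function(i) {
      covered(res$a_start[i], res$a_end[i]) > 0.5 ||
        covered(res$b_start[i], res$b_end[i]) > 0.5
    }, logical(1))
    res <- res[!drop, , drop = FALSE]
  }
  res[order(res$a_start), , drop = FALSE]
}

#' Summarize the three repeat classes
#'
#' @param ssrs,tandems,dispersed hit tables from [findSsrs()],
#'   [findTandems()], [findDispersed()].
#' @return list with `total`, per-class counts, the SSR unit-length
#'   distribution with percentages, SSR motif composition within each
#'   unit length, and dispersed orientation-class counts with
#'   percentages.
#' @export
repeatSummary <- function(ssrs, tandems, dispersed) {
  n_ssr <- nrow(ssrs); n_tan <- nrow(tandems); n_dis <- nrow(dispersed)
  unit_dist <- NULL
  motif_comp <- NULL
  if (n_ssr) {
    cnt <- table(factor(ssrs$unit_length, levels = 1:6))
    unit_dist <- data.frame(unit_length = 1:6, count = as.integer(cnt),
                            percentage = round(100 * as.integer(cnt) /
                                                 n_ssr, 2))
    motif_comp <- do.call(rbind, lapply(split(ssrs, ssrs$unit_length),
      function(g) {
        tt <- table(g$motif)
        data.frame(unit_length = g$unit_length[1], motif = names(tt),
                   count = as.integer(tt),
                   percentage = round(100 * as.integer(tt) / nrow(g), 2))
      }))
    rownames(motif_comp) <- NULL
  }
  dis_cls <- NULL
  if (n_dis) {
    tt <- table(factor(dispersed$class,
                       levels = c("forward", "palindromic", "reverse",
                                  "complement")))
    dis_cls <- data.frame(class = names(tt), count = as.integer(tt),
                          percentage = round(100 * as.integer(tt) /
                                               n_dis, 2))
  }
  list(total = n_ssr + n_tan + n_dis,
       n_ssr = n_ssr, n_tandem = n_tan, n_dispersed = n_dis,
       ssr_unit_distribution = unit_dist,
       ssr_motif_composition = motif_comp,
       dispersed_classes = dis_cls)
}
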