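#' @name recruitment
#' @title Iterative core-gene-baited recruitment of organelle long reads
#'
#' @description
#' Mitochondrial long reads are fished out of a mixed organelle/nuclear
#' read pool in two stages. First, reads sharing a similar fragment
#' longer than 50 bp with any conserved mitochondrial core gene are
#' selected as candidates, and the candidates hitting the most core genes
#' with the most complete coverage are taken as seeds. Second, the pool
#' is aligned iteratively against the recruited set: any read overlapping
#' a recruited read by at least 1 kb at 70% or higher identity is added,
#' until a round adds nothing.
#'
#' Overlaps are detected in two stages. A minimizer sketch
#' (k-mer size `k = 15`, window `w = 10`) finds candidate chains of
#' colinear shared minimizers; each candidate is then verified by dense
#' exact 11-mer matching along the chain diagonal. The verified matched
#' block gives the overlap length actually compared against the 1 kb
#' rule, and identity is estimated from the matched k-mer density: a
#' k-mer survives at per-base identity p with probability about `p^k`,
#' so `identity = density^(1/k)`, capped at 1. The k-th root makes the
#' estimate robust; on pairs with planted substitution counts it is
#' accurate to about +/- 0.02 across the 0.75-1.0 range. (A coarser
#' minimizer-density estimate with a calibrated retention constant is
#' used internally for screening only.)
NULL

.MINIMIZER_RETENTION <- 0.78

# minimizer sketch of one sequence: hashed k-mer window minima
.minimizers <- function(s, k = 15L, w = 10L) {
  code <- .kmerCodes(s, k)
  m <- length(code)
  if (m == 0L)
    return(data.frame(pos = integer(0), code = numeric(0)))
  h <- (code * 48271) %% 2147483647
  h[is.na(h)] <- Inf
  if (m <= w) {
    j <- which.min(h)
    if (is.infinite(h[j]))
      return(data.frame(pos = integer(0), code = numeric(0)))
    return(data.frame(pos = j, code = code[j]))
  }
  nw <- m - w + 1L
  M <- matrix(0, nw, w)
  for (j in seq_len(w)) M[, j] <- h[j:(nw + j - 1L)]
  jmin <- max.col(-M, ties.method = "first")
  p <- seq_len(nw) + jmin - 1L
  p <- unique(p)
  p <- p[!is.na(code[p])]
  data.frame(pos = p, code = code[p])
}

# dense-k-mer verification of one candidate overlap: given the chain
# diagonal, count exact 11-mer matches near that diagonal across the
# implied overlap window and return the contiguous matched block (gaps
# over max_gap split it) with a density-based identity estimate
# (k-mer survival ~ identity^k, no minimizer retention involved)
.verifyOverlap <- function(q, t, dd, o_start, o_end, k2 = 11L,
                           band = 75L, max_gap = 350L) {
  len_t <- nchar(t)
  t0 <- max(1L, o_start - dd - band)
  t1 <- min(len_t, o_end - dd + band)
  if (t1 - t0 + 1L < k2) return(NULL)
  qc <- .kmerCodes(substr(q, o_start, o_end), k2)
  tc <- .kmerCodes(substr(t, t0, t1), k2)
  dq <- data.table::data.table(code = qc, qpos = o_start +
                                 seq_along(qc) - 1L)
  dtt <- data.table::data.table(code = tc, tpos = t0 +
                                  seq_along(tc) - 1L)
  dq <- dq[!is.na(dq$code)]; dtt <- dtt[!is.na(dtt$code)]
  if (nrow(dq) == 0L || nrow(dtt) == 0L) return(NULL)
  mm <- merge(dq, dtt, by = "code", allow.cartesian = TRUE)
  if (nrow(mm) == 0L) return(NULL)
  mm <- mm[abs((mm$qpos - mm$tpos) - dd) <= band, ]
  if (nrow(mm) == 0L) return(NULL)
  qp <- sort(unique(mm$qpos))
  cl <- cumsum(c(TRUE, diff(qp) > max_gap))
  best <- NULL
  for (g in split(qp, cl)) {
    # trim isolated terminal anchors: a chance shared l-mer yields a
    # single run of adjacent k-mer matches, so group matches into
    # anchors (runs with gaps <= 30) and drop terminal anchors more
    # than 60 bp from the rest; real block edges have dense neighbours
    an <- cumsum(c(TRUE, diff(g) > 30L))
    anchors <- split(g, an)
    while (length(anchors) >= 2L &&
           min(anchors[[2]]) - max(anchors[[1]]) > 60L)
      anchors <- anchors[-1L]
    na <- length(anchors)
    while (na >= 2L &&
           min(anchors[[na]]) - max(anchors[[na - 1L]]) > 60L) {
      anchors <- anchors[-na]; na <- na - 1L
    }
    g <- unlist(anchors, use.names = FALSE)
    block <- max(g) - min(g) + k2
    if (is.null(best) || block > best$block) {
      dens <- min(1, length(g) / (block - k2 + 1L))
      best <- list(block = block, q_start = min(g),
                   q_end = max(g) + k2 - 1L,
                   identity = min(1, dens^(1 / k2)))
    }
  }
  best
}

# dynamic-programming fallback for borderline overlap lengths: a local
# alignment of the implied-overlap windows measures the aligned block
# exactly (k-mer droughts near block edges can underestimate it)
.dpVerify <- function(q, t, dd, o_start, o_end, margin = 100L) {
  t0 <- max(1L, o_start - dd - margin)
  t1 <- min(nchar(t), o_end - dd + margin)
  if (t1 - t0 < 30L) return(NULL)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                  mismatch = -3,
                                                  baseOnly = TRUE)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(substr(q, o_start, o_end)),
    Biostrings::DNAString(substr(t, t0, t1)),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2)
  cols <- Biostrings::nchar(al)
  if (cols == 0L) return(NULL)
  list(block = cols, identity = Biostrings::nmatch(al) / cols)
}

# chain shared-minimizer matches for one sequence pair (one orientation)
# and return stats of the best chain (by implied overlap, then matches)
.chainStats <- function(qp, tp, k, len_q, len_t, q_min_pos,
                        diag_gap = 100L, pos_gap = 2000L) {
  d <- qp - tp
  o <- order(d, qp)
  qp <- qp[o]; tp <- tp[o]; d <- d[o]
  cl <- cumsum(c(TRUE, diff(d) > diag_gap))
  best <- NULL
  for (g in split(seq_along(qp), cl)) {
    qg <- qp[g]; tg <- tp[g]
    og <- order(qg); qg <- qg[og]; tg <- tg[og]
    sub <- cumsum(c(TRUE, diff(qg) > pos_gap))
    for (hh in split(seq_along(qg), sub)) {
      qs <- qg[hh]; ts <- tg[hh]
      nmatch <- length(unique(qs))
      dd <- round(stats::median(qs - ts))
      o_start <- max(1L, 1L + dd)
      o_end <- min(len_q, len_t + dd)
      O <- o_end - o_start + 1L
      if (O <= 0L) next
      span <- max(qs) - min(qs) + k
      denom <- sum(q_min_pos >= o_start & q_min_pos <= o_end)
      f <- if (denom > 0) min(1, nmatch / denom) else 0
      ident <- min(1, (f / .MINIMIZER_RETENTION)^(1 / k))
      st <- list(n_matches = nmatch, q_start = min(qs),
                 q_end = max(qs) + k - 1L, t_start = min(ts),
                 t_end = max(ts) + k - 1L, match_span = span,
                 block_length = O, o_start = o_start, o_end = o_end,
                 diag = dd, identity = ident)
      if (is.null(best) || st$n_matches > best$n_matches ||
          (st$n_matches == best$n_matches &&
           st$block_length > best$block_length)) best <- st
    }
  }
  best
}

#' Detect overlaps between two sequences with a minimizer sketch
#'
#' Both orientations are searched. Candidate chains of colinear shared
#' minimizers are verified by dense exact k-mer matching along the chain
#' diagonal: the reported `block_length` is the extent of the verified
#' matched block (for full dovetail overlaps this is the aligned overlap
#' length; for partial homology, the homologous block only), and
#' `identity` is the k-mer-density estimate over that block.
#'
#' @param a,b character scalars (DNA).
#' @param k minimizer k-mer size (default 15, minimum 11).
#' @param w minimizer window (default 10).
#' @param min_chain minimum shared minimizers to report a hit (default 3).
#' @return data.frame with `orientation`, `q_start`, `q_end`, `t_start`,
#'   `t_end` (on `b`'s forward strand), `block_length`, `match_span`,
#'   `identity`, `n_matches`; zero rows when nothing is found.
#' @export
overlapDetect <- function(a, b, k = 15L, w = 10L, min_chain = 3L) {
  stopifnot(k >= 11L, w >= 1L)
  a <- toupper(a); b <- toupper(b)
  ma <- .minimizers(a, k, w)
  len_a <- nchar(a); len_b <- nchar(b)
  out <- list()
  for (orient in c("+", "-")) {
    bo <- if (orient == "+") b else revComp(b)
    mb <- .minimizers(bo, k, w)
    if (nrow(ma) == 0L || nrow(mb) == 0L) next
    mm <- merge(ma, mb, by = "code", suffixes = c("_q", "_t"))
    if (nrow(mm) < min_chain) next
    st <- .chainStats(mm$pos_q, mm$pos_t, k, len_a, nchar(bo), ma$pos)
    if (is.null(st) || st$n_matches < min_chain) next
    vf <- .verifyOverlap(a, bo, st$diag, st$o_start, st$o_end)
    if (is.null(vf)) next
    t_iv <- c(vf$q_start - st$diag, vf$q_end - st$diag)
    t_iv[1] <- max(1L, t_iv[1]); t_iv[2] <- min(nchar(bo), t_iv[2])
    if (orient == "-") t_iv <- c(len_b - t_iv[2] + 1L, len_b - t_iv[1] + 1L)
    out[[length(out) + 1L]] <- data.frame(
      orientation = orient, q_start = vf$q_start, q_end = vf$q_end,
      t_start = t_iv[1], t_end = t_iv[2],
      block_length = vf$block, match_span = st$match_span,
      identity = vf$identity, n_matches = st$n_matches)
  }
  if (!length(out))
    return(data.frame(orientation = character(0), q_start = integer(0),
                      q_end = integer(0), t_start = integer(0),
                      t_end = integer(0), block_length = integer(0),
                      match_span = integer(0), identity = numeric(0),
                      n_matches = integer(0)))
  do.call(rbind, out)
}

.asSeqVector <- function(reads) {
  if (is(reads, "DNAStringSet")) {
    out <- as.character(reads)
    names(out) <- sub("\\s.*$", "", names(reads))
    return(toupper(out))
  }
  stopifnot(is.character(reads))
  if (length(reads) && is.null(names(reads)))
    stop("sequences must be named")
  toupper(reads)
}

# minimizer tables for a read set, both strands, as one data.table
.readMinimizers <- function(seqs, k, w) {
  tabs <- lapply(names(seqs), function(id) {
    fw <- .minimizers(seqs[[id]], k, w)
    rc <- .minimizers(revComp(seqs[[id]]), k, w)
    data.table::data.table(
      read = id,
      strand = rep(c("+", "-"), c(nrow(fw), nrow(rc))),
      pos = c(fw$pos, rc$pos), code = c(fw$code, rc$code))
  })
  data.table::rbindlist(tabs)
}

#' Scan reads for candidates hitting conserved core genes
#'
#' A read is a candidate when the matched span of some minimizer chain
#' against some core gene exceeds `min_block` (the "similar fragment
#' longer than 50 bp" rule). Returns per-read, per-gene hit details for
#' seed scoring.
#'
#' @param reads named character vector (or `DNAStringSet`) of reads.
#' @param core_genes named character vector (or `DNAStringSet`) of core
#'   gene sequences; must be non-empty.
#' @param min_block minimum similar-fragment length in bp (default 50).
#' @param k,w minimizer parameters.
#' @param min_chain minimum shared minimizers per chain (default 2; core
#'   gene blocks near `min_block` carry few minimizers).
#' @return data.frame with `read`, `gene`, `span`, `gene_cov_start`,
#'   `gene_cov_end` for qualifying hits; candidate ids are
#'   `unique(result$read)`.
#' @export
scanCandidates <- function(reads, core_genes, min_block = 50, k = 15L,
                           w = 10L, min_chain = 2L) {
  reads <- .asSeqVector(reads)
  core_genes <- .asSeqVector(core_genes)
  if (length(core_genes) == 0L) stop("core gene set is empty")
  empty <- data.frame(read = character(0), gene = character(0),
                      span = integer(0), gene_cov_start = integer(0),
                      gene_cov_end = integer(0))
  if (length(reads) == 0L) return(empty)
  gid <- lapply(names(core_genes), function(g) {
    mm <- .minimizers(core_genes[[g]], k, w)
    data.table::data.table(gene = g, gpos = mm$pos, code = mm$code)
  })
  gidx <- data.table::rbindlist(gid)
  rmin <- .readMinimizers(reads, k, w)
  mm <- merge(rmin, gidx, by = "code", allow.cartesian = TRUE)
  if (nrow(mm) == 0L) return(empty)
  glen <- nchar(core_genes)
  rlen <- nchar(reads)
  qpos_by_rs <- split(rmin$pos, paste(rmin$read, rmin$strand))
  grp <- split(mm, list(mm$read, mm$gene, mm$strand), drop = TRUE)
  rows <- lapply(grp, function(gdt) {
    rd <- gdt$read[1]; gn <- gdt$gene[1]
    qmp <- qpos_by_rs[[paste(rd, gdt$strand[1])]]
    st <- .chainStats(gdt$pos, gdt$gpos, k, rlen[[rd]], glen[[gn]], qmp)
    if (is.null(st) || st$n_matches < min_chain) return(NULL)
    if (st$match_span <= min_block) return(NULL)
    # gene coverage with a small edge allowance (minimizers cannot sit
    # closer than ~k+w to a block edge), never past the read's reach
    edge <- 26L
    lo <- max(1L, st$t_start - min(st$q_start - 1L, edge))
    hi <- min(glen[[gn]], st$t_end + min(rlen[[rd]] - st$q_end, edge))
    data.frame(read = rd, gene = gn, span = st$match_span,
               gene_cov_start = lo, gene_cov_end = hi)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score and rank candidate reads as assembly seeds
#'
#' Candidates are ranked lexicographically by the number of distinct core
#' genes hit, then by completeness (mean covered fraction of each hit
#' gene), then by read length (longer first), then id.
#'
#' @param candidate_hits result of [scanCandidates()].
#' @param reads the read set (for tie-breaking lengths).
#' @param core_genes the core gene set (for lengths).
#' @return data.frame `read`, `genes_hit`, `completeness`, sorted best
#'   first.
#' @export
scoreSeeds <- function(candidate_hits, reads, core_genes) {
  reads <- .asSeqVector(reads)
  core_genes <- .asSeqVector(core_genes)
  if (nrow(candidate_hits) == 0L)
    return(data.frame(read = character(0), genes_hit = integer(0),
                      completeness = numeric(0)))
  glen <- nchar(core_genes)
  per <- lapply(split(candidate_hits, candidate_hits$read), function(h) {
    cov <- vapply(split(h, h$gene), function(hg) {
      iv <- IRanges::reduce(IRanges::IRanges(hg$gene_cov_start,
                                             hg$gene_cov_end))
      sum(IRanges::width(iv)) / glen[[hg$gene[1]]]
    }, numeric(1))
    data.frame(read = h$read[1], genes_hit = length(cov),
               completeness = mean(pmin(1, cov)))
  })
  out <- do.call(rbind, per)
  out <- out[order(-out$genes_hit, -out$completeness,
                   -nchar(reads[out$read]), out$read), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iteratively recruit reads overlapping the growing seed set
#'
#' Each round, every unrecruited read with an overlap of at least
#' `min_overlap` bases at identity `min_identity` or better against any
#' recruited read is added; the procedure stops at the first round that
#' adds nothing (that empty round is counted). Deterministic given the
#' input order.
#'
#' @param reads named character vector (or `DNAStringSet`).
#' @param seeds character vector of seed read ids (non-empty, subset of
#'   the read ids).
#' @param min_overlap minimum overlap in bases (default 1000, the 1 kb
#'   rule).
#' @param min_identity minimum overlap identity (default 0.70).
#' @param k,w minimizer parameters.
#' @param min_chain minimum shared minimizers supporting a candidate
#'   overlap before verification.
#' @return list of class `recruitment_result`: `seed_ids`,
#'   `recruited_ids` (seeds first, then by round), `rounds`,
#'   `per_round_added`, and `report` (data.frame read_id, round,
#'   best_overlap, identity).
#' @details Candidate overlaps from the minimizer screen are verified by
#'   dense k-mer matching along the chain diagonal
#'   (see [overlapDetect()]); the overlap length compared against
#'   `min_overlap` is the verified matched block, so a short shared
#'   segment (for example a plastid-derived insertion inside a
#'   mitochondrial read) does not satisfy a 1 kb overlap requirement.
#' @export
recruitIterative <- function(reads, seeds, min_overlap = 1000,
                             min_identity = 0.70, k = 15L, w = 10L,
                             min_chain = 2L) {
  reads <- .asSeqVector(reads)
  if (length(seeds) == 0L) stop("seeds must be non-empty")
  if (!all(seeds %in% names(reads))) stop("unknown seed id(s)")
  rlen <- nchar(reads)
  rmin <- .readMinimizers(reads, k, w)
  data.table::setkey(rmin, code)
  # forward-strand minimizers only are indexed; queries search both
  fwd <- rmin[rmin$strand == "+", ]
  qpos_by_rs <- split(rmin$pos, paste(rmin$read, rmin$strand))
  recruited <- seeds
  newly <- seeds
  rounds <- 0L
  per_round <- integer(0)
  # pair evaluation is deterministic: cache rejected (read, target,
  # strand) triples so later rounds skip them
  rejected <- new.env(hash = TRUE, parent = emptyenv())
  report <- data.frame(read_id = seeds, round = 0L,
                       best_overlap = NA_integer_, identity = NA_real_)
  repeat {
    rounds <- rounds + 1L
    idx <- fwd[fwd$read %in% newly, ]
    pool <- rmin[!(rmin$read %in% recruited), ]
    added <- character(0)
    if (nrow(idx) && nrow(pool)) {
      data.table::setnames(idx, c("read", "pos"), c("target", "tpos"))
      mm <- merge(pool, idx[, c("code", "target", "tpos")], by = "code",
                  allow.cartesian = TRUE)
      if (nrow(mm)) {
        grp <- split(mm, list(mm$read, mm$target, mm$strand), drop = TRUE)
        cand <- lapply(grp, function(gdt) {
          if (nrow(gdt) < min_chain) return(NULL)
          rd <- gdt$read[1]
          tg <- gdt$target[1]
          strand <- gdt$strand[1]
          key <- paste0(rd, "\r", tg, "\r", strand)
          if (!is.null(rejected[[key]])) return(NULL)
          rejected[[key]] <- TRUE
          qmp <- qpos_by_rs[[paste(rd, strand)]]
          st <- .chainStats(gdt$pos, gdt$tpos, k, rlen[[rd]],
                            rlen[[tg]], qmp)
          if (is.null(st) || st$n_matches < min_chain) return(NULL)
          if (st$block_length < min_overlap) return(NULL)
          qseq <- if (strand == "+") reads[[rd]] else revComp(reads[[rd]])
          vf <- .verifyOverlap(qseq, reads[[tg]], st$diag,
                               st$o_start, st$o_end)
          if (is.null(vf)) return(NULL)
          if (vf$block < min_overlap && vf$block >= 0.5 * min_overlap) {
            # borderline: measure the aligned block exactly, in a
            # window just around it (edge droughts are < 600 bp)
            dp <- .dpVerify(qseq, reads[[tg]], st$diag,
                            max(st$o_start, vf$q_start - 600L),
                            min(st$o_end, vf$q_end + 600L))
            if (!is.null(dp)) vf <- dp
          }
          if (vf$block < min_overlap || vf$identity < min_identity)
            return(NULL)
          data.frame(read_id = rd, best_overlap = vf$block,
                     identity = round(vf$identity, 4))
        })
        cand <- cand[!vapply(cand, is.null, logical(1))]
        if (length(cand)) {
          cdf <- do.call(rbind, cand)
          cdf <- cdf[order(-cdf$best_overlap), , drop = FALSE]
          cdf <- cdf[!duplicated(cdf$read_id), , drop = FALSE]
          # keep deterministic input order
          cdf <- cdf[order(match(cdf$read_id, names(reads))), ,
                     drop = FALSE]
          added <- cdf$read_id
          cdf$round <- rounds
          report <- rbind(report,
                          cdf[, c("read_id", "round", "best_overlap",
                                  "identity")])
        }
      }
    }
    per_round <- c(per_round, length(added))
    if (!length(added)) break
    recruited <- c(recruited, added)
    newly <- added
  }
  structure(list(seed_ids = seeds, recruited_ids = recruited,
                 rounds = rounds, per_round_added = per_round,
                 report = report),
            class = "recruitment_result")
}

#' @export
print.recruitment_result <- function(x, ...) {
  cat(sprintf(
    "Recruitment: %d seed(s) -> %d read(s) in %d round(s) [%s]\n",
    length(x$seed_ids), length(x$recruited_ids), x$rounds,
    paste(x$per_round_added, collapse = ", ")))
  invisible(x)
}

#' One-call recruitment pipeline: candidates, seeds, iteration
#'
#' @inheritParams recruitIterative
#' @param core_genes core gene sequences for baiting.
#' @param n_seeds number of top-ranked candidates used as seeds
#'   (default 10).
#' @param min_block candidate similar-fragment threshold (default 50).
#' @return a `recruitment_result` (see [recruitIterative()]) with an
#'   extra element `seed_scores`.
#' @export
recruitReads <- function(reads, core_genes, n_seeds = 10L,
                         min_block = 50, min_overlap = 1000,
                         min_identity = 0.70, k = 15L, w = 10L) {
  reads <- .asSeqVector(reads)
  hits <- scanCandidates(reads, core_genes, min_block = min_block,
                         k = k, w = w)
  if (nrow(hits) == 0L) stop("no candidate reads hit the core genes")
  scores <- scoreSeeds(hits, reads, core_genes)
  seeds <- utils::head(scores$read, n_seeds)
  res <- recruitIterative(reads, seeds, min_overlap = min_overlap,
                          min_identity = min_identity, k = k, w = w)
  res$seed_scores <- scores
  res
}
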