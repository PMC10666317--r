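#' @name molevo
#' @title Pairwise Ka/Ks and nucleotide diversity
#'
#' @description
#' Pairwise synonymous/nonsynonymous substitution rates from codon-aligned
#' CDS pairs, by Nei-Gojobori (NG86) counting with Jukes-Cantor correction,
#' or by the Li-Wu-Luo degeneracy-class method with the modified weighting
#' of twofold-degenerate sites (MLWL), which apportions twofold sites
#' between synonymous and nonsynonymous classes using the observed
#' transition/transversion ratio instead of the fixed 1/3. Nucleotide
#' diversity (pi) is the mean pairwise difference per site across an
#' alignment, with complete deletion of gap columns.
NULL

.BASES <- c("A", "C", "G", "T")

.isTransition <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
  (x == "C" & y == "T") | (x == "T" & y == "C")
}

# codon-aware cleanup of an aligned pair: drop codon columns containing a
# gap in either sequence, then drop a shared terminal stop; error on
# internal stops or empty result
.cleanCodonPair <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) stop("aligned sequences differ in length")
  if (nchar(a) %% 3L != 0L) stop("alignment length not divisible by 3")
  ca <- .codons(a); cb <- .codons(b)
  keep <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("no codons left after gap filtering")
  k <- length(ca)
  if (translateCodon(ca[k]) == "X" && translateCodon(cb[k]) == "X") {
    ca <- ca[-k]; cb <- cb[-k]
  }
  if (length(ca) == 0L) stop("no codons left after stop removal")
  bad <- which(translateCodon(ca) == "X" | translateCodon(cb) == "X")
  if (length(bad))
    stop("internal stop codon at codon position ",
         paste(bad, collapse = ", "))
  list(a = ca, b = cb)
}

# NG86 site counting for one codon: fraction of the three possible changes
# at each position that are synonymous; changes creating a stop codon are
# counted as nonsynonymous. Returns c(syn, nonsyn), syn + nonsyn == 3.
# Cached over the 64 codons.
.ng86SiteCodon <- function(codon) {
  if (is.null(.pkgCache$ng86_sites)) .pkgCache$ng86_sites <- list()
  hit <- .pkgCache$ng86_sites[[codon]]
  if (!is.null(hit)) return(hit)
  aa0 <- translateCodon(codon)
  chars <- .chars(codon)
  syn <- 0
  for (p in 1:3) {
    for (alt in setdiff(.BASES, chars[p])) {
      mut <- chars; mut[p] <- alt
      aa1 <- translateCodon(paste(mut, collapse = ""))
      if (aa1 != "X" && aa1 == aa0) syn <- syn + 1 / 3
    }
  }
  out <- c(syn = syn, nonsyn = 3 - syn)
  .pkgCache$ng86_sites[[codon]] <- out
  out
}

# pathway-averaged synonymous/nonsynonymous difference counts for one
# codon pair; paths through stop codons are discarded when an alternative
# exists, otherwise all paths are used
.ng86DiffCodon <- function(c1, c2) {
  idx <- which(.chars(c1) != .chars(c2))
  d <- length(idx)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- if (d == 1L) list(idx) else if (d == 2L)
    list(idx, rev(idx)) else
    lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
           function(o) idx[o])
  paths <- lapply(perms, function(ord) {
    cur <- .chars(c1); tgt <- .chars(c2)
    syn <- 0; non <- 0; valid <- TRUE
    for (p in ord) {
      aa_from <- translateCodon(paste(cur, collapse = ""))
      cur[p] <- tgt[p]
      aa_to <- translateCodon(paste(cur, collapse = ""))
      if (aa_to == "X" && !all(cur == tgt)) valid <- FALSE
      if (aa_from == aa_to && aa_to != "X") syn <- syn + 1 else non <- non + 1
    }
    list(syn = syn, non = non, valid = valid)
  })
  ok <- vapply(paths, `[[`, logical(1), "valid")
  use <- if (any(ok)) paths[ok] else paths
  c(sd = mean(vapply(use, `[[`, numeric(1), "syn")),
    nd = mean(vapply(use, `[[`, numeric(1), "non")))
}

.jc <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

.kaksResult <- function(method, ka, ks, sites_n, sites_s) {
  ratio <- if (is.na(ka) || is.na(ks) || ks == 0) NA_real_ else ka / ks
  data.frame(method = method, ka = ka, ks = ks, ratio = ratio,
             sites_n = sites_n, sites_s = sites_s)
}

#' Ka and Ks by the Nei-Gojobori (1986) method
#'
#' Synonymous and nonsynonymous site counts are averaged over the two
#' sequences; differences in multi-hit codons are averaged over all
#' mutational pathways (pathways through stop codons are excluded when
#' alternatives exist); proportions are corrected with the Jukes-Cantor
#' formula. Changes creating stop codons count as nonsynonymous in site
#' counting, so `sites_n + sites_s == 3 * codons` exactly.
#'
#' @param a,b aligned CDS strings (equal length, in frame; gap codons are
#'   removed by complete deletion, terminal stops stripped).
#' @return one-row data.frame with `method`, `ka`, `ks`, `ratio` (NA when
#'   `ks` is 0 or a correction is undefined), `sites_n`, `sites_s`.
#' @examples
#' a <- strrep("ATGGCTGAA", 20)
#' b <- paste0("ATGGCCGAA", strrep("ATGGCTGAA", 19))  # one fourfold change
#' ng86(a, b)[, c("ka", "ks")]
#' @export
ng86 <- function(a, b) {
  pair <- .cleanCodonPair(a, b)
  sa <- vapply(pair$a, .ng86SiteCodon, numeric(2))
  sb <- vapply(pair$b, .ng86SiteCodon, numeric(2))
  S <- (sum(sa["syn", ]) + sum(sb["syn", ])) / 2
  N <- (sum(sa["nonsyn", ]) + sum(sb["nonsyn", ])) / 2
  dif <- mapply(.ng86DiffCodon, pair$a, pair$b)
  Sd <- sum(dif["sd", ]); Nd <- sum(dif["nd", ])
  ks <- .jc(if (S > 0) Sd / S else NA_real_)
  ka <- .jc(if (N > 0) Nd / N else NA_real_)
  .kaksResult("NG86", ka, ks, N, S)
}

# degeneracy class of each codon position: number of synonymous one-step
# changes (stop-creating changes nonsynonymous): 0 -> class 0; 3 -> class
# 4; 1 or 2 -> class 2 (standard LWL simplification)
.lwlClassCodon <- function(codon) {
  if (is.null(.pkgCache$lwl_class)) .pkgCache$lwl_class <- list()
  hit <- .pkgCache$lwl_class[[codon]]
  if (!is.null(hit)) return(hit)
  aa0 <- translateCodon(codon)
  chars <- .chars(codon)
  out <- vapply(1:3, function(p) {
    nsyn <- 0L
    for (alt in setdiff(.BASES, chars[p])) {
      mut <- chars; mut[p] <- alt
      aa1 <- translateCodon(paste(mut, collapse = ""))
      if (aa1 != "X" && aa1 == aa0) nsyn <- nsyn + 1L
    }
    if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
  }, integer(1))
  .pkgCache$lwl_class[[codon]] <- out
  out
}

.k2pClass <- function(P, Q) {
  P <- unname(P); Q <- unname(Q)
  a <- 1 - 2 * P - Q
  b <- 1 - 2 * Q
  if (a <= 0 || b <= 0) return(c(A = NA_real_, B = NA_real_))
  c(A = 0.5 * log(1 / a) - 0.25 * log(1 / b), B = 0.5 * log(1 / b))
}

#' Ka and Ks by the modified Li-Wu-Luo method (MLWL)
#'
#' Sites are partitioned into nondegenerate, twofold- and
#' fourfold-degenerate classes; transition and transversion differences
#' per class are corrected with Kimura's two-parameter model. The
#' modification replaces LWL85's fixed 1/3 synonymous weight for twofold
#' sites with `kappa/(kappa+2)`, where the transition/transversion ratio
#' `kappa` is estimated from the fourfold-degenerate sites; with
#' `kappa = 1` the estimator reduces to LWL85. Set `use_kappa = FALSE`
#' for plain LWL85 weighting.
#'
#' @inheritParams ng86
#' @param use_kappa logical; apply the kappa-based twofold weighting
#'   (default `TRUE`).
#' @return one-row data.frame as in [ng86()] (method "MLWL" or "LWL85").
#' @export
mlwl <- function(a, b, use_kappa = TRUE) {
  pair <- .cleanCodonPair(a, b)
  nc <- length(pair$a)
  cls_a <- vapply(pair$a, .lwlClassCodon, integer(3))
  cls_b <- vapply(pair$b, .lwlClassCodon, integer(3))
  L <- c("0" = 0, "2" = 0, "4" = 0)
  for (cl in c(0L, 2L, 4L)) {
    L[as.character(cl)] <- (sum(cls_a == cl) + sum(cls_b == cl)) / 2
  }
  # differences per position, split 0.5/0.5 between the two codons' classes
  ts <- c("0" = 0, "2" = 0, "4" = 0)
  tv <- c("0" = 0, "2" = 0, "4" = 0)
  for (i in seq_len(nc)) {
    ch_a <- .chars(pair$a[i]); ch_b <- .chars(pair$b[i])
    for (p in which(ch_a != ch_b)) {
      w <- c(as.character(cls_a[p, i]), as.character(cls_b[p, i]))
      if (.isTransition(ch_a[p], ch_b[p])) {
        ts[w[1]] <- ts[w[1]] + 0.5; ts[w[2]] <- ts[w[2]] + 0.5
      } else {
        tv[w[1]] <- tv[w[1]] + 0.5; tv[w[2]] <- tv[w[2]] + 0.5
      }
    }
  }
  AB <- lapply(c("0", "2", "4"), function(cl) {
    if (L[cl] == 0) return(c(A = 0, B = 0))
    .k2pClass(ts[cl] / L[cl], tv[cl] / L[cl])
  })
  names(AB) <- c("0", "2", "4")
  kappa <- 1
  if (use_kappa) {
    A4 <- AB[["4"]]["A"]; B4 <- AB[["4"]]["B"]
    if (!is.na(A4) && !is.na(B4) && B4 > 0 && A4 > 0)
      kappa <- max(0.1, min(20, 2 * A4 / B4))
  }
  wsyn <- kappa / (kappa + 2)
  S <- L["2"] * wsyn + L["4"]
  N <- L["0"] + L["2"] * (1 - wsyn)
  num_s <- L["2"] * AB[["2"]]["A"] + L["4"] * (AB[["4"]]["A"] + AB[["4"]]["B"])
  num_n <- L["0"] * (AB[["0"]]["A"] + AB[["0"]]["B"]) + L["2"] * AB[["2"]]["B"]
  ks <- if (S > 0) unname(num_s / S) else NA_real_
  ka <- if (N > 0) unname(num_n / N) else NA_real_
  .kaksResult(if (use_kappa) "MLWL" else "LWL85", ka, ks,
              unname(N), unname(S))
}

#' Nucleotide diversity (pi) of a multiple alignment
#'
#' Mean pairwise difference per site: columns containing a gap or
#' ambiguity in any sequence are removed (complete deletion) unless
#' `pairwise_deletion = TRUE`, in which case each pair uses its own
#' gap-free columns.
#'
#' @param seqs character vector of >= 2 aligned sequences (equal length).
#' @param pairwise_deletion logical (default `FALSE`, complete deletion).
#' @return list with `pi`, `n_sequences`, `sites_used` (complete deletion:
#'   shared gap-free columns; pairwise deletion: the mean over pairs).
#' @examples
#' piDiversity(c(a = "ACGTACGT", b = "ACGTACGA"))$pi
#' @export
piDiversity <- function(seqs, pairwise_deletion = FALSE) {
  n <- length(seqs)
  if (n < 2L) stop("pi requires at least 2 sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("aligned sequences differ in length")
  mat <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  ok <- matrix(mat %in% .BASES, nrow = n)
  pairs <- utils::combn(n, 2)
  if (!pairwise_deletion) {
    keep <- colSums(ok) == n
    sites <- sum(keep)
    if (sites == 0L) stop("no gap-free columns")
    m <- mat[, keep, drop = FALSE]
    dtot <- sum(apply(pairs, 2, function(ij) sum(m[ij[1], ] != m[ij[2], ])))
    pi <- dtot / (ncol(pairs) * sites)
    return(list(pi = pi, n_sequences = n, sites_used = sites))
  }
  per <- apply(pairs, 2, function(ij) {
    keep <- ok[ij[1], ] & ok[ij[2], ]
    if (!any(keep)) return(c(0, 0))
    c(sum(mat[ij[1], keep] != mat[ij[2], keep]), sum(keep))
  })
  pi <- mean(per[1, ] / pmax(per[2, ], 1))
  list(pi = pi, n_sequences = n, sites_used = mean(per[2, ]))
}

#' Classify the selection regime from a Ka/Ks ratio
#'
#' @param result a result row from [ng86()]/[mlwl()], or a numeric ratio.
#' @param tol tolerance around 1 counted as neutral (default 1e-9).
#' @return one of "positive", "purifying", "neutral", "undetermined"
#'   (missing ratio, e.g. `ks == 0`).
#' @export
classifySelection <- function(result, tol = 1e-9) {
  ratio <- if (is.data.frame(result)) result$ratio else as.numeric(result)
  vapply(ratio, function(r) {
    if (is.na(r)) "undetermined"
    else if (abs(r - 1) <= tol) "neutral"
    else if (r > 1) "positive" else "purifying"
  }, character(1))
}

#' Read an aligned FASTA into a named character vector
#'
#' Gaps ("-") are preserved; sequences are uppercased.
#'
#' @param path path to an aligned FASTA file.
#' @return named character vector.
#' @export
readAlignment <- function(path) {
  set <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(set)), sub("\\s.*$", "", names(set)))
}
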