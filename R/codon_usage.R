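#' @name codon_usage
#' @title Codon counting and relative synonymous codon usage
#'
#' @description
#' RSCU for a codon c in a synonym family f of size k is
#' `n_c * k / sum(n_c' for c' in f)`: the observed usage relative to the
#' expectation under uniform usage within the family. Values average to 1
#' within every family with nonzero usage; single-codon families (Met,
#' Trp) are always exactly 1 when used.
NULL

# synonym families from the standard genetic code; stops excluded unless
# requested; met_family (e.g. c("ATG","CTG","TTG")) moves the listed
# codons into one family labelled "Met*", mirroring conventions that group
# alternative initiation codons with AUG
.codonFamilies <- function(include_stops = FALSE, met_family = NULL) {
  tab <- .codonTable()
  fam <- setNames(unname(tab), names(tab))
  if (!include_stops) fam <- fam[fam != "X"]
  if (!is.null(met_family)) {
    met_family <- toupper(chartr("U", "T", met_family))
    stopifnot("ATG" %in% met_family)
    fam[names(fam) %in% met_family] <- "Met*"
  }
  fam
}

#' Count codons across a set of CDS
#'
#' Multi-copy CDS are deduplicated by exact sequence ("unique CDS") so
#' that multi-copy genes are counted once; terminal stop codons are
#' excluded by default.
#'
#' @param cds_list character vector of in-frame CDS.
#' @param dedupe logical, drop exact duplicate sequences (default `TRUE`).
#' @param drop_terminal_stop logical (default `TRUE`).
#' @return list with `counts` (named integer vector over the 64 codons)
#'   and `n_cds` (number of sequences counted).
#' @examples
#' countCodons("ATGTAA")$counts[["ATG"]]
#' @export
countCodons <- function(cds_list, dedupe = TRUE, drop_terminal_stop = TRUE) {
  cds_list <- toupper(cds_list)
  cds_list <- cds_list[!is.na(cds_list)]
  if (dedupe) cds_list <- unique(cds_list)
  bad <- which(nchar(cds_list) %% 3L != 0L)
  if (length(bad))
    stop("frame error: CDS ", paste(bad, collapse = ", "),
         " not divisible by 3")
  all_codons <- unlist(lapply(cds_list, function(s) {
    co <- .codons(s)
    if (drop_terminal_stop && length(co) &&
        translateCodon(co[length(co)]) == "X")
      co <- co[-length(co)]
    co
  }))
  counts <- setNames(integer(64), names(.codonTable()))
  tab <- table(all_codons[all_codons %in% names(counts)])
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts, n_cds = length(cds_list))
}

#' Relative synonymous codon usage
#'
#' @param counts result of [countCodons()], or a named integer vector of
#'   codon counts.
#' @param include_stops include stop codons as a family (default `FALSE`).
#' @param met_family optional codon set grouped into one
#'   initiation-codon family with ATG (e.g. `c("ATG","CTG","TTG")`).
#' @return data.frame with `codon`, `amino_acid`, `family`,
#'   `family_size`, `count`, `rscu` (NA for families with zero total).
#' @examples
#' cc <- countCodons(c("GCTGCTGCGTAA"))
#' rscu(cc)[c("GCT", "GCG"), "rscu"]
#' @export
rscu <- function(counts, include_stops = FALSE, met_family = NULL) {
  if (is.list(counts)) counts <- counts$counts
  fam <- .codonFamilies(include_stops, met_family)
  codons <- names(fam)
  n <- counts[codons]
  n[is.na(n)] <- 0L
  fam_tot <- vapply(split(as.numeric(n), fam), sum, numeric(1))
  fam_size <- table(fam)
  k <- as.integer(fam_size[fam])
  tot <- unname(fam_tot[fam])
  vals <- ifelse(tot > 0, as.numeric(n) * k / tot, NA_real_)
  out <- data.frame(codon = codons,
                    amino_acid = translateCodon(codons),
                    family = unname(fam), family_size = k,
                    count = as.integer(n), rscu = vals)
  rownames(out) <- codons
  out
}

#' Census of over-represented codons and their A/T third-base bias
#'
#' Counts codons with RSCU strictly greater than 1 and the share of them
#' ending in A or T, the usual summary of A/T bias in organelle genomes.
#'
#' @param table result of [rscu()].
#' @return list with `n_gt1`, `n_gt1_AT_ending`, `percentage`
#'   (`100 * n_AT / n_gt1`, NA when no codon exceeds 1).
#' @export
atEndingCensus <- function(table) {
  gt1 <- table[!is.na(table$rscu) & table$rscu > 1, ]
  n <- nrow(gt1)
  at <- sum(substr(gt1$codon, 3, 3) %in% c("A", "T"))
  list(n_gt1 = n, n_gt1_AT_ending = at,
       percentage = if (n > 0) round(100 * at / n, 2) else NA_real_)
}
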