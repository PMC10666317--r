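#' @name editing
#' @title C-to-U RNA editing: codon effects and summaries
#'
#' @description
#' Plant mitochondrial mRNAs undergo cytidine-to-uridine editing, seen as
#' C->T changes at the cDNA level. Given per-gene edit sites (1-based CDS
#' positions whose reference base is C), these functions apply the edits,
#' classify each codon change by the hydropathy transition of the encoded
#' amino acid, and aggregate counts, percentages, codon-position usage,
#' target amino acids, and functional effects (stop gain, start creation).
#'
#' The hydropathy classes follow the convention used for organelle editing
#' tables: hydrophobic = A, V, L, I, P, F, M, W; hydrophilic = R, N, D, C,
#' Q, E, H, K, S, T, Y, G; stop is its own class. Glycine never occurs in
#' such tables for C->T edits and is assigned hydrophilic (Kyte-Doolittle
#' sign); override with the `hydrophobic` argument if needed.
NULL

.HYDROPHOBIC_DEFAULT <- c("A", "V", "L", "I", "P", "F", "M", "W")

.hydroClass <- function(aa, hydrophobic = .HYDROPHOBIC_DEFAULT) {
  ifelse(aa == "X", "stop",
         ifelse(aa %in% hydrophobic, "hydrophobic", "hydrophilic"))
}

#' Apply C-to-T edit sites to a CDS
#'
#' @param cds character scalar CDS.
#' @param sites integer vector of 1-based CDS positions, or a data.frame
#'   with a `cds_position` column.
#' @return the edited CDS (same length; exactly the given positions
#'   changed C -> T).
#' @examples
#' applyEdits("CCA", c(1, 2))  # "TTA"
#' @export
applyEdits <- function(cds, sites) {
  if (is.data.frame(sites)) sites <- sites$cds_position
  sites <- as.integer(sites)
  if (length(sites) == 0L) return(cds)
  chars <- .chars(toupper(cds))
  if (any(sites < 1L | sites > length(chars)))
    stop("edit site outside CDS (length ", length(chars), ")")
  ref <- chars[sites]
  if (any(ref != "C"))
    stop("edit site(s) whose reference base is not C at CDS position(s): ",
         paste(sites[ref != "C"], collapse = ", "))
  chars[sites] <- "T"
  paste(chars, collapse = "")
}

#' Classify one edited codon change
#'
#' The two codons must differ only by C->T substitutions (position 1
#' and/or 2 in observed organelle editing, but position 3 is accepted and
#' classified the same way).
#'
#' @param from_codon,to_codon 3-letter DNA codons.
#' @param hydrophobic amino acids treated as hydrophobic.
#' @return one-row data.frame: `from_codon`, `to_codon`, `from_aa`,
#'   `to_aa` (stop as "X"), `positions_edited` (comma-separated),
#'   `category` (e.g. "hydrophilic-hydrophobic").
#' @examples
#' classifyChange("TCA", "TTA")$category  # S -> L
#' @export
classifyChange <- function(from_codon, to_codon,
                           hydrophobic = .HYDROPHOBIC_DEFAULT) {
  from_codon <- toupper(from_codon); to_codon <- toupper(to_codon)
  if (nchar(from_codon) != 3L || nchar(to_codon) != 3L)
    stop("codons must be 3 bp")
  f <- .chars(from_codon); t <- .chars(to_codon)
  d <- which(f != t)
  if (length(d) == 0L) stop("codons are identical")
  if (any(f[d] != "C" | t[d] != "T"))
    stop("validation error: change ", from_codon, " -> ", to_codon,
         " is not pure C->T editing")
  from_aa <- translateCodon(from_codon)
  to_aa <- translateCodon(to_codon)
  cat_from <- .hydroClass(from_aa, hydrophobic)
  cat_to <- .hydroClass(to_aa, hydrophobic)
  data.frame(from_codon = from_codon, to_codon = to_codon,
             from_aa = from_aa, to_aa = to_aa,
             positions_edited = paste(d, collapse = ","),
             category = paste(cat_from, cat_to, sep = "-"))
}

#' Summarize a set of codon-change counts
#'
#' @param changes data.frame with columns `from_codon`, `to_codon`,
#'   `count` (positive integers); one row per distinct codon change.
#' @param hydrophobic amino acids treated as hydrophobic.
#' @return list with:
#'   \item{total_sites}{sum of counts}
#'   \item{per_category}{data.frame category, count, percentage (2 dp)}
#'   \item{unchanged_percentage}{hydrophilic-hydrophilic plus
#'     hydrophobic-hydrophobic}
#'   \item{per_codon_position}{counts for pos1-only, pos2-only, pos3-only
#'     and dual (1+2) edits}
#'   \item{per_target_aa}{data.frame to_aa, count, percentage}
#'   \item{changes}{the input annotated with classification columns}
#' @export
summarizeEdits <- function(changes, hydrophobic = .HYDROPHOBIC_DEFAULT) {
  if (nrow(changes) == 0L)
    return(list(total_sites = 0L, per_category = NULL,
                unchanged_percentage = NA_real_,
                per_codon_position = NULL, per_target_aa = NULL,
                changes = changes))
  stopifnot(all(changes$count > 0))
  cls <- do.call(rbind, Map(classifyChange, changes$from_codon,
                            changes$to_codon,
                            MoreArgs = list(hydrophobic = hydrophobic)))
  cls$count <- changes$count
  total <- sum(cls$count)
  agg <- function(key) {
    cnt <- vapply(split(cls$count, cls[[key]]), sum, numeric(1))
    data.frame(key = names(cnt), count = unname(cnt),
               percentage = round(100 * unname(cnt) / total, 2))
  }
  per_cat <- agg("category"); names(per_cat)[1] <- "category"
  per_aa <- agg("to_aa"); names(per_aa)[1] <- "to_aa"
  pos_key <- ifelse(cls$positions_edited == "1", "pos1",
             ifelse(cls$positions_edited == "2", "pos2",
             ifelse(cls$positions_edited == "3", "pos3", "dual")))
  per_pos <- vapply(split(cls$count, pos_key), sum, numeric(1))
  unchanged <- sum(per_cat$percentage[per_cat$category %in%
    c("hydrophilic-hydrophilic", "hydrophobic-hydrophobic")])
  list(total_sites = total, per_category = per_cat,
       unchanged_percentage = unchanged,
       per_codon_position = per_pos, per_target_aa = per_aa,
       changes = cls)
}

#' Functional consequences of editing a CDS
#'
#' @param cds in-frame CDS (unedited).
#' @param sites edit sites as in [applyEdits()].
#' @return list with `premature_stop` (logical), `stop_codon_index`
#'   (first internal codon edited to a stop, or NA), and `start_created`
#'   (TRUE when codon 1 is ACG edited to ATG).
#' @export
detectFunctionalEffects <- function(cds, sites) {
  if (nchar(cds) %% 3L != 0L) stop("CDS not in frame")
  edited <- applyEdits(cds, sites)
  co0 <- .codons(cds); co1 <- .codons(edited)
  k <- length(co1)
  internal <- which(translateCodon(co1[-k]) == "X" &
                    translateCodon(co0[-k]) != "X")
  list(premature_stop = length(internal) > 0L,
       stop_codon_index = if (length(internal)) internal[1] else NA_integer_,
       start_created = co0[1] == "ACG" && co1[1] == "ATG")
}

#' Build edit sites from a per-gene site table and classify them on a CDS
#'
#' Convenience wrapper: given a CDS and its 1-based edit positions,
#' returns the per-codon changes with counts, ready for
#' [summarizeEdits()]. Dual edits within one codon are counted once as a
#' single codon change (positions 1+2).
#'
#' @param cds in-frame CDS.
#' @param sites integer CDS positions (reference base C).
#' @return data.frame `from_codon`, `to_codon`, `count`.
#' @export
codonChangesFromSites <- function(cds, sites) {
  if (is.data.frame(sites)) sites <- sites$cds_position
  sites <- as.integer(sites)
  if (length(sites) == 0L)
    return(data.frame(from_codon = character(0), to_codon = character(0),
                      count = integer(0)))
  codon_idx <- (sites - 1L) %/% 3L + 1L
  co <- .codons(toupper(cds))
  rows <- lapply(split(sites, codon_idx), function(ss) {
    ci <- (ss[1] - 1L) %/% 3L + 1L
    within <- ss - (ci - 1L) * 3L
    from <- co[ci]
    chars <- .chars(from)
    if (any(chars[within] != "C"))
      stop("edit site(s) not on C in codon ", ci)
    chars[within] <- "T"
    data.frame(from_codon = from, to_codon = paste(chars, collapse = ""))
  })
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(list(count = rep(1L, nrow(out))),
                          by = out[c("from_codon", "to_codon")], FUN = sum)
  agg
}
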