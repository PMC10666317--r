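#' Read genome records from a FASTA file
#'
#' Sequences are uppercased and validated against the IUPAC nucleotide
#' alphabet; a non-IUPAC character (e.g. "*") is a format error reported
#' with its record and position.
#'
#' @param path path to a FASTA file with at least one record.
#' @param circular logical, mark records as circular (default `FALSE`;
#'   organelle assemblies are typically read with `circular = TRUE`).
#' @return a list of [GenomeRecord-class] objects, in file order.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">x", "acgt"), tf)
#' readFasta(tf)[[1]]
#' @export
readFasta <- function(path, circular = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("not a readable FASTA file: ",
                                           path, " (", conditionMessage(e), ")"))
  if (length(set) == 0L) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i) {
    s <- toupper(as.character(set[[i]]))
    if (!nzchar(s))
      stop("FASTA format error: empty sequence for record '", ids[i], "'")
    bad <- regexpr(sprintf("[^%s]", paste(.IUPAC_CHARS, collapse = "")), s)
    if (bad > 0L)
      stop("FASTA format error: non-IUPAC character '",
           substr(s, bad, bad), "' in record '", ids[i],
           "' at sequence position ", bad)
    GenomeRecord(ids[i], chartr("U", "T", s), circular = circular)
  })
}

#' Write genome records to a FASTA file
#'
#' @param records a list of [GenomeRecord-class] objects, or a named
#'   character vector of sequences.
#' @param path output path.
#' @param width line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
  if (is.character(records)) {
    seqs <- Biostrings::DNAStringSet(records)
  } else {
    seqs <- Biostrings::DNAStringSet(vapply(records, genomeSeq, character(1)))
    names(seqs) <- vapply(records, genomeId, character(1))
  }
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Basic genome statistics
#'
#' GC content is computed over unambiguous bases only:
#' `100 * (G + C) / (A + C + G + T)`; N and ambiguity codes are excluded
#' from the denominator. An all-N sequence has undefined GC, reported as
#' `NA`.
#'
#' @param genome a [GenomeRecord-class].
#' @param genes optional list of [GeneModel-class]; if supplied, gene
#'   counts per category are tabulated (each copy of a multi-copy gene
#'   counts separately).
#' @return a list with elements `length`, `gc_percent` (rounded to 2
#'   decimals) and `gene_counts` (named integer vector, possibly empty).
#' @examples
#' genomeStats(GenomeRecord("g", "GGCC"))$gc_percent
#' @export
genomeStats <- function(genome, genes = list()) {
  stopifnot(is(genome, "GenomeRecord"))
  f <- Biostrings::alphabetFrequency(genome@sequence)
  acgt <- f[c("A", "C", "G", "T")]
  gc <- if (sum(acgt) == 0) NA_real_ else
    round(100 * sum(acgt[c("C", "G")]) / sum(acgt), 2)
  counts <- integer(0)
  if (length(genes)) {
    cats <- vapply(genes, function(g) g@category, character(1))
    copies <- vapply(genes, function(g) g@copyNumber, integer(1))
    counts <- vapply(split(copies, cats), sum, integer(1))
  }
  list(length = genomeLength(genome), gc_percent = gc, gene_counts = counts)
}

# resolve one exon interval on a (possibly circular) genome to a string
.exonSeq <- function(s, L, circular, start, end) {
  if (start < 1L || start > L)
    stop("coordinate error: exon start ", start, " outside genome [1,", L, "]")
  if (end < start) stop("coordinate error: exon end before start")
  if (end <= L) return(substr(s, start, end))
  if (!circular)
    stop("coordinate error: exon end ", end, " beyond linear genome end ", L)
  if (end - start + 1L > L)
    stop("coordinate error: exon longer than the genome")
  paste0(substr(s, start, L), substr(s, 1L, end - L))
}

#' Extract the CDS of a gene from a genome
#'
#' Exon sequences are concatenated in the order given and, for
#' minus-strand genes, reverse-complemented. On circular genomes an exon
#' whose end coordinate exceeds the genome length wraps across the origin.
#' Pseudogenes carry no coding contract; they are skipped with a message
#' and return `NA`.
#'
#' @param genome a [GenomeRecord-class].
#' @param gene a [GeneModel-class].
#' @return character scalar CDS (5' to 3'), or `NA_character_` for a
#'   pseudogene.
#' @export
extractCds <- function(genome, gene) {
  stopifnot(is(genome, "GenomeRecord"), is(gene, "GeneModel"))
  if (isPseudo(gene)) {
    message("skipping pseudogene '", geneName(gene), "' (no CDS contract)")
    return(NA_character_)
  }
  s <- genomeSeq(genome)
  L <- nchar(s)
  parts <- vapply(seq_along(gene@exons), function(i) {
    .exonSeq(s, L, isCircular(genome),
             IRanges::start(gene@exons)[i], IRanges::end(gene@exons)[i])
  }, character(1))
  cds <- paste(parts, collapse = "")
  if (gene@strand == "-") cds <- revComp(cds)
  cds
}

#' Protein length implied by a CDS
#'
#' The CDS must be in frame and include its terminal stop codon; the
#' returned length is `nchar(cds)/3 - 1` (terminal stop not counted). An
#' internal stop codon triggers a warning naming its codon position.
#'
#' @param cds character scalar, in-frame CDS ending in a stop codon.
#' @return integer number of amino acids.
#' @examples
#' proteinLength("ATGTAA")  # 1
#' @export
proteinLength <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("frame error: CDS length ", n, " not divisible by 3")
  cod <- .codons(cds)
  aa <- translateCodon(cod)
  k <- length(cod)
  if (aa[k] != "X")
    stop("CDS does not end in a stop codon (last codon ", cod[k], ")")
  internal <- which(aa[-k] == "X")
  if (length(internal))
    warning("internal stop codon at codon position ",
            paste(internal, collapse = ", "))
  k - 1L
}

#' Read a gene table (TSV dialect)
#'
#' Columns: `name`, `category`, `strand`, `exons` (semicolon-separated
#' `start-end` pairs, 1-based inclusive), `start_codon`, `stop_codon`,
#' `copies`, `pseudo` (0/1).
#'
#' @param path path to the TSV.
#' @return a list of [GeneModel-class] objects.
#' @export
readGeneTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "category", "strand", "exons", "start_codon",
            "stop_codon", "copies", "pseudo")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("gene table missing column(s): ",
                         paste(miss, collapse = ", "))
  lapply(seq_len(nrow(tab)), function(i) {
    iv <- do.call(rbind, lapply(strsplit(tab$exons[i], ";")[[1]],
                                function(p) as.integer(strsplit(p, "-")[[1]])))
    GeneModel(tab$name[i],
              IRanges::IRanges(start = iv[, 1], end = iv[, 2]),
              strand = tab$strand[i], category = tab$category[i],
              startCodon = tab$start_codon[i], stopCodon = tab$stop_codon[i],
              copyNumber = tab$copies[i], pseudo = as.logical(tab$pseudo[i]))
  })
}

#' Write gene models to the TSV gene-table dialect
#'
#' @param genes list of [GeneModel-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneTable <- function(genes, path) {
  rows <- lapply(genes, function(g) {
    data.frame(name = g@name, category = g@category, strand = g@strand,
               exons = paste(sprintf("%d-%d", IRanges::start(g@exons),
                                     IRanges::end(g@exons)), collapse = ";"),
               start_codon = g@startCodon, stop_codon = g@stopCodon,
               copies = g@copyNumber, pseudo = as.integer(g@pseudo))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
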