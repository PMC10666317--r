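#' @import methods
#' @importFrom stats median rgamma runif setNames
#' @importFrom utils head read.delim write.table
NULL

# data.table is used via :: ; opt in to its [ semantics
.datatable.aware <- TRUE

# IUPAC nucleotide alphabet accepted on input; internally sequences are
# over {A,C,G,T,N} (ambiguity codes are kept as-is but never generated).
.IUPAC_CHARS <- c("A", "C", "G", "T", "N", "R", "Y", "S", "W", "K", "M",
                  "B", "D", "H", "V", "U")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                 B = "V", D = "H", H = "D", V = "B", U = "A")

#' Reverse complement of a DNA character string
#'
#' @param x character scalar over the IUPAC alphabet.
#' @return character scalar, the reverse complement.
#' @examples
#' revComp("ACGT")
#' @export
revComp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(rev(unname(.COMPLEMENT[chars])), collapse = "")
}

# complement without reversal (used for the "complement" dispersed class)
.comp <- function(x) {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  paste(unname(.COMPLEMENT[chars]), collapse = "")
}

# reverse without complement (used for the "reverse" dispersed class)
.rev <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

.pkgCache <- new.env(parent = emptyenv())

# The standard genetic code keyed by DNA codon (T not U); cached.
.codonTable <- function() {
  if (is.null(.pkgCache$codon_table)) {
    gc <- Biostrings::GENETIC_CODE
    .pkgCache$codon_table <- setNames(ifelse(gc == "*", "X", gc),
                                      names(gc))
  }
  .pkgCache$codon_table
}

#' Translate one codon to a one-letter amino acid (stop as "X")
#'
#' Codons containing N or other ambiguity codes translate to "X" unless the
#' ambiguity is synonymous-irrelevant (not resolved here).
#'
#' @param codon character vector of 3-letter DNA codons.
#' @return character vector of one-letter amino acids; stop codons are "X".
#' @export
translateCodon <- function(codon) {
  tab <- .codonTable()
  codon <- toupper(codon)
  aa <- unname(tab[codon])
  aa[is.na(aa)] <- "X"
  aa
}

# draw n bases at a GC target; returns a character scalar
.randomDNA <- function(n, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# split a string into a character vector of single characters
.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# split an in-frame CDS string into codons
.codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3 (frame error)")
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}
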