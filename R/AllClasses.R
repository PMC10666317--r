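#' GenomeRecord: a (possibly circular) genome sequence
#'
#' Container for one genome sequence with an identifier and circularity
#' flag. Plant mitochondrial and plastid genomes are usually circular;
#' position arithmetic on circular records is taken modulo the length, so
#' features may span the origin.
#'
#' @slot id character scalar, sequence identifier.
#' @slot sequence a [Biostrings::DNAString] (uppercase).
#' @slot circular logical scalar.
#'
#' @seealso [readFasta()], [extractCds()], [genomeStats()]
#' @export
setClass("GenomeRecord",
  representation(id = "character", sequence = "DNAString",
                 circular = "logical"),
  validity = function(object) {
    msg <- NULL
    if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
      msg <- c(msg, "'id' must be a non-empty character scalar")
    if (length(object@circular) != 1L || is.na(object@circular))
      msg <- c(msg, "'circular' must be TRUE or FALSE")
    if (length(object@sequence) == 0L)
      msg <- c(msg, "'sequence' must be non-empty")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GenomeRecord
#'
#' @param id sequence identifier.
#' @param sequence character scalar or [Biostrings::DNAString]; uppercased.
#' @param circular logical, is the genome circular (default `TRUE`).
#' @return a [GenomeRecord-class] object.
#' @examples
#' g <- GenomeRecord("mt", "ACGTACGT", circular = TRUE)
#' genomeLength(g)
#' @export
GenomeRecord <- function(id, sequence, circular = TRUE) {
  if (is.character(sequence))
    sequence <- Biostrings::DNAString(toupper(sequence))
  new("GenomeRecord", id = id, sequence = sequence, circular = circular)
}

#' @describeIn GenomeRecord-class genome length in bases
#' @param x,object a `GenomeRecord`.
#' @export
genomeLength <- function(x) length(x@sequence)

#' @describeIn GenomeRecord-class sequence as a character scalar
#' @export
genomeSeq <- function(x) as.character(x@sequence)

#' @describeIn GenomeRecord-class record identifier
#' @export
genomeId <- function(x) x@id

#' @describeIn GenomeRecord-class circularity flag
#' @export
isCircular <- function(x) x@circular

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s': %d bp, %s\n", object@id,
              length(object@sequence),
              if (object@circular) "circular" else "linear"))
})

#' Rotate the origin of a circular genome
#'
#' Returns the same circular sequence with its origin moved to `offset + 1`
#' (the base previously at that position becomes position 1). Used to check
#' that feature detection is invariant under choice of origin.
#'
#' @param x a circular [GenomeRecord-class].
#' @param offset integer number of bases to rotate by (0 is a no-op).
#' @return a [GenomeRecord-class].
#' @export
rotateGenome <- function(x, offset) {
  stopifnot(is(x, "GenomeRecord"), isCircular(x))
  L <- genomeLength(x)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0) return(x)
  s <- genomeSeq(x)
  GenomeRecord(x@id, paste0(substr(s, offset + 1L, L), substr(s, 1L, offset)),
               circular = TRUE)
}

#' GeneModel: an annotated gene on a genome
#'
#' Describes one gene (or one copy of a multi-copy gene): its exon
#' intervals on the genome, strand, declared start/stop codons, functional
#' category and pseudogene status. Coordinates are 1-based inclusive; on a
#' circular genome an exon may run past the sequence end, in which case it
#' wraps across the origin.
#'
#' Exons are listed in genomic (plus-strand) order; for minus-strand genes
#' the extracted CDS is the reverse complement of the concatenated exons.
#'
#' @slot name gene name (e.g. "atp1").
#' @slot category functional category (e.g. "ATP synthase", "tRNA").
#' @slot strand "+" or "-".
#' @slot exons an [IRanges::IRanges] of exon intervals.
#' @slot startCodon declared start codon ("ATG", or an alternative such as
#'   "ACG"/"TTG" used by some plant mitochondrial genes).
#' @slot stopCodon declared stop codon.
#' @slot copyNumber integer >= 1.
#' @slot pseudo logical; pseudogenes carry no coding contract and are
#'   skipped by CDS-level operations.
#' @export
setClass("GeneModel",
  representation(name = "character", category = "character",
                 strand = "character", exons = "IRanges",
                 startCodon = "character", stopCodon = "character",
                 copyNumber = "integer", pseudo = "logical"),
  validity = function(object) {
    msg <- NULL
    if (!object@strand %in% c("+", "-"))
      msg <- c(msg, "'strand' must be '+' or '-'")
    if (length(object@exons) == 0L && !object@pseudo)
      msg <- c(msg, "non-pseudo gene must have at least one exon")
    if (length(object@exons) > 1L) {
      o <- IRanges::order(object@exons)
      ex <- object@exons[o]
      if (any(IRanges::start(ex)[-1L] <= IRanges::end(ex)[-length(ex)]))
        msg <- c(msg, "exons must be non-overlapping")
    }
    if (object@copyNumber < 1L)
      msg <- c(msg, "'copyNumber' must be >= 1")
    if (is.null(msg)) TRUE else msg
  })

#' Construct a GeneModel
#'
#' @param name gene name.
#' @param exons an [IRanges::IRanges] (or 2-column matrix of start,end) of
#'   exon intervals, 1-based inclusive, in genomic order.
#' @param strand "+" or "-".
#' @param category functional category label.
#' @param startCodon,stopCodon declared codons (default "ATG"/"TAA").
#' @param copyNumber integer, number of copies this model represents.
#' @param pseudo logical, pseudogene flag.
#' @return a [GeneModel-class].
#' @examples
#' GeneModel("atp9", IRanges::IRanges(101, 325), strand = "+",
#'           category = "ATP synthase", startCodon = "TTG")
#' @export
GeneModel <- function(name, exons, strand = "+", category = "unknown",
                      startCodon = "ATG", stopCodon = "TAA",
                      copyNumber = 1L, pseudo = FALSE) {
  if (is.matrix(exons))
    exons <- IRanges::IRanges(start = exons[, 1], end = exons[, 2])
  new("GeneModel", name = name, category = category, strand = strand,
      exons = exons, startCodon = startCodon, stopCodon = stopCodon,
      copyNumber = as.integer(copyNumber), pseudo = pseudo)
}

#' @describeIn GeneModel-class gene name
#' @param x,object a `GeneModel`.
#' @export
geneName <- function(x) x@name

#' @describeIn GeneModel-class exon intervals as an IRanges
#' @export
geneExons <- function(x) x@exons

#' @describeIn GeneModel-class number of introns (exons - 1)
#' @export
intronCount <- function(x) max(0L, length(x@exons) - 1L)

#' @describeIn GeneModel-class pseudogene flag
#' @export
isPseudo <- function(x) x@pseudo

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s' [%s] strand %s, %d exon(s), %d intron(s)%s\n",
              object@name, object@category, object@strand,
              length(object@exons), max(0L, length(object@exons) - 1L),
              if (object@pseudo) ", pseudogene" else ""))
})
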