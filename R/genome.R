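#' Load a reference genome from FASTA
#'
#' Reads a (small) reference genome into memory as an uppercase
#' \code{Biostrings::DNAStringSet}. An index side-car (\code{.fai}) is
#' permitted but not required.
#'
#' @param fasta_path Path to a FASTA file.
#' @return An object of class \code{genome_sequence}: a named list with the
#'   \code{DNAStringSet} and contig lengths.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("genome FASTA not found: ", fasta_path)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  # FASTA headers may carry descriptions after whitespace; contig name is
  # the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1L)
  obj <- list(seqs = seqs, lengths = stats::setNames(Biostrings::width(seqs), names(seqs)))
  class(obj) <- "genome_sequence"
  obj
}

#' Extract genomic sequence over a 0-based half-open interval
#'
#' @param genome A \code{genome_sequence} from [read_genome()].
#' @param contig Contig name.
#' @param start0 0-based inclusive start.
#' @param end0 0-based exclusive end.
#' @return Uppercase DNA string (character scalar).
#' @export
genome_subseq <- function(genome, contig, start0, end0) {
  stopifnot(inherits(genome, "genome_sequence"))
  if (!contig %in% names(genome$seqs)) stop("unknown contig: ", contig)
  len <- genome$lengths[[contig]]
  if (start0 < 0 || end0 > len || start0 > end0) {
    stop(sprintf("interval [%d, %d) outside contig %s bounds [0, %d)",
                 start0, end0, contig, len))
  }
  if (start0 == end0) return("")
  toupper(as.character(Biostrings::subseq(genome$seqs[[contig]], start0 + 1L, end0)))
}

#' Reverse complement a DNA string
#'
#' @param dna DNA character scalar (A/C/G/T/N).
#' @return Reverse complement, uppercase.
#' @export
revcomp <- function(dna) {
  if (nchar(dna) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(dna))))
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence with", length(x$seqs), "contig(s):\n")
  for (nm in names(x$lengths)) cat(sprintf("  %s: %d bp\n", nm, x$lengths[[nm]]))
  invisible(x)
}
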