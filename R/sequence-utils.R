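# Low-level sequence helpers shared across modules. Sequences are plain
# uppercase character strings in the user-facing API; Biostrings is used
# where it is the canonical tool (genetic codes, reverse complement).

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA sequences (IUPAC letters).
#' @return Character vector of reverse complements, uppercased.
#' @examples
#' revcomp("ATGCCC")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  nonempty <- nzchar(x)
  if (any(nonempty)) {
    out[nonempty] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x[nonempty])))
    )
  }
  out
}

#' Invertebrate mitochondrial (and other) genetic code tables
#'
#' Returns a named character vector mapping codons (DNA alphabet) to
#' one-letter amino acids, with `"*"` for stops. The default is NCBI
#' translation table 5, the invertebrate mitochondrial code, in which
#' ATA = Met, TGA = Trp and AGA/AGG = Ser.
#'
#' @param table Genetic code identifier passed to
#'   [Biostrings::getGeneticCode()] (default `"5"`).
#' @return Named character vector codon -> amino acid.
#' @export
mito_code <- function(table = "5") {
  code <- Biostrings::getGeneticCode(as.character(table))
  stats::setNames(as.character(code), names(code))
}

#' Sense (non-stop) codons of a genetic code
#' @inheritParams mito_code
#' @return Character vector of codons whose translation is not a stop.
#' @export
sense_codons <- function(table = "5") {
  code <- mito_code(table)
  names(code)[code != "*"]
}

#' Stop codons of a genetic code
#' @inheritParams mito_code
#' @return Character vector of stop codons.
#' @export
stop_codons <- function(table = "5") {
  code <- mito_code(table)
  names(code)[code == "*"]
}

# Split a sequence into single characters.
seq_chars <- function(seq) strsplit(toupper(seq), "", fixed = TRUE)[[1]]

# Translate a vector of codons under a code table.
translate_codons <- function(codons, table = "5") {
  unname(mito_code(table)[codons])
}

# 1-based inclusive substring, no wraparound.
seq_slice <- function(seq, start, end) substr(seq, start, end)

#' Read a FASTA file into a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning plain
#' uppercase strings, which is the representation used throughout the
#' package.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_seqs <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
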