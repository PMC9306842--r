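#' @importFrom ape read.FASTA write.FASTA as.DNAbin
NULL

IUPAC_DNA <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N", "-")

#' Construct an alignment object
#'
#' An alignment is stored as a named character vector of equal-length
#' upper-case sequences restricted to the IUPAC nucleotide alphabet plus
#' gap. Record order is meaningful and preserved by all operations.
#'
#' @param seqs named character vector of sequences.
#' @return an object of class `gmyc_alignment`.
#' @export
gmyc_alignment <- function(seqs) {
  if (length(seqs) == 0L)
    stop_gmyc("alignment has no records", class = "empty_input_error")
  nm <- names(seqs)
  if (is.null(nm) || any(!nzchar(nm)))
    stop_gmyc("all records must be named", class = "validation_error")
  if (anyDuplicated(nm))
    stop_gmyc("duplicate record names: ",
              paste(unique(nm[duplicated(nm)]), collapse = ", "),
              class = "validation_error")
  seqs <- toupper(seqs)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop_gmyc("sequences have unequal lengths (",
              paste(range(widths), collapse = "-"), ")",
              class = "alignment_error")
  if (widths[1] < 1L)
    stop_gmyc("alignment length must be >= 1", class = "alignment_error")
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 IUPAC_DNA)
  if (length(bad))
    stop_gmyc("non-IUPAC characters in alignment: ",
              paste(bad, collapse = " "), class = "alignment_error")
  structure(seqs, class = "gmyc_alignment")
}

#' @export
print.gmyc_alignment <- function(x, ...) {
  cat("Alignment:", length(x), "records x", nchar(x[[1]]), "columns\n")
  invisible(x)
}

#' @export
`[.gmyc_alignment` <- function(x, i) {
  structure(unclass(x)[i], class = "gmyc_alignment")
}

#' Number of alignment columns
#' @param aln a `gmyc_alignment`.
#' @return integer number of columns.
#' @export
alignment_length <- function(aln) nchar(unclass(aln)[[1]])

#' Read a FASTA alignment
#'
#' Sequence names are taken as the first whitespace-delimited token of the
#' description line, so that they can be matched against tree tip labels
#' produced by phylogenetics tools (which apply the same truncation).
#'
#' @param path path to a FASTA file.
#' @return a [gmyc_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path))
    stop_gmyc("no such file: ", path, class = "io_error")
  # ape warns (and returns NULL) on an empty file; we raise a typed error
  dna <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dna) || length(dna) == 0L)
    stop_gmyc("empty FASTA file: ", path, class = "empty_input_error")
  names(dna) <- sub("\\s.*$", "", names(dna))
  if (length(unique(lengths(dna))) != 1L)
    stop_gmyc("sequences have unequal lengths in ", path,
              class = "alignment_error")
  mat <- as.character(as.matrix(dna))
  seqs <- toupper(apply(mat, 1L, paste, collapse = ""))
  gmyc_alignment(seqs)
}

#' Write a FASTA alignment
#'
#' @param aln a [gmyc_alignment()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  dna <- ape::as.DNAbin(t(sapply(strsplit(tolower(unclass(aln)), ""),
                                 identity)))
  rownames(dna) <- names(aln)
  ape::write.FASTA(dna, path)
  invisible(path)
}
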