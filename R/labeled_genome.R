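#' Labeled genome: named DNA sequences tagged with a subgenome
#'
#' The basic sequence container of the package: a set of chromosome-scale DNA
#' sequences, each carrying a subgenome label (`"A"` or `"C"`). Labels default
#' to being inferred from the sequence names (leading `"A"`/`"C"` after an
#' optional `"chr"` prefix, as in `A01`, `chrC09`), matching common *Brassica*
#' chromosome naming; pass `subgenome` explicitly for arbitrary names.
#'
#' @param seqs Named character vector of DNA sequences (A/C/G/T/N).
#' @param subgenome Optional character vector of `"A"`/`"C"` labels, one per
#'   sequence (recycled names taken from `seqs`). If `NULL`, inferred from
#'   sequence names.
#' @return An object of class `labeled_genome`: a list with elements `seq`
#'   (named uppercase character vector) and `subgenome` (named label vector).
#' @examples
#' g <- labeled_genome(c(A01 = "ACGTACGT", C01 = "ACGAACGA"))
#' subgenome_labels(g)
#' @export
labeled_genome <- function(seqs, subgenome = NULL) {
  if (!is.character(seqs) || length(seqs) == 0L)
    stop("'seqs' must be a non-empty named character vector")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("every sequence must be named")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence names: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  bad <- grepl("[^ACGTNacgtn]", seqs)
  if (any(bad))
    stop("non-ACGTN characters in sequence '", names(seqs)[bad][1L], "'")
  seqs <- toupper(seqs)
  if (is.null(subgenome)) {
    subgenome <- infer_subgenome(names(seqs))
  } else {
    if (length(subgenome) != length(seqs))
      stop("'subgenome' must have one label per sequence")
    subgenome <- as.character(subgenome)
  }
  if (!all(subgenome %in% c("A", "C")))
    stop("subgenome labels must be \"A\" or \"C\"; offending sequence(s): ",
         paste(names(seqs)[!subgenome %in% c("A", "C")], collapse = ", "))
  names(subgenome) <- names(seqs)
  structure(list(seq = seqs, subgenome = subgenome), class = "labeled_genome")
}

#' Infer subgenome labels from sequence names
#'
#' @param x Character vector of sequence names.
#' @return Character vector of `"A"`/`"C"` (or `NA` where no label can be
#'   read).
#' @export
infer_subgenome <- function(x) {
  stripped <- sub("^chr", "", x, ignore.case = TRUE)
  lab <- toupper(substr(stripped, 1L, 1L))
  lab[!lab %in% c("A", "C")] <- NA_character_
  lab
}

#' @export
print.labeled_genome <- function(x, ...) {
  cat("labeled_genome:", length(x$seq), "sequence(s),",
      format(sum(nchar(x$seq)), big.mark = ","), "bp total\n")
  df <- data.frame(name = names(x$seq), subgenome = unname(x$subgenome),
                   length = unname(nchar(x$seq)))
  print(utils::head(df, 12L), row.names = FALSE)
  if (nrow(df) > 12L) cat("...", nrow(df) - 12L, "more\n")
  invisible(x)
}

#' @export
length.labeled_genome <- function(x) length(x$seq)

#' Sequence lengths of a labeled genome
#' @param genome A `labeled_genome`.
#' @return Named integer vector of sequence lengths in bp.
#' @export
seq_lengths <- function(genome) {
  stopifnot(inherits(genome, "labeled_genome"))
  vapply(genome$seq, nchar, integer(1L))
}

#' Subgenome labels of a labeled genome
#' @param genome A `labeled_genome`.
#' @return Named character vector of `"A"`/`"C"` labels.
#' @export
subgenome_labels <- function(genome) {
  stopifnot(inherits(genome, "labeled_genome"))
  genome$subgenome
}

#' Read a genome from FASTA
#'
#' @param path FASTA file.
#' @param subgenome Optional explicit labels (named by sequence, or one per
#'   sequence in file order); inferred from names when `NULL`.
#' @return A [labeled_genome()].
#' @export
read_genome_fasta <- function(path, subgenome = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- as.character(ss)
  # drop FASTA description beyond the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (!is.null(subgenome) && !is.null(names(subgenome)))
    subgenome <- unname(subgenome[names(seqs)])
  labeled_genome(seqs, subgenome = subgenome)
}

#' Write a genome to FASTA
#'
#' Deterministic output: the same genome always serializes to the same bytes.
#'
#' @param genome A `labeled_genome`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "labeled_genome"))
  ss <- Biostrings::DNAStringSet(genome$seq)
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  revcomp_vec(as.character(x))
}
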