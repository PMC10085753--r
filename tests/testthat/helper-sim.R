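# small scenario builders shared across test files

tiny_config <- function(seed = 42L, chrom_length = 100000L, n_chrom = 1L,
                        divergence = 0.05, depth = 8, error = 0) {
  sim_config(seed = seed, n_chrom_per_subgenome = n_chrom,
             chrom_length = chrom_length, homoeolog_divergence = divergence,
             depth = depth, read_error_rate = error)
}

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# a directly constructed read-alignments row (defaults: clean primary mate)
aln_row <- function(qname, rname, pos, mapq = 60L, nm = 0L, xa = NA_character_,
                    flag = 0x1 + 0x2 + 0x40, alen = 100L) {
  structure(data.frame(qname = qname, flag = as.integer(flag), rname = rname,
                       pos = as.integer(pos), mapq = as.integer(mapq),
                       cigar = sprintf("%dM", alen), nm = as.integer(nm),
                       xa = xa, alen = as.integer(alen),
                       stringsAsFactors = FALSE),
            class = c("read_alignments", "data.frame"))
}

aln_table <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("read_alignments", "data.frame")
  out
}

# hand-built coverage window table
window_table <- function(seq, start, raw, width = 100L, masked = NULL,
                         normalized = NULL) {
  df <- data.frame(seq = seq, start = as.integer(start),
                   end = as.integer(start + width), raw_median = raw,
                   stringsAsFactors = FALSE)
  if (!is.null(masked)) df$masked <- masked
  if (!is.null(normalized)) df$normalized <- normalized
  df
}
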