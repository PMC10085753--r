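#' Emulated short-read mapping with known origins
#'
#' Places every read of a simulated [read_set][simulate_reads()] onto a
#' target genome at its true coordinate and at the corresponding coordinate
#' on the homoeologous chromosome (coordinates are shared between homoeologs
#' in the substitution-only model), counts mismatches at both sites, and
#' reports the lower-mismatch site as the primary alignment with the other
#' as an XA-style alternate. The mapping quality reflects how well the two
#' sites are separated (`min(60, 6 * |NM difference|)`, 0 on a tie), which
#' reproduces the behaviour the coverage analysis depends on: reads spanning
#' homoeolog-diagnostic positions map confidently, reads from fully
#' conserved stretches are ambiguous. Mates landing on different
#' chromosomes lose the properly-paired flag.
#'
#' @param reads A [simulate_reads()] result.
#' @param target A [labeled_genome()] whose sequence names match the
#'   haplotype chromosome names (e.g. the ancestral genome or an assembly).
#' @param homology Homology map data frame (`a_chrom`, `c_chrom`) pairing
#'   homoeologous chromosomes, e.g. the `homology` element of an
#'   `ancestral_pair` or `tetraploid_individual`.
#' @return A `read_alignments` data frame: one row per mate with `qname`,
#'   `flag`, `rname`, `pos` (0-based), `mapq`, `cigar`, `nm`, `xa`
#'   (XA-style string or `NA`), `alen` (aligned length).
#' @export
map_reads <- function(reads, target, homology) {
  stopifnot(inherits(reads, "read_set"), inherits(target, "labeled_genome"))
  partner <- c(setNames(homology$c_chrom, homology$a_chrom),
               setNames(homology$a_chrom, homology$c_chrom))
  tr <- reads$truth
  rl <- reads$read_length
  n <- nrow(tr)

  res <- vector("list", 2L)
  for (m in 1:2) {
    seqs <- if (m == 1L) reads$read1 else revcomp(reads$read2)
    pos <- if (m == 1L) tr$frag_start else tr$frag_end - rl
    self_chr <- tr$chrom
    alt_chr <- unname(partner[self_chr])

    nm_self <- integer(n)
    nm_alt <- rep(rl + 1L, n)  # no homoeologous site -> effectively unmappable there
    for (chr in unique(self_chr)) {
      if (!chr %in% names(target$seq))
        stop("read origin chromosome '", chr, "' absent from target genome")
      i <- which(self_chr == chr)
      nm_self[i] <- count_mismatches(target$seq[[chr]], pos[i], seqs[i])
    }
    for (chr in unique(alt_chr[!is.na(alt_chr)])) {
      if (!chr %in% names(target$seq)) next
      i <- which(!is.na(alt_chr) & alt_chr == chr)
      nm_alt[i] <- count_mismatches(target$seq[[chr]], pos[i], seqs[i])
    }

    # primary = fewer mismatches; tie broken to the lexicographically
    # smaller chromosome name (deterministic), with MAPQ 0
    alt_wins <- nm_alt < nm_self | (nm_alt == nm_self & alt_chr < self_chr)
    rname <- ifelse(alt_wins, alt_chr, self_chr)
    oname <- ifelse(alt_wins, self_chr, alt_chr)
    nm1 <- ifelse(alt_wins, nm_alt, nm_self)
    nm2 <- ifelse(alt_wins, nm_self, nm_alt)
    mapq <- ifelse(nm2 == nm1, 0L, pmin(60L, 6L * (nm2 - nm1)))
    strand_char <- if (m == 1L) "+" else "-"
    xa <- ifelse(is.na(oname) | nm2 > rl, NA_character_,
                 sprintf("%s,%s%d,%dM,%d;", oname, strand_char, pos + 1L,
                         rl, nm2))

    res[[m]] <- data.frame(qname = tr$id, mate = m, rname = rname, pos = pos,
                           mapq = as.integer(mapq), nm = as.integer(nm1),
                           xa = xa, stringsAsFactors = FALSE)
  }
  proper <- res[[1L]]$rname == res[[2L]]$rname
  for (m in 1:2) {
    base <- 0x1 + ifelse(proper, 0x2, 0L)
    res[[m]]$flag <- as.integer(base +
      (if (m == 1L) 0x20 + 0x40 else 0x10 + 0x80))
  }
  aln <- rbind(res[[1L]], res[[2L]])
  aln$mate <- NULL
  aln$cigar <- sprintf("%dM", rl)
  aln$alen <- rl
  aln <- aln[, c("qname", "flag", "rname", "pos", "mapq", "cigar", "nm",
                 "xa", "alen")]
  class(aln) <- c("read_alignments", "data.frame")
  aln
}

#' Write read alignments as SAM
#'
#' Emits a minimal valid SAM: `@HD`/`@SQ` header, per-record FLAG, RNAME,
#' 1-based POS, MAPQ, CIGAR, and the `NM:i` and `XA:Z` tags the coverage
#' analysis consumes. SEQ/QUAL are written as `*` unless `include_seq` is a
#' function returning sequences (kept lean: downstream stages never read
#' them).
#'
#' @param aln A `read_alignments` data frame.
#' @param seq_lengths Named vector of reference sequence lengths.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, seq_lengths, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                       as.integer(seq_lengths))), con)
  xa_tag <- ifelse(is.na(aln$xa) | !nzchar(aln$xa), "",
                   paste0("\tXA:Z:", aln$xa))
  writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*\tNM:i:%d%s",
                     aln$qname, aln$flag, aln$rname, aln$pos + 1L, aln$mapq,
                     aln$cigar, aln$nm, xa_tag), con)
  invisible(path)
}

#' Read a SAM file into a read-alignments table
#'
#' Parses the columns the coverage analysis needs (QNAME, FLAG, RNAME, POS,
#' MAPQ, CIGAR) plus the `NM:i` and `XA:Z` tags. The aligned reference
#' length is derived from the CIGAR (M/D/N/=/X operations). Unmapped records
#' (FLAG 0x4 or RNAME `*`) are dropped.
#'
#' @param path SAM path.
#' @return A `read_alignments` data frame (0-based `pos`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) {
    out <- data.frame(qname = character(), flag = integer(),
                      rname = character(), pos = integer(), mapq = integer(),
                      cigar = character(), nm = integer(), xa = character(),
                      alen = integer(), stringsAsFactors = FALSE)
    class(out) <- c("read_alignments", "data.frame")
    return(out)
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(f) < 11L)
  if (length(short))
    stop("malformed SAM record at line ", short[1L],
         ": fewer than 11 fields")
  get <- function(j) vapply(f, `[`, character(1L), j)
  tagval <- function(prefix) vapply(f, function(x) {
    hit <- x[startsWith(x, prefix)]
    if (length(hit)) substring(hit[1L], nchar(prefix) + 1L) else NA_character_
  }, character(1L))
  flag <- as.integer(get(2L))
  mapq <- suppressWarnings(as.integer(get(5L)))
  if (anyNA(flag) || anyNA(mapq))
    stop("SAM stream without usable FLAG/MAPQ fields")
  out <- data.frame(qname = get(1L), flag = flag, rname = get(3L),
                    pos = as.integer(get(4L)) - 1L, mapq = mapq,
                    cigar = get(6L),
                    nm = suppressWarnings(as.integer(tagval("NM:i:"))),
                    xa = tagval("XA:Z:"), stringsAsFactors = FALSE)
  out <- out[!bitwAnd(out$flag, 0x4) & out$rname != "*", , drop = FALSE]
  out$alen <- cigar_ref_length(out$cigar)
  row.names(out) <- NULL
  class(out) <- c("read_alignments", "data.frame")
  out
}

# reference-consuming length of a CIGAR string (M/D/N/=/X)
cigar_ref_length <- function(cigar) {
  vapply(regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar)), function(ops) {
    if (length(ops) == 0L || identical(ops, "*")) return(0L)
    n <- as.integer(sub("[MIDNSHP=X]$", "", ops))
    op <- substring(ops, nchar(ops), nchar(ops))
    sum(n[op %in% c("M", "D", "N", "=", "X")])
  }, integer(1L))
}

# SAM flag helpers
flag_properly_paired <- function(flag) bitwAnd(flag, 0x2) > 0L
flag_secondary <- function(flag) bitwAnd(flag, 0x100) > 0L
flag_supplementary <- function(flag) bitwAnd(flag, 0x800) > 0L
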