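#' Homoeologous-exchange region set of one genome
#'
#' The per-genome unit of cross-variety comparison: a merged, disjoint set
#' of intervals on the shared ancestral coordinate system, with the total
#' affected base count and the proportion of the ancestral genome involved.
#'
#' @param genome_name Identifier of the genome/variety.
#' @param intervals Data frame with `seq`, `start`, `end` (0-based
#'   half-open) or a `GRanges`.
#' @param seqlengths Named vector of ancestral sequence lengths.
#' @return Object of class `he_set`: list with `genome_name`, `regions`
#'   (reduced `GRanges`), `total_bp`, `proportion`.
#' @export
he_set <- function(genome_name, intervals, seqlengths) {
  if (is.null(names(seqlengths)) || any(!nzchar(names(seqlengths))))
    stop("'seqlengths' must be named")
  if (methods::is(intervals, "GRanges")) {
    gr <- intervals
  } else if (nrow(intervals) == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    if (!all(intervals$seq %in% names(seqlengths)))
      stop("interval on sequence absent from 'seqlengths': ",
           paste(setdiff(unique(intervals$seq), names(seqlengths)),
                 collapse = ", "))
    gr <- GenomicRanges::GRanges(intervals$seq,
                                 IRanges::IRanges(intervals$start + 1L,
                                                  intervals$end))
  }
  GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
  GenomeInfoDb::seqlengths(gr) <- as.integer(seqlengths)
  gr <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  total <- sum(IRanges::width(gr))
  structure(list(genome_name = genome_name, regions = gr,
                 total_bp = as.numeric(total),
                 proportion = as.numeric(total) / sum(as.numeric(seqlengths))),
            class = "he_set")
}

#' @export
print.he_set <- function(x, ...) {
  cat(sprintf("he_set '%s': %d region(s), %s bp (proportion %.4g)\n",
              x$genome_name, length(x$regions),
              format(x$total_bp, big.mark = ","), x$proportion))
  invisible(x)
}

#' Project called HE regions onto the ancestral coordinate system
#'
#' Union-merges the ancestral-axis intervals of a genome's HE regions into a
#' disjoint [he_set()] — the shared frame in which varieties are compared.
#'
#' @param regions HE region data frame (with `ancestral_seq`,
#'   `ancestral_start`, `ancestral_end`).
#' @param genome_name Genome identifier.
#' @param seqlengths Named ancestral sequence lengths.
#' @return An [he_set()].
#' @export
project_to_ancestral <- function(regions, genome_name, seqlengths) {
  iv <- if (nrow(regions) == 0L)
    data.frame(seq = character(), start = integer(), end = integer())
  else
    data.frame(seq = regions$ancestral_seq, start = regions$ancestral_start,
               end = regions$ancestral_end, stringsAsFactors = FALSE)
  he_set(genome_name, iv, seqlengths)
}

check_same_frame <- function(sets) {
  if (length(sets) < 2L) stop("at least two HE sets are required")
  ref <- GenomeInfoDb::seqlengths(sets[[1L]]$regions)
  for (s in sets[-1L]) {
    sl <- GenomeInfoDb::seqlengths(s$regions)
    if (!identical(names(sl), names(ref)) || !identical(unname(sl), unname(ref)))
      stop("HE sets are on different ancestral coordinate systems")
  }
  invisible(ref)
}

#' Base-level intersection across all genomes
#'
#' Computes the bp-level k-way intersection of the HE sets; maximal
#' contiguous shared runs are counted as regions.
#'
#' @param sets List of [he_set()]s on the same ancestral genome.
#' @return List with `regions` (`GRanges`), `n_regions`, `total_bp`.
#' @export
intersect_all <- function(sets) {
  check_same_frame(sets)
  shared <- Reduce(function(x, y) GenomicRanges::intersect(x, y),
                   lapply(sets, `[[`, "regions"))
  shared <- GenomicRanges::reduce(shared)
  list(regions = shared, n_regions = length(shared),
       total_bp = as.numeric(sum(IRanges::width(shared))))
}

#' Pairwise minimum-normalized sharing matrix
#'
#' Entry (i, j) is the shared base count of genomes i and j divided by the
#' smaller of their two HE totals, so a set nested inside another scores 1.
#' Entries involving a genome with no HE at all are undefined (`NA`).
#'
#' @param sets List of [he_set()]s on the same ancestral genome.
#' @return Symmetric k x k matrix of fractions with unit diagonal.
#' @export
pairwise_sharing_matrix <- function(sets) {
  check_same_frame(sets)
  k <- length(sets)
  nm <- vapply(sets, `[[`, character(1L), "genome_name")
  tot <- vapply(sets, `[[`, numeric(1L), "total_bp")
  m <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    if (tot[i] > 0) m[i, i] <- 1
    for (j in seq_len(k)) {
      if (j <= i) next
      if (tot[i] == 0 || tot[j] == 0) next
      shared <- sum(IRanges::width(
        GenomicRanges::intersect(sets[[i]]$regions, sets[[j]]$regions)))
      m[i, j] <- m[j, i] <- shared / min(tot[i], tot[j])
    }
  }
  m
}

#' Expected shared bases under the independence null
#'
#' Null model for k-way sharing: if each genome's exchanged territory were
#' placed independently and uniformly, the chance that one base is
#' exchanged in every genome is the product of the per-genome proportions,
#' so the expected shared total is `ancestral_length * prod(proportions)`.
#'
#' @param proportions Per-genome HE proportions, each in \[0, 1\].
#' @param ancestral_length Ancestral genome length in bp.
#' @return Expected number of shared bases (real, typically fractional).
#' @export
expected_shared_bp <- function(proportions, ancestral_length) {
  proportions <- as.numeric(proportions)
  if (any(!is.finite(proportions)) || any(proportions < 0) ||
      any(proportions > 1))
    stop("proportions must lie in [0, 1]")
  if (ancestral_length <= 0) stop("ancestral_length must be positive")
  ancestral_length * prod(proportions)
}

#' Write an HE set (or shared regions) as BED
#' @param x An [he_set()] or a `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_he_set_bed <- function(x, path) {
  gr <- if (inherits(x, "he_set")) x$regions else x
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# hexfinder HE set (BED, ancestral coordinates)", con)
  if (length(gr))
    writeLines(sprintf("%s\t%d\t%d",
                       as.character(GenomeInfoDb::seqnames(gr)),
                       GenomicRanges::start(gr) - 1L,
                       GenomicRanges::end(gr)), con)
  invisible(path)
}

#' Read an HE set from a BED file
#' @param path BED path (3+ columns, 0-based half-open).
#' @param genome_name Genome identifier.
#' @param seqlengths Named ancestral sequence lengths.
#' @return An [he_set()].
#' @export
read_he_set_bed <- function(path, genome_name, seqlengths) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (!length(lines))
    return(he_set(genome_name,
                  data.frame(seq = character(), start = integer(),
                             end = integer()), seqlengths))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 3L)
  if (length(bad)) stop("malformed BED line ", bad[1L], " in ", path)
  he_set(genome_name,
         data.frame(seq = vapply(f, `[`, character(1L), 1L),
                    start = as.integer(vapply(f, `[`, character(1L), 2L)),
                    end = as.integer(vapply(f, `[`, character(1L), 3L)),
                    stringsAsFactors = FALSE),
         seqlengths)
}

#' Read sequence lengths from a FASTA index (fai)
#' @param path `.fai` path (as produced by `samtools faidx`).
#' @return Named numeric vector of sequence lengths.
#' @export
read_fai <- function(path) {
  t <- read.table(path, sep = "\t", stringsAsFactors = FALSE)
  setNames(as.numeric(t[[2L]]), t[[1L]])
}
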