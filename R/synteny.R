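#' Build the in silico ancestral genome
#'
#' Concatenates the two diploid parent genomes into one reference, the frame
#' used for subgenome assignment: every sequence keeps its content and
#' carries its source subgenome label.
#'
#' @param a_parent,c_parent [labeled_genome()]s for the A and C parents
#'   (both required, non-empty).
#' @return A [labeled_genome()] holding all sequences of both parents.
#' @export
build_ancestral <- function(a_parent, c_parent) {
  stopifnot(inherits(a_parent, "labeled_genome"),
            inherits(c_parent, "labeled_genome"))
  if (length(a_parent$seq) == 0L || length(c_parent$seq) == 0L)
    stop("both subgenome parents are required and must be non-empty")
  clash <- intersect(names(a_parent$seq), names(c_parent$seq))
  if (length(clash))
    stop("sequence name collision between parents: ",
         paste(clash, collapse = ", "))
  labeled_genome(c(a_parent$seq, c_parent$seq),
                 subgenome = c(a_parent$subgenome, c_parent$subgenome))
}

#' Find trusted syntenic regions between the two parent genomes
#'
#' Aligns the A parent to the C parent, keeps the one best alignment per
#' region, and retains blocks with identity above `min_identity` and length
#' above `min_length` (strict inequalities). These blocks delimit the
#' reliably homoeologous territory in which exchange calls are accepted.
#'
#' @param a_parent,c_parent [labeled_genome()]s.
#' @param params [align_params()] for the underlying alignment.
#' @param min_identity Identity threshold (exclusive), default 0.85.
#' @param min_length Length threshold in bp (exclusive), default 1000.
#' @return Data frame of trusted regions with the block on both coordinate
#'   systems: `a_chrom`, `a_start`, `a_end`, `c_chrom`, `c_start`, `c_end`,
#'   `identity` (0-based half-open).
#' @export
find_trusted_regions <- function(a_parent, c_parent,
                                 params = align_params(),
                                 min_identity = 0.85, min_length = 1000L) {
  rec <- best_hit_filter(align_genomes(a_parent, c_parent, params))
  rec <- rec[rec$identity > min_identity & rec$block_length > min_length, ,
             drop = FALSE]
  data.frame(a_chrom = rec$query_name, a_start = rec$query_start,
             a_end = rec$query_end, c_chrom = rec$target_name,
             c_start = rec$target_start, c_end = rec$target_end,
             identity = rec$identity, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Call candidate homoeologous exchange regions
#'
#' Aligns an assembly to the ancestral genome, keeps the one best alignment
#' per region, and reports every block whose assembly-side subgenome label
#' differs from its ancestral-side label — sequence sitting on an A
#' chromosome whose best hit is a C region of the ancestral genome, or vice
#' versa. Concordant blocks are discarded.
#'
#' @param assembly [labeled_genome()] of the allotetraploid assembly; every
#'   sequence must carry a subgenome label.
#' @param ancestral [labeled_genome()] from [build_ancestral()].
#' @param params [align_params()].
#' @param overlap_tol Query-axis overlap tolerated between retained best
#'   hits, bp. Alignment chains routinely run a handful of conserved bases
#'   past an exchange junction; a strict zero tolerance would let the
#'   flanking chain displace the whole exchanged-segment alignment over a
#'   ~10 bp overlap.
#' @return Data frame of candidate HE regions: `assembly_seq`,
#'   `assembly_start`, `assembly_end`, `assembly_subgenome`,
#'   `ancestral_seq`, `ancestral_start`, `ancestral_end`,
#'   `ancestral_subgenome`, `strand`, `identity`, `length` (assembly-axis
#'   span), `passed_trusted` (`NA` until filtered).
#' @export
call_candidate_he <- function(assembly, ancestral, params = align_params(),
                              overlap_tol = 200L) {
  stopifnot(inherits(assembly, "labeled_genome"),
            inherits(ancestral, "labeled_genome"))
  if (anyNA(assembly$subgenome))
    stop("unlabeled assembly sequence: ",
         paste(names(assembly$seq)[is.na(assembly$subgenome)], collapse = ", "))
  # query-axis best hits: every assembly position keeps its single highest
  # hit, while an ancestral region may serve both its own chromosome and an
  # exchanged segment (a 1-to-1 filter would let the donor chromosome's
  # self-alignment displace every exchanged segment's alignment)
  rec <- best_hit_filter(align_genomes(assembly, ancestral, params),
                         axis = "query", overlap_tol = overlap_tol)
  asm_lab <- assembly$subgenome[rec$query_name]
  anc_lab <- ancestral$subgenome[rec$target_name]
  rec <- rec[asm_lab != anc_lab, , drop = FALSE]
  out <- data.frame(assembly_seq = rec$query_name,
                    assembly_start = rec$query_start,
                    assembly_end = rec$query_end,
                    assembly_subgenome = unname(assembly$subgenome[rec$query_name]),
                    ancestral_seq = rec$target_name,
                    ancestral_start = rec$target_start,
                    ancestral_end = rec$target_end,
                    ancestral_subgenome = unname(ancestral$subgenome[rec$target_name]),
                    strand = rec$strand,
                    identity = rec$identity,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$length <- out$assembly_end - out$assembly_start
  out$passed_trusted <- rep(NA, nrow(out))
  out
}

#' Filter candidate HE regions
#'
#' Retains candidates with identity above `min_identity`, assembly-axis
#' length above `min_length` (both strict), and at least one base of overlap
#' on the ancestral axis with a trusted syntenic region — the guard against
#' false positives caused by assembly gaps in the parents.
#'
#' @param candidates [call_candidate_he()] output.
#' @param trusted [find_trusted_regions()] output.
#' @param min_identity Identity threshold (exclusive), default 0.90.
#' @param min_length Length threshold in bp (exclusive), default 100.
#' @return The retained subset with `passed_trusted = TRUE`.
#' @export
filter_candidates <- function(candidates, trusted,
                              min_identity = 0.90, min_length = 100L) {
  if (nrow(candidates) == 0L) return(candidates)
  cand_gr <- GenomicRanges::GRanges(candidates$ancestral_seq,
                                    IRanges::IRanges(candidates$ancestral_start + 1L,
                                                     candidates$ancestral_end))
  # a trusted block occupies territory on both parents' coordinate systems
  tr_gr <- GenomicRanges::GRanges(
    c(trusted$a_chrom, trusted$c_chrom),
    IRanges::IRanges(c(trusted$a_start, trusted$c_start) + 1L,
                     c(trusted$a_end, trusted$c_end)))
  hit <- IRanges::overlapsAny(cand_gr, tr_gr, minoverlap = 1L)
  keep <- candidates$identity > min_identity &
    candidates$length > min_length & hit
  out <- candidates[keep, , drop = FALSE]
  out$passed_trusted <- rep(TRUE, nrow(out))
  row.names(out) <- NULL
  out
}

#' Merge nearby HE regions of the same direction
#'
#' Regions on the same assembly sequence with the same donor/recipient
#' direction whose assembly intervals lie within `max_gap` of each other are
#' merged; the merged identity is the length-weighted mean and the ancestral
#' interval is the enclosing span (regions hitting different ancestral
#' sequences are never merged). Idempotent.
#'
#' @param regions Filtered HE region data frame.
#' @param max_gap Maximum gap bridged, bp (default 5000).
#' @return Merged, sorted HE region data frame.
#' @export
merge_he_regions <- function(regions, max_gap = 5000L) {
  if (nrow(regions) == 0L) return(regions)
  key <- paste(regions$assembly_seq, regions$ancestral_seq,
               regions$assembly_subgenome, regions$ancestral_subgenome,
               sep = "\r")
  pieces <- lapply(split(seq_len(nrow(regions)), key), function(idx) {
    r <- regions[idx[order(regions$assembly_start[idx])], , drop = FALSE]
    grp <- cumsum(c(TRUE, r$assembly_start[-1L] - r$assembly_end[-nrow(r)] > max_gap))
    do.call(rbind, lapply(split(seq_len(nrow(r)), grp), function(g) {
      s <- r[g, , drop = FALSE]
      out <- s[1L, , drop = FALSE]
      out$assembly_start <- min(s$assembly_start)
      out$assembly_end <- max(s$assembly_end)
      out$ancestral_start <- min(s$ancestral_start)
      out$ancestral_end <- max(s$ancestral_end)
      out$identity <- sum(s$identity * s$length) / sum(s$length)
      out$length <- out$assembly_end - out$assembly_start
      out$strand <- if (length(unique(s$strand)) == 1L) s$strand[1L] else "."
      out
    }))
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$assembly_seq, out$assembly_start), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' One-call synteny-based HE detection
#'
#' Convenience wrapper running the full synteny branch: trusted regions from
#' the parents, candidate calling of the assembly against the ancestral
#' genome, the identity/length/trusted-overlap filters, and merging.
#'
#' @param assembly Assembly [labeled_genome()].
#' @param a_parent,c_parent Parent [labeled_genome()]s.
#' @param params [align_params()].
#' @param trusted_min_identity,trusted_min_length Trusted-region thresholds.
#' @param min_identity,min_length Candidate thresholds.
#' @param merge_gap Merge distance in bp.
#' @return List with `trusted`, `candidates`, `regions` (filtered + merged).
#' @export
call_he <- function(assembly, a_parent, c_parent, params = align_params(),
                    trusted_min_identity = 0.85, trusted_min_length = 1000L,
                    min_identity = 0.90, min_length = 100L,
                    merge_gap = 5000L) {
  trusted <- find_trusted_regions(a_parent, c_parent, params,
                                  trusted_min_identity, trusted_min_length)
  ancestral <- build_ancestral(a_parent, c_parent)
  cand <- call_candidate_he(assembly, ancestral, params)
  kept <- filter_candidates(cand, trusted, min_identity, min_length)
  list(trusted = trusted, candidates = cand,
       regions = merge_he_regions(kept, merge_gap))
}

#' Write HE regions as BED6 (assembly coordinates)
#'
#' `name` encodes direction as `<donor>><recipient>` (donor = ancestral-side
#' subgenome), score = round(1000 * identity).
#'
#' @param regions HE region data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_he_bed <- function(regions, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# hexfinder homoeologous-exchange regions (BED6, assembly coordinates)",
             con)
  if (nrow(regions))
    writeLines(sprintf("%s\t%d\t%d\t%s>%s\t%d\t%s",
                       regions$assembly_seq, regions$assembly_start,
                       regions$assembly_end, regions$ancestral_subgenome,
                       regions$assembly_subgenome,
                       round(1000 * regions$identity), regions$strand), con)
  invisible(path)
}

#' Write HE regions with all fields as TSV
#' @param regions HE region data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_he_tsv <- function(regions, path) {
  write.table(regions, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an HE region TSV written by [write_he_tsv()]
#' @param path TSV path.
#' @return HE region data frame.
#' @export
read_he_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Base-level accuracy of HE calls against a truth set
#'
#' Compares called regions with planted-event truth intervals by bp-weighted
#' interval intersection on the assembly axis: sensitivity is the fraction
#' of truth bases covered by calls, precision the fraction of called bases
#' that are true.
#'
#' @param regions Called HE region data frame (assembly coordinates).
#' @param truth Truth data frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. the `truth` element of a planted individual or
#'   [read_truth_bed()] output.
#' @return List with `sensitivity`, `precision`, `truth_bp`, `called_bp`,
#'   `shared_bp`.
#' @export
evaluate_he_calls <- function(regions, truth) {
  to_gr <- function(seqs, s, e)
    GenomicRanges::reduce(GenomicRanges::GRanges(seqs,
                                                 IRanges::IRanges(s + 1L, e)))
  tr <- to_gr(truth$chrom, truth$start, truth$end)
  if (nrow(regions)) {
    ca <- to_gr(regions$assembly_seq, regions$assembly_start,
                regions$assembly_end)
    shared <- sum(IRanges::width(GenomicRanges::intersect(ca, tr)))
    called_bp <- sum(IRanges::width(ca))
  } else {
    shared <- 0L
    called_bp <- 0L
  }
  truth_bp <- sum(IRanges::width(tr))
  list(sensitivity = if (truth_bp > 0) shared / truth_bp else NA_real_,
       precision = if (called_bp > 0) shared / called_bp else NA_real_,
       truth_bp = truth_bp, called_bp = called_bp, shared_bp = shared)
}
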