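#' Select subgenome-diagnostic reads
#'
#' From alignments against the ancestral genome, keeps the reads that can be
#' attributed reliably to one subgenome: every primary alignment of the read
#' has mapping quality at or above `min_mapq` (inclusive, default 5) and the
#' properly-paired flag set, and the read has no supplementary alignment
#' anywhere in the stream. Secondary records are ignored for the quality
#' test but do not disqualify a read.
#'
#' @param aln A `read_alignments` data frame (e.g. [map_reads()] or
#'   [read_sam()] output) of alignments to the ancestral genome.
#' @param min_mapq Minimum mapping quality, inclusive.
#' @return Character vector of retained read ids (QNAMEs).
#' @export
select_diagnostic_reads <- function(aln, min_mapq = 5L) {
  if (!all(c("qname", "flag", "mapq") %in% names(aln)))
    stop("alignment stream without qname/flag/mapq fields")
  if (nrow(aln) == 0L) return(character())
  if (anyNA(aln$flag) || anyNA(aln$mapq))
    stop("alignment stream without usable FLAG/MAPQ fields")
  supp <- flag_supplementary(aln$flag)
  primary <- !flag_secondary(aln$flag) & !supp
  ok <- aln$mapq >= min_mapq & flag_properly_paired(aln$flag)

  with_primary <- unique(aln$qname[primary])
  disqualified <- unique(aln$qname[supp | (primary & !ok)])
  sort(setdiff(with_primary, disqualified))
}

#' Accumulate per-base read depth with alternate hits
#'
#' Each primary alignment of a diagnostic read adds one over its reference
#' interval. Each XA-style alternate site whose edit distance is equal to or
#' less than the primary alignment's edit distance also adds one, over an
#' interval of the read's aligned length at the alternate position;
#' higher-edit-distance alternates are ignored. Alternates naming unknown
#' sequences are skipped with a warning and counted in the `qc` attribute.
#'
#' @param aln A `read_alignments` data frame of alignments to the genome
#'   under analysis.
#' @param diagnostic Character vector of read ids to count (from
#'   [select_diagnostic_reads()]); `NULL` counts all reads.
#' @param seq_lengths Named vector of reference sequence lengths.
#' @return Named list of per-base integer depth vectors, with attribute
#'   `qc` = number of skipped alternate sites.
#' @export
accumulate_depth <- function(aln, diagnostic = NULL, seq_lengths) {
  primary <- !flag_secondary(aln$flag) & !flag_supplementary(aln$flag)
  use <- primary
  if (!is.null(diagnostic)) use <- use & aln$qname %in% diagnostic
  a <- aln[use, , drop = FALSE]

  starts <- a$pos
  ends <- pmin(a$pos + a$alen, unname(seq_lengths[a$rname]))
  seqs <- a$rname
  skipped <- 0L

  # alternate sites with NM <= primary NM join the pileup; the common
  # single-entry case is pre-screened on its edit distance before any
  # field-level parsing (most alternates fail the test and never get split)
  has_xa <- !is.na(a$xa) & nzchar(a$xa)
  single <- has_xa & !grepl(";.", a$xa)
  if (any(single)) {
    alt_nm_fast <- suppressWarnings(
      as.integer(sub("^.*,([0-9]+);?$", "\\1", a$xa[single])))
    drop <- which(single)[!is.na(alt_nm_fast) & alt_nm_fast > a$nm[single]]
    has_xa[drop] <- FALSE
  }
  if (any(has_xa)) {
    xi <- which(has_xa)
    parts <- strsplit(a$xa[xi], ";", fixed = TRUE)
    rep_i <- rep(xi, lengths(parts))
    fields <- strsplit(unlist(parts), ",", fixed = TRUE)
    ok_f <- lengths(fields) == 4L
    fields <- fields[ok_f]; rep_i <- rep_i[ok_f]
    alt_seq <- vapply(fields, `[`, character(1L), 1L)
    alt_posf <- vapply(fields, `[`, character(1L), 2L)
    alt_pos <- abs(as.integer(alt_posf)) - 1L  # strand sign on the position
    alt_nm <- as.integer(vapply(fields, `[`, character(1L), 4L))
    counted <- alt_nm <= a$nm[rep_i]
    unknown <- counted & !alt_seq %in% names(seq_lengths)
    if (any(unknown)) {
      skipped <- sum(unknown)
      warning(skipped, " alternate site(s) referenced unknown sequence(s); skipped")
    }
    sel <- counted & !unknown
    if (any(sel)) {
      starts <- c(starts, alt_pos[sel])
      ends <- c(ends, pmin(alt_pos[sel] + a$alen[rep_i][sel],
                           unname(seq_lengths[alt_seq[sel]])))
      seqs <- c(seqs, alt_seq[sel])
    }
  }

  depth <- lapply(names(seq_lengths), function(chr) {
    len <- as.integer(seq_lengths[[chr]])
    i <- which(seqs == chr)
    if (!length(i)) return(integer(len))
    add <- tabulate(starts[i] + 1L, nbins = len)
    rem <- tabulate(ends[i] + 1L, nbins = len + 1L)[seq_len(len)]
    cumsum(add - rem)
  })
  names(depth) <- names(seq_lengths)
  attr(depth, "qc") <- c(skipped_alternates = skipped)
  depth
}

#' Windowed median depth
#'
#' Sliding windows of `window` bp at `step` bp; the final window is
#' truncated at the sequence end, and sequences shorter than the window give
#' a single whole-sequence window. The window statistic is the median of
#' per-base depth.
#'
#' @param depth Named list of per-base depth vectors ([accumulate_depth()]).
#' @param window Window width in bp (default 100000).
#' @param step Step in bp (default 20000).
#' @return Data frame of `coverage_windows`: `seq`, `start`, `end` (0-based
#'   half-open), `raw_median`.
#' @export
windowed_median <- function(depth, window = 100000L, step = 20000L) {
  out <- lapply(names(depth), function(chr) {
    d <- depth[[chr]]
    len <- length(d)
    if (len <= window) {
      starts <- 0L
    } else {
      starts <- seq.int(0L, len - window, by = step)
      if (max(starts) + window < len) starts <- c(starts, max(starts) + step)
    }
    ends <- pmin(starts + window, len)
    med <- vapply(seq_along(starts),
                  function(i) median(d[(starts[i] + 1L):ends[i]]),
                  numeric(1L))
    data.frame(seq = chr, start = as.integer(starts), end = as.integer(ends),
               raw_median = med, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  row.names(res) <- NULL
  res
}

#' Mask high-coverage windows and normalize to the genome-wide average
#'
#' Windows whose raw median reaches `mask_fold` times the mean window median
#' of their own sequence (inclusive threshold) are masked — these are
#' collapsed-repeat/centromeric signatures — and excluded from the
#' normalization statistic. The remaining windows are standardized by the
#' genome-wide mean of unmasked window medians, so the unmasked mean of
#' `normalized` is exactly 1.
#'
#' @param windows [windowed_median()] output.
#' @param mask_fold Masking threshold as a multiple of the per-sequence mean
#'   (inclusive), default 10.
#' @return The window data frame with `masked` and `normalized` columns.
#' @export
mask_and_normalize <- function(windows, mask_fold = 10) {
  seq_mean <- stats::ave(windows$raw_median, windows$seq, FUN = mean)
  windows$masked <- windows$raw_median >= mask_fold * seq_mean
  if (all(windows$masked)) stop("no usable windows: all windows masked")
  g <- mean(windows$raw_median[!windows$masked])
  windows$normalized <- windows$raw_median / g
  windows
}

#' Classify homoeolog dosage from normalized coverage
#'
#' For each region, takes the mean normalized depth of the unmasked windows
#' overlapping it and snaps it to the nearest of the five dosage anchors
#' 0, 0.5, 1, 1.5, 2 (ties round toward 1). On this scale a balanced 2:2
#' region reads ~1, the two sides of a partial (3:1) conversion read ~0.5
#' and ~1.5, and a complete (4:0) conversion reads ~0 and ~2. Regions
#' covered only by masked windows are flagged with an undefined class.
#'
#' @param windows [mask_and_normalize()] output.
#' @param regions Data frame with `seq`, `start`, `end` (0-based half-open).
#' @param anchors Dosage anchors (exposed for completeness).
#' @return Data frame of dosage calls: region coordinates,
#'   `mean_normalized_depth`, `ratio_class`, `homoeolog_ratio`, `flagged`.
#' @export
classify_dosage <- function(windows, regions,
                            anchors = c(0, 0.5, 1, 1.5, 2)) {
  labels <- c("4:0 loss", "3:1 loss side", "2:2", "3:1 gain side", "4:0 gain")
  res <- lapply(seq_len(nrow(regions)), function(i) {
    r <- regions[i, ]
    w <- windows[windows$seq == r$seq & windows$start < r$end &
                   windows$end > r$start & !windows$masked, , drop = FALSE]
    if (nrow(w) == 0L)
      return(data.frame(seq = r$seq, start = r$start, end = r$end,
                        mean_normalized_depth = NA_real_,
                        ratio_class = NA_real_,
                        homoeolog_ratio = NA_character_, flagged = TRUE,
                        stringsAsFactors = FALSE))
    m <- mean(w$normalized)
    d <- abs(anchors - m)
    cand <- which(d == min(d))
    if (length(cand) > 1L) cand <- cand[which.min(abs(anchors[cand] - 1))]
    data.frame(seq = r$seq, start = r$start, end = r$end,
               mean_normalized_depth = m, ratio_class = anchors[cand],
               homoeolog_ratio = labels[cand], flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Summarize normalized depth of windows inside a region
#'
#' Helper for dosage read-outs: the summary statistic (default median) of
#' unmasked windows fully contained in (`contained = TRUE`) or overlapping
#' the region.
#'
#' @param windows [mask_and_normalize()] output.
#' @param seq,start,end Region (0-based half-open).
#' @param contained Require full containment of the window (default) rather
#'   than any overlap.
#' @param stat Summary function, default [median()].
#' @return List with `value` (the statistic) and `n_windows`.
#' @export
region_depth_summary <- function(windows, seq, start, end,
                                 contained = TRUE, stat = median) {
  w <- if (contained) {
    windows[windows$seq == seq & windows$start >= start &
              windows$end <= end & !windows$masked, , drop = FALSE]
  } else {
    windows[windows$seq == seq & windows$start < end &
              windows$end > start & !windows$masked, , drop = FALSE]
  }
  list(value = if (nrow(w)) stat(w$normalized) else NA_real_,
       n_windows = nrow(w))
}

#' Write normalized window coverage as bedGraph
#'
#' @param windows [mask_and_normalize()] output; masked windows are skipped.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(windows, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("track type=bedGraph name=\"normalized window coverage\"", con)
  w <- windows[!windows$masked, , drop = FALSE]
  if (nrow(w))
    writeLines(sprintf("%s\t%d\t%d\t%.6g", w$seq, w$start, w$end,
                       w$normalized), con)
  invisible(path)
}

#' End-to-end coverage dosage analysis
#'
#' Runs the full coverage branch: diagnostic-read selection on the ancestral
#' alignments, alternate-hit aware depth on the target alignments, windowed
#' medians, masking/normalization, and (optionally) dosage classification of
#' supplied regions.
#'
#' @param aln_ancestral Alignments of the reads to the ancestral genome.
#' @param aln_target Alignments of the same reads to the genome under
#'   analysis.
#' @param target_lengths Named vector of target sequence lengths.
#' @param regions Optional regions to classify.
#' @param min_mapq,window,step,mask_fold Stage parameters (defaults follow
#'   the package-wide analysis settings).
#' @return List with `diagnostic` (ids), `depth`, `windows`, `calls`.
#' @export
coverage_analysis <- function(aln_ancestral, aln_target, target_lengths,
                              regions = NULL, min_mapq = 5L,
                              window = 100000L, step = 20000L,
                              mask_fold = 10) {
  diag_ids <- select_diagnostic_reads(aln_ancestral, min_mapq)
  depth <- accumulate_depth(aln_target, diag_ids, target_lengths)
  windows <- mask_and_normalize(windowed_median(depth, window, step),
                                mask_fold)
  calls <- if (!is.null(regions) && nrow(regions))
    classify_dosage(windows, regions) else NULL
  list(diagnostic = diag_ids, depth = depth, windows = windows,
       calls = calls)
}
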