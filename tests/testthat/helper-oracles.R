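# Independent oracles used to pin down expected values. These deliberately
# reimplement each operation in the most naive way possible (exhaustive
# enumeration, per-base bitmaps, literal pileup loops) and never share code
# with the package internals they check.

# exhaustive maximum-score conflict-free subset of alignment records
oracle_best_subset_score <- function(records) {
  n <- nrow(records)
  conflicts <- function(i, j) {
    (records$query_name[i] == records$query_name[j] &&
       records$query_start[i] < records$query_end[j] &&
       records$query_start[j] < records$query_end[i]) ||
      (records$target_name[i] == records$target_name[j] &&
         records$target_start[i] < records$target_end[j] &&
         records$target_start[j] < records$target_end[i])
  }
  best <- 0
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) > 0L)
    ok <- TRUE
    if (length(idx) > 1L) {
      for (a in seq_along(idx)[-1L]) {
        for (b in seq_len(a - 1L)) {
          if (conflicts(idx[a], idx[b])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (ok) best <- max(best, sum(records$score[idx]))
  }
  best
}

# random mutually-entangled alignment records for filter stress tests
random_alignment_records <- function(n, n_seqs = 2L, span = 1000L) {
  qn <- sample(paste0("q", seq_len(n_seqs)), n, replace = TRUE)
  tn <- sample(paste0("t", seq_len(n_seqs)), n, replace = TRUE)
  qs <- sample.int(span, n, replace = TRUE) - 1L
  ts <- sample.int(span, n, replace = TRUE) - 1L
  qw <- sample(20:400, n, replace = TRUE)
  tw <- sample(20:400, n, replace = TRUE)
  sc <- sample(50:1000, n, replace = TRUE)
  data.frame(query_name = qn, query_len = span + 500L,
             query_start = qs, query_end = qs + qw,
             target_name = tn, target_len = span + 500L,
             target_start = ts, target_end = ts + tw,
             strand = sample(c("+", "-"), n, replace = TRUE),
             matches = sc, block_length = pmax(qw, tw),
             identity = 1, score = as.numeric(sc), stringsAsFactors = FALSE)
}

# per-base bitmap over one toy chromosome per sequence name
intervals_to_bitmap <- function(df, seqlens) {
  maps <- lapply(seqlens, function(L) logical(L))
  for (i in seq_len(nrow(df))) {
    s <- df$seq[i]
    maps[[s]][(df$start[i] + 1L):df$end[i]] <- TRUE
  }
  maps
}

bitmap_total <- function(maps) sum(vapply(maps, sum, numeric(1L)))

bitmap_and <- function(a, b) Map(`&`, a, b)

# number of maximal TRUE runs across all sequences
bitmap_runs <- function(maps) {
  sum(vapply(maps, function(m) {
    r <- rle(m)
    sum(r$values)
  }, numeric(1L)))
}

random_interval_set <- function(n, seqlens, max_width = 5000L) {
  seqs <- sample(names(seqlens), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n),
              function(i) sample.int(seqlens[[seqs[i]]] - w[i], 1L) - 1L,
              integer(1L))
  data.frame(seq = seqs, start = s, end = s + w, stringsAsFactors = FALSE)
}

# literal per-base pileup of primary alignments
naive_pileup <- function(aln, seq_lengths) {
  depth <- lapply(seq_lengths, function(L) integer(L))
  for (i in seq_len(nrow(aln))) {
    flag <- aln$flag[i]
    if (bitwAnd(flag, 0x100) > 0L || bitwAnd(flag, 0x800) > 0L) next
    chr <- aln$rname[i]
    from <- aln$pos[i] + 1L
    to <- min(aln$pos[i] + aln$alen[i], seq_lengths[[chr]])
    depth[[chr]][from:to] <- depth[[chr]][from:to] + 1L
  }
  depth
}

# literal sliding windows over one depth vector
naive_windows <- function(d, window, step) {
  len <- length(d)
  if (len <= window) {
    starts <- 0L
  } else {
    starts <- seq.int(0L, len - window, by = step)
    if (max(starts) + window < len) starts <- c(starts, max(starts) + step)
  }
  vapply(starts, function(s) median(d[(s + 1L):min(s + window, len)]),
         numeric(1L))
}

# Monte-Carlo placement null: re-place every genome's intervals uniformly
# (keeping each set's widths, rejecting within-genome overlap) and measure
# the k-way shared base count
mc_shared_bp <- function(width_sets, L, n_rep) {
  vapply(seq_len(n_rep), function(r) {
    shared <- rep(TRUE, L)
    for (widths in width_sets) {
      m <- logical(L)
      for (w in widths) {
        repeat {
          s <- sample.int(L - w + 1L, 1L) - 1L
          if (!any(m[(s + 1L):(s + w)])) break
        }
        m[(s + 1L):(s + w)] <- TRUE
      }
      shared <- shared & m
    }
    sum(shared)
  }, numeric(1L))
}
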