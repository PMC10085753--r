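#' Aligner parameters
#'
#' Parameters of the built-in whole-genome aligner. Anchors are k-mers that
#' occur exactly once in the target genome (unique-match seeding, as in the
#' MUMmer family); adjacent anchors on one diagonal are merged into exact
#' runs, and runs on the same diagonal within `max_chain_gap` are chained
#' into gap-free alignment records. A chain must contain at least one run of
#' `min_anchor_run` consecutive matching bases to be reported (this removes
#' chance k-mer collisions between unrelated sequences).
#'
#' @param k K-mer size (>= 11).
#' @param min_anchor_run Minimum exact-match seed length in bp.
#' @param max_chain_gap Maximum anchor-to-anchor gap chained across, bp.
#' @param min_block Minimum reported block length in bp (>= 1).
#' @return A validated list of class `align_params`.
#' @export
align_params <- function(k = 15L, min_anchor_run = 31L,
                         max_chain_gap = 10000L, min_block = 100L) {
  p <- list(k = as.integer(k), min_anchor_run = as.integer(min_anchor_run),
            max_chain_gap = as.integer(max_chain_gap),
            min_block = as.integer(min_block))
  if (p$k < 11L) stop("k must be >= 11")
  if (p$min_block < 1L) stop("min_block must be >= 1")
  if (p$min_anchor_run < p$k) stop("min_anchor_run must be >= k")
  if (p$max_chain_gap < 0L) stop("max_chain_gap must be >= 0")
  class(p) <- "align_params"
  p
}

empty_alignments <- function() {
  data.frame(query_name = character(), query_len = integer(),
             query_start = integer(), query_end = integer(),
             target_name = character(), target_len = integer(),
             target_start = integer(), target_end = integer(),
             strand = character(), matches = integer(),
             block_length = integer(), identity = numeric(),
             score = numeric(), stringsAsFactors = FALSE)
}

#' Align two labeled genomes
#'
#' Whole-genome alignment by unique k-mer anchor seeding and collinear
#' (diagonal) chaining on both strands. Each record is a maximal gap-free
#' chain; `matches` and `identity` come from direct base comparison of the
#' chained spans. Records shorter than `params$min_block` are dropped.
#' Coordinates are 0-based half-open; minus-strand query coordinates refer to
#' the forward query strand.
#'
#' @param query,target [labeled_genome()]s (non-empty).
#' @param params An [align_params()].
#' @return Data frame of alignment records ordered by target sequence then
#'   `target_start`, with columns `query_name`, `query_len`, `query_start`,
#'   `query_end`, `target_name`, `target_len`, `target_start`, `target_end`,
#'   `strand`, `matches`, `block_length`, `identity`, `score`.
#' @export
align_genomes <- function(query, target, params = align_params()) {
  stopifnot(inherits(query, "labeled_genome"),
            inherits(target, "labeled_genome"),
            inherits(params, "align_params"))
  if (length(query$seq) == 0L || length(target$seq) == 0L)
    stop("empty sequence set")

  k <- params$k
  hits <- anchor_scan(unname(query$seq), unname(target$seq), k)
  if (nrow(hits) == 0L) return(empty_alignments())

  diag <- hits$tpos - hits$qpos
  o <- order(hits$qidx, hits$tidx, hits$strand, diag, hits$qpos)
  qidx <- hits$qidx[o]; tidx <- hits$tidx[o]; strand <- hits$strand[o]
  qpos <- hits$qpos[o]; tpos <- hits$tpos[o]; dg <- diag[o]
  n <- length(qpos)

  new_grp <- c(TRUE, qidx[-1L] != qidx[-n] | tidx[-1L] != tidx[-n] |
                 strand[-1L] != strand[-n] | dg[-1L] != dg[-n])
  # maximal runs of step-1 consecutive hits = exact-match runs
  new_run <- new_grp | c(TRUE, qpos[-1L] != qpos[-n] + 1L)
  rs <- which(new_run)
  re <- c(rs[-1L] - 1L, n)
  run_qs <- qpos[rs]; run_qe <- qpos[re] + k
  run_len <- run_qe - run_qs

  # chain runs on one diagonal while the inter-run gap is small enough
  run_grp_start <- new_grp[rs]
  nr <- length(rs)
  gap <- c(0L, run_qs[-1L] - run_qe[-nr])
  new_chain <- run_grp_start | gap > params$max_chain_gap
  chain_id <- cumsum(new_chain)
  cs <- which(new_chain)
  ce <- c(cs[-1L] - 1L, nr)

  has_seed <- vapply(seq_along(cs), function(i)
    max(run_len[cs[i]:ce[i]]) >= params$min_anchor_run, logical(1L))

  ch_qs <- run_qs[cs]; ch_qe <- run_qe[ce]
  ch_qidx <- qidx[rs[cs]]; ch_tidx <- tidx[rs[cs]]
  ch_strand <- strand[rs[cs]]; ch_diag <- dg[rs[cs]]
  span <- ch_qe - ch_qs
  keep <- has_seed & span >= params$min_block
  if (!any(keep)) return(empty_alignments())
  ch_qs <- ch_qs[keep]; ch_qe <- ch_qe[keep]; ch_qidx <- ch_qidx[keep]
  ch_tidx <- ch_tidx[keep]; ch_strand <- ch_strand[keep]
  ch_diag <- ch_diag[keep]; span <- span[keep]

  qlens <- nchar(query$seq); tlens <- nchar(target$seq)

  # identity by direct base comparison of the (strand-oriented) chained span
  matches <- integer(length(span))
  oriented_cache <- new.env(parent = emptyenv())
  oriented_seq <- function(qi, st) {
    key <- paste(qi, st, sep = ":")
    if (!is.null(oriented_cache[[key]])) return(oriented_cache[[key]])
    s <- if (st > 0L) query$seq[[qi]] else revcomp_cpp(query$seq[[qi]])
    oriented_cache[[key]] <- s
    s
  }
  for (i in seq_along(span)) {
    qs <- oriented_seq(ch_qidx[i], ch_strand[i])
    nm <- span_mismatches(qs, ch_qs[i], target$seq[[ch_tidx[i]]],
                          ch_qs[i] + ch_diag[i], span[i])
    matches[i] <- span[i] - nm
  }

  # map oriented query coordinates back to the forward strand
  qlen_i <- unname(qlens[ch_qidx])
  fwd_qs <- ifelse(ch_strand > 0L, ch_qs, qlen_i - ch_qe)
  fwd_qe <- ifelse(ch_strand > 0L, ch_qe, qlen_i - ch_qs)

  rec <- data.frame(query_name = names(query$seq)[ch_qidx],
                    query_len = qlen_i,
                    query_start = as.integer(fwd_qs),
                    query_end = as.integer(fwd_qe),
                    target_name = names(target$seq)[ch_tidx],
                    target_len = unname(tlens[ch_tidx]),
                    target_start = as.integer(ch_qs + ch_diag),
                    target_end = as.integer(ch_qe + ch_diag),
                    strand = ifelse(ch_strand > 0L, "+", "-"),
                    matches = matches,
                    block_length = as.integer(span),
                    stringsAsFactors = FALSE)
  rec$identity <- rec$matches / rec$block_length
  rec$score <- as.numeric(rec$matches)
  rec[order(rec$target_name, rec$target_start, rec$query_name,
            rec$query_start), , drop = FALSE]
}

#' Keep the one best alignment per region
#'
#' Emulates MUMmer's `delta-filter -1` 1-to-1 filtering: returns a subset of
#' records in which no two records overlap on the query axis and no two
#' overlap on the target axis, chosen to maximize total score
#' (score = matches, so longer blocks dominate). The optimum is computed
#' exactly per connected component of the conflict graph by branch-and-bound;
#' ties prefer records with lower `target_start`, then lower `query_start`.
#' Components larger than 24 records fall back to greedy selection (never
#' reached on collinear data).
#'
#' @param records Alignment records from one [align_genomes()] run.
#' @param axis Which axes must be conflict-free: `"both"` (default, the
#'   1-to-1 semantics) or `"query"` (each query position keeps its single
#'   highest-scoring hit but a reference region may serve several queries —
#'   the "highest hit" semantics used for candidate exchange calling, where
#'   the donor chromosome's self-alignment must not outcompete the
#'   exchanged segment's alignment to the same ancestral territory).
#' @param overlap_tol Overlap in bp up to which two records are not
#'   considered in conflict (default 0: strict). Chains abutting a
#'   homoeologous junction can extend a few conserved bases across it, so
#'   candidate exchange calling uses a small non-zero tolerance.
#' @return The filtered subset, ordered by target sequence then start.
#' @export
best_hit_filter <- function(records, axis = c("both", "query"),
                            overlap_tol = 0L) {
  axis <- match.arg(axis)
  n <- nrow(records)
  if (is.null(n) || n == 0L) return(records)
  qs <- records$query_start; qe <- records$query_end
  ts <- records$target_start; te <- records$target_end
  qn <- records$query_name; tn <- records$target_name
  tol <- as.integer(overlap_tol)

  conflict <- function(i, j) {
    (qn[i] == qn[j] &&
       min(qe[i], qe[j]) - max(qs[i], qs[j]) > tol) ||
      (axis == "both" && tn[i] == tn[j] &&
         min(te[i], te[j]) - max(ts[i], ts[j]) > tol)
  }
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (conflict(i, j)) { adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i) }

  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      queue <- i
      comp[i] <- cid
      while (length(queue)) {
        v <- queue[1L]; queue <- queue[-1L]
        nb <- adj[[v]][comp[adj[[v]]] == 0L]
        comp[nb] <- cid
        queue <- c(queue, nb)
      }
    }
  }

  keep <- logical(n)
  for (cc in seq_len(cid)) {
    members <- which(comp == cc)
    if (length(members) == 1L) { keep[members] <- TRUE; next }
    ord <- members[order(-records$score[members], ts[members], qs[members])]
    if (length(ord) <= 24L) {
      keep[mwis_exact(ord, records$score, adj)] <- TRUE
    } else {
      chosen <- integer()
      for (i in ord)
        if (!any(i %in% unlist(adj[chosen]))) chosen <- c(chosen, i)
      keep[chosen] <- TRUE
    }
  }
  out <- records[keep, , drop = FALSE]
  out[order(out$target_name, out$target_start, out$query_name,
            out$query_start), , drop = FALSE]
}

# exact maximum-score conflict-free subset over one component (branch & bound,
# depth-first in the given preference order; first optimum found is kept)
mwis_exact <- function(ord, score, adj) {
  m <- length(ord)
  suffix <- rev(cumsum(rev(score[ord])))
  best_score <- -Inf
  best_set <- integer()
  recurse <- function(pos, chosen, cur) {
    if (pos > m) {
      if (cur > best_score) { best_score <<- cur; best_set <<- chosen }
      return(invisible())
    }
    if (cur + suffix[pos] <= best_score) return(invisible())
    v <- ord[pos]
    if (!any(chosen %in% adj[[v]]))
      recurse(pos + 1L, c(chosen, v), cur + score[v])
    recurse(pos + 1L, chosen, cur)
  }
  recurse(1L, integer(), 0)
  best_set
}
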