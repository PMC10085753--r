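#' Read alignments from PAF
#'
#' Bridge for substituting an external aligner (minimap2, nucmer via
#' conversion) for the built-in one. Standard 12+ column PAF; identity is
#' recomputed as `matches / block_length` (columns 10/11). Coordinates stay
#' 0-based half-open as in PAF itself.
#'
#' @param path PAF file.
#' @return Alignment record data frame as returned by [align_genomes()].
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(empty_alignments())
  f <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(f) < 12L)
  if (length(short))
    stop("malformed PAF line ", short[1L], ": expected >= 12 columns, got ",
         lengths(f)[short[1L]])
  m <- do.call(rbind, lapply(f, `[`, 1:12))
  num <- function(j) suppressWarnings(as.integer(m[, j]))
  rec <- data.frame(query_name = m[, 1L], query_len = num(2L),
                    query_start = num(3L), query_end = num(4L),
                    target_name = m[, 6L], target_len = num(7L),
                    target_start = num(8L), target_end = num(9L),
                    strand = m[, 5L], matches = num(10L),
                    block_length = num(11L), stringsAsFactors = FALSE)
  bad <- which(!complete.cases(rec) | !rec$strand %in% c("+", "-"))
  if (length(bad)) stop("malformed PAF line ", bad[1L],
                        ": non-numeric coordinate or bad strand")
  if (any(rec$query_start >= rec$query_end) ||
      any(rec$target_start >= rec$target_end))
    stop("PAF interval with start >= end")
  rec$identity <- rec$matches / rec$block_length
  rec$score <- as.numeric(rec$matches)
  rec
}

#' Write alignments to PAF
#'
#' Lossless for the fields carried by the alignment record data frame
#' (round-trips through [read_paf()]); the mapping-quality column is written
#' as 255 (unavailable).
#'
#' @param records Alignment record data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(records, path) {
  need <- c("query_name", "query_len", "query_start", "query_end", "strand",
            "target_name", "target_len", "target_start", "target_end",
            "matches", "block_length")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack PAF field(s): ", paste(missing, collapse = ", "))
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t255",
                   records$query_name, records$query_len,
                   records$query_start, records$query_end, records$strand,
                   records$target_name, records$target_len,
                   records$target_start, records$target_end,
                   records$matches, records$block_length)
  con <- file(path, "wb")
  writeLines(lines, con)
  close(con)
  invisible(path)
}
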