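#' Generate a pair of diverged ancestral diploid genomes
#'
#' Draws an A-parent genome with the configured GC content, then derives the
#' C-parent by i.i.d. substitutions at rate `homoeolog_divergence`
#' (substitution-only: no indels, so homologous coordinates are identical on
#' both genomes and the homology map is a per-chromosome identity map).
#' Generation is fully determined by `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An object of class `ancestral_pair`: list with `a` and `c`
#'   ([labeled_genome()]s, chromosomes `A01..`/`C01..`) and `homology`, a
#'   data frame pairing each A chromosome with its C homoeolog.
#' @export
generate_ancestral_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)
  n <- config$n_chrom_per_subgenome
  len <- config$chrom_length
  gc <- config$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- c("A", "C", "G", "T")
  # each base maps to its three possible substitution targets
  alt <- matrix(c("C", "G", "T",
                  "A", "G", "T",
                  "A", "C", "T",
                  "A", "C", "G"), nrow = 4L, byrow = TRUE,
                dimnames = list(bases, NULL))

  a_seqs <- character(n)
  c_seqs <- character(n)
  for (i in seq_len(n)) {
    av <- sample(bases, len, replace = TRUE, prob = base_prob)
    cv <- av
    pos <- which(runif(len) < config$homoeolog_divergence)
    if (length(pos)) {
      pick <- sample.int(3L, length(pos), replace = TRUE)
      cv[pos] <- alt[cbind(match(av[pos], bases), pick)]
    }
    a_seqs[i] <- paste(av, collapse = "")
    c_seqs[i] <- paste(cv, collapse = "")
  }
  names(a_seqs) <- sprintf("A%02d", seq_len(n))
  names(c_seqs) <- sprintf("C%02d", seq_len(n))
  homology <- data.frame(a_chrom = names(a_seqs), c_chrom = names(c_seqs),
                         start = 0L, end = len, length = len,
                         stringsAsFactors = FALSE)
  structure(list(a = labeled_genome(a_seqs),
                 c = labeled_genome(c_seqs),
                 homology = homology),
            class = "ancestral_pair")
}

#' @export
print.ancestral_pair <- function(x, ...) {
  cat("ancestral_pair: A parent", length(x$a$seq), "chrom /",
      "C parent", length(x$c$seq), "chrom,",
      format(sum(nchar(x$a$seq)), big.mark = ","), "bp per subgenome\n")
  invisible(x)
}

#' Construct an event-free allotetraploid individual
#'
#' Four haplotypes (`A1`, `A2`, `C1`, `C2`) copied from the ancestral pair
#' (the simulated line is fully inbred: no heterozygosity between homologous
#' copies), plus a collapsed assembly taking haplotypes `A1` and `C1`
#' verbatim — the haploid-collapsed representation a genome assembler would
#' produce.
#'
#' @param pair An [generate_ancestral_pair()] result.
#' @return An object of class `tetraploid_individual`.
#' @export
tetraploid_individual <- function(pair) {
  stopifnot(inherits(pair, "ancestral_pair"))
  hap <- list(A1 = pair$a$seq, A2 = pair$a$seq,
              C1 = pair$c$seq, C2 = pair$c$seq)
  structure(list(haplotypes = hap,
                 assembly = labeled_genome(c(pair$a$seq, pair$c$seq)),
                 ancestral = list(A = pair$a$seq, C = pair$c$seq),
                 homology = pair$homology,
                 truth = empty_truth()),
            class = "tetraploid_individual")
}

#' @export
print.tetraploid_individual <- function(x, ...) {
  cat("tetraploid_individual: 4 haplotypes x",
      length(x$haplotypes$A1) + length(x$haplotypes$C1), "chromosomes,",
      nrow(x$truth), "truth event record(s)\n")
  invisible(x)
}

empty_truth <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             direction = character(), dosage = character(),
             reciprocity = character(), copy = integer(),
             stringsAsFactors = FALSE)
}

#' Specify homoeologous exchange events
#'
#' Vectorized constructor for planted-event specifications. Coordinates are
#' 0-based half-open on the recipient chromosome. `dosage = "partial"`
#' converts exactly one of the two homologous copies (`copy` selects which;
#' copy 1 is the one the collapsed assembly represents), `"complete"`
#' converts both. `reciprocity = "reciprocal"` additionally writes the
#' recipient's original homoeologous segment into the donor subgenome's
#' haplotype(s), giving a 2:2 segment swap.
#'
#' @param chrom Recipient chromosome name(s).
#' @param start,end 0-based half-open recipient interval(s).
#' @param direction `"A_replaces_C"` (recipient on a C chromosome) or
#'   `"C_replaces_A"`.
#' @param dosage `"partial"` or `"complete"`.
#' @param reciprocity `"nonreciprocal"` (default) or `"reciprocal"`.
#' @param copy For partial events, which homologous copy (1 or 2) is
#'   converted; ignored for complete events.
#' @return A data frame of class `he_events`.
#' @export
he_events <- function(chrom, start, end, direction,
                      dosage = "partial",
                      reciprocity = "nonreciprocal",
                      copy = 1L) {
  ev <- data.frame(chrom = as.character(chrom),
                   start = as.integer(start), end = as.integer(end),
                   direction = as.character(direction),
                   dosage = as.character(dosage),
                   reciprocity = as.character(reciprocity),
                   copy = as.integer(copy),
                   stringsAsFactors = FALSE)
  if (!all(ev$direction %in% c("A_replaces_C", "C_replaces_A")))
    stop("direction must be \"A_replaces_C\" or \"C_replaces_A\"")
  if (!all(ev$dosage %in% c("partial", "complete")))
    stop("dosage must be \"partial\" or \"complete\"")
  if (!all(ev$reciprocity %in% c("nonreciprocal", "reciprocal")))
    stop("reciprocity must be \"nonreciprocal\" or \"reciprocal\"")
  if (!all(ev$copy %in% c(1L, 2L))) stop("copy must be 1 or 2")
  if (any(ev$start < 0L) || any(ev$end <= ev$start))
    stop("event intervals must satisfy 0 <= start < end")
  class(ev) <- c("he_events", "data.frame")
  ev
}

#' Plant homoeologous exchange events into an individual
#'
#' Overwrites the recipient interval on one (`partial`) or both (`complete`)
#' recipient haplotypes with the homoeologous ancestral donor segment; a
#' `reciprocal` event also writes the ancestral recipient segment into the
#' corresponding donor haplotype(s). Donor segments are taken from the stored
#' ancestral sequences, so planting is deterministic and order-independent.
#' The collapsed assembly is rebuilt from haplotypes `A1`/`C1`. Total
#' haplotype length is conserved (substitution-only model).
#'
#' @param individual A [tetraploid_individual()].
#' @param events An [he_events()] specification.
#' @return The modified individual, with `truth` extended by one record per
#'   converted recipient interval (reciprocal events contribute a second
#'   record for the donor-side interval).
#' @export
plant_events <- function(individual, events) {
  stopifnot(inherits(individual, "tetraploid_individual"))
  if (!inherits(events, "he_events")) {
    if (is.data.frame(events) && nrow(events) == 0L) return(individual)
    stop("'events' must be created with he_events()")
  }
  if (nrow(events) == 0L) return(individual)
  ind <- individual
  hom <- ind$homology

  # recipient chromosome must belong to the direction's recipient subgenome
  recipient_sub <- ifelse(events$direction == "A_replaces_C", "C", "A")
  for (i in seq_len(nrow(events))) {
    pool <- if (recipient_sub[i] == "C") hom$c_chrom else hom$a_chrom
    if (!events$chrom[i] %in% pool)
      stop("event ", i, ": recipient chromosome '", events$chrom[i],
           "' is not a ", recipient_sub[i],
           "-subgenome chromosome in the homology map")
    ci <- match(events$chrom[i],
                if (recipient_sub[i] == "C") hom$c_chrom else hom$a_chrom)
    if (events$end[i] > hom$length[ci])
      stop("event ", i, ": interval [", events$start[i], ", ", events$end[i],
           ") outside chromosome '", events$chrom[i], "' (length ",
           hom$length[ci], ")")
  }

  # reject overlapping events on the same chromosome
  for (chr in unique(events$chrom)) {
    e <- events[events$chrom == chr, , drop = FALSE]
    if (nrow(e) > 1L) {
      o <- order(e$start)
      e <- e[o, , drop = FALSE]
      bad <- which(e$start[-1L] < e$end[-nrow(e)])
      if (length(bad))
        stop("overlapping events on ", chr, ": [", e$start[bad[1L]], ", ",
             e$end[bad[1L]], ") and [", e$start[bad[1L] + 1L], ", ",
             e$end[bad[1L] + 1L], ")")
    }
  }

  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    rec_sub <- recipient_sub[i]
    don_sub <- setdiff(c("A", "C"), rec_sub)
    ci <- match(ev$chrom, if (rec_sub == "C") hom$c_chrom else hom$a_chrom)
    don_chrom <- if (rec_sub == "C") hom$a_chrom[ci] else hom$c_chrom[ci]

    don_seg <- substr(ind$ancestral[[don_sub]][[don_chrom]],
                      ev$start + 1L, ev$end)
    rec_seg <- substr(ind$ancestral[[rec_sub]][[ev$chrom]],
                      ev$start + 1L, ev$end)

    rec_haps <- if (ev$dosage == "complete") paste0(rec_sub, 1:2)
                else paste0(rec_sub, ev$copy)
    for (h in rec_haps)
      substr(ind$haplotypes[[h]][[ev$chrom]], ev$start + 1L, ev$end) <- don_seg

    if (ev$reciprocity == "reciprocal") {
      don_haps <- if (ev$dosage == "complete") paste0(don_sub, 1:2)
                  else paste0(don_sub, ev$copy)
      for (h in don_haps)
        substr(ind$haplotypes[[h]][[don_chrom]], ev$start + 1L, ev$end) <- rec_seg
    }

    rec_row <- data.frame(chrom = ev$chrom, start = ev$start, end = ev$end,
                          direction = ev$direction, dosage = ev$dosage,
                          reciprocity = ev$reciprocity, copy = ev$copy,
                          stringsAsFactors = FALSE)
    ind$truth <- rbind(ind$truth, rec_row)
    if (ev$reciprocity == "reciprocal") {
      flip <- if (ev$direction == "A_replaces_C") "C_replaces_A" else "A_replaces_C"
      don_row <- data.frame(chrom = don_chrom, start = ev$start, end = ev$end,
                            direction = flip, dosage = ev$dosage,
                            reciprocity = ev$reciprocity, copy = ev$copy,
                            stringsAsFactors = FALSE)
      ind$truth <- rbind(ind$truth, don_row)
    }
  }
  ind$assembly <- labeled_genome(c(ind$haplotypes$A1, ind$haplotypes$C1))
  ind
}

#' Simulate paired-end reads from a tetraploid individual
#'
#' Fragments are drawn uniformly across the four haplotypes (probability
#' proportional to haplotype length, i.e. equal shares for the equal-length
#' complements), fragment lengths are Gaussian, mates are forward–reverse,
#' and per-base substitution errors are applied at `read_error_rate`.
#' The number of fragments is `depth * L / (2 * read_length)` where `L` is
#' the haploid subgenome complement length (one A plus one C chromosome
#' set), so total read bases equal `depth * L`. Base qualities are uniform
#' `"I"` (downstream stages never use them). Seeded by `config$seed + 1`.
#'
#' @param individual A [tetraploid_individual()].
#' @param config A [sim_config()].
#' @return An object of class `read_set`: list with `id`, `read1`, `read2`
#'   (character vectors), `quality` (one string), `read_length`, and `truth`
#'   (data frame: `id`, `haplotype`, `chrom`, `frag_start`, `frag_end`,
#'   0-based half-open fragment coordinates).
#' @export
simulate_reads <- function(individual, config) {
  stopifnot(inherits(individual, "tetraploid_individual"))
  validate_sim_config(config)
  if (config$depth <= 0) stop("invalid sim_config field 'depth': must be > 0")
  set.seed(config$seed + 1L)
  rl <- config$read_length
  hap_names <- names(individual$haplotypes)
  hap_tot <- vapply(individual$haplotypes,
                    function(s) sum(nchar(s)), numeric(1L))
  haploid_len <- sum(nchar(individual$haplotypes$A1)) +
    sum(nchar(individual$haplotypes$C1))
  n_pairs <- round(config$depth * haploid_len / (2 * rl))
  if (n_pairs < 1L) stop("configuration yields no read pairs")

  hap_idx <- sample.int(length(hap_names), n_pairs, replace = TRUE,
                        prob = hap_tot / sum(hap_tot))
  flen <- pmax(rl, as.integer(round(rnorm(n_pairs, config$fragment_mean,
                                          config$fragment_sd))))

  id <- sprintf("r%07d", seq_len(n_pairs))
  read1 <- character(n_pairs)
  read2 <- character(n_pairs)
  t_hap <- character(n_pairs)
  t_chrom <- character(n_pairs)
  t_start <- integer(n_pairs)
  t_end <- integer(n_pairs)

  for (h in seq_along(hap_names)) {
    sel <- which(hap_idx == h)
    if (!length(sel)) next
    seqs <- individual$haplotypes[[h]]
    lens <- nchar(seqs)
    ch <- sample.int(length(seqs), length(sel), replace = TRUE,
                     prob = lens / sum(lens))
    fl <- pmin(flen[sel], lens[ch])
    st <- as.integer(floor(runif(length(sel)) * (lens[ch] - fl + 1L)))
    en <- st + fl
    for (k in seq_along(seqs)) {
      m <- which(ch == k)
      if (!length(m)) next
      s <- seqs[[k]]
      read1[sel[m]] <- substring(s, st[m] + 1L, st[m] + rl)
      read2[sel[m]] <- substring(s, en[m] - rl + 1L, en[m])
    }
    t_hap[sel] <- hap_names[h]
    t_chrom[sel] <- names(seqs)[ch]
    t_start[sel] <- st
    t_end[sel] <- en
  }
  read2 <- revcomp(read2)

  if (config$read_error_rate > 0) {
    read1 <- inject_errors(read1, config$read_error_rate)
    read2 <- inject_errors(read2, config$read_error_rate)
  }

  structure(list(id = id, read1 = read1, read2 = read2,
                 quality = strrep("I", rl), read_length = rl,
                 truth = data.frame(id = id, haplotype = t_hap,
                                    chrom = t_chrom, frag_start = t_start,
                                    frag_end = t_end,
                                    stringsAsFactors = FALSE)),
            class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  cat("read_set:", length(x$id), "read pairs,", x$read_length, "bp reads\n")
  invisible(x)
}

# per-base substitution errors; only reads drawn with >=1 error are touched
inject_errors <- function(reads, rate) {
  rl <- nchar(reads)
  nerr <- rbinom(length(reads), rl, rate)
  idx <- which(nerr > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(rl[i], nerr[i])
    for (p in pos) {
      old <- substr(reads[i], p, p)
      substr(reads[i], p, p) <- sample(setdiff(bases, old), 1L)
    }
  }
  reads
}

#' Write a read set to paired FASTQ files
#'
#' @param reads A [simulate_reads()] result.
#' @param prefix Output prefix; files `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` are written (add `.gz` to `suffix` to compress).
#' @param suffix File suffix, default `".fastq"`.
#' @return Character vector of the two paths, invisibly.
#' @export
write_fastq <- function(reads, prefix, suffix = ".fastq") {
  stopifnot(inherits(reads, "read_set"))
  paths <- paste0(prefix, c("_1", "_2"), suffix)
  for (m in 1:2) {
    seqs <- if (m == 1L) reads$read1 else reads$read2
    rec <- as.vector(rbind(paste0("@", reads$id, "/", m), seqs, "+",
                           strrep("I", nchar(seqs))))
    con <- if (grepl("\\.gz$", paths[m])) gzfile(paths[m], "wb") else file(paths[m], "wb")
    writeLines(rec, con)
    close(con)
  }
  invisible(paths)
}

#' Write the realized truth set as BED6
#'
#' One line per converted recipient interval, 0-based half-open, with
#' `name = "<donor>><recipient>|<dosage>"` (e.g. `A>C|partial`), score 0 and
#' strand `"."`. An empty truth set yields a file holding only the header
#' comment.
#'
#' @param individual A [tetraploid_individual()] (planted).
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(individual, path) {
  stopifnot(inherits(individual, "tetraploid_individual"))
  tr <- individual$truth
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# hexfinder planted homoeologous-exchange truth set (BED6)", con)
  if (nrow(tr)) {
    donor <- ifelse(tr$direction == "A_replaces_C", "A", "C")
    recip <- ifelse(tr$direction == "A_replaces_C", "C", "A")
    lines <- sprintf("%s\t%d\t%d\t%s>%s|%s\t0\t.",
                     tr$chrom, tr$start, tr$end, donor, recip, tr$dosage)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a truth BED written by [write_truth_bed()]
#'
#' @param path BED path.
#' @return Data frame with `chrom`, `start`, `end`, `direction`, `dosage`.
#' @export
read_truth_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), direction = character(),
                      dosage = character(), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(f) < 6L)
  if (length(bad)) stop("malformed BED line ", bad[1L], " in ", path)
  m <- do.call(rbind, f)
  name <- strsplit(m[, 4L], "[>|]")
  donor <- vapply(name, `[`, character(1L), 1L)
  data.frame(chrom = m[, 1L],
             start = as.integer(m[, 2L]),
             end = as.integer(m[, 3L]),
             direction = ifelse(donor == "A", "A_replaces_C", "C_replaces_A"),
             dosage = vapply(name, `[`, character(1L), 3L),
             stringsAsFactors = FALSE)
}
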