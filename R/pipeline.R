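#' Pipeline configuration
#'
#' Collects every stage parameter of the analysis in one validated,
#' serializable place, with the package-wide defaults: trusted regions at
#' identity > 0.85 over > 1,000 bp; candidates at identity > 0.90 over
#' > 100 bp with trusted overlap; diagnostic reads at MAPQ >= 5; windows of
#' 100 kb at 20 kb step with a 10x mask; 5 kb merge gap. Unknown keys are
#' rejected so a typo cannot silently fall back to a default.
#'
#' @param ... Named overrides of the defaults (nested lists for the
#'   `simulate`, `align`, `trusted`, `candidate`, `coverage` blocks).
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(n_chrom_per_subgenome = 2L, chrom_length = 2e6,
                    homoeolog_divergence = 0.05, gc_content = 0.37,
                    read_length = 150L, fragment_mean = 400L,
                    fragment_sd = 50L, depth = 30, read_error_rate = 0.001),
    events = NULL,
    align = list(k = 15L, min_anchor_run = 31L, max_chain_gap = 10000L,
                 min_block = 100L),
    trusted = list(min_identity = 0.85, min_length = 1000L),
    candidate = list(min_identity = 0.90, min_length = 100L),
    merge_gap = 5000L,
    coverage = list(run = TRUE, min_mapq = 5L, window = 100000L,
                    step = 20000L, mask_fold = 10),
    verbosity = 1L)
  overrides <- list(...)
  cfg <- merge_config(defaults, overrides, path = "")
  class(cfg) <- "pipeline_config"
  cfg
}

merge_config <- function(base, over, path) {
  if (length(over) == 0L) return(base)
  nms <- names(over)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("configuration overrides must be named")
  for (nm in nms) {
    key <- if (nzchar(path)) paste0(path, "$", nm) else nm
    if (!nm %in% names(base)) stop("unknown configuration key: ", key)
    if (is.list(base[[nm]]) && !is.data.frame(base[[nm]]) &&
        is.list(over[[nm]]) && !is.data.frame(over[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], key)
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Write / read a pipeline configuration as YAML
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_pipeline_config <- function(config, path) {
  cfg <- unclass(config)
  if (!is.null(cfg$events)) cfg$events <- as.list(as.data.frame(cfg$events))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$events))
    raw$events <- do.call(he_events, raw$events)
  do.call(pipeline_config, raw)
}

log_msg <- function(verbosity, level, ...) {
  if (verbosity > 0L)
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Simulates the study scenario (ancestral pair, planted individual, reads),
#' runs the synteny-based HE caller on the planted assembly against the
#' ancestral genome, runs the coverage dosage analysis of the simulated
#' reads against the event-free assembly, and writes all stage outputs plus
#' a run manifest (versions, configuration, seeds, output checksums) to
#' `config$out_dir`. Rerunning with the same configuration reproduces
#' byte-identical outputs.
#'
#' @param config A [pipeline_config()]; `out_dir` must be set.
#' @return Invisibly, a list with the in-memory stage results
#'   (`pair`, `individual`, `he`, `coverage`, `he_set`, `manifest`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(config$out_dir)) stop("config$out_dir must be set")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  v <- config$verbosity
  out <- function(f) file.path(config$out_dir, f)

  log_msg(v, "INFO", "simulating ancestral pair and individual")
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
  pair <- generate_ancestral_pair(scfg)
  ind <- tetraploid_individual(pair)
  if (!is.null(config$events)) ind <- plant_events(ind, config$events)
  write_genome_fasta(pair$a, out("a_parent.fasta"))
  write_genome_fasta(pair$c, out("c_parent.fasta"))
  write_genome_fasta(ind$assembly, out("assembly.fasta"))
  write_truth_bed(ind, out("truth.bed"))

  log_msg(v, "INFO", "synteny-based HE calling")
  ap <- do.call(align_params, config$align)
  he <- call_he(ind$assembly, pair$a, pair$c, ap,
                trusted_min_identity = config$trusted$min_identity,
                trusted_min_length = config$trusted$min_length,
                min_identity = config$candidate$min_identity,
                min_length = config$candidate$min_length,
                merge_gap = config$merge_gap)
  write_he_bed(he$regions, out("he_regions.bed"))
  write_he_tsv(he$regions, out("he_regions.tsv"))

  ancestral <- build_ancestral(pair$a, pair$c)
  anc_len <- seq_lengths(ancestral)
  hset <- project_to_ancestral(he$regions, "simulated", anc_len)
  write_he_set_bed(hset, out("he_regions.ancestral.bed"))

  cov <- NULL
  if (isTRUE(config$coverage$run)) {
    log_msg(v, "INFO", "simulating reads and running coverage dosage analysis")
    reads <- simulate_reads(ind, scfg)
    write_fastq(reads, out("reads"), suffix = ".fastq.gz")
    aln_anc <- map_reads(reads, ancestral, ind$homology)
    # the event-free assembly: what the same line would look like without HE
    baseline <- tetraploid_individual(pair)$assembly
    aln_tgt <- map_reads(reads, baseline, ind$homology)
    write_sam(aln_anc, anc_len, out("reads.ancestral.sam"))
    regions <- if (nrow(ind$truth))
      data.frame(seq = ind$truth$chrom, start = ind$truth$start,
                 end = ind$truth$end, stringsAsFactors = FALSE) else NULL
    cov <- coverage_analysis(aln_anc, aln_tgt, seq_lengths(baseline),
                             regions = regions,
                             min_mapq = config$coverage$min_mapq,
                             window = config$coverage$window,
                             step = config$coverage$step,
                             mask_fold = config$coverage$mask_fold)
    write_bedgraph(cov$windows, out("coverage.bedgraph"))
    if (!is.null(cov$calls))
      write.table(cov$calls, out("dosage_calls.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }

  log_msg(v, "INFO", "writing manifest")
  cfg_path <- out("config.yaml")
  write_pipeline_config(config, cfg_path)
  files <- setdiff(list.files(config$out_dir), "manifest.json")
  manifest <- list(
    package = "hexfinder",
    version = as.character(packageVersion("hexfinder")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    outputs = as.list(tools::md5sum(file.path(config$out_dir, files))))
  names(manifest$outputs) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(pair = pair, individual = ind, he = he, coverage = cov,
                 he_set = hset, manifest = manifest))
}

#' Generate the canonical demonstration fixture
#'
#' The package's reference scenario: two chromosomes per subgenome at 5%
#' homoeolog divergence, six planted events spanning the partial, complete
#' and reciprocal cases at 20–100 kb, and 30x paired-end reads. Writes
#' FASTA genomes, gzipped FASTQ reads, the truth BED, the read-origin
#' table, and the generating configuration; regeneration with the same
#' seed is byte-stable.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param chrom_length Chromosome length in bp (default 1 Mb).
#' @param depth Read depth (default 30).
#' @param write_reads Write FASTQ files (the expensive part), default TRUE.
#' @return Invisibly, the planted `tetraploid_individual`.
#' @export
make_fixtures <- function(out_dir, seed = 1L, chrom_length = 1e6,
                          depth = 30, write_reads = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(seed = seed, n_chrom_per_subgenome = 2L,
                    chrom_length = chrom_length, homoeolog_divergence = 0.05,
                    depth = depth, read_error_rate = 0.001)
  pair <- generate_ancestral_pair(cfg)
  ind <- tetraploid_individual(pair)
  u <- function(x) as.integer(round(x * chrom_length / 1e6))
  events <- he_events(
    chrom = c("C01", "C01", "C02", "C02", "A01", "A02"),
    start = u(c(100000, 400000, 150000, 600000, 700000, 300000)),
    end = u(c(200000, 440000, 250000, 620000, 780000, 320000)),
    direction = c("A_replaces_C", "A_replaces_C", "A_replaces_C",
                  "A_replaces_C", "C_replaces_A", "C_replaces_A"),
    dosage = c("partial", "complete", "complete", "partial", "partial",
               "complete"),
    reciprocity = c("nonreciprocal", "nonreciprocal", "reciprocal",
                    "nonreciprocal", "nonreciprocal", "reciprocal"))
  ind <- plant_events(ind, events)
  write_genome_fasta(pair$a, file.path(out_dir, "a_parent.fasta"))
  write_genome_fasta(pair$c, file.path(out_dir, "c_parent.fasta"))
  write_genome_fasta(ind$assembly, file.path(out_dir, "assembly.fasta"))
  write_truth_bed(ind, file.path(out_dir, "truth.bed"))
  if (write_reads) {
    reads <- simulate_reads(ind, cfg)
    write_fastq(reads, file.path(out_dir, "reads"), suffix = ".fastq.gz")
    con <- gzfile(file.path(out_dir, "read_origins.tsv.gz"), "wb")
    write.table(reads$truth, con, sep = "\t", quote = FALSE,
                row.names = FALSE)
    close(con)
  }
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "sim_config.yaml"))
  invisible(ind)
}
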