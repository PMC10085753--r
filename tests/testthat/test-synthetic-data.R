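# simulator: ancestral pair, event planting, read simulation, truth BED

test_that("zero divergence gives identical subgenomes and full homology", {
  cfg <- tiny_config(seed = 1L, chrom_length = 20000L, divergence = 0)
  pair <- generate_ancestral_pair(cfg)
  expect_identical(unname(pair$a$seq), unname(pair$c$seq))
  expect_equal(sum(pair$homology$length), 20000L)
})

test_that("planted divergence is recovered by base comparison", {
  cfg <- tiny_config(seed = 5L, chrom_length = 1000000L, divergence = 0.05)
  pair <- generate_ancestral_pair(cfg)
  a <- strsplit(pair$a$seq[[1L]], "")[[1L]]
  c2 <- strsplit(pair$c$seq[[1L]], "")[[1L]]
  expect_lt(abs(mean(a != c2) - 0.05), 0.005)
})

test_that("generation and FASTA serialization are seed-deterministic", {
  cfg <- tiny_config(seed = 9L, chrom_length = 30000L)
  p1 <- generate_ancestral_pair(cfg)
  p2 <- generate_ancestral_pair(cfg)
  expect_identical(p1$a$seq, p2$a$seq)
  expect_identical(p1$c$seq, p2$c$seq)
  f1 <- tempfile(fileext = ".fasta"); f2 <- tempfile(fileext = ".fasta")
  write_genome_fasta(p1$a, f1); write_genome_fasta(p2$a, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  back <- read_genome_fasta(f1)
  expect_identical(back$seq, p1$a$seq)
  unlink(c(f1, f2))
})

test_that("gc_content biases base composition as configured", {
  cfg <- tiny_config(seed = 2L, chrom_length = 200000L)
  pair <- generate_ancestral_pair(cfg)
  gc <- sum(strsplit(pair$a$seq[[1L]], "")[[1L]] %in% c("G", "C")) / 200000
  expect_lt(abs(gc - 0.37), 0.01)
})

test_that("invalid configuration is rejected naming the field", {
  expect_error(sim_config(homoeolog_divergence = 0.5), "homoeolog_divergence")
  expect_error(sim_config(fragment_mean = 100, read_length = 150),
               "fragment_mean")
  expect_error(sim_config(chrom_length = 100), "chrom_length")
  expect_error(sim_config(read_error_rate = 0.2), "read_error_rate")
})

test_that("planting an empty event list is a no-op", {
  cfg <- tiny_config(seed = 3L, chrom_length = 20000L)
  ind <- tetraploid_individual(generate_ancestral_pair(cfg))
  ind2 <- plant_events(ind, he_events("C01", 0, 10, "A_replaces_C")[0L, ])
  expect_identical(ind2$haplotypes, ind$haplotypes)
  expect_equal(nrow(ind2$truth), 0L)
})

test_that("dosage arithmetic: copies altered per event class", {
  cfg <- tiny_config(seed = 4L, chrom_length = 50000L)
  pair <- generate_ancestral_pair(cfg)
  ind0 <- tetraploid_individual(pair)
  altered <- function(ind) {
    names(which(vapply(names(ind$haplotypes), function(h)
      !identical(ind$haplotypes[[h]], ind0$haplotypes[[h]]), logical(1L))))
  }
  partial <- plant_events(ind0, he_events("C01", 10000, 20000,
                                          "A_replaces_C", "partial"))
  expect_identical(altered(partial), "C1")
  complete <- plant_events(ind0, he_events("C01", 10000, 20000,
                                           "A_replaces_C", "complete"))
  expect_identical(altered(complete), c("C1", "C2"))
  recip <- plant_events(ind0, he_events("A01", 10000, 20000,
                                        "C_replaces_A", "partial",
                                        reciprocity = "reciprocal"))
  expect_setequal(altered(recip), c("A1", "C1"))
  recip2 <- plant_events(ind0, he_events("C01", 10000, 20000,
                                         "A_replaces_C", "complete",
                                         reciprocity = "reciprocal"))
  expect_setequal(altered(recip2), c("A1", "A2", "C1", "C2"))
  # substitution-only model conserves haplotype lengths
  expect_identical(lapply(recip2$haplotypes, nchar),
                   lapply(ind0$haplotypes, nchar))
})

test_that("a complete conversion erases divergence over the interval", {
  cfg <- tiny_config(seed = 6L, chrom_length = 100000L)
  pair <- generate_ancestral_pair(cfg)
  ind <- plant_events(tetraploid_individual(pair),
                      he_events("C01", 20000, 70000, "A_replaces_C",
                                "complete"))
  seg_c <- substr(ind$haplotypes$C1[["C01"]], 20001, 70000)
  seg_a <- substr(pair$a$seq[["A01"]], 20001, 70000)
  expect_identical(seg_c, seg_a)
  expect_identical(ind$haplotypes$C1[["C01"]], ind$haplotypes$C2[["C01"]])
  # one partial event leaves the other copy untouched
  part <- plant_events(tetraploid_individual(pair),
                       he_events("C01", 20000, 70000, "A_replaces_C",
                                 "partial"))
  expect_identical(part$haplotypes$C2[["C01"]],
                   tetraploid_individual(pair)$haplotypes$C2[["C01"]])
})

test_that("overlapping or out-of-bounds events are rejected", {
  cfg <- tiny_config(seed = 7L, chrom_length = 30000L)
  ind <- tetraploid_individual(generate_ancestral_pair(cfg))
  expect_error(plant_events(ind, he_events(c("C01", "C01"), c(1000, 5000),
                                           c(6000, 9000),
                                           "A_replaces_C")),
               "overlapping")
  expect_error(plant_events(ind, he_events("C01", 25000, 35000,
                                           "A_replaces_C")),
               "outside")
  expect_error(plant_events(ind, he_events("A01", 0, 1000, "A_replaces_C")),
               "recipient")
})

test_that("read count, pairing and error-free fidelity match the model", {
  cfg <- tiny_config(seed = 8L, chrom_length = 100000L, depth = 10,
                     error = 0)
  pair <- generate_ancestral_pair(cfg)
  ind <- tetraploid_individual(pair)
  reads <- simulate_reads(ind, cfg)
  haploid <- 2 * 100000
  expect_lt(abs(length(reads$id) - 10 * haploid / (2 * 150)) /
              (10 * haploid / (2 * 150)), 0.01)
  # every error-free read substring-matches its origin haplotype
  idx <- seq(1L, length(reads$id), by = 37L)
  for (i in idx) {
    tr <- reads$truth[i, ]
    hap <- ind$haplotypes[[tr$haplotype]][[tr$chrom]]
    expect_identical(reads$read1[i],
                     substr(hap, tr$frag_start + 1L, tr$frag_start + 150L))
    expect_identical(revcomp(reads$read2[i]),
                     substr(hap, tr$frag_end - 150L + 1L, tr$frag_end))
  }
  # seeded determinism extends to the FASTQ bytes
  reads2 <- simulate_reads(ind, cfg)
  expect_identical(reads$read1, reads2$read1)
  f1 <- tempfile(); f2 <- tempfile()
  write_fastq(reads, f1); write_fastq(reads2, f2)
  expect_identical(unname(tools::md5sum(paste0(f1, "_1.fastq"))),
                   unname(tools::md5sum(paste0(f2, "_1.fastq"))))
  unlink(c(paste0(f1, c("_1", "_2"), ".fastq"),
           paste0(f2, c("_1", "_2"), ".fastq")))
})

test_that("read errors land at the configured rate", {
  cfg <- tiny_config(seed = 12L, chrom_length = 60000L, depth = 5,
                     error = 0.01)
  pair <- generate_ancestral_pair(cfg)
  ind <- tetraploid_individual(pair)
  reads <- simulate_reads(ind, cfg)
  nm <- 0L; tot <- 0L
  for (i in seq(1L, length(reads$id), by = 11L)) {
    tr <- reads$truth[i, ]
    hap <- ind$haplotypes[[tr$haplotype]][[tr$chrom]]
    ref <- substr(hap, tr$frag_start + 1L, tr$frag_start + 150L)
    nm <- nm + sum(strsplit(reads$read1[i], "")[[1L]] !=
                     strsplit(ref, "")[[1L]])
    tot <- tot + 150L
  }
  expect_lt(abs(nm / tot - 0.01), 0.005)
})

test_that("truth BED round-trips, including the empty case", {
  cfg <- tiny_config(seed = 10L, chrom_length = 30000L)
  ind <- tetraploid_individual(generate_ancestral_pair(cfg))
  planted <- plant_events(ind, he_events(
    chrom = c("C01", "A01"), start = c(5000, 12000), end = c(9000, 15000),
    direction = c("A_replaces_C", "C_replaces_A"),
    dosage = c("partial", "complete"),
    reciprocity = c("nonreciprocal", "reciprocal")))
  path <- tempfile(fileext = ".bed")
  write_truth_bed(planted, path)
  back <- read_truth_bed(path)
  expect_equal(nrow(back), 3L)  # reciprocal contributes the donor-side record
  expect_equal(back$chrom, planted$truth$chrom)
  expect_equal(back$start, planted$truth$start)
  expect_equal(back$end, planted$truth$end)
  expect_equal(back$direction, planted$truth$direction)
  write_truth_bed(ind, path)
  empty <- read_truth_bed(path)
  expect_equal(nrow(empty), 0L)
  expect_true(startsWith(readLines(path)[1L], "#"))
  unlink(path)
})
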