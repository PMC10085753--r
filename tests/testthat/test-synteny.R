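# synteny-based HE calling: ancestral build, trusted regions, candidates,
# filters, merging

test_that("ancestral genome is the labeled concatenation of both parents", {
  a <- labeled_genome(c(A01 = "ACGTACGTACGTACGT", A02 = "TTTTCCCCGGGGAAAA"))
  c2 <- labeled_genome(c(C01 = "ACGAACGAACGAACGA", C02 = "TTTACCCAGGGTAAAC"))
  anc <- build_ancestral(a, c2)
  expect_equal(length(anc$seq), 4L)
  expect_equal(unname(anc$subgenome), c("A", "A", "C", "C"))
  expect_equal(sum(nchar(anc$seq)), sum(nchar(a$seq)) + sum(nchar(c2$seq)))
  expect_error(build_ancestral(a, labeled_genome(c(A01 = "ACGT"))),
               "collision")
})

test_that("trusted regions cover nearly all of a 5%-diverged chromosome", {
  cfg <- tiny_config(seed = 201L, chrom_length = 300000L, divergence = 0.05)
  pair <- generate_ancestral_pair(cfg)
  tr <- find_trusted_regions(pair$a, pair$c)
  expect_gte(sum(tr$a_end - tr$a_start) / 300000, 0.95)
  expect_true(all(tr$identity > 0.85))
})

test_that("divergence past the identity threshold yields no trusted regions", {
  cfg <- tiny_config(seed = 202L, chrom_length = 100000L, divergence = 0.20)
  pair <- generate_ancestral_pair(cfg)
  expect_equal(nrow(find_trusted_regions(pair$a, pair$c)), 0L)
})

test_that("short high-identity blocks fail the trusted length threshold", {
  set.seed(203)
  block <- random_dna(900L)
  a <- labeled_genome(c(A01 = block))
  c2 <- labeled_genome(c(C01 = block))
  expect_equal(nrow(find_trusted_regions(a, c2)), 0L)
  # the same block at > 1 kb passes
  block2 <- random_dna(1200L)
  tr <- find_trusted_regions(labeled_genome(c(A01 = block2)),
                             labeled_genome(c(C01 = block2)))
  expect_equal(nrow(tr), 1L)
})

test_that("an assembly identical to the ancestral genome yields no candidates", {
  cfg <- tiny_config(seed = 204L, chrom_length = 100000L)
  pair <- generate_ancestral_pair(cfg)
  ind <- tetraploid_individual(pair)
  anc <- build_ancestral(pair$a, pair$c)
  expect_equal(nrow(call_candidate_he(ind$assembly, anc)), 0L)
})

test_that("planted conversions surface as direction-correct candidates", {
  cfg <- tiny_config(seed = 205L, chrom_length = 200000L)
  pair <- generate_ancestral_pair(cfg)
  anc <- build_ancestral(pair$a, pair$c)
  ind <- plant_events(tetraploid_individual(pair),
                      he_events("C01", 60000, 110000, "A_replaces_C",
                                "complete"))
  cand <- call_candidate_he(ind$assembly, anc)
  expect_gte(nrow(cand), 1L)
  hit <- cand[cand$assembly_seq == "C01" &
                cand$assembly_start < 110000 & cand$assembly_end > 60000, ]
  expect_gte(nrow(hit), 1L)
  expect_equal(hit$assembly_subgenome, "C")
  expect_equal(hit$ancestral_subgenome, "A")

  recip <- plant_events(tetraploid_individual(pair),
                        he_events("C01", 60000, 110000, "A_replaces_C",
                                  "partial", reciprocity = "reciprocal"))
  cand2 <- call_candidate_he(recip$assembly, anc)
  dirs <- paste0(cand2$ancestral_subgenome, ">", cand2$assembly_subgenome)
  expect_setequal(unique(dirs), c("A>C", "C>A"))
})

test_that("candidate filters apply the printed thresholds strictly", {
  cand <- data.frame(assembly_seq = "C01", assembly_start = 0L,
                     assembly_end = c(5000L, 5000L, 100L, 5000L),
                     assembly_subgenome = "C", ancestral_seq = "A01",
                     ancestral_start = 0L,
                     ancestral_end = c(5000L, 5000L, 100L, 5000L),
                     ancestral_subgenome = "A", strand = "+",
                     identity = c(0.95, 0.90, 0.95, 0.95),
                     length = c(5000L, 5000L, 100L, 5000L),
                     passed_trusted = NA, stringsAsFactors = FALSE)
  trusted <- data.frame(a_chrom = "A01", a_start = 0L, a_end = 10000L,
                        c_chrom = "C01", c_start = 0L, c_end = 10000L,
                        identity = 0.95, stringsAsFactors = FALSE)
  # row 2: identity exactly 0.90 -> removed; row 3: length exactly 100 -> removed
  kept <- filter_candidates(cand, trusted)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$identity > 0.90 & kept$length > 100))
  expect_true(all(kept$passed_trusted))
  # a candidate overlapping no trusted region is removed regardless of identity
  far <- cand[1L, ]; far$ancestral_start <- 50000L; far$ancestral_end <- 55000L
  expect_equal(nrow(filter_candidates(far, trusted)), 0L)
  # 1 bp of overlap suffices
  edge <- cand[1L, ]; edge$ancestral_start <- 9999L; edge$ancestral_end <- 15000L
  expect_equal(nrow(filter_candidates(edge, trusted)), 1L)
})

test_that("filtering is monotone in the identity threshold", {
  set.seed(206)
  cand <- data.frame(assembly_seq = "C01",
                     assembly_start = seq(0L, 19000L, by = 1000L),
                     assembly_end = seq(500L, 19500L, by = 1000L),
                     assembly_subgenome = "C", ancestral_seq = "A01",
                     ancestral_start = seq(0L, 19000L, by = 1000L),
                     ancestral_end = seq(500L, 19500L, by = 1000L),
                     ancestral_subgenome = "A", strand = "+",
                     identity = runif(20, 0.85, 1),
                     length = 500L, passed_trusted = NA,
                     stringsAsFactors = FALSE)
  trusted <- data.frame(a_chrom = "A01", a_start = 0L, a_end = 20000L,
                        c_chrom = "C01", c_start = 0L, c_end = 20000L,
                        identity = 0.95, stringsAsFactors = FALSE)
  prev <- filter_candidates(cand, trusted, min_identity = 0.86,
                            min_length = 100L)
  for (thr in c(0.90, 0.94, 0.98)) {
    cur <- filter_candidates(cand, trusted, min_identity = thr,
                             min_length = 100L)
    expect_true(all(cur$assembly_start %in% prev$assembly_start))
    prev <- cur
  }
})

test_that("merging joins same-direction neighbours and is idempotent", {
  base <- data.frame(assembly_seq = "C01",
                     assembly_start = c(0L, 6000L, 20000L),
                     assembly_end = c(5000L, 11000L, 25000L),
                     assembly_subgenome = "C", ancestral_seq = "A01",
                     ancestral_start = c(0L, 6000L, 20000L),
                     ancestral_end = c(5000L, 11000L, 25000L),
                     ancestral_subgenome = "A", strand = "+",
                     identity = c(0.95, 0.99, 0.97),
                     length = c(5000L, 5000L, 5000L),
                     passed_trusted = TRUE, stringsAsFactors = FALSE)
  m <- merge_he_regions(base, max_gap = 5000L)
  expect_equal(nrow(m), 2L)
  expect_equal(m$assembly_start[1L], 0L)
  expect_equal(m$assembly_end[1L], 11000L)
  expect_equal(m$identity[1L], (0.95 * 5000 + 0.99 * 5000) / 10000)
  expect_identical(merge_he_regions(m, max_gap = 5000L), m)
  # opposite directions never merge
  mixed <- base[1:2, ]
  mixed$assembly_subgenome[2L] <- "A"
  mixed$ancestral_subgenome[2L] <- "C"
  expect_equal(nrow(merge_he_regions(mixed, max_gap = 5000L)), 2L)
})

test_that("calling is label-symmetric under an A/C swap", {
  cfg <- tiny_config(seed = 207L, chrom_length = 120000L)
  pair <- generate_ancestral_pair(cfg)
  ind <- plant_events(tetraploid_individual(pair),
                      he_events("C01", 30000, 80000, "A_replaces_C",
                                "complete"))
  anc <- build_ancestral(pair$a, pair$c)
  cand <- call_candidate_he(ind$assembly, anc)

  relabel <- function(g) labeled_genome(
    g$seq, subgenome = ifelse(g$subgenome == "A", "C", "A"))
  cand_sw <- call_candidate_he(relabel(ind$assembly), relabel(anc))
  expect_equal(cand_sw$assembly_seq, cand$assembly_seq)
  expect_equal(cand_sw$assembly_start, cand$assembly_start)
  expect_equal(cand_sw$assembly_subgenome,
               ifelse(cand$assembly_subgenome == "A", "C", "A"))
  expect_equal(cand_sw$ancestral_subgenome,
               ifelse(cand$ancestral_subgenome == "A", "C", "A"))
})

test_that("filtered regions satisfy their invariants on planted data", {
  cfg <- tiny_config(seed = 208L, chrom_length = 200000L)
  pair <- generate_ancestral_pair(cfg)
  ind <- plant_events(tetraploid_individual(pair),
                      he_events(c("C01", "A01"), c(50000L, 120000L),
                                c(90000L, 150000L),
                                c("A_replaces_C", "C_replaces_A"),
                                c("complete", "partial")))
  res <- call_he(ind$assembly, pair$a, pair$c)
  r <- res$regions
  expect_true(all(r$assembly_subgenome != r$ancestral_subgenome))
  expect_true(all(r$identity > 0.90))
  expect_true(all(r$length > 100))
  expect_true(all(r$passed_trusted))
  expect_equal(r$length, r$assembly_end - r$assembly_start)
  acc <- evaluate_he_calls(r, ind$truth)
  expect_gte(acc$sensitivity, 0.90)
  expect_gte(acc$precision, 0.90)
})

test_that("HE region TSV and BED outputs round-trip/parse", {
  r <- data.frame(assembly_seq = "C01", assembly_start = 100L,
                  assembly_end = 5000L, assembly_subgenome = "C",
                  ancestral_seq = "A01", ancestral_start = 100L,
                  ancestral_end = 5000L, ancestral_subgenome = "A",
                  strand = "+", identity = 0.987, length = 4900L,
                  passed_trusted = TRUE, stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv"); bed <- tempfile(fileext = ".bed")
  write_he_tsv(r, tsv)
  expect_equal(read_he_tsv(tsv)$assembly_end, 5000L)
  write_he_bed(r, bed)
  lines <- readLines(bed)
  expect_true(startsWith(lines[1L], "#"))
  expect_match(lines[2L], "^C01\t100\t5000\tA>C\t987\t\\+$")
  unlink(c(tsv, bed))
})
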