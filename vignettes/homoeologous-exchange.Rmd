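---
title: "Detecting homoeologous exchange in allotetraploid genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting homoeologous exchange in allotetraploid genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

An allotetraploid such as *Brassica napus* carries two complete diploid
subgenomes (A, from *B. rapa*; C, from *B. oleracea*). Because the two
subgenomes are highly similar, recombination occasionally pairs a chromosome
with its homoeolog instead of its homolog and copies a segment from one
subgenome over the corresponding segment of the other. This *homoeologous
exchange* (HE) changes gene copy number: with four homologous copies of any
region (two per subgenome), the A:C homoeolog ratio can move from the
balanced 2:2 to 3:1 (a *partial* conversion, one copy replaced), to 4:0
(*complete*, both copies replaced), or stay 2:2 while swapping content (a
*reciprocal* exchange).

`hexfinder` detects HE with the two complementary analyses used in practice:

1. **Synteny**: align the tetraploid assembly to an *in silico "ancestral"
   genome* — the concatenation of the two diploid parent genomes — and flag
   assembly regions whose best hit lies on the *other* subgenome.
2. **Read coverage (dosage)**: map short reads to a reference, compute
   normalized windowed coverage, and read copy-number departures off the
   scale on which balanced regions sit at 1: partial conversions read ~0.5
   (lost side) and ~1.5 (gained side), complete conversions ~0 and ~2.

Because real allotetraploid assemblies are large and their true exchange
history is unknown, the package also ships a simulator that generates the
whole study scenario with *planted, known* events, so every stage can be
tested against exact ground truth.

## The simulator

`generate_ancestral_pair()` draws an A-parent genome by i.i.d. base sampling
(default GC fraction 0.37, a typical plant nuclear value; recorded for
reproducibility, nothing downstream depends on it) and derives the C parent
by i.i.d. substitutions at the configured `homoeolog_divergence`.

The model is **substitution-only**: no indels, no transposons, no
rearrangements. This is a deliberate trade — the homology map between
subgenomes becomes the identity map on coordinates, so every downstream
expectation (mismatch counts, interval overlaps, dosage fractions) is exactly
computable, and tests can be exact rather than fuzzy. The price is realism:
the simulator does not produce assembly gaps, repeat families, collapsed
centromeres or length variation, so passing tests demonstrate correctness of
the *method logic*, not robustness to the full messiness of real assemblies
(see *Limitations*).

Key defaults and why:

* `homoeolog_divergence = 0.05`. The analysis thresholds of record are 85%
  identity for trusted syntenic blocks and 90% for exchange candidates; 5%
  divergence places simulated homoeologs between those two cut-offs, which is
  the regime the method is designed for. It is a free parameter and all
  thresholds are config-exposed.
* `read_length = 150`, Gaussian fragments of 400 ± 50 bp: ordinary modern
  short-read libraries.
* `depth = 30` — fold coverage of the *haploid subgenome complement* (one A
  plus one C chromosome set). The number of fragments is
  `depth * L / (2 * read_length)`, so total read bases equal `depth * L`;
  each of the four haplotypes then receives `depth / 4`, and a locus of a
  balanced region collects `depth / 2` per subgenome chromosome.
* `read_error_rate = 0.001` substitutions per base; base qualities are
  written as a uniform `I` because no downstream stage consumes them.
* Heterozygosity between homologous copies (A1 vs A2) is fixed at zero: the
  emulated material is a line inbred by repeated self-fertilization.

`tetraploid_individual()` holds four haplotypes (A1, A2, C1, C2) and a
collapsed assembly that takes A1 and C1 *verbatim* — the haploid-collapsed
representation an assembler produces. `plant_events()` overwrites recipient
intervals with the ancestral donor segment on one copy (`partial`, the
`copy` field selects which, so an event can be present in or absent from the
assembly) or both (`complete`); `reciprocal` events also write the recipient
segment back into the donor subgenome. Donor sequence is taken from the
stored ancestral genomes, which makes planting deterministic and
order-independent; total haplotype length is conserved.

## The built-in aligner

Whole-genome alignment is provided by exact k-mer anchoring and collinear
chaining, with PAF import/export so an external aligner can be substituted
for real data.

* **Anchors are k-mers unique in the target genome** (default k = 15). This
  is the crucial design choice, in the spirit of the unique-match seeding of
  the MUMmer family: k-mers conserved between the two homoeologs occur twice
  in the ancestral target and are never anchors, so an assembly segment
  anchors only to the subgenome it actually came from, and alignment chains
  *break* at exchange junctions instead of bridging them.
* Anchor runs on one diagonal are chained while gaps stay below
  `max_chain_gap` (default 10 kb). A chain must contain at least one exact
  run of `min_anchor_run` = 31 bases, which suppresses chance collisions
  between unrelated regions. Chains are gap-free (the substitution-only
  model needs no gapped extension); `matches` and `identity` come from
  direct base comparison of the chained spans. A consequence of the 10 kb
  chain gap is that *exchanged segments shorter than the gap can be bridged
  and absorbed* by the flanking same-subgenome chain; events comfortably
  above 10 kb are unaffected (see *Limitations*).
* PAF ingestion recomputes identity as `matches / block_length` and feeds
  the same downstream machinery.

### One-best-alignment filtering

`best_hit_filter()` reproduces 1-to-1 filtering: it returns the
maximum-total-score subset of records in which no two records overlap on the
query axis and no two overlap on the target axis. The optimum is computed
exactly per connected component of the conflict graph (branch-and-bound,
with a greedy fallback above 24 records per component that synthetic data
never reaches); ties prefer lower target, then query, start.

Two deliberate departures from a strict global 1-to-1 apply **only inside
candidate exchange calling** (`call_candidate_he()`):

* **Query-axis uniqueness** (`axis = "query"`). Under a both-axes filter the
  donor chromosome's own full-length alignment and an exchanged segment's
  alignment always claim the same ancestral territory, and the former always
  carries the higher total score — a global 1-to-1 would therefore discard
  *every* exchange candidate. Candidate calling asks the literal question
  "what is this assembly region's highest hit in the ancestral genome?",
  which is per-query-location best-hit filtering; the reference side is
  intentionally allowed to serve both its own chromosome and an exchanged
  segment.
* **A 200 bp overlap tolerance** (`overlap_tol`). Exchange junction bases
  are usually conserved between homoeologs, so chains on both sides run a
  geometric-tail handful of bases past the junction; flanking and exchanged
  records then overlap by ~5–30 bp. With zero tolerance that tiny overlap
  lets the flanking chain displace the whole candidate. At 5% divergence the
  probability of a conserved run reaching 200 bp is ~3 × 10⁻⁵, so the
  tolerance forgives junction slippage while genuine conflicts — which
  overlap by entire block lengths — still conflict. Both knobs are exposed.

## Synteny-based HE calling

`call_he()` chains the stages exactly in pipeline order:

1. `find_trusted_regions()`: align A parent to C parent, 1-to-1 filter, keep
   blocks with identity > 0.85 over > 1,000 bp (strict inequalities, as all
   thresholds here). These mark reliably homoeologous territory.
2. `build_ancestral()`: concatenate the parents; subgenome labels ride on
   sequence names (leading `A`/`C` after an optional `chr` prefix) or an
   explicit label vector.
3. `call_candidate_he()`: align assembly to ancestral, query-axis best hits,
   keep records whose assembly-side label differs from the ancestral-side
   label.
4. `filter_candidates()`: identity > 0.90, assembly-axis length > 100 bp,
   and at least 1 bp of ancestral-axis overlap with a trusted region. The
   1 bp operationalization is the strictest literal reading of "overlap";
   the length is measured on the assembly axis (the two axes agree under
   the gap-free model).
5. `merge_he_regions()`: same-direction regions on one assembly sequence
   within 5 kb merge; merged identity is the length-weighted mean. The
   merge rule is this package's own plumbing (region reporting needs one),
   and it is idempotent.

`evaluate_he_calls()` scores calls against a truth set by bp-weighted
interval intersection. On the canonical scenario (2 × 2 Mb chromosomes per
subgenome, 5% divergence, six planted events of 5–100 kb) the caller runs at
≥ 0.98 sensitivity and ~1.0 precision; the only systematic loss is an event
below the 10 kb chain gap, absorbed as described above.

## Coverage dosage analysis

The coverage branch consumes read alignments (SAM or the in-package
emulated mapper, which places each simulated read at its true coordinate
and at the homoeologous coordinate and keeps the lower-mismatch site):

1. `select_diagnostic_reads()` keeps reads attributable to one subgenome
   from their ancestral mapping: MAPQ ≥ 5 (inclusive), properly paired,
   primary, and no supplementary alignment anywhere for that read.
2. `accumulate_depth()` adds 1 per primary alignment interval, plus 1 per
   XA-style alternate site whose edit distance is ≤ the primary's — the
   alternate-aware rule that keeps near-identical homoeologous placements
   from deflating coverage. Alternates carry no CIGAR, so their interval
   length is taken as the primary's aligned length.
3. `windowed_median()`: median per-base depth in 100 kb windows at 20 kb
   step (median, not mean, so short dropouts and spikes inside a window do
   not move it). Per-base depth is used as the window statistic.
4. `mask_and_normalize()`: windows at ≥ 10× their chromosome's mean window
   median are masked (collapsed-repeat/centromere signature; windows are
   the masking unit), then all windows are divided by the genome-wide mean
   of unmasked window medians — mask first, then standardize, so the mean
   of unmasked normalized values is exactly 1.
5. `classify_dosage()` snaps a region's mean normalized depth (over
   unmasked overlapping windows) to the nearest of {0, 0.5, 1, 1.5, 2},
   ties rounding toward 1 (the minimal-assumption reading of "~0.5" etc.;
   midpoints 0.25/0.75/1.25/1.75 are therefore the effective class
   boundaries). Note that any-overlap window selection dilutes the mean
   when the region is not much larger than the window; for read-outs of
   individual known regions, `region_depth_summary()` with contained
   windows is the sharper instrument and is what the acceptance analysis
   reports.

On the canonical simulation, a planted partial conversion reads 0.50 / 1.51
(lost / gained side) and a complete conversion 0.00 / 2.01 — the 2:2 → 3:1
→ 4:0 dosage ladder on the normalized scale.

## Cross-genome comparison

`project_to_ancestral()` merges each genome's HE calls into a disjoint
interval set on the ancestral coordinate frame — the only frame all
varieties share, and this package's explicit choice of comparison frame.
`intersect_all()` computes the bp-level k-way intersection (maximal
contiguous shared runs counted as regions); `pairwise_sharing_matrix()`
normalizes pairwise shared bases by the smaller of the two totals, so a
nested set scores 1. The null for "how much k-way sharing would chance
give?" is per-base independence: `expected_shared_bp()` returns
`L × ∏ pᵢ` from the per-genome proportions. A seeded Monte-Carlo placement
oracle (random re-placement of each set's intervals, preserving widths)
backs this closed form in the tests rather than serving as the headline
statistic. With ten genomes at ~3% exchanged territory each, the
expectation on a 1 Gb genome is ~6 × 10⁻⁷ bp — effectively zero shared
bases by chance, which is why observed recurrent regions indicate exchange
hotspots.

## Numerical and engineering choices

* Coordinates are 0-based half-open everywhere internally (PAF and BED
  already are; SAM's 1-based positions are converted at the boundary).
* All randomness flows from explicit integer seeds; identical configuration
  gives byte-identical FASTA/FASTQ/BED/SAM outputs.
* Degenerate inputs fail loudly: empty genomes, unlabeled sequences,
  overlapping events, all-masked window sets and malformed PAF/SAM/BED
  lines raise errors naming the offender.
* Problem sizes in the shipped tests: the end-to-end blocks use two 2 Mb
  chromosomes per subgenome with 30× reads (≈ 800,000 read pairs), the
  property suites use 10²–10⁵ bp toys with exhaustive or per-base oracles.
  These sizes exercise every window/step/masking code path at full
  parameter defaults while keeping the whole suite in the minutes range.

## Limitations

* No indels, repeats, aneuploidy or assembly error in the simulator; real
  data will add alignment fragmentation and coverage artifacts the tests do
  not emulate. The PAF and SAM bridges exist precisely so real aligner
  output can be substituted.
* Exchanged segments shorter than `max_chain_gap` (10 kb default) can be
  absorbed by flanking chains in the synteny branch; lower the gap for
  fine-scale work (at the cost of fragmenting chains across sparse-anchor
  stretches). Gene-conversion-scale events (< 100 bp) are out of scope by
  the candidate length filter.
* The dosage classifier assumes the five-anchor copy-number ladder; it will
  misread aneuploidy or segmental duplication, which move coverage without
  homoeologous exchange — the synteny branch is the disambiguator.
* `classify_dosage()` means over any-overlap windows; regions near the
  window size are diluted toward 1 (see above).
* The emulated mapper assigns MAPQ from the mismatch separation of the two
  homoeologous placements only; it reproduces the diagnostic-read logic on
  simulated data but is not a general-purpose aligner.
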