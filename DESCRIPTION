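Package: hexfinder
Title: Detection of Homoeologous Exchange in Allopolyploid Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homoeologous exchange (HE) between the subgenomes of an
    allotetraploid from a genome assembly and short-read data. Implements
    synteny-based HE calling against an in silico "ancestral" genome built by
    concatenating the two diploid parent genomes (trusted syntenic regions,
    subgenome-discordant best hits, identity/length/overlap filters), a
    read-coverage dosage analysis (diagnostic-read selection, alternate-hit
    aware depth, 100 kb/20 kb windowed medians, repeat masking, genome-average
    normalization, 2:2/3:1/4:0 homoeolog-ratio classification), and
    cross-variety shared-region statistics with an independence null. Ships a
    seeded simulator of diverged ancestral diploids, haplotype-resolved
    allotetraploid individuals with planted exchange events, and paired-end
    reads with machine-readable truth sets, so the whole pipeline is testable
    end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
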