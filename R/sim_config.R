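#' Simulation configuration
#'
#' Free parameters of the allotetraploid simulator. Defaults describe the
#' canonical study conditions used throughout the package's tests: two 2 Mb
#' chromosomes per subgenome, 5% homoeolog divergence (between the paper-style
#' 85% trusted-region and 90% candidate identity cut-offs), 150 bp paired-end
#' reads at 30-fold coverage of the haploid subgenome complement.
#'
#' @param seed Integer seed; every stochastic operation derives its stream
#'   from it.
#' @param n_chrom_per_subgenome Number of chromosomes per subgenome (>= 1).
#' @param chrom_length Chromosome length in bp.
#' @param homoeolog_divergence Per-base substitution fraction between A and C
#'   homoeologs, in \[0, 0.3\].
#' @param gc_content GC fraction of the generated sequences, in (0, 1).
#' @param read_length Read length in bp.
#' @param fragment_mean,fragment_sd Mean and SD of the sequencing fragment
#'   length in bp; `fragment_mean >= 2 * read_length` is required.
#' @param depth Fold-coverage of the haploid subgenome complement (one A plus
#'   one C chromosome set).
#' @param read_error_rate Per-base substitution error rate in reads, in
#'   \[0, 0.05\].
#' @return An object of class `sim_config` (validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_chrom_per_subgenome = 2L,
                       chrom_length = 2e6,
                       homoeolog_divergence = 0.05,
                       gc_content = 0.37,
                       read_length = 150L,
                       fragment_mean = 400L,
                       fragment_sd = 50L,
                       depth = 30,
                       read_error_rate = 0.001) {
  cfg <- list(seed = as.integer(seed),
              n_chrom_per_subgenome = as.integer(n_chrom_per_subgenome),
              chrom_length = as.integer(chrom_length),
              homoeolog_divergence = as.numeric(homoeolog_divergence),
              gc_content = as.numeric(gc_content),
              read_length = as.integer(read_length),
              fragment_mean = as.integer(fragment_mean),
              fragment_sd = as.numeric(fragment_sd),
              depth = as.numeric(depth),
              read_error_rate = as.numeric(read_error_rate))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) stop("invalid sim_config field '", field, "': ", msg,
                          call. = FALSE)
  }
  chk(is.finite(cfg$seed), "seed", "must be a finite integer")
  chk(cfg$n_chrom_per_subgenome >= 1L, "n_chrom_per_subgenome", "must be >= 1")
  chk(cfg$homoeolog_divergence >= 0 && cfg$homoeolog_divergence <= 0.3,
      "homoeolog_divergence", "must be in [0, 0.3]")
  chk(cfg$gc_content > 0 && cfg$gc_content < 1, "gc_content",
      "must be in (0, 1)")
  chk(cfg$read_length >= 1L, "read_length", "must be positive")
  chk(cfg$fragment_mean >= 2L * cfg$read_length, "fragment_mean",
      "must be >= 2 * read_length")
  chk(cfg$chrom_length >= 10L * cfg$fragment_mean, "chrom_length",
      "must be >= 10 * fragment_mean")
  chk(cfg$fragment_sd >= 0, "fragment_sd", "must be >= 0")
  chk(cfg$depth > 0, "depth", "must be > 0")
  chk(cfg$read_error_rate >= 0 && cfg$read_error_rate <= 0.05,
      "read_error_rate", "must be in [0, 0.05]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
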