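# Shared fixtures, built once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fixture_env)) assign(name, builder(), .fixture_env)
  get(name, .fixture_env)
}

# A compact synthetic experiment: fast enough for module-level tests.
mini_config <- function(seed = 42) {
  srnaforge::sim_config(
    n_chromosomes = 2, chrom_length = 120000, n_mirna_loci = 12,
    n_clustered = 4, n_mirtrons = 2, n_multicopy = 1, n_known = 4,
    n_conserved_novel = 3, n_decoys = 4, mean_depth = 8000, seed = seed)
}

mini_sim <- function() {
  fixture("mini_sim", function() {
    srnaforge::simulate_srna_experiment(mini_config())
  })
}

mini_run <- function() {
  fixture("mini_run", function() {
    sim <- mini_sim()
    dir <- file.path(tempdir(), "srnaforge_mini")
    srnaforge::write_simdata(sim, dir)
    cfg <- srnaforge::pipeline_config(
      genome = file.path(dir, "genome.fa"),
      annotation = file.path(dir, "annotation.gff3"),
      reads_f3 = file.path(dir, "reads_F3.fastq"),
      reads_f4 = file.path(dir, "reads_F4.fastq"),
      ortholog_mature = file.path(dir, "ortholog_mature.fa"))
    res <- suppressWarnings(
      srnaforge::run_pipeline(cfg, file.path(dir, "out")))
    list(sim = sim, res = res, dir = dir, cfg = cfg)
  })
}

# The default-scale study conditions (~2 Mb genome, ~100 hairpin loci,
# ~200k reads over two libraries): used by the acceptance tests.
default_run <- function() {
  fixture("default_run", function() {
    sim <- srnaforge::simulate_srna_experiment(srnaforge::sim_config(seed = 1))
    dir <- file.path(tempdir(), "srnaforge_default")
    srnaforge::write_simdata(sim, dir)
    cfg <- srnaforge::pipeline_config(
      genome = file.path(dir, "genome.fa"),
      annotation = file.path(dir, "annotation.gff3"),
      reads_f3 = file.path(dir, "reads_F3.fastq"),
      reads_f4 = file.path(dir, "reads_F4.fastq"),
      ortholog_mature = file.path(dir, "ortholog_mature.fa"))
    res <- suppressWarnings(
      srnaforge::run_pipeline(cfg, file.path(dir, "out")))
    list(sim = sim, res = res, dir = dir)
  })
}

# A tiny two-chromosome genome with a planted perfect hairpin, for
# alignment and window tests.
toy_genome <- function(seed = 5, len = 2000) {
  set.seed(seed)
  g <- vapply(1:2, function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  names(g) <- c("Chr1", "Chr2")
  g
}

as_dss <- function(chars) {
  x <- Biostrings::DNAStringSet(chars)
  names(x) <- names(chars)
  x
}

# Plant `seq` at 1-based `pos` on chromosome `chrom` of a character genome.
plant_seq <- function(genome_chars, chrom, pos, seq) {
  g <- genome_chars[[chrom]]
  substr(g, pos, pos + nchar(seq) - 1) <- seq
  genome_chars[[chrom]] <- g
  genome_chars
}

# A GC-rich perfect hairpin: arm + AU loop + reverse complement of the arm.
perfect_hairpin <- function(arm_len = 22, loop_len = 10, seed = 3) {
  set.seed(seed)
  arm <- paste(sample(c("G", "C", "A", "T"), arm_len, TRUE,
                      prob = c(.35, .35, .15, .15)), collapse = "")
  loop <- paste(sample(c("A", "T"), loop_len, TRUE), collapse = "")
  list(arm = arm, loop = loop,
       seq = paste0(arm, loop, .oracle_revcomp(arm)))
}
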