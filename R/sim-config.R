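#' Configuration for the synthetic small RNA experiment
#'
#' Defines the study conditions the generator emulates: a two-library
#' (castrated `F3` vs intact `F4`) small RNA experiment over a compact
#' genome with planted miRNA hairpin loci, isomiR spectra, genomic
#' clusters, mirtrons, multi-copy loci, expressed non-hairpin decoy loci,
#' ncRNA contamination and planted fold changes under Poisson technical
#' noise. Defaults describe a ~2 Mb genome with ~100 hairpin loci and
#' ~200,000 reads across the two libraries.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome (bp).
#' @param n_mirna_loci Number of planted miRNA genes (before multi-copy
#'   duplication).
#' @param n_clustered How many of the loci are planted in clusters with
#'   inter-locus gaps < 10,000 bp (groups of 2-3).
#' @param n_mirtrons How many loci coincide exactly with annotated introns.
#' @param n_multicopy How many genes are planted at two identical loci on
#'   one chromosome.
#' @param n_known How many genes are exported to the known mature/hairpin
#'   reference FASTA and annotated as known.
#' @param n_conserved_novel How many non-known genes are exported, with at
#'   most 2 substitutions, to the ortholog mature FASTA.
#' @param n_decoys Number of expressed non-hairpin decoy loci (planted
#'   negatives for discovery precision).
#' @param frac_de Fraction of miRNA products with a planted fold change.
#' @param fc_magnitude Magnitude of the planted log2 fold change (F3/F4).
#' @param mean_depth Expected reads per library.
#' @param isomir_decay Geometric decay rate of offset-variant abundance; 0
#'   emits only the reference isomiR.
#' @param nta_prob Per-read probability of a 1-nt non-templated 3' A/U
#'   addition.
#' @param contam_frac Fraction of reads drawn from annotated rRNA/tRNA loci.
#' @param star_frac Mean abundance of the star product relative to its
#'   mature.
#' @param adapter 3' adapter sequence ligated to every insert.
#' @param read_length Fixed sequencer read length (nt).
#' @param overdispersion Negative-binomial overdispersion of product
#'   counts; 0 (default) gives pure Poisson noise, matching the
#'   differential-expression test's assumption.
#' @param error_rate Per-read probability of one random substitution
#'   (robustness knob; off by default).
#' @param seed RNG seed; identical configs (including seed) give
#'   byte-identical outputs.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chromosomes = 4, chrom_length = 500000,
                       n_mirna_loci = 100, n_clustered = 12, n_mirtrons = 5,
                       n_multicopy = 4, n_known = 40, n_conserved_novel = 15,
                       n_decoys = 20, frac_de = 0.3, fc_magnitude = 2,
                       mean_depth = 100000, isomir_decay = 0.35,
                       nta_prob = 0.08, contam_frac = 0.05, star_frac = 0.12,
                       adapter = "TCGTATGCCGTCTTCTGCTTG", read_length = 35,
                       overdispersion = 0, error_rate = 0, seed = 1) {
  cfg <- as.list(environment())
  counts <- c("n_chromosomes", "chrom_length", "n_mirna_loci", "n_clustered",
              "n_mirtrons", "n_multicopy", "n_known", "n_conserved_novel",
              "n_decoys", "mean_depth", "read_length")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v))
      stop(f, " must be a non-negative integer count")
  }
  if (cfg$chrom_length <= 0) stop("chrom_length must be positive")
  if (cfg$n_chromosomes <= 0) stop("n_chromosomes must be positive")
  fracs <- c("frac_de", "isomir_decay", "nta_prob", "contam_frac")
  for (f in fracs) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(f, " must be in [0, 1]")
  }
  if (cfg$n_known + cfg$n_conserved_novel > cfg$n_mirna_loci)
    stop("n_known + n_conserved_novel exceeds n_mirna_loci")
  if (cfg$n_clustered + cfg$n_mirtrons + cfg$n_multicopy > cfg$n_mirna_loci)
    stop("special plantings (clustered + mirtrons + multicopy) exceed n_mirna_loci")
  if (cfg$n_clustered == 1) stop("a cluster needs at least 2 loci")
  if (!grepl("^[ACGT]+$", cfg$adapter)) stop("adapter must be ACGT")
  structure(cfg, class = "sim_config")
}
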