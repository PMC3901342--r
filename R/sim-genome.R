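# Interval bookkeeping for non-overlapping feature placement. `occ` is a
# per-chromosome list of IRanges of claimed intervals.

.occ_new <- function(chroms) setNames(rep(list(IRanges::IRanges()), length(chroms)), chroms)

.occ_free <- function(occ, chrom, start, end, gap = 0) {
  q <- IRanges::IRanges(max(1, start - gap), end + gap)
  length(IRanges::findOverlaps(q, occ[[chrom]])) == 0
}

.occ_claim <- function(occ, chrom, start, end) {
  occ[[chrom]] <- c(occ[[chrom]], IRanges::IRanges(start, end))
  occ
}

# Sample a free interval of `len` on a random (or given) chromosome,
# keeping `gap` bp clear on both sides. Errors after bounded retries.
.occ_place <- function(occ, len, chrom_lengths, what, chrom = NULL,
                       gap = 0, tries = 2000) {
  chroms <- names(chrom_lengths)
  for (i in seq_len(tries)) {
    ch <- if (is.null(chrom)) sample(chroms, 1) else chrom
    maxs <- chrom_lengths[[ch]] - len + 1
    if (maxs < 1) next
    s <- sample.int(maxs, 1)
    if (.occ_free(occ, ch, s, s + len - 1, gap))
      return(list(chrom = ch, start = s, end = s + len - 1))
  }
  stop("could not place ", what, " after ", tries,
       " attempts (constraint: length ", len, ", clear gap ", gap, " bp)")
}

.rand_seq <- function(n, probs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(probs), n, replace = TRUE, prob = probs), collapse = "")
}

#' Generate a synthetic genome with gene models and ncRNA annotation
#'
#' Chromosomes are uniform-random sequence. Each chromosome carries
#' protein-coding gene models (exons separated by introns, each gene
#' including one short intron sized 50-61 bp that can host a mirtron) plus
#' scattered rRNA, tRNA and snoRNA features. Planting of miRNA loci happens
#' afterwards in [plant_mirna_loci()].
#'
#' @param config A [sim_config()].
#' @return A list with `genome` (named [Biostrings::DNAStringSet]),
#'   `annotation` (a `GRanges` with columns `type`, `ID`, `Parent`), and
#'   `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- paste0("Chr", seq_len(config$n_chromosomes))
    genome <- Biostrings::DNAStringSet(
      vapply(chroms, function(ch) .rand_seq(config$chrom_length), ""))
    names(genome) <- chroms
    clens <- setNames(rep(config$chrom_length, length(chroms)), chroms)
    occ <- .occ_new(chroms)

    feats <- list()
    add <- function(chrom, start, end, strand, type, id, parent = NA) {
      feats[[length(feats) + 1]] <<- data.frame(
        chrom = chrom, start = start, end = end, strand = strand,
        type = type, ID = id, Parent = parent, stringsAsFactors = FALSE)
    }

    genes_per_chrom <- max(2L, ceiling((config$n_mirtrons + 3) /
                                         config$n_chromosomes) + 3L)
    gi <- 0
    for (ch in chroms) {
      for (g in seq_len(genes_per_chrom)) {
        gi <- gi + 1
        n_exons <- sample(3:4, 1)
        exon_lens <- sample(200:600, n_exons, replace = TRUE)
        intron_lens <- sample(500:2000, n_exons - 1, replace = TRUE)
        # one short, mirtron-sized intron per gene
        intron_lens[sample.int(n_exons - 1, 1)] <- sample(50:61, 1)
        span <- sum(exon_lens) + sum(intron_lens)
        pos <- .occ_place(occ, span, clens, "gene model", chrom = ch,
                          gap = 200)
        occ <- .occ_claim(occ, ch, pos$start, pos$end)
        strand <- sample(c("+", "-"), 1)
        gid <- sprintf("gene%03d", gi)
        add(ch, pos$start, pos$end, strand, "gene", gid)
        at <- pos$start
        for (e in seq_len(n_exons)) {
          add(ch, at, at + exon_lens[e] - 1, strand, "exon",
              sprintf("%s.e%d", gid, e), gid)
          at <- at + exon_lens[e]
          if (e < n_exons) {
            add(ch, at, at + intron_lens[e] - 1, strand, "intron",
                sprintf("%s.i%d", gid, e), gid)
            at <- at + intron_lens[e]
          }
        }
      }
      nc <- list(rRNA = list(6, 100:300), tRNA = list(8, 70:90),
                 snoRNA = list(3, 100:150))
      for (ty in names(nc)) {
        for (k in seq_len(nc[[ty]][[1]])) {
          len <- sample(nc[[ty]][[2]], 1)
          pos <- .occ_place(occ, len, clens, ty, chrom = ch, gap = 100)
          occ <- .occ_claim(occ, ch, pos$start, pos$end)
          add(ch, pos$start, pos$end, sample(c("+", "-"), 1), ty,
              sprintf("%s_%s_%d", ty, ch, k))
        }
      }
    }
    ann <- do.call(rbind, feats)
    gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start, ann$end),
                                 strand = ann$strand)
    S4Vectors::mcols(gr)$type <- ann$type
    S4Vectors::mcols(gr)$ID <- ann$ID
    S4Vectors::mcols(gr)$Parent <- ann$Parent
    GenomeInfoDb::seqlengths(gr) <- clens
    list(genome = genome, annotation = gr, config = config)
  })
}
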