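#' Simulate per-product counts for two libraries under Poisson noise
#'
#' Counts follow the technical-noise model the differential-expression test
#' assumes: for a product with expected mean `m` and planted log2 fold
#' change `lfc` (F3/F4 scale), `F3 ~ Poisson(m * 2^(lfc/2))` and
#' `F4 ~ Poisson(m * 2^(-lfc/2))`. An optional negative-binomial
#' overdispersion can be switched on for robustness studies.
#'
#' @param mean Vector of expected per-product means (reads).
#' @param lfc Vector of planted log2 fold changes (F3 over F4).
#' @param overdispersion NB overdispersion; 0 = Poisson.
#' @return Integer matrix with columns `F3`, `F4`.
#' @export
simulate_product_counts <- function(mean, lfc = 0, overdispersion = 0) {
  n <- length(mean)
  lfc <- rep_len(lfc, n)
  m3 <- mean * 2^(lfc / 2)
  m4 <- mean * 2^(-lfc / 2)
  draw <- function(mu) {
    if (overdispersion > 0) rnbinom(n, mu = mu, size = 1 / overdispersion)
    else rpois(n, mu)
  }
  cbind(F3 = draw(m3), F4 = draw(m4))
}

# isomiR variant grid with geometrically decaying weights. decay = 0 keeps
# only the reference (0, 0).
.isomir_grid <- function(decay) {
  if (decay <= 0) return(data.frame(d5 = 0L, d3 = 0L, w = 1))
  g <- expand.grid(d5 = -2:2, d3 = -3:3)
  g$w <- decay^(abs(g$d5) + abs(g$d3))
  g
}

.complement1 <- function(b) c(A = "T", C = "G", G = "C", T = "A")[b]

#' Realize two FASTQ read libraries from planted truth
#'
#' Per product, library counts are drawn from the Poisson model of
#' [simulate_product_counts()] and split multinomially over isomiR offset
#' variants (5' offsets -2..2, 3' offsets -3..3) with geometrically
#' decaying weights; each read independently gains a 1-nt non-templated 3'
#' A/U addition with probability `nta_prob`. Contaminant reads are drawn
#' from annotated rRNA/tRNA loci with lengths spanning 13-38 nt (some fall
#' outside the 15-35 retention window on purpose). Every insert is extended
#' with the 3' adapter and clipped to the fixed read length.
#'
#' @param planted Output of [plant_mirna_loci()].
#' @param config The same [sim_config()].
#' @return A list: `reads` (list of character vectors `F3`, `F4`),
#'   `expression` (per-product realized counts with planted truth),
#'   `variants` (per distinct emitted insert: product, offsets, nta,
#'   per-library counts), `n_contam` (contaminant reads per library).
#' @export
simulate_libraries <- function(planted, config = planted$config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- planted$genome
  truth <- planted$truth
  ann <- planted$annotation
  clens <- setNames(as.numeric(Biostrings::width(genome)), names(genome))

  with_seed(derive_seed(config$seed, "reads"), {
    prod <- truth$products
    # product template locus: first planted locus of the gene, or decoy row
    first_loci <- truth$loci[!duplicated(truth$loci$gene_id), ]
    rownames(first_loci) <- first_loci$gene_id
    tmpl <- lapply(seq_len(nrow(prod)), function(i) {
      p <- prod[i, ]
      if (p$type == "decoy") {
        d <- truth$decoys[truth$decoys$product_id == p$product_id, ]
        list(chrom = d$chrom, start = d$start, end = d$end, strand = d$strand)
      } else {
        l <- first_loci[p$gene_id, ]
        if (p$type == "mature")
          list(chrom = l$chrom, start = l$mature_start, end = l$mature_end,
               strand = l$strand)
        else
          list(chrom = l$chrom, start = l$star_start, end = l$star_end,
               strand = l$strand)
      }
    })

    counts <- simulate_product_counts(prod$mean, prod$lfc,
                                      config$overdispersion)
    grid <- .isomir_grid(config$isomir_decay)

    variant_rows <- list()
    for (i in seq_len(nrow(prod))) {
      t <- tmpl[[i]]
      # genomic interval of each offset variant, in read orientation
      if (t$strand == "+") {
        vs <- t$start + grid$d5; ve <- t$end + grid$d3
      } else {
        vs <- t$start - grid$d3; ve <- t$end - grid$d5
      }
      keep <- vs >= 1 & ve <= clens[[t$chrom]] & ve > vs
      g <- grid[keep, , drop = FALSE]
      vs <- vs[keep]; ve <- ve[keep]
      w <- g$w / sum(g$w)
      k3 <- if (counts[i, 1] > 0) rmultinom(1, counts[i, 1], w)[, 1] else
        integer(length(w))
      k4 <- if (counts[i, 2] > 0) rmultinom(1, counts[i, 2], w)[, 1] else
        integer(length(w))
      emitted <- which(k3 + k4 > 0)
      if (!length(emitted)) next
      seqs <- as.character(Biostrings::extractAt(
        genome[[t$chrom]], IRanges::IRanges(vs[emitted], ve[emitted])))
      if (t$strand == "-")
        seqs <- .revcomp(seqs)
      # templated base just downstream of the 3' end, for NTA choice
      nxt <- vapply(emitted, function(e) {
        if (t$strand == "+") {
          pos <- ve[e] + 1
          if (pos > clens[[t$chrom]]) return("N")
          as.character(Biostrings::extractAt(genome[[t$chrom]],
                                             IRanges::IRanges(pos, pos)))
        } else {
          pos <- vs[e] - 1
          if (pos < 1) return("N")
          .revcomp(as.character(Biostrings::extractAt(
            genome[[t$chrom]], IRanges::IRanges(pos, pos))))
        }
      }, "")
      for (ei in seq_along(emitted)) {
        e <- emitted[ei]
        n3 <- k3[e]; n4 <- k4[e]
        a3 <- rbinom(1, n3, config$nta_prob)
        a4 <- rbinom(1, n4, config$nta_prob)
        ntab <- if (nxt[ei] == "A") "T" else "A"
        if (n3 - a3 + n4 - a4 > 0)
          variant_rows[[length(variant_rows) + 1]] <- data.frame(
            product_id = prod$product_id[i], sequence = seqs[ei],
            offset5 = g$d5[e], offset3 = g$d3[e], nta = "",
            count_f3 = n3 - a3, count_f4 = n4 - a4, stringsAsFactors = FALSE)
        if (a3 + a4 > 0)
          variant_rows[[length(variant_rows) + 1]] <- data.frame(
            product_id = prod$product_id[i],
            sequence = paste0(seqs[ei], ntab),
            offset5 = g$d5[e], offset3 = g$d3[e], nta = ntab,
            count_f3 = a3, count_f4 = a4, stringsAsFactors = FALSE)
      }
    }
    variants <- do.call(rbind, variant_rows)

    # contaminant reads from annotated rRNA/tRNA loci
    contam <- ann[S4Vectors::mcols(ann)$type %in% c("rRNA", "tRNA")]
    nc3 <- rpois(1, config$mean_depth * config$contam_frac)
    nc4 <- rpois(1, config$mean_depth * config$contam_frac)
    draw_contam <- function(nc) {
      if (nc == 0) return(character(0))
      f <- sample.int(length(contam), nc, replace = TRUE)
      len <- sample(13:38, nc, replace = TRUE)
      fs <- GenomicRanges::start(contam)[f]
      fw <- IRanges::width(contam)[f]
      len <- pmin(len, fw)
      off <- floor(runif(nc) * (fw - len + 1))
      ch <- as.character(GenomeInfoDb::seqnames(contam))[f]
      out <- character(nc)
      for (cc in unique(ch)) {
        ii <- which(ch == cc)
        out[ii] <- as.character(Biostrings::extractAt(
          genome[[cc]], IRanges::IRanges(fs[ii] + off[ii],
                                         fs[ii] + off[ii] + len[ii] - 1)))
      }
      flip <- runif(nc) < 0.5
      out[flip] <- .revcomp(out[flip])
      out
    }
    contam3 <- draw_contam(nc3)
    contam4 <- draw_contam(nc4)

    make_reads <- function(lib) {
      cnt <- if (lib == "F3") variants$count_f3 else variants$count_f4
      inserts <- c(rep(variants$sequence, cnt),
                   if (lib == "F3") contam3 else contam4)
      reads <- substr(paste0(inserts, config$adapter,
                             strrep("A", config$read_length)),
                      1, config$read_length)
      if (config$error_rate > 0) {
        hit <- which(runif(length(reads)) < config$error_rate)
        for (r in hit) {
          p <- sample.int(nchar(reads[r]), 1)
          b <- substr(reads[r], p, p)
          substr(reads[r], p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }
      }
      reads
    }
    reads <- list(F3 = make_reads("F3"), F4 = make_reads("F4"))

    expression <- cbind(prod,
                        count_f3 = counts[, "F3"], count_f4 = counts[, "F4"])
    list(reads = reads, expression = expression, variants = variants,
         n_contam = c(F3 = length(contam3), F4 = length(contam4)))
  })
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper: [generate_genome()], [plant_mirna_loci()] and
#' [simulate_libraries()] under one config.
#'
#' @param config A [sim_config()].
#' @return A list with `genome`, `annotation`, `truth`, `libs`, `config`.
#' @export
simulate_srna_experiment <- function(config = sim_config()) {
  g <- generate_genome(config)
  p <- plant_mirna_loci(g, config)
  libs <- simulate_libraries(p, config)
  list(genome = p$genome, annotation = p$annotation, truth = p$truth,
       libs = libs, config = config)
}

#' Write all generator outputs to a directory
#'
#' Writes `genome.fa`, `annotation.gff3`, `reads_F3.fastq`,
#' `reads_F4.fastq` (Phred+33 with uniform dummy qualities),
#' `known_mature.fa`, `known_hairpin.fa`, `ortholog_mature.fa`,
#' `truth_loci.tsv` and `truth_expression.tsv`.
#'
#' @param sim Output of [simulate_srna_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simdata <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  ann <- sim$annotation
  p <- S4Vectors::mcols(ann)$Parent
  S4Vectors::mcols(ann)$Parent <- IRanges::CharacterList(
    lapply(p, function(x) if (is.na(x)) character(0) else x))
  rtracklayer::export(ann, file.path(dir, "annotation.gff3"),
                      format = "gff3")
  for (lib in c("F3", "F4")) {
    reads <- sim$libs$reads[[lib]]
    x <- Biostrings::DNAStringSet(reads)
    names(x) <- sprintf("%s_read%07d", lib, seq_along(x))
    Biostrings::writeXStringSet(
      x, file.path(dir, sprintf("reads_%s.fastq", lib)), format = "fastq",
      qualities = Biostrings::BStringSet(strrep("I", nchar(reads))))
  }
  write_fa <- function(x, path) {
    if (!length(x)) x <- setNames(character(0), character(0))
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  }
  write_fa(sim$truth$known_mature, file.path(dir, "known_mature.fa"))
  write_fa(sim$truth$known_hairpin, file.path(dir, "known_hairpin.fa"))
  write_fa(sim$truth$ortholog_mature, file.path(dir, "ortholog_mature.fa"))
  write.table(sim$truth$loci, file.path(dir, "truth_loci.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$libs$expression, file.path(dir, "truth_expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
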