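.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.mutate <- function(seq, n) {
  if (n == 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(seq_along(ch), n)
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# Build one planted precursor: a GC-rich mature arm of 21-23 nt, an AU-rich
# loop of 8-15 nt, and the reverse-complemented arm carrying 0-2
# substitutions. The long complementary stem guarantees a folding energy
# far below the -20 kcal/mol gate under any reasonable nearest-neighbor
# table. `total_len`, when given (mirtrons), fixes arm + loop sizes so the
# precursor exactly fills its host intron.
.make_precursor <- function(total_len = NULL) {
  if (is.null(total_len)) {
    a <- sample(21:23, 1)
    loop_len <- sample(8:15, 1)
  } else {
    ok <- expand.grid(a = 21:23, l = 8:15)
    ok <- ok[2 * ok$a + ok$l == total_len, , drop = FALSE]
    if (!nrow(ok)) stop("no arm/loop sizes fit precursor length ", total_len)
    pick <- ok[sample.int(nrow(ok), 1), ]
    a <- pick$a; loop_len <- pick$l
  }
  mature <- .rand_seq(a, c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))
  star <- .mutate(.revcomp(mature), sample(0:2, 1))
  loop <- .rand_seq(loop_len, c(A = 0.35, C = 0.15, G = 0.15, T = 0.35))
  arm <- sample(c("5p", "3p"), 1)
  if (arm == "5p") {
    prec <- paste0(mature, loop, star)
    mspan <- c(1L, a)
    sspan <- c(a + loop_len + 1L, 2L * a + loop_len)
  } else {
    prec <- paste0(star, loop, mature)
    sspan <- c(1L, a)
    mspan <- c(a + loop_len + 1L, 2L * a + loop_len)
  }
  list(precursor = prec, mature = mature, star = star, arm = arm,
       mature_span = mspan, star_span = sspan)
}

# Precursor-internal span -> genomic coordinates given the planted locus.
.span_to_genomic <- function(p1, p2, strand, span) {
  if (strand == "+") c(p1 + span[1] - 1L, p1 + span[2] - 1L)
  else c(p2 - span[2] + 1L, p2 - span[1] + 1L)
}

# TRUE when [start, end] on chrom is at least `mingap` bp from every row of
# `df` (a loci data.frame), ignoring rows of cluster `exclude_cluster`.
# Keeps planted loci from forming unplanned sub-10 kb clusters.
.far_enough <- function(df, chrom, start, end, mingap, exclude_cluster = NA) {
  if (is.null(df) || !nrow(df)) return(TRUE)
  rows <- df[df$chrom == chrom, , drop = FALSE]
  if (!is.na(exclude_cluster))
    rows <- rows[is.na(rows$cluster_id) | rows$cluster_id != exclude_cluster, ,
                 drop = FALSE]
  if (!nrow(rows)) return(TRUE)
  gaps <- pmax(start - rows$end, rows$start - end)
  all(gaps >= mingap)
}

#' Plant miRNA loci, decoys and expression truth into a synthetic genome
#'
#' Writes hairpin precursors into the genome sequence honoring the
#' configured cluster, mirtron and multi-copy placements; assigns
#' known / conserved-novel / species-specific labels; draws per-product
#' expected expression and planted fold changes; and plants expressed
#' non-hairpin decoy loci as discovery negatives. Known genes are added to
#' the annotation as `pre_miRNA`/`miRNA`/`miRNA_star` features and exported
#' (in [write_simdata()]) as the known reference; conserved-novel matures
#' are exported with at most 2 substitutions as the ortholog set.
#'
#' @param sim Output of [generate_genome()].
#' @param config The same [sim_config()].
#' @return A list: `genome` (with precursors written in), `annotation`
#'   (including known-miRNA features), `truth` (list with `loci`,
#'   `products`, `known_mature`, `known_hairpin`, `ortholog_mature`),
#'   and `config`.
#' @export
plant_mirna_loci <- function(sim, config = sim$config) {
  stopifnot(inherits(config, "sim_config"))
  genome <- sim$genome
  ann <- sim$annotation
  clens <- setNames(as.numeric(Biostrings::width(genome)), names(genome))
  n <- config$n_mirna_loci

  with_seed(derive_seed(config$seed, "plant"), {
    # Occupancy: exons and ncRNA block planting; introns/intergenic are open.
    occ <- .occ_new(names(genome))
    blocked <- ann[S4Vectors::mcols(ann)$type %in%
                     c("exon", "rRNA", "tRNA", "snoRNA")]
    for (ch in names(genome)) {
      occ[[ch]] <- IRanges::ranges(blocked[GenomeInfoDb::seqnames(blocked) == ch])
    }

    # Roles: mirtrons, clustered, multicopy, then singletons.
    if (config$n_clustered + config$n_mirtrons + config$n_multicopy > n)
      stop("special plantings exceed n_mirna_loci")
    role <- rep("singleton", n)
    idx <- 1L
    if (config$n_mirtrons) {
      role[idx:(idx + config$n_mirtrons - 1)] <- "mirtron"
      idx <- idx + config$n_mirtrons
    }
    if (config$n_clustered) {
      role[idx:(idx + config$n_clustered - 1)] <- "clustered"
      idx <- idx + config$n_clustered
    }
    if (config$n_multicopy) {
      role[idx:(idx + config$n_multicopy - 1)] <- "multicopy"
    }

    status <- rep("specific_novel", n)
    known_ids <- sample.int(n, config$n_known)
    status[known_ids] <- "known"
    rest <- setdiff(seq_len(n), known_ids)
    status[sample(rest, config$n_conserved_novel)] <- "conserved_novel"

    # Cluster grouping: split the clustered ids into runs of 2-3.
    cluster_of <- rep(NA_integer_, n)
    cl_ids <- which(role == "clustered")
    ci <- 0
    while (length(cl_ids)) {
      take <- min(length(cl_ids), sample(2:3, 1))
      if (length(cl_ids) - take == 1) take <- take + 1  # no orphan singleton
      ci <- ci + 1
      cluster_of[cl_ids[seq_len(take)]] <- ci
      cl_ids <- cl_ids[-seq_len(take)]
    }

    # Mirtron hosts: distinct short introns, pairwise well-separated so no
    # two mirtrons form an unplanned cluster.
    introns <- ann[S4Vectors::mcols(ann)$type == "intron"]
    short <- introns[IRanges::width(introns) >= 50 & IRanges::width(introns) <= 61]
    short <- short[sample.int(length(short))]
    picked <- integer(0)
    for (k in seq_along(short)) {
      if (length(picked) == config$n_mirtrons) break
      ok <- TRUE
      for (p in picked) {
        if (as.character(GenomeInfoDb::seqnames(short[k])) ==
            as.character(GenomeInfoDb::seqnames(short[p])) &&
            min(abs(GenomicRanges::start(short[k]) - GenomicRanges::end(short[p])),
                abs(GenomicRanges::start(short[p]) - GenomicRanges::end(short[k]))) < 12000) {
          ok <- FALSE
          break
        }
      }
      if (ok) picked <- c(picked, k)
    }
    if (length(picked) < config$n_mirtrons)
      stop("not enough well-separated short introns to host ",
           config$n_mirtrons, " mirtrons")
    hosts <- short[picked]

    loci <- list()
    add_locus <- function(gene_id, chrom, start, end, strand, pc, st, role,
                          clu) {
      ms <- .span_to_genomic(start, end, strand, pc$mature_span)
      ss <- .span_to_genomic(start, end, strand, pc$star_span)
      loci[[length(loci) + 1]] <<- data.frame(
        gene_id = gene_id, chrom = chrom, start = start, end = end,
        strand = strand, status = st, arm = pc$arm, role = role,
        cluster_id = clu, mature_seq = pc$mature, star_seq = pc$star,
        precursor_seq = pc$precursor,
        mature_start = ms[1], mature_end = ms[2],
        star_start = ss[1], star_end = ss[2], stringsAsFactors = FALSE)
    }

    # Non-cluster loci keep a 12 kb clear zone from every other planted
    # locus so no unplanned sub-10 kb cluster forms; physical collisions
    # with exons/ncRNA/other loci are checked with a 50 bp margin.
    iso_gap <- 12000
    loci_df <- function() if (length(loci)) do.call(rbind, loci) else NULL
    place_free <- function(len, what, chrom = NULL, mingap = iso_gap,
                           exclude_cluster = NA, tries = 3000) {
      df <- loci_df()
      for (t in seq_len(tries)) {
        ch <- if (is.null(chrom)) sample(names(clens), 1) else chrom
        maxs <- clens[[ch]] - len + 1
        s <- sample.int(maxs, 1)
        if (.occ_free(occ, ch, s, s + len - 1, gap = 50) &&
            .far_enough(df, ch, s, s + len - 1, mingap, exclude_cluster))
          return(list(chrom = ch, start = s, end = s + len - 1))
      }
      stop("could not place ", what, " after ", tries,
           " attempts (constraints: ", len, " bp free, ", mingap,
           " bp from other planted loci)")
    }

    mirtron_i <- 0
    for (g in seq_len(n)) {
      gid <- sprintf("mir%03d", g)
      if (role[g] == "mirtron") {
        mirtron_i <- mirtron_i + 1
        h <- hosts[mirtron_i]
        ch <- as.character(GenomeInfoDb::seqnames(h))
        s <- GenomicRanges::start(h); e <- GenomicRanges::end(h)
        strand <- as.character(GenomicRanges::strand(h))
        pc <- .make_precursor(total_len = e - s + 1)
        occ <- .occ_claim(occ, ch, s, e)
        add_locus(gid, ch, s, e, strand, pc, status[g], role[g], NA)
      } else if (role[g] == "clustered") {
        pc <- .make_precursor()
        len <- nchar(pc$precursor)
        clu <- cluster_of[g]
        prev <- loci_df()
        members <- if (!is.null(prev)) prev[!is.na(prev$cluster_id) &
                                              prev$cluster_id == clu, ] else NULL
        if (is.null(members) || !nrow(members)) {
          pos <- place_free(len, paste0("cluster ", clu))
        } else {
          last <- members[which.max(members$end), ]
          placed <- FALSE
          for (t in seq_len(500)) {
            gap <- sample(500:8000, 1)
            s <- last$end + gap
            if (s + len - 1 <= clens[[last$chrom]] &&
                .occ_free(occ, last$chrom, s, s + len - 1, gap = 50) &&
                .far_enough(prev, last$chrom, s, s + len - 1, iso_gap,
                            exclude_cluster = clu)) {
              pos <- list(chrom = last$chrom, start = s, end = s + len - 1)
              placed <- TRUE
              break
            }
          }
          if (!placed) stop("could not extend cluster ", clu,
                            " (constraint: gap < 10 kb on ", last$chrom, ")")
        }
        occ <- .occ_claim(occ, pos$chrom, pos$start, pos$end)
        strand <- sample(c("+", "-"), 1)
        add_locus(gid, pos$chrom, pos$start, pos$end, strand, pc,
                  status[g], role[g], clu)
      } else {
        pc <- .make_precursor()
        len <- nchar(pc$precursor)
        pos <- place_free(len, "miRNA locus")
        occ <- .occ_claim(occ, pos$chrom, pos$start, pos$end)
        strand <- sample(c("+", "-"), 1)
        add_locus(gid, pos$chrom, pos$start, pos$end, strand, pc,
                  status[g], role[g], NA)
        if (role[g] == "multicopy") {
          # second identical copy on the same chromosome, well apart
          pos2 <- place_free(len, paste0("second copy of ", gid),
                             chrom = pos$chrom, mingap = 15000)
          occ <- .occ_claim(occ, pos2$chrom, pos2$start, pos2$end)
          add_locus(gid, pos2$chrom, pos2$start, pos2$end, strand, pc,
                    status[g], "multicopy", NA)
        }
      }
    }
    loci <- do.call(rbind, loci)

    # Write precursors into the genome (reverse-complemented on -).
    for (ch in unique(loci$chrom)) {
      rows <- loci[loci$chrom == ch, ]
      repl <- ifelse(rows$strand == "+", rows$precursor_seq,
                     .revcomp(rows$precursor_seq))
      genome[[ch]] <- Biostrings::replaceAt(
        genome[[ch]], IRanges::IRanges(rows$start, rows$end), repl)
    }

    # Decoy loci: expressed 22-mers of plain genomic sequence.
    decoys <- list()
    fixed_loci <- loci
    for (d in seq_len(config$n_decoys)) {
      pos <- local({
        for (t in seq_len(3000)) {
          ch <- sample(names(clens), 1)
          s <- sample.int(clens[[ch]] - 21L, 1)
          if (.occ_free(occ, ch, s, s + 21L, gap = 50) &&
              .far_enough(fixed_loci, ch, s, s + 21L, iso_gap))
            return(list(chrom = ch, start = s, end = s + 21L))
        }
        stop("could not place decoy locus (constraint: 22 bp free, ",
             iso_gap, " bp from planted loci)")
      })
      occ <- .occ_claim(occ, pos$chrom, pos$start, pos$end)
      strand <- sample(c("+", "-"), 1)
      seq <- as.character(Biostrings::extractAt(
        genome[[pos$chrom]], IRanges::IRanges(pos$start, pos$end)))
      if (strand == "-") seq <- .revcomp(seq)
      decoys[[d]] <- data.frame(
        product_id = sprintf("decoy%02d", d), chrom = pos$chrom,
        start = pos$start, end = pos$end, strand = strand, seq = seq,
        stringsAsFactors = FALSE)
    }
    decoys <- if (length(decoys)) do.call(rbind, decoys) else NULL

    # Known genes join the annotation as pre_miRNA / miRNA / miRNA_star.
    kn <- loci[loci$status == "known", ]
    if (nrow(kn)) {
      kn_first <- kn[!duplicated(kn$gene_id), ]
      knames <- setNames(sprintf("ssc-miR-K%d", seq_len(nrow(kn_first))),
                         kn_first$gene_id)
      rows <- lapply(seq_len(nrow(kn)), function(i) {
        r <- kn[i, ]
        nm <- knames[[r$gene_id]]
        data.frame(
          chrom = r$chrom,
          start = c(r$start, r$mature_start, r$star_start),
          end = c(r$end, r$mature_end, r$star_end),
          strand = r$strand,
          type = c("pre_miRNA", "miRNA", "miRNA_star"),
          ID = c(paste0(nm, "_pre"), nm, paste0(nm, "*")),
          Parent = NA, stringsAsFactors = FALSE)
      })
      krows <- do.call(rbind, rows)
      kgr <- GenomicRanges::GRanges(krows$chrom,
                                    IRanges::IRanges(krows$start, krows$end),
                                    strand = krows$strand,
                                    seqinfo = GenomeInfoDb::seqinfo(ann))
      S4Vectors::mcols(kgr)$type <- krows$type
      S4Vectors::mcols(kgr)$ID <- krows$ID
      S4Vectors::mcols(kgr)$Parent <- krows$Parent
      ann <- c(ann, kgr)
      loci$name <- ifelse(loci$status == "known", knames[loci$gene_id], NA)
      known_mature <- setNames(kn_first$mature_seq, knames[kn_first$gene_id])
      known_hairpin <- setNames(kn_first$precursor_seq,
                                paste0(knames[kn_first$gene_id], "_pre"))
    } else {
      loci$name <- NA_character_
      known_mature <- character(0)
      known_hairpin <- character(0)
    }

    # Ortholog export for conserved-novel genes: mature with <=2 subs.
    cons <- loci[loci$status == "conserved_novel" & !duplicated(loci$gene_id), ]
    ortho <- character(0)
    if (nrow(cons)) {
      ortho <- vapply(cons$mature_seq, function(s) .mutate(s, sample(0:2, 1)), "")
      names(ortho) <- sprintf("bta-miR-O%d", seq_len(nrow(cons)))
    }

    # Products: one mature and one star per gene, plus decoys.
    genes <- loci[!duplicated(loci$gene_id), ]
    ng <- nrow(genes)
    base <- rlnorm(ng, meanlog = 0, sdlog = 1.2)
    starw <- config$star_frac * rlnorm(ng, 0, 0.5)
    # occasional star-arm dominance; conserved-novel genes stay
    # mature-dominant so their label refers to the arm that is catalogued
    flip <- runif(ng) < 0.05 & genes$status != "conserved_novel"
    starw[flip] <- 2.5
    prod <- data.frame(
      product_id = c(paste0(genes$gene_id, "_mature"),
                     paste0(genes$gene_id, "_star")),
      gene_id = rep(genes$gene_id, 2),
      type = rep(c("mature", "star"), each = ng),
      seq = c(genes$mature_seq, genes$star_seq),
      weight = c(base, base * starw), stringsAsFactors = FALSE)
    if (!is.null(decoys)) {
      prod <- rbind(prod, data.frame(
        product_id = decoys$product_id, gene_id = decoys$product_id,
        type = "decoy", seq = decoys$seq,
        weight = 0.3 * rlnorm(nrow(decoys), 0, 1)))
    }
    prod$mean <- prod$weight / sum(prod$weight) *
      config$mean_depth * (1 - config$contam_frac)
    prod$lfc <- 0
    is_mirna <- prod$type %in% c("mature", "star")
    de_pick <- which(is_mirna)[runif(sum(is_mirna)) < config$frac_de]
    prod$lfc[de_pick] <- sample(c(-1, 1), length(de_pick), replace = TRUE) *
      config$fc_magnitude
    prod$is_de <- prod$lfc != 0
    prod$weight <- NULL

    truth <- list(loci = loci, products = prod, decoys = decoys,
                  known_mature = known_mature, known_hairpin = known_hairpin,
                  ortholog_mature = ortho)
    list(genome = genome, annotation = ann, truth = truth, config = config)
  })
}
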