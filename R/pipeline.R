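#' Pipeline configuration
#'
#' Input paths and every stage parameter, with the analysis defaults:
#' 15-35 nt retention window, two end-confined mismatches, a -20 kcal/mol
#' folding-energy gate, 10 kb cluster window, 2-substitution conservation
#' budget, and differential-expression calls at more than 2-fold with
#' p < 0.001.
#'
#' @param genome,annotation,reads_f3,reads_f4 Input paths (FASTA, GFF3,
#'   FASTQ/FASTA).
#' @param ortholog_mature Optional FASTA of ortholog matures for
#'   conservation classification.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len Read retention window (nt).
#' @param max_end_mismatches,max_loci Alignment parameters.
#' @param delta_g_max Hairpin energy gate (kcal/mol).
#' @param window_length,flank Precursor window excision.
#' @param cluster_window Cluster gap threshold (bp).
#' @param mirtron_tolerance Splice-boundary tolerance (nt).
#' @param conservation_max_subs Conservation substitution budget.
#' @param fc_threshold,p_threshold DE call thresholds.
#' @param min_mirna_overlap Known-miRNA classification overlap (nt).
#' @param seed RNG seed (the pipeline itself is deterministic; the seed is
#'   recorded for provenance).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, annotation, reads_f3, reads_f4,
                            ortholog_mature = NULL,
                            adapter = "TCGTATGCCGTCTTCTGCTTG",
                            min_len = 15, max_len = 35,
                            max_end_mismatches = 2, max_loci = 20,
                            delta_g_max = -20, window_length = 90, flank = 5,
                            cluster_window = 10000, mirtron_tolerance = 3,
                            conservation_max_subs = 2, fc_threshold = 2,
                            p_threshold = 0.001, min_mirna_overlap = 16,
                            seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  do.call(pipeline_config, yaml::read_yaml(path))
}

.write_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# srnaforge config_hash=%s", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full small RNA analysis pipeline
#'
#' preprocess -> align -> classify -> assign known -> discover novel ->
#' annotate (isomiRs, clusters, mirtrons, density) -> quantify (TMM,
#' exact binomial DE). All stage outputs are written as TSV under `outdir`
#' with the configuration hash embedded in each header; reruns with an
#' identical configuration are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with all stage tables (`tags`, `hits`,
#'   `categories`, `known_assign`, `novel_assign`, `isomirs`, `products`,
#'   `genes`, `clusters`, `density`, `de`, `merge`, `summary`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("genome", "annotation", "reads_f3", "reads_f4")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("input not found: ", f, " = ", config[[f]] %||% "<missing>")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- rlang::hash(unclass(config))

  genome <- .stage("load", Biostrings::readDNAStringSet(config$genome))
  names(genome) <- sub("\\s.*", "", names(genome))
  ann <- .stage("load", rtracklayer::import(config$annotation))
  ortho <- if (!is.null(config$ortholog_mature) &&
               file.exists(config$ortholog_mature))
    as.character(Biostrings::readDNAStringSet(config$ortholog_mature))
  else character(0)

  pp <- .stage("preprocess", preprocess_reads(
    config$reads_f3, config$reads_f4, config$adapter,
    min_len = config$min_len, max_len = config$max_len))
  tags <- pp$tags

  aln <- .stage("align", align_tags(tags, genome,
                                    config$max_end_mismatches,
                                    config$max_loci))

  cats <- .stage("classify", classify_tags(tags, aln, ann,
                                           config$min_mirna_overlap))

  ftype <- S4Vectors::mcols(ann)$type
  known_feats <- ann[ftype %in% c("miRNA", "miRNA_star")]
  known_products <- if (length(known_feats)) data.frame(
    product_id = S4Vectors::mcols(known_feats)$ID,
    gene_id = sub("\\*$", "", S4Vectors::mcols(known_feats)$ID),
    type = ifelse(ftype[ftype %in% c("miRNA", "miRNA_star")] == "miRNA",
                  "mature", "star"),
    chrom = as.character(GenomeInfoDb::seqnames(known_feats)),
    start = GenomicRanges::start(known_feats),
    end = GenomicRanges::end(known_feats),
    strand = as.character(GenomicRanges::strand(known_feats)),
    stringsAsFactors = FALSE) else
      data.frame(product_id = character(0), gene_id = character(0),
                 type = character(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0))

  eligible <- cats$sequence[cats$category %in% c("known_mirna", "candidate")]
  known_assign <- .stage("assign_known", assign_products(
    tags, aln, known_products, eligible = eligible))

  # discovery runs on candidate tags not absorbed by known products
  cand_seqs <- setdiff(cats$sequence[cats$category == "candidate"],
                       known_assign$sequence)
  cand <- .stage("discover", candidate_loci(tags, aln, cand_seqs))
  folded <- .stage("discover", fold_candidates(
    cand, genome, hairpin_rules(delta_g_max = config$delta_g_max),
    config$window_length, config$flank))
  known_pre <- ann[ftype == "pre_miRNA"]
  novel <- .stage("discover", call_novel(folded, known_pre))

  if (nrow(novel)) {
    # a gene is conserved when either duplex arm matches an ortholog mature
    st_m <- classify_conservation(novel$mature_seq, ortho,
                                  config$conservation_max_subs)
    st_s <- ifelse(is.na(novel$star_seq), "specific_novel",
                   classify_conservation(ifelse(is.na(novel$star_seq), "A",
                                                novel$star_seq), ortho,
                                         config$conservation_max_subs))
    novel$status <- ifelse(st_m == "conserved_novel" |
                             st_s == "conserved_novel",
                           "conserved_novel", "specific_novel")
    # sequential names per library and class, in genomic order
    lib <- ifelse(novel$present_f3, "F3", "F4")
    cls <- ifelse(novel$status == "conserved_novel", "C", "S")
    nm <- character(nrow(novel))
    for (l in c("F3", "F4")) for (cc in c("C", "S")) {
      ii <- which(lib == l & cls == cc)
      nm[ii] <- sprintf("ssc-miR-%s-%s%d", l, cc, seq_along(ii))
    }
    novel$name <- nm
  }

  novel_products <- if (nrow(novel)) {
    rows <- lapply(seq_len(nrow(novel)), function(i) {
      r <- novel[i, ]
      # every locus of a multi-locus gene carries the products
      loci <- parse_locus(strsplit(r$loci, ",", fixed = TRUE)[[1]])
      mature <- data.frame(product_id = paste0(r$gene_id, "_mature"),
                           gene_id = r$gene_id, type = "mature",
                           chrom = r$chrom, start = r$mature_start,
                           end = r$mature_end, strand = r$strand,
                           stringsAsFactors = FALSE)
      star <- if (!is.na(r$star_start))
        data.frame(product_id = paste0(r$gene_id, "_star"),
                   gene_id = r$gene_id, type = "star", chrom = r$chrom,
                   start = r$star_start, end = r$star_end,
                   strand = r$strand, stringsAsFactors = FALSE)
      rbind(mature, star)
    })
    do.call(rbind, rows)
  } else known_products[0, ]

  novel_assign <- .stage("assign_novel", assign_products(
    tags, aln, novel_products, eligible = cand_seqs))

  all_assign <- rbind(known_assign, novel_assign)
  iso <- .stage("isomirs", catalog_isomirs(all_assign))

  prod_meta <- rbind(known_products[!duplicated(known_products$product_id),
                                    c("product_id", "gene_id", "type")],
                     novel_products[!duplicated(novel_products$product_id),
                                    c("product_id", "gene_id", "type")])
  psum <- merge(iso$products, prod_meta, by = "product_id")
  dominance <- flag_arm_dominance(psum)

  cm <- .stage("quantify", build_counts(iso$products))
  factors <- .stage("quantify", tmm_factors(cm$counts))
  de <- .stage("quantify", call_de(cm$counts, factors,
                                   config$fc_threshold, config$p_threshold))

  # gene-level tables: known genes (expressed) + novel genes
  g3 <- tapply(psum$total_f3, psum$gene_id, sum)
  g4 <- tapply(psum$total_f4, psum$gene_id, sum)
  known_gene_ids <- unique(known_products$gene_id)
  known_genes <- data.frame(
    gene_id = known_gene_ids, name = known_gene_ids, status = "known",
    present_f3 = known_gene_ids %in% names(g3)[g3 > 0],
    present_f4 = known_gene_ids %in% names(g4)[g4 > 0],
    stringsAsFactors = FALSE)
  known_pre_df <- if (length(known_pre)) data.frame(
    gene_id = sub("_pre$", "", S4Vectors::mcols(known_pre)$ID),
    chrom = as.character(GenomeInfoDb::seqnames(known_pre)),
    start = GenomicRanges::start(known_pre),
    end = GenomicRanges::end(known_pre),
    strand = as.character(GenomicRanges::strand(known_pre)),
    stringsAsFactors = FALSE) else NULL

  novel_loci_df <- if (nrow(novel)) {
    rows <- lapply(seq_len(nrow(novel)), function(i) {
      l <- parse_locus(strsplit(novel$loci[i], ",", fixed = TRUE)[[1]])
      cbind(gene_id = novel$gene_id[i], l)
    })
    do.call(rbind, rows)
  } else NULL

  all_loci <- rbind(
    if (!is.null(known_pre_df))
      cbind(known_pre_df, status = "known") else NULL,
    if (!is.null(novel_loci_df))
      cbind(novel_loci_df[, c("gene_id", "chrom", "start", "end", "strand")],
            status = "novel") else NULL)

  cl <- .stage("clusters", detect_clusters(all_loci, config$cluster_window))
  introns <- ann[ftype == "intron"]
  # Splice boundaries are reconstructed from the duplex, not the trimmed
  # precursor (which can gain flank pairs beyond the spliced ends): one
  # mature end sits on a splice site, and the opposite boundary is the
  # star's 3' end minus its 2-nt Dicer overhang.
  mirtron_loci <- all_loci
  if (nrow(novel)) {
    for (i in seq_len(nrow(novel))) {
      r <- novel[i, ]
      sel <- which(mirtron_loci$gene_id == r$gene_id &
                     mirtron_loci$start == r$prec_start)
      if (length(sel) != 1 || is.na(r$star_start) || is.na(r$mature_arm))
        next
      if (r$mature_arm == "5p") {
        span <- if (r$strand == "+") c(r$mature_start, r$star_end - 2)
        else c(r$star_start + 2, r$mature_end)
      } else {
        span <- if (r$strand == "+") c(r$star_start - 2, r$mature_end)
        else c(r$mature_start, r$star_end + 2)
      }
      mirtron_loci$start[sel] <- min(span)
      mirtron_loci$end[sel] <- max(span)
    }
  }
  mirtron_flags <- .stage("mirtrons",
                          detect_mirtrons(mirtron_loci, introns,
                                          config$mirtron_tolerance))
  all_loci$cluster_id <- cl$assignments$cluster_id
  all_loci$mirtron <- mirtron_flags

  clens <- setNames(Biostrings::width(genome), names(genome))
  genes_models <- ann[ftype == "gene"]
  dens <- .stage("density", genomic_density(
    if (nrow(novel)) novel_loci_df else all_loci[0, ], clens, genes_models))

  merge_sets <- merge_library_gene_sets(
    c(known_genes$name[known_genes$present_f3],
      if (nrow(novel)) novel$name[novel$present_f3]),
    c(known_genes$name[known_genes$present_f4],
      if (nrow(novel)) novel$name[novel$present_f4]))

  genes <- rbind(
    known_genes,
    if (nrow(novel)) data.frame(gene_id = novel$gene_id, name = novel$name,
                                status = novel$status,
                                present_f3 = novel$present_f3,
                                present_f4 = novel$present_f4,
                                stringsAsFactors = FALSE))

  results <- list(config = config, stats = pp$stats, tags = tags,
                  hits = aln$hits, categories = cats,
                  known_assign = known_assign, novel_assign = novel_assign,
                  isomirs = iso$isomirs, products = psum,
                  dominance = dominance, folded = folded, novel = novel,
                  genes = genes, loci = all_loci,
                  clusters = cl$clusters, density = dens$density,
                  intergenic_fraction = dens$intergenic_fraction,
                  factors = factors, de = de, merge = merge_sets)
  results$summary <- summary_stats(results)

  for (nmout in c("tags", "hits", "categories", "isomirs", "products",
                  "folded", "novel", "genes", "loci", "clusters", "density",
                  "de", "summary")) {
    df <- results[[nmout]]
    if (is.data.frame(df) && nrow(df))
      .write_tsv(df, file.path(outdir, paste0(nmout, ".tsv")), hash)
  }
  invisible(results)
}

#' Merge per-library gene sets
#'
#' @param genes_f3,genes_f4 Character vectors of gene names detected in
#'   each library.
#' @return A list: `table` (gene, in_f3, in_f4), `n_f3`, `n_f4`,
#'   `n_common`, `n_union` (`= n_f3 + n_f4 - n_common`).
#' @export
#' @examples
#' merge_library_gene_sets(paste0("g", 1:269), paste0("g", 103:366))$n_union
merge_library_gene_sets <- function(genes_f3, genes_f4) {
  genes_f3 <- unique(genes_f3); genes_f4 <- unique(genes_f4)
  all <- union(genes_f3, genes_f4)
  list(table = data.frame(gene = all, in_f3 = all %in% genes_f3,
                          in_f4 = all %in% genes_f4,
                          stringsAsFactors = FALSE),
       n_f3 = length(genes_f3), n_f4 = length(genes_f4),
       n_common = length(intersect(genes_f3, genes_f4)),
       n_union = length(all))
}

#' Summary statistics of a pipeline run
#'
#' Per-library known / conserved-novel / specific-novel gene tallies,
#' differential-expression totals split by direction with the percentage of
#' the gene union (1 decimal), isomiR count range, cluster and mirtron
#' counts, and the intergenic fraction.
#'
#' @param results The list returned by [run_pipeline()].
#' @return A data.frame with `metric` and `value` columns.
#' @export
summary_stats <- function(results) {
  g <- results$genes
  tab <- function(lib) {
    pres <- if (lib == "F3") g$present_f3 else g$present_f4
    c(known = sum(g$status == "known" & pres),
      conserved_novel = sum(g$status == "conserved_novel" & pres),
      specific_novel = sum(g$status == "specific_novel" & pres))
  }
  t3 <- tab("F3"); t4 <- tab("F4")
  de <- results$de
  n_up <- sum(de$call == "up"); n_down <- sum(de$call == "down")
  n_union <- results$merge$n_union
  iso_rng <- if (nrow(results$products))
    range(results$products$n_isomirs) else c(NA, NA)
  rows <- rbind(
    data.frame(metric = c("f3_known", "f3_conserved_novel",
                          "f3_specific_novel", "f3_total"),
               value = c(t3, sum(t3))),
    data.frame(metric = c("f4_known", "f4_conserved_novel",
                          "f4_specific_novel", "f4_total"),
               value = c(t4, sum(t4))),
    data.frame(metric = c("genes_f3", "genes_f4", "genes_common",
                          "genes_union"),
               value = c(results$merge$n_f3, results$merge$n_f4,
                         results$merge$n_common, n_union)),
    data.frame(metric = c("de_up", "de_down", "de_total", "de_pct_of_union"),
               value = c(n_up, n_down, n_up + n_down,
                         if (n_union > 0)
                           round(100 * (n_up + n_down) / n_union, 1) else 0)),
    data.frame(metric = c("isomir_min", "isomir_max"), value = iso_rng),
    data.frame(metric = c("n_clusters", "n_mirtrons",
                          "intergenic_pct_novel"),
               value = c(nrow(results$clusters), sum(results$loci$mirtron),
                         round(100 * results$intergenic_fraction, 1))))
  rownames(rows) <- NULL
  rows
}
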