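# Feature type -> tag category, in priority order after known_mirna.
.CATEGORY_PRIORITY <- c("rRNA", "tRNA", "snoRNA", "other_ncRNA", "mRNA")

.feature_category <- function(type) {
  type <- as.character(type)
  ifelse(type %in% c("rRNA", "tRNA", "snoRNA"), type,
         ifelse(type == "exon", "mRNA",
                ifelse(type %in% c("snRNA", "scRNA", "SRP_RNA", "ncRNA",
                                   "misc_RNA"), "other_ncRNA", NA)))
}

#' Classify tags against the annotation hierarchy
#'
#' Every tag receives exactly one category. A tag with any hit overlapping
#' a known mature miRNA locus by at least `min_mirna_overlap` nt (same
#' strand) is `known_mirna`; otherwise the first matching category in the
#' fixed priority order rRNA > tRNA > snoRNA > other_ncRNA > mRNA (exon
#' overlap, either strand); otherwise `candidate`. Tags without hits are
#' `unmapped`; repeat-flagged tags are `repeat`.
#'
#' @param tags Tag table (column `sequence`).
#' @param aln Output of [align_tags()].
#' @param annotation Annotation `GRanges` with a `type` column; known
#'   mature loci are the `miRNA` and `miRNA_star` features.
#' @param min_mirna_overlap Minimum overlap for a known-miRNA call (nt).
#' @return A data.frame `sequence`, `category`.
#' @export
classify_tags <- function(tags, aln, annotation, min_mirna_overlap = 16) {
  seqs <- unique(tags$sequence)
  cat <- setNames(rep("unmapped", length(seqs)), seqs)
  cat[aln$repeat_tags] <- "repeat"
  hits <- aln$hits
  if (nrow(hits)) {
    mapped <- setdiff(unique(hits$sequence), aln$repeat_tags)
    cat[mapped] <- "candidate"
    hg <- loci_granges(hits)
    types <- as.character(S4Vectors::mcols(annotation)$type)
    known <- annotation[types %in% c("miRNA", "miRNA_star")]
    if (length(known)) {
      ov <- GenomicRanges::findOverlaps(hg, known,
                                        minoverlap = min_mirna_overlap)
      kseq <- unique(hits$sequence[S4Vectors::queryHits(ov)])
      cat[kseq] <- "known_mirna"
    }
    fcat <- .feature_category(types)
    for (cc in .CATEGORY_PRIORITY) {
      feats <- annotation[!is.na(fcat) & fcat == cc]
      if (!length(feats)) next
      ov <- GenomicRanges::findOverlaps(hg, feats, ignore.strand = TRUE)
      cseq <- unique(hits$sequence[S4Vectors::queryHits(ov)])
      todo <- cseq[cat[cseq] == "candidate"]
      cat[todo] <- cc
    }
  }
  data.frame(sequence = seqs, category = unname(cat[seqs]),
             stringsAsFactors = FALSE)
}

#' Assign tags to quantifiable products by locus overlap
#'
#' Assigns each eligible tag to the product (mature or star of a gene)
#' whose locus it overlaps, with 5'/3' offsets within the isomiR bounds.
#' A mismatched 3' tail of up to `max_nta` A/T bases that is inconsistent
#' with the genomic template is recorded as a non-templated addition (NTA)
#' and excluded from the 3' offset. Ambiguous overlaps resolve to the
#' largest overlap, then the lexicographically lowest product id; identical
#' matures at multiple loci share one product, so multi-locus assignments
#' collapse.
#'
#' @param tags Tag table with `sequence`, `count_f3`, `count_f4`.
#' @param aln Output of [align_tags()].
#' @param products Data.frame of product loci: `product_id`, `type`,
#'   `chrom`, `start`, `end`, `strand` (one row per locus; multi-copy
#'   products repeat their `product_id`).
#' @param eligible Optional character vector of tag sequences to consider
#'   (e.g. those classified `known_mirna` or `candidate`).
#' @param max_offset5,max_offset3 IsomiR offset bounds (nt).
#' @param max_nta Maximum NTA length (nt).
#' @return A data.frame: `sequence`, `product_id`, `offset5`, `offset3`,
#'   `nta`, `count_f3`, `count_f4`.
#' @export
assign_products <- function(tags, aln, products, eligible = NULL,
                            max_offset5 = 4, max_offset3 = 6, max_nta = 3) {
  hits <- aln$hits
  if (!is.null(eligible)) hits <- hits[hits$sequence %in% eligible, ]
  if (!nrow(hits) || !nrow(products))
    return(data.frame(sequence = character(0), product_id = character(0),
                      offset5 = integer(0), offset3 = integer(0),
                      nta = character(0), count_f3 = integer(0),
                      count_f4 = integer(0)))
  hg <- loci_granges(hits)
  pg <- loci_granges(products)
  empty <- data.frame(sequence = character(0), product_id = character(0),
                      offset5 = integer(0), offset3 = integer(0),
                      nta = character(0), count_f3 = integer(0),
                      count_f4 = integer(0))
  ov <- GenomicRanges::findOverlaps(hg, pg)
  if (!length(ov)) return(empty)
  h <- hits[S4Vectors::queryHits(ov), ]
  p <- products[S4Vectors::subjectHits(ov), ]
  olap <- pmin(h$end, p$end) - pmax(h$start, p$start) + 1
  L <- nchar(h$sequence)

  # NTA: trailing contiguous 3'-end mismatches of A/T (vs the template)
  nta <- character(nrow(h))
  offs <- strsplit(h$mismatch_offsets, ",", fixed = TRUE)
  for (i in seq_len(nrow(h))) {
    o <- suppressWarnings(as.integer(offs[[i]]))
    o <- o[!is.na(o)]
    tail_len <- 0
    while ((L[i] - 1 - tail_len) %in% o &&
           substr(h$sequence[i], L[i] - tail_len, L[i] - tail_len) %in%
           c("A", "T") && tail_len < max_nta) {
      tail_len <- tail_len + 1
    }
    if (tail_len > 0)
      nta[i] <- substr(h$sequence[i], L[i] - tail_len + 1, L[i])
  }
  ntalen <- nchar(nta)

  same_strand <- h$strand == p$strand
  if (any(!same_strand)) {
    h <- h[same_strand, ]; p <- p[same_strand, ]
    olap <- olap[same_strand]; nta <- nta[same_strand]
    ntalen <- ntalen[same_strand]
  }
  plus <- h$strand == "+"
  off5 <- ifelse(plus, h$start - p$start, p$end - h$end)
  off3raw <- ifelse(plus, h$end - p$end, p$start - h$start)
  off3 <- off3raw - ntalen

  keep <- abs(off5) <= max_offset5 & abs(off3) <= max_offset3
  cand <- data.frame(sequence = h$sequence, product_id = p$product_id,
                     offset5 = off5, offset3 = off3, nta = nta,
                     overlap = olap, stringsAsFactors = FALSE)[keep, ]
  if (!nrow(cand))
    return(data.frame(sequence = character(0), product_id = character(0),
                      offset5 = integer(0), offset3 = integer(0),
                      nta = character(0), count_f3 = integer(0),
                      count_f4 = integer(0)))
  # best product per tag: largest overlap, then lowest product id
  cand <- cand[order(cand$sequence, -cand$overlap, cand$product_id), ]
  best <- cand[!duplicated(cand$sequence), ]
  rownames(tags) <- tags$sequence
  best$count_f3 <- tags[best$sequence, "count_f3"]
  best$count_f4 <- tags[best$sequence, "count_f4"]
  best$overlap <- NULL
  rownames(best) <- NULL
  best
}

#' Catalog isomiRs and select reference sequences
#'
#' One record per distinct assigned sequence per product. The reference
#' isomiR is the record with the highest summed count over both libraries
#' (ties broken by the lexicographically smallest sequence) — the most
#' abundant variant, which need not equal the annotated reference.
#'
#' @param assignments Output of [assign_products()].
#' @return A list: `isomirs` (per-variant table with `is_reference`) and
#'   `products` (per-product summary: `n_isomirs`, `ref_sequence`,
#'   `total_f3`, `total_f4`).
#' @export
catalog_isomirs <- function(assignments) {
  if (!nrow(assignments))
    return(list(isomirs = assignments,
                products = data.frame(product_id = character(0),
                                      n_isomirs = integer(0),
                                      ref_sequence = character(0),
                                      total_f3 = integer(0),
                                      total_f4 = integer(0))))
  iso <- assignments[order(assignments$product_id,
                           -(assignments$count_f3 + assignments$count_f4),
                           assignments$sequence), ]
  iso$is_reference <- !duplicated(iso$product_id)
  tot3 <- tapply(iso$count_f3, iso$product_id, sum)
  tot4 <- tapply(iso$count_f4, iso$product_id, sum)
  nvar <- tapply(iso$sequence, iso$product_id, length)
  refs <- iso$sequence[iso$is_reference]
  names(refs) <- iso$product_id[iso$is_reference]
  pid <- sort(unique(iso$product_id))
  products <- data.frame(product_id = pid,
                         n_isomirs = as.integer(nvar[pid]),
                         ref_sequence = unname(refs[pid]),
                         total_f3 = as.integer(tot3[pid]),
                         total_f4 = as.integer(tot4[pid]),
                         stringsAsFactors = FALSE)
  rownames(iso) <- NULL
  list(isomirs = iso, products = products)
}

#' Flag star-arm dominance per gene
#'
#' The star strand is usually the minor product, but a gene is flagged
#' star-dominant when its star product's total read count exceeds the
#' mature product's.
#'
#' @param product_totals Data.frame with `product_id`, `gene_id`, `type`
#'   (`"mature"`/`"star"`), `total_f3`, `total_f4`.
#' @return A data.frame per gene: totals per arm and `dominant_arm`.
#' @export
flag_arm_dominance <- function(product_totals) {
  pt <- product_totals[product_totals$type %in% c("mature", "star"), ]
  tot <- pt$total_f3 + pt$total_f4
  m <- tapply(tot[pt$type == "mature"], pt$gene_id[pt$type == "mature"], sum)
  s <- tapply(tot[pt$type == "star"], pt$gene_id[pt$type == "star"], sum)
  genes <- sort(unique(pt$gene_id))
  mt <- ifelse(genes %in% names(m), m[genes], 0)
  st <- ifelse(genes %in% names(s), s[genes], 0)
  data.frame(gene_id = genes, mature_total = as.integer(mt),
             star_total = as.integer(st),
             dominant_arm = ifelse(st > mt, "star", "mature"),
             stringsAsFactors = FALSE)
}
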