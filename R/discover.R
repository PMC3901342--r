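#' Group candidate-tag hits into candidate loci
#'
#' Overlapping hits of candidate tags are merged (strand-aware) into
#' candidate loci; each locus is represented by its most abundant tag
#' (ties: lexicographically smallest sequence), the putative mature.
#'
#' @param tags Tag table with counts.
#' @param aln Output of [align_tags()].
#' @param candidate_seqs Sequences classified `candidate`.
#' @return A data.frame per locus: `locus_id`, `chrom`, `start`, `end`,
#'   `strand` (merged span), `rep_sequence`, `rep_start`, `rep_end`,
#'   `count_f3`, `count_f4` (summed over member tags).
#' @export
candidate_loci <- function(tags, aln, candidate_seqs) {
  hits <- aln$hits[aln$hits$sequence %in% candidate_seqs, , drop = FALSE]
  if (!nrow(hits))
    return(data.frame(locus_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), rep_sequence = character(0),
                      rep_start = integer(0), rep_end = integer(0),
                      count_f3 = integer(0), count_f4 = integer(0)))
  hg <- loci_granges(hits)
  merged <- GenomicRanges::reduce(hg)
  ov <- GenomicRanges::findOverlaps(hg, merged)
  grp <- S4Vectors::subjectHits(ov)
  rownames(tags) <- tags$sequence
  c3 <- tags[hits$sequence, "count_f3"]
  c4 <- tags[hits$sequence, "count_f4"]
  out <- lapply(seq_along(merged), function(i) {
    ii <- which(grp == i)
    tot <- c3[ii] + c4[ii]
    best <- ii[order(-tot, hits$sequence[ii])][1]
    # counts per locus: each member tag contributes once
    seqs <- unique(hits$sequence[ii])
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(merged))[i],
               start = GenomicRanges::start(merged)[i],
               end = GenomicRanges::end(merged)[i],
               strand = as.character(GenomicRanges::strand(merged))[i],
               rep_sequence = hits$sequence[best],
               rep_start = hits$start[best], rep_end = hits$end[best],
               count_f3 = sum(tags[seqs, "count_f3"]),
               count_f4 = sum(tags[seqs, "count_f4"]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom, out$start, out$strand), ]
  out$locus_id <- sprintf("cand%04d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("locus_id", "chrom", "start", "end", "strand", "rep_sequence",
          "rep_start", "rep_end", "count_f3", "count_f4")]
}

#' Fold and evaluate candidate loci into precursor candidates
#'
#' For each candidate locus, excises both arm-hypothesis windows around the
#' representative mature ([extract_precursor_windows()]) and folds them
#' ([fold_mfe()]). Excision is two-phase: the window fold locates the
#' miRNA:miRNA* duplex ([infer_star()]), the window is trimmed to the
#' duplex extent plus 2 nt, and the trimmed precursor is refolded — flank
#' sequence beyond the duplex would otherwise inflate the precursor span
#' and dilute its energy density. Rules ([evaluate_hairpin()]) are applied
#' to the refolded precursor; the best passing hypothesis (lowest folding
#' energy) is kept.
#'
#' @param cand Output of [candidate_loci()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param rules [hairpin_rules()].
#' @param window_length,flank Window excision parameters, see
#'   [extract_precursor_windows()].
#' @param params Energy parameters, see [energy_params()].
#' @return A data.frame per locus with `pass`, `reasons`, `delta_g`,
#'   `structure`, precursor/mature/star genomic coordinates and arm.
#' @export
fold_candidates <- function(cand, genome, rules = hairpin_rules(),
                            window_length = 90, flank = 5,
                            params = energy_params()) {
  eval_hypothesis <- function(seq, mspan) {
    fold <- fold_mfe(seq, params)
    ev <- evaluate_hairpin(seq, fold, mspan, rules)
    out <- list(ev = ev, seq = seq, mspan = mspan, offset = 0L)
    star <- infer_star(fold, mspan)
    if (is.null(star)) return(out)
    t1 <- max(1L, min(mspan[1], star[1]) - 2L)
    t2 <- min(nchar(seq), max(mspan[2], star[2]) + 2L)
    if (t2 - t1 + 1 < 40 || mspan[1] < t1 || mspan[2] > t2) return(out)
    sub <- substr(seq, t1, t2)
    fold2 <- fold_mfe(sub, params)
    ev2 <- evaluate_hairpin(sub, fold2, mspan - t1 + 1L, rules)
    ref <- list(ev = ev2, seq = sub, mspan = mspan - t1 + 1L,
                offset = t1 - 1L)
    if (ev2$pass || !ev$pass) ref else out
  }
  rows <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, ]
    hit <- list(chrom = r$chrom, start = r$rep_start, end = r$rep_end,
                strand = r$strand)
    win <- extract_precursor_windows(hit, genome, window_length, flank)
    best <- NULL
    for (w in seq_len(nrow(win))) {
      hy <- eval_hypothesis(win$sequence[w],
                            c(win$mature_start[w], win$mature_end[w]))
      hy$win <- win[w, ]
      if (is.null(best) ||
          (hy$ev$pass && !best$ev$pass) ||
          (hy$ev$pass == best$ev$pass && hy$ev$delta_g < best$ev$delta_g)) {
        best <- hy
      }
    }
    if (is.null(best)) return(NULL)
    ev <- best$ev; w <- best$win
    # offsets within best$seq -> window offsets -> genomic coordinates
    to_genomic <- function(span) {
      if (is.null(span) || any(is.na(span)))
        return(c(NA_integer_, NA_integer_))
      span <- span + best$offset
      if (w$strand == "+") c(w$start + span[1] - 1L, w$start + span[2] - 1L)
      else c(w$end - span[2] + 1L, w$end - span[1] + 1L)
    }
    prec <- to_genomic(ev$precursor_span)
    star <- if (ev$pass) infer_star(ev$fold, best$mspan) else NULL
    starg <- to_genomic(star)
    star_seq <- if (!is.null(star))
      substr(best$seq, star[1], star[2]) else NA_character_
    data.frame(locus_id = r$locus_id, chrom = r$chrom, strand = r$strand,
               pass = ev$pass, reasons = paste(ev$reasons, collapse = ";"),
               delta_g = ev$delta_g, mfei = ev$mfei,
               structure = ev$fold$structure,
               precursor_seq = best$seq,
               prec_start = prec[1], prec_end = prec[2],
               mature_arm = ev$mature_arm,
               mature_seq = r$rep_sequence,
               mature_start = r$rep_start, mature_end = r$rep_end,
               star_seq = star_seq, star_start = starg[1],
               star_end = starg[2],
               count_f3 = r$count_f3, count_f4 = r$count_f4,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call novel miRNA genes from passing precursor candidates
#'
#' Candidates overlapping a known pre-miRNA locus are merged into the known
#' gene (not reported as novel). Remaining passing candidates are
#' deduplicated by locus overlap (>= 50% reciprocal) and candidates with an
#' identical mature sequence at several loci merge into one multi-locus
#' gene. Per-library presence requires at least one assigned read in that
#' library.
#'
#' @param folded Output of [fold_candidates()].
#' @param known_pre `GRanges` of known pre-miRNA loci (or NULL).
#' @return A data.frame of novel genes: `gene_id`, `mature_seq`, `loci`
#'   (comma-separated locus strings), `n_loci`, `delta_g` (best), plus
#'   per-locus coordinate columns of the primary locus and library
#'   presence flags.
#' @export
call_novel <- function(folded, known_pre = NULL) {
  if (!nrow(folded)) return(data.frame())
  cand <- folded[folded$pass, , drop = FALSE]
  if (!nrow(cand)) return(data.frame())
  if (!is.null(known_pre) && length(known_pre)) {
    cg <- GenomicRanges::GRanges(cand$chrom,
                                 IRanges::IRanges(cand$prec_start,
                                                  cand$prec_end))
    ov <- GenomicRanges::findOverlaps(cg, known_pre, ignore.strand = TRUE)
    drop <- unique(S4Vectors::queryHits(ov))
    if (length(drop)) cand <- cand[-drop, , drop = FALSE]
    if (!nrow(cand)) return(data.frame())
  }
  # dedup by >=50% reciprocal locus overlap; strand-agnostic, since the
  # antisense image of a fold-back locus is itself hairpin-like
  cg <- loci_granges(data.frame(chrom = cand$chrom, start = cand$prec_start,
                                end = cand$prec_end, strand = cand$strand))
  ov <- GenomicRanges::findOverlaps(cg, cg, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  wq <- IRanges::width(cg)[qh]; ws <- IRanges::width(cg)[sh]
  inter <- pmin(cand$prec_end[qh], cand$prec_end[sh]) -
    pmax(cand$prec_start[qh], cand$prec_start[sh]) + 1
  recip <- inter >= 0.5 * wq & inter >= 0.5 * ws
  keep_edge <- recip
  # union-find over reciprocal-overlap edges
  parent <- seq_len(nrow(cand))
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (k in which(keep_edge)) {
    a <- find(qh[k]); b <- find(sh[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(nrow(cand)), find, 1L)
  # one representative per overlap component: highest total count
  tot <- cand$count_f3 + cand$count_f4
  reps <- vapply(split(seq_len(nrow(cand)), comp), function(ii)
    ii[order(-tot[ii], cand$mature_seq[ii])][1], 1L)
  cand <- cand[reps, , drop = FALSE]

  # identical mature at several (non-overlapping) loci -> one gene
  grp <- split(seq_len(nrow(cand)), cand$mature_seq)
  genes <- lapply(grp, function(ii) {
    ii <- ii[order(cand$chrom[ii], cand$prec_start[ii])]
    primary <- ii[which.max(cand$count_f3[ii] + cand$count_f4[ii])]
    r <- cand[primary, ]
    r$loci <- paste(locus_string(cand$chrom[ii], cand$prec_start[ii],
                                 cand$prec_end[ii], cand$strand[ii]),
                    collapse = ",")
    r$n_loci <- length(ii)
    r
  })
  out <- do.call(rbind, genes)
  out <- out[order(out$chrom, out$prec_start), ]
  out$gene_id <- sprintf("novel%03d", seq_len(nrow(out)))
  out$present_f3 <- out$count_f3 > 0
  out$present_f4 <- out$count_f4 > 0
  rownames(out) <- NULL
  out
}

#' Classify a novel mature as conserved or species-specific
#'
#' Conserved iff the mature is within `max_subs` substitutions of an
#' ortholog mature of equal length (Hamming distance), or within `max_subs`
#' total differences allowing one end extension/truncation (the length
#' difference counts toward the budget, anchored at either end).
#'
#' @param mature Character vector of mature sequences.
#' @param orthologs Character vector of ortholog matures (possibly empty).
#' @param max_subs Substitution budget.
#' @return Character vector: `"conserved_novel"` or `"specific_novel"`.
#' @export
classify_conservation <- function(mature, orthologs, max_subs = 2) {
  if (!length(orthologs))
    return(rep("specific_novel", length(mature)))
  ham <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    sum(av != bv)
  }
  one <- function(m) {
    for (o in orthologs) {
      lm <- nchar(m); lo <- nchar(o)
      d <- abs(lm - lo)
      if (d > max_subs) next
      if (d == 0) {
        if (ham(m, o) <= max_subs) return("conserved_novel")
      } else {
        k <- min(lm, lo)
        if (ham(substr(m, 1, k), substr(o, 1, k)) + d <= max_subs ||
            ham(substr(m, lm - k + 1, lm), substr(o, lo - k + 1, lo)) + d <=
            max_subs)
          return("conserved_novel")
      }
    }
    "specific_novel"
  }
  vapply(mature, one, "", USE.NAMES = FALSE)
}

#' Detect miRNA genomic clusters
#'
#' Precursor loci on one chromosome are chained while the end-to-start gap
#' to the next locus is below `window` (strand ignored); maximal chains of
#' at least two loci are clusters.
#'
#' @param loci Data.frame with `chrom`, `start`, `end` (one row per locus)
#'   and optionally an id column.
#' @param window Maximum gap in bp (strictly less than).
#' @return A list: `assignments` (input order, `cluster_id` or NA) and
#'   `clusters` (per cluster: chrom, n members, span, `max_gap`).
#' @export
detect_clusters <- function(loci, window = 10000) {
  n <- nrow(loci)
  cluster_id <- rep(NA_integer_, n)
  clusters <- list()
  cid <- 0
  for (ch in unique(loci$chrom)) {
    ii <- which(loci$chrom == ch)
    ii <- ii[order(loci$start[ii])]
    if (length(ii) < 2) next
    gaps <- loci$start[ii][-1] - loci$end[ii][-length(ii)]
    brk <- c(0, cumsum(gaps >= window))
    for (g in unique(brk)) {
      members <- ii[brk == g]
      if (length(members) < 2) next
      cid <- cid + 1
      cluster_id[members] <- cid
      mg <- gaps[brk[-1] == g & brk[-length(brk)] == g]
      clusters[[cid]] <- data.frame(
        cluster_id = cid, chrom = ch, n = length(members),
        start = min(loci$start[members]), end = max(loci$end[members]),
        max_gap = max(mg), stringsAsFactors = FALSE)
    }
  }
  list(assignments = cbind(loci, cluster_id = cluster_id),
       clusters = if (length(clusters)) do.call(rbind, clusters) else
         data.frame(cluster_id = integer(0), chrom = character(0),
                    n = integer(0), start = integer(0), end = integer(0),
                    max_gap = integer(0)))
}

#' Detect mirtrons
#'
#' A precursor is a mirtron when both of its ends lie within `tolerance` nt
#' of the donor/acceptor boundaries of a single annotated intron on the
#' same strand — the hallmark of splicing-derived (microprocessor-
#' independent) precursors.
#'
#' @param loci Data.frame of precursor loci (`chrom`, `start`, `end`,
#'   `strand`).
#' @param introns `GRanges` of annotated introns.
#' @param tolerance Boundary tolerance in nt.
#' @return Logical vector, one flag per locus.
#' @export
detect_mirtrons <- function(loci, introns, tolerance = 3) {
  if (is.null(introns) || !length(introns)) {
    warning("no intron annotation; all mirtron flags FALSE")
    return(rep(FALSE, nrow(loci)))
  }
  flags <- rep(FALSE, nrow(loci))
  ic <- as.character(GenomeInfoDb::seqnames(introns))
  is_ <- GenomicRanges::start(introns)
  ie <- GenomicRanges::end(introns)
  istr <- as.character(GenomicRanges::strand(introns))
  for (i in seq_len(nrow(loci))) {
    sel <- ic == loci$chrom[i] & istr == loci$strand[i] &
      abs(is_ - loci$start[i]) <= tolerance &
      abs(ie - loci$end[i]) <= tolerance
    flags[i] <- any(sel)
  }
  flags
}

#' Genomic density of pre-miRNAs and intergenic fraction
#'
#' @param loci Data.frame of precursor loci (`chrom`, `start`, `end`).
#' @param chrom_lengths Named vector of chromosome lengths (bp).
#' @param gene_models Optional `GRanges` of gene spans; when given, the
#'   fraction of loci not overlapping any gene model is reported.
#' @return A list: `density` (per chromosome: n loci, Mb, density per Mb
#'   rounded to 2 decimals) and `intergenic_fraction` (or NA).
#' @export
genomic_density <- function(loci, chrom_lengths, gene_models = NULL) {
  if (any(chrom_lengths <= 0)) stop("zero-length chromosome")
  n <- vapply(names(chrom_lengths),
              function(ch) sum(loci$chrom == ch), 0)
  dens <- data.frame(chrom = names(chrom_lengths), n = as.integer(n),
                     mb = chrom_lengths / 1e6,
                     density = round(n / (chrom_lengths / 1e6), 2),
                     row.names = NULL)
  ig <- NA_real_
  if (!is.null(gene_models) && nrow(loci)) {
    lg <- GenomicRanges::GRanges(loci$chrom,
                                 IRanges::IRanges(loci$start, loci$end))
    ov <- GenomicRanges::countOverlaps(lg, gene_models, ignore.strand = TRUE)
    ig <- sum(ov == 0) / nrow(loci)
  }
  list(density = dens, intergenic_fraction = ig)
}
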