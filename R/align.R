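#' Align unique tags to a genome with end-confined mismatches
#'
#' Finds every locus on both strands where a tag matches with at most
#' `max_end_mismatches` mismatches, all confined to the two outermost
#' positions of either end; the core (read offsets 2..L-3, 0-based) must
#' match exactly. The core is located with an exact substring dictionary
#' ([Biostrings::matchPDict()]) and the four end positions are verified
#' against the genome. Tags with more than `max_loci` qualifying loci are
#' flagged repeat-derived and carry no hits in the output.
#'
#' @param tags Data.frame with a `sequence` column (uppercase ACGT,
#'   15-35 nt), e.g. from [filter_and_collapse()].
#' @param genome Named [Biostrings::DNAStringSet].
#' @param max_end_mismatches Maximum total mismatches (at the 4 outermost
#'   read positions).
#' @param max_loci Hit count above which a tag is called repeat-derived.
#' @return A list: `hits` (data.frame `sequence`, `chrom`, `start`, `end`,
#'   `strand`, `n_mismatch`, `mismatch_offsets` — comma-separated 0-based
#'   read offsets), `n_loci` (named vector per tag sequence, qualifying
#'   loci before the repeat filter), `repeat_tags` (character).
#' @export
align_tags <- function(tags, genome, max_end_mismatches = 2, max_loci = 20) {
  seqs <- unique(tags$sequence)
  if (!length(seqs))
    return(list(hits = data.frame(), n_loci = integer(0),
                repeat_tags = character(0)))
  if (any(grepl("[^ACGT]", seqs))) stop("tags must be uppercase ACGT")
  L <- nchar(seqs)
  if (any(L < 15 | L > 35)) stop("tag lengths must be within 15-35 nt")
  clens <- setNames(Biostrings::width(genome), names(genome))

  hit_rows <- list()
  chrom_str <- setNames(as.character(genome), names(genome))
  for (orient in c("+", "-")) {
    query <- if (orient == "+") seqs else .revcomp(seqs)
    # fixed-width core seed at query positions 3..13, always inside the
    # mismatch-protected interior (offsets 2..L-3) for L >= 15
    seed <- substr(query, 3, 13)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(seed))
    for (ch in names(genome)) {
      mi <- Biostrings::matchPDict(pd, genome[[ch]])
      cnt <- S4Vectors::elementNROWS(mi)
      if (!sum(cnt)) next
      ir <- unlist(mi)
      qi <- rep(seq_along(cnt), cnt)
      s1 <- IRanges::start(ir) - 2L
      nmm <- verify_tag_hits(chrom_str[[ch]], s1, query[qi],
                             as.integer(max_end_mismatches))
      idx <- which(nmm >= 0)
      if (!length(idx)) next
      qii <- qi[idx]
      gseq <- as.character(Biostrings::extractAt(
        genome[[ch]], IRanges::IRanges(s1[idx], s1[idx] + L[qii] - 1L)))
      q <- query[qii]
      qpos <- cbind(1L, 2L, L[qii] - 1L, L[qii])
      mm <- matrix(FALSE, length(idx), 4)
      for (k in 1:4) {
        mm[, k] <- substr(gseq, qpos[, k], qpos[, k]) !=
          substr(q, qpos[, k], qpos[, k])
      }
      offs <- vapply(seq_along(idx), function(r) {
        qp <- qpos[r, ][mm[r, ]]
        if (!length(qp)) return("")
        ro <- if (orient == "+") qp - 1L else L[qii[r]] - qp
        paste(sort(ro), collapse = ",")
      }, "")
      hit_rows[[length(hit_rows) + 1]] <- data.frame(
        sequence = seqs[qii], chrom = ch, start = s1[idx],
        end = s1[idx] + L[qii] - 1L, strand = orient,
        n_mismatch = nmm[idx], mismatch_offsets = offs,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    data.frame(sequence = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               n_mismatch = integer(0), mismatch_offsets = character(0))
  hits <- unique(hits)
  n_loci <- table(factor(hits$sequence, levels = seqs))
  n_loci <- setNames(as.integer(n_loci), names(n_loci))
  repeat_tags <- names(n_loci)[n_loci > max_loci]
  hits <- hits[!hits$sequence %in% repeat_tags, , drop = FALSE]
  hits <- hits[order(hits$sequence, hits$chrom, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  list(hits = hits, n_loci = n_loci, repeat_tags = repeat_tags)
}

#' Per-tag locus counts and multi-copy report
#'
#' @param aln Output of [align_tags()].
#' @return A data.frame per tag: `sequence`, `n_loci`, `repeat_flag`
#'   (excluded from discovery when TRUE), sorted by locus count.
#' @export
count_loci <- function(aln) {
  out <- data.frame(sequence = names(aln$n_loci),
                    n_loci = as.integer(aln$n_loci),
                    repeat_flag = names(aln$n_loci) %in% aln$repeat_tags,
                    stringsAsFactors = FALSE)
  out[order(-out$n_loci, out$sequence), , drop = FALSE]
}
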