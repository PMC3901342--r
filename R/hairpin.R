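#' Default hairpin-quality rules
#'
#' The rule set that stands in for a learned pre-miRNA classifier: every
#' threshold is explicit and auditable. A candidate passes iff its folding
#' energy is at most `delta_g_max`, the fold is a single stem-loop, the
#' mature lies entirely within one arm, at least `min_paired_frac` of
#' mature bases are paired, the terminal loop size is within `loop_range`,
#' and the trimmed precursor span is within `precursor_range`.
#'
#' The minimum free energy gate alone separates hairpins poorly from random
#' windows of comparable length, so the classifier surrogate additionally
#' requires the minimal folding free energy index
#' `MFEI = (|dG| / precursor length * 100) / GC%` to reach `min_mfei`;
#' genuine pre-miRNA hairpins typically exceed 0.85 while other RNA and
#' random sequence fall well below.
#'
#' @param delta_g_max Maximum folding free energy (kcal/mol); the classic
#'   small-RNA discovery gate is -20.
#' @param min_paired_frac Minimum fraction of mature bases paired.
#' @param loop_range Allowed terminal loop sizes (nt).
#' @param precursor_range Allowed trimmed precursor lengths (nt).
#' @param min_mfei Minimum MFE index of the trimmed precursor.
#' @return A named list of thresholds.
#' @export
hairpin_rules <- function(delta_g_max = -20, min_paired_frac = 0.6,
                          loop_range = c(3, 25), precursor_range = c(50, 150),
                          min_mfei = 0.85) {
  list(delta_g_max = delta_g_max, min_paired_frac = min_paired_frac,
       loop_range = loop_range, precursor_range = precursor_range,
       min_mfei = min_mfei)
}

#' Excise candidate precursor windows around an aligned mature
#'
#' Two arm hypotheses are excised per hit: hypothesis `5p` assumes the
#' mature sits on the 5' arm of the precursor (window extends downstream in
#' transcript orientation), hypothesis `3p` assumes the 3' arm (window
#' extends upstream). Windows are clipped at chromosome edges; a hypothesis
#' whose clipped window is shorter than the mature plus 15 nt is dropped.
#' Minus-strand windows are reported in genomic coordinates with the
#' reverse-complemented sequence.
#'
#' @param hit A list or one-row data.frame with `chrom`, `start`, `end`,
#'   `strand` (1-based inclusive).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param window_length Window span in bp.
#' @param flank Extra bases beyond the mature's outer edge.
#' @return A data.frame with one row per surviving hypothesis: `hypothesis`,
#'   `chrom`, `start`, `end`, `strand`, `sequence` (transcript orientation),
#'   `mature_start`, `mature_end` (1-based offsets of the mature within
#'   `sequence`).
#' @export
extract_precursor_windows <- function(hit, genome, window_length = 90,
                                      flank = 5) {
  chrom <- as.character(hit$chrom)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  clen <- Biostrings::width(genome[chrom])
  s <- as.integer(hit$start); e <- as.integer(hit$end)
  strand <- as.character(hit$strand)
  mlen <- e - s + 1
  if (strand == "+") {
    cand <- data.frame(
      hypothesis = c("5p", "3p"),
      start = c(s - flank, e + flank - window_length),
      end = c(s - flank + window_length - 1, e + flank))
  } else {
    cand <- data.frame(
      hypothesis = c("5p", "3p"),
      start = c(e + flank - window_length + 1, s - flank),
      end = c(e + flank, s - flank + window_length))
  }
  cand$start <- pmax(cand$start, 1L)
  cand$end <- pmin(cand$end, clen)
  keep <- (cand$end - cand$start + 1) >= (mlen + 15)
  cand <- cand[keep, , drop = FALSE]
  if (!nrow(cand)) return(cand)
  seqs <- as.character(Biostrings::extractAt(
    genome[[chrom]], IRanges::IRanges(cand$start, cand$end)))
  if (strand == "-")
    seqs <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
  # mature offsets within the transcript-oriented window
  if (strand == "+") {
    m1 <- s - cand$start + 1L
  } else {
    m1 <- cand$end - e + 1L
  }
  data.frame(hypothesis = cand$hypothesis, chrom = chrom,
             start = cand$start, end = cand$end, strand = strand,
             sequence = seqs, mature_start = m1, mature_end = m1 + mlen - 1L,
             stringsAsFactors = FALSE)
}

#' Score a folded window against the hairpin rules
#'
#' Applies the rule set from [hairpin_rules()] to a folded precursor
#' window. The reported precursor span is trimmed to the outermost base
#' pair plus 2 nt on each side; because exterior unpaired bases carry no
#' energy, the trimmed precursor folds to the same structure and energy as
#' the window, so the energy gate is applied to the trimmed precursor.
#'
#' @param window_seq The window sequence that was folded.
#' @param fold A [fold_mfe()] result for `window_seq`.
#' @param mature_span Integer vector `c(start, end)`: 1-based offsets of the
#'   mature within the window.
#' @param rules Thresholds from [hairpin_rules()].
#' @return A list of class `hairpin_candidate`: `pass`, `reasons`
#'   (character vector of failed rule codes), `delta_g`, `mature_arm`
#'   (`"5p"`/`"3p"`/`NA`), `precursor_span`, `loop_span`,
#'   `n_paired_mature`, `fold`.
#' @export
evaluate_hairpin <- function(window_seq, fold, mature_span,
                             rules = hairpin_rules()) {
  n <- nchar(window_seq)
  m1 <- mature_span[1]; m2 <- mature_span[2]
  if (m1 < 1 || m2 > n || m1 > m2) stop("mature_span outside window")
  pt <- fold$pairs
  reasons <- character(0)
  arm <- NA_character_
  prec <- c(NA_integer_, NA_integer_)
  loop <- c(NA_integer_, NA_integer_)
  npair <- sum(pt[m1:m2] > 0)
  mfei <- NA_real_

  if (all(pt == 0)) {
    reasons <- "no_structure"
  } else {
    paired <- which(pt > 0 & seq_along(pt) < pt)
    i_out <- min(paired); j_out <- pt[i_out]
    i_in <- max(paired); j_in <- pt[i_in]
    loop <- c(i_in + 1L, j_in - 1L)
    prec <- c(max(1L, i_out - 2L), min(n, j_out + 2L))
    loop_size <- j_in - i_in - 1L
    if (fold$delta_g > rules$delta_g_max) reasons <- c(reasons, "delta_g")
    if (m1 <= loop[2] && m2 >= loop[1]) {
      reasons <- c(reasons, "mature_in_loop")
    } else if (!(m1 >= prec[1] && m2 <= i_in) &&
               !(m1 >= j_in && m2 <= prec[2])) {
      reasons <- c(reasons, "mature_outside_stem")
    } else {
      arm <- if (m2 <= i_in) "5p" else "3p"
    }
    if (npair / (m2 - m1 + 1) < rules$min_paired_frac)
      reasons <- c(reasons, "low_pairing")
    if (loop_size < rules$loop_range[1] || loop_size > rules$loop_range[2])
      reasons <- c(reasons, "loop_size")
    plen <- prec[2] - prec[1] + 1L
    if (plen < rules$precursor_range[1] || plen > rules$precursor_range[2])
      reasons <- c(reasons, "precursor_length")
    pseq <- strsplit(substr(window_seq, prec[1], prec[2]), "")[[1]]
    gc <- mean(pseq %in% c("G", "C", "g", "c"))
    mfei <- if (gc > 0) (abs(fold$delta_g) / plen * 100) / (gc * 100) else 0
    if (mfei < rules$min_mfei) reasons <- c(reasons, "mfei")
  }
  structure(list(pass = length(reasons) == 0, reasons = reasons,
                 delta_g = fold$delta_g, mature_arm = arm,
                 mature_span = c(m1, m2), precursor_span = prec,
                 loop_span = loop, n_paired_mature = npair, mfei = mfei,
                 fold = fold),
            class = "hairpin_candidate")
}

#' Infer the star strand from Dicer duplex geometry
#'
#' The star is the pairing partner of the mature shifted so that both
#' duplex ends carry the 2-nt 3' overhang Dicer leaves. Unpaired mature
#' ends are resolved by walking inward to the nearest paired base and
#' shifting the partner coordinate by the same amount. Pairs whose
#' pairing register (`i + pt[i]`) deviates from the mature's median
#' register by more than `max_register_shift` belong to a different helix
#' (e.g. a flank extension across a large internal loop) and are ignored,
#' so genuine duplex bulges still shift the star ends while spurious
#' long-range pairs do not.
#'
#' @param fold A [fold_mfe()] result for the precursor window.
#' @param mature_span `c(start, end)` offsets of the mature in the window.
#' @param min_length Minimum star length; shorter partners return `NULL`.
#' @param max_register_shift Maximum deviation from the median pairing
#'   register for a pair to count as duplex pairing.
#' @return `c(start, end)` offsets of the star within the window, or
#'   `NULL` when the partner region is shorter than `min_length`.
#' @export
infer_star <- function(fold, mature_span, min_length = 16,
                       max_register_shift = 6) {
  pt <- fold$pairs
  n <- length(pt)
  m1 <- mature_span[1]; m2 <- mature_span[2]
  paired <- (m1:m2)[pt[m1:m2] > 0]
  if (!length(paired)) return(NULL)
  reg <- paired + pt[paired]
  keep <- abs(reg - stats::median(reg)) <= max_register_shift
  paired <- paired[keep]
  if (!length(paired)) return(NULL)
  a <- min(paired); b <- max(paired)
  # star 3' end partners the mature 5' end; 2-nt 3' overhangs on both ends
  star_end <- pt[a] + (a - m1) + 2L
  star_start <- pt[b] - (m2 - b) + 2L
  star_start <- max(1L, star_start)
  star_end <- min(n, star_end)
  if (star_end - star_start + 1L < min_length) return(NULL)
  c(star_start, star_end)
}
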