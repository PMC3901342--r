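#' Trim a 3' adapter from reads
#'
#' Scans each read for the best adapter-prefix match: the match consuming
#' the most adapter bases wins, ties broken by the leftmost start. A match
#' must cover at least `min_overlap` adapter bases with a mismatch fraction
#' of at most `max_mismatch_rate`. Reads without a qualifying match are
#' returned unchanged and flagged untrimmed (an insert at least as long as
#' the read carries no adapter). Trimming never lengthens a read.
#'
#' @param reads Character vector of read sequences.
#' @param adapter The 3' adapter sequence.
#' @param min_overlap Minimum adapter bases a match must cover.
#' @param max_mismatch_rate Maximum mismatch fraction within the overlap.
#' @return A data.frame with columns `insert` (trimmed sequence) and
#'   `trimmed` (logical).
#' @export
#' @examples
#' trim_adapter("ACGTACGTACGTACGTACGTAATCGTATGCC", "TCGTATGCCGTCTTCTGCTTG")
trim_adapter <- function(reads, adapter, min_overlap = 6,
                         max_mismatch_rate = 0.1) {
  stopifnot(nchar(adapter) >= min_overlap)
  if (!length(reads))
    return(data.frame(insert = character(0), trimmed = logical(0)))
  pos <- trim_adapter_cpp(toupper(reads), toupper(adapter),
                          as.integer(min_overlap), max_mismatch_rate)
  trimmed <- pos >= 0
  insert <- ifelse(trimmed, substr(reads, 1, pos), reads)
  data.frame(insert = insert, trimmed = trimmed, stringsAsFactors = FALSE)
}

# Read a FASTQ/FASTA file into sequences + mean Phred quality (NA for FASTA).
.read_reads <- function(path) {
  if (!file.exists(path)) stop("read file not found: ", path)
  first <- readLines(path, n = 1)
  if (startsWith(first, "@")) {
    x <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
    q <- as(Biostrings::quality(x), "IntegerList")
    list(seq = as.character(x), mean_q = vapply(q, mean, 0))
  } else {
    x <- Biostrings::readDNAStringSet(path)
    list(seq = as.character(x), mean_q = rep(NA_real_, length(x)))
  }
}

#' Collapse post-trim inserts into unique tags with per-library counts
#'
#' Inserts outside the length window or containing non-ACGT characters are
#' discarded; identical sequences are merged with counts accumulated per
#' library. Collapsing conserves the total retained read count per library.
#'
#' @param inserts_f3,inserts_f4 Character vectors of post-trim inserts.
#' @param min_len,max_len Retention window in nt (inclusive).
#' @return A list: `tags` (data.frame `sequence`, `count_f3`, `count_f4`,
#'   sorted by total count), and `discarded` (counts by reason and
#'   library).
#' @export
filter_and_collapse <- function(inserts_f3, inserts_f4, min_len = 15,
                                max_len = 35) {
  one <- function(ins) {
    n <- nchar(ins)
    bad_char <- grepl("[^ACGT]", ins)
    short <- !bad_char & n < min_len
    long <- !bad_char & n > max_len
    keep <- !bad_char & !short & !long
    list(kept = ins[keep],
         discarded = c(too_short = sum(short), too_long = sum(long),
                       non_acgt = sum(bad_char)))
  }
  f3 <- one(toupper(inserts_f3))
  f4 <- one(toupper(inserts_f4))
  all_seq <- c(f3$kept, f4$kept)
  if (!length(all_seq)) {
    tags <- data.frame(sequence = character(0), count_f3 = integer(0),
                       count_f4 = integer(0))
  } else {
    lib <- rep(c("F3", "F4"), c(length(f3$kept), length(f4$kept)))
    tab <- table(sequence = all_seq, lib = factor(lib, c("F3", "F4")))
    tags <- data.frame(sequence = rownames(tab),
                       count_f3 = as.integer(tab[, "F3"]),
                       count_f4 = as.integer(tab[, "F4"]),
                       stringsAsFactors = FALSE)
    tags <- tags[order(-(tags$count_f3 + tags$count_f4), tags$sequence), ]
    rownames(tags) <- NULL
  }
  list(tags = tags,
       discarded = rbind(F3 = f3$discarded, F4 = f4$discarded))
}

#' Preprocess two raw read libraries into unique tags
#'
#' Quality gate (mean Phred below `min_mean_phred` discards the read; only
#' applied to FASTQ input), adapter trimming ([trim_adapter()]), length
#' window and collapsing ([filter_and_collapse()]).
#'
#' @param path_f3,path_f4 FASTQ or FASTA files for the two libraries.
#' @param adapter 3' adapter sequence.
#' @param min_len,max_len Retention window (nt).
#' @param min_overlap,max_mismatch_rate Adapter-match parameters, see
#'   [trim_adapter()].
#' @param min_mean_phred Mean-quality gate for FASTQ reads.
#' @return A list: `tags` (unique tags with per-library counts), `stats`
#'   (per-library totals: raw, low-quality, untrimmed-kept, discarded by
#'   reason, retained).
#' @export
preprocess_reads <- function(path_f3, path_f4, adapter,
                             min_len = 15, max_len = 35, min_overlap = 6,
                             max_mismatch_rate = 0.1, min_mean_phred = 20) {
  one <- function(path) {
    r <- .read_reads(path)
    lowq <- !is.na(r$mean_q) & r$mean_q < min_mean_phred
    seqs <- r$seq[!lowq]
    tr <- trim_adapter(seqs, adapter, min_overlap, max_mismatch_rate)
    list(inserts = tr$insert, n_raw = length(r$seq), n_lowq = sum(lowq),
         n_untrimmed = sum(!tr$trimmed))
  }
  f3 <- one(path_f3)
  f4 <- one(path_f4)
  fc <- filter_and_collapse(f3$inserts, f4$inserts, min_len, max_len)
  stats <- data.frame(
    library = c("F3", "F4"),
    raw = c(f3$n_raw, f4$n_raw),
    low_quality = c(f3$n_lowq, f4$n_lowq),
    untrimmed = c(f3$n_untrimmed, f4$n_untrimmed),
    too_short = fc$discarded[, "too_short"],
    too_long = fc$discarded[, "too_long"],
    non_acgt = fc$discarded[, "non_acgt"],
    retained = c(sum(fc$tags$count_f3), sum(fc$tags$count_f4)))
  list(tags = fc$tags, stats = stats)
}

#' Read-length distribution of collapsed tags
#'
#' Histogram of retained read counts by tag length (15-35 nt) per library,
#' weighted by counts, with the fraction of reads in the 21-24 nt window
#' characteristic of Dicer products.
#'
#' @param tags Tag table from [filter_and_collapse()].
#' @param min_len,max_len Histogram support.
#' @return A list: `table` (length, count_f3, count_f4, frac_f3, frac_f4)
#'   and `frac_21_24` (named vector per library).
#' @export
summarize_length_distribution <- function(tags, min_len = 15, max_len = 35) {
  lens <- min_len:max_len
  L <- nchar(tags$sequence)
  agg <- function(cnt) {
    v <- vapply(lens, function(l) sum(cnt[L == l]), 0)
    setNames(v, lens)
  }
  c3 <- agg(tags$count_f3)
  c4 <- agg(tags$count_f4)
  t3 <- sum(c3); t4 <- sum(c4)
  tab <- data.frame(length = lens, count_f3 = c3, count_f4 = c4,
                    frac_f3 = if (t3 > 0) c3 / t3 else 0 * c3,
                    frac_f4 = if (t4 > 0) c4 / t4 else 0 * c4,
                    row.names = NULL)
  in_window <- lens >= 21 & lens <= 24
  list(table = tab,
       frac_21_24 = c(F3 = if (t3 > 0) sum(c3[in_window]) / t3 else 0,
                      F4 = if (t4 > 0) sum(c4[in_window]) / t4 else 0))
}
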