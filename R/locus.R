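#' Format genomic loci as locus strings
#'
#' Loci are 1-based, inclusive intervals on a named chromosome and strand,
#' rendered as `"Chr4:104560738-104560800+"`.
#'
#' @param chrom Chromosome names.
#' @param start,end 1-based inclusive coordinates (`start <= end`).
#' @param strand `"+"` or `"-"`.
#' @return Character vector of locus strings.
#' @seealso [parse_locus()]
#' @export
#' @examples
#' locus_string("Chr4", 104560738, 104560800, "+")
locus_string <- function(chrom, start, end, strand) {
  stopifnot(all(start <= end), all(strand %in% c("+", "-")))
  sprintf("%s:%d-%d%s", chrom, as.integer(start), as.integer(end), strand)
}

#' Parse locus strings
#'
#' Inverse of [locus_string()]; round-trips exactly.
#'
#' @param x Character vector like `"Chr4:104560738-104560800+"`.
#' @return A data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
parse_locus <- function(x) {
  m <- regmatches(x, regexec("^(.+):([0-9]+)-([0-9]+)([+-])$", x))
  bad <- vapply(m, length, 1L) != 5L
  if (any(bad)) stop("malformed locus string: ", x[bad][1])
  data.frame(chrom = vapply(m, `[`, "", 2L),
             start = as.integer(vapply(m, `[`, "", 3L)),
             end = as.integer(vapply(m, `[`, "", 4L)),
             strand = vapply(m, `[`, "", 5L),
             stringsAsFactors = FALSE)
}

# data.frame (chrom/start/end/strand) -> GRanges, keeping extra columns.
loci_granges <- function(df) {
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  extra <- setdiff(names(df), c("chrom", "start", "end", "strand"))
  if (length(extra)) S4Vectors::mcols(gr) <- df[extra]
  gr
}
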