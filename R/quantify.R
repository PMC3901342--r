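#' Build the product x library count matrix
#'
#' Per-product raw counts summed over all isomiRs; mature and star arms are
#' separate rows. Library size is the column sum.
#'
#' @param product_summary Per-product totals, e.g. `products` from
#'   [catalog_isomirs()] (`product_id`, `total_f3`, `total_f4`).
#' @return A list: `counts` (integer matrix, rownames = product ids,
#'   columns `F3`, `F4`) and `lib_sizes`.
#' @export
build_counts <- function(product_summary) {
  if (!nrow(product_summary)) stop("empty count matrix")
  m <- as.matrix(product_summary[, c("total_f3", "total_f4")])
  dimnames(m) <- list(product_summary$product_id, c("F3", "F4"))
  storage.mode(m) <- "integer"
  list(counts = m, lib_sizes = colSums(m))
}

#' Pairwise TMM normalization factor
#'
#' Trimmed mean of M-values between two count vectors: per-gene M (log2
#' ratio of library-size-scaled proportions) and A (mean log2 abundance)
#' are computed over genes positive in both libraries; the most extreme
#' `trim_m` of M and `trim_a` of A are trimmed from both tails; the factor
#' is 2 to the precision-weighted mean of the remaining M, with weights the
#' inverse asymptotic variance of M under Poisson counts.
#'
#' @param counts_a,counts_b Non-negative count vectors of equal length;
#'   `counts_a` is the numerator library.
#' @param trim_m,trim_a Two-sided trim fractions for M and A.
#' @return The scalar factor `f` such that library a's proportions exceed
#'   library b's by `f` on the trimmed average (identical compositions give
#'   1). Use [tmm_factors()] for per-library factors with geometric mean 1.
#' @export
tmm_factor <- function(counts_a, counts_b, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(length(counts_a) == length(counts_b))
  na <- sum(counts_a); nb <- sum(counts_b)
  pos <- counts_a > 0 & counts_b > 0
  if (!any(pos)) {
    warning("no gene positive in both libraries; factor 1")
    return(1)
  }
  a <- counts_a[pos]; b <- counts_b[pos]
  M <- log2((a / na) / (b / nb))
  A <- 0.5 * (log2(a / na) + log2(b / nb))
  w <- 1 / ((na - a) / (na * a) + (nb - b) / (nb * b))
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  keep <- rank(M, ties.method = "first") >= loM &
    rank(M, ties.method = "first") <= hiM &
    rank(A, ties.method = "first") >= loA &
    rank(A, ties.method = "first") <= hiA
  if (!any(keep)) keep <- rep(TRUE, n)
  2^(sum(w[keep] * M[keep]) / sum(w[keep]))
}

#' Per-library TMM factors (geometric mean 1)
#'
#' @param counts A 2-column count matrix (`F3`, `F4`).
#' @inheritParams tmm_factor
#' @return Named numeric vector of two factors with geometric mean 1.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  f <- tmm_factor(counts[, 1], counts[, 2], trim_m, trim_a)
  out <- c(sqrt(f), 1 / sqrt(f))
  names(out) <- colnames(counts)
  out
}

#' Normalize raw read counts
#'
#' `normalized = raw / (library_size * factor) * 1e6` — reads per million
#' after TMM scaling.
#'
#' @param raw Raw read counts.
#' @param library_size Total assigned reads in the library.
#' @param factor TMM normalization factor for the library.
#' @return Normalized read counts.
#' @export
normalize_counts <- function(raw, library_size, factor = 1) {
  if (any(library_size <= 0)) stop("library_size must be positive")
  if (any(factor <= 0)) stop("factor must be positive")
  raw / (library_size * factor) * 1e6
}

#' Replicate-free differential expression test
#'
#' Under Poisson technical noise without biological replicates,
#' conditioning on the total `n = k1 + k2` makes `k1` Binomial(n, p0) with
#' `p0 = s1 / (s1 + s2)` (effective library sizes). The two-sided p-value
#' is the sum of binomial probabilities not exceeding the probability of
#' the observed `k1` — computed by exact summation for all totals.
#' `k1 = k2 = 0` returns 1 by convention.
#'
#' @param k1,k2 Read counts in the two libraries (vectors).
#' @param s1,s2 Effective library sizes (column sum times TMM factor).
#' @return Vector of two-sided p-values in (0, 1].
#' @export
de_test <- function(k1, k2, s1, s2) {
  stopifnot(all(s1 > 0), all(s2 > 0))
  nn <- length(k1)
  s1 <- rep_len(s1, nn); s2 <- rep_len(s2, nn)
  out <- numeric(nn)
  for (i in seq_len(nn)) {
    n <- k1[i] + k2[i]
    if (n == 0) { out[i] <- 1; next }
    p0 <- s1[i] / (s1[i] + s2[i])
    d <- dbinom(0:n, n, p0)
    # relative tolerance absorbs floating-point ties (cf. binom.test)
    out[i] <- min(1, sum(d[d <= d[k1[i] + 1] * (1 + 1e-7)]))
  }
  out
}

#' Call differential expression between the two libraries
#'
#' Normalized counts, log2 fold change (F3 over F4; a pseudocount is added
#' to both normalized values only when either raw count is zero, for
#' display — the test itself handles zeros exactly), exact binomial
#' p-value, and the call: `up`/`down` iff the absolute fold change strictly
#' exceeds `fc_threshold` and p is strictly below `p_threshold`. `up` means
#' higher in F3.
#'
#' @param counts 2-column matrix from [build_counts()].
#' @param factors TMM factors from [tmm_factors()] (or c(1, 1)).
#' @param fc_threshold Linear fold-change threshold (calls require strictly
#'   more than this fold).
#' @param p_threshold P-value threshold (strict).
#' @param pseudocount Added to both normalized counts when either raw count
#'   is zero.
#' @return A data.frame: `product_id`, raw and normalized counts, `log2fc`,
#'   `pvalue`, `call`, plus `scatter` attributes columns `log2_norm_f3`,
#'   `log2_norm_f4` for plotting.
#' @export
call_de <- function(counts, factors = c(1, 1), fc_threshold = 2,
                    p_threshold = 0.001, pseudocount = 0.5) {
  lib <- colSums(counts)
  eff <- lib * factors
  n3 <- normalize_counts(counts[, 1], lib[1], factors[1])
  n4 <- normalize_counts(counts[, 2], lib[2], factors[2])
  zero <- counts[, 1] == 0 | counts[, 2] == 0
  num <- ifelse(zero, n3 + pseudocount, n3)
  den <- ifelse(zero, n4 + pseudocount, n4)
  log2fc <- log2(num / den)
  p <- de_test(counts[, 1], counts[, 2], eff[1], eff[2])
  call <- ifelse(abs(log2fc) > log2(fc_threshold) & p < p_threshold,
                 ifelse(log2fc > 0, "up", "down"), "ns")
  data.frame(product_id = rownames(counts),
             raw_f3 = counts[, 1], raw_f4 = counts[, 2],
             norm_f3 = n3, norm_f4 = n4,
             log2_norm_f3 = log2(num), log2_norm_f4 = log2(den),
             log2fc = log2fc, pvalue = p, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}
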