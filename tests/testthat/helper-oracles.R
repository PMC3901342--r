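# Independent oracles: brute-force / enumeration implementations used only
# to check the package's fast paths. They share the published energy table
# (a set of physical constants) but none of the implementation code.

.oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

.pairable <- function(a, b) {
  paste0(a, b) %in% c("CG", "GC", "GU", "UG", "AU", "UA")
}

.ptype <- function(a, b) paste0(a, b)

# Energy of a complete single-stem structure given as a list of pairs
# (outer to inner), computed directly from the tables.
stem_energy_oracle <- function(chars, pairs, params) {
  k <- length(pairs)
  p1 <- pairs[[1]]
  t1 <- .ptype(chars[p1[1]], chars[p1[2]])
  e <- if (t1 %in% c("GU", "UG", "AU", "UA")) params$terminal_au else 0
  cap <- function(v, s) v[min(s, length(v) - 1) + 1]  # size-indexed, 0-based
  for (q in seq_len(k - 1)) {
    a <- pairs[[q]]; b <- pairs[[q + 1]]
    n1 <- b[1] - a[1] - 1; n2 <- a[2] - b[2] - 1
    ta <- .ptype(chars[a[1]], chars[a[2]])
    tb <- .ptype(chars[b[1]], chars[b[2]])
    e <- e + if (n1 == 0 && n2 == 0) params$stack[ta, tb]
    else if (n1 == 0 || n2 == 0) cap(params$bulge, n1 + n2)
    else cap(params$internal, n1 + n2)
  }
  inner <- pairs[[k]]
  e + cap(params$hairpin, inner[2] - inner[1] - 1)
}

# Exhaustive enumeration of all legal single-stem structures; returns the
# minimum energy (0 if no negative structure) and the number enumerated.
enum_stem_mfe <- function(seq, params = srnaforge::energy_params(),
                          min_hairpin = 3, max_loop = 30) {
  chars <- strsplit(chartr("TU", "UU", toupper(seq)), "")[[1]]
  n <- length(chars)
  best <- 0
  count <- 0
  rec <- function(pairs) {
    last <- pairs[[length(pairs)]]
    i <- last[1]; j <- last[2]
    if (j - i - 1 >= min_hairpin) {
      count <<- count + 1
      e <- stem_energy_oracle(chars, pairs, params)
      if (e < best) best <<- e
    }
    kmax <- j - min_hairpin - 2
    if (kmax < i + 1) return(invisible())
    for (k in (i + 1):kmax) {
      n1 <- k - i - 1
      if (n1 > max_loop) break
      lmin <- k + min_hairpin + 1
      if (lmin > j - 1) next
      for (l in lmin:(j - 1)) {
        n2 <- j - l - 1
        if (n1 + n2 > max_loop) next
        if (!.pairable(chars[k], chars[l])) next
        rec(c(pairs, list(c(k, l))))
      }
    }
  }
  for (i in seq_len(max(0, n - min_hairpin - 1))) {
    for (j in (i + min_hairpin + 1):n) {
      if (.pairable(chars[i], chars[j])) rec(list(c(i, j)))
    }
  }
  list(mfe = best, n_structures = count)
}

# Brute-force tag alignment: slide over every position of every chromosome
# on both strands, apply the end-mismatch rule literally.
brute_align <- function(tag, genome_chars, max_end_mm = 2) {
  L <- nchar(tag)
  hits <- list()
  for (ch in names(genome_chars)) {
    gv <- strsplit(genome_chars[[ch]], "")[[1]]
    G <- length(gv)
    if (G < L) next
    for (strand in c("+", "-")) {
      q <- if (strand == "+") tag else .oracle_revcomp(tag)
      qv <- strsplit(q, "")[[1]]
      neq <- matrix(FALSE, G - L + 1, L)
      for (t in seq_len(L))
        neq[, t] <- gv[t:(G - L + t)] != qv[t]
      total <- rowSums(neq)
      interior <- rowSums(neq[, 3:(L - 2), drop = FALSE])
      ok <- which(total <= max_end_mm & interior == 0)
      for (s in ok) {
        qp <- which(neq[s, ])
        ro <- if (strand == "+") qp - 1L else L - qp
        hits[[length(hits) + 1]] <- data.frame(
          chrom = ch, start = s, end = s + L - 1L, strand = strand,
          n_mismatch = total[s],
          mismatch_offsets = paste(sort(ro), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      n_mismatch = integer(0),
                      mismatch_offsets = character(0)))
  out <- do.call(rbind, hits)
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

# Direct application of the TMM formula (quantile trimming + precision
# weights), written independently of the package implementation.
tmm_direct <- function(a, b, trim_m = 0.30, trim_a = 0.05) {
  na <- sum(a); nb <- sum(b)
  keep <- a > 0 & b > 0
  a <- a[keep]; b <- b[keep]
  M <- log2((a / na) / (b / nb))
  A <- 0.5 * (log2(a / na) + log2(b / nb))
  w <- 1 / ((na - a) / (na * a) + (nb - b) / (nb * b))
  qm <- stats::quantile(M, c(trim_m, 1 - trim_m), type = 1)
  qa <- stats::quantile(A, c(trim_a, 1 - trim_a), type = 1)
  sel <- M >= qm[1] & M <= qm[2] & A >= qa[1] & A <= qa[2]
  2^(sum(w[sel] * M[sel]) / sum(w[sel]))
}

# Two-sided binomial p by full enumeration over k = 0..n.
binom_two_sided_enum <- function(k1, n, p0) {
  probs <- vapply(0:n, function(k) choose(n, k) * p0^k * (1 - p0)^(n - k), 0)
  sum(probs[probs <= probs[k1 + 1] * (1 + 1e-7)])
}

# Brute-force all-pairs cluster chaining: a locus belongs to a cluster with
# another iff a chain of loci with consecutive gaps < window links them.
brute_clusters <- function(loci, window = 10000) {
  n <- nrow(loci)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (loci$chrom[i] != loci$chrom[j]) next
    gap <- max(loci$start[j] - loci$end[i], loci$start[i] - loci$end[j])
    if (gap < window) { adj[i, j] <- TRUE; adj[j, i] <- TRUE }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] > comp[i]) { comp[j] <- comp[i]; changed <- TRUE }
      if (adj[i, j] && comp[i] > comp[j]) { comp[i] <- comp[j]; changed <- TRUE }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  in_cluster <- comp %in% as.integer(names(sizes)[sizes >= 2])
  list(component = comp, in_cluster = in_cluster)
}
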