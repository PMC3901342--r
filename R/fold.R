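#' Fold a sequence into its minimum-free-energy single stem-loop
#'
#' Dynamic program over secondary structures restricted to a single
#' stem-loop (one terminal loop, no multibranch): a chain of nested
#' Watson-Crick or GU pairs separated by stacks, bulges or internal loops
#' and closed by a hairpin loop of at least `min_hairpin_loop` unpaired
#' bases. The energy model is nearest-neighbor stacking plus loop
#' initiation penalties by size and a terminal penalty when the
#' exterior-most pair is AU/UA/GU/UG; unpaired exterior bases contribute
#' nothing. Pre-miRNA validation only requires stem-loops, and the
#' restriction keeps an exhaustive enumeration oracle tractable.
#'
#' If no structure with negative energy exists the all-unpaired structure
#' is returned with `delta_g = 0`.
#'
#' @param sequence A nucleotide string (ACGU; T is read as U).
#' @param params Energy parameter list, see [energy_params()].
#' @param min_hairpin_loop Minimum hairpin loop size in nt.
#' @param max_loop Maximum total size of a bulge or internal loop; larger
#'   gaps between consecutive pairs are disallowed.
#' @return A list of class `fold_result`: `sequence`, `structure`
#'   (dot-bracket), `delta_g` (kcal/mol), and `pairs` (1-based pair table,
#'   0 = unpaired).
#' @export
#' @examples
#' fold_mfe("GGGGAAAACCCC")$structure  # "((((....))))"
fold_mfe <- function(sequence, params = energy_params(),
                     min_hairpin_loop = 3L, max_loop = 30L) {
  stopifnot(is.character(sequence), length(sequence) == 1, nchar(sequence) > 0)
  seq <- toupper(sequence)
  if (grepl("[^ACGTU]", seq)) stop("non-ACGTU character in sequence")
  res <- fold_mfe_cpp(seq, params$stack,
                      replace(params$hairpin, !is.finite(params$hairpin), 1e9),
                      replace(params$bulge, !is.finite(params$bulge), 1e9),
                      replace(params$internal, !is.finite(params$internal), 1e9),
                      params$terminal_au,
                      as.integer(min_hairpin_loop), as.integer(max_loop))
  structure(list(sequence = sequence, structure = res$structure,
                 delta_g = res$delta_g, pairs = res$pairs),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n",
      sprintf("delta G = %.2f kcal/mol\n", x$delta_g), sep = "")
  invisible(x)
}

# Pair table (1-based, 0 = unpaired) from a dot-bracket string.
pair_table <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced dot-bracket")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced dot-bracket")
  pt
}
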