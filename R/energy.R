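# Turner 2004 nearest-neighbor free energies (delta-G at 37 C, kcal/mol).
# Stacking is tabulated for Watson-Crick and GU wobble pairs; loop
# initiation penalties are indexed by total loop size (0..30; larger loops
# reuse the size-30 value). Values are the published Turner 2004 set.

PAIR_TYPES <- c("CG", "GC", "GU", "UG", "AU", "UA")

# stack_raw[p1, p2rev]: energy of outer pair p1 = (i, j) stacked on the
# inner pair given in reversed orientation p2rev = (j-1, i+1), the
# orientation in which the set is usually printed.
.stack_raw <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
), nrow = 6, byrow = TRUE, dimnames = list(PAIR_TYPES, PAIR_TYPES))

.rev_pair <- c(CG = "GC", GC = "CG", GU = "UG", UG = "GU", AU = "UA", UA = "AU")

# Reindex so stack[p1, p2] is outer pair (i,j) over inner pair (i+1,j-1),
# both read 5'->3' on the top strand.
.stack <- .stack_raw[, .rev_pair[PAIR_TYPES]]
colnames(.stack) <- PAIR_TYPES

# Loop initiation penalties by loop size 0..30 (kcal/mol). Inf marks sizes
# that cannot occur (hairpin loops < 3, bulges of 0, internal loops < 2).
.hairpin_init <- c(Inf, Inf, Inf, 5.40, 5.60, 5.70, 5.40, 6.00, 5.50, 6.40,
                   6.50, 6.60, 6.70, 6.80, 6.90, 6.90, 7.00, 7.10, 7.10,
                   7.20, 7.20, 7.30, 7.30, 7.40, 7.40, 7.50, 7.50, 7.50,
                   7.60, 7.60, 7.70)
.bulge_init <- c(Inf, 3.80, 2.80, 3.20, 3.60, 4.00, 4.40, 4.60, 4.70, 4.80,
                 4.90, 5.00, 5.10, 5.20, 5.30, 5.40, 5.40, 5.50, 5.50, 5.60,
                 5.70, 5.70, 5.80, 5.80, 5.80, 5.90, 5.90, 6.00, 6.00, 6.00,
                 6.10)
.internal_init <- c(Inf, Inf, 1.00, 1.00, 1.10, 2.00, 2.00, 2.10, 2.30, 2.40,
                    2.50, 2.60, 2.70, 2.80, 2.90, 2.90, 3.00, 3.10, 3.10,
                    3.20, 3.30, 3.30, 3.40, 3.40, 3.50, 3.50, 3.50, 3.60,
                    3.60, 3.70, 3.70)

.terminal_au <- 0.50

#' Nearest-neighbor energy parameters
#'
#' The Turner 2004 delta-G (37 C) parameter set used by [fold_mfe()]:
#' stacking energies for Watson-Crick and GU pairs, hairpin / bulge /
#' internal loop initiation penalties by loop size, and the terminal AU/GU
#' penalty applied to the exterior-most pair of a stem.
#'
#' @return A list with elements `stack` (6x6 matrix indexed by pair type,
#'   `stack[p1, p2]` = outer pair `p1` stacked on inner pair `p2`),
#'   `hairpin`, `bulge`, `internal` (penalties for loop sizes 0..30),
#'   `terminal_au` (scalar), and `pair_types` (the row/column order).
#' @export
#' @examples
#' energy_params()$stack["GC", "GC"]  # a GC/GC stack, -3.4 kcal/mol
energy_params <- function() {
  list(stack = .stack,
       hairpin = .hairpin_init,
       bulge = .bulge_init,
       internal = .internal_init,
       terminal_au = .terminal_au,
       pair_types = PAIR_TYPES)
}
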