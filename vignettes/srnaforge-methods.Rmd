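---
title: "Methods: small RNA discovery, characterization and two-library comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA discovery, characterization and two-library comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Deep sequencing of the 15–35 nt RNA fraction of a tissue yields millions of
short reads, most of them mature microRNAs, their passenger (star) strands,
length/end variants (isomiRs), and fragments of abundant structural RNA.
`srnaforge` implements the complete analysis for a two-library design
without biological replicates — for example a castrated (F3) versus intact
(F4) sibling-pair comparison: read cleaning, genome mapping with
end-confined mismatches, discovery of novel miRNA genes by hairpin folding,
conservation classification, isomiR/cluster/mirtron characterization,
TMM-normalized quantification, and an exact replicate-free differential
expression test. A synthetic-data generator plants every one of these
features into a compact genome so the whole pipeline is testable end to end
without external data.

# Preprocessing

Reads below a mean Phred of 20 are dropped (the raw-data quality filter of
the original instrument software is not reproducible; a mean-quality gate is
the configurable surrogate). The 3′ adapter is found by a deterministic
prefix scan: a match at read position $s$ covers
$\mathrm{ov} = \min(|A|,\ L - s + 1)$ adapter bases and qualifies when
$\mathrm{ov} \ge 6$ and the mismatch fraction is at most $0.1$; the match
consuming the most adapter bases wins, ties broken leftmost. Untrimmed
full-length reads are kept (flagged): an insert at least as long as the read
carries no adapter. Inserts outside 15–35 nt or containing non-ACGT symbols
are discarded; the survivors collapse into unique tags with per-library
counts. Collapsing conserves retained read totals per library, a property
asserted in the test suite.

# Alignment with end-confined mismatches

A tag aligns at a locus when at most two mismatches separate it from the
genome, all confined to the two outermost positions of either end; the core
(read offsets 2..L−3) must match exactly. Both mismatches may sit at one
end. This is the strictest reading of "up to two end-nucleotide mismatches"
and accommodates exactly the two end phenomena the biology produces:
isomiR end variation and non-templated 3′ additions. Implementation: an
11-nt seed at query positions 3–13 (always inside the protected core for
15–35-nt tags) is matched exactly with a Biostrings dictionary on both
strands, and each seed hit is verified in C++ against the full tag. Tags
with more than 20 qualifying loci are flagged repeat-derived and excluded
from discovery. A brute-force scan over every position of both strands
serves as the oracle in the tests; the two agree exactly on all tested
genomes.

Coordinates are 1-based inclusive throughout and render as
`Chr4:104560738-104560800+`; BED-style export would subtract one from the
start.

# Hairpin folding

Novel miRNA discovery rests on folding candidate precursor windows. The
folding engine is a single stem-loop minimum-free-energy dynamic program:
structures are chains of nested Watson-Crick or GU pairs separated by
stacks, bulges or internal loops, closed by a terminal loop of at least 3
nt — no multibranch loops, which pre-miRNA validation does not need, and
whose exclusion keeps an exhaustive enumeration oracle tractable. The
energy model is the published Turner 2004 ΔG°37 set: the stacking table
(Watson-Crick and GU), hairpin/bulge/internal loop initiation penalties by
loop size (capped at size 30; larger hairpin loops reuse the size-30
value, larger bulge/internal gaps are disallowed), and a +0.50 kcal/mol
terminal penalty when the exterior-most pair is AU/UA/GU/UG. Deliberate
simplifications relative to a full folding engine: no loop-sequence
(mismatch) terms, no special tetraloop bonuses, no asymmetry (Ninio)
penalty, and the terminal penalty applies only at the exterior-most pair.
These terms shift absolute energies by a few kcal/mol at most; the planted
stems of the generator carry 19–25 complementary, GC-biased pairs
(ΔG ≈ −30 to −50 kcal/mol), so the −20 kcal/mol discovery gate is
insensitive to them, and the exhaustive oracle in the tests applies the
same tables so the dynamic program is verified against enumeration for all
sequences up to 20 nt.

```{r}
library(srnaforge)
fold_mfe("GGGGAAAACCCC")
#> GGGGAAAACCCC
#> ((((....))))
#> delta G = -4.30 kcal/mol
```

# Precursor excision and the hairpin classifier

For each candidate locus (overlapping hits of unannotated tags merged,
represented by the most abundant tag as the putative mature), two
90-nt windows with a 5-nt flank are excised — one per arm hypothesis — and
folded. Excision is two-phase: the window fold locates the miRNA:miRNA*
duplex, the window is trimmed to the duplex extent plus 2 nt, and the
trimmed precursor is refolded. Without the refold, random flank sequence
that happens to pair onto the stem inflates the reported precursor span and
dilutes its energy density. Because exterior unpaired bases carry no
energy, the gate is effectively applied to the trimmed precursor (the
stated resolution of whether the energy gate concerns the window or the
precursor).

A candidate passes when all of the following hold (each threshold
configurable via `hairpin_rules()`):

* folding free energy ≤ −20 kcal/mol — the classic discovery gate;
* a single terminal loop of 3–25 nt;
* the mature lies entirely within one arm, with ≥ 60% of its bases paired;
* trimmed precursor span within 50–150 nt;
* MFE index `MFEI = (|ΔG|/length × 100) / GC%` ≥ 0.85.

The rule set stands in for a learned hairpin classifier, with every
threshold explicit and auditable. The MFEI criterion is essential rather
than decorative: measured on this generator, expressed non-hairpin decoy
windows pass the first four rules at ~37% through the best-of-two-hypotheses
path (random ~90-mers often reach −20 kcal/mol), while their MFEI
concentrates near 0.65; genuine pre-miRNA hairpins typically exceed 0.85.
With the MFEI rule, 0 of 300 simulated decoy windows pass while every
planted hairpin is recovered.

The star strand follows Dicer geometry: the pairing partner of the mature
shifted to leave 2-nt 3′ overhangs at both duplex ends. Pairs whose
pairing register (`i + pt[i]`) deviates more than 6 nt from the mature's
median register belong to a different helix (a flank extension across a
large internal loop) and are ignored; genuine 1–2 nt duplex bulges still
shift the star ends.

# Annotation, isomiRs and novel gene calling

Each tag receives exactly one category: known miRNA first (≥ 16 nt
same-strand overlap with a known mature or star locus), then
rRNA > tRNA > snoRNA > other ncRNA > mRNA exon, else candidate; unmapped
and repeat-derived tags are so labelled. Putting miRNA assignment first
prevents losing miRNAs that happen to overlap spurious annotations.

Tags assign to products by locus overlap (not sequence identity alone, so
paralogs with identical matures resolve genomically; identical matures at
several loci collapse to one product). Offsets are bounded at ±4 (5′) and
±6 (3′); a mismatched 3′ tail of up to 3 A/T bases inconsistent with the
genomic template is recorded as a non-templated addition and removed from
the 3′ offset. Per product, the reference isomiR is the most abundant
variant (ties to the lexicographically smallest sequence) — which need not
equal the annotated reference sequence; a gene whose star product
out-expresses its mature is flagged star-dominant.

Novel genes come from passing hairpin candidates: candidates overlapping a
known precursor merge into the known gene; the rest deduplicate by ≥ 50%
reciprocal overlap, strand-agnostically, because the antisense image of a
fold-back locus is itself hairpin-like and would otherwise double-report;
identical matures at distant loci merge into one multi-locus gene. A novel
gene is conserved when either duplex arm is within 2 substitutions of an
ortholog mature (equal-length Hamming, or total differences allowing one
end extension); both arms are checked because for star-dominant genes the
catalogued mature is the biological star. Names are assigned sequentially
in genomic order per library and class.

Clusters chain precursors on a chromosome while the end-to-start gap is
strictly below 10 kb, strand ignored; maximal chains of ≥ 2 are clusters.
Mirtron flags require both precursor ends within 3 nt of one intron's
donor/acceptor boundaries on the same strand; the pipeline reconstructs
those ends from the duplex (one mature end sits on a splice site; the
opposite boundary is the star 3′ end minus its 2-nt overhang), which is
robust to flank pairs that the trimmed precursor span may acquire.
Genomic density is loci per Mb, rounded to 2 decimals.

# Quantification and differential expression

Counts are per product (mature and star separately), summed over isomiRs.
TMM normalization is implemented from its definition: per-gene
$M_g = \log_2\frac{y_{gA}/N_A}{y_{gB}/N_B}$ and
$A_g = \tfrac12(\log_2 y_{gA}/N_A + \log_2 y_{gB}/N_B)$ over genes positive
in both libraries, two-sided trimming of 30% on M and 5% on A, and a
precision-weighted mean of the surviving M with inverse asymptotic-variance
weights; the pair of library factors is scaled to geometric mean 1. The
implementation is checked against a direct-formula oracle and against the
established edgeR implementation (both within 5%). Normalized counts follow
`raw / (library size × factor) × 10⁶`.

Without replicates, only technical (Poisson) variation is modelled:
conditional on the total $n = k_1 + k_2$, $k_1 \sim
\mathrm{Binomial}(n, p_0)$ with $p_0 = s_1/(s_1+s_2)$ and $s_i$ the
effective (TMM-scaled) library sizes. The two-sided p-value sums binomial
probabilities not exceeding the probability of the observed count. The
summation is exact for every total — at the totals this analysis produces
(≤ ~10⁶) exact evaluation is fast, so no normal approximation is used and
no approximation boundary needs validating. $k_1=k_2=0$ gives p = 1 by
convention. A product is called differential iff the fold change strictly
exceeds 2 **and** p < 0.001, both strict; `up` means higher in F3. P-values
are used raw, matching the stated threshold convention (Benjamini-Hochberg
is available via `p.adjust` on the output if desired). For display only, a
0.5 pseudocount enters the log2 fold change when either raw count is zero;
the test itself handles zeros exactly (an `0 vs 83,244` product is an
extreme but valid call).

Null calibration is asserted in the tests: over 5,000 null products at mean
500, the fraction with p < 0.001 lies within the binomial 99% interval
around 0.001 (the exact test is conservative at discrete counts). Power:
with planted 4-fold changes and means ≥ 200, over 95% of planted products
are called with the correct direction.

# The synthetic-data generator

The generator emulates the study conditions end to end. Defaults describe
a 2 Mb genome (4 × 500 kb), 100 planted miRNA genes — 12 clustered
(groups of 2–3, gaps 0.5–8 kb), 5 mirtrons occupying annotated 50–61 nt
introns exactly, 4 duplicated on one chromosome, 40 exported as the known
reference, 15 exported (with ≤ 2 substitutions) as orthologs — plus 20
expressed non-hairpin decoy loci, and ~100,000 expected reads per library:
the scale at which the whole pipeline runs in minutes on one CPU while
every downstream stage has enough signal to be measured. Planted hairpins
are a GC-biased 21–23 nt mature, an AU-rich 8–15 nt loop and the
reverse-complemented arm with 0–2 substitutions, so the −20 kcal/mol gate
is met by construction under any reasonable nearest-neighbor table.
Expression follows a log-normal across genes (sdlog 1.2); star arms
average 12% of their mature with occasional dominance; 30% of products
carry a planted log2 fold change of ±2 on the F3/F4 scale
($F3 \sim \mathrm{Poisson}(m\,2^{+\mathrm{lfc}/2})$,
$F4 \sim \mathrm{Poisson}(m\,2^{-\mathrm{lfc}/2})$). IsomiR variants at 5′
offsets −2..2 and 3′ offsets −3..3 decay geometrically (rate 0.35) around
the reference; 8% of reads gain a 1-nt non-templated A/U; 5% of reads come
from annotated rRNA/tRNA loci with lengths 13–38 nt so the length filter
is exercised; every insert is extended with the adapter and clipped to
35 nt. Identical configurations (including seed) produce byte-identical
outputs; non-clustered loci keep a 12 kb clear zone so no unplanned
cluster contaminates the truth tables.

What the generator does **not** emulate: color-space sequencing and its
error profile (the analysis operates on nucleotide tags either way),
realistic quality-score models, ligation bias, genuine isomiR abundance
laws (the geometric decay is a stand-in, not a claim about real data),
A-to-I editing, and cross-mapping between paralog families. Passing tests
therefore demonstrate correctness of the algorithms under the stated noise
model, not performance on real libraries.

# Numerical choices and tie-breaks

* Reference isomiR ties: lexicographically smallest sequence.
* Candidate-locus representative ties: highest count, then smallest
  sequence; overlap-component representative likewise.
* Ambiguous product assignment: largest overlap, then lowest product id.
* Cluster gaps: end-to-start, strict `< window`, strand-agnostic.
* Degenerate inputs: empty tag sets give all-zero length tables; an empty
  count matrix errors; a zero-length chromosome errors; missing intron
  annotation yields all-FALSE mirtron flags with a warning.
* All randomness flows through stage-specific 31-bit seeds derived from
  the single user seed; library code restores the caller's RNG state.

# Problem sizes used by the tests and acceptance script

Module tests run on toy genomes (2–30 kb) and a compact simulation
(2 × 120 kb, 12 genes, ~16k reads). The acceptance checks run the default
configuration above (~2 Mb, 100 genes + 20 decoys, ~200k reads; about two
minutes end to end), plus count-level experiments for DE power (300
products) and null calibration (5,000 products). The folding oracle
enumerates all single-stem structures for random sequences up to 20 nt;
the alignment oracle scans 5–8 kb genomes exhaustively.

# Known limitations

* The single-stem restriction cannot represent multibranch folds; a real
  precursor inside a larger structured transcript may fold differently in
  a full partition-function engine.
* The rule-based hairpin classifier is tuned for discovery specificity on
  hairpin-vs-random discrimination; it does not learn species-specific
  sequence composition as a trained classifier would.
* Without biological replicates the binomial test measures technical
  reproducibility only; its p-values overstate certainty about biological
  effects, which is inherent to the design it implements.
* Conservation classification is Hamming-based; it does not model seed
  families or synteny.
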