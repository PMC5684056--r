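---
title: "Karyotype morphometrics and parsimony phylogenetics with karyophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype morphometrics and parsimony phylogenetics with karyophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

karyophy implements the two computational stages of a classical plant
cytotaxonomy workflow — karyotype morphometrics and maximum-parsimony
phylogenetics of the nuclear ITS region — together with the simulators
needed to exercise both at desk scale. This vignette explains the models
and conventions behind each stage, the parameters that matter, and the
design choices that were genuinely open.

## The karyotype model

A karyotype survey measures, on photographed metaphase plates, the
short-arm length $S$ and long-arm length $L$ of every chromosome in a
set of cells (here in µm). The pipeline reduces those replicate
measurements to one row per homolog pair:

* **Full length** $C = S + L$, taken per chromosome *before* averaging.
  When a directly measured total length is recorded alongside the arms
  (the usual practice), that value is preferred; this is why a published
  full-length column, and the haploid total derived from it, can differ
  from the sum of the averaged arm columns by ±0.01 µm per row. The
  haploid set length is the sum of the pair full-length means.
* **Relative length** $= 100 \, C_i / \sum_j C_j$, in percent. Rounded
  values sum to 100 within ±0.1.
* **Arm ratio** $r = L/S \ge 1$; arms recorded in the opposite order are
  swapped with a warning (field data do arrive both ways) rather than
  rejected.
* **Centromere class** from the arm ratio, using the Levan-derived
  bounds common in *Lilium* work: median (m) 1.00–1.70, submedian (sm)
  1.71–3.00, subterminal (st) 3.01–7.00, terminal (t) ≥ 7.01.

### Rounding and the class-boundary gaps

Published class bounds leave gaps on the real line (1.70 → 1.71,
3.00 → 3.01, 7.00 → 7.01). karyophy closes them by rounding the ratio
**half-up to two decimals first** and then testing inclusive bounds, so
every rounded ratio falls in exactly one class. Half-up rounding (not
R's default half-to-even) is used wherever a printed table value is
reproduced: it is what turns 1.425 into 1.43 and 10.476 into 10.48, the
values printed for the reference complement. `round_half_up()` is
exported so reports stay consistent with the tables.

The reference complement's relative-length column reproduces exactly in
nine of twelve rows; rows 2, 6 and 12 print values 0.01 below the
recomputation, a pattern consistent with the source table having been
derived from unrounded raw means. Those three cells are compared with a
±0.015 tolerance rather than guessed at.

## Homolog pairing

Pairing is the one genuinely open design problem. With explicit
`pair_label`s (the authoritative path) records are simply grouped. For
unlabelled records two automatic rules are provided:

* **`method = "arms"` (default).** Within a cell, the longest unpaired
  chromosome is paired with its nearest neighbour in $(S, L)$ space;
  across cells, each cell's pairs are assigned greedily to running
  $(S, L)$ centroids seeded from the first cell. This mimics how a
  cytologist matches homologs — by size *and* centromere position — and
  exploits the fact that multiplicative measurement noise leaves short
  arms almost noise-free in absolute terms.
* **`method = "rank"`.** Sort by full length and pair consecutive ranks.
  This naive rule is only reliable when between-pair length gaps exceed
  the measurement noise. In the reference complement six pairs lie
  within 0.05–0.24 µm of their neighbour in total length while differing
  strongly in arm ratio, and simulation shows the consequence starkly:
  at 2% arm noise over 3 individuals × 3 cells, arm-geometry pairing
  recovers the published formula in 99/100 seeds, size-rank pairing in
  1/100 (`analysis/03_karyotype_recovery.R` reruns this). Rank pairing
  is retained for well-separated complements and for comparability.

Auto-pairing requires an even count per cell; aneuploid or
B-chromosome-bearing cells must be labelled explicitly, since no
automatic rule can decide which chromosome is supernumerary.

## Karyotype formulas

The formula object counts chromosomes per centromere class, splitting
plain from satellited (secondary-constriction) chromosomes, plus
supernumerary B chromosomes, which are excluded from 2n (written
"24 + 2B"). The canonical rendering is

```
2n = 2x = 24 = 2m + 2m(sat) + 2sm + 8st + 10t
```

The parser additionally accepts the dialects found across the
literature: uppercase `(SAT)`, counted secondary-constriction notes
such as `4st (2sc)` (two of the four st chromosomes satellited), loose
spacing, and an optional ploidy clause. Parsing validates that the
counts sum to 2n; `parse_formula(format_formula(x))` is the identity on
counts, property-tested over random complements.

## Idiograms

The haploid idiogram orders pairs by descending relative length and
draws each as a bar split at the centromere
(`short_fraction` $= \bar S / \bar C \le 0.5$), with satellites as
detached blocks on their arm. The contract-bearing numbers are in
`build_idiogram()`; the SVG writer is cosmetic.

## Parsimony phylogenetics

The ITS stage re-implements unweighted (Fitch) parsimony from first
principles; `ape` supplies only the tree container and Newick/FASTA
plumbing, and `phangorn` appears solely as an independent cross-check
in the test suite.

* **Scoring.** Nucleotides are bitmasks (A=1, C=2, G=4, T=8); IUPAC
  ambiguity codes map to their state sets and gaps/N/? to the full set,
  i.e. missing data that never forces a change. One postorder sweep
  intersects child state sets, counting an extra change whenever the
  intersection is empty. Trees are scored as unrooted; the score is
  invariant to rooting and taxon order.
* **Exhaustive search** enumerates all $(2n-5)!!$ unrooted topologies by
  recursive tip insertion — the guaranteed optimum, refused above 8 taxa
  (10395 topologies).
* **Heuristic search** uses random-addition stepwise insertion (each
  taxon placed on the score-minimising branch) followed by
  nearest-neighbour-interchange hill climbing, repeated over `n_starts`
  random addition orders. The original analysis tool's exact swap
  options are not recoverable, so the heuristic is oracle-bounded
  instead: with the default 10 starts it attained the exhaustive optimum
  on 100/100 random 6-taxon × 50-site matrices (NNI alone from a single
  start is stuck in a local optimum on roughly a tenth of such rugged
  random landscapes — random restarts are the standard remedy, and the
  matrices real ITS data produce are far less rugged).
* **Ties.** All equally parsimonious topologies are retained from a
  search. Within a bootstrap replicate exactly one best tree is counted
  (score first, then canonical topology order), so supports sum
  sensibly.

### Bootstrap and rooting

Felsenstein's nonparametric bootstrap resamples alignment columns with
replacement to the original length — realised as integer site weights,
which is arithmetically identical and avoids copying the matrix — runs
one random-addition search per replicate, and records the best tree's
bipartitions. Support is $100 \times$ count/replicates; retention is
**inclusive** at the threshold (70.0% is kept at a threshold of 70,
69.9% is not), matching the convention of reporting "bootstrap
percentages ≥ 70". Splits are stored canonically as the taxon side
excluding a reference taxon, so identical splits compare as strings.
Rooting places the root on the branch to the named outgroup; each
internal node then carries its split's retained support as an integer
percent label. Whether a published consensus was strict or majority-rule
among co-optimal trees is generally unstated; karyophy exposes the full
set of co-optimal trees and the full support table so either summary can
be formed.

### ITS partitioning

`partition_its()` slices a transcript with 1-based inclusive
coordinates; the defaults are the reference transcript's regions
(ITS1 1–229, 5.8S 230–393, ITS2 394–590), giving 229/164/197 bases on a
590-base input, concatenating back to the input. Too-short sequences
are rejected with the deficit named.

## The simulators, and what they do not show

* **Metaphase simulation** draws each arm as
  truth × (1 + Normal(0, cv)), emits two homolog records per pair per
  cell, shuffles record order and withholds labels. Defaults mirror a
  typical survey: 3 individuals, 2% arm noise. Multiplicative noise was
  chosen over additive because 2% of a 0.42 µm short arm is a plausible
  measurement error while a fixed additive error would destroy small
  arms. Not emulated: correlated within-cell condensation differences,
  aneuploid cells, B chromosomes, or satellite-length ambiguity (the
  fixture treats printed arms as satellite-inclusive, since the source
  does not say otherwise).
* **Sequence simulation** is Jukes–Cantor: uniform root states, change
  probability $\tfrac{3}{4}(1 - e^{-4b/3})$ per branch of length $b$,
  uniform among the three other states. This is test-harness policy —
  the simplest model sufficient to test parsimony recovery — not a claim
  about ITS evolution; no indels, rate variation or base-composition
  bias are simulated, so passing recovery tests show algorithmic
  correctness, not robustness to real ITS alignment artefacts.

Both simulators are deterministic given their seed; replicate loops use
per-replicate derived stream seeds (`derive_seed()`), so results do not
depend on replicate order and stay within 32-bit integer range.

## Problem sizes and numerical conventions

The validation experiments use 6-taxon matrices (105 topologies, where
the exhaustive oracle is cheap), 50–590 sites (590 being the reference
ITS length), 100-seed recovery loops, and 200–1000 bootstrap
replicates — sizes chosen so the whole battery runs in well under a
minute while keeping binomial noise far from the asserted margins.
Scores are integers, so oracle-equality checks are exact; the only real
tolerances are the ±0.015 on the three rounding-ambiguous
relative-length cells and the 3-standard-error bands on simulation
means.

## Known limitations

* Automatic pairing presumes a regular diploid complement; aneuploidy
  and B chromosomes require labels.
* The heuristic search is oracle-validated at small taxon counts only;
  for many-taxon matrices the number of starts, not NNI, is the main
  quality lever.
* Karyotype asymmetry indices, image-based measurement, multiple
  sequence alignment and model-based (ML/Bayesian) inference are out of
  scope.
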