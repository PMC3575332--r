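---
title: "Genome-independent imputation for pseudo-testcross genotype matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-independent imputation for pseudo-testcross genotype matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maskovr)
```

## The problem

Genotyping by sequencing (GBS) delivers thousands of SNP markers for a
two-parent outcrossing (CP) progeny at low cost, but shallow, uneven
sequencing leaves a large fraction of calls missing -- often a third of
the matrix, with strong variance between individuals -- and introduces
genotyping errors. In a pseudo-testcross design, markers heterozygous in
exactly one parent segregate 1:1, so each individual's genotypes along a
correctly ordered linkage group form long phase blocks separated by a
handful of crossovers. Errors masquerade as double recombinants,
inflating the perceived recombination count per individual by an order of
magnitude and, through it, the map length; missing values make multipoint
ordering expensive and unstable. Reference-genome-based imputation is not
available for most such species.

`maskovr` corrects both defects directly from the expected block
structure, with no reference genome: given markers pre-ordered within
linkage groups, it treats each individual's encoded genotype sequence as
a piecewise-constant signal plus noise, finds the phase transitions
(recombination edges) by convolution, and resets every block to its
majority genotype -- simultaneously imputing missing calls and
overwriting isolated erroneous ones.

## Encoding and the three passes

Calls are encoded per marker phase: heterozygous in phase `1-` or
homozygous in phase `0-` map to `+1`, the complementary configurations to
`-1`, missing to `0`. Flipping a marker's phase negates its encoded
values, so all downstream statistics are phase-equivariant.

For one individual on one group the algorithm runs three passes:

1. **Compression.** Missing values carry no recombination information and
   dilute the edge signal, so they are removed; an index map remembers
   the original coordinates.
2. **Edge detection.** The compressed sequence is convolved with the
   antisymmetric sign mask of length $2E+1$,
   $M = (-1, \dots, -1, 0, +1, \dots, +1)$, a windowed first derivative.
   A clean phase transition scores exactly $\pm 2E$; positions with
   $|\mathrm{conv}| > T$ (default $T = E$) mark an edge. A contiguous
   above-threshold run of one sign collapses to a single edge placed at
   the leftmost maximum of the run -- a clean edge produces a symmetric
   two-position plateau whose leftmost maximum is the true boundary, so
   a deterministic tie rule is needed and this one is exact in the
   error-free case.
3. **Winner-take-all filling.** Each block between consecutive edges is
   set uniformly to its majority sign (ties take the block's leftmost
   entry); adjacent blocks that end up equal are merged and their edge
   dropped. The corrected sequence is then expanded back to the original
   coordinates: each formerly missing position inherits its nearest
   non-missing neighbour's value, with equidistant ties going to the
   left (proximal) neighbour, so a recombination inside a missing run is
   placed at the run's proximal end -- a conservative choice.

Individuals with more than `max_missing` (default 70%) missing data on a
group are passed through unimputed and flagged rather than dropped, so
the matrix keeps its shape.

### What the parameters mean

* `E` (default 5) is the half-width of the convolution window, described
  operationally as the maximum number of expected consecutive errors.
  Larger `E` detects edges more reliably but localizes them less
  precisely and enlarges the terminal dead zones.
* `T` (default `E`) is the edge threshold on $|\mathrm{conv}|$, strict
  inequality. Since an isolated cluster of $j$ opposing calls scores
  $2j$, clusters up to $\lfloor E/2 \rfloor$ stay below the default
  threshold and are corrected by the majority vote; larger clusters are
  detected as a pair of edges and preserved as a genuine short block.
  This correction capacity -- $\lfloor E/2 \rfloor$, not $E$ -- is the
  exact arithmetic of the sign mask with threshold $E$.
* `max_missing` (default 0.70) caps the tolerated missing fraction per
  individual and group.

### Numerical and boundary choices

The mask coefficients are the signs $\mathrm{sign}(k)$; any antisymmetric
weighting computes *a* first derivative, and the sign mask is chosen
because it makes the clean-edge score exactly $2E$ and the error
arithmetic above exact. Convolution values within $E$ positions of either
end of the compressed sequence are set to zero: a truncated antisymmetric
window on constant input would otherwise produce spurious nonzero scores.
The consequence is a documented dead zone -- crossovers within $E$
compressed positions of a group end are absorbed into the terminal block.
Likewise two true crossovers closer than $2E+2$ compressed positions
interact inside one window and may be merged or shifted. On the package's
own exhaustive enumeration (all vectors of length $\le 16$, $E \le 3$,
crossovers $\ge E+1$ from the ends and $> 2E+1$ apart, isolated error
clusters $\le \lfloor E/2 \rfloor$ placed $\ge E+1$ from every crossover,
correct calls in strict majority per block), the three passes return
exactly the minimum-Hamming-distance piecewise-constant sequence with the
true number of edges, verified against brute-force enumeration of all
segmentations. Outside that class the output is still piecewise constant
and deterministic, but no optimality is claimed.

One caution: the single application of the three passes is not a fixed
point for every conceivable input. With $E = 1$ two adjacent
opposite-sign runs can create a tie block whose leftmost-entry rule
resolves differently on a second pass (e.g. `1 -1 -1 1`); for $E \ge 2$
the convolution cannot jump across the threshold between adjacent
positions, the configuration is unreachable, and repeated application
reproduces the first pass on realistic inputs, as the test suite checks.

## Map statistics

The supporting statistics are deliberately standard:

* **Segregation classes.** Markers are classified ABxAA / AAxAB / ABxAB
  from parental zygosity; only the uni-parental testcross classes are
  mapped, one parent per map.
* **Genotype bins.** After imputation, markers with identical genotype
  vectors are collapsed into bins mapped as a single locus (the bin's
  first member is its representative).
* **Two-point statistics.** The recombination fraction between two
  markers is the discordant fraction of informative meioses, with the
  complementary phase adopted (and recorded) when $\hat r > 0.5$. The
  LOD score is the testcross likelihood ratio against $r = 0.5$:
  $R\log_{10}(\hat r/0.5) + (n-R)\log_{10}((1-\hat r)/0.5)$.
* **Grouping.** Single-linkage clustering joins markers with LOD $\ge 7$
  and $\hat r \le 0.35$ by default; linkage groups are the connected
  components. Raising the LOD threshold can only split, never merge.
* **Distances.** Map length along a given bin order is the sum of
  adjacent-bin Kosambi distances,
  $d = 25\ln\bigl((1+2r)/(1-2r)\bigr)$ cM -- a sequential approximation
  to multipoint regression mapping, adequate when adjacent bins are
  tightly linked.
* **Segregation distortion.** Every marker's two testcross classes are
  tested against 1:1 with $\chi^2 = (o_1-o_2)^2/n$, df = 1, plotted
  against the fixed thresholds 3.841 / 6.635 / 10.828 ($P$ = 0.05, 0.01,
  0.001). Raw statistics are reported, matching the way distortion scans
  are conventionally displayed; a Benjamini-Hochberg column is available
  behind a flag, off by default.
* **Ordering.** `order_markers_greedy()` is a nearest-neighbour chaining
  heuristic provided so synthetic end-to-end runs need no external
  ordering tool. It provably recovers a strictly monotone
  recombination-fraction structure, but a single double recombinant can
  make $\hat r$ locally non-monotone and swap neighbouring bins; it is
  not a substitute for multipoint ordering and is documented as such.

Phases are read from input when available; otherwise `assign_phases()`
anchors the first marker of each group at `1-` and phases each subsequent
marker by majority agreement with its predecessor, which is reliable
whenever adjacent markers are tightly linked and mostly co-typed.

## The simulator and what it does (not) emulate

`sim_params()` defaults describe the study conditions the package is
demonstrated under: 71 individuals; seven linkage groups of 87.6, 46.4,
73.6, 78.5, 53.1, 68.4 and 55.1 cM; 500 markers per group placed
uniformly at random; an overall missing fraction of 0.36 with
per-individual rates drawn from a Beta distribution with standard
deviation 0.10 (emulating sequencing-depth variance between individuals);
and a 2% symmetric per-call error rate. The true error rate behind real
GBS data of this kind is unknown -- only its symptom, a grossly inflated
perceived recombination count, is observable -- so the error rate is an
explicit free parameter; 2% makes the inflation severe (roughly 90
perceived recombinations per individual against ~4.4 true crossovers)
and exercises the correction hard.

Meiosis is simulated without crossover interference (Poisson counts with
mean $L/100$ per gamete, uniform positions). Distances are nevertheless
summarized with the Kosambi function downstream; at these group lengths
the mismatch is small but real, and the simulator makes no claim to
reproduce interference, segregation distortion, locus-specific error
rates, read-depth-correlated missingness within individuals, or marker
clustering (a hotspot option is deliberately out of scope). Passing
recovery tests on this generator therefore demonstrates correctness of
the algorithmic machinery under a realistic error/missingness budget, not
performance on any particular real data set.

Every operation is reproducible under a fixed seed; `degrade()` reseeds
deterministically at `seed + 1` so it is reproducible when called
standalone as well as through `simulate_progeny()`.

## Problem sizes used in the checks

The bundled verification runs use: the exhaustive oracle and clean-edge
enumerations at vector lengths $\le 16$ and $E \le 3$ (about 5,400
qualifying cases plus all single-crossover vectors); randomized
invariant checks on a few hundred vectors; and one study-shaped progeny
(71 x 3,500 markers) for recovery, grouping and distortion -- sizes at
which the full suite completes in about a minute while still covering
every code path at the study's scale.

## Known limitations

* Markers must be pre-ordered within linkage groups; the imputation
  never re-orders them, and a badly wrong input order degrades output
  silently (every spurious alternation looks like recombination).
* Crossovers within $E$ compressed positions of a group end, or closer
  than $2E+2$ positions to each other, are not resolvable at the given
  `E`; error clusters larger than $\lfloor E/2 \rfloor$ survive as short
  blocks.
* AB$\times$AB (hk$\times$hk) markers are out of scope; both parental
  maps are built from uni-parental testcross markers only.
* The adjacent-bin map length underestimates slightly when double
  crossovers fall between consecutive bins, and the greedy ordering is a
  heuristic (see above).
* Skipped individuals (missing above `max_missing`) retain missing
  values; downstream binning requires complete data and will direct the
  user to impute first or subset to fully imputed individuals.
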