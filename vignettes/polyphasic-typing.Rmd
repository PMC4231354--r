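---
title: "Polyphasic typing of dairy bifidobacteria: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polyphasic typing of dairy bifidobacteria: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifidotyper)
```

`bifidotyper` implements the computational layer of a polyphasic survey of
cold-tolerant bifidobacteria (*Bifidobacterium crudilactis*,
*B. mongoliense*) in raw-milk cheeses: species typing by PCR-RFLP,
semi-quantitative enumeration, DNA–DNA relatedness, G+C content, multilocus
sequence analysis and phenotypic numerical taxonomy. This vignette explains
each model, its assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data generators do and do not emulate.

## In-silico PCR-RFLP

A marker amplicon (the 16S rRNA gene in the motivating survey) is digested
with AluI (site AGCT, cut after 2 bases) and TaqI (TCGA, cut after 1), and
the fragment-size pattern per enzyme is looked up in a labelled library;
the per-enzyme label combination determines the species (V-X →
*B. crudilactis*, V-IX → *B. mongoliense*).

Digestion works on 0-based, half-open coordinates; a cut position is a
between-residue index, so fragment arithmetic is exact and
`sum(sizes) == length` always holds for a linear molecule. Only literal
top-strand occurrences of the recognition site are scanned: IUPAC
ambiguity codes in the substrate never match, because the behaviour of a
restriction enzyme on a base that Sanger sequencing could not resolve is
undefined and silently guessing would fabricate cut sites. AluI and TaqI
sites are palindromic, so top-strand scanning loses nothing for the
shipped scheme; the contract simply extends to user-defined enzymes.

Pattern matching is deliberately *not* exact. The shipped band sizes are
gel estimates: the three patterns sum to 1054, 1050 and 996 bp even
though they describe amplicons of one locus, so no sequence can satisfy
all of them exactly. Observed and expected bands are therefore paired in
rank order and accepted when every band deviates by at most a relative
tolerance (default `rel_tolerance = 0.10`); the score is one minus the
mean relative deviation, with ties broken by the smallest maximum
deviation and then by label. Two detection modes are provided because it
is unknowable from printed sizes alone whether they were read from gels
or predicted from sequence: the default `min_band = 0`
("sequence-predicted") keeps every fragment — pattern V contains a 5-bp
band that only exists on paper — while a "gel" mode with `min_band`
around 50 bp models what 2.5% agarose resolves; removals are flagged,
never silent.

Amplicon extraction matches primers with up to `max_mismatch` mismatches,
choosing the fewest-mismatch placement and breaking ties leftmost for the
forward and rightmost for the reverse primer, which yields the longest
product — the behaviour of a permissive PCR. The genus-specific primers of
the original typing scheme are not republished here, so the primer pair is
a user input; the CO1/CO2 near-full-length pair printed in the survey's
sequencing methods is used in examples. A failed amplification raises a
classed condition rather than returning an empty sequence.

## Semi-quantitative enumeration

The survey design inoculates one enrichment tube per ten-fold dilution
10^−d^, d = 0..6. A positive tube at dilution 10^−d^ is attributed
1 cfu/ml, i.e. the undiluted sample held about 10^d^ cfu/ml, so the
estimated log₁₀ count is simply the deepest positive exponent. This is a
semi-quantitative rule, not an MPN maximum-likelihood estimate — with one
tube per dilution the two coincide in spirit and the rule is what the
survey applied. Three edge cases are fixed by design:

* an all-negative series gives count 0 with `detected = FALSE`;
* a series positive only at d = 0 gives count 0 with `detected = TRUE` —
  prevalence and abundance are decoupled at the bottom of the scale;
* a non-monotone series (negative tube below a positive one, plausible
  near the detection limit) resolves to the deepest positive and is
  flagged. "Average of the last positive dilutions" is ambiguous for such
  series; deepest-positive is the conservative single-valued reading.

Group summaries report percent positive rounded half-up to an integer
(the policy that reproduces every printed survey percentage, including
13/44 → 30%), and mean ± sample SD (n − 1 denominator) of log counts over
*all* samples with non-detections contributing 0. Both conventions were
confirmed by reconstruction: the printed retail cell 3.6 ± 2.07 is the
mean and n − 1 SD of (4, 4, 5, 5, 0) — a population SD would give 1.85 —
and 4.6 ± 2.70 likewise for (7, 5, 5, 6, 0). That second cell also fixes
a design detail: a 7-log count cannot be encoded by a series stopping at
10^−6^, so the maximum exponent is a parameter (default 6, the survey
design) and the CSV reader infers the range from the tube columns
present.

## DNA–DNA relatedness and G+C content

In the renaturation-kinetics assay, sheared single-stranded DNA of
organisms A and B and their equal mixture re-anneal while A260 is
recorded. Each rate (V~a~, V~b~, V~m~) is minus the ordinary
least-squares slope of A260 against time over `(3, T]` minutes: the first
3 minutes are excluded because the cuvette temperature is still
stabilising, and T defaults to each reading timepoint (21 and 24 min),
with the reported relatedness the mean over timepoints. The percentage is

$$\%\,\mathrm{rel.} = 100\,\frac{4V_m - V_a - V_b}{2\sqrt{V_a V_b}}.$$

The printed form of this expression in the motivating survey is
typographically ambiguous ("4 V~m~ − (V~a~ + V~b~) / 2 (V~a~ × V~b~)^½^");
the implementation uses the standard De Ley (1970) grouping above, which
is symmetric in (V~a~, V~b~), scale-invariant, 100% when all three rates
are equal and 0% when V~m~ = (V~a~ + V~b~)/4. Noisy input can push the
value outside [0, 100]; it is reported unclamped with a flag, because
silent truncation hides assay problems.

G+C content comes from the melting midpoint: Tm is the temperature at
half of the total hyperchromic rise, linearly interpolated between
recorded points, and GC = a·Tm + b. The calibration depends on solvent
and instrument and the survey does not state the one it used, so (a, b)
is configuration; the shipped default (2.44, −169.1) is the classical
1×SSC relation GC = 2.44 (Tm − 69.3), offered as a documented default
only.

## Multilocus sequence analysis

Strains are typed on internal fragments of seven housekeeping loci with
fixed template sizes (clpC 501, fusA 666, gyrB 600, ileS 489, purF 627,
rplB 591, rpoB 357 bp). Allele assignment takes an exact database match
first (existing number, identity 100%); otherwise the query is a novel
allele, numbered with the next free integer locally (no remote registry)
and reported with its identity to the nearest existing allele — global
alignment rather than Hamming distance, so indel-bearing novel alleles
are tolerated; a length deviating more than 10% from the template is
rejected as a sequencing-quality failure instead. Identity percentages
are labelled "nearest-allele identity" because the reference set of the
analogous printed column is not fully specified.

A sequence type is an exact seven-allele tuple; distinct tuples and ST
identifiers are in bijection. Concatenation uses the fixed order
clpC-fusA-gyrB-ileS-purF-rplB-rpoB regardless of input order — MLST
databases disagree on ordering, so it is pinned and documented; full
templates concatenate to 3831 bp. Pairwise identity counts identical
columns over all aligned columns with gap columns in the denominator, so
100% identity occurs iff the sequences are equal. Trees are Saitou–Nei
neighbor joining on distances 1 − identity/100: the original analysis
names only its GUI software, so NJ on uncorrected distances is the
documented default and is recorded in the tree's metadata. NJ can return
negative branch lengths on non-additive input; they are clamped to zero
with the excess shifted to the adjacent branches (preserving adjacent
path lengths) and flagged.

## Phenotypic numerical taxonomy

Binary test panels (carbohydrate acidification, enzymatic reactions) are
compared by the Jaccard index: shared positives over shared positives
plus mismatches. Joint negatives are excluded — the defining property of
Jaccard versus simple matching: two strains are not similar merely
because both fail the same sugars — and untested entries are excluded
pairwise. A pair with no informative comparable test has undefined
similarity and raises a condition. Dendrograms are UPGMA
(unweighted average linkage on 1 − similarity): cluster-to-cluster
distance is the mean over original leaf pairs, merge heights are
non-decreasing so the output is ultrametric, and tied merges resolve to
the lexicographically smallest strain pair so output is deterministic.
The agglomeration is implemented explicitly to guarantee that tie-break
and to expose the merge table; the test suite cross-checks it against
`stats::hclust(method = "average")` and a naive quadratic oracle.

## Synthetic data: what it emulates, and what passing tests show

Every generator plants known truth and is deterministic for a fixed seed
(integer-state RNG, no locale dependence):

* `generate_sequence_with_pattern` builds a molecule whose digest equals
  a requested size list exactly, by stamping one recognition site across
  each junction and scrubbing accidental sites from random filler
  (rejection with single-base repair), then verifying by round-trip
  digestion.
* `generate_typing_sequence` plants the patterns of *several* enzymes in
  one molecule. Because the printed per-enzyme size sums disagree, each
  pattern's cut positions are scaled to a common compromise length
  (~3% per-band deviation for the shipped scheme, well inside the 10%
  matching tolerance).
* `simulate_survey` emulates the survey layout — four production-step
  groups of 44 samples, one tube per dilution, exponents 0–6 — with
  per-group prevalences defaulting to (0.82, 0.77, 0.09, 0.77), the step
  pattern of the more abundant species. Positive samples draw true log
  counts from round(N(3, 1.5)) clamped to 0..6, a spread consistent with
  the reported per-step means once non-detections are included; tubes
  are positive for every d ≤ true count.
* `simulate_renaturation` inverts the De Ley relation
  (V~m~ = (p/100·2√(V~a~V~b~) + V~a~ + V~b~)/4) so the noise-free
  estimate equals the planted percentage exactly, then adds per-point
  Gaussian noise. Defaults V~a~ = 0.012, V~b~ = 0.010 AU/min from
  A260 = 1.0 give a realistic ~25% decline over a 24-min recording;
  default noise 0.01 AU is 1% of the initial absorbance.
* `evolve_alleles` applies Poisson(rate × branch length × locus length)
  substitutions along a known tree; `simulate_phenotype_panels` flips an
  archetype's test outcomes with a small probability per strain.

These generators validate the *computations*: rule application, formula
algebra, estimator recovery, topology reconstruction. They do not emulate
16S secondary structure, GC-content composition, chimeras, partial
digests, inter-locus recombination or correlated phenotype blocks — so
green tests certify the arithmetic and algorithms, not performance on
real chromatograms or kits. Three published quantities are out of
computational reach without external data and remain documented
limitations rather than tests: relatedness tables from unpublished raw
kinetics, the concatenated-gene tree against real genome accessions, and
database identity percentages requiring deposited allele sequences. The
identity arithmetic itself (100% for identical 1452-bp sequences; one
substitution prints as 99.9%) is asserted on synthetic sequences.

## Numerical choices and problem sizes

Tolerances: band matching 0.10 relative (gel estimates); matrix symmetry
1e−8; boundary flagging of the De Ley percentage at 1e−8 so
floating-point dust at exactly 100% is not flagged. Ties: pattern
matching by score, then maximum deviation, then label; UPGMA
lexicographic; alignment traceback delegated to Biostrings'
deterministic implementation (scores 1/−1 with linear gap −2 by
default). Degenerate inputs raise classed conditions
(`amplification_failure`, `insufficient_data`, `no_transition`,
`quality_failure`, `undefined_similarity`, `infeasible_sizes`) rather
than returning sentinel values.

The validation suite exercises: 30 random 200-bp digests against a naive
quadratic oracle; a 100-amplicon typing panel; 100 noisy replicates per
level of a five-level relatedness ladder; all 15 five-taxon topologies
against a least-squares brute-force oracle plus random 6×6 UPGMA
matrices; and 200 simulated surveys of 4 × 44 samples — sizes chosen so
each check has clear statistical meaning while the whole suite stays
interactive.
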