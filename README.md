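# bifidotyper

Polyphasic typing and semi-quantitative enumeration of dairy
bifidobacteria, in R.

Raw-milk cheeses (St Marcellin and relatives) carry two unusual,
cold-tolerant *Bifidobacterium* species — *B. crudilactis* and
*B. mongoliense* — that multiply during ripening at 12 °C. Surveying them
combines several classical computations that are usually done ad hoc:
reading species off restriction-fragment gel patterns, turning enrichment
dilution series into log counts, deriving genome relatedness from
renaturation kinetics, and clustering strains by multilocus sequences and
phenotypes. `bifidotyper` implements that whole computational layer as
tested, reusable functions, for microbiologists running comparable
surveys and for anyone who wants the calculations behind such studies to
be reproducible.

## What it computes

* **In-silico PCR-RFLP typing** — amplicon extraction by primer matching,
  restriction digestion (AluI = AG^CT, TaqI = T^CGA), gel detection-limit
  filtering, tolerance-based matching of fragment patterns against a
  labelled library (AluI pattern V = 5-95-152-206-285-311 bp; TaqI
  IX = 120-210-250-470 bp; X = 132-200-664 bp), and combination-based
  species calls (V-X → *B. crudilactis*, V-IX → *B. mongoliense*).
* **Semi-quantitative enumeration** — one enrichment tube per ten-fold
  dilution 10⁻ᵈ; the estimated count is 10ᵈ cfu/ml for the deepest
  positive dilution, so log₁₀ N̂ = d. Grouped summaries report percent
  positive (half-up integer rounding) and mean ± SD (n − 1) of log counts
  with non-detections contributing 0.
* **DNA–DNA relatedness** — renaturation rates Vₐ, V_b, V_m as negative
  OLS slopes of A260 vs time (first 3 min excluded), combined by the
  De Ley relation
  `% = 100 (4·V_m − V_a − V_b) / (2 √(V_a · V_b))`,
  read at 21 and 24 min and averaged. Tm-based G+C via a configurable
  linear calibration (default GC = 2.44·Tm − 169.1, the classical 1×SSC
  relation).
* **MLSA** — allele assignment against per-locus databases for
  clpC/fusA/gyrB/ileS/purF/rplB/rpoB, sequence types as exact
  seven-allele tuples, fixed-order concatenation (3831 bp at template
  sizes), identity distances (1 − identity/100 after global alignment)
  and Saitou–Nei neighbor-joining trees.
* **Phenotypic numerical taxonomy** — Jaccard similarity over binary test
  panels (joint negatives and untested entries excluded) and UPGMA
  dendrograms with deterministic tie-breaking.
* **Synthetic data with planted truth** for every stage: sequences that
  digest to requested fragment sizes, dual-enzyme typing amplicons,
  dilution-series surveys, renaturation kinetics, melting curves, allele
  sets evolved along known trees, phenotype panels.

## Worked example

```r
library(bifidotyper)

## type two synthetic amplicons carrying planted patterns
seqs <- list(
  generate_typing_sequence(c(AluI = "V", TaqI = "X"),  seed = 1, id = "iso1"),
  generate_typing_sequence(c(AluI = "V", TaqI = "IX"), seed = 2, id = "iso2"))
rflp_type(seqs)
#> In-silico PCR-RFLP typing of 2 sequence(s)
#>  sequence_id AluI_label AluI_score TaqI_label TaqI_score
#>         iso1          V  0.9765798          X  0.9703608
#>         iso2          V  0.9986550         IX  0.9982776
#>                   taxon_call
#>  Bifidobacterium crudilactis
#>  Bifidobacterium mongoliense
```

Scores are 1 minus the mean relative band-size deviation: both isolates
sit within ~3% of the library patterns, and the label combinations map
to the two species.

```r
## retail-cheese counts: samples at 4, 4, 5, 5 log cfu/g plus one
## non-detection
est <- lapply(seq_along(c(4, 4, 5, 5, 0)), function(i) {
  n <- c(4, 4, 5, 5, 0)[i]
  estimate_log_count(dilution_series(paste0("s", i), "retail", "B. crudilactis",
                                     0:6, if (n > 0) 0:6 <= n else rep(FALSE, 7)))
})
survey_table(summarize_survey(est))
#>    group          taxon positives  mean_count
#> 1 retail B. crudilactis 4/5 (80%) 3.60 ± 2.07

## relatedness of two strains from renaturation kinetics
sim <- simulate_renaturation(95, noise_sd = 0.002, seed = 3)
ddh(sim$A, sim$B, sim$mix)
#> DNA-DNA relatedness: 92.6% (mean over readings at 21, 24 min)
#>   per timepoint: t21 = 92.7%, t24 = 92.5%
```

The survey row is the standard printed form — positives with an integer
percentage, mean ± sample SD of log counts over all samples — and the
DDH estimate recovers the planted 95% relatedness to within the noise of
the two slope fits (averaging replicate runs tightens it further).

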