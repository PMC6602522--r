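---
title: "Regional missense tolerance: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional missense tolerance: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtratio)
```

## The model

Purifying selection removes deleterious missense alleles from a population,
so regions of a protein under strong functional constraint show *less*
standing missense variation than the sequence context would produce under
neutrality. Synonymous variation, being largely neutral, provides an internal
control for regional mutability and sampling depth. The Missense Tolerance
Ratio compares the two:

$$\mathrm{MTR}_i \;=\;
\frac{\text{mis\_obs}_i \,/\, (\text{mis\_obs}_i + \text{syn\_obs}_i)}
     {\text{mis\_exp}_i \,/\, (\text{mis\_exp}_i + \text{syn\_exp}_i)}$$

where the four tallies are summed over a sliding window of $w$ codons
centred at amino-acid position $i$ and truncated at the transcript termini:
$H = \max(1, i - (w-1)/2)$, $J = \min(L, i + (w-1)/2)$. Expected counts come
from exhaustive enumeration: every CDS base has three possible alternates,
each classified by the standard genetic code as synonymous, missense or
stop-type. Observed counts are the distinct single-nucleotide variants that
pass quality filtering.

Because the score is a ratio of *proportions*, it is invariant to uniform
scaling of all four tallies — a region with twice the coverage does not get
twice the signal — and because observed and expected proportions are built
from the same enumeration, sequence composition (e.g. CpG content or codon
bias affecting how many of the 9 possible changes per codon are synonymous)
cancels to first order.

### Significance testing

At each codon the window's observed variants are treated as $n$ Bernoulli
trials with missense probability $p$ equal to the expected missense
proportion of the same window:

$$P(X = x) = \binom{n}{x} p^x (1-p)^{n-x},\qquad
n = \text{mis\_obs}+\text{syn\_obs},\; x = \text{mis\_obs}.$$

The two-sided p-value sums the probability of every outcome no more likely
than the observed one (minimum-likelihood convention, the same used by
`stats::binom.test`, with a $1+10^{-7}$ relative guard against floating-point
ties). The raw p-values of **all** tested codons of **all** transcripts in a
run form one Benjamini–Hochberg family (joint scope; a per-transcript scope
exists behind a flag for single-gene use). Intolerant regions are maximal
runs of codons with $q < 0.1$ **and** $\mathrm{MTR} < 1$: the test is
two-sided ("deviates from expectation") while intolerance is directional, so
significant codons with $\mathrm{MTR} \ge 1$ are reported separately as
tolerant-significant and never called intolerant.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `window_size` | 31 | codons | 21 gives finer resolution but jitters with little information per window; 41 is smoother but blurs short motifs. 31 is the recommended compromise; any odd size ≥ 3 is accepted. |
| `fdr_threshold` | 0.1 | q-value | empirically chosen operating point for region calling; stricter thresholds shrink regions from their edges first. |
| `fdr_scope` | joint | — | exome-wide family matches the published semantics; per-transcript is appropriate when a single gene is analysed in isolation. |
| `min_population_exomes` | 15 000 | exomes | below this, stratified profiles are too sparse to be meaningful; population labels failing it are skipped with a message. |
| `population_windows` | {31, 41} | codons | stratified data are sparser, so the narrow 21-codon window is refused for per-ancestry profiles. |
| `pass_only` / `dot_is_pass` | TRUE / FALSE | — | only FILTER = PASS single-nucleotide records are counted; a missing FILTER (`.`) fails unless explicitly allowed. |
| `assembly` | GRCh37 | label | echoed to the run summary; the code is assembly-agnostic and never touches a reference genome. |

## Counting rules and degenerate inputs

* **Counting unit.** Observed variation is counted as *distinct (site, alt)
  alleles*, never weighted by allele count or frequency. Whether the
  published scores weight by allele count is not documented; distinct-variant
  counting is the conservative reading of "variants" and is flagged here as
  the package's choice.
* **Stop-type changes.** The labelling is binary (missense vs synonymous);
  stop-gained, stop-lost and anything in a terminal stop codon is labelled
  but excluded from both observed and expected tallies. This keeps the
  expected proportion consistent with the observed one rather than inventing
  a third category's treatment.
* **Expected model.** Every possible SNV counts equally — no trinucleotide
  mutation-rate adjustment. Transition/transversion and CpG effects therefore
  perturb the expected proportion slightly; they partially cancel in the
  ratio because both proportions share the enumeration.
* **No observed variants in a window** → MTR = NA, no test, excluded from
  the BH family (`m` counts non-NA tests only).
* **No possible missense variants in a window** cannot occur for a non-empty
  coding window (every sense codon has missense alternates); it raises a
  degenerate-window error rather than returning Inf.
* **Ambiguous bases** (N, IUPAC codes) reject the transcript at
  construction, mirroring the non-ambiguous-sequence requirement of the
  source data.
* **Ties in the exact test** are absorbed by the $1+10^{-7}$ relative
  tolerance; p-values are reported at full double precision (no flooring at
  2.2e-16 anywhere in computation).
* **Minus-strand transcripts.** The genomic map is stored strand-resolved;
  genomic ref/alt alleles of minus-strand records are reverse-complemented at
  ingestion so the entire core works in coding-strand space.

## What the synthetic generator emulates — and what it does not

`simulation_scenario()` states a world: transcripts with uniform random sense
codons (ATG start, stop end, no internal stops), and an observation model in
which each possible synonymous variant is seen independently with probability
$\pi_{obs}$ and each possible missense variant with $\pi_{obs} \times \rho$,
where $\rho \le 1$ is the missense retention of any depleted region covering
its codon ($\rho = 1$ elsewhere). Defaults follow the stated test scenarios:
20 transcripts × 400 codons, $\pi_{obs} = 0.6$, and for power checks one
60-codon region per transcript with $\rho = 0.2$. $\pi_{obs} = 0.6$ is a
deliberately information-rich regime (roughly the saturation of well-covered
genes in current population panels); $\rho = 0.2$ corresponds to strong but
not absolute purifying selection. Per-transcript random substreams are split
from the scenario seed, so results are independent of transcript order and
bit-reproducible.

The generator deliberately omits: mutation-rate heterogeneity (CpG,
trinucleotide context), coverage variation, demography and drift, linkage,
allele frequencies, and genotype-level sampling. A green simulation test
therefore establishes the *statistical machinery* (enumeration, windowing,
ratio, exact test, FDR, region calling) under the stated independence model —
it does not establish calibration on real cohort data, where dependence and
rate heterogeneity can inflate or deflate the realized FDR.

Under the fully neutral model every significant codon is a false discovery,
so the realized false-discovery proportion per replicate is 1 when anything
is called and 0 otherwise; the acceptance criterion bounds its 50-replicate
mean at 0.15, and the exact test's conservatism keeps the measured value far
below the bound.

## Design choices that were genuinely open

* **Two-sided test.** The source describes testing whether the observed
  proportion "deviates" from expectation — two-sided — while the display rule
  colours only depleted regions. We keep the two-sided minimum-likelihood
  test and gate the region call on MTR < 1, rather than switching to a
  one-sided depletion test; this preserves the tolerant-significant codons as
  a first-class, inspectable output.
* **Joint FDR.** One BH family per run. Running one gene alone therefore
  produces different q-values than running it inside an exome — that is a
  property of FDR, not a bug; the per-transcript flag exists for the
  single-gene use case.
* **Query precedence.** A 4-field line whose last two fields are single bases
  is always chromosome-position-ref-alt; 2-field lines are
  chromosome-position when the first token looks like a chromosome name, and
  transcript:protein-position otherwise. Both `:` and `-` separate the
  transcript form, since the source names the format without fixing a
  delimiter.
* **TSV dialect.** Columns `chrom, pos, ref, alt, filter, population` with
  `#` comments; in CDS mode the `chrom` column carries the transcript id.
  Defined here because only the data sources, not a portable format, are
  documented upstream.

## Known limitations

* Expected counts are unweighted by mutation rate, so MTR is a selection
  measure only relative to the uniform-opportunity null; regions rich in
  hypermutable contexts are slightly mis-calibrated.
* Windowed scores smear region boundaries by up to $(w-1)/2$ codons in each
  direction; recovery tests score this honestly via codon-level Jaccard
  against truth.
* Overlapping windows make neighbouring tests strongly dependent. BH remains
  valid under this positive dependence, but called region *lengths* should
  not be over-interpreted.
* No canonical-transcript logic: every supplied transcript is scored
  independently.
* The flat file and queries operate on precomputed tables; there is no
  server, no Ensembl/VEP access, and no lollipop/domain rendering.

## A minimal end-to-end run

```{r example, eval = FALSE}
sc <- simulation_scenario(seed = 42, n_transcripts = 3,
                          length_range = c(300, 300), pi_obs = 0.6,
                          depleted_regions = data.frame(
                            transcript = 1, start_codon = 120,
                            end_codon = 179, rho = 0.2))
sim <- cmd_simulate(sc, tempfile("sim"))
res <- cmd_compute(sim$paths$fasta, sim$paths$observed, tempfile("out"))
res$regions            # called intolerant regions
head(read_mtr_table(res$paths$table))
```
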