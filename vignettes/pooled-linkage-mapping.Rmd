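---
title: "Pooled-read linkage mapping: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-read linkage mapping: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poollink)
```

## The problem

A recessive mutation segregates in an F2 population from a biparental
cross. Instead of genotyping every plant, the population is sequenced as a
handful of phenotype bulks (e.g. four bulks of five mutant-phenotype plants
and two bulks of six wild-phenotype plants, 3'-tag RNA-seq one library per
bulk). At every transcript SNV that distinguishes the parents, the fraction
of reads carrying the mutant-parent allele in each bulk carries information
about the recombination fraction $\alpha$ between that SNV and the causal
locus: tight linkage drives mutant-phenotype bulks toward pure mutant-parent
reads, while an unlinked SNV sits near 50%. This package estimates $\alpha$
per SNV by maximum likelihood from those read counts, and verifies linkage
afterwards on individually genotyped plants with exact two-point statistics.

## The pooled-read likelihood

Three layers separate $\alpha$ from the observed read count, and each is
modelled explicitly.

**Bulk composition.** Let $G$ be the number of mutant-parent alleles at the
marker among the $n$ diploid plants of a bulk ($0 \le G \le 2n$). A plant
drawn into a recessive-phenotype bulk is homozygous mutant at the causal
locus, so it carries 2, 1 or 0 mutant-parent marker alleles with
probabilities $(1-\alpha)^2$, $2\alpha(1-\alpha)$, $\alpha^2$. For a
dominant-phenotype bulk the analogous probabilities follow from enumerating
the 16 equiprobable gamete pairings conditioned on at least one wild-type
causal allele: $\alpha(2-\alpha)/3$, $2(1-\alpha+\alpha^2)/3$,
$(1-\alpha^2)/3$. (The recessive case is the textbook one; the dominant
case is derived here and validated in the tests against brute-force gamete
enumeration.) $G$ is then the sum over $n$ independent plants — a trinomial
sum, computed by $n$-fold convolution (`pmf_G()`).

**Mixing.** Bulks are made by pooling tissue, not DNA molecules counted
exactly, so the mutant-parent fraction $\Gamma$ of the library deviates
from $G/2n$. This is modelled as
$\Gamma \sim \mathrm{Beta}(G\xi,\ (2n-G)\xi)$, with mean exactly $G/2n$ and
a single concentration parameter $\xi$, the *mixing accuracy coefficient*.
At $G = 0$ or $G = 2n$ one shape parameter vanishes; the distribution is
taken as the point mass at 0 or 1 (its weak limit), so a pure bulk can only
produce pure reads. The simulator uses the identical convention, keeping
generator and likelihood exactly matched.

**Reads.** Given $\Gamma$, the mutant-parent read count among $c$ counted
reads is $M \sim \mathrm{Bin}(c, \Gamma)$; marginalising $\Gamma$ gives the
beta-binomial (`read_likelihood()`, computed in log space).

The per-SNV log-likelihood sums over pools the log of
$\sum_G P(G \mid \alpha) \, P(m \mid c, G, \xi)$, and `estimate_rf()`
maximises it over $\alpha \in [0, 0.5]$ (coupling phase; repulsion is not
modelled, and estimates cap at 0.5, the no-linkage boundary).

### Tunable parameters

* `xi` (default 10, dimensionless): the only free nuisance parameter. It is
  a property of how carefully the bulks were assembled and is *not*
  estimable per SNV, so it is fixed by the user. `xi = 10` corresponds to a
  mixing standard deviation of about 0.05 around a balanced bulk of five
  plants — sloppy hand-pooling; `xi` in the hundreds approaches pure
  binomial sampling. Point estimates are fairly insensitive to `xi` (the
  beta mean does not depend on it); interval widths and the exclusion test
  are more sensitive, which is why `xi` is surfaced everywhere rather than
  hidden.
* `grid_step` (default $10^{-4}$): the likelihood is scanned on a dense
  grid and the best grid point refined by a local bracketed search. This is
  deterministic, immune to multimodality on the cheap, and has no random
  restarts.
* `ci_level` (default 0.8): the interval is a profile likelihood-ratio
  interval, $\{\alpha : 2[\ell(\hat\alpha) - \ell(\alpha)] \le
  \chi^2_{1,0.8} = 1.642\}$, reported as the connected component containing
  the maximum and truncated to $[0, 0.5]$ — estimates at the boundary
  naturally yield intervals of the form $(0, u]$.
* The LOD score is $[\ell(\hat\alpha) - \ell(0.5)]/\ln 10$.

### The improbable-ratio exclusion test

Real pooled libraries contain artefacts — above all *index hopping*, where
multiplexed libraries trade a few percent of reads. An SNV whose libraries
disagree with every possible $\alpha$ should be excluded rather than given
a meaningless estimate. The test implemented (`improbable_ratio_test()`)
computes, for each pool and each $\alpha$ on a grid, the exact two-sided
tail probability of the observed count under the $G$-marginalised read
model (the total probability of all outcomes no more probable than the
observed one), and excludes the SNV only when at **every** $\alpha$ at
least one pool falls below the threshold (default $10^{-3}$) — i.e. no
single recombination fraction makes all libraries plausible at once.

Two properties of this rule deserve emphasis, both consequences of taking
the bulk-composition variance seriously at small $n$:

* **It is conservative for small bulks.** With $n = 5$, the probability
  that a recessive bulk contains one marker heterozygote is
  $10\alpha(1-\alpha)^9$ — about 0.39 at $\alpha = 0.1$ — and one
  heterozygote legitimately produces ~10% wrong-parent reads. A single
  library contaminated at the few-percent level is therefore
  *statistically indistinguishable* from loose linkage: such an SNV is
  retained, and the contamination inflates its $\hat\alpha$ upward instead.
  This matches what pooled screens actually experience: hopping biases the
  top of the ranking rather than being removable by a per-SNV test. Even a
  maximally contradictory pair (one pure-wild and one pure-mutant library)
  retains a tail probability of order $0.5^{2n}$ from composition variance
  alone, which at $n = 5$ sits near the default threshold. A looser
  threshold (e.g. 0.05) restores practical power at $n = 5$; large bulks
  ($n \gtrsim 100$) are excluded decisively at any threshold.
* **It never punishes internally consistent data.** Pools sitting at their
  expected counts for *some* $\alpha$ are always retained, whatever the
  threshold, because that $\alpha$ certifies them jointly.

The threshold and the scan step are exposed; the per-pool tails at the most
favourable $\alpha$ are returned for diagnostics.

## Variant filtering

`filter_snvs()` applies three exclusion rules with a fixed precedence so
that rejection tallies are reproducible: (1) site quality `QUAL < 20`;
(2) not a biallelic single-nucleotide substitution, or parental origin not
assignable ("novel" — the variant is not a clean homozygous difference
between the parent libraries); (3) counted depth below 40 in *any* library,
parents and pools alike. Parental origin tolerates a minor-allele fraction
of up to 0.1 per parent library (`het_tol`), absorbing sequencing error and
light contamination without accepting genuinely heterozygous parents.
Per-pool counts then keep only the two parental alleles: `m` is the
mutant-parent allele depth and `c` adds the wild-type-parent depth; other
alleles are discarded from the denominator.

## Co-segregation statistics on individual genotypes

Once candidate markers are genotyped on single plants, linkage is tested
exactly. For a codominant marker scored against the phenotype, the six-cell
table (marker genotype × phenotype class) has coupling-phase probabilities

| cell | dom AA | dom Aa | dom aa | rec AA | rec Aa | rec aa |
|------|--------|--------|--------|--------|--------|--------|
| $P$ | $\frac{1-\alpha^2}{4}$ | $\frac{1-\alpha+\alpha^2}{2}$ | $\frac{\alpha(2-\alpha)}{4}$ | $\frac{\alpha^2}{4}$ | $\frac{\alpha(1-\alpha)}{2}$ | $\frac{(1-\alpha)^2}{4}$ |

with `A` the wild-parent allele. `estimate_rf_ml()` maximises the
multinomial likelihood on $[0, 0.5]$; `lod_score()` reports
$\log_{10} L(\hat\alpha)/L(0.5)$, and is reported as missing at
$\hat\alpha = 0.5$ (there is no linkage to score). For perfect
co-segregation the LOD reduces to the closed form
$n_{rec}\log_{10}4 + n_{dom}\log_{10}(4/3)$.

Supporting conventions, chosen to match standard practice for these
statistics:

* Both chi-square tests (3:1 phenotype segregation, df 1; six-cell joint
  segregation against the 3:6:3:1:2:1 independence expectation, df 5) are
  Pearson statistics without continuity correction.
* Phenotype classes are two: dominant and recessive; phenotypic
  sub-classes of the mutant (e.g. non-nodulating vs. white-noduling) are
  merged into "recessive" before tabulation.
* Coupling phase is asserted, not inferred. A table that decisively fits
  better with the allele labels swapped (swapped fit at least 3 LOD above
  a coupling fit stuck at the 0.5 cap) raises an error asking for
  relabelling, rather than silently producing a wrong estimate; weak
  label noise in unlinked markers is left alone.
* Marker–marker recombination fractions use the full 3×3 codominant
  two-locus likelihood (`pairwise_rf_matrix()`).
* `order_loci()` searches locus orders exhaustively (branch-and-bound,
  ≤ 10 loci, deterministic lexicographic tie-break, canonical
  orientation) for the minimum sum of adjacent fractions, and maps
  distances as $100\,\alpha$ cM — no Haldane/Kosambi transform, because at
  the fractions where these markers live ($\alpha < 0.12$) the correction
  is below the estimation noise.

## CAPS screening and variant consequences

`find_sites()` matches IUPAC motifs on both strands (overlaps reported,
palindromes counted once); `screen_caps()` calls an enzyme diagnostic when
the *multiset of fragment lengths* differs between alleles — stricter than
comparing site counts, and the criterion that still fires when an indel
shifts a site without changing the count. Cut positions are approximated by
the motif start: true cleavage offsets (which for enzymes like MboII lie
outside the recognition site) are enzyme metadata that do not change
whether a digest distinguishes two alleles, only the exact fragment sizes;
this is a documented limitation, and predicted fragment lengths should not
be read as gel band positions.

`variant_effect()` applies a substitution or single-base deletion to a CDS
and translates both alleles to the first stop. A frameshift is reported
with the number of erroneous residues and whether termination is premature,
defined as the mutant protein being strictly shorter than the reference
protein. A frameshift near the natural stop can abolish the stop codon
without shortening the product within the given CDS; such cases are
reported with `stop_found_mut = FALSE` rather than guessed at, since
read-through length depends on sequence beyond the CDS.

## What the simulator emulates — and what it does not

`simulate_bsa_experiment()` generates: an F2 population by independent
gametes, each a Markov chain over the ordered loci at the designed
recombination fractions (two-point model, no crossover interference — only
two-point quantities are ever estimated); phenotype deterministically from
the causal genotype; bulks drawn without replacement within phenotype
class; reads from exactly the Beta–binomial stack of the likelihood; and
optional index hopping, modelled as each read being replaced with
probability `hop_rate` by a read drawn from the pooled allele mix of the
other libraries — a deliberate, simple stand-in for a demultiplexing
artefact whose true mechanics are instrument-specific.

Because generator and estimator share the model, passing round-trip tests
demonstrates *internal* correctness (the estimator recovers what the model
generates), not robustness to everything real data adds: mapping errors,
allele-specific expression, expression-level-dependent coverage,
paralogous mismapping, or phenotype misclassification are all outside the
generator. The default study conditions mirror a realistic small design —
four recessive bulks of 5 and two dominant bulks of 6, coverage 100,
`xi = 10`; simulated populations of 160–200 plants keep bulk assembly
feasible at the 3:1 phenotype ratio.

Monte Carlo problem sizes used by the test-suite calibration checks: 500
independent replicates for estimator bias and interval coverage at
$\alpha = 0.1$ (coverage lands near the nominal 80%), 12 seeded 200-SNV
screens for the end-to-end ranking property, and $2\times10^4$ bulks for
distributional agreement of $G$ (total-variation distance under 0.02).
These sizes were chosen to make the Monte Carlo error comfortably smaller
than the tolerances being asserted.

## Candidate reporting

`rank_by_rf()` orders SNVs ascending by $\hat\alpha$ (ties: LOD then id),
listing excluded SNVs separately. `define_interval()` widens the span of
two anchor homolog positions by a factor (default 3) of the span *on each
side*, clipped at zero, half-open — the "triple the distance up and down
the chromosome" reading; the alternative reading (total width ×3) would be
narrower, and the per-side reading was chosen as the more conservative
candidate net. `candidate_filter()` then intersects an externally produced
differential-expression table (id, position, log2 fold change, adjusted
p-value — the standard DESeq2 results shape) with the interval at a strict
`padj < 0.05`; genes with missing adjusted p-values are reported in their
own bucket rather than silently dropped. Differential expression is never
computed here — it is an input contract.

## Known limitations

* $\xi$ is assumed shared across pools and SNVs, and known. A
  hierarchical extension estimating it from control SNVs is possible but
  out of scope.
* The exclusion test's power collapses for small bulks at strict
  thresholds (see above); this is a property of the model, not a bug, and
  the practical mitigations are larger bulks, looser thresholds, or
  marker-level verification of the top candidates.
* Repulsion-phase designs, multipoint likelihoods, interference models
  and sliding-window smoothing over genome coordinates are not
  implemented.
* All coordinates are transcript-space; no liftover or strand
  normalisation is attempted.
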