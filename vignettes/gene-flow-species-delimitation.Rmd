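---
title: "Delimiting bacterial species by gene flow: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting bacterial species by gene flow: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`coreflow` turns a core-genome concatenate — one aligned nucleotide sequence
per genome plus an in-frame gene map — into gene-flow-based species
assignments. This vignette explains the statistical machinery, the defaults
and their units, what the synthetic-data generator does and does not emulate,
and the design decisions taken where the procedure was genuinely open.

## The h/m homoplasy statistic

At each polymorphic column, every non-modal allele is scored by the minimum
number of independent mutational origins its carriers require on a guide
tree. We compute this as the small-parsimony (Fitch, with Hartigan's
generalization to multifurcating nodes) score of the *binary*
carrier-versus-rest character, floored at one; genomes with `-`/`N` (or a
genome deliberately masked) are fully ambiguous leaves and never force a
change, which makes masking a leaf exactly equivalent to pruning it. The
binary score is invariant to rooting, and it reproduces the intuitive
classification: alleles confined to one clade need a single origin, alleles
scattered across clades need at least two and are *homoplasic*. An
alternative formulation — minimum gains of the focal allele among
maximum-parsimony multistate labelings — was rejected because a reconstruction
that places the allele at the root with free losses can explain any
discordant pattern with "one origin", emptying the definition.

`h` counts homoplasic alleles, `m` the single-origin ones. Singleton alleles
(one carrier) count toward `m` by default: a single carrier trivially has one
origin, and this convention is load-bearing — a diverged genome that does
*not* recombine with the population contributes thousands of singletons,
diluting `h/m`, which is precisely the "substantial and significant drop"
signal used both to exclude non-recombining genomes within a species and to
call a candidate a distinct species. `include_singletons = FALSE` restricts
the tally to alleles with at least two carriers.

The guide tree is neighbor joining on closed-form K2P distances
(`ape::nj`, negative branches clamped to zero). The full-scale analysis this
re-implements used maximum-likelihood distance matrices; the homoplasy count
only consumes the tree's topology and relative shape, for which NJ/K2P is an
adequate, dependency-free stand-in, and the choice is configurable
(`p-distance`, `JC`, `K2P`).

Uncertainty is quantified by leave-one-out resampling: the ratio is
recomputed `resamples = 100` times excluding exactly one genome each time
(every genome once, then redraws). The sample SD of these ratios is the SD
used by the clonality threshold and the rank-sum tests compare these
resample distributions.

## The clonal null and the 3·SD rule

For each species we estimate from the data: GC content; κ, the
transition/transversion *rate* ratio of the K2P model; and relative
substitution rates for the three codon positions (proportional to polymorphic
site counts by position). Note that under K2P the observed transition to
transversion *site-count* ratio equals κ/2 — there are two transversion
targets per base — so the estimate doubles the count ratio; without this the
null would be simulated at half the true transition bias and would
systematically under-produce convergent homoplasy.

The clonal simulator draws a root sequence i.i.d. with P(G) = P(C) = GC/2 and
evolves each branch as a per-site continuous-time K2P chain with site rates
scaled by codon position (mean rate 1, so branch lengths stay in expected
substitutions per site). The per-site Poisson jump process with K2P jump
probabilities *is* the K2P Markov chain, so branch end states are drawn from
the closed-form transition probabilities — exact and orders of magnitude
faster than event-by-event simulation. Using the species GC at the root is a
deliberate simplification (K2P's stationary distribution is uniform); at the
branch lengths involved composition drift is negligible.

Because recombination inflates the branch lengths of trees inferred from real
data, the null is simulated 99 times with multiplicative rescaling factors on
a geometric grid (0.05–5, a range that brackets both deflation and the
roughly tree-length-proportional inflation seen at high r/m), and the
replicate whose π is closest to the observed π is kept; its h/m (computed
with its own re-estimated NJ tree, for symmetry with the real data) is the
clonal expectation. The species is *clonal* if
`real h/m ≤ null h/m + 3·SD`.

**Power at small scale.** The 3·SD rule was designed for Mb-scale core
genomes where a clonal species still accumulates thousands of convergent
homoplasies. On a 100-kb alignment at π ≈ 0.01 a clonal population carries
only h ≈ 30–70, so the world-to-world spread of (real − null) — Poisson noise
on h, the Monte-Carlo noise of the single selected replicate, parameter
estimation noise, and the π-grid granularity — is comparable to the 3·SD band
itself, and roughly a fifth of truly clonal populations fall just outside it.
The package reports what the rule says; users working with short concatenates
should treat marginal non-clonal calls with caution and weigh the LD verdict.

## The LD clonality test

r² is computed for all pairs of biallelic loci that pass the filters: exactly
two alleles, minor allele in ≥ 2 genomes (singletons understate
recombination), < 25% missing at the column; haplotype frequencies use the
genomes non-missing at both loci. Pairs are profiled against concatenate
distance — the only distance knowable from a concatenate, a documented
limitation — in 1,000-bp windows, capped by default at 25 kb: gene-conversion
tracts average ~1 kb, so all distance signal lives in the first few kb and
longer-range pairs only dilute the test.

The clonality verdict is a Spearman rank correlation, significant-negative
(P < 10⁻⁴; the matching multiple-testing level α = 0.0226 is recorded in the
output) meaning gene flow. The correlation is taken over the *raw pairs*
rather than the per-window means. This is a measured deviation from the
windowed-means design: with a 100-kb concatenate there are ≤ 100 windows and
only the first 2–5 carry decay, so a rank correlation over window means is
bounded near |ρ| ≈ 0.1–0.5 with far too few points to ever cross P < 10⁻⁴,
whereas the pairwise test keeps the full sample (10⁵–10⁶ pairs) and separates
cleanly (recombining populations P ≈ 10⁻⁴⁰–10⁻²⁵⁰, clonal populations
P > 0.02 across seeds). The windowed profile is still computed, reported, and
available to the test via `on = "binned"`.

## Between-species gene flow and h/m_norm

A candidate genome is threaded onto the reference alignment (from synthetic
data directly; from unaligned genes via bidirectional-best-hit protein
matching at ≥ 70% identity excluding terminal gaps and ≥ 80% length
conservation, single-copy in the candidate, codon-aware back-threading).
Three tallies follow: the reference alone (`h/m_ref`), reference + candidate
(`h/m_cand`), and reference + a null sequence (`h/m_0`) made by mutating the
reference consensus under Jukes–Cantor until its observed divergence first
reaches the candidate's mean p-distance to the reference (the aggregator is
configurable to `max`). The stopped state of that mutate-until-crossing walk
is sampled directly — mismatch set uniform of size ⌈d·L⌉, each mismatched
base uniform over the three alternatives — which is distributionally exact
under JC symmetry and avoids simulating hundreds of thousands of steps.

Verdicts: *distinct species* when the candidate's inclusion drops the
resampled h/m significantly (one-sided rank-sum P < 10⁻⁴) and substantially
(median relative drop ≥ 0.10, the configurable reading of "substantial");
otherwise *same species* when h/m_cand is significantly above h/m_0;
*ambiguous* otherwise, and forced ambiguous when h/m_ref and h/m_0 are within
one resampling SD (the normalizer is then unstable). `h/m_norm` is reported
unclipped — values above 1 occur legitimately.

A caveat observed on synthetic data: for a candidate drawn from the *same*
population (divergence ≈ π), adding it systematically raises h/m by ~10–15%
(its recombination-shared alleles promote reference singletons from m to h)
while the normalizer h/m_ref − h/m_0 is small, so h/m_norm concentrates
around 1.2–1.7 rather than 1. The verdict logic is unaffected; h/m_norm is
best read quantitatively when the candidate is diverged enough that
h/m_0 ≪ h/m_ref, which is the regime of real between-species comparisons.

## Introgression scan

Non-overlapping 100-bp windows along the shared concatenate (remainder
dropped, windows free to span gene junctions). A window is introgressed when
the best candidate-versus-reference identity strictly exceeds the *minimum*
within-reference identity — "at least one reference genome more similar to
the candidate than to another reference genome" — and also reaches the
identity threshold (90/95/98/100%, increasingly recent events). Ties are
conservative (not introgressed); windows with fewer than 50 comparable
columns in any required pair are skipped; the score S_i is the percent of
evaluated windows called. The scan is refused (applicability check) when any
reference genome is closer to the candidate than to a conspecific, because
the within/between contrast is then meaningless.

## MEPS availability

Homologous recombination needs a minimal stretch of strictly identical DNA to
initiate (experimentally ~25–90 bp). `simulate_pair` builds 1-Mb JC-diverged
pairs at a target identity (same exact stopped-state sampler as the
convergent null); `count_identical_segments` counts identical L-mers with a
1-bp slide — the sliding interpretation maximizes the count of available
substrates and matches the analytic baseline
`(L_seq − L + 1)(1 − d)^L`; a non-overlapping grid mode exists for
sensitivity analysis. The exponential decay in L and d is why observed gene
flow collapses within a few percent of divergence. In Monte-Carlo checks the
tolerance is 3× the larger of the empirical SE and the Poisson SE of the
mean, the latter guarding grid cells whose expected count is ≈ 0 and whose
empirical SD degenerates to exactly zero.

## The synthetic world

Defaults were fixed once, before any calibration, at values a microbial
population geneticist would call typical: GC 0.5; κ = 2; codon-position rate
weights (1, 0.5, 2.5) — third position fastest, second slowest; Yule trees
with root-to-tip depth 0.0075 substitutions/site giving π ≈ 0.01 (ordinary
within-species core diversity); gene conversion at 0.3 initiation events per
site per unit branch length with geometric tracts of mean 1,000 bp, i.e.
r/m ≈ 3, a typically recombining species (heavy recombiners reach 10+,
clonal species 0).

What the generator emulates: tree-structured clonal descent, K2P substitution
with codon-position rates, gene conversion between contemporaneous lineages
with every event logged (donor, recipient branch, time, tract), candidate
genomes evolved from the true root with optional ongoing exchange, and
ground-truth introgression masks. What it does not: indels (real concatenates
have gaps; the statistics handle them, the generator does not produce them),
selection, population-size changes, divergence-dependent recombination
barriers (the pipeline, not the generator, must discover divergence effects),
and donor choice at event resolution — the donor sequence is the most recent
ancestral node of the donor branch alive at the event time, a node-resolution
approximation. Generators are bit-reproducible from their seed, and replay of
a truth log is re-simulation under the logged seed (tract contents are not
stored). A green recovery test therefore establishes that the pipeline
detects the signals this world produces at realistic parameter values — not
that it is robust to indels, selection, or misaligned real data.

## Numerical and engineering choices

* Coordinates are 0-based half-open internally, 1-based inclusive in
  human-readable output; ambiguity codes other than N are treated as N.
* Consensus ties break alphabetically (A < C < G < T); modal-allele ties in
  the tally resolve the same way.
* π uses pairwise deletion of missing columns; a pair with no comparable
  columns is excluded (all pairs excluded is an error).
* JC/K2P corrections refuse saturated inputs (log argument ≤ 0) and advise
  the p-distance fallback.
* Origin counting is C++ (a few hundred site-allele scores per millisecond);
  everything else is vectorized R. The LD pair sweep is block-processed to
  bound memory and subsamples uniformly (seeded) above 5×10⁶ pairs.
* All randomness flows from a single integer seed per entry point; sweep
  replicate *i* uses `seed + i`. Pipeline artifacts embed the config hash and
  seed, never timestamps, so identical runs are byte-identical.

## Known limitations

Concatenate distance is a proxy for chromosomal distance; the guide tree is a
point estimate (no tree uncertainty is propagated into h/m); the 3·SD
clonality rule is under-powered below a few hundred kb (see above); h/m_norm
is unstable when the candidate is barely diverged from the reference; and the
ortholog matcher is exhaustive pairwise alignment, suitable for desk-scale
gene sets rather than whole-genome annotation runs.
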