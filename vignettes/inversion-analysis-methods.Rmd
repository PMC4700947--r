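---
title: "Methods: inversion structural typing, diversity statistics, and the simulated neutrality null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inversion structural typing, diversity statistics, and the simulated neutrality null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's account of its models and of the design
choices made where more than one defensible option existed. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The locus model

The package analyses a polymorphic inversion with two arrangement
families: standard (H1) and inverted (H2). Recombination between
arrangements is suppressed across the inverted interval in
heterokaryotypes, so the families diverge deeply while staying internally
recombining. An H2-restricted duplication splits the inverted family into
H2′ (without) and H2D (with the duplication). Default coordinates are the
human 17q21.31 locus on GRCh37: inversion chr17:43,705,166–44,164,259,
duplication (CNP155) chr17:44,210,855–44,294,624. All files use 1-based
inclusive coordinates (VCF convention); all internal arithmetic is
0-based half-open. The annotated duplication interval is ~84 kb even
though the polymorphism is conventionally described as a 155-kb
duplication; the package takes the printed coordinates as authoritative
and leaves the naming discrepancy alone.

## Structural typing

**Tag votes.** Each tag SNP votes with its diagnostic-allele count (0, 1
or 2). Votes are combined by *unanimity*: any disagreement yields
`ambiguous` with the tally attached, and no majority override is applied.
This is a deliberate abstain-over-guess design: with a per-tag error rate
ε, the probability that a sample carries at least one erroneous tag grows
roughly as 1 − (1 − ε)^(2k) for k tags, and under unanimity essentially
all of those become *abstentions* rather than silent miscalls — a wrong
confident call would require every tag to err coherently. The test suite
checks exactly this: at ε = 0.02 with 5 tags, confidently typed samples
are ≥ 99% correct while a tracked fraction abstains. Missing genotypes
are excluded from voting, with a configurable minimum-informative-tags
threshold (default 1); all tags missing is an error condition distinct
from ambiguity.

**Duplication dosage** is the unanimous diagnostic count over duplication
tags, bounded by the number of H2 haplotypes implied by the inversion
genotype; exceeding it sets a conflict flag. H1/H1 individuals with
nonzero dosage are flagged as possible standard-background copy-number
variants and never typed H2D, since the duplication tags mark only the
inverted background.

**Read-depth confirmation.** Depth tracks are segmented by a 3-state
hidden Markov chain (loss/neutral/gain) decoded by Viterbi. Emissions are
negative binomial with mean `ratio × baseline` — ratios 0.5 / 1.0 / 1.5
by default, matching copy numbers 1 / 2 / ≥3 — and `size = dispersion`
(default 100). The baseline is the track median, so decisions depend only
on depth ratios and uniform rescaling of a track leaves the state path
unchanged in practice (tested). Transitions apply a symmetric log-scale
switch penalty (default 12); initial scores prefer neutral, and all ties
break toward neutral. The decoder is verified against exhaustive
enumeration of all 3^k paths on short tracks. Tracks shorter than 3
windows get a single segment with a low-confidence flag. A tag-based
dosage d is *depth-confirmed* when a gain segment overlaps the
duplication interval with mean ratio within 0.25 of 1 + d/2 (for d = 0,
when no gain segment overlaps it); disagreement sets the conflict flag
but keeps the tag-based call — conflicts are data, not failures.

**Heterokaryotype phasing** is deterministic: homozygous sites copy to
both haplotypes, heterozygous sites with a known H2-family diagnostic
allele are split accordingly, and heterozygous sites without diagnostic
information become missing on both haplotypes, never guessed. This
trades completeness for the guarantee that no phased allele is invented,
which is what makes heterokaryotype-only trees robust to phasing error.

## Panel QC chain

Candidate SNPs are pruned when their (single-base) position lies strictly
inside a segmental-duplication interval — boundary behaviour is strict
interval membership, since a SNP has one position. After merging in the
tagging SNPs, sites are dropped as monomorphic when all non-missing
genotype *alleles* agree (any heterozygote is polymorphic; all-missing
sites count as monomorphic and are flagged). Monomorphism is assessed
over all genotyped samples jointly, and the genotyping rate is computed
over the final retained panel. The two report identities
(`after_pruning = in − removed`, `final = after_pruning + tags − mono`)
are asserted on every run. Restricting the cohort to fewer samples can
flip a site's monomorphism status, so sample restriction and the filter
do not commute in general; the test suite documents this with a
counter-example.

## Diversity statistics

**π** is the mean over unordered haplotype pairs of the per-pair
mismatch count divided by the comparable span (the span length L minus
the pair's missing matrix sites), i.e. pairwise deletion with per-pair
renormalization. Sites absent from the matrix are treated as invariant
across the span.

**Tajima's D** uses the canonical constants (a1, a2, b1, b2, c1, c2,
e1, e2) computed from the sample size, with complete-case site handling:
any site with a missing call is dropped, which keeps the constants exact
for a single n per window. D is undefined — propagated as `NA`, never
0 — when S = 0. Whether published per-subtype diversity tables used
pairwise deletion or complete cases is generally unstated; both
behaviours are reachable (π uses pairwise deletion, D complete cases),
and the choice is asserted in the documentation rather than guessed into
a single shared code path.

**Windows** tile the region at 25 kb (the conventional width for this
locus) without overlap; the final partial window is emitted with its true
width and a `partial` flag. Because a site's complete-case status does
not depend on the window it falls in, per-window S sums exactly to the
total S.

**Fst.** The default estimator is the Hudson-type ratio of averages with
*unbiased* within-group heterozygosity, `1 − Σ Hw / Σ Hb` with
`Hw = p(1−p)·n/(n−1)` summed over both groups. The plug-in form (raw
sample heterozygosities) is also available (`estimator =
"hudson_plugin"`), as is a Weir–Cockerham variant (`"wc"`). The unbiased
form is the default because the plug-in estimator is biased upward by
about `(1/n1 + 1/n2)/2` under panmixia — with groups of 20 haplotypes
that is +0.05, large enough to matter at the stratification thresholds
used here (0.20 "low", 0.50 "high") — whereas the corrected form is
centred at 0 for panmictic groups (property-tested) and still equals 1
for fixed differences. Sites monomorphic across both groups are excluded;
negative estimates are reported as computed (clamping is opt-in); groups
with fewer than 2 haplotypes are excluded and reported.

**Tree.** Neighbor joining on the proportion-of-mismatches distance, with
negative branch lengths clamped to 0, standing in for Bayesian MCMC
reconstruction. The supported claim is qualitative topology — on data
generated with deep between-family divergence and shallow within-family
diversity, all H1 haplotypes form one clade — not branch support. MCMC
tree inference is deliberately out of scope.

## The forward simulator

A diploid Wright–Fisher population of constant size Ne (selfing allowed,
no separate sexes). Each generation, all 2·Ne offspring chromosomes are
gametes of uniformly sampled parents: crossover count ~ Poisson(r·L)
with uniform breakpoints, mutation count ~ Poisson(μ·L) with uniform
infinite-sites positions (continuous, so recurrent mutation is
impossible). In arrangement-heterozygous parents, breakpoints falling
inside the inversion interval are resampled outside it, so the inverted
segment always descends from a single parental chromosome and carries
that chromosome's arrangement flag.

A replicate introduces the inversion on one uniformly chosen chromosome
(optionally after a neutral burn-in that builds standing variation),
restarts from the same standing variation with fresh randomness whenever
the inversion is lost (restarts are counted), and samples both
arrangement classes without replacement at the *first* generation where
the inversion frequency reaches the target — taking "until a target
frequency is reached" literally, which makes the conditioning
well-defined. A cap on total post-introduction generations turns an
unreachable target into an explicit failure result, never a silent
restart. Whether the original conditioning scheme resampled trajectories
or restarted on loss is not documented; restart-on-loss is implemented
and stated as an interpretation.

**Scope of the no-gene-flow guarantee.** Mutations *inside* the inversion
interval can never cross between arrangement classes (tested exhaustively
per replicate). Flanking mutations can and do cross, because crossovers
outside the inversion remain legal in heterokaryotypes — which is the
biology of an inversion, not a leak. All null D values are therefore
computed over the inversion interval, where the privacy guarantee is
exact. Gene flux between arrangements (double crossover / gene
conversion inside the interval) is set to zero with no config hook; at
the evolutionary depths simulated here it would only blur the
arrangement contrast the null is built to capture.

**Parameters.** The full-scale configuration is Ne = 10,000 diploids, a
500-kb region and target frequency 0.337 (the highest known frequency of
the 17q21 inversion), with a 1,000-replicate null. μ and r are not part
of the published description; the package adopts human-like
μ = 1.25e-8 and r = 1e-8 per bp per generation at full scale, giving
θ = 4·Ne·μ·L = 250 and ρ = 4·Ne·r·L = 200 over the region. Desk-scale
defaults (Ne = 500, L = 50 kb) rescale μ and r to hold θ and ρ fixed, so
expected diversity summaries are comparable across scales. The inversion
occupies the central 80% of the simulated region by default, leaving
recombining flanks on both sides. Default sample sizes mirror the
published data — 64 inverted and 300 standard chromosomes (32 and 150
homozygotes) — and are validated against the class sizes guaranteed at
the crossing generation. Burn-in defaults to none (the frequency
trajectory does not depend on it); null-building runs that care about
standing variation conventionally use 10·Ne generations, exposed in the
config.

**Null and test.** Per replicate, Tajima's D is computed for each
arrangement over the inversion interval; empirical quantiles use type-7
interpolation at 0.5/2.5/97.5/99.5 percent (equal-tailed percentile
intervals — the published interval construction is not spelled out, and
equal-tailed is the assumption implemented). Undefined-D replicates are
tracked separately and never silently zeroed. The observed summary is
the *mean* D across defined windows (median available), compared
two-sidedly by default with the rank-based `(k+1)/(n+1)` p-value. The
self-calibration property — same-process observations fall outside the
95% interval about 5% of the time — follows from exchangeability alone
and is verified with a scaled 200-replicate null against 400 fresh
replicates.

## What the synthetic cohort generator does and does not emulate

The generator draws an H1 founder and an H2 founder differing at non-tag
sites with probability `divergence_scale` (default 0.3, deep
between-family divergence), plants tag diagnostic alleles on the
appropriate founders (perfect tagging by default; a per-tag error rate is
available to stress the typer, since no tag discordance rate is published
for this locus), then gives each haplotype private mutations at
`within_family_theta` per non-tag site (default 0.002; optionally one
rate per family, the standard family usually the deeper one). Mutations
are infinite-sites on a fixed integer position grid, matching biallelic
SNP data downstream. Subtypes are drawn per individual from group
frequencies; the default six-group configuration uses the published group
sizes (523/181/156/549/350/361) with per-group cumulative H2 frequencies
matching the published pattern (0.7% Sub-Saharan Africa … 33.7% South
Europe) and H2D enriched over H2′ outside Sub-Saharan Africa, the split
being this package's choice where only cumulative frequencies are
published. Depth tracks are negative-binomial per 1-kb window
(dispersion 100 — frozen after checking that 1,000 seeded
duplication-free tracks produce no run of ≥ 3 windows above 1.5×
baseline) around `baseline × (2 + dosage)/2` inside the duplication
interval.

What this does *not* emulate: coalescent genealogy within families (no
shared internal branches beyond the founder), linkage disequilibrium
decay, realistic site-frequency spectra, sequencing-read-level artefacts,
assay chemistry, or the real 17q21 sequence. Passing recovery tests on
these fixtures therefore demonstrates correctness of the *inference
machinery* under its stated model, not robustness to every failure mode
of real genotype panels. Real-data quantities that depend on the study's
unreleased genotypes (published per-subtype diversity tables, observed
Fst values, the real tree) are explicitly not reproduction targets.

## Problem sizes

The test suite runs scaled experiments chosen as the smallest sizes at
which each property is statistically meaningful: oracle equivalence on
100+ random fixtures per statistic; typing recovery on 500 samples;
conditioning on 100 accepted replicates at Ne = 500 / 50 kb; calibration
with a 200-replicate null and 400 trials at Ne = 100 / 20 kb; the
coalescent-control comparison at Ne = 50 with θ = 6. The full published
scale (Ne = 10,000, 500 kb, 1,000 replicates) is reachable through the
same `sim_config()` by changing the numbers.

## Known limitations

- The demographic model is a single panmictic constant-size population;
  no bottlenecks, growth, structure or selection. Departures from the
  null cannot be attributed to selection versus demography.
- The unanimity vote rule trades call rate for reliability; cohorts with
  noisy tags will see abstentions grow quickly with panel size.
- The plug-in Fst variant is biased at small sample sizes (see above);
  it exists for definitional comparability, not inference.
- The NJ tree has no support values; it answers "do arrangements form
  separate clades", nothing finer.
- The simulator's restart-on-loss conditioning slightly differs from
  trajectory-resampling schemes; for a neutral allele the accepted
  trajectories are the same conditional process, but runtimes differ.
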