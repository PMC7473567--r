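---
title: "Models and methods behind symbiocoal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind symbiocoal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symbiocoal)
```

symbiocoal studies how the transmission mode of an intracellular
bacterial symbiont — vertical through the host germ line, horizontal
between hosts, or a mixture — shapes its effective recombination rate
and, through it, genome evolution.  The package contains two simulators
(a forward host-structured inheritance model and a backward coalescent
with gene conversion), the summary statistics that fingerprint
recombination in consensus alignments, a random-forest regression ABC
estimator of the population-scaled mutation rate theta and the per-site
recombination rate rho\*l, and within-host analyses operating directly
on read pileups and read pairs.  Everything runs on synthetic data
generated by the package itself.

## The host-structured transmission model

Hosts form a Wright-Fisher population of constant size `NH`.  Each host
carries `NS` symbiont cells.  One generation proceeds as follows:

1. every offspring host draws a uniformly random parent host;
2. the offspring's symbiont population is founded by `bottleneck` (B)
   cells sampled with replacement from the parent's `NS` cells — the
   transmission bottleneck of oocyte colonization — and instantly
   regrown to `NS` by multinomial resampling of the founders;
3. with probability `H` per symbiont per generation, an offspring
   symbiont is instead acquired horizontally: it copies a uniformly
   random cell from a uniformly random host of the parental generation,
   bypassing the bottleneck.  (A horizontally acquired lineage may
   re-enter its own parental host line with probability 1/NH; at the
   host numbers of interest this is indistinguishable from excluding
   it, and it makes the model exactly solvable.)

Mutations accrue on each lineage as Poisson(`mutation_rate`) counts per
generation and are compared by infinite-alleles difference counting:
two sampled cells differ by every mutation on either path back to their
common ancestor.  The default `mutation_rate` of 2e-3 per genome per
generation corresponds to a ~1 Mb symbiont genome mutating at ~2e-9 per
bp per generation.

### Closed-form expectation for pairwise differences

Tracking two sampled lineages backward, the state is only whether they
occupy the same host (S) or different hosts (D).  One backward
generation from S: both lineages are vertical with probability
$(1-H)^2$, in which case they pass through the same bottleneck and
coalesce with probability $a = 1/B + (1 - 1/B)/N_S$ (same founder, or
distinct founders that chose the same parental cell); any event
involving a horizontal acquisition places that lineage on a uniform
cell of the parental generation, giving coalescence probability
$1/(N_H N_S)$.  Collecting terms:

$$p_S = (1-H)^2 a + H(2-H)\frac{1}{N_H N_S}, \qquad
  p_D = \frac{1}{N_H N_S},$$

and the no-coalescence transitions are
$P(S\to S) = (1-H)^2(1-a) + H(2-H)(N_S-1)/(N_H N_S)$,
$P(S \to D) = H(2-H)(1-1/N_H)$,
$P(D\to S) = (N_S-1)/(N_H N_S)$, $P(D\to D) = 1 - 1/N_H$.  Note that
$p_D$ is independent of $H$: from different hosts the two lineages meet
either through host-lineage coalescence (then collide with probability
$1/N_S$) or through horizontal acquisition, and both routes give exactly
$1/(N_H N_S)$.  The expected coalescence times solve the 2x2 linear
system $T_S = 1 + P(S\to S) T_S + P(S\to D) T_D$,
$T_D = 1 + P(D\to S) T_S + P(D\to D) T_D$, and the expected number of
differences between two symbionts from distinct random hosts is
$2\,\mu_g\,T_D$ (`expected_pairwise_differences()`).  At $H = 1$ the
system collapses to the panmictic Kingman value $T_D = T_S = N_H N_S$;
at $H = 0$ with $B = 1$, $T_S \to 1$, reproducing the regime in which
within-host populations are nearly devoid of variation while host
lineages diverge.

Because the derivation is exact for the implemented generation update,
the forward simulator and the formula must agree up to Monte Carlo
error; `pairwise_diff_check()` and `run_validation()` verify agreement
within two pairwise differences over an eight-point grid spanning
$H \in \{0, 0.1, 0.5, 1\}$, $N_H \le 150$, $N_S \le 10$ with 100
replicates per point (a negative-control hook,
`expectation_offset`, confirms the check can fail).  Burn-in follows
the stationarity guard of at least $10\,N_H N_S$ generations, an order
of magnitude beyond the longest coalescent time scale in the system.

## The coalescent with gene conversion

`simulate_coalescent_gc()` draws neutral haplotype samples under a
Kingman coalescent with bacterial gene conversion, the training engine
for the ABC fit.  It is an exact ancestral-recombination-graph
construction, not a sequentially Markovian approximation, and no clonal
frame is imposed.  Time is scaled so a lineage pair coalesces at rate
1; mutation strikes at rate theta/2 per carried site and gene
conversion initiates at rate rho/2 per genome site.  An initiation at
site $s$ converts the tract $[s, \min(s+l-1, L)]$ — the tract length is
fixed at `tract_length` per simulation, truncated at the sequence end,
so tracts at or beyond the genome length act as single crossovers —
and splits the lineage into the ancestral material inside and outside
the tract.  Initiations that would not change any marginal genealogy
(tract missing the material, or covering all of it) are thinned away
exactly by sampling only admissible initiation sites.  Ancestral
segments carry descendant bitmasks so mutations map directly to the
samples that inherit them; material whose marginal most recent common
ancestor has been reached is trimmed, which keeps the graph walk fast
even at the upper end of the recombination prior.  Mutations are
mapped to distinct integer positions by uniform draw with collision
rejection; a constructor guard requires the genome length to exceed ten
times the expected number of segregating sites.

The simulator is calibrated against closed forms (mean segregating
sites versus the Watterson expectation at every rho; the
site-frequency spectrum against the 1/i law using replicate-level
standard errors, since sites within one replicate share a genealogy and
pooled counts are overdispersed) and cross-checked against an
independent coalescent engine through the system Python, at matched
population-scaled rates, on the four-gamete summary the ABC consumes.
The independent engine draws geometric tract lengths with mean equal to
our fixed tract, so the check asserts statistical agreement of the
summary, not equality of event processes.

## Summary statistics

`summary_vector()` computes per-site nucleotide diversity (pi),
per-site Watterson's theta, and the six-bin four-gamete profile: for
every unordered pair of non-singleton biallelic sites (minor allele
count at least 2), whether all four haplotypic allele combinations
occur, binned by inter-site distance into half-open bins bounded at 10,
1e2, 1e3, 1e4, 1e5 and 1e6 bp.  Under infinite-sites mutation on a
single tree at most three combinations are possible, so the bin
proportions trace the decay of linkage with distance and carry the
recombination signal.  Empty bins are reported as missing, never as
zero; pairs beyond 1e6 bp are excluded and counted.  Columns containing
gaps or ambiguity codes are excluded from variant positions, and the
usable length (genome length minus excluded columns) is the denominator
of all per-site statistics.  Sites with any missing call are dropped
complete-case, with the count reported.

Tajima's D uses the standard variance constants and returns a flagged
`NA` (never a silent zero) when there are no segregating sites.
Folded spectra tally minor-allele counts, with ties at n/2 assigned to
the n/2 class.  Between-host differentiation uses Hudson's Fst as a
ratio of averages — chosen for robustness to unequal sample sizes —
with a sample-size correction when haplotype counts are supplied and a
95% percentile bootstrap over sites (1,000 replicates by default).  A
site bootstrap presumes quasi-independent sites; for forward-model
sequences, which share one genealogy per run, the metapopulation
generator's `n_loci` argument concatenates independent realizations
into genome windows to emulate a recombining genome before Fst is
interpreted.

## The regression-ABC estimator

Priors follow the training design: theta log-uniform on (3e-5, 1e-2)
per bp, rho log-uniform on (1e-6, 1e-2) per bp, tract length uniform on
(1, 1e5) bp rounded to integers.  Each draw is simulated at the
observed sample size, summarized, and used to train one random
regression forest per target: theta on its natural scale and
log10(rho\*l) — the reported compound parameter is the per-site rate
rho\*l, and the drawn tract length is kept only as a diagnostic.
Missing four-gamete bins are imputed to zero with paired indicator
features, so the forest can distinguish "no pairs in this bin" from "no
failures".  Forests default to 500 trees (out-of-bag variance estimates
are stable there; configurable) with `ranger`; out-of-bag R-squared
scores are reported per target and per sample size, and models must be
trained at the sample size of the data they score (`estimate()`
enforces this).

Confidence intervals combine two variance components: the
infinitesimal-jackknife estimate of the forest's own sampling variance
(computed from per-tree predictions and inbag counts, with the finite-B
Monte Carlo bias correction), plus a locally estimated residual
variance — the mean squared out-of-bag residual among the 100 training
simulations whose out-of-bag predictions are closest to the new
prediction.  The jackknife component alone answers "how variable is
this forest's output", not "how far is the truth likely to be"; with
desk-scale training data it is an order of magnitude too small, and
intervals built from it alone cover the truth for under a third of
held-out simulations.  Adding the local residual component restores
~95% empirical coverage for both targets while letting interval width
track the information actually present (narrow for data-rich, wide for
degenerate inputs).  A summary vector with no segregating sites
triggers an explicit low-information warning.

`r_over_m()` converts the estimate to the conventional ratio of
nucleotide changes introduced by recombination versus mutation,
r/m = rho\*l \* theta_recombinant / theta_genome, which reduces to
rho\*l itself when donors are drawn from the same population as the
genome (theta_recombinant = theta_genome).

### What recovery desk-scale tests do and do not show

The package's default training configuration is 2,000 simulations of
20 kb genomes — a desk-scale surrogate for a full-fidelity run of 1e5
simulations at genome scale (~1 Mb), which is documented configuration,
not test default.  At 20 kb the recombination target is only partially
identifiable: out-of-bag Spearman correlation between true and
predicted log10(rho\*l) plateaus near 0.71-0.74 regardless of forest
size, while theta recovery reaches 0.96.  Two mechanisms cap it, both
artifacts of the short genome rather than of the estimator: simulations
in the lower theta tercile carry too few non-singleton SNP pairs for
stable four-gamete proportions (Spearman rises from 0.44 in the bottom
theta tercile to 0.81 in the top), and 80% of tract-length draws exceed
20 kb, so the data can only reflect rho\*min(l, L) while the label is
rho\*l.  Both effects shrink as the genome grows; at the megabase scale
of real symbiont genomes all six distance bins populate and SNP-pair
counts grow a thousandfold.  Interval coverage is unaffected (the local
residual variance widens intervals exactly where the signal is weak),
and the point estimates remain approximately median-unbiased over the
prior interior.

## Within-host analyses

`call_within_host_variants()` applies three filters to pileup columns
in order: columns with depth outside one standard deviation of the
genome-wide mean are dropped (copy-number and mapping artifacts);
columns within 5 bp (configurable — the window is a documented choice)
of an indel-bearing column are dropped; and an alternate allele is
called only when the binomial upper tail
$P(X \ge \mathrm{alt\_count} \mid \mathrm{depth}, e)$ falls below alpha
(default 0.05 per site, uncorrected, matching a cumulative-binomial
error model; a Bonferroni mode exists but is off by default).  The
per-site error rate $e$ defaults to the mean phred-implied error of the
column's base qualities and can be fixed globally.  Within-host
diversity per usable site is $2p(1-p)\,d/(d-1)$ at called sites.  On
error-only input the called fraction stays below alpha, and variants at
frequency 0.1 or more at depth 100 are recovered with recall above
0.99.

`read_pair_four_gamete()` is the read-backed confirmation that
recombinant haplotypes exist inside hosts: because each read pair
derives from one DNA fragment, allele pairs co-observed on a read pair
belong to one chromosome.  For each site pair with at least 100 joint
observations, the four configurations AB/Ab/aB/ab are tallied and the
pair is flagged only when every configuration exceeds proportion 0.05
(strict), making the flags conservative to sequencing error.  Pairs
from at most three haplotypes are never flagged in error-free data;
"adjacent" means co-observable within the library insert span, which is
a generator parameter rather than a constant.

## Synthetic data

`make_metapopulation_alignment()` emits host-labelled consensus
alignments from either simulator; `make_reads()` draws paired reads
from weighted haplotype mixtures with independent uniform substitution
errors (no indel errors — indel-bearing columns for filter tests are
injected explicitly) and emits a mutually consistent read table, pileup
and phasing table; `make_vcf_fixture()` builds filter records that
each violate exactly one named threshold.  Quality strings are a
constant phred matching the error rate, so quality-derived and fixed
error modes agree on generated data.  The generators are
seed-deterministic.  They do not emulate GC-biased coverage, duplicate
reads, mapping error or host contamination; tests passing on them show
the statistical machinery is correct under the stated error model, not
that real libraries satisfy that model.

## Numerical choices and limitations

- Coordinates are 1-based inclusive everywhere on disk; distance bins
  are half-open on the left.
- The ARG event budget (default 2e7) aborts pathological parameter
  combinations with the offending parameters named.
- Sample sizes for the coalescent are capped at 64 by the descendant
  bitmask representation; the study designs of interest use n <= 24.
- Forest seeds, simulation seeds and generator seeds are all threaded
  from user-supplied seeds; identical inputs give bit-identical
  outputs.
- The transmission model fixes host population size and symbiont
  carrying capacity; host demography, selection, and inference of H
  from data are out of scope.
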