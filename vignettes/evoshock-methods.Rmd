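---
title: "EvoShock: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EvoShock: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EvoShock)
```

EvoShock analyses a laboratory-evolution design in which a bacterial
population is profiled through an acute stress response (shock) and,
after hundreds of generations of selection, through inheritable
tolerance (adaptation). This vignette documents the statistical models
each stage implements, the parameters a user may want to change, what
the synthetic-data generator does and does not emulate, and the design
decisions taken where the methodology left genuine freedom.

## Differential expression

The data are gene-level log2 measurements: two-channel log ratios
against a common reference, assumed normalised upstream (the package
does no background correction or array normalisation). For a contrast
of treatment state $t$ against control state $c$, replicates are paired
by index and the per-replicate log ratio is
$\log_2 R_i = x_{t,i} - x_{c,i}$. A gene is called significant when
both

$$|\overline{\log_2 R}| \ge 1.0 \quad\text{and}\quad
  |Z| \ge 2.0, \qquad
  Z = \frac{\overline{\log_2 R}}{s / \sqrt{n}},$$

with inclusive thresholds. The one-sample form of $Z$ over replicates
is a design decision: the joint fold-change/Z rule is conventionally
stated without a formula, and with triplicate designs the one-sample
statistic over the replicate log ratios is the natural reading; both
cutoffs are arguments of `callDE()`. A zero-variance ratio vector gets
an infinite-Z sentinel so that its significance is decided by the ratio
cutoff alone — with three replicates this occurs for degenerate
(e.g. rounded) data and silently dropping such genes would bias calls.
Genes with a missing value in any replicate are excluded from that
contrast with a message, not imputed.

Temporal patterns among significant genes are clustered with Euclidean
K-means (`temporalClusters()`, default $k = 10$, 10 restarts, fixed
seed, `iter.max = 100`). K-means is used because response trajectories
are compared by shape and magnitude in log2 space where Euclidean
distance is meaningful; if K-means leaves requested clusters empty
(identical trajectories), the empty clusters are reported rather than
re-fitted with smaller $k$, so the requested and effective $k$ are both
visible.

## Transcriptome state space

Absolute states are replicate-mean profiles over all genes; relative
states are contrast vectors restricted to genes whose largest absolute
mean log2 ratio over the contrasts strictly exceeds $\log_2 2$ ("more
than 2-fold" is read as a strict inequality; the boundary case of a
gene at exactly 2-fold is excluded). The 2-fold filter applies only to
relative states; the absolute-state analysis uses all genes, since
filtering by change would build the very contrast structure the
absolute view is meant to be independent of. Both modes are available
through `relativeStates(foldFilter = )`.

Distances are $d = 1 - r$ with $r$ the Pearson correlation of two
profiles, giving $d \in [0, 2]$. The alternative $(1 - r)/2$ would
compress the range; $1 - r$ is the convention of the clustering tools
this analysis style descends from, and the choice only rescales, never
reorders, distances. Trees are average linkage on this distance;
supports are the percentage of trees, from resampling genes (rows) with
replacement, that contain the same clade (`bootstrapTree()`, default
1000 resamples). Resampling genes is the standard bootstrap for
expression support trees; resampling samples would conflate replicate
noise with profile identity. A degenerate resample that leaves a
profile with zero variance yields an undefined correlation, which is
treated as $r = 0$ (unrelated) for that resample.

`microevolutionMetrics()` quantifies five features of the distance
structure: **distinctness** (minimum between-group vs maximum
within-group distance for a stated two-group labelling),
**discreteness** (distance of a designated state to its nearest
neighbour), **resilience** (whether the last state of a temporal
trajectory has returned closer to the origin than every intermediate
state), **memory** (designated relative-state pairs ranked by
similarity) and **convergence** (the global arg-min pair of the
relative-state distance matrix). Ties in the arg-min are broken
lexicographically on the sorted label pair, so results are reproducible
on degenerate inputs.

## Co-expression networks

Gene-gene Pearson correlations are computed within a condition group
(the reference design has twelve arrays per group). Zero-variance genes
are dropped with a message; groups below three samples are an error and
three samples produce a warning, as correlation estimates on so few
columns are unstable.

Edges connect pairs with $|r| \ge \theta$ and carry the correlation and
its sign. Thresholding on $|r|$ with a sign attribute (rather than on
$r > \theta$) keeps anti-correlated pairs visible while using a single
rule; whether a published network of this kind included negative edges
at high cutoff is typically ambiguous, and the sign attribute lets the
user filter either way. Isolated genes are excluded from the node set,
so node counts are comparable across thresholds.

The default threshold is 0.98; `rmtThreshold()` can re-derive a
threshold from the data by the random-matrix-theory transition: for
each candidate $\theta$ the pruned correlation matrix's eigenvalue
spectrum is unfolded and the nearest-neighbour spacing distribution
(NNSD) is tested against the exponential (Poisson) law; the selected
threshold is the smallest candidate not rejected at $\alpha = 0.05$.
Noise-dominated correlation matrices show GOE-like level repulsion;
genuine modular signal shows Poisson spacings, so the transition marks
where pruning has removed the noise background. Numerical choices:
unfolding fits a smoothing spline (df = 10) to the cumulative count of
*distinct* eigenvalues — pruning creates exact degeneracies (blocks of
unit eigenvalues from isolated genes) that carry no spacing information
and are collapsed first; the chi-square test uses about $\sqrt{N}$
equal-probability bins under the exponential law, capped so each
expected count is at least 5, with $N - 2$ degrees of freedom; spectra
with fewer than 15 usable spacings are treated as untestable rather
than accepted. If no candidate is accepted the grid maximum is returned
with a warning — on strongly blocked matrices the spectrum can stay
degenerate at every candidate, and the maximum is then the conservative
(sparsest) choice.

Modules are detected by fast-greedy agglomerative modularity
maximisation (`detectModules()`, via igraph), cutting the merge path
exactly at the modularity maximum. Fast-greedy is a *heuristic*: even
on graphs of at most eight nodes it reaches the exhaustive-search
maximum-modularity partition only on most, not all, random graphs, and
the package's test suite measures that agreement rather than assuming
it. Modules below `minSize = 5` nodes are retained and flagged "small"
instead of dropped, so the partition always covers every node.
`compareNetworks()` reports shared and specific nodes, the shrinkage
percentage $(|B| - |A|)/|B| \times 100$, top-$k$ degree hubs and, given
two partitions, the module assignment of every shared node in both
networks.

## Dynamic operons

A predicted polycistron is split into suboperons using two requirements
evaluated in **every** replicate of a condition: a boundary between
adjacent genes is a split when the larger-over-smaller ratio of their
mean depths strictly exceeds `fold = 2`; and co-membership in a
multi-gene suboperon requires at least `minPairs = 1` uniquely mapped
bridging read pairs between every adjacent internal pair. The pair
requirement is read as support *within* the resulting transcription
units (membership evidence); the alternative reading — a split is
confirmed only when pairs are *absent across* the boundary — is
available as `boundaryMode = "across"`. The ">2-fold" change is
measured between adjacent genes, not between suboperon means: the
adjacent-gene ratio is what a coverage step at a boundary produces, and
it makes the rule invariant to uniform depth scaling of a replicate.

Genes are "expressed" when mean depth reaches `minDepth = 5` reads in
every replicate; 5 is a conventional floor below which a mean coverage
estimate over a gene is unreliable. Unexpressed genes are excluded from
suboperon membership and break contiguity. Replicate counts other than
three are an error unless `replicates` is set, mirroring the triplicate
design the rule is phrased for. `compareOperons()` emits a call per
polycistron exactly when the split-point sets of two conditions differ,
reporting each differing boundary and which condition has it.

## Mutation analysis

Consensus calls are the intersection of caller outputs keyed on
(chrom, pos, ref, alt) — the same position with a different alternate
allele is a different call. Non-consensus calls go to a side report
with per-caller support, replacing manual inspection with a
machine-readable artefact. Effects are annotated at codon level under
the bacterial genetic code (translation table 11), strand-aware;
single-base indels in coding sequence are frameshifts. Pooled
frequencies are $\mathrm{alt}/(\mathrm{ref} + \mathrm{alt})$; a
mutation is a beneficial candidate when non-synonymous (missense,
nonsense or frameshift) **and** its pooled frequency strictly exceeds
0.80. The mutation rate is $\mu_g = n / G$ over $G$ generations,
reported to two significant figures; all consensus mutations count
(SNPs and single-base indels), and the generation count is taken as an
input, not recomputed.

## The synthetic-data generator

The generator's defaults encode the reference design: nine cellular
states (wild type unshocked; four shock time points at 0.15% ethanol;
two adapted strains each with and without their ethanol dose), three
biological replicates per state, homoscedastic Gaussian noise of 0.25
log2 units, planted differential effects of 2.0 log2 units, and a
pooled sequencing depth of 140x. Planted structure:

- *differential genes*: a fraction of genes shifted by ± the effect
  size in the designated states;
- *co-expression blocks*: one latent factor per block with loading
  $a = \sigma\sqrt{\rho/(1-\rho)}$, giving expected within-block
  correlation $\rho$;
- *memory signatures*: a common random contrast signature added to the
  treatment states of two designated contrasts, making them the most
  similar relative-state pair;
- *operons*: per-base Poisson coverage around per-gene planted means,
  with bridging pair counts positive within planted transcription units
  and zero across planted splits;
- *pooled loci*: Poisson total depth, binomial alternate reads at the
  true frequency.

One master seed drives derived substreams per generator, so identical
configuration and seed give identical output without coupling the
generators. The Gaussian noise model is a deliberate stand-in: the
noise law of two-channel arrays is not specified by the analysis being
modelled, and homoscedastic log2 noise is the simplest model consistent
with ratio-based calling. Consequences for interpretation: passing
recovery tests show the *rules* are implemented correctly and behave
well under their nominal noise model; they do not establish robustness
to array-specific artefacts (spatial effects, intensity-dependent
variance, probe cross-hybridisation), to mapping bias in coverage, or
to non-binomial overdispersion in pooled counts, none of which the
generator emulates. FASTQ-level read simulation and aligner behaviour
are out of scope; coverage and link tables are generated directly.

Planted mutations are verified independently of the annotation code
path: `plantMutations()` establishes each planted effect by translating
the entire mutant CDS and comparing proteins, whereas
`annotateEffects()` classifies from the single affected codon, so
agreement between the two is a genuine cross-check.

## Problem sizes in tests

The package's tests and the acceptance script use: 10 000 genes for the
null false-positive control; 500 genes at 10% planted differential for
recovery; 100 random graphs of at most eight nodes against the
exhaustive modularity oracle (all set partitions enumerated); 100
planted polycistrons at depth 50 and fold 3.5 for boundary recovery;
1000 pooled loci at depth 140 and true frequency 0.85; 1000 bootstrap
resamples for group support. These sizes give stable Monte-Carlo
estimates (binomial standard errors below one percentage point for the
rate-type quantities) while keeping a full run in minutes on one CPU.

## Known limitations

- Fast-greedy modularity is a heuristic; on a minority of small dense
  graphs it does not attain the exhaustive maximum (see above), and on
  large networks the gap is unquantified.
- The RMT threshold search degrades to the grid maximum on spectra too
  degenerate to test; this is conservative but means the "transition
  point" interpretation does not apply there.
- Effect annotation handles SNPs and single-base indels only, and
  assigns a variant in overlapping genes to the first annotated
  overlap.
- The state-space metrics summarise a distance matrix; they inherit all
  limitations of Pearson correlation on replicate-mean profiles
  (sensitivity to a few high-magnitude genes, blindness to nonlinear
  relations).
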