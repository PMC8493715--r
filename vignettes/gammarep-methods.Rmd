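---
title: "Methods: models, estimators and design choices in gammarep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in gammarep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`gammarep` analyses T cell receptor gamma (TRG) repertoires in the chicken, a
"γδ-high" species in which γδ T cells form a large fraction of circulating
T cells. The pipeline runs from pooled 5'RACE amplicon reads to biological
summaries: per-gene (TRGV) usage profiles, coverage-standardised diversity,
public/private clonotype structure across birds and lines, and the
relationship between recombination signal sequence (RSS) quality and gene
usage. A ground-truthed simulator makes every stage testable without any
external sequencing data.

This vignette documents the models, the estimators, the tunable parameters,
and the places where the design was genuinely open and a choice had to be
made.

# The germline locus model

The packaged reference (`trg_reference()`) models the chicken TRG locus:
40 TRGV genes in four families (TRGV1–TRGV4 with 6/22/7/5 members and
2/8/0/3 pseudogenes), three TRGJ genes and one TRGC, with genes numbered
within each family from distal to proximal relative to TRGC. Two sets of
germline-identical TRGV2 genes are represented exactly as such, so that read
assignment is genuinely ambiguous for them and yields the grouped calls
`TRGV2.7/2.18` and `TRGV2.4/2.8/2.14/2.19`.

The nucleotide sequences in the bundle are *synthetic placeholders*
(the file is named accordingly): they are built so that the family
structure holds under the package's identity rule — at least 75% identity
within a family and below 75% between families — and so that each
functional gene carries an IMGT-style junction anchor (the conserved
2nd-CYS codon on V, the J-PHE codon on J) and a heptamer/23-spacer/nonamer
RSS. Counts, names, family membership, expression status and the ordering
are curated metadata; the bases are not biological sequence. Analyses that
depend only on locus structure (family summaries, naming, assignment
ambiguity, junction extraction geometry) behave as they would on the real
locus; analyses of sequence content (e.g. actual RSS quality of a given
gene) do not.

**Sequence identity** is `100 × identical positions / length of the shorter
sequence`. The formula leaves open how identical positions are counted; we
count matched positions of an end-gap-free global (overlap) alignment with
match +1, mismatch −1, gap −2, which caps identity at 100 by construction.
Because several alignments can be co-optimal with different match counts,
the implementation orders the two sequences lexicographically before
aligning, which makes the measure exactly symmetric. Family assignment uses
the standard 75% subgroup threshold; ties between families resolve to the
lexicographically first family with a warning.

# Locus-structure validation in silico

`in_silico_pcr()` and `digest_fragments()` are the computational counterpart
of the PCR–restriction-digest experiment used to discriminate alternative
locus structures (a tandem duplication present in one assembly and absent in
another). Primer sites are matched with a configurable mismatch budget on
both strands; enzyme recognition sites (DrdI's REBASE definition
`GACNNNN^NNGTC` ships as data) are matched exactly per IUPAC code — enzymes
do not cut near-sites, so no mismatch tolerance applies. Fragment lengths
always partition the molecule, and `classify_structure()` compares an
observed fragment multiset against candidate structures within a per-fragment
tolerance, returning `"ambiguous"` unless exactly one candidate matches.

# Read processing and annotation

**Demultiplexing** assigns each read to the unique sample barcode within
`max_mismatches` (default 0) at a configurable offset, checking both the
read and its reverse complement and re-orienting matched reads. Reads
matching zero or several barcodes are kept in an `undetermined` stream with
a reason — no read is ever dropped, which the tests assert as a conservation
property.

**Segment assignment** aligns each read, in both orientations, against every
functional germline segment with Smith–Waterman local alignment
(match +5, mismatch −4, linear gap −8; the match/mismatch weights are the
classic nucleotide dot-plot weights, the gap penalty is a conventional
choice). The optimum is exact — at ≤ 43 reference segments exhaustive
alignment is affordable — and ties between equally scoring references
produce a grouped call joining the tied genes in locus order. An exact
k-mer prescreen (k = 12 by default) shortlists candidate references for
speed; the tests verify it does not change calls. Scores below `min_score`
(default 60) yield no call. All tie-breaks (alignment traceback, strand
preference, grouped-id ordering) are fixed so outputs are bit-reproducible.

**Junction extraction** maps the V segment's anchor codon and the J
segment's anchor end through the two alignments (walking the CIGAR, so
indels are handled) onto the read, and reports the anchor-inclusive
junction — the common AIRR convention, recorded in the output metadata. If
an anchor falls outside its alignment's reference span the read is flagged
`no_junction` rather than guessed.

**Productivity**: a junction is *in frame* when its length is divisible by
three; stop codons are sought in frame 0; *productive* = in frame and
stop-free. Downstream tables filter on the in-frame flag by default (the
usage analyses are defined on in-frame rearrangements); the stop-codon
filter is exposed separately via `filter = "productive"`.

Grouped V calls are retained for analysis only when they are one of the two
germline-identical groups above; any other grouped call is written to the
rearrangement output but flagged `ambiguous_v_excluded` and skipped by the
clonotype table, keeping interpretation straightforward.

# Usage profiles and uncertainty

A clonotype is the pair (V group, junction nucleotide sequence). Usage
proportions are computed per bird and tissue (a bird's reads in a tissue
sum to 1 across V groups) and averaged *unweighted* across birds, so each
bird counts once regardless of sequencing depth — the same logic as a
bird-level random effect. Where the original analysis fitted a linear mixed
model with bird as a random effect and derived intervals from 500 bootstrap
replicates of logit-transformed proportions, this package deliberately does
not re-implement mixed-model machinery: it uses a **hierarchical bird-level
bootstrap on the logit scale** (resample birds with replacement, average
logits, back-transform the 2.5/97.5 percentiles; 500 replicates by
default). This matches the transformation and replicate count of the
original design and yields comparable intervals, but p-values produced by
`bootstrap_contrast()` are bootstrap tail probabilities, not Satterthwaite
mixed-model p-values, and are labelled as such. Zero proportions are
continuity-adjusted before the logit by adding half a read to the numerator
and one read to the denominator.

The acceptance suite measures the empirical coverage of these intervals on
simulated 8-bird data. Percentile bootstrap intervals under-cover at small
n — at n = 8 birds their empirical coverage sits around 88–92% against the
nominal 95%, depending on the simulation draw — which is an inherent
property of the percentile method at this sample size, not a defect of the
resampling. Interval widths should therefore be read as mildly
anti-conservative at study-scale bird counts; the acceptance script reports
the measured coverage over 1 000 simulation repeats.

# Coverage-standardised diversity

Diversity is reported as Hill numbers: q = 0 (richness), q = 1 (exponential
Shannon entropy) and q = 2 (inverse Simpson concentration), all in units of
"effective number of equally common clonotypes". Because repertoire samples
of different depth are not comparable at a common *size* when discovery
curves are far from plateau, estimates are standardised to a common
**sample coverage** (the estimated fraction of the community's abundance
represented by observed clonotypes), defaulting to coverage 0.1. That
default is deliberately low — repertoires are so diverse that deeper
coverage is unattainable at practical depth — and is flagged here because
at such low coverage the estimates characterise the abundant end of the
clone-size distribution rather than total richness.

The estimator family is the standard coverage-based rarefaction/
extrapolation framework:

* Full-sample coverage uses the Good–Turing estimate
  $\hat C = 1 - \frac{f_1}{n}\cdot\frac{(n-1)f_1}{(n-1)f_1 + 2f_2}$ with
  $f_k$ the number of clonotypes seen $k$ times.
* Rarefied coverage and rarefied Hill numbers use the exact expectation
  formulas (hypergeometric expectations of frequency counts); interpolated
  q = 0 and q = 1 values therefore agree with exhaustive enumeration over
  all subsamples, which the tests verify for n ≤ 8.
* Extrapolated richness uses the Chao1-anchored form with
  $\hat f_0 = f_1^2/(2f_2)$ (the bias-corrected variant when $f_2 = 0$).
  For q = 1 and q = 2 the extrapolation is anchored on asymptotic
  estimators (an entropy estimator of the Good–Turing/jackknife family,
  and the unbiased inverse-Simpson) and relaxes from the observed value to
  the asymptote with the same geometric factor as the richness
  extrapolation — continuous at m = n and convergent as m grows. These
  anchored forms are documented in the code; where the literature admits
  variants, continuity and convergence were the selection criteria.
* The coverage-to-size inversion finds the *smallest* m whose coverage
  reaches the target (binary search over the monotone curve; closed form on
  the extrapolation side). When a sample has no singletons (or no
  doubletons while below target) the extrapolated coverage curve is flat,
  the target is unreachable, and the observed value is returned with a
  note rather than an extrapolated guess.

Uncertainty on diversity uses a clonotype-level multinomial bootstrap
(default 200 replicates) rather than analytic variance formulas — a
documented divergence, chosen for simplicity and because the same machinery
serves all three orders. Units below 100 reads are dropped with a warning:
rarefying tiny samples to low coverage discards essentially all information.
Birds' reads are pooled within a tissue unit before estimation by default,
and summaries across birds are taken afterwards; both modes are available
through the `by` argument.

# Public and private clonotypes

A clonotype's **penetrance** in a line is the fraction of the line's birds
in which it appears, pooling every tissue at any read frequency; the
denominator is all birds of the line present in the table. Bins are
half-open: `p100` at penetrance 1, `p80` in [0.8, 1), `p60` in [0.6, 0.8),
otherwise `private`. The bins are mutually exclusive for stacked displays;
**cross-line sharing** uses them cumulatively — a clone public at level L in
one line is shared when it reaches level L *or higher* in the other — in
both a read-weighted and an equal-weight mode, whose contrast exposes
expanded public clones. Lines with unequal bird counts are compared after
down-sampling the larger line to the smaller one's bird count (uniformly at
random, seeded). Between-line comparisons of per-gene public shares use the
rank-sum test (`stats::wilcox.test`, unpaired form — the original figure
legends name an "unpaired Wilcoxon signed rank test", which as an unpaired
two-sample comparison is the rank-sum/Mann–Whitney test; the naming
discrepancy is resolved in favour of the test that matches the design),
with optional Benjamini–Hochberg correction.

Publicity keys clones by (V group, junction nucleotide sequence): identical
junctions on different V genes are distinct clones, since publicity is
analysed per gene.

# RSS scoring and usage regression

Published recombination-information-content (RIC) scores come from trained
Bayesian models that cannot be re-derived here; `rss_model()` is an
explicit **position-weight-matrix stand-in**: per-position log-odds over
the heptamer and nonamer (spacer ignored), trained on a set of RSS
sequences with a 0.5 pseudocount against a uniform background. Its scores
order sequences sensibly (the training consensus attains the maximum;
mutations at conserved positions lower the score) but are *not* numerically
comparable to published RIC values; `usage_regression()` therefore accepts
externally computed scores directly, so the original analysis can be rerun
verbatim when such scores are available. The regression itself is ordinary
least squares of usage proportion on score via `stats::lm`, reporting
slope, intercept, R² and the two-sided slope p-value.

# The simulator

`simulation_config()` defines the study conditions the package targets:
eight birds of a line across up to seven tissues, 5 000 reads per
bird × tissue sample, 300 private clonotypes per bird, a usage distribution
dominated by one gene at 35% of the repertoire with the remainder spread
geometrically, junctions assembled from a trimmed V tail (geometric trim,
mean ≈ 1 nt, capped so the anchor survives), a Poisson(8) untemplated
insertion, and a trimmed J head (mean ≈ 2 nt). Reads are
barcode + universal adapter + the rearranged body + a constant-region head,
with independent per-base substitution errors (default 0.1%, the
amplicon-sequencing regime; indels are not simulated — substitution errors
dominate this platform and indel-free truth keeps the junction-recovery
oracle exact).

Two design points matter for interpretation:

* **Usage is carved out, not perturbed, by public clones.** Within a V
  gene, a bird's reads are split between its clones with private clones at
  weight 1 and planted public clones at their `expansion_factor`; across
  genes, totals follow `v_usage` exactly. Planting public clones therefore
  never distorts the usage distribution, and a public clone's expected read
  share within its gene is `e/(e + k)` for expansion `e` against `k`
  private clones — which is how the acceptance run plants a clone at an
  expected 75% share.
* **Junctions are adjusted to frame.** By default insertion lengths are
  stretched to the nearest in-frame total, emulating the in-frame
  repertoire the analyses are defined on and keeping parameter-recovery
  oracles deterministic.

What the simulator does *not* emulate: convergent recombination (public
clones are planted as literally identical junctions, matching the
observation of nucleotide-identical shared CDR3s, not generated by a
recombination model), PCR amplification bias beyond the per-clone expansion
factor, thymic selection, indels, and quality-score structure. Passing
tests therefore demonstrate that the *pipeline machinery* recovers planted
truth under realistic read structure — not that the biological generative
model is realistic.

# Numerical and reproducibility choices

* Smith–Waterman tie-breaks: smallest reference start, then smallest query
  start, then shortest alignment; `N` never matches anything, so all-N
  reads score 0 everywhere and yield `no_v`.
* Every stochastic step (simulation, bootstraps, down-sampling) takes an
  integer seed and is exactly reproducible; the simulator is
  byte-deterministic per seed, which the tests assert on written FASTQ.
* The pipeline manifest records md5 checksums of every output; identical
  inputs, configuration and seed give identical checksums.
* Problem sizes in the test and acceptance suites are chosen to exercise
  the study conditions at full scale where it matters (one 8-bird ×
  5-tissue × 5 000-read recovery run, 200 000 reads end to end) and small
  deterministic fixtures everywhere else; enumeration oracles run at n ≤ 8
  where exhaustive subsampling is exact.

# Known limitations

* The packaged reference's sequences (and hence its RSS set) are synthetic;
  regression of usage on packaged RSS scores demonstrates the analysis
  path, not a biological result.
* Mixed-model inference is intentionally out of scope; percentile bootstrap
  intervals under-cover by several points at n = 8 birds, as quantified in
  the acceptance suite.
* Coverage standardisation at 0.1 characterises the abundant clone mass;
  conclusions about total richness at that coverage are not supported.
* Publicity detection is presence/absence at any frequency and therefore
  depth-sensitive: deeper samples detect more low-frequency clones and can
  only raise penetrance.
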