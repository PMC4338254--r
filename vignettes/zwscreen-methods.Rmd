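---
title: "Methods: screening pooled gonad RNA-seq for W-linked markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening pooled gonad RNA-seq for W-linked markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zwscreen)
```

## The problem and the model

In a ZW/ZZ system, females carry one W chromosome that males lack entirely.
A transcript encoded on the W is therefore *absent from male genomes*, not
merely down-regulated in males. Given gonadal RNA-seq from pools of females
and pools of males, W-linked transcripts should show two signatures at
once: structural zeros in every male pool, and overwhelming statistical
support for a sex difference in expression. zwscreen operationalises both,
together with the assay-design steps that turn a candidate into a PCR
sexing marker.

### Count model

Counts for contig $i$ in pool $j$ are modelled as negative binomial,

$$ y_{ij} \sim \mathrm{NB}\big(\mu_{ij},\ \varphi_i\big), \qquad
   \mu_{ij} = \theta \cdot o_{ij}, \qquad
   \mathrm{Var}(y_{ij}) = \mu_{ij} + \varphi_i \mu_{ij}^2, $$

with offset $o_{ij} = \mathrm{library\ size}_j \times \mathrm{length}_i$ —
the "normalise over library size and gene length" convention, exposed
directly in `normalize_counts()`. The gene-wise dispersion $\varphi_i$ is
estimated by method of moments on offset-scaled counts, with the sample
variance pooled *within* sexes so a genuine sex effect does not inflate it,
and floored at zero:

$$ \hat\varphi = \max\!\Big(0, \frac{s^2 - \bar m}{\bar m^2}\Big). $$

This is deliberately the simplest defensible estimator: there is no
information sharing across contigs. Empirical-Bayes shrinkage of
dispersions (as the established differential-expression packages do) would
stabilise estimates at these small pool counts, but it couples every
contig's result to the whole matrix; for a screen whose decisive criteria
are structural (exclusivity, length), the per-contig estimator keeps each
row's verdict self-contained and auditable. This is a documented divergence
from empirical-Bayes screening tools.

### The differential-expression posterior

"Likelihood of differential expression equal to 1" is made precise as a
two-model comparison. Model M0 fits one shared rate $\theta$; model M1 fits
sex-specific rates $\theta_F, \theta_M$, each by maximum likelihood under
the NB model with $\hat\varphi$ held fixed (one-dimensional optimisation on
the log scale; the all-zero side has the exact boundary solution
$\hat\theta = 0$ with log-likelihood 0). Each model receives a
BIC-penalised score $S = \hat\ell - \tfrac{k}{2}\log n$ ($k$ free rates,
$n$ pools), and

$$ P(\mathrm{DE}\mid y) =
   \frac{p_1 e^{S_1}}{p_0 e^{S_0} + p_1 e^{S_1}}, $$

computed in log space, with prior $p_1 = 0.05$ by default. The screening
criterion `posterior_ok` requires $P(\mathrm{DE}) \ge 1 - 10^{-6}$.
Both the prior and the threshold are exposed in `screen_config()`.

Properties worth knowing:

* the posterior is invariant to a global rescaling of library sizes (an
  offset-model property, tested);
* for identical counts in all pools M1 gains no likelihood and pays half a
  $\log n$ penalty, so the posterior drops *below* the prior;
* under null simulations the fraction of contigs passing the
  $1 - 10^{-6}$ threshold is far below the prior — the criterion is
  calibrated conservatively by construction, since passing requires a
  penalised log-likelihood gap of about $16.7$ nats.

### The candidate rule

`select_candidates()` demands all of: **exclusivity** (zero reads in every
male pool — `max_male_reads_total = 0` — and presence in at least one
female pool), **length strictly over 500 bp** (`min_length_bp = 501`; a
500 bp contig fails), **posterior** at threshold, and absence from the
contaminant **exclusion list** (an input: database-lookup contaminant
identification is out of scope). Exclusivity is defined on mapped counts;
assembly-graph read provenance is not modelled. Ordering is deterministic:
descending posterior, ties by contig id.

## What the simulator emulates — and what it does not

`simulate_transcriptome()` + `simulate_count_matrix()` generate the study
design the screen assumes: 6 female + 6 male pools of 2 fish, NB counts
with log-normal gene-wise dispersions (meanlog $\log 0.1$, sdlog 0.5 —
typical bulk RNA-seq values), log-normal library sizes with CV 0.2 (per-pool
depth variability is a free choice; no published value constrains it), and
six transcript classes: autosomal, Z-linked (mildly male-biased, fold 2,
as a dosage effect), W-linked (structural zeros in male pools, enforced by
construction rather than drawn), female-/male-biased autosomal (fold 4),
and bacterial contaminants expressed in a random half of pools regardless
of sex — the class that can mimic female-exclusivity by sampling chance
and so exercises the exclusion-list path. Expression is parameterised as
expected reads per pool at a reference depth of $10^6$ (log-normal,
meanlog $\log 100$, sdlog 1), with a floor of 20 expected reads per female
pool for W-linked transcripts: the regime in which the screen is *meant*
to have full sensitivity. Transcript lengths are uniform on 501–3000 bp by
default so that recovery is a property of the screen, not a lottery
against the strict length cut-off.

Reproducibility: every operation takes one integer seed and derives
per-transcript child streams, so output is bit-identical across runs and
invariant to evaluation order.

Not emulated: read-level data (no FASTQ, no sequencing-error or mapping
model), assembly artefacts (chimeras, fragmented contigs, multi-mapping),
GC or length biases in expression, and correlated library composition.
Passing tests therefore demonstrate the *logic* of the screen under its
own statistical assumptions, not robustness to assembly pathology in real
transcriptomes.

## Primer thermodynamics and design constraints

`melting_temperature()` uses the unified nearest-neighbor parameter set
(stacking $\Delta H$/$\Delta S$ per dinucleotide with terminal initiation
terms), $T_m(K) = 1000\,\Delta H / (\Delta S + R \ln(C_T/4))$ for a
non-self-complementary oligo, and the monovalent-salt correction
$+16.6 \log_{10}[\mathrm{Na^+}]$. Defaults: 50 mM Na⁺, 500 nM oligo. The
design constraints default to the sexing-assay settings — $T_m$ 59/60/61 °C,
pair difference ≤ 1 °C, homopolymer runs ≤ 3, a 1-base G/C 3′ clamp
(clamp means: the terminal base(s) are G or C), product 480–520 bp with
optimum 500 — and `enumerate_candidate_pairs()` is exhaustive within the
18–27 bp length bounds, ranked by
$|T_{m,F} - 60| + |T_{m,R} - 60| + |\mathrm{product} - 500|/100$ with
leftmost-position tie-breaks. Product size is the inclusive 5′-to-5′ span.
Primer-design tools differ in their exact $T_m$ formulas (salt model,
divalent corrections); the compatibility surface here is the *constraint
logic*, not numeric agreement of $T_m$ values with any specific tool.

Mismatched duplexes (for allele-specific design) use a destabilisation
floor rather than full mismatch-pair tables: every stack touching a
mismatched position loses its stacking enthalpy while the duplex keeps the
full entropy term. Dropping both terms — the more obvious rule — is not
monotone: removing a weak AT-rich stack can *raise* the computed $T_m$.
Keeping $\Delta S$ guarantees that each additional mismatch strictly
lowers $T_m$, which is the property the ranking relies on. The model is
for ranking on- vs off-target designs; it is not quantitative mismatch
thermodynamics, and it is isolated in one function should a full
mismatch table ever be wanted.

## Species diagnostics

`global_align()` is an exact Needleman–Wunsch global aligner with affine
gaps (a gap of length $k$ costs $\mathrm{open} + k\cdot\mathrm{extend}$).
Default scoring: match $+2$, mismatch $-1$, open $12$, extend $2$ — plain
DNA scoring echoing the gap weights conventional for these alignments
(protein matrices applied to DNA, as some alignment GUIs do, are not
reproducible and are not imitated). Tie-breaking in the traceback is
deterministic: diagonal, then gap-in-B, then gap-in-A. The row-wise DP is
vectorised (the in-row affine recurrence is folded into a cumulative
maximum), so kilobase pairs align in about a second.

`design_diagnostic_primers()` enumerates windows whose 3′-terminal base
sits on an interspecies difference (so polymerase extension fails on the
off-target species) and which cover at least `min_differences = 2`
differences; each window gets an on-target $T_m$ (perfect duplex) and
off-target $T_m$ (same oligo against the other species, mismatch floor as
above), and forward/reverse pairs are ranked by the pair's minimum
$\Delta T_m$ — "maximum melting-temperature difference between the
species". Before pairing, the 100 strongest windows per orientation are
kept; with ~50 differences per kilobase this bounds the pair table without
touching the top of the ranking, since ranking is monotone in the
per-primer $\Delta T_m$ values.

`in_silico_pcr()` applies the allele-specific binding rule — no
3′-terminal mismatch, at most 2 internal mismatches — on both strands and
in both role orientations, reporting inclusive 5′-to-5′ products. Binding
is sequence-rule-based only; annealing-temperature-dependent amplification
efficiency is out of scope.

## Clock dating

`p_distance()` is the uncorrected proportion of differing sites, rounded
half-up to 4 decimals *before* division by the clock rates — the printed
age brackets are reproducible only from the rounded percentage, not from
the raw fraction (e.g. $6/396/0.044 = 0.3444$ rounds to $0.34$, whereas
$0.0152/0.044 = 0.3454$ rounds to the printed $0.35$). Base R rounds half
to even, so a dedicated half-up rule is used for all reported values; the
convention is inferred from the printed pairs and documented as such.
`divergence_time_range()` divides by the fastest and slowest calibrated
rates (bundled presets: cytochrome b 0.0076–0.0036, control region
0.044–0.004 changes/site/Myr) and rounds half-up to 2 decimals. No
multiple-hit correction is applied — the method is raw p-distance by
design; corrected distances would be a config-gated extension.

## Validation reporting

`call_genotype()` maps band presence to ZW and absence to ZZ,
deterministically. `concordance_report()` tabulates agreement with
phenotypic sex per population and overall. Discordant individuals are
*annotated*, never re-called: without karyotyping, a phenotypic female
lacking the band could be a naturally feminised ZZ neo-female or a W/Z
recombinant, so the report carries both hypotheses as a label. The
packaged `synthetic_cohort_replica.tsv` (115 individuals, one discordant
female) is a synthetic stand-in built with the cohort simulator; the
discordant record's population is deliberately left unassigned.

## Numerical choices and degenerate inputs

* NB likelihood maximisation: `optimize()` over $\log\theta$ within ±8
  log-units of the Poisson estimate $\sum y / \sum o$, tolerance $10^{-10}$;
  $\varphi < 10^{-12}$ switches to the exact Poisson branch. Optimiser
  failure is caught and flagged (`converged = FALSE`) with the Poisson
  estimate as fallback; all-zero rows use the exact boundary solution.
* All-zero dispersion rows return $\hat\varphi = 0$ with an `all_zero`
  flag; under-dispersion floors at 0.
* `enumerate_candidate_pairs()` on an infeasible template returns a
  zero-row table with a structured failure summary (counts per failed
  criterion) instead of an error.
* Candidate ordering, pair ranking and alignment traceback all have
  deterministic tie-breaks, so every output is stable across runs.
* Child seeds are derived as a fixed integer mix of the base seed and the
  row index, kept below $2^{31}$.

## Problem sizes used in the checks

The packaged test-and-acceptance workload is sized for a laptop-class
single core: the end-to-end demonstration screens 1,000 transcripts
(20 W-linked) across 6+6 pools; null calibration runs 100 seeded
replicates of 100 all-autosomal contigs; diagnostic-design recovery runs
20 seeded 1 kb ortholog pairs at 5% divergence; alignment is checked
against exhaustive path enumeration on short pairs (2–6 bp per side, where
enumeration is tractable) and against an independent aligner
(`Biostrings::pairwiseAlignment`) up to 60 bp. Dataset-scale quantities
from real screens (tens of thousands of contigs, assembly N50s, candidate
counts) depend on external sequencing data and are out of scope; the
corresponding code paths are exercised on simulated inputs instead.

## Known limitations

* The DE posterior is analogous to, but not numerically interchangeable
  with, empirical-Bayes screening tools; equivalence cannot be asserted
  because such tools' settings (normalisation, prior estimation) interact
  with whole-matrix context.
* Exclusivity on mapped counts cannot see multi-mapping or assembly
  provenance; a Z-linked paralogue absorbing male reads would look
  female-exclusive here and must be caught downstream (as the wet-lab PCR
  step does in practice).
* The mismatch $T_m$ model ranks designs; it does not predict absolute
  off-target melting temperatures.
* `in_silico_pcr()` predicts binding by sequence rules only: no
  secondary-structure, primer-dimer or efficiency modelling.
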