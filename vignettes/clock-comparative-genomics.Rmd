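---
title: "Methods: comparative genomics and rhythm analysis of KaiABC-type clocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics and rhythm analysis of KaiABC-type clocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

The cyanobacterial circadian clock of *Synechococcus elongatus* PCC 7942 is
a posttranslational oscillator built from KaiA, KaiB and KaiC, embedded in
a network of input factors (Pex, LdpA, PrkE, NhtA, IrcA, CdpA) and output
factors (SasA, RpaA, RpaB, LabA, LalA, Crm, CpmA, plus CikA acting on both
sides). Homologs of these factors — including the diverged KaiB1–3/KaiC1–3
paralog subgroups named after the three *Synechocystis* sp. PCC 6803
copies — occur across Bacteria and Archaea in widely varying combinations.

`clockmine` implements the computational machinery needed to survey such
clock systems and their transcriptional output: reciprocal best-hit (RBH)
homology screening, per-strain factor inventories, co-occurrence
statistics over deduplicated clock systems, harmonic-regression detection
of diurnal transcripts with phase/amplitude estimation and circular
correlation of phase programs, and position-frequency-matrix profiling of
KaiC sequence motifs. A seeded synthetic-data module generates every
substrate the pipeline consumes together with ground-truth tables, so the
whole chain is validated end to end on data with known answers.

# Homology screening

## Alignment engine

Candidate homologs are scored with exact Smith–Waterman local alignment
under BLOSUM62 with affine gaps (open 11, extend 1; a gap of length $k$
costs $11 + k$). The alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; the package adds the masking rule
(nonstandard residues B, Z, U, O, J are mapped to X, and X scores 0
against everything, including itself), BLAST-style statistics, and the
search logic around it. Exact alignment — rather than a word-seeded
heuristic — makes desk-scale results bit-reproducible; for genuinely large
databases, `read_blast_tab()` imports standard 12-column tabular output so
externally computed BLASTP hits can be substituted without touching the
rest of the pipeline.

Because exact alignment has no seeding heuristics, its raw scores are
converted to expectation values with the Karlin–Altschul formula
$E = K m n e^{-\lambda S}$ using the conventional gapped-BLOSUM62
constants $\lambda = 0.267$, $K = 0.041$ (both configurable). These
e-values will not numerically match BLASTP's (which applies
composition-based adjustments and effective-search-space corrections), but
all screening decisions are threshold-based, and the thresholds are
preserved: forward searches retain at most 10 000 hits at $E \le 10^{-5}$;
reverse searches use a permissive $E \le 10$.

## Reciprocal filtering and subtypes

A subject is accepted only if its best reverse hit against the query
genome is the original query — the classic RBH criterion, which minimises
false positives by construction. "Best" is defined totally and
deterministically: ascending e-value, then descending bit score, then
lexicographic subject id, so results are invariant under database
permutation. A subject that is an RBH partner of several query subtypes
(e.g. both the KaiC1 and the KaiC3 query) is assigned exactly one subtype:
the query with the highest forward bit score, ties broken by lower e-value
and then lexicographic query id.

# Inventories and summaries

Accepted hits are aggregated into one *clock system* per strain: the set
of detected factors with copy numbers. Strains without at least one
KaiC-family homolog are dropped, since KaiC is the core of the oscillator
and its absence makes the remaining factors uninterpretable as a timing
system. The 7942 KaiB/KaiC labels are merged onto the KaiB1/KaiC1
subgroups they are most similar to, leaving 21 factor labels; the merge
map is an explicit configuration value (`default_factor_merge()`) because
the exact identity of the merged factor set is a modelling choice.

Genus-level summaries average the percent similarity (BLAST-style
*positives* over alignment length — similarity, not identity, which is
also why the generator mutates residues toward positive-scoring exchange
partners) of accepted hits per factor across a genus's retained genomes;
a genus with no accepted hit for a factor has no entry rather than a zero.
Copy numbers are reported exactly for 0–5 and condensed to ">5" above
that. Protein-length analyses emit a joint table per factor pair
(organisms carrying both factors; all copy combinations) and marginal
empirical CDFs per factor.

# Co-occurrence testing

Genome databases oversample some genera, so co-occurrence is computed
over *unique* factor combinations: presence rows (boolean on copy number
$\ge 1$; copies are never weighted) are deduplicated before testing. For
each factor pair the 2×2 contingency table (both present / first only /
second only / neither) is tested with the right-sided Fisher's exact
test — the upper hypergeometric tail $P(X \ge a)$ with margins fixed —
computed with log-factorials and a largest-term-first summation, exact to
near machine precision (validated against full enumeration for every
table up to $n = 30$). The null hypothesis is pairwise independence
across clock systems.

P-values are corrected with the Benjamini–Hochberg step-up procedure
(`stats::p.adjust`); a pair is significant when the adjusted p is at or
below the accepted false discovery rate of $10^{-2}$. The threshold is
applied to *adjusted* values. Factors constant across all unique systems
(always present — e.g. the KaiC-family column guaranteed by the retention
filter — or always absent) are excluded from testing: their tables admit
a single configuration and the test is degenerate at $p = 1$.

Factors are ordered by agglomerative hierarchical clustering with average
linkage on the adjusted p-values used directly as distances (diagonal 0);
columns are sorted lexicographically beforehand so ties break
deterministically. The significance network has an edge wherever
$p_\mathrm{adj} \le 0.01$, edge weight $p_\mathrm{adj}$, and node degree
as a node attribute; it is exported as an edge-list TSV and GraphML.

# Rhythm analysis

## Model

Expression matrices are l2m transformed — $\log_2$ of each value relative
to its gene's arithmetic mean — which centres profiles and makes
amplitudes comparable; zeros are handled by adding the smallest positive
matrix value first (logged), and all-zero rows are dropped. Biological
replicates sampled on their own time grids can be concatenated into one
series per gene, each observation keeping its own timepoint.

Each gene is fit with the sinusoidal foreground model
$$y = \beta_0 + \beta_1 t + c\cos(\omega t) + d\sin(\omega t), \qquad
\omega = 2\pi/\mathrm{period},$$
against the linear background $y = \beta_0 + \beta_1 t$, by least
squares. The period defaults to 24 h and is configurable; a warning is
raised when the sampling span is shorter than one period (designs driven
by ultradian light cycles should not be analysed this way). The
oscillation p-value is the F-test of the two harmonic coefficients
(2 numerator degrees of freedom); the amplitude is $A = \sqrt{c^2+d^2}$
(arbitrary units on the l2m scale) and the peak phase
$\varphi = \frac{\mathrm{period}}{2\pi}\,\mathrm{atan2}(d, c) \bmod
\mathrm{period}$, in circadian-time hours. Time values are taken as given
in the input header; no lights-on re-zeroing is attempted. Genes are
called oscillating when the BH-adjusted $q \le 0.05$, with the adjustment
shared with the co-occurrence module.

## Smoothing and where the p-value comes from

Profiles can be smoothed with a Savitzky–Golay filter
(`signal::sgolayfilt`; window 5, polynomial order 2 by default, valid
only for uniform sampling) to remove pseudo peaks. The package
deliberately splits the two uses of the fit:

* *phase and amplitude* are reported from the fit to the smoothed
  profile, where pseudo peaks would otherwise distort the descriptors;
* the *detection p-value* is always computed from the raw series.

The reason is statistical: smoothing shrinks the residual noise by the
filter's coefficient energy and correlates adjacent residuals, so an
F-test on the smoothed series no longer follows its null distribution —
on simulated pure-trend genes its type-I error at $p \le 0.05$ is
roughly six-fold inflated, while on the raw series the F-test is exact
under Gaussian noise (the acceptance checks verify calibration in the
[0.03, 0.07] band on 1000 seeded trend-only genes).

A related point governs expectations for phase accuracy. The
least-squares harmonic fit is the maximum-likelihood phase estimator, and
the Cramér–Rao bound gives a phase standard deviation of
$\sigma\sqrt{2/n}/A$ radians — at $\sigma = 0.5$, $A = 1$, $n = 12$
samples this is $\approx 0.78$ h, so no estimator can place much more
than ~80% of genes within ±1 h of their true peak under those conditions.
Smoothing cannot improve this (it adds no information), which the
validation suite measures directly; the honest recovery rate at that
noise level is reported by the acceptance script as
`phase_within_1h_rate`.

## Comparing phase programs

Within- and between-dataset comparisons are restricted to genes (or
homolog-map groups) oscillating in *both* datasets, because phase and
amplitude are only meaningful descriptors for significant oscillators.
Peak phases, converted to angles $\alpha = 2\pi\varphi/\mathrm{period}$,
are compared with the Jammalamadaka–SenGupta circular correlation
$$\rho_{ccc} = \frac{\sum_i \sin(\alpha_i-\bar\alpha)\sin(\beta_i-\bar\beta)}
{\sqrt{\sum_i \sin^2(\alpha_i-\bar\alpha)\,\sum_i \sin^2(\beta_i-\bar\beta)}}$$
with circular means $\bar\alpha,\bar\beta$, and its asymptotic normal
statistic for the p-value. $\rho_{ccc}$ is invariant under common
rotation of either phase vector and flips sign under reflection; zero
circular variance in either sample leaves it undefined (flagged).
Amplitudes are compared with the Pearson correlation. Comparisons with
fewer than three shared oscillators are skipped with a warning. The
*core diurnal set* is the set of genes (or homolog groups) oscillating
significantly in every analysed dataset.

# Motif conservation

Multiple sequence alignments are computed externally (e.g. Clustal Omega)
and imported in aligned-FASTA or Clustal format. Alignment columns are
projected onto the coordinates of a reference sequence (the KaiC-7942
homolog): column $i$ maps to the count of non-gap reference characters up
to $i$ when the reference is non-gap there, and to a gap otherwise —
a deterministic replacement for manual alignment adjustment. Within
motif windows given in reference residue numbers, per-position relative
frequencies are tabulated over the 20 amino acids plus the gap character
as a 21st symbol (frequencies sum to 1), together with the dominant
residue, a consensus string, and the fraction of records matching a
wildcard pattern (X matches any amino acid; gap columns never match).

Only anchors with established KaiC-7942 coordinates ship as defaults:
the CII phosphosites S431/T432, the dephosphorylation-critical T426, and
the CII ATP-binding Walker A motif (P-loop), located by its GXXXXGKT
consensus in the reference. Other functional elements (R-finger,
catalytic glutamates, the 422 and 438–444 loops, the A-loop span,
KaiA-binding residues) have no complete published coordinate set and are
left to explicit user configuration via `motif_window()` rather than
hard-coded guesses.

# Synthetic data

The generators produce exactly the statistical structure each stage
assumes, plus truth tables for recovery scoring:

* `simulate_proteomes()` — per-taxon FASTA collections with family
  members derived from their query by seeded point substitutions (drawn
  among BLOSUM62-positive exchange partners, mimicking accepted
  mutations) down to an exact target identity, optional paralog copies
  and per-taxon prevalence, and decoys drawn from the queries' pooled
  residue composition. Emulated: the patchy distribution of clock
  factors over genomes. Not emulated: phylogenetic correlation between
  taxa, domain architecture, indels.
* `simulate_clock_systems()` — boolean presence matrices with
  independent Bernoulli columns except planted pairs, drawn jointly from
  the 2×2 distribution solved from the marginals and a specified odds
  ratio (cells sampled by inverse CDF). This matches the co-occurrence
  null exactly, so planted enrichments are the only violations.
* `simulate_expression()` — a stated fraction of genes follows
  $\beta_0 + \beta_1 t + A\cos(2\pi(t-\varphi)/\mathrm{period})$ plus
  Gaussian noise; the rest only trend plus noise. Defaults mirror a
  typical diurnal microarray design: 12 samples every 4 h spanning 48 h,
  unit amplitude, uniform phases, noise SD 0.5 on the log2 scale. Not
  emulated: probe-level microarray noise physics, heteroskedasticity,
  missing values.

Identical configuration and seed give byte-identical outputs (verified
by checksum in the tests); seeds are recorded in output file headers.
Because the generators are idealised, green tests demonstrate
correctness of the machinery under the stated models — calibration,
recovery, invariances — not performance on real microarray or proteome
data, where normalisation artefacts, phylogenetic structure and
non-sinusoidal waveforms add complications the models omit.

# Pipeline, problem sizes, and numerical choices

`run_pipeline()` executes simulate → RBH → inventory → co-occurrence →
rhythm detection in dependency order on a validated configuration whose
defaults are the canonical thresholds (forward $E \le 10^{-5}$, 10 000
hits, reverse $E \le 10$, FDR 0.01, $q \le 0.05$, period 24 h, SG window
5 / order 2). Every output table carries the configuration hash in a
comment header and a manifest records per-file checksums; reruns with
the same configuration are byte-identical. The numbered scripts under
`analysis/` run the same stages as a narrative workflow on a larger
simulated cohort.

Validation problem sizes were chosen to give tight Monte-Carlo error
while keeping the full suite fast on a single CPU: 10 taxa × (5 families
+ 20 decoys) for RBH recovery; 1000 seeded 69-system presence matrices
for null calibration; exhaustive 2×2 enumeration to $n = 30$; 1000 genes
for type-I and power measurements; 200 genes for phase recovery; ≥100
seeded pairs for the alignment oracle.

Numerical details worth knowing: hypergeometric tails are summed on the
log scale from the largest term; a foreground fit with (near-)zero
residual yields $p = 0$ (exact sinusoid) or $p = 1$ (background already
perfect) rather than a 0/0 F statistic; rank-deficient harmonic designs
are flagged, not fitted; clustering input must be symmetric with a zero
diagonal; empty databases, empty forward-hit sets and sub-3-gene
comparisons degrade to empty results with warnings rather than errors.

# Known limitations

* The built-in e-values are calibrated differently from BLASTP's; only
  threshold semantics, not numeric e-values, transfer.
* Co-occurrence treats clock systems as exchangeable; there is no
  phylogenetic correction, so shared ancestry can masquerade as
  functional association.
* Harmonic regression assumes a sinusoidal waveform and a linear
  background; sharply peaked or asymmetric diurnal profiles lose power.
* Phase accuracy is noise-limited (Cramér–Rao, above); ±1 h phase calls
  at low SNR should not be over-interpreted.
* The motif module profiles conservation in reference coordinates; it
  does not align sequences itself and cannot describe insertions
  relative to the reference.
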