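---
title: "Methods: pharmacogenomic association scanning with EHR-derived phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacogenomic association scanning with EHR-derived phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmscan)
```

## What the package does

`pharmscan` implements a population-scale pharmacogenomics analysis as a
reusable pipeline. Starting from diploid genotypes (VCF), ATC-coded
prescription records, ICD10-coded diagnosis records, self-reported adverse
drug effects (ADEs), and a covariate table, it:

1. classifies putatively functional variants in candidate pharmacogenes
   (loss-of-function, missense, promoter TFBS hits);
2. derives per-person ADE phenotypes from a configurable ICD10 code list
   with per-code confirmation requirements and a 12-group diagnostic
   mapping;
3. builds drug-exposure cohorts at ATC level 4;
4. tests variant–drug–ADE associations with covariate-adjusted logistic
   models, including conditional adjustment for known variants;
5. refines and replicates hits by diagnostic group with a Bonferroni gate
   and a sum-of-z meta-analysis; and
6. validates copy-number calls in segmental-duplication genes with a k-mer
   read-count proxy.

Because real cohorts of this kind are access-controlled, the package ships a
first-class synthetic cohort generator with planted effects, so every stage
is testable end to end.

## The statistical model

For one variant and one drug-exposure cohort, case status is any ADE among
persons prescribed a drug in the cohort's ATC level-4 group. The association
model is a logistic regression

$$\operatorname{logit} P(\text{ADE}_i = 1) = \beta_0 + \beta_g g_i +
\boldsymbol{\gamma}^\top \mathbf{x}_i$$

where $g_i$ is the genotype — additive dosage $0/1/2$ for single variants,
carrier coding $0/1$ for multi-variant (star-type) alleles, matching the two
analysis styles the carrier/non-carrier count tables imply — and
$\mathbf{x}_i$ holds BMI, sex, age, four genetic principal components, and
genotyping platform (WGS vs chip). Fits are maximum likelihood by iteratively
reweighted least squares (`stats::glm`, convergence tolerance $10^{-10}$,
at most 100 iterations); the genotype Wald test gives the reported p.
Perfect separation is flagged (status `separated`) when $|\hat\beta_g| > 15$
rather than reported as a spuriously huge effect. A covariate-free carrier
fit is algebraically identical to the crude 2×2 odds ratio
$\widehat{OR} = ad/bc$ with Woolf's log-method interval
$\exp(\ln\widehat{OR} \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$; the test suite
verifies this equivalence to $10^{-6}$, which pins the model-fitting and
closed-form routes to each other.

Conditional analysis refits the model with the dosages of known variants as
extra covariates and reports the index variant's Wald p. When the index and
conditioning variants are perfectly correlated the fit is flagged
`collinear` instead.

### Scan filters

The candidate scan tests each (variant, drug) pair implied by a
PharmGKB-style gene–drug map, with linkage at *gene* level: a variant is
tested against every drug associated with any variant of its gene. Pairs are
skipped — with the reason tallied — when the variant does not segregate, the
drug has no prescriptions, no prescribed person has an ADE, no carrier is
prescribed, or fewer than 500 persons are prescribed (statistical power
floor). Significance in this scan is nominal p < 0.05, deliberately without
multiplicity correction; the genome-wide scan instead restricts to MAF ≥ 1%
and filters at the suggestive threshold $10^{-6}$. The genome-wide stage
additionally requires at least 1000 distinct prescribed persons per ATC-4
cohort before a phenotype is considered.

### Replication and meta-analysis

Hits passing the suggestive filter are refined by diagnostic group: the
association is refit once per group with group ADEs as cases and ADE-free
persons as controls (persons with ADEs only in other groups are excluded
entirely); the group minimising p is carried forward, ties broken towards
the larger case count and then lexicographically — a deterministic rule so
reruns cannot flip the refinement. Replication fits use the reduced
covariate set age, BMI, and sex. Replication significance is a Bonferroni
gate p < α/m (0.01 at α = 0.05 and m = 5 tests). Discovery and replication
are combined with the unweighted directional Stouffer (sum-of-z) method:
two-sided p-values are converted to one-sided via $p/2$ signed by the effect
direction, $z_i = \Phi^{-1}(1 - p_i)\,s_i$, and
$z = \sum z_i / \sqrt{k}$. Sidedness of the combination is not uniquely
dictated by convention, so both one- and two-sided meta p-values are
reported.

## Functional classification rules

**Loss of function.** Stop-gain: an SNV converting a CDS codon to
TAA/TAG/TGA. Frameshift: an indel overlapping the CDS whose length change is
not a multiple of 3. Essential splice: the two intronic bases flanking any
exon (donor GT / acceptor AG positions); extended splice regions are out of
scope. A candidate LoF call is withdrawn (category `none` plus a reason)
when the alternate allele equals the ancestral allele, or when the variant
lies in the 3'-most 5% of the transcript. The 5% rule is computed on
*spliced transcript* length (the LOFTEE-style convention); CDS-based
measurement was the main alternative, but spliced length also covers UTR
variants near transcript ends and degrades gracefully for transcripts with
long 3' UTRs. Intronic (splice) variants use the nearest exon boundary's
spliced coordinate. Ancestral alleles are accepted as an optional argument
(e.g. from a VCF `AA` INFO key); when absent, no ancestral exclusion is
applied.

**Missense.** A coding SNV that changes the encoded amino acid and is not a
LoF call. Stop-gain takes precedence. Protein-impact scores (SIFT/PolyPhen)
are out of scope.

**Promoter scan.** The 5000 bp immediately upstream of the transcription
start site on the transcript strand (1-based closed, clipped at the contig
start) is scanned with TRANSFAC-style position weight matrices using
Match-style scoring: with position information content
$I(i) = \sum_b f(i,b)\ln 4f(i,b)$, a window scores
$(\sum_i I(i) f(i, b_i) - \text{Min}) / (\text{Max} - \text{Min}) \in [0,1]$,
computed once over the whole matrix (matrix similarity) and once over the
core — defined here as the 5 consecutive positions of maximal summed
information, leftmost on ties, since the matrix library's own core
annotations are proprietary. Default cut-offs are matrix similarity 0.95 and
core similarity 0.90; the published minFP/minFN profile files are commercial
and not reproducible, so both cuts are plain configurable parameters. Hits
can optionally be intersected with a liver ChIP-seq interval mask, keeping
only hits overlapping a masked interval. The scanner is verified against an
independent brute-force scorer on random matrices and sequences.

## k-mer copy-number proxy

For a gene inside a segmental duplication, read-mapping-based genotypes are
unreliable, so copy number is estimated directly from reads: diagnostic
k-mers (default k = 25, canonical form = lexicographic minimum of k-mer and
reverse complement) are those occurring exactly once genome-wide with that
occurrence inside the target region; a disjoint control region provides
copy-number-2 normalisation. The estimate is
$\widehat{cn} = 2\,\mathrm{median}(\text{diagnostic counts}) /
\mathrm{median}(\text{control counts})$, with diagnostic counts below 10% of
the control median treated as absent (sequencing-error tolerance). The
k-mer length, canonical counting, and median-ratio normalisation follow
common k-mer-genotyping practice and are all parameters. Linearity is
checked by simulation: copies 0–3 at 30× coverage on a 30 kb toy reference
with 3 kb target and control regions recover slope 1 ± 0.1. These sizes keep
the simulation well-conditioned (several hundred reads per region) while the
whole check runs in seconds.

## The synthetic cohort generator

The generator is the package's substitute for the access-controlled study
data; its defaults are the study conditions the downstream tests assume.

- **Genotypes** are Hardy–Weinberg draws at MAFs sampled from a five-bin
  spectrum (<0.05%, 0.05–0.5%, 0.5–1%, 1–5%, >5%) with default weights
  0.552/0.217/0.034/0.072/0.125 — the observed spectrum of candidate
  pharmacogene variants. Individual MAFs can be forced per variant for
  power-controlled fixtures.
- **Covariates**: sex ~ Bernoulli(0.5), age ~ U(18, 90), BMI ~ N(26, 4),
  PC1–PC4 ~ N(0, 1), platform WGS with probability 0.15. None of these
  distributions is published; these are plausibility choices.
- **Prescriptions**: per-person, per-drug Bernoulli (default 0.2) across
  ATC level-4 groups, one record per (person, drug) with a uniform date in
  January 2004 – August 2015. No temporal causality is simulated.
- **ADEs** arise among prescribed persons from the logistic model
  `logit P = logit(base_ade_rate) + Σ β_planted · g + covariate terms`, with
  covariate terms centred at their generating means so `base_ade_rate` is
  the rate for an average person. ICD10 codes are drawn uniformly from the
  configured code list (confirmation set generatively where required);
  group membership follows the 12-group mapping.
- **Contamination**: a small drug-independent background ADE rate (default
  0.001) supports the drug-independent association check, and a small
  self-report rate (default 0.002) exercises the self-report channel. Both
  are an order of magnitude below the default drug-conditional base rate
  0.05, so planted logistic truth dominates; both can be raised or zeroed.
- **LD pairs** for conditional-analysis tests are drawn from the two-locus
  haplotype distribution with the requested allele frequencies and
  positive-D correlation; infeasible r² targets raise an error naming the
  attainable bound.

Identical seeds give byte-identical output files. The generator does *not*
emulate imputation error, pedigree or population structure (the PCs are pure
noise), drug dose or adherence, temporal ordering of prescription and
diagnosis, or coding noise in ICD10/ATC assignment. Passing tests therefore
demonstrate correctness of the estimators under a clean logistic
data-generating process — not robustness to the messiness of real EHR data.

## The bundled ADE code list

The 79-code ICD10 list and its 12-group mapping are shipped as an editable
example config (`inst/extdata/ade_codes_synthetic.tsv`). It is a *synthetic*
stand-in assembled from public drug-induced ICD10 codes with plausible
group assignments and confirmation requirements; the study's own list is a
supplementary data file that is not redistributed here. Which codes require
physician confirmation is marked per code in the config, since no published
enumeration exists. Matching is prefix-based at the precision given in the
list (so `M60` matches `M60.9`), reflecting variable EHR coding depth.

## Numerical and design choices

- MAF bins are half-open and lower-inclusive; MAF is always computed on the
  minor allele of the observed sample, so it never exceeds 0.5.
- 2×2 tables with a zero cell return a `zero_cell` status; the
  Haldane–Anscombe +0.5 correction is opt-in, never silent.
- Thresholds (minimum 500 prescribed per candidate pair, 1000 per GWAS
  cohort, MAF ≥ 1%, suggestive 10⁻⁶, α = 0.05, m = 5) are all exposed as
  arguments with those defaults.
- Prescription deduplication: persons are counted once per ATC-4 group
  regardless of refills; whether the original analysis deduplicated before
  its cohort-size filter is unstated, and distinct-person counting is the
  conservative choice.
- Persons with missing genotype at a tested variant are dropped from that
  test only; a multi-variant allele carrier is `NA` only when every defining
  site is missing.
- The pipeline orchestrator (`run_pipeline()`) writes a provenance manifest
  (package version, seed, thresholds, input-file MD5 hashes) and is
  rerun-identical for a fixed config.
- Monte-Carlo problem sizes in the tests (100 seeds at n = 5000 for
  parameter recovery; 2000 null variant–drug tests at n = 4000; 50
  PWM fixtures; copies 0–3 at 30×) were chosen to make the checked
  proportions statistically stable while keeping the whole suite fast to
  run routinely.

## Known limitations

- The rule-based functional annotator covers stop-gain, frameshift, and
  essential splice sites only; it is not a full effect predictor (no
  stop-loss, start-loss, or extended splice-region calls).
- Star-allele haplotyping and HLA imputation are out of scope; multi-variant
  alleles enter via the carrier rule over a user-supplied variant list.
- The k-mer CN estimator does not detect breakpoints or resolve hybrid
  alleles; it is a region-level dosage proxy.
- Logistic fits are plain ML; the optional interpretation of separated fits
  (e.g. Firth correction) is left to the user, who sees an explicit
  `separated` status rather than an estimate.
- No mixed-model association, kinship pruning, or imputation machinery is
  included; these belong to upstream QC.
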