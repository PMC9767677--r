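---
title: "Calling somatic mutations from droplet scRNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling somatic mutations from droplet scRNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Droplet single-cell RNA-seq reads cover the expressed fraction of each
cell's genome, so in principle they carry that cell's somatic mutations.
In practice a naive per-cell pileup produces on the order of millions of
raw variant sites per patient, nearly all of them artifacts: sequencing
error, mapping error, allele-specific expression, RNA editing, and
library-preparation chemistry all masquerade as mutations. What rescues
the problem is biology: a genuine somatic mutation is *clonal* — it was
acquired by one cell after embryonic differentiation and is inherited by
that cell's descendants, which in a tissue all belong to one major cell
lineage (and, for a post-thymic T-cell mutation, to one TCR clonotype).
`scmutcall` encodes that constraint as a cascade of filters over a
sparse per-cell allele-count matrix and calls only variants whose
cell-level distribution looks clonal.

## The filter cascade

Input is a sparse matrix of (reference, variant) read counts for every
cell at every candidate substitution locus, plus cell metadata (patient,
major lineage, subtype, optional TCR clonotype). Candidate enumeration
is deliberately maximally sensitive — any cell with a single variant
read nominates a locus within its patient — because all specificity
lives downstream:

1. **Singlet removal.** A variant seen in exactly one cell is
   uninterpretable and dropped.
2. **Cross-lineage removal.** Somatic mutations postdate embryonic
   differentiation, so carriers spanning two major lineages (of T/NK,
   B/plasma, myeloid, endothelial, epithelial, fibroblast, tumor) mark
   a site-specific artifact or germline variation. Sharing between
   *subtypes* of one lineage is expected and allowed.
3. **Per-cell binomial allelic filter.** Without copy-number change, an
   expressed heterozygous mutation should give roughly balanced allele
   counts; a cell with `ref = 9, var = 1` has one-sided
   $P(X \le 1 \mid n = 10, p = 1/2) = 11/1024 < 0.05$ and its call is
   ignored. The test is one-sided toward reference excess on purpose:
   variant-heavy cells are biologically expected (allele-specific
   expression, transcriptional bursting) and must not be discarded.
   Ignored cells keep their reads and still count as reference-bearing
   cells; a candidate left with fewer than two credible carriers is
   dropped.
4. **Lineage enrichment.** For each candidate, cells of its patient are
   cross-tabulated as (top lineage vs all others) × (variant cells vs
   reference cells), where the top lineage is the one with most variant
   cells (ties broken lexicographically and flagged). The one-sided
   Fisher exact p is the hypergeometric tail, and the enrichment factor
   is the prevalence ratio
   $\frac{v_t/(v_t+r_t)}{v_o/(v_o+r_o)}$, defined as $+\infty$ when the
   mutation is absent outside the top group — maximal enrichment, which
   passes the fold threshold.
5. **Fixed final thresholds.** $p < 10^{-4}$, factor $\ge 5$, at least
   5 variant cells in the top lineage, at least 20 reference cells in
   the reference population, absence from the known-SNP mask, and no
   sharing of the site between patients. No multiple-testing correction
   is applied anywhere: the cascade is an operating point defined by raw
   thresholds, and correcting would move it.
6. **Transcribed-strand context bias filter.** DNA mutational processes
   produce strand-symmetric counts once contexts are read off the
   transcribed strand; RNA-level artifacts (library chemistry, RNA
   editing) do not. Calls are pooled into classes keyed by
   (trinucleotide context, alt) in reference orientation; for classes
   with at least 10 strand-assignable members, the split of host-gene
   strands is tested against balance (two-sided exact binomial,
   $p < 0.005$) and a failing class is removed wholesale, including its
   strand-unassignable members — erring toward specificity. Smaller
   classes are untested: with fewer than 10 members the test has
   essentially no power at this alpha, and removing untestable calls
   would trade sensitivity for nothing.
7. **Proximity clustering.** Within a patient, calls on one chromosome
   within 4 bp of each other (transitively chained) betray alignment
   artifacts and are removed as a cluster.

"Reference population" for the coverage rule means cells outside the
top group that cover the reference allele without a credible variant
call — the same cells that fill the Fisher table's bottom-right cell,
plus carriers whose call the allelic filter ignored.

## Benchmarking

Against an orthogonal DNA table (tumor pileup variant/reference reads,
matched-normal variant reads, orthogonal caller status), each scRNA
call is classified TP (called by both), TP_pileup_only (≥2 tumor pileup
variant reads, none in the normal, no orthogonal call — typically low
DNA coverage or mitochondrial sites), FP (<5 variant and >20 reference
DNA reads: the DNA had power and saw nothing), or indeterminate
(insufficient DNA depth; excluded from both statistics). DNA-only calls
become FN when the scRNA data had adequate coverage to call them
(interpreted as ≥5 cells of the best-covered lineage with any read and
≥20 reference cells elsewhere — the source wording is ambiguous here
and this reading is flagged in the documentation). Then

$$\mathrm{precision} = \frac{TP + TP_{po}}{TP + TP_{po} + FP}, \qquad
  \mathrm{sensitivity} = \frac{TP}{TP + FN}.$$

The precision numerator includes pileup-corroborated calls because the
category semantics make them true detections the orthogonal caller
missed, not errors of the scRNA pipeline.

The clonotype benchmark reruns the identical cascade inside clonotyped
CD8⁺ T cells, grouping by clonotype (≥5 variant cells in the most
prevalent clonotype, ≥20 reference cells in the others), and reports
the fraction of calls whose variant cells sit in a single clonotype —
near 1 when mutations postdate clonal expansion.

## Burden profiles and lineage tracing

Per (patient, lineage) group with ≥100 cells, the burden profile is the
proportion of cells carrying exactly 1, 2, 3 or >3 PASS mutations;
groups below 100 cells are excluded for lack of discriminatory power.
For subtype lineage tracing, a binary mutation × subtype presence
matrix is built (presence = ≥1 carrier cell by default), after
excluding mutations in any cluster's top-100 differentially expressed
genes — detection is expression-dependent, and marker-gene mutations
would pull transcriptionally similar subtypes together for the wrong
reason. DEG lists are caller-supplied inputs: differential expression
belongs to the upstream clustering stack, not to this package.
Distances are asymmetric-binary (double absences ignored; an empty
union gives distance 0), trees are Saitou–Nei neighbor joining
(`ape::nj`; negative branch lengths clamped to zero and flagged), and
edge supports come from 100 bootstrap resamples of mutation rows with
explicitly drawn indices under one seed, so repeated runs are
identical and row order does not matter (rows are canonically sorted
before resampling).

## The synthetic-data generator

`simulate_dataset()` emulates the data regime the caller targets, on a
hermetic few-hundred-kb genome with genes on both strands so the
annotation and strand logic run without downloads:

- 1,200 cells per patient over the seven major lineages (400 T/NK, 250
  myeloid, 200 tumor, 100 B/plasma, 90 fibroblast, 80 endothelial, 80
  epithelial), with subtypes, and expanded CD8⁺ clonotypes of 40, 30,
  25, 20 and 15 cells;
- 60 truth mutations per patient with clonal structure: a truncal tumor
  clone (18) with two nested subclones (10 each, 40% and 35% of tumor
  cells), two clonal-hematopoiesis myeloid clones (7 and 5 mutations;
  30% and 15% of myeloid cells), and two post-thymic mutations per
  expanded clonotype; optionally mutations shared between two
  clonotypes (pre-thymic) or between patients;
- per-gene expression rates drawn log-normally (median ≈ 0.65, clipped
  to [0.25, 0.95]), Bernoulli expression per cell × locus, Poisson
  depth (mean 8), balanced binomial allele sampling for carriers,
  allelic dropout as monoallelic expression (default 10%), and binomial
  sequencing error for non-carriers (default $10^{-3}$).

Truth loci are placed ≥10 bp apart and with at most 9 members per
context class, so the proximity and strand filters never touch truth by
construction — artifact behaviour is tested through
`inject_artifacts()`, which plants labeled cross-lineage errors,
singlet errors, and strand-asymmetric context classes whose members
otherwise look like credible lineage-restricted calls. Each truth
mutation carries a *detectability* flag computed from the realized
counts (≥5 credible carriers in its lineage, ≥20 reference cells
elsewhere, Fisher/enrichment thresholds met, patient-unique, unmasked):
on noise-free data the cascade's PASS set equals the detectable truth
set exactly, which is the package's central closure property.

What the generator does *not* model — ambient RNA, doublets, UMI
structure, realistic transcriptome-wide expression profiles, read-level
errors with positional structure — bounds what passing tests show:
they demonstrate the cascade's logic and operating point, not its
error rate on real tissue, whose published benchmark figures came from
matched exome data.

```{r example}
library(scmutcall)
sim <- simulate_dataset(sim_config(seed = 1, error_rate = 0, ado_rate = 0))
calls <- call_mutations(sim$acm, sim$cells, sim$genome, sim$masks)
setequal(calls$locus, sim$truth$locus[sim$truth$detectable])  # TRUE
```

## Numerical and design choices

- Exact tests use closed-form tails (`phyper`, `pbinom`); the test
  suite pins them against independent full-enumeration oracles to
  $|\Delta p| < 10^{-9}$.
- Sidedness follows the cascade's direction: the allelic filter tests
  reference excess only; the Fisher test tests enrichment in the top
  group only. Both choices are deliberate readings of directional
  filter descriptions that do not state sidedness.
- Thresholds are arguments of `call_config()` (and CLI flags) rather
  than a configuration file: callers compose configuration objects in
  code, and a key-value file would only add a parser.
- Coordinates are 1-based inclusive (VCF convention) throughout;
  mitochondrial contig aliases (`chrM`, `MT`, …) collapse to `MT`.
- The BAM adapter defaults to base quality ≥20 and mapping quality ≥30
  (the counting conventions are not fixed by any published operating
  point; both are configurable) and reads cell barcodes from the `CB`
  tag.
- Degenerate inputs: an all-zero enrichment table returns $p = 1$,
  factor 0; an empty union in the binary distance returns 0; equal
  distances resolve to a deterministic NJ topology; zero denominators
  in precision/sensitivity report an absent value, never 0.
- Test and acceptance runs use one patient at 1,200 cells and ~100–260
  loci per dataset; each simulation takes a few seconds and the full
  pipeline under a minute on one core.

## Known limitations

Substitutions only (no indels); no UMI deduplication or ambient-RNA
correction; gene/exonic annotation is interval overlap on supplied
BED/GFF, not consequence prediction; copy-number effects on allele
balance are not modeled (the allelic filter's balanced-allele
assumption weakens inside amplifications); and the cross-patient mask
assumes patients are genetically unrelated.
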