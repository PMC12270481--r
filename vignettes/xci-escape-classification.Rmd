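---
title: "Calling escape from X inactivation with allele-specific expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling escape from X inactivation with allele-specific expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciae)
library(dplyr)
```

## The problem

In female somatic cells one of the two X chromosomes is transcriptionally
silenced (X-chromosome inactivation, XCI). The choice of which parental X
is silenced is normally made independently in early embryonic cells, so
adult tissues are a mosaic of the two states and bulk RNA-seq shows both
alleles of most X-linked genes at roughly equal levels — the allelic signal
of silencing cancels out. A minority of genes *escape* XCI and are
expressed from the inactive X (Xi) as well; their escape can differ between
tissues and between individuals.

Direct, gene-level measurement of escape in bulk data is possible only in
the rare females whose XCI is *non-mosaic* (nmXCI): essentially every cell
silences the same parental X, so the read ratio at any heterozygous
X-linked SNP (hetSNP) directly reads out expression from the active X (Xa)
versus Xi. `xciae` implements the full analysis around this idea:

1. **Screen** a cohort for nmXCI donors using allelic expression,
2. compute filtered per-gene, per-tissue **allelic expression** in those
   donors,
3. **test** each gene × tissue for significant Xi expression with an exact
   one-sided binomial test,
4. derive cross-tissue and cross-individual **consensus XCI statuses**, and
5. apply automated **curation** rules for the known failure modes of the
   binomial test on read counts.

Because the real donor-level data of this kind are access-controlled, the
package ships a first-class synthetic generator that emits the same file
dialects the pipeline reads, together with a truth record the pipeline
never sees.

## The allelic-expression statistic and the screen

For a hetSNP with `r` reference and `a` alternate RNA reads, allelic
expression is

\[ \mathrm{AE} = \left| 0.5 - \frac{r}{r+a} \right| \in [0, 0.5], \]

0 meaning perfectly biallelic and 0.5 perfectly monoallelic expression.

```{r}
compute_ae(50, 50)
compute_ae(975, 25)
compute_ae(100, 0)
```

The screen statistic for one sample is the **median AE over nonPAR X
genes not previously classified as variable**. Pseudoautosomal (PAR) genes
are excluded because they are not subject to XCI; previously-variable
genes because they would blur the contrast. In a mosaic tissue the median
sits well below 0.5; a median **strictly greater than 0.475** — less than
2.5% of reads from the inactive allele — is called nmXCI. The 0.475
boundary is read strictly ("higher than"); the boundary case never arises
in practice. A verdict requires at least 10 usable genes (configurable):
a median over fewer genes is too unstable to call a donor. The standard
error of the median is a seeded nonparametric bootstrap over genes (1,000
resamples by default); the estimator is a reporting aid and never enters
the verdict.

Candidate donors are then confirmed by requiring every retained tissue's
median nonPAR AE to clear the same threshold, after removing samples on an
explicit exclusion list (e.g. EBV-transformed lymphoblast lines). An
optional outlier rule flags a tissue whose median nonPAR AE falls more
than 0.05 below the donor's median of tissue medians; it is off by
default because it is a stand-in for a judgement call, and when enabled
every exclusion is logged with its reason.

## Filters, merging and SNP selection

Two filter modes mirror the two analysis stages:

| parameter                        | screen | detailed |
|----------------------------------|--------|----------|
| genotype depth per allele (>=)   | 20     | 10       |
| minor allele fraction (>)        | 0.10   | 0.10     |
| RNA read depth (>)               | 10     | 7        |

Inequalities are applied exactly as written: genotype depth is inclusive,
the other two strict. "RNA read depth" is interpreted as
`refCount + altCount` rather than the table's `totalCount`: the AE
statistic uses only the two alleles, and other-base reads are most often
errors. Screen-mode genotype filters consider WES calls only (the screen
design runs off an exome call set); detailed mode filters each assay's
calls on their own depths.

When a site is counted from both WES- and WGS-derived site lists, the
record with the higher total read count is kept; exact ties go to WGS,
which is PCR-free and typically less biased. A gene with several hetSNPs
is represented by one: in screen mode the SNP with the highest RNA count
in the sample, in detailed mode the SNP surviving filters in the most
tissues, ties broken by summed read count and finally by lowest genomic
coordinate for determinism.

The Xi allele of a donor-SNP is the allele with the smaller read count
summed over all the donor's tissues, fixed across tissues; this is the
count-based operationalisation of "reads from Xi" and is only meaningful
in confirmed nmXCI donors. An exact all-tissue tie is uninformative and
resolves to the alternate allele with a warning.

PAR membership uses configurable intervals (GRCh38 defaults: PAR1
chrX:10,001–2,781,479; PAR2 chrX:155,701,383–156,030,895) and the
gene-body midpoint, so every gene gets exactly one label even when it
straddles a boundary.

## The escape test and consensus categories

For a gene × tissue with `x` Xi reads out of depth `d`, escape is tested
with the exact one-sided binomial tail

\[ p = P(X \ge x), \quad X \sim \mathrm{Binomial}(d,\ 0.025), \]

the null being that at most 2.5% of reads come from Xi. Benjamini–Hochberg
FDR correction is applied **within each tissue separately**, and — because
each donor has their own site list and Xi phase — within each donor; the
adjustment universe is all tested hetSNPs of one donor in one tissue.
`q < 0.01` (strict) declares escape.

Per donor, a gene is categorised across the tissues in which it is
expressed (i.e. in which its selected SNP survived the RNA filters):

* significant in **all** tissues → `escape_across_tissues`,
* significant in **none** → `inactive_across_tissues`,
* significant in **more than one but not all** → `variable`,
* expressed in a **single** tissue → `escape_single_tissue` /
  `inactive_single_tissue`,
* PAR genes → `PAR`, overriding everything.

Significance in exactly one of several tissues falls outside the wording
for `variable`; such genes are classed `inactive_across_tissues` with a
`single_tissue_signal` flag so curation can revisit them. Across donors,
unanimous escape-type (or inactive-type) calls keep their label — named
`*_across_tissues` if any donor had multi-tissue coverage — while any
donor-level `variable` call or escape/inactive disagreement between donors
makes the gene `variable`.

## Curation

Binomial tests on read counts have two well-known failure modes:
over-dispersion makes very deep sites "significant" at biologically
mono-allelic ratios, and shallow sites cannot reach significance at all.
Curation re-examines every consensus call with three ordered, auditable
rules (`over_estimation`, `low_read_count`, `low_power`); at most one rule
changes a gene, PAR labels are never touched, and every evaluation is
written to an audit table.

* **over_estimation** — at least one significant tissue but the allelic
  ratio exceeds the empirical mono-allelic guideline of 0.4 (Xi fraction
  below 0.1) in *every* tissue: reclassify toward inactive.
* **low_read_count** — a `variable` gene whose escape pattern is broken by
  exactly one non-significant tissue, with Xi fraction at or above the
  consistency threshold τ = 0.05 everywhere: rescue to
  `escape_across_tissues`.
* **low_power** — per tissue, the smallest detectable Xi fraction is the
  smallest `f` with `P(X >= ceiling(f·d)) < 0.01`; tissues where this
  exceeds τ are incapable of detecting escape at τ and, when their point
  estimate is ≥ τ, are treated as consistent-but-underpowered rather than
  contradicting escape. If every expressed tissue then supports escape
  (and at least one is actually significant), rescue to escape.

Two refinements beyond the obvious reading proved necessary. The
low-power rule requires at least one *non-significant* tissue (there must
be something to excuse) and declines to fire when the AE pattern is
mono-allelic everywhere — otherwise it would re-promote exactly the genes
`over_estimation` demotes, and curation would not be idempotent. The
significance level used for the minimal detectable fraction is the fixed
q-threshold 0.01 rather than a data-dependent BH-adjusted level, so that
whether a tissue counts as underpowered does not depend on unrelated genes
tested in the same tissue.

The quantitative operationalisation (τ = 0.05, the 0.4 ↔ Xi-fraction-0.1
mapping, rule order) is this package's design; the thresholds are exposed
in `curation_rules()` and are the module's main documented assumption.

## The synthetic generator

`sim_config()` describes a cohort generatively. Each donor has an XCI skew
δ ∈ [0.5, 1]: the fraction of cells silencing the same parental X (0.5 =
balanced mosaic, 1.0 = nmXCI; truth labels donors with δ ≥ 0.995 nmXCI).
Each gene has an Xi expression fraction π ∈ [0, 0.5] (PAR 0.5, escape
drawn U(0.15, 0.4), inactive a small leak 0.005 — deliberately below the
2.5% null so the null stays realistic; variable genes toss a per-tissue
Bernoulli(0.5) and draw π ∈ U(0.1, 0.3) where they escape). The expected
fraction of reads from the haplotype on Xi in the majority lineage is

\[ f = \delta \pi + (1-\delta)(1-\pi), \]

which makes the two regimes transparent: at δ = 0.5 every gene converges
to balanced expression regardless of π (why mosaic bulk tissue is
uninformative), and at δ = 1 the minor-read fraction *is* π.

Counts are drawn binomially (optionally beta-binomially with concentration
κ) at a negative-binomial depth per SNP × tissue, with per-tissue
lognormal depth factors. Reference-mapping bias is a single parameter
`b`: the probability that a read from a site with *balanced* true
expression is counted as reference, applied as an odds tilt
`p' = pb / (pb + (1-p)(1-b))`, so `b = 0.5` is exactly neutral.
Haplotype→ref/alt phase is randomised per SNP. Truth structure (who is
nmXCI, gene classes, phase) and count noise take separate seeds so noise
can be re-drawn over fixed truth.

Defaults emulate the screen's study conditions: 285 donors, 3 at δ = 1.0
and the rest U(0.5, 0.9); WES genotype depth NB(mean 80, size 10) —
exome-like on-target coverage — and RNA depth NB(mean 50, size 5). These
are stand-ins for an unpublished population skew distribution and are
labelled as such.

What the generator does **not** model: read-level artifacts (mapping,
duplicates, strand), linkage between neighbouring SNPs beyond shared
gene-level π, copy-number changes, cell-type composition within a tissue,
and any correlation of escape between tissues beyond the per-tissue
Bernoulli. Tests passing on this generator therefore demonstrate that the
statistical machinery recovers the written generative model — not that
real tissues satisfy it.

## Numerical and scale choices

Binomial tails come from `pbinom` and are validated in the test suite
against an independent log-space summation oracle to 1e-12 for all depths
up to 200. BH correction is `p.adjust(method = "BH")` per donor × tissue
group. Degenerate inputs are contracts, not silent values: zero-total AE,
Xi counts above depth and p-values outside [0, 1] raise typed errors;
genes with no surviving SNP are absent rather than NA.

The shipped simulations are sized for a laptop-class run: the screen
recovery check uses the full 285-donor design (~17k count rows), the
classification recovery check one nmXCI donor × 500 genes × 10 tissues,
and the cohort-specificity property 1,000 mosaic donors with a 40-gene
panel and a single SNP per gene. These sizes are the package's choices for
a fast, reproducible demonstration; all of them scale up through
`sim_config()` without code changes.

## Known limitations

* Xi-allele assignment is count-based; no population phasing. In a donor
  with δ exactly 1 and a gene with π near 0.5 the assignment can flip at
  low depth, which slightly biases Xi fractions toward 0.5 from below.
* The screen cannot distinguish primary from secondary skewing, and the
  package deliberately does not attempt to infer the cause of nmXCI.
* The curation thresholds are calibrated stand-ins for expert judgement;
  on real data the audit table is the intended review surface, not a
  replacement for inspection.
* FDR is controlled per donor × tissue; pooling donors within a tissue is
  a defensible alternative the package does not implement.
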