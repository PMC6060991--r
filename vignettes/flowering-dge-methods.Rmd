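---
title: "Methods: tag-count screening of flowering-related genes and miRNA-mRNA integration"
author: "floweringDGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tag-count screening and miRNA-mRNA integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(floweringDGE)
```

## The study design this package models

`floweringDGE` implements the analysis of a three-library digital gene
expression (DGE) study of flowering in common wild rice (*Oryza rufipogon*):
one tag-count library from the vegetative stage of a single-flowering
sub-group (**V1**), one from the vegetative stage of a double-flowering
sub-group (**V2**), and one from the flowering stage of the double-flowering
sub-group (**F2**). Each library is a single sequencing run of several
million tags; there are **no biological replicates** — one library per
condition. Every statistical choice below follows from that design.

The pipeline is: RPKM normalization → exact two-library differential
expression screen for the three pairwise comparisons → set logic isolating
genes differentially expressed only against the flowering stage →
hypergeometric GO/KEGG term enrichment of that set → integration of
differentially expressed miRNAs with sign-opposed target mRNAs → qRT-PCR
validation arithmetic.

## Expression level: RPKM with the longest-transcript rule

A gene's expression in a library is

$$\mathrm{RPKM} = \frac{10^9 \, C}{N \, L},$$

with $C$ the gene's tag count, $N$ the library's **total mapped reads** and
$L$ the gene's effective length in bp. When a gene has several transcript
models the longest one defines $L$ (`effectiveGeneLength()`). $N$ is total
mapped reads rather than total raw reads because "per million mapped reads"
is the definition of the unit; the mapping-summary table (see below) keeps
both totals so either convention can be derived.

`mappingSummary()` reproduces the per-library sequencing summary: each read
category as a percentage of total reads, rounded **half away from zero to
2 decimals** — the convention of the printed table it mirrors (R's default
round-half-even would print 6.45 → 6.4). The three additivity identities
(unique + multi-position = mapped; perfect + ≤3-mismatch = mapped;
mapped + unmapped = total) are validated and a violated identity is
reported by name. The in-text alternative that divides by mapped rather
than total reads is available as the optional `pct_of_mapped` column.

## The differential-expression screen

### The exact two-library test

With a single library per condition, the only sampling model available is
the count itself. Conditional on observing $x$ tags for a gene in a library
of $N_1$ total tags, the number of tags $y$ in a second library of $N_2$
tags follows, under the null of equal underlying expression,

$$P(y \mid x) \;=\; \left(\frac{N_2}{N_1}\right)^{\!y}
  \frac{(x+y)!}{x!\,y!\,\bigl(1+N_2/N_1\bigr)^{x+y+1}},$$

the classic conditional test for comparing two tag libraries
(`acProbability()`). This distribution is exactly negative binomial with
size $x+1$ and success probability $N_1/(N_1+N_2)$, which the test suite
uses as an independent cross-check; the implementation itself evaluates the
pmf in log space (`lgamma`) so tag totals in the millions neither overflow
nor underflow.

**Two-sidedness.** The source analysis never states a sidedness convention,
so the package uses the common conservative choice: the doubled smaller
tail, $p = \min\{1,\, 2\min[P(Y\le y \mid x),\, P(Y\ge y\mid x)]\}$
(`acPvalueTwoSided()`). Note that this convention conditions on the *first*
library's count, so exchanging the two libraries (and their sizes) is **not
an exact symmetry**: at tiny counts the two orderings can differ by a factor
of 2 (e.g. $x=2, y=0, N_1=N_2$ gives 0.25 one way and 0.5 swapped). The two
orderings agree asymptotically (the test suite checks agreement of
$\log p$ to a few percent at moderate counts). Users comparing libraries
should keep the reference/test orientation fixed across genes, as
`screenDEGs()` does.

**Tail summation.** The smaller tail is summed directly, term by term in
log space, starting at the observed $y$ and moving away from the
distribution's mode; summation stops once a term falls **60 nats** below the
largest term seen, bounding the truncated mass below $10^{-20}$ relative.
The larger tail is obtained from the complement, which is numerically safe
precisely because the directly-summed tail is the small one. Terms are
evaluated in chunks of 256 to keep the computation vectorized.

### Fold change, FDR, and the call rule

The reported effect size is a pseudocounted, library-size-normalized log
ratio

$$\log_2\!\frac{(y + c)/N_2}{(x + c)/N_1}, \qquad c = 1 \text{ tag},$$

finite for all count pairs including zeros (a zero observed against 63 tags
at equal depth gives exactly 6). The pseudocount of one tag is the smallest
unit of evidence in a DGE library; it leaves genes with a true two-fold
change comfortably above the screen threshold while preventing infinite
ratios. Whether the original analysis used raw counts, RPKM, or pseudocounts
is not stated; the pseudocount is a parameter (`pseudocount`).

Multiple testing is controlled by the Benjamini–Hochberg step-up
(`bhAdjust()`; the source analysis says only that an FDR threshold was
used, and BH is the standard reading). A gene is called **up** or **down**
when

$$\mathrm{FDR} \le 0.001 \quad\text{and}\quad |\log_2 \mathrm{ratio}| \ge 1,$$

the printed thresholds, both configurable. Genes with zero tags in both
libraries carry no information for the test and are removed before BH so
they cannot dilute the correction.

## Set logic over the three comparisons

Each pairwise comparison contributes the set of its significant genes
(direction ignored, matching the aggregate counts the design reports).
`vennCounts()` reports the seven disjoint regions. The "exclusively related
to flowering" set is, by default,

$$(\mathrm{V1F2} \cap \mathrm{V2F2}) \setminus \mathrm{V1V2}:$$

genes that differ from the flowering-stage library under **both** vegetative
baselines but do not differ between the two vegetative samples. The source
figure never writes this formula, and whether its printed count derives from
this or a direction-aware variant cannot be determined from the text alone;
the expression is therefore a configurable string over the labels
`V1F2`, `V1V2`, `V2F2` with `&`, `|`, `-` and parentheses
(`floweringExclusiveGenes()`), and the default is this package's documented
reading, not a claim about the original computation.

## Term enrichment

`enrich()` tests each term for over-representation of the study set against
a population background with the exact upper-tail hypergeometric probability
$P(X \ge k)$ (`hypergeomPvalue()`, delegating to `phyper`). Choices:

* **Correction**: the source says "corrected P value" without naming a
  method; BH is the default, Bonferroni available.
* **Families**: q-values are computed within each namespace (the three GO
  categories and KEGG pathways are separate multiple-testing families).
* **Population**: the "genome background" is ambiguous between the genome
  and the expressed gene set; the pipeline uses all genes with at least one
  mapped tag, and `enrich()` accepts any population vector.
* **Zero-hit terms** are still tested ($k=0$, $p=1$) so the BH denominator
  does not depend on the study set, making q-values reproducible across
  studies of the same annotation.

`categoryBreakdown()` reports (gene, term) assignment counts per GO
namespace as percentages of total assignments, one decimal, half-up — the
arithmetic behind "45.8 / 31.5 / 22.7%"-style splits.

No GO-graph propagation is performed: term maps are flat files, as in the
analysis being modeled.

## miRNA-mRNA integration

A miRNA represses its targets, so a candidate regulatory pair is a
differentially expressed miRNA and a predicted target that is significantly
differentially expressed **in the opposite direction** in the V1-vs-F2
comparison (`antagonisticPairs()`). Conventions, fixed by the worked
example the package ships (the 28-row pair table):

* Target lists keep their presentation order and **duplicated entries are
  preserved**, because the printed summary splits (27 and 66 target
  entries) count listed entries, not distinct genes.
* Pair tables group one row per miRNA (`groupByMirna()`), and
  `pairSummary()` counts distinct miRNAs by direction but target entries as
  listed.
* Opposition is evaluated against up/down membership sets rather than a
  single gene-to-direction map: the printed table lists one gene in both
  directions under different miRNAs, and membership sets reproduce the
  table as printed while behaving identically on any consistent screen
  output.
* "Flowering-related" is an input annotation flag (`filterFlowering()`),
  not a hard-coded ontology query; the original retrieval criterion is
  unstated. The printed flowering subset admits three defensible sizes
  (10 printed miRNA groups, 12 distinct miRNAs, 20 target rows), so the
  loader exposes the full table and the tests assert all three counts
  rather than privileging one.

Target prediction is out of scope: the target map is an input inherited
from a prior small-RNA study.

## qRT-PCR validation arithmetic

`standardCurve()` fits mean CT against $\log_{10}$ of input amount over a
serial dilution (at least three points) and converts the slope to an
amplification efficiency $E = 10^{-1/\mathrm{slope}} - 1$; a perfect
doubling per cycle gives slope $-1/\log_{10} 2 \approx -3.3219$ and
$E = 100\%$. A flat series has no defined efficiency and is rejected. The
fit's $R^2$ is computed from residual and total sums of squares directly.

`ddctFoldChange()` implements relative quantification: technical-replicate
CTs are averaged (the design reports means of three technical replicates of
one biological sample, so no biological-replicate error model exists to
fit), $\Delta CT$ is target minus reference (OsActin for mRNA, U6 for
miRNA), and the fold change is $2^{-\Delta\Delta CT}$. Exact base-2
amplification is assumed regardless of the measured efficiency, matching
standard practice; an efficiency-corrected variant
$(1+E)^{-\Delta\Delta CT}$ is available. Antisymmetry
(fold(a,b) · fold(b,a) = 1) holds exactly and is asserted in tests.

`expressionConcordance()` is the Pearson correlation between qPCR and
sequencing log2 fold changes over the same genes, with degenerate
(zero-variance) input rejected rather than silently returning `NA`.

## The synthetic-data generator

`simulateCountLibraries()` emulates the study's scale and structure with
planted, recoverable truth:

* **Defaults mirror the emulated study**: 27,405 genes; library sizes equal
  to the three mapped-read totals (5.86, 5.97, 5.79 million tags); 44
  differentially expressed miRNAs of which 6 are novel; planted DE fraction
  0.10 per comparison (the study's called fraction is ~2.7–4.3 thousand of
  ~27 thousand genes per comparison); planted $|\log_2$ fold$|$ uniform on
  $[1.5, 3]$ (no fold-size information is given for the real libraries, so
  the range is chosen to sit clearly above the screen threshold of 1 while
  staying in the few-fold regime typical of developmental comparisons —
  stated, not fitted).
* **Baseline**: per-gene relative rates are log-normal
  ($\sigma_{\log_{10}} = 0.8$, a realistic several-decade dynamic range),
  normalized so gene-assigned tags form 75% of each library (the observed
  unique-match share of total reads is 74–76%). If planted up-folds push a
  library's summed rate above 0.95, **all** libraries are rescaled by one
  common factor — ratios, and hence all planted truth, are unchanged.
* **Noise**: counts are Poisson with mean rate × library size — exactly the
  sampling model of the conditional test, and the only defensible noise
  model for a design with one library per condition. Consequently the
  simulation does **not** emulate biological variability, and passing
  recovery tests demonstrate correctness of the screen's arithmetic, not
  robustness to overdispersion in replicated designs.
* **Truth derivation**: a fold planted in one library necessarily perturbs
  both comparisons that involve that library, so the ground truth
  (`SimTruth`) is derived from the realized per-library rate ratios of all
  three comparisons rather than from the planting labels; planted gene sets
  are disjoint across comparisons.
* **miRNA tables** (`simulateMirnaTables()`): each miRNA receives 1–8
  targets of which a configurable fraction (default 0.6) is sign-opposed in
  V1-vs-F2 (the recorded true pairs) and the rest are non-opposed decoys;
  an annotation table flags a configurable fraction (default 0.3) of genes
  as flowering-related.

All randomness derives from the single `seed` field; identical
configurations give bit-identical output.

### What the recovery suites measure

The test suite and the acceptance script re-run the full screen on
simulated studies (1,000–2,000 genes, three libraries of $10^6$ tags —
compact versions of the default conditions chosen so the suites run in
seconds) and measure:

* the **null call rate** with no planted effects (must not exceed the
  nominal FDR of 0.001);
* **recall** of planted V1-vs-F2 genes and the **Jaccard index** between
  the recovered and true flowering-exclusive sets, both evaluated over
  **adequately expressed** genes, defined as an expected reference-library
  count of at least 20 tags. The qualifier matters: a planted two-to-
  eight-fold change on a gene with a handful of expected tags is invisible
  to any exact test at these depths, in both comparisons it must pass to
  enter the intersection set. The 20-tag floor is where the test's power
  at the weakest planted fold (1.5 log2 units) becomes high at FDR ≤ 0.001
  with ~1,000 genes tested;
* **precision/recall of antagonistic-pair recovery** against the planted
  pair truth, which are exactly 1 when every planted target passes the
  screen.

## Running the pipeline

`makeDemo()` writes a complete simulated study (all input TSVs, a synthetic
term map, the truth JSON and a `config.yaml`); `runPipeline()` executes all
stages from one config (list or YAML), writes every stage output as TSV/JSON
under the configured output directory, and emits a `manifest.json` whose
record counts match the emitted files. A run refuses to overwrite an
existing manifest unless `force = TRUE`; re-running with `force` reproduces
identical outputs for the same inputs and seed.

```{r demo, eval = FALSE}
demo <- makeDemo(seed = 1, outdir = "demo_study", nGenes = 2000)
manifest <- runPipeline(demo$config)
str(manifest$counts)
```

## Known limitations

* No replicate-aware inference (negative-binomial dispersion, shrinkage):
  out of scope for a one-library-per-condition design.
* The exact test's doubled-tail convention is conservative and not exactly
  exchange-symmetric (see above).
* The flowering-exclusive set formula is a documented reading of an
  ambiguous figure, exposed as a parameter.
* Term maps are flat; no GO true-path propagation.
* The simulator's Poisson noise understates the variability of real
  replicated RNA-seq; conclusions about real data should rest on the
  arithmetic correctness shown here, not on simulated power alone.
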