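---
title: "Projecting CpG methylation and expression onto KEGG pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting CpG methylation and expression onto KEGG pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methpath)
```

## The problem

DNA methylation of CpG sites near or within a gene can silence (or,
less often, enhance) its transcription, and a change in one regulator
propagates through the expression network it sits in. Interpreting a
cohort's methylation array or bisulfite-sequencing data therefore
benefits from viewing it *on* the pathway: each gene colored by the
methylation of its CpG sites, optionally next to its expression, with
samples grouped by a phenotype or mutation status. `methpath` implements
that projection as composable functions — parse a KGML pathway, load and
filter the site-level data, aggregate per gene and group, and emit
deterministic SVG.

A vertebrate methylome has orders of magnitude more CpG sites than
genes, and most sites barely vary across a cohort. The package's core
analytic stance follows from this: *site selection comes first*.
Averaging all of a gene's sites dilutes a strong differential signal at
one site with the flat majority, so every analysis accepts a filter
specification, and genes whose sites are all filtered away are shown in
a dedicated "no passing sites" gray rather than a misleading average.

## Data model and matching

A methylation matrix has CpG sites as rows and samples as columns, beta
values in $[0,1]$ (the ratio of methylated to total signal). Row keys
embed the annotation as underscore-separated fields —
`gene[_siteid][_chrom:pos][_location]` — with the location drawn from the
Annovar region vocabulary (upstream, downstream, exonic, intronic, UTR5,
UTR3, splicing, intergenic, ncRNA). The parser is total: tokens that
match no field pattern fold back into the gene symbol, so gene names
containing underscores survive. Probe- or position-keyed matrices
(Illumina arrays, Bismark coverage) are converted by `annotate_matrix()`
from a four-column annotation table; a probe annotated to $k$ genes
fans out into $k$ rows sharing one beta vector, and unannotated probes
are dropped and counted. Because of fan-out, row-key uniqueness is
enforced on the (gene, site) pair rather than the bare site id.

Sites match a pathway entry when the gene symbol equals *any* of the
entry's KGML aliases, case-insensitively — KEGG packs several symbols
into one graphics name, and metadata files mix cases freely.

## Filters and display values

A site passes a `filter_spec()` when **all** active criteria hold:

| criterion | default | semantics |
|---|---|---|
| `sd_threshold` | off | sample SD (denominator $n-1$) of non-missing betas strictly greater than the threshold; fewer than 2 observations fails |
| `beta_range` | off | every non-missing beta inside $[lo, hi]$ (`range_mode = "all"`); an `"any"` mode accepts one in-range sample |
| `locations` | off | site's location in the chosen set |
| `site_list` | off | site id or `chrom:pos` in an explicit list |

The sample (not population) SD is the conventional estimator for a
cohort-level dispersion; the strict inequality means a threshold of 0.2
excludes a site with SD exactly 0.2. The "all samples in range"
reading of the beta-range filter is the strict one; the "any" mode is
provided because both are defensible and the choice materially changes
which sites survive.

Per sample, a gene's methylation display value is the mean beta over its
passing sites; per group, an aggregator over the members' values. The
group aggregator defaults to the **mean** for methylation and the
**median** for expression. Field usage genuinely varies here — averaging
is the natural companion of beta values, while the median is robust for
heavy-tailed FPKM — so both are implemented and the default is a
documented choice, not a claim that one is canonical.

Expression display values are
$f = \log_2\!\frac{x + \varepsilon}{\mathrm{median} + \varepsilon}$
clipped to $[-s, +s]$ with $s = 4$ by default. The pseudocount
$\varepsilon = 0.01$ FPKM (configurable) keeps zero-FPKM genes finite;
it biases folds only for genes whose median is within a couple of orders
of magnitude of $\varepsilon$, i.e. essentially unexpressed ones. A value
equal to the median maps to exactly 0. Group-wise expression takes the
median of the members' raw FPKM and applies the same formula.

Colors interpolate linearly in 8-bit RGB — dark blue `#00008B` at
$\beta = 0$, white at $0.5$, dark red `#8B0000` at $1$; expression uses
the same poles but *inverted* (over-expression blue), so a methylated,
silenced gene is dark red on both layers. Linear RGB is chosen over a
perceptually uniform space for simplicity and byte-determinism; the
endpoints are configuration, the monotonicity of each segment is a
tested invariant.

## Similarity and correlation

The similar-pattern search compares the target gene's per-sample mean
beta against every loaded site (not only the current pathway, since hits
feed the pathway-independent grid). The distance is the root-mean-square
difference over samples where both vectors are observed:
$d = \sqrt{\tfrac{1}{|S|}\sum_{s \in S}(a_s - b_s)^2}$. Normalizing by
the shared-sample count keeps sites with missing data comparable; the
plain (unnormalized) Euclidean distance is available as an option.
Candidates sharing fewer than two samples with the target are skipped and
logged; per gene only the closest site is kept; ties break
lexicographically by gene symbol so rankings are reproducible.
Pairwise-complete handling of missing values (rather than imputation)
was chosen as the least-assumption option.

Methylation–expression coupling uses Spearman's rank correlation (mean
ranks for ties) with the $t$-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$
on $n-2$ degrees of freedom for the p-value. A constant vector makes
$\rho$ undefined; that is reported as a state, never an error, and an
undefined correlation cannot pass a screen. The screen itself is a plain
threshold on $\rho$ (default $-0.7$) applied to each gene's most negative
site; Benjamini–Hochberg adjustment of the p-values is available behind a
flag but does not change the pass rule, because the screen is a visual
selection device rather than a formal test.

## The synthetic cohort

`synthetic_spec()` describes the generated study: a balanced two-group
cohort (20 + 20 samples) in which five genes carry one *planted* CpG site
with group beta means 0.2 versus 0.7 ($\Delta\beta = 0.5$), all other
sites share one background mean (0.45), and Gaussian noise of SD 0.05 is
added and clipped to $[0,1]$. Three of the planted genes are
expression-*coupled*: their FPKM is
$\mathrm{base} \cdot 2^{-k\beta}$ of the planted site ($k = 4$) with
log-normal noise (sdlog 0.1) — a strictly monotone-decreasing coupling,
so their methylation–expression correlation is strongly negative while
uncoupled genes stay near zero. These values emulate the shape of a
two-group tumor cohort split by a driver mutation, where a subset of
sites is hyper-methylated in one group and silences key regulators:
bimodal betas at differential sites, flat background, clean group
structure.

What the generator does **not** emulate: probe-level technical bias,
co-methylation of neighboring sites, batch effects, cell-type
composition, or the long-tailed site-count-per-gene distribution of a
real 450K annotation. Passing the recovery tests therefore demonstrates
the *correctness of the machinery* — that the SD filter retains exactly
sites whose dispersion exceeds the threshold, and the screen exactly the
strongly anti-correlated genes — not that those thresholds are optimal
for any real cohort.

With these settings the planted sites have SD
$\approx \sqrt{0.25^2 + 0.05^2} \approx 0.255$ and background sites
$\approx 0.05$, so the 0.2 threshold separates them with enormous
margin; recovery at precision = recall = 1 is the expected outcome, and
a failure would indicate a defect, not bad luck. The truth table is
written next to the matrices so recovery tests are self-describing.

## Numerical and rendering choices

* KGML `x`/`y` are box **centers** (the KGML convention); conversion to
  top-left corners happens only at draw time.
* Serialization re-emits parsed graphs; `parse(serialize(g))` is the
  structural identity, property-tested over random graphs.
* Unrecognized relation subtypes are kept as `unknown` (and drawn dotted)
  rather than dropped; unknown interactions are information.
* SVG numbers are printed with fixed two-decimal formatting and no
  timestamps or generated ids, so a fixed plan renders to identical
  bytes — the basis of the playback and caching guarantees.
* When methylation and expression are shown together, the two boxes are
  drawn side by side (left/right) within the gene's rectangle; stacked
  placements are a GUI convention that does not survive in a static
  image.
* KEGG REST access goes through an injectable transport function and a
  byte-identical file cache, so analyses are reproducible offline and
  tests never touch the network.

## Problem sizes

The test suite exercises random KGML graphs up to 20 entries (100
round-trips), 200 randomized filter cases against a brute-force oracle,
20-site × 15-sample similarity matrices with 10% missingness against an
all-pairs oracle, and the full synthetic cohort (60 sites × 40 samples)
end to end; the complete suite runs in well under a minute. These sizes
are chosen to cover the combinatorics (ties, missing values, degenerate
sites) rather than to stress throughput; the implementation is vectorized
per site and comfortably handles array-scale inputs restricted to a
pathway's genes.

## Limitations

* No differential-methylation statistics beyond the filters — no region
  calling, no bump hunting; outputs of such tools enter as site lists.
* No normalization of raw array intensities; betas must be precomputed.
* Group-wise displays hide within-group dispersion; the bar-plot view
  exists precisely to check a gene before trusting its group box.
* The correlation screen tests association sites-wise, not causality,
  and applies no multiplicity control by default.
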