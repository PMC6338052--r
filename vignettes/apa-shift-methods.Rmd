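---
title: "Methods: detecting 3'UTR shortening and lengthening with apaShift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting 3'UTR shortening and lengthening with apaShift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apaShift)
```

## The two-isoform model

apaShift assumes that, for each analyzed gene, exactly two 3'UTR isoform
classes matter: a *short* isoform ending at the most proximal annotated
polyadenylation site (molar abundance $m$) and a *long* isoform ending at the
canonical transcript 3' end (molar abundance $M$). The exonic bases of the
canonical transcript are partitioned into the **PRE** region (5' end up to
the proximal site; transcribed in both isoforms) and the **POST** region
(proximal site to the canonical end; long isoform only).

Under uniform read sampling, per-base PRE coverage is proportional to $m+M$
and per-base POST coverage to $M$. Writing $c_\mathrm{PRE}, c_\mathrm{POST}$
for the region counts and $L_\mathrm{PRE}, L_\mathrm{POST}$ for their lengths,

$$\widehat{m/M} \;=\;
\frac{c_\mathrm{PRE}/L_\mathrm{PRE}}{c_\mathrm{POST}/L_\mathrm{POST}} - 1 .$$

The between-condition statistic is the ratio of ratios,

$$\mathrm{roar} \;=\;
\frac{(\widehat{m/M})_\mathrm{contrast}}{(\widehat{m/M})_\mathrm{baseline}},$$

with *contrast* the later / differentiated condition. roar > 1 therefore
means relative shortening during the transition and roar < 1 lengthening.
Intermediate polyA sites between the proximal one and the canonical end are
not modelled; reads from intermediate isoforms inflate PRE relative to POST
and bias $\widehat{m/M}$ upward in both conditions, which partially cancels
in the ratio.

The estimator is undefined when $c_\mathrm{POST}=0$ and can come out negative
when the POST per-base rate exceeds the PRE rate — impossible under the model,
so such genes are flagged (`negative_mM`, `zero_post`, `zero_pre`,
`undefined_roar`) and excluded from classification rather than clamped.

## Significance and classification

The roar value is computed on counts pooled across replicates within each
condition (a single effect estimate per gene), while significance is assessed
on every baseline × contrast replicate pairing separately: each pairing forms
a 2×2 table $[[c_\mathrm{PRE}^{b}, c_\mathrm{POST}^{b}],
[c_\mathrm{PRE}^{c}, c_\mathrm{POST}^{c}]]$ tested with a two-sided Fisher
exact test. Requiring *every* pairing to reach significance is a conservative
consistency filter that substitutes for replicate-level dispersion modelling;
no multiple-testing correction is applied, the p-values are nominal by
design.

A gene is called SHORTENED iff roar > 1, all pairwise p < α, and the PRE
(common) region FPKM exceeds the expression floor in **both** conditions;
LENGTHENED symmetrically with roar < 1. Defaults: α = 0.05, FPKM floor = 1,
roar boundary = 1 — all strict inequalities, all configurable
(`classifyApa()`, pipeline `thresholds`). Genes failing the FPKM floor or
carrying a validity flag are NOT_TESTABLE; testable genes failing criterion 1
or 2 are UNCHANGED, so the four calls partition the gene universe.

Across a time course the per-comparison call sets are intersected: a gene is
"always lengthened" iff LENGTHENED in every comparison. Intersecting full
calls (direction *and* significance in each comparison) is deliberate; a gene
NOT_TESTABLE anywhere can never be in an intersection. Venn region counts are
exact set algebra, not approximations.

The two-sided Fisher p is computed vectorized from the conditional
hypergeometric distribution (`dhyper`), summing the probabilities of all
tables no more probable than the observed one with the customary
$(1+10^{-7})$ relative tolerance on the equality comparison. The test suite
checks it against `stats::fisher.test` and against exhaustive enumeration via
binomial-coefficient log-probabilities for every table with total ≤ 60.

## Segmentation geometry

* Canonical transcript: the gene's transcript with the largest exonic length;
  ties break to the lexicographically smallest transcript id (ASCII order,
  locale-independent) for reproducibility.
* Proximal site: the most 5' site (smallest coordinate on +, largest on −)
  inside the canonical transcript's 3'UTR. When no site falls in the 3'UTR,
  the same rule is applied over the transcript's full genomic span; that
  fallback is this package's documented choice for an operationally
  under-specified situation, and genes without any usable site are excluded
  with reason `no_apa_site`.
* Split rule: the genome is cut at the site's start coordinate; exonic bases
  genomically left of the site base form one part, the site base and
  everything right of it the other; the 5'-side part (left on +, right on −)
  is PRE. A split that leaves either region empty excludes the gene
  (`degenerate_pre` / `degenerate_post`).
* Coordinates are held 1-based closed in `GRanges` internally; BED input and
  output are 0-based half-open at the file boundary (rtracklayer converts on
  read; the BED writer subtracts 1 from starts). GTF is read 1-based closed
  as the format defines. A polyA site on an exon boundary belongs to the
  exon whose half-open interval contains it, which is exactly the width-1
  overlap semantics used. Genes on unplaced contigs receive no special
  treatment.
* 3'UTRs come from explicit `three_prime_utr` features when present,
  otherwise they are inferred as the exonic bases 3' of the CDS/stop codon;
  transcripts with neither go straight to the fallback rule.

## Read counting

A primary, mapped alignment overlapping a region by ≥ 1 base is counted.
A read overlapping both PRE and POST of the same gene is assigned to POST
only (default `boundary = "post"`): such reads span the proximal site and can
only derive from the long isoform, so this keeps the most information;
`boundary = "both"` is available. Counting is unstranded by default
(`stranded = "none"`); `forward`/`reverse` enable strand-matched counting for
stranded libraries. Secondary, supplementary and unmapped alignments are
ignored; duplicates are kept; mates of a pair are counted independently; a
read overlapping two genes counts for both (reported via message). The
library size used for FPKM is the number of primary mapped alignments.
Files that htslib cannot parse are rejected outright rather than skipped
record by record.

FPKM of the PRE region, $c / (L/10^3 \cdot N/10^6)$, is the expression filter
because PRE is the sequence common to both isoforms.

## CLIP binding-site enrichment

Overlaps are evaluated on entire gene spans (min exon start to max exon end
of the canonical transcript) and ignore strand — binding anywhere in the
locus is counted, since the mechanism of action need not be transcript-local.
Sites are first reduced to robust clusters: FDR < 0.01 **or** biological
complexity BC ≥ 5 (a site missing both scores is dropped). Enrichment of a
call set against the analyzed-gene universe (all genes with a segmentation
that entered the statistics) uses a one-sided (greater) Fisher exact test,
because the question is over-representation; a two-sided variant is a flag
away. The sample odds ratio $ad/bc$ is reported, infinity allowed.

## qPCR quantification

The long-vs-common strategy uses one amplicon inside POST (long isoform
only) and one inside PRE (both isoforms). Per replicate the ΔΔCt index is
$E^{-(\mathrm{Ct}_\mathrm{long}-\mathrm{Ct}_\mathrm{common})}$; the reference
gene Ct cancels algebraically but is required so incomplete measurements are
caught. Replicates combine by geometric mean (arithmetic on the Ct scale);
the condition ratio contrast/baseline > 1 indicates relative lengthening.
Amplification efficiency defaults to the ideal $E=2$ per cycle and is
configurable; standard-curve calibration is out of scope.

## The synthetic data generator

`simulateApaGenome()` and `simulateApaCounts()` emulate the statistical
structure the analysis relies on, not sequence-level realism:

* genes on both strands, 1–4 exons of 300–1500 bp (≥ 1500 exonic bases
  total), introns 100–2000 bp, 5 kb gaps on four synthetic chromosomes;
* 3'UTRs spanning 30–50% of the exonic length, clipped to 600–2500 bases —
  the long UTRs typical of neuronal transcripts — with the proximal site
  placed so POST covers 40–80% of the UTR (a mostly-distal extension);
* 6.7% of genes have no 3'UTR polyA site (the site sits upstream in the
  transcript), exercising the fallback; ~20% of multi-exon genes carry a
  second shorter transcript, exercising canonical selection;
* relative expression is lognormal(0, 0.5); per replicate the gene total is
  negative binomial with mean `expression_level × meanDepth` and variance
  $\mu + \phi\mu^2$ (dispersion $\phi = 0$ degenerates to Poisson), split
  binomially between PRE and POST with
  $p_\mathrm{PRE} = L_\mathrm{PRE}/(L_\mathrm{PRE} + \lambda L_\mathrm{POST})$
  for long-isoform fraction $\lambda$ — exactly the coverage model the
  estimator assumes;
* true classes default to 80% unchanged, 10% shortened, 10% lengthened;
  shifted genes move from their baseline long fraction to
  $\lambda + 0.75(1-\lambda)$ (lengthened) or $\max(0.08, 0.3\lambda)$
  (shortened) from the second condition onward, i.e. a uniform shift across
  the time course; the four-time-point preset uses 3/3/3/2 replicates;
* `emitAlignments()` writes single-end SAM reads placed uniformly within the
  region each count belongs to, so counting them back reproduces the counts
  exactly (reads longer than an interval piece are shortened to it).

Because the generator satisfies the estimator's assumptions by construction,
passing tests demonstrate correctness of the implementation and calibration
of the statistical procedure — not robustness to features of real data the
generator omits: intermediate polyA sites, positional coverage bias, mapping
ambiguity, overlapping genes, annotation errors, or isoform-specific
expression changes.

## Numerical and design choices

* Fisher equality tolerance $(1+10^{-7})$ matches common practice and makes
  the [[5,0],[0,5]]-style symmetric tables sum both tails exactly.
* All randomness flows through explicit `seed` arguments; the caller's RNG
  state is saved and restored, and identical seeds give byte-identical
  artifacts (the demo writes config paths relative to the config file so
  whole run directories are relocatable and reproducible).
* Text outputs are sorted with locale-independent radix order before
  writing; reruns are byte-identical.
* Degenerate inputs error early with named conditions: config problems raise
  `apa_config_error` (CLI exit 2), missing/invalid inputs `apa_input_error`
  (CLI exit 3).
* Problem sizes used by the acceptance script — 2,000 null genes at depth
  200, 500 genes with 50+50 planted shifts at depth 300, $10^5$ reads for
  estimator consistency, 300 genes for the partition check, 100 genes for
  the SAM round trip, a 40-gene demo run — were chosen as the smallest sizes
  at which the stochastic quantities are stable to well within their margins.

## Known limitations

* One proximal site per gene: multi-site 3'UTRs are reduced to the most
  proximal versus the canonical end.
* The all-pairings rule is conservative; genes with high baseline long
  fraction (little room to lengthen) or very short POST regions have limited
  power, and truly shifted genes can be missed — the worked example in the
  README shows this pattern.
* No fragment-length model and no paired-end awareness beyond counting mates
  independently.
* No FDR control across genes (by design, matching the nominal-p criterion),
  so the call lists are meant to be consumed together with their roar
  magnitudes, not as an error-controlled discovery set.
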