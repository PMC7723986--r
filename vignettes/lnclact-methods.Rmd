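---
title: "Methods: lncRNA identification and downstream analysis in a 2-vs-3 lactation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lncRNA identification and downstream analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery behind `lnclact`, the
choices that were genuinely open when the package was designed, and what
the synthetic-data generator does and does not emulate.

## The analysis problem

The package targets a common comparative design in lactation biology:
bulk RNA-seq of mammary tissue from a handful of animals at two
physiological stages — here two samples at peak lactation (LP) and three
at the dry period (DP). Transcripts are assembled upstream (outside this
package); the analysis downstream must (i) separate genuine long
non-coding RNAs from assembly noise and coding transcripts, (ii) call
differential expression with almost no replication, (iii) attach
candidate target genes to the differential lncRNAs by genomic proximity
and co-expression, and (iv) summarize function via term enrichment and a
regulatory network, validated by qPCR on a small panel.

## Identification cascade

Five exclusion rules are applied to every candidate transcript, in a
fixed order, recording *all* failures rather than stopping at the first
— the audit trail is the point; pass/fail itself is order-independent.

| rule | keep when | notes |
|---|---|---|
| exon count | >= 2 exons | single-exon models are mostly assembly noise |
| length | spliced length > 200 nt | strictly greater: a 200-nt transcript is removed |
| expression | max FPKM over samples >= 0.5 | inclusive at 0.5 |
| annotation overlap | no exonic base shared with a known transcript, either strand | intron-only overlap is allowed |
| coding potential | longest ORF < 300 nt | inclusive: 300 nt is coding |

Three of these needed a decision the thresholds alone do not fix:

* **FPKM rule across samples.** Per-sample, mean or max is not implied
  by the threshold. We keep a transcript if its *maximum* FPKM reaches
  0.5: stage-specific lncRNAs — expressed only in lactation or only in
  the dry period — are precisely the objects of study, and a mean rule
  would discard them.
* **Strand-awareness of the overlap rule.** The removal of
  annotation-overlapping transcripts is *strand-agnostic* at exon
  resolution. If it were strand-aware, the antisense class could only
  contain exon-overlapping transcripts, which the coding-potential and
  expression rules treat poorly; if classification also required exonic
  overlap, antisense lncRNAs could never survive the cascade at all.
  Instead, classification is done after filtering: a survivor is
  *antisense* when its span overlaps a known gene's span on the opposite
  strand (exonic or intronic), otherwise *lincRNA*.
* **ORF threshold.** 300 nt (100 codons) is the conventional heuristic
  boundary for lncRNA annotation and matches the short-ORF profile such
  sets show; it is a configurable stand-in for external coding-potential
  tools. When external verdict files are supplied, a transcript is kept
  as non-coding only if the ORF rule *and every external tool* agree —
  one coding call from any source removes it.

ORF scoring scans the three forward frames of the strand-resolved
spliced sequence for ATG-initiated, stop-terminated frames and reports
the longest, counting the stop codon. A codon containing an ambiguous
base (N) neither starts, extends nor terminates an ORF: any ORF whose
span would contain such a codon is discarded, so ambiguity never
manufactures coding potential.

## Expression and the exact test

FPKM is computed from plain spliced length:
`fpkm = counts * 1e9 / (length * library_size)`. No effective-length
correction is applied; for the filter threshold and correlation use
made of FPKM here, fragment-length corrections change nothing
structurally and would import an aligner-specific notion of length.

Differential expression uses the conditional negative-binomial exact
test with a single common dispersion:

* Counts are equalized to the geometric-mean library size and rounded
  to pseudo-counts. TMM-style compositional normalization is
  deliberately not layered on top — with five libraries the extra
  estimation machinery is orthogonal to the test and the hook is left
  configurable.
* The common dispersion $\varphi$ (Var $= \mu + \varphi\mu^2$)
  maximizes the likelihood conditional on per-group totals, summed over
  features, via bounded 1-D search on $[0, 10]$; a boundary optimum
  returns $\varphi = 0$ (Poisson). With n = 5 there is far too little
  information for tagwise or trended dispersion — a documented
  limitation, not an oversight.
* Conditional on the total $S$, the group-A sum of i.i.d. NB variables
  with common $\varphi$ has an exactly computable null (group sums are
  NB with size $n_g/\varphi$, and the conditional law does not depend
  on the mean). The two-sided p-value sums the probabilities of all
  splits no more probable than the observed one ("small-p" rule, no
  doubling), capped at 1; $\varphi = 0$ reduces to a binomial null.
  Probabilities are accumulated in log space, with a $10^{-10}$ relative
  tolerance when comparing tied outcomes.
* Significance uses the raw p-value — |log2 FC| >= 1 and p < 0.05 — as
  the headline rule; a BH-adjusted column is emitted alongside for
  users who want FDR control. The 0.5 pseudo-count applied when a group
  mean is zero affects the *displayed* fold change only, never the test.

The test suite checks this implementation against two independent
routes: numeric convolution of per-sample pmfs for every 2-vs-3 split
with total <= 30 (at $\varphi \in \{0, 0.1, 0.5\}$, agreement to
$10^{-10}$), and a full joint enumeration of all compositions at a fixed
total. The dispersion estimator is cross-checked against the standard
qCML implementation in `edgeR`, which serves as oracle only — the
package never calls it in the analysis path.

## Target prediction

*Cis* targets are genes whose span lies within 100 kb of the lncRNA
span, strand-agnostic and boundary-inclusive, with the distance defined
as the count of bases strictly between the spans (0 when they touch or
overlap). The window is anchored on the whole lncRNA span rather than a
TSS: lncRNA TSS annotation from short-read assembly is unreliable, and
the genomic phrase "upstream and downstream" of a locus is naturally a
span extension.

*Trans* targets are DEL x DEG pairs with |r| > 0.95 (strict) and
p < 0.05 (strict) from the Pearson t-test on n = 5 FPKM values.
Correlations are computed on raw FPKM by default (log transform
available) to match how such profiles are conventionally screened. At
n = 5 the test is fragile by construction: a pair must be essentially
collinear to clear 0.95, and zero-variance profiles are skipped with a
logged count rather than aborting a run.

## Enrichment

One hypergeometric upper-tail test per term, computed by log-space
summation of `lchoose` terms; the background is the set of annotated
genes in the supplied mapping (reproducible from inputs, unlike a
whole-genome background). A term is flagged when the overlap is
*strictly greater than 5 genes* and p < 0.05; both thresholds and the
choice of raw versus BH-adjusted p are exposed per run, since GO-style
and pathway-style conventions differ. GO and KEGG mappings are treated
identically — both reduce to over-representation on a gene-to-term
table; the web tools' bespoke corrections are replaced by BH.

## qPCR concordance

Relative expression uses 2^-ddCt with the *arithmetic mean of the two
reference-gene Cts* (equivalent to geometric-mean normalization of
expression) and the DP group mean as calibrator — DP is the comparison
baseline throughout the design. PCR efficiency is fixed at 2. Two exact
invariances are tested: adding a per-sample constant to all Cts changes
nothing, and the two reference genes are exchangeable.

## The synthetic study

`simulate_lnc_study()` generates every pipeline input with planted
ground truth. Design parameters default to the study conditions: 2
chromosomes of 1 Mb, 100 coding genes, 40 true lncRNAs (30 lincRNA, 10
antisense), 10 decoys per failure mode, 2 LP vs 3 DP samples, planted
|log2 FC| = 2 on 30% of lncRNAs and genes, NB dispersion
$\varphi = 0.1$, library sizes around 20 million, 20 terms with one
planted enriched term, and Ct noise of 0.15 cycles.

Constructional guarantees replace rejection sampling wherever a
property must hold surely:

* Coding genes carry a planted ATG...stop ORF of >= 300 nt confined to
  the first 70% of the spliced sequence, so decoys that overlap a 3'
  exon tail cannot disturb it.
* Non-coding sequence is built from <= 240-nt random chunks separated
  by a 12-nt cassette containing TAG in all three frames, which provably
  caps any ORF below 300 nt — no rejection loop, any length.
* Antisense lncRNAs sit inside a host gene's (enlarged) first intron on
  the opposite strand: span overlap without exonic overlap, so they
  survive the strand-agnostic overlap rule and classify as antisense.
  Exon-overlap decoys attach to a host's 3'-most exon on *both* strands
  to exercise the rule's strand handling.
* Low-FPKM decoys are drawn truncated below the FPKM = 0.5 count
  threshold in every sample; all other candidates are conditioned on
  clearing it in at least one sample. Planted DE features get a
  baseline-mean floor of 50 so the planted effects sit in the regime
  the power analysis describes.
* Trans pairs share their per-sample expression state: members are
  drawn Poisson($\mu \cdot G_s \cdot e^{z_s}$) with
  $G_s \sim$ Gamma($1/\varphi$, $\varphi$) and a mild
  $z_s \sim N(0, 0.25)$ shared within a hub, and partner genes take the
  hub's DE sign. Each member's marginal remains NB($\mu$, $\varphi$),
  so DE power is unaffected, while the pair correlation is limited only
  by Poisson noise (median r about 0.999 at the hub base mean of 500).
  An *independent-noise* latent factor cannot achieve
  P(|r| > 0.95) >= 0.9 at n = 5 under $\varphi = 0.1$ — measured
  recovery plateaus near 0.6–0.86 even at extreme factor spreads —
  which is why the shared-state construction is used.
* Each generator stage draws from its own RNG stream derived from the
  master seed by stage name, so adding a stage never perturbs earlier
  stages' draws; all outputs are byte-identical under a fixed seed.

What the generator does *not* emulate: read-level artifacts (FASTQ,
mapping bias, duplicates), GC and length biases, batch effects,
multi-isoform genes, overlapping gene models, chained or partial
assembly errors, and tagwise dispersion heterogeneity. Passing
planted-truth tests therefore demonstrates that the *analysis logic* is
correct under the stated model, not that the pipeline is robust to all
failure modes of real assemblies; the filter cascade in particular sees
decoys that each violate exactly one rule, whereas real noise violates
several at once (which is easier to catch).

## Problem sizes and numerical choices

Test and acceptance runs use the default study scale (2 Mb genome, 190
transcripts, 5 samples) plus reduced configurations (24 genes, 250 kb
chromosomes) for module-level checks; oracle sweeps cover all 2-vs-3
splits with totals up to 30, and Monte-Carlo checks use 1,000–10,000
replicates — sizes at which every stated tolerance is resolvable in
seconds to a few minutes on one CPU. Ties in the exact test are compared
with a $10^{-10}$ log-space tolerance; hypergeometric tails and NB
conditional laws are accumulated in log space; optimization tolerances
are $10^{-6}$ on $\varphi$. Degenerate inputs have defined behavior
rather than errors where a run should continue (zero-variance
correlation pairs are skipped and counted; an all-zero count feature
gets p = 1), and hard errors where silence would corrupt results
(missing FPKM rows, unknown strand, malformed GTF lines with their line
numbers).

## Known limitations

Common dispersion only; raw-p DE calls as the headline rule; no
effective-length FPKM correction; correlation on n = 5 is inherently
unstable and the |r| > 0.95 screen should be read as a shortlist, not
an inference; enrichment ignores term topology (GO DAG, pathway
structure); the network export computes no statistics beyond degree.
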