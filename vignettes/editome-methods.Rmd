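---
title: "Comparative A-to-I editome analysis: model, assumptions, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative A-to-I editome analysis: model, assumptions, and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological question and the computational model

ADAR1 deaminates adenosine to inosine in double-stranded RNA, and sequencers
read inosine as guanosine. A-to-I editing therefore shows up in RNA-seq as an
A>G mismatch against the genome on the transcribed strand, or as T>C in
reference coordinates when the edited adenosine lies on the minus strand. The
confound is germline variation: a heterozygous A/G SNP looks exactly like a
50%-edited site. The pipeline implemented here follows the standard RNA–DNA
difference design:

1. **Germline masking.** Whole-exome base-count pileups are scanned and any
   position with adequate DNA depth and a non-reference allele fraction at or
   above a threshold is masked (`call_exome_snps()`); an externally supplied
   known-variant list can be merged in (`merge_known_variants()`). Positions
   whose DNA evidence never reaches the depth threshold are recorded as
   *unassessable* and, by default, excluded from calling — a conservative
   choice, since editing there cannot be distinguished from an unexamined
   variant.
2. **Per-animal edit calling** (`call_edit_sites()`). Inside a gene of known
   strand only the strand-consistent change is eligible; intergenic positions
   accept either orientation and are reported as unstranded, because without
   an annotated transcript the edited strand is unknowable. A call requires
   depth ≥ 10, ≥ 3 variant reads, and an editing fraction in [0.05, 0.95];
   the upper bound removes residual homozygous variants. A position where a
   third base reaches 5% of reads is flagged *complex* and dropped as a
   likely unmasked variant or alignment artifact.
3. **Replicate consensus** (`consensus_sites()`, `consensus_genes()`). A
   *site* counts for a genotype only if the identical coordinate-and-change
   is called in all replicate animals. A *gene* counts if every animal has at
   least one passing call anywhere in the gene's full span — UTRs, exons and
   introns — so a gene can reach consensus through different sites in
   different animals. Site identity includes the change, so A>G and T>C
   events at one coordinate are distinct sites (they imply different edited
   transcripts). A k-of-n relaxation exists but the all-animals rule is the
   default and the one used throughout.
4. **Annotation** (`assign_features()`). Each consensus site gets exactly one
   feature class with precedence 3'UTR > 5'UTR > CDS > intron, else
   intergenic. The precedence puts UTRs first because 3'UTR editing is the
   biologically salient compartment in this comparison; a base annotated as
   both exon and UTR is reported as UTR. Repeat-element class (SINE, LINE,
   DNA transposon, other retrotransposon) is assigned independently — a site
   can be both intronic and inside a SINE — with ties broken by the smallest
   overlapping element, then alphabetically.
5. **Comparison** (`venn_partition()`, `unique_sets()`, `percent_change()`).
   Consensus gene and site sets from the four genotypes are partitioned into
   the 15 exclusive Venn cells; the singleton cells are the uniquely edited
   sets; site counts are expressed as percent change against the wild-type
   baseline.
6. **ISG statistics** (`isg_edit_proportion()`, `deg_isg_summary()`).
   Interferon-stimulated-gene membership is always an input list, never
   computed, because ISG catalogues are external, versioned resources. The
   enrichment question — are a genotype's uniquely edited sites
   over-represented in ISG transcripts relative to its shared sites? — is a
   2×2 exact test, computed by hypergeometric enumeration (two-sided, summing
   all tables with fixed margins whose probability does not exceed the
   observed table's). The sample odds ratio is reported, with a
   Haldane–Anscombe-corrected version for degenerate margins. Intergenic
   sites carry no transcript and are excluded from this test.

A thin orchestration layer (`run_pipeline()`, `validate_inputs()`,
`simulate_study()`) runs the stages file-to-file with a manifest for
provenance; rerunning an identical configuration reproduces byte-identical
outputs.

## The synthetic study and what it does (and does not) emulate

Editome comparisons of this design need animal-scale RNA-seq and exome data,
which cannot be regenerated at desk scale; the package therefore carries a
first-class generator whose defaults *are* the study conditions every test
and the acceptance script use:

* **Design**: 4 genotypes (`WT`, `Adar_het`, `RdRp_tg`, `DoubleHet`) × 4
  animals.
* **Genome**: two 250 kb contigs; 200 genes with 100 bp 5'UTR, 2–3 CDS exons
  of 200 bp, 300 bp introns and a 300 bp 3'UTR; repeat elements at 120
  SINE, 60 LINE, 30 DNA-transposon and 30 other-retrotransposon copies per
  Mb, free to overlap genes as in real genomes. The slim gene structure is
  deliberate: with ~2.5 genic shared sites per gene, gene-level consensus is
  informative rather than saturated, so uniquely edited *genes* (not just
  sites) can exist, mirroring the four-way overlap structure of the original
  comparison.
* **Colony variation**: 200 germline SNPs, half heterozygous, shared by all
  animals and visible in both DNA and RNA evidence.
* **Editing regime**: 1000 shared sites edited in every genotype plus a
  DoubleHet-unique pool of round(0.575 × 1000) = 575 sites — the midpoint of
  the 50–65% excess window that characterises the double heterozygote.
  Per-site editing fractions are uniform on (0.2, 0.8). Placement weights:
  intergenic 0.5, 3'UTR 0.3, CDS 0.1, intron 0.1 — edits concentrate in
  intergenic space and 3'UTRs, with exons and introns represented about
  equally.
* **Sequencing**: depth Poisson(50) for RNA and Poisson(40) for DNA,
  truncated at ≥ 1; symmetric substitution errors at rate 0.005, i.e. each
  non-template base at 0.005/3 per read. The error model is chosen so the
  A>G signal separates from noise analytically.
* **ISG regime**: 20% of genes are ISGs; their expression multipliers are 1,
  1, 2 and 8 for WT, Adar_het, RdRp_tg and DoubleHet — the double
  heterozygote at four-fold the RdRp transgenic, inside the three-to-five-fold
  window that motivates the comparison.

All randomness flows from one seed; stages and animals use fixed offsets from
it, so identical configurations give byte-identical FASTA, BED, TSV and JSON
outputs.

Deliberate simplifications, and hence the limits of what green tests show
about real data: coverage is homogeneous (no mappability or GC structure);
errors are independent and symmetric (no strand bias, no base-quality
structure); there is no alignment step, so no misalignment artifacts and no
hyper-edited reads lost to mapping; the simulated "exome" covers the whole
toy genome so intergenic positions are assessable for germline variation
(real exome capture would leave most intergenic DNA unassessable, and the
conservative drop-unassessable default would then bite); expression level and
RNA coverage are decoupled, keeping the binomial detection model exact;
splicing, hyper-editing clusters and read-level simulation are out of scope.

## The analytic detection oracle

For a site with editing fraction $f$, the per-read variant probability is
$p = f(1-e) + (1-f)\,e/3$ with error rate $e$. Marginalising over truncated
Poisson depth $d$, the per-animal detection probability is

$$P(\text{call}) = \sum_{d \ge d_{\min}} w_d
  \Pr\!\big[k_{\min}(d) \le B(d, p) \le k_{\max}(d)\big]
  \big(1 - \Pr[B(d, e/3) \ge \lceil c\,d\rceil]\big)^2$$

where $k_{\min}, k_{\max}$ encode the variant-read and fraction-window
thresholds and the final factor is the probability of surviving the
complex-site filter ($c = 0.05$) on each of the two non-variant non-reference
bases, treated as independent of the variant count — an approximation
verified against Monte Carlo to within the sampling error of $2\times 10^5$
draws. `detection_probability()` implements this; the expected consensus
count for a genotype is $\sum_i P_i^{4}$ over its applicable sites, and the
expected consensus gene count follows from
$\big(1 - \prod_{i \in \text{gene}} (1 - P_i)\big)^{4}$. The companion
`false_positive_probability()` uses the same machinery with $p = e/3$ and
*omits* the complex factor, making it a deliberate upper bound for one-sided
comparisons of empirical false-positive rates.

Two numerical points about the recovery tests. Expected per-animal miss
counts under the defaults are below one, where a normal ±3 SE band is
meaningless for a count; per-animal checks therefore use exact Poisson
prediction intervals (99.95%), while pooled checks across all 16 animals use
the stated 3 SE. And "detectable" DoubleHet-unique sites — the denominator of
the unique-set recovery check — are those with consensus probability
$P_i^4 \ge 0.5$.

## Differential-expression plumbing

`minimal_deg_call()` exists so the ISG summary logic can be exercised end to
end on synthetic data: per-gene log2 fold change of group means with one
pseudocount, an exact two-sample Wilcoxon rank test, and Benjamini–Hochberg
adjustment. It is documented as a stand-in, not a count-model DE method. With
four animals per group the exact rank test's smallest attainable two-sided p
is $2/70 \approx 0.029$, so BH-adjusted significance below 0.05 is
unattainable by construction whenever fewer than roughly half the genes
respond; the qualitative concordance test (more responsive genes in the
DoubleHet contrast than the RdRp contrast) therefore uses a permissive
adjusted-p threshold of 0.2. Real analyses should substitute a dedicated DE
table — the pipeline accepts one as input and never recomputes it if given.

## Numerical and format conventions

Coordinates are 1-based inclusive everywhere inside the package; BED files
are 0-based half-open on disk and converted exactly once at read/write time,
with the round trip under test. VCF output is minimal (CHROM/POS/ID/REF/ALT
plus INFO); editing fractions are recomputed from variant reads over depth on
read, so call round trips are exact in every field. Venn cells are reported
for all $2^4 - 1$ label combinations including empty ones. Thresholds are
exposed in `pipeline_config()` and defaulted to the values above; they are
conventions of standard RNA-editing practice, not estimates. Degenerate
inputs follow explicit contracts: empty genotypes summarise to zero counts
without error, a zero baseline makes percent change an error rather than an
Inf, an all-intergenic site set makes the ISG proportion an error, and ties
in annotation are broken deterministically (smallest interval, then
alphabetical), so repeated runs are identical.

## Problem sizes used by the test suite

Unit and property tests run on a small colony (two contigs of 30 and 20 kb,
16 genes, 120 shared sites); the recovery and concordance suites and the
acceptance script regenerate the full default conditions above (half a
megabase, 16 RNA pileups of ~500k records each) and finish in a few minutes.
Brute-force oracle comparisons run at up to a few thousand randomized
positions against naive linear-scan reimplementations, within the instance
sizes where exhaustive checking is exact.
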