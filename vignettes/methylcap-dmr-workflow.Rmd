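---
title: "Calling and annotating condition-specific DMRs from methylCap-seq coverage"
author: "capdmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and annotating condition-specific DMRs from methylCap-seq coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capdmr)
library(GenomicRanges)
```

## The analysis problem

Methyl-CpG capture sequencing (methylCap-seq) enriches the methylated
fraction of a genome with a methyl-binding-domain column and sequences the
captured fragments. Coverage is therefore an *enrichment* signal: regions
with dense, heavily methylated CpGs accumulate reads, everything else sits
at a background rate set by library size. Comparing two pooled libraries —
a case (e.g. tumor) pool and a matched control pool — yields
*condition-specific hypermethylated regions* (DMRs), and the biology lives
in where those regions fall: in CpG islands (CGIs) or in their 2-kb
flanking *shores*, in promoters with or without a CGI, in *orphan* CGIs
that belong to no annotated gene, near the TSS or deep inside gene bodies.

capdmr implements that full desk-side analysis as composable stages:

1. **Annotation** (`read_annotation`, `derive_shores`,
   `derive_promoters`): gene models and CGI tracks in, derived shores and
   promoter windows out.
2. **Peak calling** (`estimate_background`, `call_peaks`): binned coverage
   in, confidence-scored hypermethylated peaks out.
3. **Dual-threshold screen** (`extract_specific`): two peak sets in,
   case-specific / control-specific / common regions out.
4. **Context classification** (`classify_primary`,
   `classify_subcontexts`, `classify_cgi_feature`, `classify_orphan`,
   `gene_venn`, `split_promoters`, `tss_metaprofile`).
5. **Reporting** (`build_report`, `write_report`) and small wet-lab
   calculators (`bsp_fraction`, `msre_methylation`, `ddct_expression`).
6. **Simulation** (`sim_config`, `make_toy_bundle`,
   `plant_and_simulate`): a synthetic two-condition experiment with known
   truth, used throughout the test suite.

`run_pipeline(pipeline_config(...))` chains stages 1–5 (optionally fed by
stage 6) deterministically under one seed.

## The peak model and its confidence score

Read pileup is summarised as fragment counts per fixed-width bin (50 bp by
default). Outside methylated regions counts are modelled as Poisson with a
single genome-wide rate $\lambda$, estimated by a 1%-trimmed mean of all
bins — the trim discards both dropout bins and the hypermethylated tail,
and with ~40,000 bins on the default toy genome the estimate is accurate
to a few percent.

Each bin receives the confidence

$$c = P(X \le \mathrm{obs} - 1), \qquad X \sim \mathrm{Poisson}(\lambda),$$

the probability that background falls *strictly below* the observation.
The strict convention fixes tie handling and guarantees an observation of
zero can never score above zero. Qualifying bins (those at or above a
confidence threshold) merge into peaks when their gaps are narrower than
`merge_gap_bp`; a peak's confidence is the maximum over its qualifying
bins, and peaks spanning fewer than `min_peak_bins` bins (default 2) are
dropped.

This caller is deliberately minimal and is labelled in every output as a
stand-in: it does no fragment-model building, no mixture fitting, and no
peak-level FDR. All the downstream screen needs is a monotone per-region
confidence in $[0,1]$, and a one-parameter Poisson model supplies that
transparently. Because the Poisson is discrete, the screen is
conservative: at threshold 0.975 the null qualifying-bin rate is about
1.4% rather than the nominal 2.5% (the test suite asserts the bound).

## The dual-threshold screen

The screen takes two confidence thresholds, a high one (0.975) and a low
one (0.950). A region is **case-specific** when it is covered by case
peaks at confidence ≥ 0.975 *and* not covered by control peaks at
confidence ≥ 0.950; control-specific is the mirror image; the intersection
of the two low-threshold covers is the **common** methylation shared by
the conditions. The published description of the strategy states the two
thresholds and their purpose (suppressing false DMR calls); the veto
reading implemented here — strong evidence in the focal condition, absence
of even weak evidence in the other — is the interpretation that is
conservative in exactly that direction, and it is what `extract_specific`
documents and tests.

Subtraction operates at base resolution by default: an overlapped peak is
trimmed, not discarded, and fragments shorter than `min_length_bp`
(default 100 bp) are dropped and counted in the run log. Because "removing
the common peaks" is also readable as whole-peak removal, a
`mode = "whole_peak"` switch discards any high-confidence peak that
overlaps the other condition's low cover by even one base; both modes are
oracle-tested.

One numerical choice matters here. Peaks that feed the screen are called
*without* gap bridging (`screen_merge_gap_bp = 0`: only adjacent
qualifying bins merge), while reported peak sets bridge sub-200-bp gaps as
usual. Bridging is harmless for presentation but poisonous inside the
veto: a bridged control peak contains interior bins with *no* evidence at
all, and subtracting those bases erodes genuine case-specific regions.
Under the default background (Poisson 5 per 50-bp bin) two spurious
control bins within 200 bp of each other arise every few kilobases, and
each such pair would veto a ≥250-bp span. Screening on unbridged covers
keeps the veto exactly as large as the evidence.

## Genomic-context classification

All classification is overlap-based (≥ 1 bp) over a validated
`annotation_bundle`:

* **Primary context** — `TSS` if the region overlaps any gene's symmetric
  TSS window (±2 kb by default), else `intragenic` on gene-body overlap,
  else `intergenic`. The priority order makes the labels a partition, so
  the three counts always sum to the number of DMRs.
* **Subcontexts** — promoter window (default −2000/+500 around the TSS,
  strand-aware, configurable; the structural category is standard but no
  universal window exists, so the default is declared rather than
  inherited), 5′ UTR, exon, intron (gene-body union minus exon union),
  downstream (2 kb past the 3′ end, strand-aware), enhancer (only when a
  track is supplied), miRNA (miRNA gene bodies). Multiple labels may
  attach.
* **CGI feature** — `cgi`, `shore`, `cgi_and_shore`, or `none`. Shores
  are the 2-kb flanks of merged islands with *all* island bases excised,
  including a neighbouring island's: islands and shores partition their
  bases, which the Venn-style gene tallies rely on.
* **Orphan status** — an island is gene-associated iff it overlaps a gene
  body or a gene's association window (upstream reach configurable,
  default equal to the promoter upstream); otherwise orphan.
* **Gene Venn** — each DMR is attributed to *every* gene whose body or
  association window it overlaps; a gene's category (island and shore /
  island only / shore only) pools all its attributed DMRs. Gene counts
  and DMR counts are reported separately because the attribution is
  many-to-many.
* **Promoter split** — promoter-overlapping DMRs partitioned by whether
  an overlapped promoter window contains island bases; a DMR touching
  promoters of discordant status counts once, in the with-CGI arm (a
  declared tie rule, covered by a test).
* **TSS metaprofile** — for every gene and every peak inside ±5 kb of its
  TSS, each covered profile bin is incremented, strand-oriented so
  negative offsets are upstream for minus-strand genes too.

## What the simulator emulates — and what it does not

`make_toy_bundle` builds a small linear genome (one 2-Mb chromosome by
default) with non-overlapping gene models, promoter-associated CGIs on a
random subset of protein-coding genes, and orphan CGIs placed so far from
every gene (association window + shore width + margin) that their orphan
status holds by construction. `plant_and_simulate` then plants
hypermethylated regions — 20 case-specific, 20 control-specific and 20
common by default, 1 kb each, bin-aligned — inside deliberately chosen
context masks (CGI promoter, CGI-free promoter, shore, orphan island,
intragenic, intergenic), and draws bin counts as Poisson(5) background
with a 6-fold mean multiplier inside planted regions of the matching
condition(s). A dedicated `spike` contig carries fully methylated
fragments (enriched in both conditions) and unmethylated fragments
(background in both), mirroring the exogenous spike-in control used to
verify capture specificity; their mean-coverage ratio sits near the
enrichment factor.

Those defaults are the reference study condition for every recovery
statement the package makes: under them, planted regions are recovered
with per-region Jaccard ≥ 0.8 and every planted context label is
recovered exactly (asserted in the acceptance tests, measured afresh by
`scripts/acceptance.R`).

The simulator deliberately does **not** emulate: individual reads,
alignment or duplicate-removal artifacts (counts are generated directly at
bin resolution); fragment-length or GC effects; CpG-level methylation
(capture data cannot resolve it anyway); within-pool heterogeneity (each
condition is one pooled library, matching the pooled design the analysis
targets); chromatin context or copy-number variation. Passing the
recovery tests therefore demonstrates the correctness of the interval
logic and the screen under the stated noise model — not performance on
real libraries, where background is overdispersed and enrichment varies
continuously. The Poisson caller's conservatism is the main safeguard the
package offers against that gap, and `call_peaks` accepts any
externally computed confidence via `read_peaks` if a stronger caller is
available.

## Numerical choices and degenerate inputs

* Coordinates are BED (0-based half-open) in every file read or written;
  in memory everything is a `GRanges` (1-based closed). The conversion
  happens exactly once, at the parser/writer boundary, and a round-trip
  test pins it.
* Windows are clipped to chromosome bounds everywhere; a promoter window
  at a chromosome start simply loses its out-of-range bases.
* Empty inputs are values, not errors: an empty CGI list yields an empty
  shore set, an empty screen yields empty DMR sets and an all-zero report
  with suppressed percentages (no division by zero).
* All-zero coverage *is* an error in `estimate_background` (there is no
  signal to calibrate against), as are same-condition peak sets in
  `extract_specific`, unstranded genes in `derive_promoters`, and
  infeasible placement requests in the simulator (a "capacity" error,
  not an infinite loop).
* The chi-square in the report is plain Pearson by default; Yates
  correction is a flag and the report records which was used. The 2×2
  construction (genes hypermethylated via a CGI vs via a shore alone,
  case vs control) is declared in the output, since published analyses of
  this design do not always print the table behind their test.
* Replicate Cts in `ddct_expression` are averaged before differencing
  (geometric mean of quantities); per-replicate folding is an option.
  MSRE fractions clamp to [0, 1] with a warning because qPCR noise
  routinely produces slightly negative cycle shifts.

## Problem sizes

The test suite and the acceptance script run entirely on simulated data:
a 2-Mb toy chromosome (40,000 bins of 50 bp) for end-to-end recovery, 1-Mb
chromosomes for the per-base oracle checks (shore derivation, screen
subtraction), and a few hundred random regions per classifier oracle.
These sizes keep each property check in seconds while leaving every
code path — including chromosome-boundary clipping and the spike contig —
exercised. The stages are linear in bins and regions; scaling the same
code to a real genome is a matter of memory for the bin vectors (3 × 10⁹
bp / 50 ≈ 6 × 10⁷ bins per condition), not of algorithm.

## Known limitations

* The caller's single Poisson parameter understates real library
  overdispersion; on real data its confidences are optimistic and the
  conservative dual-threshold screen compensates only partially.
* One TSS per gene model: no transcript isoforms, hence no alternative
  promoters.
* Enhancers are an optional input track, never predicted.
* Gene-set enrichment is a generic hypergeometric test with
  Benjamini–Hochberg adjustment over user-supplied sets; it does not
  parse ontologies and will not reproduce results of web-service
  enrichment tools with curated backgrounds.
* The headline genome-scale counts of any real study (tens of millions of
  reads, hundreds of thousands of peaks) depend on the real libraries and
  are out of scope for a simulation-backed package; what is reproduced is
  the *arithmetic* of the published ratio splits and every structural
  property of the method.

## A complete run

```{r, eval = FALSE}
cfg <- pipeline_config(simulation = sim_config(seed = 1), seed = 1,
                       out_dir = "capdmr_run")
run <- run_pipeline(cfg)
print(run$report)

# recovery against the planted truth
jac <- region_jaccard(run$truth$planted_case,
                      run$extraction$case_specific$regions)
summary(jac)
```

Every artifact (truth BED, coverage bedGraphs, peak BED6+1, DMR BED4,
annotation TSVs, metaprofile TSV, JSON report and config echo) lands in
`out_dir`, and rerunning with the same config reproduces the files
byte-identically.
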