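---
title: "Streamlined PWS/AS molecular diagnostics: methods and design"
author: "pwsasdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Streamlined PWS/AS molecular diagnostics: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwsasdx)
```

## The diagnostic problem

Prader–Willi syndrome (PWS) and Angelman syndrome (AS) are reciprocal
imprinting disorders of chromosome 15q11-q13: PWS follows loss of the
paternally expressed genes of the region, AS follows loss of maternal
*UBE3A* expression. The same phenotype can arise from a recurrent
multi-megabase deletion (type I spanning BP1–BP3, type II spanning
BP2–BP3, or atypical), from uniparental disomy 15 (UPD — segmental
isodisomy, total isodisomy, or heterodisomy), from an imprinting-center
(IC) defect (microdeletion or epimutation), or from a point mutation.
The mechanism determines recurrence risk and surveillance, so a
diagnostic workup should establish it, not just the diagnosis.

`pwsasdx` implements an integrated workflow over data a clinical
laboratory already produces: methylation-sensitive MLPA (MS-MLPA) as
step 1, then three analyses of whole-exome sequencing (WES) data — small
variants (supplied as interpreted findings), exon-level copy number, and
absence of heterozygosity (AOH) — combined by a deterministic decision
procedure into a mechanism call with an evidence trail.

## Coordinate conventions and the region registry

All coordinates are GRCh37, 1-based and inclusive at both ends; BED
input (0-based half-open) is converted at the boundary. The registry
(`load_region_registry()`) carries:

* the 5-Mb critical region chr15:22,892,936–27,892,936 around *SNRPN*
  (contains *SNRPN* and *UBE3A*);
* the 16 region genes in genomic order with breakpoint-zone tags —
  *TUBGCP5*, *CYFIP1*, *NIPA2*, *NIPA1* in BP1–BP2; *MKRN3* … *HERC2*
  in BP2–BP3; *APBA2* distal;
* BP1/BP2/BP3 positions, per-chromosome centromere intervals and
  lengths, and a segmental-duplication mask.

Gene, breakpoint, and centromere base positions are a *curated* GRCh37
default from standard annotation, user-overridable via YAML; the
classification logic depends only on gene ordering and zone membership.
The shipped segmental-duplication mask covers the BP1/BP2/BP3 flanks; an
empty mask is valid and simply ignores nothing.

## AOH detection

Variants are categorized homozygous (two identical non-missing alleles),
heterozygous, or ignored (inside the segdup mask); missing and
half-calls are dropped. Maximal runs of neighboring non-ignored
same-zygosity variants form intervals per chromosome; interval spans run
from the first to the last supporting variant (the alternative
midpoint-between-discordant-flanks convention inflates sizes and is not
used). Runs never span a centromere; a variant exactly on a centromere
boundary belongs to the arm containing it. Ignored variants never affect
interval formation but are tabulated per span. The X chromosome is
excluded for 46,XY specimens.

Decision rules, with their parameters (all arguments of `detect_aoh()`):

* **Critical-region positivity**: fewer than 4 heterozygous SNVs
  (`PASS`-or-missing FILTER by default; indels form intervals but never
  count toward this tally) in the critical region. Controls average 42.5
  heterozygous variants (SD 12.76, observed minimum 16), putting 4 about
  3 SDs below the mean.
* **Reporting floor** 1.5 Mb: homozygous blocks below it are common in
  normal genomes and are not reported.
* **LOH / UPD consistency**: a 15q homozygous block strictly > 5 Mb
  qualifies when the methylation signal is abnormal; without methylation
  support the threshold is ≥ 8 Mb.
* **Minimum block support** (`min_block_variants = 20`): a block must
  rest on at least 20 supporting variants before it can enter the LOH or
  consanguinity rules. Runs-of-homozygosity callers apply the same kind
  of minimum-marker guard; a handful of consecutive homozygous calls
  spanning megabases at low marker density is an artifact, not AOH.
* **Consanguinity**: qualifying blocks (≥ 5 Mb, supported) on two or
  more autosomes other than 15 suggest identity by descent rather than
  UPD; one extra chromosome can be an isolated event, several cannot.
  The flag vetoes the UPD interpretation.
* **Total vs segmental isodisomy**: qualifying blocks covering ≥ 95% of
  the analyzable (variant-covered) 15q span are total isodisomy,
  otherwise segmental (count, sizes and locations reported). The 0.95
  boundary is a configurable default; no published value exists.

## Exon-level CNV calling

Coverage is **doubly normalized**: each specimen column is divided by
its own median across all targeted exons (median rather than mean so the
statistic is robust to the CNV being sought), then the specimen's value
at each exon is compared with the comparator mean and SD at that exon.
Comparator statistics use the comparators only — the test specimen never
contributes to its own reference. A minimum of four comparators is
required; exons whose comparator mean is zero are excluded and logged;
exons with zero comparator SD and a non-zero deviation have no defined
Z and are excluded with a warning (exact agreement is Z = 0).

Exons with ratio < 0.8 or > 1.2 (strict inequalities; the boundary
values are not flagged) are potential deletions/duplications. Contiguous
same-direction flagged exons are grouped; contiguity means adjacent rows
of the design table and by default breaks at gene boundaries
(`break_on_gene = FALSE` uses pure row adjacency — the downstream extent
classification unions genes across segments, so the pipeline result is
the same either way). Because the Z scores are treated as independent,
the group score is the Stouffer combination |ΣZᵢ|/√k; a simple sum of
|Z| would let long mediocre runs reach any threshold and is not used. A
group is positive at combined score ≥ 5 SD with at least one exon at
ratio ≤ 0.6 (deletions) or ≥ 1.4 (duplications). Positive groups of
fewer than 12 exons are marked `confirmation_required` and the
classifier treats them as confirmed only when MLPA copy number agrees —
short NGS CNV calls have low positive predictive value, and MLPA is the
designated orthogonal confirmer; runs of ≥ 12 consecutive exons stand on
their own.

The QC gate (`cnv_qc_gate()`) marks a specimen `cnv_fail` instead of
analyzing it when comparators are short, the specimen median raw
coverage is below 30× or the robust dispersion (scaled MAD) of per-exon
ratios exceeds 0.3. MAD rather than SD because a genuine CNV over part
of the target inflates the SD but is not noise. The 30× floor and 0.3
ceiling are package defaults chosen to pass clean batches and fail
degraded archival DNA; they are exposed as arguments.

Deleted gene content classifies extent: type I when the BP1–BP2 genes
are deleted together with the BP2–BP3 block (anchors *MKRN3*, *SNRPN*,
*UBE3A*, *HERC2*), type II when the BP2–BP3 block is deleted with all
BP1–BP2 genes intact, SNRPN-only when the deletion is confined to the
*SNRPN*/IC span, atypical for other multi-gene patterns, single-gene
otherwise.

## MS-MLPA interpretation

Copy-number probes call deleted at ratio ≤ 0.7 and duplicated at ≥ 1.3
(the ubiquitous MLPA convention; configurable). The region summary needs
deleted probes in ≥ 2 distinct region genes for `deletion_multi_gene`,
deleted probes confined to *SNRPN* for `deletion_snrpn_only` (the IC
microdeletion signature), and reports one deleted non-*SNRPN* gene as
`deletion_single_gene`.

Methylation probes (five, targeting *SNRPN* and *MAGEL2* only) are
banded: 80–100 is the PWS-consistent band (loss of the paternal allele),
40–60 the control band. Only those two bands are established reference
ranges; the AS band defaults to [0, 20] and is labeled as a configurable
default. Values above 100 are clamped with a warning. The pattern is the
majority call across probes — multiple probes over two imprinted genes
are the assay's advantage over single-probe methylation PCR — and a tie
or no in-band probe is `uninterpretable`.

## Integrated classification

The decision procedure (`classify_mechanism()`) follows the clinical
workflow order. With a **normal** methylation pattern only a supplied
pathogenic/likely-pathogenic variant makes a diagnosis: *SNRPN* → PWS
point mutation, *UBE3A* → AS point mutation, *MAGEL2* → caveat
(possible Schaaf–Yang syndrome if paternally defective); anything else
is negative. Variant pathogenicity assertion is out of scope — findings
arrive as metadata.

With an **abnormal** pattern the syndrome follows parent-of-origin
(paternal loss ⇒ PWS, maternal ⇒ AS) and the mechanism resolves in
order: confirmed multi-gene deletion → deletion class by extent (when
the CNV arm failed QC, extent is derived from the deleted MLPA probes);
SNRPN-confined deletion → IC microdeletion; otherwise UPD-consistent
AOH → segmental or total isodisomy; otherwise the **indeterminate
disjunction** "heterodisomy or IC epimutation", always carrying the
caveat that only genotyping of chromosome 15 markers in parental DNA
can separate them — the call never asserts heterodisomy definitively.
Where WES CNV and MLPA copy number disagree on a deletion, MLPA wins;
unconfirmed short WES segments are downgraded to caveats. AOH positivity
over a confirmed deletion is attributed to hemizygosity, not UPD.
Mosaicism is not called; intermediate signals surface as caveats.

Reports (`render_report()`) are deterministic JSON + text containing the
call, per-module evidence, every threshold in force, and caveats; a
structural schema ships with the package.

## The synthetic-specimen generator

`generate_specimen()` emits seed-reproducible bundles
(VCF + coverage TSV + MLPA TSV + metadata) whose statistical structure
matches what the detectors assume, per mechanism class:

* **Heterozygous-count model** (printed control statistics): critical
  region counts drawn from normal(42.5, 12.76), rounded, floored at 16
  (the observed control minimum) — this floor is what guarantees control
  specificity.
* **Events**: deletions emit ratio-0.5 coverage over the deleted span
  (type I BP1–BP3, type II BP2–BP3, IC microdeletion
  chr15:25,200,019–25,223,890), no heterozygotes inside the span, and
  deleted MLPA probes; isodisomy emits copy-neutral homozygous-only
  spans (segmental: 12.4 Mb over the critical region; total: the whole
  15q arm); heterodisomy/epimutation emit normal zygosity and copy
  number; a consanguinity recipe plants supported homozygous blocks on
  chr2, chr7 and chr15 with normal methylation.
* **Coverage**: per-exon lognormal baseline (median 100×, sdlog 0.25),
  multiplicative normal noise SD 0.05, per-specimen library-size factors,
  8 comparators. The design holds the 16-gene 15q panel plus a
  whole-exome backbone of background targets so the intra-specimen
  median stays anchored in copy-neutral territory even under a full
  BP1–BP3 deletion, as it does in a real exome. CNV-fail injection
  scales the specimen to ~12× so the QC gate fires organically.
* **Methylation emission**: band midpoints with ±5 uniform jitter (PWS
  90, normal 50, AS 10), keeping every draw inside its band.
* **Background variants** (invented; nothing printed to anchor them): a
  *thinned* exome representation — ~1.1 markers/Mb off chromosome 15
  with heterozygous fraction 0.9, ~4.3/Mb on 15q with fraction 0.8. The
  thinning preferentially keeps heterozygotes so that chance runs of
  homozygosity ≥ 5 Mb remain as improbable at the thinned density as
  they are in real dense exome data; together with the detector's
  minimum-block-support guard this keeps the consanguinity flag and the
  heterodisomy path free of false isodisomy.

`generate_validation_cohort()` builds the 28-specimen validation cohort
(4 type I + 5 type II + 5 segmental + 5 heterodisomy + 5 total + 2 IC
microdeletion + 2 epimutation; 12 male / 16 female), by default with
five CNV-fail specimens (three total-isodisomy, two heterodisomy)
mirroring the archival-DNA failure pattern. The truth label lives only
in the manifest, never in the data files.

**What the generator does not emulate**: linkage disequilibrium and
realistic variant density, population ROH structure, GC-dependent
coverage waves, mosaicism, partial-methylation signals, MLPA probe
chemistry artifacts. Passing tests therefore demonstrate that the
algorithms implement their decision rules correctly under the stated
noise model — not clinical sensitivity on real specimens, which the
wet-lab validation figures describe and which are not reproducible at a
desk.

## Problem sizes and numerical choices

The test suite and acceptance script run the full pipeline on the
28-specimen cohort, a 297-control specificity screen, 20 seeds per
mechanism class for truth-label recovery, a 10,000-draw calibration of
the heterozygous-count rule, and 120 injected-deletion simulations for
the 12-exon sensitivity property — sizes chosen to give stable
proportions while keeping a laptop run in minutes. Size arithmetic uses
length/10⁶ Mb with "> 5 Mb" strict and "≥ 8 Mb" inclusive, exactly as
stated; `interval_length_kb()` truncates. Determinism: every stochastic
step is seeded; identical (recipe, seed) pairs yield byte-identical
bundles, and reports are byte-identical across repeated rendering.

## Known limitations

* Parental origin is inferred from methylation only; no trio genotyping,
  so heterodisomy vs epimutation stays a disjunction by design.
* No breakpoint refinement below exon resolution, no B-allele modeling,
  no genome-wide CNV catalog beyond the supplied target table.
* The AS methylation band and several QC thresholds are conventions or
  package defaults, not published reference ranges; all are exposed as
  arguments and echoed into reports.
* GRCh37 only; no liftover.
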