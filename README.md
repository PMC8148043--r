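# pwsasdx

Streamlined molecular diagnostics for Prader–Willi and Angelman syndromes
(PWS/AS) in R.

PWS and AS are reciprocal imprinting disorders of chromosome 15q11-q13.
The same clinical picture can arise from several molecular mechanisms —
the recurrent type I (BP1–BP3) or type II (BP2–BP3) deletion, maternal or
paternal uniparental disomy 15 (segmental isodisomy, total isodisomy, or
heterodisomy), an imprinting-center (IC) microdeletion or epimutation, or
a point mutation in *SNRPN*/*UBE3A* — and the mechanism matters for
counseling: IC microdeletions carry up to 50% recurrence risk, isodisomy
exposes recessive chromosome-15 disease, heterodisomy does not.
Historically resolving this took a serial cascade of assays. `pwsasdx`
implements the streamlined alternative: methylation-sensitive MLPA
(MS-MLPA) first, then three analyses of ordinary whole-exome sequencing
data, integrated into a single mechanism call.

## The method

For a specimen with variant calls (VCF, GRCh37), a per-exon coverage
table with ≥4 batch comparators, and an MS-MLPA probe table:

1. **MS-MLPA interpretation** — per-probe copy-number states
   (deleted ≤ 0.7 < normal < 1.3 ≤ duplicated) and the methylation
   pattern from the *SNRPN*/*MAGEL2* methylation probes (PWS band
   80–100, normal band 40–60; loss of the paternal allele ⇒ PWS, of the
   maternal allele ⇒ AS).
2. **Exon-level CNV calling** — coverage is doubly normalized: each
   specimen is divided by its own median across targeted exons, then
   compared per exon against the comparator mean and SD, giving a ratio
   and a Z score. Exons with ratio < 0.8 (deletion) or > 1.2
   (duplication) are flagged; contiguous same-direction exons are grouped
   with Stouffer-combined score |ΣZᵢ|/√k. Groups with combined score
   ≥ 5 SD and ≥1 exon at ratio ≤ 0.6 (or ≥ 1.4) are positive; calls under
   12 exons require orthogonal (MLPA) confirmation. Deleted gene content
   classifies the extent: type I (NIPA1/NIPA2/CYFIP1/TUBGCP5 deleted),
   type II (those intact), SNRPN-only (IC microdeletion signature), or
   atypical.
3. **Absence-of-heterozygosity (AOH) detection** — variants are
   categorized homozygous / heterozygous / ignored (segmental-duplication
   mask), maximal same-zygosity runs are formed per chromosome (never
   crossing a centromere), and the 5-Mb critical region
   chr15:22,892,936–27,892,936 is assessed: fewer than 4 heterozygous
   SNVs is AOH-positive (controls average 42.5, SD 12.76). A 15q
   homozygous block > 5 Mb with abnormal methylation (≥ 8 Mb otherwise)
   is LOH consistent with isodisomy — total if qualifying blocks cover
   ≥ 95% of the analyzable 15q, segmental otherwise — unless comparable
   blocks on ≥2 other autosomes indicate consanguinity.
4. **Mechanism classification** — the evidence is integrated in clinical
   order (methylation → copy number → AOH → supplied variant findings)
   into one of: type I/II/atypical deletion, IC microdeletion, segmental
   or total isodisomy UPD, the indeterminate disjunction
   "heterodisomy or IC epimutation" (resolvable only with parental DNA),
   point mutation, or negative — with an evidence trail and caveats.

A seed-reproducible synthetic-specimen generator emits class-consistent
VCF/coverage/MLPA bundles for every mechanism class, a 28-specimen
validation cohort (composition 4+5+5+5+5+2+2), and control cohorts.

## Worked example

```r
library(pwsasdx)
reg <- load_region_registry()

# synthesize a type II deletion specimen and classify it end to end
bundle <- generate_specimen(simulation_recipe("type_II_deletion", seed = 7),
                            dir = tempdir())
call <- classify_bundle(bundle, registry = reg)
print(call)
```

```
Mechanism call for SPEC000022902
  syndrome: PWS; mechanism: type_II_deletion; defective allele: paternal
  result: Type II deletion, paternal
  evidence:
    - MS-MLPA methylation pattern: loss_of_paternal
    - MS-MLPA copy-number summary: deletion_multi_gene (deleted: ATP10A, GABRA5, GABRG3, HERC2, MAGEL2, MKRN3, NDN, NPAP1, OCA2, SNRPN, UBE3A)
    - WES CNV extent class: type_II_deletion (11 positive segment(s))
    - AOH: 7 heterozygous SNV(s) in critical region (negative); UPD-consistent LOH: TRUE
    - Multi-gene deletion: WES CNV (type_II_deletion) confirmed by MLPA copy number
```

Reading: MS-MLPA shows loss of the paternal allele (PWS) with a
multi-gene 15q11-q13 deletion; exome coverage confirms the deletion and
types it (the BP1–BP2 genes NIPA1/NIPA2/CYFIP1/TUBGCP5 are intact ⇒
type II). The deletion leaves a > 5 Mb hemizygous homozygous block on
15q — LOH-consistent in isolation — but the confirmed deletion takes
precedence over a UPD interpretation. The critical region keeps 7
heterozygous SNVs because the type II breakpoint (BP2) lies inside the
5-Mb window. `call$report$json` holds the machine-readable report.

Real specimens go through `classify_specimen(mlpa = ..., vcf = ...,
coverage = ..., meta = ...)`; a thin command-line wrapper is in
`inst/cli/pwsasdx.R` (`classify` and `simulate` subcommands).

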