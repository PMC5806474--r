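---
title: "Pedigree-aware variant filtering: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pedigree-aware variant filtering: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varseg)
```

## The problem

Family studies of rare Mendelian disease start from one VCF per sequenced
individual — typically a few hundred thousand exome variants each — and must
reduce them to a handful of candidates consistent with how the phenotype
segregates. varseg does this with a transparent, fully inspectable cascade:
every stage reads VCF and writes VCF, so the evidence for every surviving
variant can be examined at any point, and a variant that bisects several
transcripts still occupies a single line, its per-transcript contexts stored
as index-aligned, pipe-delimited INFO arrays (`VS_GENE`, `VS_REGION`,
`VS_CDNA`, `VS_MUT`, ...). Element *i* of each array always refers to the
same transcript, which is what lets downstream filters treat "any transcript
matches" as the survival rule without ever splitting records.

## Core annotation

**Gene context.** A refGene-dialect transcript table is expanded into a
region map: per transcript, exons are split against the CDS into coding
exon, 5'/3' UTR; the first `splice_bp` intronic bases on each side of an
exon become essential splice-site windows (donor on the 5' side of the
intron in transcription direction); the remaining intron is labelled
`intron`; and `promoter_bp` bases flanking the transcription start/end
become `promoter_up`/`promoter_down`. Defaults are `promoter_bp = 500` and
`splice_bp = 5`, the conventional sizes for regulatory promoter windows and
essential splice sites in exome work. All internal coordinates are 1-based
inclusive (the VCF convention); UCSC's 0-based half-open coordinates are
converted once at load. Variants overlapping nothing are intergenic and
dropped by default — on real whole-genome data this is the dominant
reduction; on the small simulated genomes it removes the deliberately
intergenic fraction of background sites.

**Functional consequence.** For an exonic SNV the reference codon is rebuilt
from CDS coordinates (reverse-complemented on minus-strand transcripts), the
alternate base substituted, and both codons translated under the standard
nuclear code: synonymous, missense, nonsense, or stoploss. Stoploss is
classified explicitly so the codon-level decision table is total. Exonic
indels are classified by frame only (`frameshift` vs `inframe_indel`); their
cDNA labels use a simplified `c.<pos>del/ins<seq>` form without HGVS
3'-shifting, which is documented as a limitation rather than half-implemented.
Splice, UTR and promoter hits are `noncoding` but keep their region label, so
"keep splice_donor" remains expressible in the mutation-type filter. A VCF
REF that disagrees with the genome FASTA triggers a warning and flags the
annotation unreliable instead of silently dropping data.

**Zygosity.** Genotype calls from upstream pipelines encode caller-specific
confidence choices, so zygosity is re-derived from allele depths alone:
with alternate fraction $f = \mathrm{alt}/(\mathrm{ref}+\mathrm{alt})$,
$f < 0.15$ is HOM_REF, $0.15 \le f \le 0.85$ HET, $f > 0.85$ HOM_ALT.
The thresholds are configuration, not biology: they keep the ordinary 50%
heterozygous band far from both homozygous calls and the 10–35% mosaic
window that the mosaicism filter targets. Calls without usable depths fall
back to GT; with neither, the sample is MISSING. Every sample of every
variant gets exactly one value.

## Filters

All filters are contractions (output ⊆ input, annotations untouched),
idempotent, and — for the single-file predicate filters — order-independent.
Threshold directions follow printed convention: call quality is *strictly*
greater-than (`> 20` drops a QUAL of exactly 20), population allele
frequency is *strictly* less-than (`< 1%` drops a frequency of exactly
0.01), read depth uses ≥. Missing QUAL or DP fails its filter
(conservative); variants absent from the frequency table pass by default,
since novel variants are precisely the interesting ones — both policies are
switchable. The allele-frequency table loads lazily one chromosome at a
time, so only chromosomes actually queried pay the load cost. Multi-allelic
records are evaluated per alternate allele and survive if any allele passes
— the least destructive reading. The multi-file filters match on
`chrom:pos:ref:alt` keys (Same Variant) or on gene symbols (Same Gene);
symbol-level matching was chosen so isoform differences between files cannot
break gene-level sharing, which is exactly the compound-heterozygote
motivating case.

## Inheritance models

Filtering operates on a family genotype view: a keys × individuals zygosity
matrix with pedigree roles. Individuals are single-sample VCFs, so an
individual without a record at a key is MISSING; MISSING is treated as
non-informative — it never eliminates a candidate on its own (a coverage gap
should not create a false negative), but affected individuals must
positively carry. This graceful-degradation stance extends to parents: the
affected-parent (dominant) and carrier-parent (recessive) checks apply only
when the parent is in the pedigree *and* genotyped at the key, so
case-only analyses without parental VCFs still run on carrier-presence rules.

* **Autosomal dominant** (complete penetrance, the default): every affected
  carries, no unaffected carries, and each affected with genotyped parents
  has an affected carrier parent. An incomplete-penetrance flag relaxes the
  unaffected-carrier veto. **De novo** mode instead screens the shared
  affected variants against all unaffected controls.
* **Autosomal recessive, HOM path**: affecteds homozygous, genotyped parents
  heterozygous carriers, any unaffected homozygote vetoes (unaffected HET
  carriers are expected).
* **Autosomal recessive, C-HET path**: per gene, at least two distinct keys
  heterozygous in every affected. With both parents genotyped the pair must
  have opposite parental origin and no single parent may carry both —
  otherwise that parent would be an unaffected compound heterozygote,
  contradicting the model. Parental origin is inferred from genotype
  presence, not read-backed phasing; there is no phasing stage, and the
  origin is reported as unknown when parents are unavailable.
* **X-linked dominant**: the dominant rules on X keys; the rules only ask
  "carries or not", under which HET- and HOM-coded hemizygous male calls
  already behave identically.
* **X-linked recessive**: affected males are hemizygous — any alt-carrying
  call satisfies the recessive requirement and males are exempt from
  compound-het pairing; affected females follow the full recessive logic;
  an unaffected male carrying a candidate eliminates it, because a
  hemizygous carrier male must be affected. Pseudoautosomal regions are not
  special-cased (documented limitation).
* **Mosaicism**: per affected sample the allele fraction is compared against
  a closed window, default $[0.10, 0.35]$ — the range in which post-zygotic
  mutations typically surface. "10–35%" is read as inclusive at both ends.

## Pipeline engine

Stage ordering is free except that annotators must precede the filters that
consume their output; `validate_config()` rejects violations (e.g. a
mutation-type filter before functional annotation) and checks that
inheritance stages have a pedigree with an affected individual and that
multi-file filters have at least two case files. Each stage writes its
per-individual VCFs into its own directory with a `##VS_STAGE=<idx>:<name>:<hash>`
provenance header; the hash chains the canonicalised stage parameters, the
upstream hash, and the md5 of every resource file the stage reads (gene map,
genome, frequency table, pedigree). Resume walks the chain and skips every
leading stage whose on-disk provenance matches, so an unchanged re-run
executes nothing and a mid-pipeline parameter edit re-executes exactly that
stage and its downstream; corrupted provenance falls back to a full re-run
with a warning. Per-stage hashing was chosen over whole-config matching as
the stronger contract: it localises invalidation to the first stage whose
inputs actually changed. The report lists one row per (variant, transcript
annotation) with the isoform tag (REF/ISO), compound-het partner keys, and
per-individual zygosity cells for cases and controls; the TSV is the
machine-readable twin of the static HTML, whose sorting/search runs
client-side in the page.

## The simulator: what it emulates, and what it does not

`simulate_case()` builds a complete, deterministic test universe: three
30 kb chromosomes (one X), five genes per chromosome with a reference and a
middle-exon-skipping alternate isoform (3 exons × 120 bp, 200 bp introns,
30 bp terminal UTRs), a background pool of twice the per-individual target
of 500 variants — 80% inside gene territory, most common (frequency
0.05–0.5) and present in the frequency table, 3% novel and absent — plus
family VCFs drawn under Hardy–Weinberg for founders and strict Mendelian
transmission for offspring (daughters receive the paternal X, sons are
maternally hemizygous). Read depths are integer draws around 30 with ±5
jitter; heterozygotes split depth evenly; the mosaic plant computes its
depths to hit the target fraction of 0.20 exactly when jitter is zero. One
causal missense variant (a compound pair for the C-HET model) is planted
consistently with each model's segregation pattern and omitted from the
frequency table, so rarity filtering behaves as in real case work. 500
background variants per individual keeps every filter doing real work while
a full seven-model end-to-end run stays in the tens of seconds.

What the simulator does **not** model: sequencing error and genotyping
noise, linkage disequilibrium and recombination, population structure,
indels and multi-allelic background sites, overlapping genes, and
real-world annotation ambiguity. Passing the planted-recovery tests
therefore demonstrates that the segregation logic and plumbing are correct
under clean inputs — not that the pipeline is robust to miscalled
genotypes, which in real data is governed by the quality/depth filters and
the missing-is-non-informative policy.

## Numerical and degenerate-input choices

* Coordinates 1-based inclusive internally; conversions happen only at
  format boundaries (refGene, BED).
* Intron splice windows shorter than `2 * splice_bp` are split
  left-window-first without overlap.
* Intronic cDNA offsets anchor to the nearer exon boundary; ties go to the
  transcriptionally upstream (donor) side. Positions upstream of the
  transcription start are numbered `c.-k` through the 5'UTR exonic length
  plus the genomic distance, which reproduces conventional promoter-variant
  numbering when the UTR is short or absent.
* Empty inputs flow through: an empty VCF yields empty outputs at every
  stage and a valid zero-row report; an empty transcript list yields an
  empty map.
* Chromosome names are normalised for the "chr" prefix at every boundary,
  since VCF, gene maps and FASTA headers disagree in the wild.
* Provenance hashing uses md5 over a canonical deparse of the parameter
  list (order-insensitive for named lists).

## Known limitations

Phased genotypes are treated as unphased; BCF/gVCF and structural variants
are out of scope; two SNVs in one codon are classified independently;
UniProt-style amino-acid coordinates are assumed to match the internal
translation (signal-peptide and isoform offsets are not reconciled); and
the Y chromosome and mitochondrial models are not implemented.
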