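# varseg

Pedigree-aware variant annotation and inheritance-model filtering for
family studies of Mendelian disease.

Exome or genome sequencing of a family yields one VCF of ~10⁵–10⁶ variants
per individual; the analyst's task is to reduce them to the handful
compatible with how the phenotype segregates. varseg does this with a
transparent filtering cascade in which **every stage reads VCF and writes
VCF**, so intermediate evidence stays inspectable, and a variant bisecting
several transcripts always stays on a single line — its per-transcript
contexts are stored in-line as index-aligned INFO arrays (`VS_GENE`,
`VS_REGION`, `VS_CDNA`, `VS_MUT`, ...).

The cascade has three parts:

1. **Core annotation** — gene context from a refGene-style transcript map
   expanded into exon / intron / essential splice-site (5 bp) / UTR /
   promoter (500 bp) regions; codon-level consequence (synonymous, missense,
   nonsense, stoploss, frameshift, inframe indel) computed against a
   reference FASTA on both strands; and zygosity re-derived from allele
   depths: with f = alt/(ref+alt), f < 0.15 → HOM_REF, 0.15 ≤ f ≤ 0.85 →
   HET, f > 0.85 → HOM_ALT.
2. **Filters** — physical location (BED regions), read depth (DP ≥ t), call
   quality (QUAL > t, strict), mutation type, population allele frequency
   (AF < t, strict, with lazy per-chromosome table loading), novelty, and
   the multi-file Same Variant / Same Gene filters.
3. **Trait-penetrance models** — autosomal dominant under complete
   penetrance ({HOM,HET} in affecteds with an affected carrier parent) and
   de novo; autosomal recessive via the homozygous path ({HET/HET} → HOM)
   and the compound-heterozygote path ({HET1/HET2} → HET1+HET2 within one
   gene, opposite parental origin, no parent carrying both); X-linked
   dominant; X-linked recessive with hemizygous males treated as homozygous
   and exempt from pairing; and mosaicism by allele-fraction window
   (default 0.10–0.35, inclusive).

A configuration-driven engine chains the stages with per-stage provenance
hashes (`##VS_STAGE` header lines), so re-running an unchanged analysis
recomputes nothing and editing one parameter re-executes only that stage
and its downstream. The run ends with a sortable/searchable HTML report and
its TSV twin. A deterministic simulator (`simulate_case()`) generates toy
genomes, gene maps with isoforms, frequency/domain/expression tables and
pedigree-linked family VCFs with a planted causal variant for each
inheritance model, so the whole pipeline is testable offline.

## Worked example

Simulate a quad family (two affected siblings, both parents) carrying a
planted compound-heterozygous missense pair, then run the standard
annotate → rarity-filter → recessive-model pipeline:

```r
library(varseg)
case <- simulate_case("AR_CHET", "demo", seed = 42, n_background = 500)
plan <- validate_config(read_pipeline_config(case$config_path))
run  <- run_pipeline(plan)
run$log
#>         stage executed n_in n_out seconds
#>         input     TRUE 1687  1687   0.298
#>     add_genes     TRUE 1687  1469   1.621
#>  add_function     TRUE 1469  1469   1.040
#>  add_zygosity     TRUE 1469  1469   0.387
#>    filter_aaf     TRUE 1469     8   0.060
#>   inheritance     TRUE    8     6   0.006
```

1,687 simulated records enter; gene annotation drops the intergenic ones,
rarity filtering (AF < 1%) removes the common background, and the
autosomal-recessive filter leaves the compound pair (plus the records the
carrier parents hold). The report has one row per (variant, transcript
annotation):

```r
read.delim(run$report_tsv)[, c(2, 4:8, 11:14)]
#>   pos gene gene_context cdna_change protein_change functional_change model            chet case_sib1 case_sib2
#>  1070 G2_1       intron c.91-251A>G              .         noncoding    AR G2_1:2:1350:G:T       HET       HET
#>  1070 G2_1         exon    c.160A>G     p.Thr54Ala          missense    AR G2_1:2:1350:G:T       HET       HET
#>  1350 G2_1         exon     c.80C>A     p.Pro27His          missense    AR G2_1:2:1070:T:C       HET       HET
#>  1350 G2_1         exon     c.80C>A     p.Pro27His          missense    AR G2_1:2:1070:T:C       HET       HET
```

Both planted variants are heterozygous in both affected siblings, each is
annotated on both isoforms of gene `G2_1` (the first lands in the
exon-skipping isoform's intron), and the `chet` column links each variant
to its partner. Re-running with `resume_pipeline(plan)` executes zero
stages; `run$report_html` is the interactive twin of the TSV.

A thin CLI wraps the same functions:

```sh
inst/cli/varseg simulate --model XLR --dir xlr_demo --seed 7
inst/cli/varseg run --config xlr_demo/config.yaml
inst/cli/varseg resume --config xlr_demo/config.yaml
```

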