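# tifseqr

Transcript isoform boundary (TIF) calling from paired 5′/3′ end sequencing
of single RNA molecules.

## The problem

Assays that sequence both ends of each cDNA molecule yield, per molecule, a
linked pair of single-nucleotide genomic positions: a transcription start
site (TSS) and a poly(A)/cleavage site (PAS). Because the two ends of the
*same* molecule stay connected, these data resolve which promoter pairs
with which terminator — the information needed to dissect overlapping
transcription units, assign promoters to genes, and identify read-through
transcripts that fuse neighbouring genes. `tifseqr` is for transcriptome
analysts who have aligned paired boundary reads (or want a fully simulated
test bed) and need deduplicated boundary tags, filtered and clustered
TSS/PAS sites, and quantified TIF calls.

## The method

Starting from raw molecule records (paired-tag TSV or name-paired BAM):

1. **Boundary extraction** — TSS = outermost base of the 5′ mate, PAS =
   outermost base of the 3′ mate; cross-chromosome, discordant-strand and
   barcode-discordant (chimeric) pairs are rejected.
2. **UMI deduplication** — molecules collapse when they differ by ≤ 1 bp
   in TSS, 0 bp in PAS and ≤ 1 UMI substitution, with the *directional*
   count gate (`count_high ≥ 2·count_low − 1`) between UMIs.
3. **Internal-priming filter** — a PAS tag is excluded when the 10 genomic
   bases downstream contain ≥ 7 adenines; `hexamer_qc()` verifies that
   kept PASs carry the `A[AT]TAAA` signal 15–30 nt upstream and flagged
   ones do not.
4. **Power-law normalization and clustering** — per-position counts are
   mapped onto the reference law `R(x) = T·x^(−α)` (α = 1.25, T = 10⁶);
   positions below 1 normalized count in more than one sample are
   excluded; tags chain into clusters at gaps ≤ 10 bp; singletons survive
   only above 1 normalized count; per-sample clusters within 10 bp merge
   into cross-sample consensus clusters.
5. **TIF calling** — molecule spans outside [300 bp, 2 Mb] are dropped; a
   (TSS cluster, PAS cluster) combination with ≥ 4 supporting
   deduplicated read pairs across samples becomes a TIF, with a
   per-sample counts matrix.
6. **Annotation** — each TIF is assigned to the same-strand overlapping
   transcript minimizing d1 + d2 (TSS/PAS distances to the transcript
   ends) and classified at 200 bp tolerance: `annotated`, `new_tss`,
   `new_pas`, `new_boundaries`, `intergenic`; intergenic TIFs merge into
   unannotated transcribed regions.
7. **Overlap & read-through** — same-strand TIF pairs starting within
   10 kb are typed by mutual overlap fraction (> 90 % both = alternative
   isoforms; < 20 % both = tandem units), the fraction of upstream PASs
   within 2 kb of the downstream TSS is reported, and TIFs bridging two
   distinct same-strand genes are called read-through candidates.

A deterministic simulator (`sim_config()` → `generate_reference()` →
`simulate_library()`) generates genomes with planted poly(A) signals and
A-rich internal-priming tracts, annotations, and multi-sample libraries
with PCR duplicates, boundary jitter, priming artifacts and
circularization chimeras — so every stage is testable against known truth.

## Worked example

```r
library(tifseqr)

cfg <- sim_config(seed = 1)            # reference study conditions
ref <- generate_reference(cfg)         # genome + annotation + truth
lib <- simulate_library(ref)           # 4-sample paired-tag library
gtf <- tempfile(fileext = ".gtf")
write_gtf(ref$transcripts, gtf)

run <- run_tif_pipeline(lib$records, ref$genome,
                        annotation = read_annotation(gtf))
run
```

```
TIF pipeline run
  input pairs      6072 (rejected 127)
  deduplicated     4533 (duplicate rate 0.311)
  span-kept        4533; priming-flagged 214
  clusters         22 TSS / 22 PAS
  TIFs             23
  categories       annotated=15 new_tss=3 new_pas=2 new_boundaries=1 intergenic=2
  read-through     1
```

6,072 molecule records (including 30 % PCR duplicates) collapse to 4,533
unique molecules; 127 pairs were rejected up front (mostly chimeras with
mismatched 5′/3′ barcodes); 214 deduplicated tags sat in planted A-rich
tracts and were removed as internal priming. The 23 called TIFs are the
23 simulated isoforms — the classification tally matches the planted
layout (15 annotated isoforms, 3 with novel TSSs including the
read-through fusion, 2 with novel PASs, 1 with both ends novel, 2
intergenic), and the single read-through call bridges the simulated gene
pair:

```r
evaluate_recovery(run$tifs, ref$truth)[c("precision", "recall")]
#> $precision  [1] 1
#> $recall     [1] 1

run$chimera
#> chimera estimate: 106/6072 cross-barcode pairs (k=4)
#>   observed fraction 0.01746, corrected rate 0.02328   # true rate 0.02
```

`run_tif_pipeline(..., out_dir = "out")` additionally writes BED6 cluster
files, a BED12 TIF file, the counts matrix (DESeq2-ready), the classified
assignments, the resolved configuration and a JSON summary. A thin CLI
wrapper lives at `inst/cli/tifseqr` (`simulate`, `run`, `dedup`
subcommands).

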