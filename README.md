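# sdrscan

Structural annotation of tyrosine-recombinase (DIRS-order) retrotransposon
copies — the *VIPER*/*TATE* elements of kinetoplastid genomes and their
relatives.

## What it does, and for whom

Copies of YR retrotransposons are defined by structure: three long ORFs
(a positionally defined gag-like gene, the tyrosine recombinase YR, and an
overlapping RT/RNase H gene) flanked by **split direct repeats** (SDRs) —
an A1 unit at the 5′ end answered by B1, A2, B2 at the 3′ end. Deciding
whether a genomic copy is intact, and where it begins and ends, is a
manual, error-prone exercise. `sdrscan` is for researchers annotating
these elements in assembled genomes. It provides:

- six-frame ORF discovery with role assignment against a reference protein
  panel, a positional gag-like rule, CH-box (CX2CX4HX4C zinc-knuckle)
  scanning and frameshift-fragment linking;
- de novo SDR detection by self-comparison — exact 8-mer seeding plus
  ungapped maximal-scoring-segment extension (match +1, mismatch −3) —
  with terminal labeling (A1/A2/B1/B2), architecture typing
  (`canonical_B1A2B2`, `variant_B1B2A2`, `A_pair_only`, `complex`),
  element boundary calling, tandem-array re-segmentation, and a
  repeat-conservation signal of recent activity (pairs at 100% identity);
- per-copy status classification: **putative autonomous** (three encoding
  ORFs — gag-like > 300 aa, YR > 250 aa, RT/RH > 600 aa — plus direct
  repeats), **potentially encoding**, **degenerate**, **inconclusive**
  (contig ends, missing-data runs), or **SIRE-like remnant** (matches only
  the A2+B2 terminal region);
- a divergence toolkit: pairwise identity with confident-region masking,
  Poisson-corrected distances *d* = −ln(1 − *p*), neighbor-joining trees,
  and the same-species monophyletic redundancy filter (collapse groups
  below 35% divergence);
- a synthetic-element generator (`make_element`, `degrade`,
  `plant_genome`, `simulate_copy_study`) that plants elements with full
  ground truth — degraded copies, tandem arrays, telomeric GGGTTA context,
  contig breaks — so every stage is verifiable at desk scale.

Standard formats go through the standard stack: Biostrings (FASTA,
translation, alignment), rtracklayer/GenomicRanges (GFF3), ape
(neighbor joining, newick).

## Worked example

Plant a scaled element (160/120/220 aa ORFs, 60/55 bp repeats) in a random
genome, extract its locus with 600 bp flanks, and run the pipeline:

```r
library(sdrscan)
cfg <- sdr_config(min_aa = c(gag_like = 100L, yr = 80L, rt_rh = 190L),
                  orf_min_aa = 60L, flank_bp = 600L,
                  contig_end_window_bp = 300L)
spec <- element_spec(orf_lengths_aa = c(gag_like = 160L, yr = 120L,
                                        rt_rh = 220L),
                     orf_overlap_bp = 60L, len_A = 60L, len_B = 55L,
                     utr5_bp = 80L, utr3_bp = 80L)
el  <- make_element(spec, seed = 1, config = cfg)
pg  <- plant_genome(list(el), background_len = 6000, min_gap = 1500,
                    seed = 2, config = cfg)
res <- run_pipeline(extract_loci(pg, flank_bp = 600), panel = el$panel,
                    config = cfg)
res$copies[[1]]
#> element_copy copy01 ( 3128 bp )
#>   status: putative_autonomous | architecture: canonical_B1A2B2
#>   role ORFs: gag_like(160 aa) yr(120 aa) rt_rh(220 aa)
#>   repeats: A1[601-660] B1[2299-2353] A2[2384-2443] B2[2474-2528]
```

The copy is called putative autonomous: all three role ORFs exceed their
thresholds and both repeat pairs are labeled. The element interval
(601–2528 within the locus) matches the planted insertion exactly — the
A1 start and B2 end are the element's boundaries. `res$summary` is a
per-genome table (counts of analyzed / encoding / three-ORF / SDR-bearing
/ autonomous copies with mean repeat sizes and identities);
`write_gff3(res$copies, "copies.gff3")` emits the annotation with ORF and
repeat child features.

Real data enter the same way: `run_pipeline("loci.fasta", "panel.fasta")`,
where the loci are candidate regions with flanking sequence and the panel
is a FASTA of canonical gag-like/YR/RT-RH proteins with `role=` tags in
the headers.

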