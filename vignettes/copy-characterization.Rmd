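---
title: "Structural characterization of tyrosine-recombinase retrotransposon copies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural characterization of tyrosine-recombinase retrotransposon copies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdrscan)
```

## The problem

VIPER and TATE are tyrosine-recombinase (YR) retrotransposons of
kinetoplastids — DIRS-order elements that integrate with a recombinase
rather than an integrase or endonuclease. Characterizing their genomic
copies is a structural problem more than a similarity problem: a copy is
interesting because of what it *contains* (three long ORFs: a poorly
conserved gag-like gene, the YR, and an extensively overlapping RT/RNase H
gene) and how it is *bounded* (split direct repeats, SDRs: an A1 unit at
the 5′ end matched by an A2 near the 3′ end, with a B1/B2 pair completing
the 3′ cluster). `sdrscan` turns that manual workflow — ORF inspection,
self-comparison for terminal repeats, boundary calling, status
classification, divergence screening — into a reproducible pipeline, and
pairs it with a synthetic-element generator so every stage can be tested
against planted ground truth.

## The pipeline

`run_pipeline(loci, panel, config)` runs, per candidate locus:

1. **ORF discovery** (`find_orfs`): every maximal ATG-initiated,
   stop-terminated ORF in six frames, nested starts collapsed to the
   longest per (frame, stop), N-spanning ORFs flagged.
2. **Role assignment** (`assign_roles`): each ORF takes the role of its
   best Smith–Waterman hit against a reference panel of canonical
   gag-like/YR/RT-RH proteins above a score floor; an unassigned ORF just
   upstream of, or overlapping, the YR ORF that meets the gag-like length
   threshold is called gag-like positionally — mirroring how the first ORF
   of these elements is identified in practice, by position rather than
   conservation. A CH-box (CX~2~CX~4~HX~4~C zinc knuckle) scan supplies
   supporting evidence. A single ORF hitting two or more role classes is
   flagged as a single-ORF layout.
3. **Frameshift linking** (`detect_frameshift_pairs`): two same-strand
   ORFs in different frames, close together, whose panel alignments cover
   adjacent regions of the same reference protein, are linked as one
   frameshifted gene; neither fragment counts as potentially encoding.
4. **Repeat self-comparison** (`find_repeat_pairs`): de novo direct-repeat
   detection within the locus (details below), followed by re-segmentation
   at head-to-tail tandem junctions, trimming to the candidate element
   span, terminal labeling (`label_terminal_repeats`), architecture typing
   (`classify_architecture`), and boundary calling (`call_boundaries`).
5. **Classification** (`classify_copy`) and per-genome summary
   (`summarize_genome`), plus the repeat-conservation activity signal and
   optional SIRE-like remnant detection.

An ORF counts as *potentially encoding* its role only above a strict
length threshold: gag-like > 300 aa, YR > 250 aa, RT/RH > 600 aa. A copy
with all three is *potentially encoding*; with labeled direct-repeat pairs
as well it is *putative autonomous*. A copy that fails these tests is
*degenerate*, unless the failure cannot be evaluated — the element region
runs into a contig end (within `contig_end_window_bp`, default 500 bp) or
is interrupted by a missing-data run (≥ `n_run_min_len` Ns, default 50) —
in which case it is *inconclusive*. Truncation evidence outranks
degeneracy only when it overlaps the element region, so a frameshifted
copy in clean sequence stays degenerate.

## Repeat detection: seeds and maximal segments

Self-comparison is seeded by exact `seed_len`-mers shared between two
positions of the locus. Each seeded diagonal is decomposed into
maximal-scoring segments (match +1, mismatch −`mismatch_penalty`,
default 3) — the ungapped-HSP notion used by blastn-style tools — so a
reported repeat begins and ends on a match and never drags net-negative
flanks along. Segments shorter than `min_repeat_len` (50 bp), with more
than `max_mismatch_frac` (10%) mismatches, or whose two units would
overlap are discarded. Extension is ungapped by design: SDR partners in
these elements have equal unit lengths.

Two numerical choices matter:

* **`seed_len = 8`.** Any repeat of length ≥ 50 with ≤ 10% mismatches
  contains, by pigeonhole, an exact run of at least
  ⌈(50 − 5)/6⌉ = 8 matches, so seeding is provably exhaustive at the
  defaults. A longer seed would be faster but could miss diffusely
  diverged repeats.
* **Tie-breaking.** The best interval per diagonal is chosen leftmost-end
  first, then longest. Decomposition is deterministic; the test suite
  checks it against an independently written exhaustive enumerator.

A low-complexity filter (distinct-trinucleotide fraction of either unit,
normalized by the attainable maximum of 64) removes pairs generated by
short-period tandem arrays. Telomeric GGGTTA arrays — the natural habitat
of TATE — are perfect direct repeats at every multiple-of-six diagonal and
would otherwise masquerade as terminal repeats; the filter plays the role
DUST plays in a blastn workflow.

Terminal labeling keeps pairs with a unit inside a `terminal_window_bp`
window of either copy end; the pair whose 5′-most unit lies nearest the 5′
terminus becomes the A pair, the remaining pair reaching nearest the 3′
terminus the B pair. The canonical architecture is A1 | B1, A2, B2; the
described variant is A1 | B1, B2, A2; a lone pair is `A_pair_only`;
anything else is `complex`. A gap larger than `gap_warn_bp` between the
ORF cluster and the nearest repeat raises a distance flag rather than a
decision — whether a distant repeat belongs to the element is left open,
as it must be.

## The synthetic generator and what it does (not) emulate

`make_element()` builds an element realizing a requested structure
exactly: stop-free ORFs of given lengths (the YR and RT/RH ORFs
overlapping in different frames), an optional CH-box, and repeat pairs of
given lengths and identities in a chosen architecture. Defaults reproduce
the best-characterized complete copies: 492/338/948 aa ORFs and canonical
SDRs with A = 173 bp and B = 219 bp at 100% identity. `degrade()` applies
substitutions (optionally ORF-preserving, so encoding status reflects
structure rather than chance stops), frameshifting deletions, missing-data
runs and truncations, updating the truth manifest including the expected
post-degradation status — computed by the same published rules the
classifier implements, from the generator's own knowledge of what
survived. `plant_genome()` inserts copies into an i.i.d. background at a
configurable GC, optionally as tandem arrays, inside telomeric hexamer
arrays, or split by contig breaks; `simulate_copy_study()` assembles a
Table-style per-genome study (by default 7 autonomous, 5
repeat-stripped encoding, 3 frameshifted degenerate copies at ~5%
inter-copy divergence).

Three harness conventions make planted truth exactly recoverable, and are
worth stating because they are *conventions*, not biology:

* planted repeat mismatches avoid the first/last 12 bp of each unit and
  are spaced ≥ 5 bp apart, so the planted pair remains a single
  score-maximal segment;
* the 12 columns flanking each planted unit (and each tandem block) are
  forced to mismatch between partners, making planted repeats true
  *maximal* repeats — which real repeats are with probability ¾ per flank
  column anyway;
* frame "fences" (a 12-mer carrying a stop in all three frames, no ATG)
  separate planted features, so an ORF scanner recovers exactly the
  planted ORFs.

The background is i.i.d. nucleotides: no codon-usage, GC-skew,
low-complexity or repeat-landscape realism. Passing the planted-truth
suites therefore demonstrates correctness of the *procedures* under the
stated noise models — substitution, indel, truncation, missing data — not
performance on real kinetoplastid assemblies, where alignment ambiguity
and assembly artifacts dominate.

## Divergence toolkit

Pairwise identities come from global affine-gap alignments with
confident-region masking: columns inside 5-column windows whose gap
fraction exceeds 50% are dropped, and identity is reported together with
the post-mask alignment length and the number of sequences, in the style
of per-genome summary tables. Unaligned termini (e.g., a truncated copy
against a complete one) are masked away rather than counted as
divergence. The masking window and threshold are a policy default;
"confident alignment" has no unique definition and the policy is exposed.

The redundancy screen reproduces the published filter: sequences are
clustered on a neighbor-joining tree (Saitou–Nei, via `ape`), and every
maximal monophyletic group from one species whose maximum pairwise
divergence is **below 0.35** collapses to its longest member. The
threshold is strict — a pair at exactly 0.35 is kept — and applies to
p-distances by default with a `corrected` switch for Poisson-corrected
distances *d* = −ln(1 − *p*), since the published wording does not fix
which scale "divergence" means. The filter is idempotent, and NJ on
additive matrices recovers the generating topology exactly (tested up to
8 leaves).

## Worked example at desk scale

```{r example}
cfg <- sdr_config(min_aa = c(gag_like = 100L, yr = 80L, rt_rh = 190L),
                  orf_min_aa = 60L, flank_bp = 600L,
                  contig_end_window_bp = 300L)
spec <- element_spec(orf_lengths_aa = c(gag_like = 160L, yr = 120L,
                                        rt_rh = 220L),
                     orf_overlap_bp = 60L, len_A = 60L, len_B = 55L,
                     utr5_bp = 80L, utr3_bp = 80L)
el <- make_element(spec, seed = 1, config = cfg)
pg <- plant_genome(list(el), background_len = 6000, min_gap = 1500,
                   seed = 2, config = cfg)
res <- run_pipeline(extract_loci(pg, flank_bp = 600), panel = el$panel,
                    config = cfg)
res$per_copy[, c("copy_id", "status", "architecture", "element_start",
                 "element_end", "sdr_A_len", "sdr_B_len")]
```

## Problem sizes

The shipped test suite runs the scaled element above across hundreds of
replicates (boundary recovery at ±0 bp in 100 planted genomes), exhaustive
oracle comparisons on short strings, and 1,000 planted 200-mers for the
repeat detector. The acceptance script runs the full-size study
conditions — 15 copies of the 492/338/948 aa element with 8 kb flanks —
plus a 128-sequence redundancy-filter study over 30 species. These sizes
were chosen so each property is measured with enough replication to be
meaningful while the whole suite stays desk-scale.

## Known limitations

* Repeat extension is ungapped; an SDR pair with an internal indel will be
  reported as two pairs or trimmed, not bridged.
* Frameshift-pair linking requires a reference panel; without one,
  fragments stay unlinked.
* Conserved-domain prediction (CDD-style) is out of scope; role evidence
  is panel alignment plus the CH-box motif.
* Boundary calls are anchored on repeats and ORFs; for copies with
  neither, no element interval is reported.
* The "most conserved copies" subsampling criterion used in manual
  curation is not reproduced; all supplied loci are analyzed.
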