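# Desk-scale study conditions: the element keeps the three-ORF overlapping
# layout and canonical SDR architecture but at reduced ORF and repeat sizes
# so many replicates run quickly; thresholds scale with it.

small_config <- function(...) {
  args <- list(min_aa = c(gag_like = 100L, yr = 80L, rt_rh = 190L),
               orf_min_aa = 60L, flank_bp = 600L,
               contig_end_window_bp = 300L, tandem_min_len = 1200L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sdr_config, args)
}

small_spec <- function(...) {
  args <- list(orf_lengths_aa = c(gag_like = 160L, yr = 120L,
                                  rt_rh = 220L),
               orf_overlap_bp = 60L, len_A = 60L, len_B = 55L,
               utr5_bp = 80L, utr3_bp = 80L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(element_spec, args)
}
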