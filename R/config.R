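#' Run configuration for the copy-characterization pipeline
#'
#' Collects every tunable parameter of the pipeline in one validated list.
#' Defaults follow the study conditions of VIPER/TATE copy analysis in
#' trypanosomatid genomes: candidate loci are taken with 8 kb of flanking
#' sequence, an ORF counts as potentially encoding its role only above a
#' role-specific protein length (gag-like > 300 aa, YR > 250 aa,
#' RT/RH > 600 aa), and same-species monophyletic groups below 35%
#' divergence are collapsed during redundancy filtering.
#'
#' @param flank_bp Flanking sequence retained around candidate loci (bp).
#' @param min_aa Named integer vector of per-role minimum protein lengths
#'   (amino acids, strict lower bounds) for an ORF to count as potentially
#'   encoding; names must be `gag_like`, `yr`, `rt_rh`.
#' @param orf_min_aa Minimum protein length for an ORF to be reported at all.
#' @param seed_len Exact-match seed length for repeat detection. The default
#'   of 8 guarantees, by pigeonhole, that every direct repeat of at least
#'   `min_repeat_len` = 50 bp with mismatch fraction at most 0.1 contains an
#'   exact seed.
#' @param min_repeat_len Minimum length (bp) of a reported repeat unit.
#' @param max_mismatch_frac Maximum mismatch fraction within a repeat pair.
#' @param mismatch_penalty Integer penalty per mismatched column during
#'   ungapped extension (match scores +1).
#' @param repeat_window_bp Extension window examined around each seed.
#' @param terminal_window_bp Window from each copy terminus within which a
#'   repeat unit is considered terminal.
#' @param flank_search_bp Maximum distance from the ORF cluster searched for
#'   element-bounding repeats when trimming a locus to its candidate element.
#' @param gap_warn_bp Gap between the ORF cluster and the nearest repeat above
#'   which an unusual-distance flag is raised.
#' @param low_complexity_filter Drop repeat pairs whose units are
#'   low-complexity (short-period tandem arrays such as telomeric hexamers).
#' @param min_distinct_3mer_frac Distinct-trinucleotide fraction below which a
#'   repeat unit counts as low-complexity.
#' @param tandem_min_len Minimum length (bp) of a direct repeat pair taken as
#'   evidence of a head-to-tail tandem array, triggering re-segmentation.
#' @param contig_end_window_bp Distance from a locus end below which a copy is
#'   treated as truncated by a contig end.
#' @param n_run_min_len Minimum N-run length treated as missing data.
#' @param min_panel_score Smith-Waterman score floor for accepting a reference
#'   panel hit as role evidence.
#' @param gag_gap_max_bp Maximum gap for the positional gag-like rule (an
#'   unassigned ORF at most this far upstream of, or overlapping, the YR ORF).
#' @param frameshift_gap_bp Maximum genomic gap between two ORFs considered as
#'   a frameshifted pair.
#' @param redundancy_threshold Divergence below which same-species
#'   monophyletic sequences are collapsed (proportion).
#' @param random_seed Seed for any stochastic step (subsampling ties).
#'
#' @return A list of class `sdr_config`.
#' @examples
#' cfg <- sdr_config()
#' cfg$min_aa
#' @export
sdr_config <- function(flank_bp = 8000L,
                       min_aa = c(gag_like = 300L, yr = 250L, rt_rh = 600L),
                       orf_min_aa = 100L,
                       seed_len = 8L,
                       min_repeat_len = 50L,
                       max_mismatch_frac = 0.1,
                       mismatch_penalty = 3L,
                       repeat_window_bp = 1000L,
                       terminal_window_bp = 1000L,
                       flank_search_bp = 3000L,
                       gap_warn_bp = 1000L,
                       low_complexity_filter = TRUE,
                       min_distinct_3mer_frac = 0.15,
                       tandem_min_len = 2000L,
                       contig_end_window_bp = 500L,
                       n_run_min_len = 50L,
                       min_panel_score = 60,
                       gag_gap_max_bp = 1000L,
                       frameshift_gap_bp = 300L,
                       redundancy_threshold = 0.35,
                       random_seed = 1L) {
  cfg <- list(
    flank_bp = as.integer(flank_bp),
    min_aa = vapply(min_aa, as.integer, integer(1)),
    orf_min_aa = as.integer(orf_min_aa),
    seed_len = as.integer(seed_len),
    min_repeat_len = as.integer(min_repeat_len),
    max_mismatch_frac = as.numeric(max_mismatch_frac),
    mismatch_penalty = as.integer(mismatch_penalty),
    repeat_window_bp = as.integer(repeat_window_bp),
    terminal_window_bp = as.integer(terminal_window_bp),
    flank_search_bp = as.integer(flank_search_bp),
    gap_warn_bp = as.integer(gap_warn_bp),
    low_complexity_filter = isTRUE(low_complexity_filter),
    min_distinct_3mer_frac = as.numeric(min_distinct_3mer_frac),
    tandem_min_len = as.integer(tandem_min_len),
    contig_end_window_bp = as.integer(contig_end_window_bp),
    n_run_min_len = as.integer(n_run_min_len),
    min_panel_score = as.numeric(min_panel_score),
    gag_gap_max_bp = as.integer(gag_gap_max_bp),
    frameshift_gap_bp = as.integer(frameshift_gap_bp),
    redundancy_threshold = as.numeric(redundancy_threshold),
    random_seed = as.integer(random_seed)
  )
  validate_sdr_config(cfg)
  class(cfg) <- "sdr_config"
  cfg
}

validate_sdr_config <- function(cfg) {
  lens <- c("flank_bp", "orf_min_aa", "seed_len", "min_repeat_len",
            "repeat_window_bp", "terminal_window_bp", "flank_search_bp",
            "gap_warn_bp", "tandem_min_len", "contig_end_window_bp",
            "n_run_min_len", "gag_gap_max_bp", "frameshift_gap_bp",
            "mismatch_penalty")
  for (nm in lens) {
    if (length(cfg[[nm]]) != 1L || is.na(cfg[[nm]]) || cfg[[nm]] <= 0L)
      stop("config field '", nm, "' must be a positive scalar", call. = FALSE)
  }
  if (!all(.ROLES %in% names(cfg$min_aa)))
    stop("min_aa must name thresholds for gag_like, yr and rt_rh",
         call. = FALSE)
  if (any(cfg$min_aa <= 0L)) stop("min_aa thresholds must be positive",
                                  call. = FALSE)
  for (nm in c("max_mismatch_frac", "redundancy_threshold",
               "min_distinct_3mer_frac")) {
    p <- cfg[[nm]]
    if (length(p) != 1L || is.na(p) || p < 0 || p > 1)
      stop("config field '", nm, "' must be a proportion in [0, 1]",
           call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.sdr_config <- function(x, ...) {
  cat("sdrscan run configuration\n")
  cat("  flank_bp:", x$flank_bp,
      " min_aa:", paste(names(x$min_aa), x$min_aa, sep = "=", collapse = " "),
      "\n")
  cat("  repeat detection: seed_len", x$seed_len,
      "min_repeat_len", x$min_repeat_len,
      "max_mismatch_frac", x$max_mismatch_frac, "\n")
  cat("  terminal_window_bp", x$terminal_window_bp,
      " contig_end_window_bp", x$contig_end_window_bp,
      " redundancy_threshold", x$redundancy_threshold, "\n")
  invisible(x)
}

# Run an expression under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
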