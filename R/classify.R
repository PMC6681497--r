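.STATUSES <- c("putative_autonomous", "potentially_encoding", "degenerate",
               "inconclusive", "sire_like_remnant")

# N runs of at least min_len within [from, to] of the sequence.
.n_runs <- function(seq, min_len, from = 1L, to = nchar(seq)) {
  if (from > to) return(NULL)
  chars <- strsplit(substring(seq, from, to), "", fixed = TRUE)[[1]]
  r <- rle(chars == "N")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(NULL)
  cbind(start = from + starts[keep] - 1L, end = from + ends[keep] - 1L)
}

#' Classify the status of an annotated copy
#'
#' A copy is `putative_autonomous` when all three role ORFs are potentially
#' encoding and labeled direct-repeat pairs are present;
#' `potentially_encoding` with the three ORFs but no repeats;
#' `sire_like_remnant` when flagged by [detect_sire_like()];
#' `inconclusive` when the candidate element lies within
#' `contig_end_window_bp` of a locus end or an N run at least
#' `n_run_min_len` long overlaps the element region (conservation cannot be
#' evaluated); otherwise `degenerate`. Truncation evidence outranks
#' `degenerate` only when it overlaps the element region, so a frameshifted
#' copy in good sequence is called degenerate, not inconclusive.
#'
#' @param copy An annotated copy from [annotate_copy()].
#' @param config An [sdr_config()].
#' @return Character scalar, one of the five status values.
#' @export
classify_copy <- function(copy, config = sdr_config()) {
  if (is.null(copy$orfs) || is.null(copy$repeat_units))
    stop("copy must be annotated (ORFs and repeats) before classification",
         call. = FALSE)
  orfs <- copy$orfs
  b <- copy$boundaries
  have_region <- !is.na(b$start)
  region <- if (have_region) c(b$start, b$end) else c(1L, copy$seq_len)
  nr <- .n_runs(copy$seq, config$n_run_min_len, region[1], region[2])
  # an ORF interrupted by missing data is not confidently encoding
  enc <- orfs$encoding
  if (!is.null(nr) && any(enc)) {
    for (i in which(enc)) {
      if (any(nr[, 1] <= orfs$end[i] & nr[, 2] >= orfs$start[i]))
        enc[i] <- FALSE
    }
  }
  roles_encoding <- unique(orfs$role[enc])
  single <- any(orfs$single_orf_layout & enc)
  three <- all(.ROLES %in% roles_encoding) || single
  labeled_pairs <- sum(copy$repeat_units$label %in% c("A1", "B1"))
  if (three) {
    return(if (labeled_pairs > 0L) "putative_autonomous"
           else "potentially_encoding")
  }
  if (isTRUE(copy$sire_like)) return("sire_like_remnant")
  # truncation/missing-data evidence must overlap the candidate element
  if (have_region) {
    near_end <- region[1] <= config$contig_end_window_bp ||
      region[2] > copy$seq_len - config$contig_end_window_bp
    if (near_end || !is.null(nr)) return("inconclusive")
  } else if (!is.null(.n_runs(copy$seq, config$n_run_min_len))) {
    return("inconclusive")
  }
  "degenerate"
}

#' Summarize a set of classified copies
#'
#' Aggregates per-dataset counts in the layout of a per-genome summary
#' table: copies analyzed, copies with at least one potentially encoding
#' ORF, copies with all three encoding ORFs, copies with reference-panel
#' support for YR and RT/RH, copies with SDRs, the modal architecture with
#' mean repeat sizes and identities, and putative autonomous copies.
#'
#' @param copies List of annotated, classified copies.
#' @param dataset_id Label for the dataset row.
#' @return A one-row data frame of class `genome_summary`.
#' @export
summarize_genome <- function(copies, dataset_id = "dataset") {
  n <- length(copies)
  if (n == 0L) {
    out <- data.frame(dataset_id = dataset_id, n_analyzed = 0L,
                      n_ge1_encoding_orf = 0L, n_three_orfs = 0L,
                      n_with_domain_support = 0L, n_with_sdrs = 0L,
                      sdr_structure = NA_character_,
                      sdr_A_len = NA_real_, sdr_A_identity = NA_real_,
                      sdr_B_len = NA_real_, sdr_B_identity = NA_real_,
                      n_autonomous = 0L, stringsAsFactors = FALSE)
    class(out) <- c("genome_summary", class(out))
    return(out)
  }
  has_enc <- vapply(copies, function(cp) any(cp$orfs$encoding), logical(1))
  three <- vapply(copies, function(cp) {
    all(.ROLES %in% cp$orfs$role[cp$orfs$encoding]) ||
      any(cp$orfs$single_orf_layout & cp$orfs$encoding)
  }, logical(1))
  domain <- vapply(copies, function(cp) {
    roles <- cp$orfs$role[cp$orfs$role_evidence == "panel_alignment" &
                            cp$orfs$encoding]
    all(c("yr", "rt_rh") %in% roles)
  }, logical(1))
  sdr <- vapply(copies, function(cp)
    sum(cp$repeat_units$label %in% c("A1", "B1")) > 0L, logical(1))
  status <- vapply(copies, function(cp) cp$status, character(1))
  arch <- vapply(copies, function(cp) cp$architecture$class, character(1))
  arch_named <- arch[!arch %in% c("none")]
  modal <- if (length(arch_named))
    names(sort(table(arch_named), decreasing = TRUE))[1] else NA_character_
  pair_stat <- function(letter, what) {
    vals <- unlist(lapply(copies, function(cp) {
      u <- cp$repeat_units
      u[[what]][u$label == paste0(letter, "1")]
    }))
    if (length(vals)) mean(vals) else NA_real_
  }
  out <- data.frame(
    dataset_id = dataset_id,
    n_analyzed = n,
    n_ge1_encoding_orf = sum(has_enc),
    n_three_orfs = sum(three),
    n_with_domain_support = sum(domain & three),
    n_with_sdrs = sum(sdr),
    sdr_structure = modal,
    sdr_A_len = pair_stat("A", "length"),
    sdr_A_identity = pair_stat("A", "pair_identity"),
    sdr_B_len = pair_stat("B", "length"),
    sdr_B_identity = pair_stat("B", "pair_identity"),
    n_autonomous = sum(status == "putative_autonomous"),
    stringsAsFactors = FALSE)
  stopifnot(out$n_autonomous <= out$n_with_sdrs,
            out$n_autonomous <= out$n_three_orfs,
            out$n_three_orfs <= out$n_analyzed)
  class(out) <- c("genome_summary", class(out))
  out
}
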