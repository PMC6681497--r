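# Trim a locus to its candidate element span using straddling repeat pairs
# anchored on the role-ORF cluster. Returns c(start, end) in locus
# coordinates, or NULL when nothing anchors an element.
.element_window <- function(seq_len, pairs, role_orfs, config) {
  if (is.null(role_orfs) || nrow(role_orfs) == 0L) return(NULL)
  core_s <- min(role_orfs$start); core_e <- max(role_orfs$end)
  w <- config$flank_search_bp
  if (!is.null(pairs) && nrow(pairs)) {
    straddle <- pairs$end1 < core_s & pairs$start2 > core_e &
      core_s - pairs$start1 <= w & pairs$end2 - core_e <= w
    down_u1 <- pairs$start1 > core_e & pairs$end1 - core_e <= w
    down_u2 <- pairs$start2 > core_e & pairs$end2 - core_e <= w
    elem_s <- if (any(straddle)) min(pairs$start1[straddle]) else core_s
    down_ends <- c(pairs$end2[straddle | down_u2], pairs$end1[down_u1])
    elem_e <- if (length(down_ends)) max(down_ends) else core_e
  } else {
    elem_s <- core_s; elem_e <- core_e
  }
  c(max(1L, elem_s), min(seq_len, elem_e))
}

#' Annotate one candidate locus
#'
#' Runs the full per-copy stage sequence: six-frame ORF discovery, role
#' assignment against the reference panel, frameshift-pair linking, repeat
#' self-comparison, tandem re-segmentation, trimming to the candidate
#' element span, terminal-repeat labeling, architecture typing, boundary
#' calling, activity signal and status classification. A locus containing
#' a head-to-tail tandem array yields one annotated copy per segment.
#'
#' @param seq Locus sequence (character scalar).
#' @param copy_id Identifier for reports.
#' @param panel Optional reference panel ([Biostrings::AAStringSet] with
#'   `role=` header tags).
#' @param config An [sdr_config()].
#' @param segment Internal flag: set when re-annotating a tandem segment.
#' @return A list of one or more annotated copies (each a list of class
#'   `element_copy`).
#' @export
annotate_copy <- function(seq, copy_id = "copy", panel = NULL,
                          config = sdr_config(), segment = FALSE) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  pairs_full <- find_repeat_pairs(
    seq, seed_len = config$seed_len,
    min_repeat_len = config$min_repeat_len,
    max_mismatch_frac = config$max_mismatch_frac,
    mismatch_penalty = config$mismatch_penalty,
    window_bp = config$repeat_window_bp,
    low_complexity_filter = config$low_complexity_filter,
    min_distinct_3mer_frac = config$min_distinct_3mer_frac)
  if (!segment) {
    segs <- segment_tandem(L, pairs_full, config$tandem_min_len)
    if (nrow(segs) > 1L) {
      out <- list()
      for (i in seq_len(nrow(segs))) {
        sub <- substring(seq, segs[i, 1], segs[i, 2])
        cps <- annotate_copy(sub, sprintf("%s.seg%d", copy_id, i), panel,
                             config, segment = TRUE)
        for (cp in cps) {
          cp$locus_offset <- segs[i, 1] - 1L
          out[[length(out) + 1L]] <- cp
        }
      }
      return(out)
    }
  }
  orfs <- find_orfs(seq, min_aa = config$orf_min_aa)
  orfs <- assign_roles(orfs, panel, config)
  orfs <- detect_frameshift_pairs(orfs, panel, config)
  role_orfs <- orfs[orfs$role %in% .ROLES, , drop = FALSE]
  win <- .element_window(L, pairs_full, role_orfs, config)
  if (is.null(win)) {
    units <- .empty_units()
    arch <- classify_architecture(units, orfs, L, config$gap_warn_bp)
    boundaries <- call_boundaries(L, units, orfs)
  } else {
    sub <- substring(seq, win[1], win[2])
    pairs_trim <- find_repeat_pairs(
      sub, seed_len = config$seed_len,
      min_repeat_len = config$min_repeat_len,
      max_mismatch_frac = config$max_mismatch_frac,
      mismatch_penalty = config$mismatch_penalty,
      window_bp = config$repeat_window_bp,
      low_complexity_filter = config$low_complexity_filter,
      min_distinct_3mer_frac = config$min_distinct_3mer_frac)
    units <- label_terminal_repeats(pairs_trim, nchar(sub),
                                    config$terminal_window_bp)
    orfs_local <- role_orfs
    orfs_local$start <- orfs_local$start - win[1] + 1L
    orfs_local$end <- orfs_local$end - win[1] + 1L
    arch <- classify_architecture(units, orfs_local, nchar(sub),
                                  config$gap_warn_bp)
    boundaries <- call_boundaries(nchar(sub), units, orfs_local)
    if (nrow(units)) {
      units$start <- units$start + win[1] - 1L
      units$end <- units$end + win[1] - 1L
    }
    if (!is.na(boundaries$start)) {
      boundaries$start <- boundaries$start + win[1] - 1L
      boundaries$end <- boundaries$end + win[1] - 1L
    }
  }
  copy <- structure(list(
    copy_id = copy_id, seq = seq, seq_len = L, orfs = orfs,
    repeat_pairs = pairs_full, repeat_units = units,
    architecture = arch, boundaries = boundaries,
    activity = activity_signal(units), sire_like = NA,
    locus_offset = 0L, status = NA_character_), class = "element_copy")
  copy$status <- classify_copy(copy, config)
  list(copy)
}

#' @export
print.element_copy <- function(x, ...) {
  cat("element_copy", x$copy_id, "(", x$seq_len, "bp )\n")
  cat("  status:", x$status, "| architecture:", x$architecture$class, "\n")
  ro <- x$orfs[x$orfs$role %in% .ROLES, , drop = FALSE]
  if (nrow(ro))
    cat("  role ORFs:", paste(sprintf("%s(%d aa%s)", ro$role,
                                      ro$protein_len_aa,
                                      ifelse(ro$encoding, "", ", sub")),
                              collapse = " "), "\n")
  lab <- x$repeat_units[x$repeat_units$label != "unlabeled", , drop = FALSE]
  if (nrow(lab))
    cat("  repeats:", paste(sprintf("%s[%d-%d]", lab$label, lab$start,
                                    lab$end), collapse = " "), "\n")
  invisible(x)
}

# Flatten copies to a per-copy report data frame.
per_copy_report <- function(copies) {
  do.call(rbind, lapply(copies, function(cp) {
    lab <- cp$repeat_units[cp$repeat_units$label != "unlabeled", ,
                           drop = FALSE]
    enc <- cp$orfs[cp$orfs$encoding, , drop = FALSE]
    a_id <- lab$pair_identity[lab$label == "A1"]
    b_id <- lab$pair_identity[lab$label == "B1"]
    data.frame(
      copy_id = cp$copy_id, seq_len = cp$seq_len, status = cp$status,
      architecture = cp$architecture$class,
      layout = cp$architecture$layout,
      n_orfs = nrow(cp$orfs),
      n_encoding_orfs = nrow(enc),
      roles_encoding = paste(sort(unique(enc$role)), collapse = ","),
      n_labeled_pairs = sum(cp$repeat_units$label %in% c("A1", "B1")),
      sdr_A_len = if (length(a_id)) lab$length[lab$label == "A1"]
      else NA_integer_,
      sdr_A_identity = if (length(a_id)) a_id else NA_real_,
      sdr_B_len = if (length(b_id)) lab$length[lab$label == "B1"]
      else NA_integer_,
      sdr_B_identity = if (length(b_id)) b_id else NA_real_,
      element_start = cp$boundaries$start + cp$locus_offset,
      element_end = cp$boundaries$end + cp$locus_offset,
      boundary_confidence = cp$boundaries$confidence,
      recent_insertion_signal = cp$activity$recent_insertion_signal,
      chbox = sum(cp$orfs$chbox_hits[cp$orfs$role == "gag_like"]) > 0L,
      frameshift = any(cp$orfs$frameshift),
      distance_flags = paste(cp$architecture$distance_flags,
                             collapse = ","),
      stringsAsFactors = FALSE)
  }))
}

#' Identity summaries for a copy set
#'
#' Mean pairwise identities in the style of a per-genome summary table:
#' nucleotide identity over the called element regions of copies with the
#' three encoding ORFs, and per-role amino-acid identity over encoding ORF
#' proteins, each reported with the number of sequences and the mean
#' post-mask alignment length.
#'
#' @param copies Annotated copies.
#' @param mask_policy See [pairwise_identity()].
#' @return List with `nucleotide` and one entry per role.
#' @export
identity_summaries <- function(copies, mask_policy = list(window = 5L,
                                                          max_gap_frac = 0.5)) {
  three <- vapply(copies, function(cp)
    all(.ROLES %in% cp$orfs$role[cp$orfs$encoding]) ||
      any(cp$orfs$single_orf_layout & cp$orfs$encoding), logical(1))
  nt <- vapply(copies[three], function(cp) {
    b <- cp$boundaries
    if (is.na(b$start)) return(NA_character_)
    substring(cp$seq, b$start, b$end)
  }, character(1))
  nt <- nt[!is.na(nt)]
  out <- list(nucleotide = mean_pairwise_identity(nt, "nucleotide",
                                                  mask_policy))
  for (r in .ROLES) {
    prots <- unlist(lapply(copies, function(cp) {
      sel <- cp$orfs$role == r & cp$orfs$encoding
      cp$orfs$protein[sel]
    }))
    out[[r]] <- mean_pairwise_identity(prots, "amino_acid", mask_policy)
  }
  out
}

#' Run the full copy-characterization pipeline
#'
#' Executes ORF annotation, SDR detection, classification and (optionally)
#' divergence summaries over a set of candidate loci, producing a
#' per-genome summary, a per-copy report, and optional GFF3/TSV output.
#' The run is a pure function of the inputs and configuration.
#'
#' @param loci FASTA path or [Biostrings::DNAStringSet] of candidate loci.
#' @param panel Optional FASTA path or [Biostrings::AAStringSet] of
#'   reference proteins with `role=` header tags.
#' @param config An [sdr_config()].
#' @param dataset_id Label for the summary row.
#' @param out_dir If given, writes `<dataset_id>.gff3`,
#'   `<dataset_id>_summary.tsv` and `<dataset_id>_copies.tsv` there.
#' @param detect_remnants Flag SIRE-like remnants using the best autonomous
#'   copy as template.
#' @param compute_identity Compute identity summaries (quadratic in copy
#'   number; off by default).
#' @return List of class `pipeline_result`: `copies`, `summary`,
#'   `per_copy`, `identity` (or `NULL`), `config`.
#' @export
run_pipeline <- function(loci, panel = NULL, config = sdr_config(),
                         dataset_id = "dataset", out_dir = NULL,
                         detect_remnants = TRUE, compute_identity = FALSE) {
  if (is.character(loci) && length(loci) == 1L)
    loci <- read_fasta(loci, "dna", allow_empty = TRUE)
  if (is.character(panel) && length(panel) == 1L)
    panel <- read_fasta(panel, "protein")
  if (is.null(names(loci)) && length(loci))
    names(loci) <- paste0("locus", seq_along(loci))
  copies <- list()
  for (i in seq_along(loci)) {
    cps <- tryCatch(
      annotate_copy(as.character(loci[[i]]), names(loci)[i], panel, config),
      error = function(e) stop("stage failure at copy '", names(loci)[i],
                               "': ", conditionMessage(e), call. = FALSE))
    copies <- c(copies, cps)
  }
  if (detect_remnants && length(copies)) {
    auto <- copies[vapply(copies, function(cp)
      cp$status == "putative_autonomous", logical(1))]
    if (length(auto)) {
      best <- auto[[which.max(vapply(auto, function(cp)
        sum(cp$repeat_units$length), numeric(1)))]]
      u <- best$repeat_units
      a2 <- u[u$label == "A2", , drop = FALSE]
      b2 <- u[u$label == "B2", , drop = FALSE]
      ro <- best$orfs[best$orfs$role %in% .ROLES, , drop = FALSE]
      if (nrow(a2) && nrow(b2) && nrow(ro)) {
        templ_term <- substring(best$seq, a2$start[1], max(b2$end))
        templ_int <- substring(best$seq, min(ro$start), max(ro$end))
        for (k in seq_along(copies)) {
          cp <- copies[[k]]
          if (cp$status != "degenerate") next
          if (any(cp$orfs$role %in% .ROLES)) next
          det <- detect_sire_like(cp$seq, templ_term, templ_int, cp$orfs)
          copies[[k]]$sire_like <- det$sire_like
          if (isTRUE(det$sire_like))
            copies[[k]]$status <- classify_copy(copies[[k]], config)
        }
      }
    }
  }
  summary <- summarize_genome(copies, dataset_id)
  per_copy <- if (length(copies)) per_copy_report(copies) else
    data.frame()
  identity <- NULL
  if (compute_identity && length(copies) >= 2L) {
    identity <- identity_summaries(copies)
    summary$mean_nt_identity <- identity$nucleotide$mean_identity_pct
    summary$mean_nt_identity_n <- identity$nucleotide$n
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gff3(copies, file.path(out_dir, paste0(dataset_id, ".gff3")))
    write_summary_tsv(summary,
                      file.path(out_dir, paste0(dataset_id,
                                                "_summary.tsv")))
    write.table(per_copy,
                file.path(out_dir, paste0(dataset_id, "_copies.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(copies = copies, summary = summary, per_copy = per_copy,
                 identity = identity, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("sdrscan pipeline result:", nrow(x$per_copy), "copies\n")
  print(x$summary)
  invisible(x)
}
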