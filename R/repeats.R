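# Maximal-scoring segment decomposition of an integer score vector.
# Recursive top-down: take the best-scoring interval (leftmost end, then
# shortest), then recurse on what is left. Child segments never outscore
# their parent, so branches whose best interval scores below `min_score`
# are pruned without losing any segment at or above it. Returns a matrix
# with columns start, end, score; NULL if nothing qualifies.
max_scoring_segments <- function(sc, min_score = 1) {
  n <- length(sc)
  if (!n) return(NULL)
  min_score <- max(1, min_score)
  out <- list()
  recurse <- function(from, to) {
    if (from > to) return(invisible(NULL))
    x <- sc[from:to]
    P <- cumsum(x)
    P0 <- c(0, P)
    prevmin <- cummin(P0)[seq_along(P)]
    vals <- P - prevmin
    e <- which.max(vals)                  # leftmost best end
    if (vals[e] < min_score) return(invisible(NULL))
    s <- min(which(P0[1:e] == prevmin[e]))  # smallest start: longest interval
    out[[length(out) + 1L]] <<- c(from + s - 1L, from + e - 1L, vals[e])
    recurse(from, from + s - 2L)
    recurse(from + e, to)
  }
  recurse(1L, n)
  if (!length(out)) return(NULL)
  m <- do.call(rbind, out)
  colnames(m) <- c("start", "end", "score")
  m[order(m[, "start"]), , drop = FALSE]
}

# Distinct-trinucleotide fraction, normalized by the attainable maximum
# (64 for long units); short-period tandem arrays such as telomeric
# hexamers score low.
.complexity_3mer <- function(chars) {
  n <- length(chars)
  if (n < 5L) return(1)
  tri <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
  length(unique(tri)) / min(n - 2L, 64L)
}

.empty_pairs <- function() {
  data.frame(start1 = integer(), end1 = integer(), start2 = integer(),
             end2 = integer(), length = integer(), mismatches = integer(),
             identity_pct = numeric(), diagonal = integer(),
             stringsAsFactors = FALSE)
}

#' Find direct repeat pairs by self-comparison
#'
#' De novo detection of same-strand direct repeats within one sequence,
#' analogous to aligning a sequence against itself. Exact `seed_len`-mer
#' matches seed ungapped two-sided extension; each seeded diagonal is
#' decomposed into maximal-scoring segments (match +1, mismatch
#' `-mismatch_penalty`), so reported repeats begin and end on a match and
#' never carry net-negative flanks. Segments shorter than `min_repeat_len`,
#' with mismatch fraction above `max_mismatch_frac`, or whose two units
#' would overlap are discarded. With the defaults (`seed_len = 8`,
#' `min_repeat_len = 50`, `max_mismatch_frac = 0.1`) every qualifying repeat
#' contains an exact seed, so detection is exhaustive.
#'
#' @param seq Character scalar over `{A,C,G,T,N}`; N never matches.
#' @param seed_len Exact seed length.
#' @param min_repeat_len Minimum repeat unit length (bp).
#' @param max_mismatch_frac Maximum mismatch fraction within a pair.
#' @param mismatch_penalty Integer penalty per mismatch during extension.
#' @param window_bp Extension window examined around each seed.
#' @param low_complexity_filter Drop pairs whose units are low-complexity.
#' @param min_distinct_3mer_frac Complexity threshold (see [sdr_config()]).
#' @param max_seed_pairs Safety cap on seed pairs examined.
#' @return Data frame with one row per repeat pair: `start1`, `end1`,
#'   `start2`, `end2` (1-based inclusive; unit 1 is 5' of unit 2), `length`,
#'   `mismatches`, `identity_pct`, `diagonal`.
#' @examples
#' find_repeat_pairs("ACGTACGT", seed_len = 4, min_repeat_len = 4)
#' @export
find_repeat_pairs <- function(seq, seed_len = 8L, min_repeat_len = 50L,
                              max_mismatch_frac = 0.1,
                              mismatch_penalty = 3L,
                              window_bp = 1000L,
                              low_complexity_filter = TRUE,
                              min_distinct_3mer_frac = 0.15,
                              max_seed_pairs = 2e6) {
  seq <- toupper(seq)
  L <- nchar(seq)
  if (L < 2L * min_repeat_len) return(.empty_pairs())
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_kmer <- L - seed_len + 1L
  if (n_kmer < 2L) return(.empty_pairs())
  kmers <- substring(seq, 1:n_kmer, seed_len:L)
  ok <- !grepl("N", kmers, fixed = TRUE)
  groups <- split(which(ok), kmers[ok])
  groups <- groups[lengths(groups) >= 2L]
  if (!length(groups)) return(.empty_pairs())
  # all ordered seed position pairs, with a safety cap on pathological input
  sizes <- lengths(groups)
  n_pairs <- sum(sizes * (sizes - 1) / 2)
  if (n_pairs > max_seed_pairs) {
    cap <- stats::quantile(sizes, 0.99)
    groups <- groups[sizes <= max(2, cap)]
    warning("seed pairs capped; dropping hyper-repetitive k-mers")
  }
  seed_p1 <- integer(0); seed_d <- integer(0)
  for (g in groups) {
    cmb <- combn(sort(g), 2L)
    seed_p1 <- c(seed_p1, cmb[1L, ])
    seed_d <- c(seed_d, cmb[2L, ] - cmb[1L, ])
  }
  keep <- seed_d > 0L
  seed_p1 <- seed_p1[keep]; seed_d <- seed_d[keep]
  if (!length(seed_d)) return(.empty_pairs())
  # any reportable segment scores at least this much (see filters below)
  floor_score <- min_repeat_len *
    (1 - (1 + mismatch_penalty) * max_mismatch_frac)
  out <- list()
  for (d in sort(unique(seed_d))) {
    n_col <- L - d
    if (n_col < min_repeat_len) next
    pos <- sort(seed_p1[seed_d == d])
    # merge seed windows on this diagonal
    ws <- pmax(1L, pos - window_bp)
    we <- pmin(n_col, pos + seed_len - 1L + window_bp)
    o <- order(ws)
    ws <- ws[o]; we <- we[o]
    merged_s <- ws[1]; merged_e <- we[1]
    wins <- list()
    if (length(ws) > 1L) {
      for (i in 2:length(ws)) {
        if (ws[i] <= merged_e + 1L) merged_e <- max(merged_e, we[i])
        else { wins[[length(wins) + 1L]] <- c(merged_s, merged_e)
               merged_s <- ws[i]; merged_e <- we[i] }
      }
    }
    wins[[length(wins) + 1L]] <- c(merged_s, merged_e)
    for (w in wins) {
      a <- w[1]; b <- w[2]
      i1 <- chars[a:b]; i2 <- chars[(a + d):(b + d)]
      m <- (i1 == i2) & i1 != "N"
      segs <- max_scoring_segments(
        ifelse(m, 1L, -as.integer(mismatch_penalty)), floor_score)
      if (is.null(segs)) next
      for (r in seq_len(nrow(segs))) {
        s <- segs[r, "start"]; e <- segs[r, "end"]
        len <- e - s + 1L
        if (len < min_repeat_len) next
        if (len > d) next                       # units must not overlap
        mis <- sum(!m[s:e])
        if (mis > max_mismatch_frac * len + 1e-9) next
        g_s <- a + s - 1L
        if (low_complexity_filter &&
            min(.complexity_3mer(chars[g_s:(g_s + len - 1L)]),
                .complexity_3mer(chars[(g_s + d):(g_s + d + len - 1L)])) <
              min_distinct_3mer_frac) next
        out[[length(out) + 1L]] <- c(g_s, g_s + len - 1L, g_s + d,
                                     g_s + d + len - 1L, len, mis, d)
      }
    }
  }
  if (!length(out)) return(.empty_pairs())
  m <- unique(do.call(rbind, out))
  df <- data.frame(start1 = m[, 1], end1 = m[, 2], start2 = m[, 3],
                   end2 = m[, 4], length = m[, 5], mismatches = m[, 6],
                   identity_pct = 100 * (m[, 5] - m[, 6]) / m[, 5],
                   diagonal = m[, 7], stringsAsFactors = FALSE)
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.empty_units <- function() {
  data.frame(label = character(), start = integer(), end = integer(),
             length = integer(), partner = character(),
             pair_identity = numeric(), stringsAsFactors = FALSE)
}

#' Label terminal repeat units
#'
#' Keeps repeat pairs with at least one unit inside a terminal window of the
#' copy, labels the pair whose 5'-most unit lies nearest the 5' terminus as
#' the A pair (A1 = 5' unit, A2 = 3' unit; ties broken by maximal
#' length x identity), and the remaining terminal pair reaching nearest the
#' 3' terminus as the B pair. Further terminal pairs stay unlabeled.
#'
#' @param pairs Data frame from [find_repeat_pairs()].
#' @param seq_len Length of the copy sequence (bp).
#' @param terminal_window_bp Terminal window width (bp).
#' @return Data frame of repeat units: `label` (A1/A2/B1/B2/unlabeled),
#'   `start`, `end`, `length`, `partner`, `pair_identity`.
#' @export
label_terminal_repeats <- function(pairs, seq_len,
                                   terminal_window_bp = 1000L) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(.empty_units())
  w5_end <- terminal_window_bp
  w3_start <- seq_len - terminal_window_bp + 1L
  touches <- function(s, e, ws, we) s <= we & e >= ws
  terminal <- touches(pairs$start1, pairs$end1, 1L, w5_end) |
    touches(pairs$start1, pairs$end1, w3_start, seq_len) |
    touches(pairs$start2, pairs$end2, 1L, w5_end) |
    touches(pairs$start2, pairs$end2, w3_start, seq_len)
  tp <- pairs[terminal, , drop = FALSE]
  if (nrow(tp) == 0L) return(.empty_units())
  quality <- tp$length * tp$identity_pct
  # A pair: 5'-most unit nearest the 5' terminus; ties by quality
  a_i <- order(tp$start1, -quality)[1]
  units <- data.frame(
    label = c("A1", "A2"),
    start = c(tp$start1[a_i], tp$start2[a_i]),
    end = c(tp$end1[a_i], tp$end2[a_i]),
    length = rep(tp$length[a_i], 2L),
    partner = c("A2", "A1"),
    pair_identity = rep(tp$identity_pct[a_i], 2L),
    stringsAsFactors = FALSE)
  rest <- tp[-a_i, , drop = FALSE]
  if (nrow(rest)) {
    quality_r <- rest$length * rest$identity_pct
    b_i <- order(-rest$end2, -quality_r)[1]
    units <- rbind(units, data.frame(
      label = c("B1", "B2"),
      start = c(rest$start1[b_i], rest$start2[b_i]),
      end = c(rest$end1[b_i], rest$end2[b_i]),
      length = rep(rest$length[b_i], 2L),
      partner = c("B2", "B1"),
      pair_identity = rep(rest$identity_pct[b_i], 2L),
      stringsAsFactors = FALSE))
    rest2 <- rest[-b_i, , drop = FALSE]
    if (nrow(rest2)) {
      for (i in seq_len(nrow(rest2))) {
        units <- rbind(units, data.frame(
          label = c("unlabeled", "unlabeled"),
          start = c(rest2$start1[i], rest2$start2[i]),
          end = c(rest2$end1[i], rest2$end2[i]),
          length = rep(rest2$length[i], 2L),
          partner = c(NA_character_, NA_character_),
          pair_identity = rep(rest2$identity_pct[i], 2L),
          stringsAsFactors = FALSE))
      }
    }
  }
  units <- units[order(units$start, units$end), , drop = FALSE]
  rownames(units) <- NULL
  units
}

#' Classify the split-direct-repeat architecture of a copy
#'
#' The canonical layout places A1 at the 5' end and B1, A2, B2 in that order
#' at the 3' end; a described variant orders the 3' units B1, B2, A2. A
#' single A pair with one unit per terminus is `A_pair_only`. Layouts
#' matching no named pattern are `complex`. A distance flag is raised when
#' the gap between the ORF cluster and the nearest repeat exceeds
#' `gap_warn_bp` (an unusually distant repeat may not belong to the element).
#'
#' @param units Labeled units from [label_terminal_repeats()].
#' @param orfs Optional ORF table with assigned roles (used for distance
#'   flags).
#' @param seq_len Copy length (bp); used to split units into 5'/3' groups.
#' @param gap_warn_bp Gap threshold for the distance flag.
#' @return List with `layout` (printable string), `class`, and
#'   `distance_flags` (character vector, possibly empty).
#' @export
classify_architecture <- function(units, orfs = NULL, seq_len = NULL,
                                  gap_warn_bp = 1000L) {
  labeled <- units[units$label != "unlabeled", , drop = FALSE]
  if (nrow(labeled) == 0L)
    return(list(layout = "", class = "none", distance_flags = character()))
  labeled <- labeled[order(labeled$start), , drop = FALSE]
  if (is.null(seq_len)) seq_len <- max(labeled$end)
  mid <- (min(labeled$start) + max(labeled$end)) / 2
  five <- labeled$label[(labeled$start + labeled$end) / 2 <= mid]
  three <- labeled$label[(labeled$start + labeled$end) / 2 > mid]
  layout <- paste0("5':", paste(five, collapse = ","),
                   " | 3':", paste(three, collapse = ","))
  has_a <- all(c("A1", "A2") %in% labeled$label)
  has_b <- all(c("B1", "B2") %in% labeled$label)
  cls <- if (has_a && has_b && identical(five, "A1")) {
    if (identical(three, c("B1", "A2", "B2"))) "canonical_B1A2B2"
    else if (identical(three, c("B1", "B2", "A2"))) "variant_B1B2A2"
    else "complex"
  } else if (has_a && !has_b && identical(five, "A1") &&
             identical(three, "A2")) {
    "A_pair_only"
  } else "complex"
  flags <- character()
  if (!is.null(orfs) && nrow(orfs)) {
    role_orfs <- orfs[orfs$role %in% .ROLES, , drop = FALSE]
    if (nrow(role_orfs)) {
      core_s <- min(role_orfs$start); core_e <- max(role_orfs$end)
      up <- labeled[labeled$end < core_s, , drop = FALSE]
      dn <- labeled[labeled$start > core_e, , drop = FALSE]
      if (nrow(up) && core_s - max(up$end) - 1L > gap_warn_bp)
        flags <- c(flags, "large_gap_5prime")
      if (nrow(dn) && min(dn$start) - core_e - 1L > gap_warn_bp)
        flags <- c(flags, "large_gap_3prime")
    }
  }
  list(layout = layout, class = cls, distance_flags = flags)
}

#' Call element boundaries from labeled repeats
#'
#' With labeled SDR units the element spans from the start of the 5'-most
#' labeled unit to the end of the 3'-most labeled unit. Without SDRs the
#' span of role-assigned ORFs is used and flagged.
#'
#' @param seq_len Copy length (bp).
#' @param units Labeled units (possibly empty).
#' @param orfs ORF table with roles.
#' @return List with `start`, `end`, `confidence` (`"sdr"` or `"orf_only"`,
#'   or `NA` when nothing anchors a boundary).
#' @export
call_boundaries <- function(seq_len, units, orfs = NULL) {
  labeled <- units[units$label != "unlabeled", , drop = FALSE]
  if (nrow(labeled)) {
    return(list(start = min(labeled$start), end = max(labeled$end),
                confidence = "sdr"))
  }
  if (!is.null(orfs) && nrow(orfs)) {
    role_orfs <- orfs[orfs$role %in% .ROLES, , drop = FALSE]
    if (nrow(role_orfs))
      return(list(start = min(role_orfs$start), end = max(role_orfs$end),
                  confidence = "orf_only"))
  }
  list(start = NA_integer_, end = NA_integer_, confidence = NA_character_)
}

#' Flag SIRE-like remnants
#'
#' SIRE is a short non-autonomous derivative corresponding to the terminal
#' A2+B2 repeat region of the full element. A locus is flagged SIRE-like
#' when it matches the terminal-repeat template over most of its length but
#' shows no internal (ORF-region) match and encodes no role ORF.
#'
#' @param seq Candidate locus sequence (character scalar).
#' @param template_terminal Terminal-repeat region of a full-length copy
#'   (A2 start through B2 end).
#' @param template_internal Optional internal (ORF) region of the full copy;
#'   matches here veto the remnant call.
#' @param orfs Optional ORF table for the locus; encoding ORFs veto the call.
#' @param min_coverage Minimum fraction of the terminal template covered.
#' @param min_identity Minimum alignment identity (proportion).
#' @return List with `sire_like` flag plus coverage/identity diagnostics.
#' @export
detect_sire_like <- function(seq, template_terminal,
                             template_internal = NULL, orfs = NULL,
                             min_coverage = 0.6, min_identity = 0.7) {
  if (is.null(template_terminal) || !nchar(template_terminal)) {
    warning("no terminal template supplied; remnant detection skipped")
    return(list(sire_like = NA, terminal_coverage = NA_real_,
                terminal_identity = NA_real_, internal_coverage = NA_real_))
  }
  if (!is.null(orfs) && nrow(orfs) && any(orfs$encoding))
    return(list(sire_like = FALSE, terminal_coverage = NA_real_,
                terminal_identity = NA_real_, internal_coverage = NA_real_))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2,
                                                  baseOnly = FALSE)
  aln_stats <- function(template) {
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(toupper(seq)),
      Biostrings::DNAString(toupper(template)),
      type = "local", substitutionMatrix = mat,
      gapOpening = 10, gapExtension = 1)
    if (Biostrings::score(pa) <= 0) return(c(cov = 0, ident = 0))
    cov <- Biostrings::nchar(Biostrings::subject(pa)) / nchar(template)
    ident <- Biostrings::pid(pa) / 100
    c(cov = cov, ident = ident)
  }
  term <- aln_stats(template_terminal)
  internal_cov <- 0
  if (!is.null(template_internal) && nchar(template_internal) > 0) {
    internal_cov <- aln_stats(template_internal)[["cov"]]
  }
  flag <- term[["cov"]] >= min_coverage && term[["ident"]] >= min_identity &&
    internal_cov < 0.2
  list(sire_like = flag, terminal_coverage = unname(term[["cov"]]),
       terminal_identity = unname(term[["ident"]]),
       internal_coverage = internal_cov)
}

#' Repeat-conservation activity signal
#'
#' During reverse transcription of split-direct-repeat elements the repeat
#' partners anneal, so A1/A2 and B1/B2 should be near-identical at
#' insertion; fully identical pairs therefore signal a recent insertion.
#'
#' @param units Labeled units from [label_terminal_repeats()].
#' @return List with `recent_insertion_signal` (`TRUE`/`FALSE`, or `NA` when
#'   no pair is labeled) and per-pair identities.
#' @export
activity_signal <- function(units) {
  labeled <- units[units$label %in% c("A1", "B1"), , drop = FALSE]
  if (nrow(labeled) == 0L)
    return(list(recent_insertion_signal = NA,
                pair_identities = numeric()))
  ids <- setNames(labeled$pair_identity, substr(labeled$label, 1L, 1L))
  list(recent_insertion_signal = all(ids == 100),
       pair_identities = ids)
}

# Split a locus at head-to-tail tandem junctions: a direct repeat pair at
# least `tandem_min_len` long whose units are adjacent (diagonal close to
# the unit length) marks a junction at the start of its second unit.
segment_tandem <- function(seq_len, pairs, tandem_min_len = 2000L) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(cbind(1L, seq_len))
  big <- pairs[pairs$length >= tandem_min_len &
                 pairs$start2 - pairs$end1 <= tandem_min_len, , drop = FALSE]
  if (nrow(big) == 0L) return(cbind(1L, seq_len))
  cuts <- sort(unique(big$start2))
  cuts <- cuts[cuts > 1L & cuts <= seq_len]
  starts <- c(1L, cuts)
  ends <- c(cuts - 1L, seq_len)
  cbind(starts, ends)
}
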