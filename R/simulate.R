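.BASES <- c("A", "C", "G", "T")
.NONSTOP <- setdiff(apply(expand.grid(.BASES, .BASES, .BASES), 1L, paste,
                          collapse = ""), .STOP_CODONS)
# Flank columns around each planted repeat unit that are forced to mismatch
# between pair partners, so a planted repeat is a true maximal repeat.
.FLANK_GUARD <- 12L

#' Specification of a synthetic VIPER/TATE-like element
#'
#' Defaults reproduce the structure of the best-characterized complete
#' copies: three long ORFs (gag-like 492 aa, YR 338 aa, RT/RH 948 aa, with
#' the YR and RT/RH ORFs overlapping), a CH-box zinc knuckle in the
#' gag-like protein, and split direct repeats in the canonical layout with
#' a 173 bp A pair and a 219 bp B pair at 100% identity.
#'
#' @param family_label Name recorded in the truth manifest.
#' @param orf_lengths_aa Named lengths (aa) of the gag-like, YR and RT/RH
#'   proteins.
#' @param orf_overlap_bp Overlap (bp) between the YR and RT/RH ORFs; nudged
#'   by one if needed so the two frames differ.
#' @param gag_yr_gap_bp Gap between the gag-like and YR ORFs.
#' @param include_chbox Embed a CH-box motif in the gag-like protein.
#' @param single_orf_layout Emit one long ORF carrying all three genes.
#' @param architecture One of `canonical_B1A2B2`, `variant_B1B2A2`,
#'   `A_pair_only`, `none`.
#' @param len_A,len_B Repeat unit lengths (bp).
#' @param identity_A,identity_B Planted pair identities (percent, in
#'   (0, 100]).
#' @param spacer_bp Spacer between 3' repeat units (bp, at least 24 so
#'   flank-guard columns stay independent).
#' @param utr5_bp,utr3_bp Untranslated regions between repeats and ORFs.
#' @return A validated list of class `element_spec`.
#' @export
element_spec <- function(family_label = "VIPER_like",
                         orf_lengths_aa = c(gag_like = 492L, yr = 338L,
                                            rt_rh = 948L),
                         orf_overlap_bp = 100L,
                         gag_yr_gap_bp = 30L,
                         include_chbox = TRUE,
                         single_orf_layout = FALSE,
                         architecture = c("canonical_B1A2B2",
                                          "variant_B1B2A2", "A_pair_only",
                                          "none"),
                         len_A = 173L, len_B = 219L,
                         identity_A = 100, identity_B = 100,
                         spacer_bp = 30L, utr5_bp = 150L, utr3_bp = 150L) {
  architecture <- match.arg(architecture)
  spec <- list(family_label = family_label,
               orf_lengths_aa = vapply(orf_lengths_aa, as.integer,
                                       integer(1)),
               orf_overlap_bp = as.integer(orf_overlap_bp),
               gag_yr_gap_bp = as.integer(gag_yr_gap_bp),
               include_chbox = isTRUE(include_chbox),
               single_orf_layout = isTRUE(single_orf_layout),
               architecture = architecture,
               len_A = as.integer(len_A), len_B = as.integer(len_B),
               identity_A = as.numeric(identity_A),
               identity_B = as.numeric(identity_B),
               spacer_bp = as.integer(spacer_bp),
               utr5_bp = as.integer(utr5_bp),
               utr3_bp = as.integer(utr3_bp))
  if (!all(.ROLES %in% names(spec$orf_lengths_aa)))
    stop("element spec error: orf_lengths_aa must name gag_like, yr, rt_rh",
         call. = FALSE)
  if (any(spec$orf_lengths_aa <= 0L))
    stop("element spec error: ORF lengths must be positive", call. = FALSE)
  if (spec$orf_overlap_bp >= 3L * spec$orf_lengths_aa[["yr"]] - 6L)
    stop("element spec error: YR/RT-RH overlap longer than the YR ORF",
         call. = FALSE)
  if (spec$orf_overlap_bp < 9L)
    stop("element spec error: orf_overlap_bp must be at least 9",
         call. = FALSE)
  if (spec$identity_A <= 0 || spec$identity_A > 100 ||
      spec$identity_B <= 0 || spec$identity_B > 100)
    stop("element spec error: identities must lie in (0, 100]",
         call. = FALSE)
  if (spec$spacer_bp < 2L * .FLANK_GUARD)
    stop("element spec error: spacer_bp must be at least ",
         2L * .FLANK_GUARD, call. = FALSE)
  if (spec$utr5_bp < nchar(.FRAME_FENCE) + .FLANK_GUARD ||
      spec$utr3_bp < nchar(.FRAME_FENCE) + .FLANK_GUARD ||
      spec$gag_yr_gap_bp < nchar(.FRAME_FENCE) + 3L)
    stop("element spec error: UTRs/gaps too short for frame fences",
         call. = FALSE)
  class(spec) <- "element_spec"
  spec
}

# n random bases at the given GC content with no ATG substring.
sample_filler <- function(n, gc = 0.5) {
  if (n <= 0L) return(character(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  v <- sample(.BASES, n, replace = TRUE, prob = p)
  repeat {
    s <- paste(v, collapse = "")
    hits <- gregexpr("ATG", s, fixed = TRUE)[[1]]
    if (hits[1] == -1L) break
    v[hits + 1L] <- sample(c("A", "C", "G"), length(hits), replace = TRUE)
  }
  v
}

.random_codons <- function(n) sample(.NONSTOP, n, replace = TRUE)

# Codons for a protein with an optional CH-box starting at aa `chbox_at`.
.orf_codons <- function(aa_len, chbox_at = NULL) {
  cod <- c("ATG", .random_codons(aa_len - 1L))
  if (!is.null(chbox_at)) {
    cys <- c("TGT", "TGC"); his <- c("CAT", "CAC")
    idx <- chbox_at + c(0L, 3L, 8L, 13L)
    stopifnot(max(idx) <= aa_len)
    cod[idx[1:2]] <- sample(cys, 2L, replace = TRUE)
    cod[chbox_at + 8L] <- sample(his, 1L)
    cod[idx[4]] <- sample(cys, 1L)
  }
  c(cod, sample(.STOP_CODONS, 1L))
}

# Build the overlapping YR/RT-RH coding block. Returns nt chars plus the
# block-local intervals of both ORFs (including stop codons).
.build_yr_rt <- function(yr_aa, rt_aa, overlap_bp) {
  yr_len <- 3L * (yr_aa + 1L)
  ov <- overlap_bp
  while ((yr_len - ov) %% 3L == 0L) ov <- ov + 1L
  rt_start <- yr_len - ov + 1L
  stopifnot(rt_start >= 7L, rt_start + 5L <= yr_len - 3L)
  k <- (rt_start - 1L) %/% 3L + 1L       # yr codon holding rt's A
  r <- (rt_start - 1L) %% 3L + 1L        # offset within that codon (2 or 3)
  for (attempt in seq_len(5000L)) {
    yr_cod <- c("ATG", .random_codons(yr_aa - 1L), sample(.STOP_CODONS, 1L))
    if (r == 2L) {
      yr_cod[k] <- sample(c("AAT", "CAT", "GAT", "TAT"), 1L)
      yr_cod[k + 1L] <- sample(grep("^G", .NONSTOP, value = TRUE), 1L)
    } else {
      yr_cod[k] <- sample(grep("A$", .NONSTOP, value = TRUE), 1L)
      yr_cod[k + 1L] <- sample(c("TGT", "TGC", "TGG"), 1L)
    }
    nt <- strsplit(paste(yr_cod, collapse = ""), "")[[1]]
    # rt-frame codons inside the yr block must be stop-free
    n_in <- (yr_len - rt_start + 1L) %/% 3L
    in_starts <- rt_start + 3L * (seq_len(n_in) - 1L)
    in_cod <- vapply(in_starts, function(s)
      paste(nt[s:(s + 2L)], collapse = ""), character(1))
    if (any(in_cod %in% .STOP_CODONS)) next
    stopifnot(in_cod[1] == "ATG")
    # no unterminated stray ATG in the rt frame upstream of rt_start
    up_starts <- rev(seq(rt_start - 3L, 1L, by = -3L))
    if (length(up_starts)) {
      up_cod <- vapply(up_starts, function(s)
        paste(nt[s:(s + 2L)], collapse = ""), character(1))
      atg_pos <- which(up_cod == "ATG")
      if (length(atg_pos)) {
        last_atg <- max(atg_pos)
        if (!any(up_cod[seq_along(up_cod) > last_atg] %in% .STOP_CODONS))
          next
      }
    }
    # complete the rt ORF beyond the yr block
    rt_total_cod <- rt_aa + 1L
    partial <- (yr_len - rt_start + 1L) %% 3L
    tail_nt <- character(0)
    n_done <- n_in
    if (partial > 0L) {
      prefix <- paste(nt[(yr_len - partial + 1L):yr_len], collapse = "")
      cands <- .NONSTOP[startsWith(.NONSTOP, prefix)]
      full <- sample(cands, 1L)
      tail_nt <- c(tail_nt, strsplit(substring(full, partial + 1L),
                                     "")[[1]])
      n_done <- n_done + 1L
    }
    n_rest <- rt_total_cod - n_done
    if (n_rest > 0L) {
      rest <- c(.random_codons(max(0L, n_rest - 1L)),
                sample(.STOP_CODONS, 1L))
      tail_nt <- c(tail_nt, strsplit(paste(rest, collapse = ""), "")[[1]])
    }
    block <- c(nt, tail_nt)
    rt_end <- rt_start + 3L * rt_total_cod - 1L
    stopifnot(length(block) == max(yr_len, rt_end))
    return(list(nt = block,
                yr = c(1L, yr_len),
                rt = c(rt_start, rt_end)))
  }
  stop("failed to satisfy overlapping ORF constraints; relax the spec",
       call. = FALSE)
}

# Mismatch positions at least `gap` apart within [lo, hi] (uniform over
# spaced configurations); falls back to unconstrained sampling when the
# spacing cannot be met.
.spaced_positions <- function(lo, hi, m, gap = 5L) {
  if (m == 0L) return(integer(0))
  span <- hi - gap * (m - 1L)
  if (span < lo) return(sort(sample(lo:hi, m)))
  x <- sort(sample(lo:span, m))
  x + gap * (0:(m - 1L))
}

.mutate_copy <- function(unit, identity_pct, guard = .FLANK_GUARD) {
  len <- length(unit)
  m <- round((1 - identity_pct / 100) * len)
  if (m == 0L) return(unit)
  lo <- guard + 1L; hi <- len - guard
  stopifnot(hi - lo + 1L >= m)
  # spacing keeps the planted pair score-maximal as one segment
  pos <- .spaced_positions(lo, hi, m)
  for (p in pos) unit[p] <- sample(setdiff(.BASES, unit[p]), 1L)
  unit
}

# Force the guard columns flanking a repeat pair to mismatch, resampling
# filler bases only. `fillable` marks positions safe to edit.
.enforce_pair_guards <- function(chars, u1, u2, fillable,
                                 guard = .FLANK_GUARD) {
  L <- length(chars)
  fix <- function(p_self, p_other) {
    if (p_self < 1L || p_self > L || p_other < 1L || p_other > L)
      return(invisible(NULL))
    if (chars[p_self] != chars[p_other]) return(invisible(NULL))
    target <- if (fillable[p_self]) p_self
    else if (fillable[p_other]) p_other else return(invisible(NULL))
    partner <- if (target == p_self) p_other else p_self
    for (b in sample(setdiff(.BASES, chars[partner]))) {
      chars[target] <<- b
      lo <- max(1L, target - 2L); hi <- min(L, target + 2L)
      if (!grepl("ATG", paste(chars[lo:hi], collapse = ""), fixed = TRUE))
        return(invisible(NULL))
    }
    chars[target] <<- setdiff(.BASES, chars[partner])[1]
    invisible(NULL)
  }
  for (k in seq_len(guard)) {
    fix(u1[1] - k, u2[1] - k)
    fix(u1[2] + k, u2[2] + k)
  }
  chars
}

#' Generate a synthetic element with ground truth
#'
#' Emits a nucleotide sequence realizing the requested ORF layout and
#' split-direct-repeat architecture exactly: stop-free ORFs of the
#' requested lengths in consistent frames (frame fences between features
#' guarantee that an ORF scanner recovers exactly the planted ORFs), an
#' embedded CH-box when requested, and repeat pairs of the requested
#' lengths and identities. Planted repeat mismatches avoid the first and
#' last 12 bp of each unit, and the 12 columns flanking each unit are
#' forced to mismatch between partners, so planted repeats are true
#' maximal repeats (a harness convention, documented in the methods
#' vignette). The element's own translated ORFs are emitted as its
#' reference panel.
#'
#' @param spec An [element_spec()].
#' @param seed Integer seed (or `NULL` to use the current RNG state).
#' @param gc Background GC content for fillers.
#' @param config An [sdr_config()]; used to record the expected status.
#' @return Object of class `synthetic_element`: list with `seq` (character),
#'   `truth`, `panel` ([Biostrings::AAStringSet]) and `spec`.
#' @examples
#' el <- make_element(element_spec(orf_lengths_aa =
#'   c(gag_like = 120L, yr = 110L, rt_rh = 210L)), seed = 1)
#' el$truth$expected_status
#' @export
make_element <- function(spec = element_spec(), seed = NULL, gc = 0.5,
                         config = sdr_config()) {
  build <- function() .make_element_impl(spec, gc, config)
  if (is.null(seed)) build() else with_seed(seed, build())
}

.make_element_impl <- function(spec, gc, config) {
  fence <- strsplit(.FRAME_FENCE, "")[[1]]
  parts <- list(); kinds <- character(0)
  regions <- list()
  cursor <- 1L
  add <- function(chars, kind, name = NA_character_) {
    if (!length(chars)) return(invisible(NULL))
    regions[[length(regions) + 1L]] <<- data.frame(
      kind = kind, name = name, start = cursor,
      end = cursor + length(chars) - 1L, stringsAsFactors = FALSE)
    parts[[length(parts) + 1L]] <<- chars
    cursor <<- cursor + length(chars)
    invisible(NULL)
  }
  add_gap <- function(total, kind = "filler", with_fence = TRUE) {
    if (with_fence) {
      add(fence, "fence")
      add(sample_filler(total - length(fence), gc), kind)
    } else add(sample_filler(total, gc), kind)
  }
  aa <- spec$orf_lengths_aa
  has_repeats <- spec$architecture != "none"
  A1 <- if (has_repeats) sample_filler(spec$len_A, gc) else character(0)
  B1 <- if (has_repeats && spec$architecture != "A_pair_only")
    sample_filler(spec$len_B, gc) else character(0)
  if (length(A1)) add(A1, "unit", "A1")
  add_gap(spec$utr5_bp, "filler")
  orf_truth <- list()
  if (spec$single_orf_layout) {
    total_aa <- sum(aa)
    cod <- .orf_codons(total_aa,
                       chbox_at = if (spec$include_chbox) 30L else NULL)
    nt <- strsplit(paste(cod, collapse = ""), "")[[1]]
    s <- cursor
    add(nt, "orf", "single")
    orf_truth[["single"]] <- data.frame(
      role = "single", start = s, end = s + length(nt) - 1L,
      aa = total_aa, intact = TRUE, frameshift = FALSE,
      stringsAsFactors = FALSE)
  } else {
    gag_cod <- .orf_codons(aa[["gag_like"]],
                           chbox_at = if (spec$include_chbox) 30L else NULL)
    gag_nt <- strsplit(paste(gag_cod, collapse = ""), "")[[1]]
    s <- cursor
    add(gag_nt, "orf", "gag_like")
    orf_truth[["gag_like"]] <- data.frame(
      role = "gag_like", start = s, end = s + length(gag_nt) - 1L,
      aa = aa[["gag_like"]], intact = TRUE, frameshift = FALSE,
      stringsAsFactors = FALSE)
    add_gap(spec$gag_yr_gap_bp, "filler")
    blk <- .build_yr_rt(aa[["yr"]], aa[["rt_rh"]], spec$orf_overlap_bp)
    s <- cursor
    add(blk$nt, "orf", "yr_rt")
    orf_truth[["yr"]] <- data.frame(
      role = "yr", start = s + blk$yr[1] - 1L, end = s + blk$yr[2] - 1L,
      aa = aa[["yr"]], intact = TRUE, frameshift = FALSE,
      stringsAsFactors = FALSE)
    orf_truth[["rt_rh"]] <- data.frame(
      role = "rt_rh", start = s + blk$rt[1] - 1L, end = s + blk$rt[2] - 1L,
      aa = aa[["rt_rh"]], intact = TRUE, frameshift = FALSE,
      stringsAsFactors = FALSE)
  }
  add_gap(spec$utr3_bp, "filler")
  unit_truth <- list()
  push_unit <- function(label, chars, identity) {
    s <- cursor
    add(chars, "unit", label)
    unit_truth[[label]] <<- data.frame(
      label = label, start = s, end = s + length(chars) - 1L,
      length = length(chars), pair_identity = identity,
      stringsAsFactors = FALSE)
  }
  if (has_repeats) {
    A2 <- .mutate_copy(A1, spec$identity_A)
    id_A <- 100 * sum(A1 == A2) / length(A1)
    if (spec$architecture == "canonical_B1A2B2") {
      B2 <- .mutate_copy(B1, spec$identity_B)
      id_B <- 100 * sum(B1 == B2) / length(B1)
      push_unit("B1", B1, id_B)
      add(sample_filler(spec$spacer_bp, gc), "filler")
      push_unit("A2", A2, id_A)
      add(sample_filler(spec$spacer_bp, gc), "filler")
      push_unit("B2", B2, id_B)
    } else if (spec$architecture == "variant_B1B2A2") {
      B2 <- .mutate_copy(B1, spec$identity_B)
      id_B <- 100 * sum(B1 == B2) / length(B1)
      push_unit("B1", B1, id_B)
      add(sample_filler(spec$spacer_bp, gc), "filler")
      push_unit("B2", B2, id_B)
      add(sample_filler(spec$spacer_bp, gc), "filler")
      push_unit("A2", A2, id_A)
    } else if (spec$architecture == "A_pair_only") {
      push_unit("A2", A2, id_A)
    }
    u1 <- unit_truth[["A1"]] <- data.frame(
      label = "A1", start = 1L, end = length(A1), length = length(A1),
      pair_identity = id_A, stringsAsFactors = FALSE)
  }
  chars <- unlist(parts)
  regions <- do.call(rbind, regions)
  fillable <- rep(FALSE, length(chars))
  fill_regs <- regions[regions$kind == "filler", , drop = FALSE]
  for (i in seq_len(nrow(fill_regs)))
    fillable[fill_regs$start[i]:fill_regs$end[i]] <- TRUE
  units <- if (length(unit_truth)) do.call(rbind, unit_truth) else NULL
  if (!is.null(units)) {
    units <- units[order(units$start), , drop = FALSE]
    rownames(units) <- NULL
    pair_of <- function(l) units[units$label == l, , drop = FALSE]
    pairs <- list(c("A1", "A2"), c("B1", "B2"))
    for (pr in pairs) {
      p1 <- pair_of(pr[1]); p2 <- pair_of(pr[2])
      if (nrow(p1) && nrow(p2))
        chars <- .enforce_pair_guards(chars, c(p1$start, p1$end),
                                      c(p2$start, p2$end), fillable)
    }
  } else {
    units <- data.frame(label = character(), start = integer(),
                        end = integer(), length = integer(),
                        pair_identity = numeric(), stringsAsFactors = FALSE)
  }
  orfs <- do.call(rbind, orf_truth)
  rownames(orfs) <- NULL
  truth <- list(length = length(chars), orfs = orfs, repeat_units = units,
                architecture = spec$architecture,
                single_orf = spec$single_orf_layout,
                family = spec$family_label,
                n_runs = NULL, truncated = FALSE,
                regions = regions)
  truth$expected_status <- truth_status(truth, config)
  panel <- .element_panel(chars, orfs, spec)
  structure(list(seq = paste(chars, collapse = ""), truth = truth,
                 panel = panel, spec = spec),
            class = "synthetic_element")
}

.element_panel <- function(chars, orfs, spec) {
  seqs <- character(0)
  if (spec$single_orf_layout) {
    nt <- paste(chars[orfs$start[1]:(orfs$end[1] - 3L)], collapse = "")
    prot <- translate_dna(nt)
    aa <- spec$orf_lengths_aa
    b1 <- aa[["gag_like"]]; b2 <- b1 + aa[["yr"]]
    seqs <- c(substr(prot, 1L, b1), substr(prot, b1 + 1L, b2),
              substring(prot, b2 + 1L))
    names(seqs) <- paste0("synthetic_", .ROLES, " role=", .ROLES)
  } else {
    for (i in seq_len(nrow(orfs))) {
      nt <- paste(chars[orfs$start[i]:(orfs$end[i] - 3L)], collapse = "")
      seqs <- c(seqs, translate_dna(nt))
    }
    names(seqs) <- paste0("synthetic_", orfs$role, " role=", orfs$role)
  }
  Biostrings::AAStringSet(seqs)
}

# Expected classification of a (possibly degraded) truth record, mirroring
# the classifier's rules.
truth_status <- function(truth, config = sdr_config()) {
  orfs <- truth$orfs
  units <- truth$repeat_units
  n_overlaps <- function(s, e) {
    if (is.null(truth$n_runs) || !nrow(truth$n_runs)) return(FALSE)
    any(truth$n_runs$length >= config$n_run_min_len &
          truth$n_runs$start <= e & truth$n_runs$end >= s)
  }
  if (truth$single_orf) {
    ok <- nrow(orfs) == 1L && orfs$intact[1] &&
      orfs$aa[1] > sum(config$min_aa) &&
      !n_overlaps(orfs$start[1], orfs$end[1])
    roles_ok <- ok
  } else {
    roles_ok <- all(vapply(.ROLES, function(r) {
      row <- orfs[orfs$role == r, , drop = FALSE]
      nrow(row) == 1L && row$intact && !row$frameshift &&
        row$aa > config$min_aa[[r]] && !n_overlaps(row$start, row$end)
    }, logical(1)))
  }
  pair_ok <- FALSE
  if (nrow(units)) {
    for (pr in list(c("A1", "A2"), c("B1", "B2"))) {
      a <- units[units$label == pr[1], , drop = FALSE]
      b <- units[units$label == pr[2], , drop = FALSE]
      if (nrow(a) && nrow(b) &&
          a$length >= config$min_repeat_len &&
          a$pair_identity >= 100 * (1 - config$max_mismatch_frac) &&
          !n_overlaps(a$start, a$end) && !n_overlaps(b$start, b$end))
        pair_ok <- TRUE
    }
  }
  if (roles_ok) return(if (pair_ok) "putative_autonomous"
                       else "potentially_encoding")
  n_issue <- FALSE
  if (!is.null(truth$n_runs) && nrow(truth$n_runs)) {
    feats <- rbind(orfs[, c("start", "end")],
                   if (nrow(units)) units[, c("start", "end")])
    for (i in seq_len(nrow(feats)))
      if (n_overlaps(feats$start[i], feats$end[i])) n_issue <- TRUE
  }
  if (n_issue || isTRUE(truth$cut_at_contig_end)) return("inconclusive")
  "degenerate"
}

#' Specification of copy degradation
#'
#' @param sub_rate Per-site substitution probability.
#' @param indel_rate Per-site probability of a 1 bp insertion or deletion in
#'   neutral regions.
#' @param frameshift_positions Element-local positions receiving a 1 bp
#'   deletion (frameshift when inside an ORF).
#' @param truncation One of `none`, `5prime`, `3prime`, `internal`.
#' @param truncation_len Bases removed by the truncation.
#' @param truncation_pos Start of an internal truncation.
#' @param n_run `NULL` or `list(position =, length =)`: replace a stretch
#'   with Ns (missing data).
#' @param preserve_orfs Resample substitutions that would create an in-frame
#'   stop in a planted ORF and never touch planted start/stop codons.
#' @param preserve_repeats Never mutate repeat units or their guard flanks,
#'   keeping planted pair identities exact.
#' @return A list of class `degradation_spec`.
#' @export
degradation_spec <- function(sub_rate = 0, indel_rate = 0,
                             frameshift_positions = integer(),
                             truncation = c("none", "5prime", "3prime",
                                            "internal"),
                             truncation_len = 0L, truncation_pos = NA_integer_,
                             n_run = NULL,
                             preserve_orfs = TRUE, preserve_repeats = TRUE) {
  truncation <- match.arg(truncation)
  if (sub_rate < 0 || sub_rate >= 1 || indel_rate < 0 || indel_rate >= 1)
    stop("rates must lie in [0, 1)", call. = FALSE)
  structure(list(sub_rate = sub_rate, indel_rate = indel_rate,
                 frameshift_positions = as.integer(frameshift_positions),
                 truncation = truncation,
                 truncation_len = as.integer(truncation_len),
                 truncation_pos = as.integer(truncation_pos),
                 n_run = n_run,
                 preserve_orfs = isTRUE(preserve_orfs),
                 preserve_repeats = isTRUE(preserve_repeats)),
            class = "degradation_spec")
}

# Shift all truth intervals after removing/inserting bases.
.shift_truth <- function(truth, at, delta) {
  bump <- function(df) {
    if (is.null(df) || !nrow(df)) return(df)
    df$start <- ifelse(df$start >= at, df$start + delta, df$start)
    df$end <- ifelse(df$end >= at, df$end + delta, df$end)
    df
  }
  truth$orfs <- bump(truth$orfs)
  truth$repeat_units <- bump(truth$repeat_units)
  truth$regions <- bump(truth$regions)
  if (!is.null(truth$n_runs)) truth$n_runs <- bump(truth$n_runs)
  truth$length <- truth$length + delta
  truth
}

#' Degrade a synthetic element
#'
#' Applies substitutions, frameshifting deletions, missing-data runs and
#' truncations to an element, updating the truth manifest (including the
#' expected post-degradation status) as it goes.
#'
#' @param el A `synthetic_element` from [make_element()].
#' @param dspec A [degradation_spec()].
#' @param seed Integer seed (or `NULL`).
#' @param config An [sdr_config()] used to recompute the expected status.
#' @return The degraded `synthetic_element`.
#' @export
degrade <- function(el, dspec = degradation_spec(), seed = NULL,
                    config = sdr_config()) {
  stopifnot(inherits(el, "synthetic_element"))
  run <- function() .degrade_impl(el, dspec, config)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.degrade_impl <- function(el, dspec, config) {
  chars <- strsplit(el$seq, "", fixed = TRUE)[[1]]
  truth <- el$truth
  L <- length(chars)
  in_any <- function(pos, df, pad = 0L) {
    if (is.null(df) || !nrow(df)) return(rep(FALSE, length(pos)))
    out <- rep(FALSE, length(pos))
    for (i in seq_len(nrow(df)))
      out <- out | (pos >= df$start[i] - pad & pos <= df$end[i] + pad)
    out
  }
  # --- substitutions ---
  if (dspec$sub_rate > 0) {
    cand <- which(as.logical(rbinom(L, 1L, dspec$sub_rate)))
    if (dspec$preserve_repeats)
      cand <- cand[!in_any(cand, truth$repeat_units, pad = .FLANK_GUARD)]
    orfs <- truth$orfs
    for (p in cand) {
      covering <- which(orfs$start <= p & orfs$end >= p)
      if (dspec$preserve_orfs && length(covering)) {
        # never touch planted start/stop codons
        if (any(p <= orfs$start[covering] + 2L |
                p >= orfs$end[covering] - 2L)) next
        ok_base <- NULL
        for (b in sample(setdiff(.BASES, chars[p]))) {
          bad <- FALSE
          for (oi in covering) {
            off <- (p - orfs$start[oi]) %% 3L
            cs <- p - off
            cod <- chars[cs:(cs + 2L)]
            cod[p - cs + 1L] <- b
            if (paste(cod, collapse = "") %in% .STOP_CODONS) bad <- TRUE
          }
          if (!bad) { ok_base <- b; break }
        }
        if (is.null(ok_base)) next
        chars[p] <- ok_base
      } else {
        chars[p] <- sample(setdiff(.BASES, chars[p]), 1L)
        if (length(covering) && !dspec$preserve_orfs) {
          off <- (p - orfs$start[covering]) %% 3L
          for (j in seq_along(covering)) {
            cs <- p - off[j]
            if (paste(chars[cs:(cs + 2L)], collapse = "") %in% .STOP_CODONS)
              truth$orfs$intact[covering[j]] <- FALSE
          }
        }
      }
    }
    if (!dspec$preserve_repeats && nrow(truth$repeat_units)) {
      u <- truth$repeat_units
      for (pr in list(c("A1", "A2"), c("B1", "B2"))) {
        i1 <- which(u$label == pr[1]); i2 <- which(u$label == pr[2])
        if (length(i1) && length(i2)) {
          s1 <- chars[u$start[i1]:u$end[i1]]
          s2 <- chars[u$start[i2]:u$end[i2]]
          n <- min(length(s1), length(s2))
          id <- 100 * sum(s1[1:n] == s2[1:n]) / n
          truth$repeat_units$pair_identity[c(i1, i2)] <- id
        }
      }
    }
  }
  # --- frameshifting deletions and neutral indels ---
  dels <- sort(unique(dspec$frameshift_positions), decreasing = TRUE)
  for (p in dels) {
    if (p < 1L || p > length(chars)) next
    covering <- which(truth$orfs$start <= p & truth$orfs$end >= p)
    if (length(covering)) {
      truth$orfs$intact[covering] <- FALSE
      truth$orfs$frameshift[covering] <- TRUE
    }
    cu <- which(truth$repeat_units$start <= p & truth$repeat_units$end >= p)
    if (length(cu)) {
      truth$repeat_units$pair_identity[cu] <- NA_real_
    }
    chars <- chars[-p]
    truth <- .shift_truth(truth, p + 1L, -1L)
  }
  if (dspec$indel_rate > 0) {
    cand <- which(as.logical(rbinom(length(chars), 1L, dspec$indel_rate)))
    protect <- in_any(cand, truth$orfs) |
      in_any(cand, truth$repeat_units, pad = .FLANK_GUARD)
    cand <- sort(cand[!protect], decreasing = TRUE)
    for (p in cand) {
      if (runif(1) < 0.5) {
        chars <- chars[-p]
        truth <- .shift_truth(truth, p + 1L, -1L)
      } else {
        chars <- append(chars, sample(.BASES, 1L), after = p)
        truth <- .shift_truth(truth, p + 1L, +1L)
      }
    }
  }
  # --- missing data run ---
  if (!is.null(dspec$n_run)) {
    s <- dspec$n_run$position
    e <- min(length(chars), s + dspec$n_run$length - 1L)
    chars[s:e] <- "N"
    nr <- data.frame(start = s, end = e, length = e - s + 1L)
    truth$n_runs <- rbind(truth$n_runs, nr)
  }
  # --- truncation ---
  clip <- function(lo, hi) {
    # remove [lo, hi] from the sequence, clipping truth features
    drop_rows <- function(df) {
      if (is.null(df) || !nrow(df)) return(df)
      gone <- df$start >= lo & df$end <= hi
      part <- !gone & (df$start <= hi & df$end >= lo)
      if ("intact" %in% names(df)) df$intact[part] <- FALSE
      if ("pair_identity" %in% names(df)) df$pair_identity[part] <- NA_real_
      df$start <- pmax(df$start, ifelse(df$start >= lo & df$start <= hi,
                                        hi + 1L, df$start))
      df$end <- pmin(df$end, ifelse(df$end >= lo & df$end <= hi,
                                    lo - 1L, df$end))
      df <- df[!gone & df$end >= df$start, , drop = FALSE]
      df
    }
    truth$orfs <<- drop_rows(truth$orfs)
    truth$repeat_units <<- drop_rows(truth$repeat_units)
    truth$regions <<- drop_rows(truth$regions)
    if (!is.null(truth$n_runs)) truth$n_runs <<- drop_rows(truth$n_runs)
    chars <<- chars[-(lo:hi)]
    truth <<- .shift_truth(truth, hi + 1L, -(hi - lo + 1L))
    truth$truncated <<- TRUE
  }
  if (dspec$truncation != "none" && dspec$truncation_len > 0L) {
    Lc <- length(chars)
    if (dspec$truncation == "5prime") clip(1L, min(dspec$truncation_len, Lc))
    else if (dspec$truncation == "3prime")
      clip(max(1L, Lc - dspec$truncation_len + 1L), Lc)
    else clip(dspec$truncation_pos,
              min(Lc, dspec$truncation_pos + dspec$truncation_len - 1L))
  }
  # drop repeat units whose partner vanished
  u <- truth$repeat_units
  if (nrow(u)) {
    keep <- vapply(seq_len(nrow(u)), function(i) {
      partner <- paste0(substr(u$label[i], 1L, 1L),
                        if (substr(u$label[i], 2L, 2L) == "1") "2" else "1")
      partner %in% u$label
    }, logical(1))
    truth$repeat_units <- u[keep, , drop = FALSE]
  }
  truth$length <- length(chars)
  truth$expected_status <- truth_status(truth, config)
  el$seq <- paste(chars, collapse = "")
  el$truth <- truth
  el
}

# Remove both terminal repeat regions (plus a small margin) so a copy keeps
# its ORFs but loses its SDRs.
strip_terminal_repeats <- function(el, margin = 40L, config = sdr_config()) {
  u <- el$truth$repeat_units
  if (!nrow(u)) return(el)
  core_s <- min(el$truth$orfs$start)
  core_e <- max(el$truth$orfs$end)
  up <- u[u$end < core_s, , drop = FALSE]
  dn <- u[u$start > core_e, , drop = FALSE]
  if (nrow(dn)) {
    cut_from <- min(dn$start) - margin
    el <- degrade(el, degradation_spec(
      truncation = "3prime",
      truncation_len = el$truth$length - cut_from + 1L), config = config)
  }
  if (nrow(up)) {
    el <- degrade(el, degradation_spec(
      truncation = "5prime",
      truncation_len = max(up$end) + margin), config = config)
  }
  el
}

#' Plant elements in a synthetic genome
#'
#' Inserts elements at recorded positions in an i.i.d. background of the
#' requested GC content, optionally as head-to-tail tandem arrays, inside a
#' telomeric GGGTTA hexamer array, or split by contig breaks (a copy cut at
#' a contig end is expected to classify as inconclusive). The 12 columns of
#' genomic context flanking each planted repeat unit are resampled if they
#' happen to match the partner unit's context, so planted repeats stay
#' maximal (harness convention).
#'
#' @param elements List of `synthetic_element` objects.
#' @param background_len Total background length (bp) distributed between
#'   and around the planted copies.
#' @param gc Background GC content.
#' @param tandem_counts Integer vector (recycled) of head-to-tail copies per
#'   element.
#' @param telomeric_idx Index of an element to wrap in GGGTTA hexamer
#'   arrays, or `NULL`.
#' @param contig_breaks Genome positions at which to split contigs, or a
#'   list `list(cut_element = i, offset = o)` to cut element `i` at `o` bp
#'   after its start.
#' @param min_gap Minimum background gap between planted blocks.
#' @param seed Integer seed (or `NULL`).
#' @param config An [sdr_config()].
#' @return Object of class `planted_genome`: `contigs` (named character
#'   vector), `truth` (one row per planted copy), `elements`, `panel`.
#' @export
plant_genome <- function(elements, background_len = 50000L, gc = 0.45,
                         tandem_counts = 1L, telomeric_idx = NULL,
                         contig_breaks = NULL, min_gap = 2000L,
                         seed = NULL, config = sdr_config()) {
  run <- function() .plant_impl(elements, background_len, gc, tandem_counts,
                                telomeric_idx, contig_breaks, min_gap,
                                config)
  if (is.null(seed)) run() else with_seed(seed, run())
}

.plant_impl <- function(elements, background_len, gc, tandem_counts,
                        telomeric_idx, contig_breaks, min_gap, config) {
  n <- length(elements)
  tandem_counts <- rep_len(as.integer(tandem_counts), n)
  block_len <- vapply(seq_len(n), function(i)
    nchar(elements[[i]]$seq) * tandem_counts[i] +
      if (!is.null(telomeric_idx) && i == telomeric_idx) 2L * 180L else 0L,
    integer(1))
  need <- sum(block_len) + (n + 1L) * min_gap
  if (background_len + sum(block_len) < need)
    stop("placement error: background_len too small for the requested ",
         "elements and min_gap", call. = FALSE)
  free <- background_len - (n + 1L) * min_gap
  extra <- if (free > 0L) {
    cuts <- sort(sample.int(free, n, replace = TRUE))
    diff(c(0L, cuts, free))
  } else rep(0L, n + 1L)
  gaps <- min_gap + extra
  telo <- paste(rep("GGGTTA", 30L), collapse = "")
  pieces <- character(0)
  truth_rows <- list()
  cursor <- 0L
  for (i in seq_len(n)) {
    bg <- paste(sample_filler(gaps[i], gc), collapse = "")
    pieces <- c(pieces, bg); cursor <- cursor + nchar(bg)
    if (!is.null(telomeric_idx) && i == telomeric_idx) {
      pieces <- c(pieces, telo); cursor <- cursor + nchar(telo)
    }
    el <- elements[[i]]
    for (t in seq_len(tandem_counts[i])) {
      s <- cursor + 1L
      pieces <- c(pieces, el$seq)
      cursor <- cursor + nchar(el$seq)
      truth_rows[[length(truth_rows) + 1L]] <- list(
        copy_id = sprintf("copy%02d%s", i,
                          if (tandem_counts[i] > 1L) paste0("_t", t) else ""),
        element_idx = i, tandem_index = t,
        start = s, end = cursor,
        expected_status = el$truth$expected_status,
        architecture = el$truth$architecture,
        cut = FALSE)
    }
    if (!is.null(telomeric_idx) && i == telomeric_idx) {
      pieces <- c(pieces, telo); cursor <- cursor + nchar(telo)
    }
  }
  pieces <- c(pieces, paste(sample_filler(gaps[n + 1L], gc), collapse = ""))
  genome <- paste(pieces, collapse = "")
  truth <- do.call(rbind, lapply(truth_rows, as.data.frame,
                                 stringsAsFactors = FALSE))
  # enforce maximal-repeat guards at element/background junctions
  chars <- strsplit(genome, "", fixed = TRUE)[[1]]
  protected <- rep(FALSE, length(chars))
  fillable <- rep(TRUE, length(chars))
  for (r in seq_len(nrow(truth))) {
    el <- elements[[truth$element_idx[r]]]
    off <- truth$start[r] - 1L
    regs <- el$truth$regions
    hard <- regs[regs$kind %in% c("unit", "orf", "fence"), , drop = FALSE]
    for (j in seq_len(nrow(hard))) {
      idx <- (hard$start[j] + off):(hard$end[j] + off)
      protected[idx] <- TRUE
      fillable[idx] <- FALSE
    }
  }
  for (r in seq_len(nrow(truth))) {
    el <- elements[[truth$element_idx[r]]]
    off <- truth$start[r] - 1L
    u <- el$truth$repeat_units
    if (!nrow(u)) next
    for (pr in list(c("A1", "A2"), c("B1", "B2"))) {
      i1 <- which(u$label == pr[1]); i2 <- which(u$label == pr[2])
      if (!length(i1) || !length(i2)) next
      chars <- .enforce_pair_guards(
        chars, c(u$start[i1] + off, u$end[i1] + off),
        c(u$start[i2] + off, u$end[i2] + off), fillable)
    }
  }
  # tandem blocks are themselves direct repeats: guard the block flanks so
  # the head-to-tail pair stays maximal at exactly the element period
  for (i in unique(truth$element_idx)) {
    rows <- which(truth$element_idx == i)
    if (length(rows) < 2L) next
    rows <- rows[order(truth$tandem_index[rows])]
    n_t <- length(rows)
    chars <- .enforce_pair_guards(
      chars, c(truth$start[rows[1]], truth$end[rows[n_t - 1L]]),
      c(truth$start[rows[2]], truth$end[rows[n_t]]), fillable)
  }
  genome <- paste(chars, collapse = "")
  # contig breaks
  breaks <- integer(0)
  if (!is.null(contig_breaks)) {
    if (is.list(contig_breaks)) {
      r <- which(truth$element_idx == contig_breaks$cut_element)[1]
      breaks <- truth$start[r] + contig_breaks$offset - 1L
    } else breaks <- as.integer(contig_breaks)
  }
  breaks <- sort(unique(breaks[breaks > 1L & breaks <= nchar(genome)]))
  bounds <- cbind(c(1L, breaks), c(breaks - 1L, nchar(genome)))
  contigs <- vapply(seq_len(nrow(bounds)), function(i)
    substring(genome, bounds[i, 1], bounds[i, 2]), character(1))
  names(contigs) <- sprintf("contig%02d", seq_along(contigs))
  truth$contig <- NA_character_
  truth$contig_start <- NA_integer_
  truth$contig_end <- NA_integer_
  for (r in seq_len(nrow(truth))) {
    ci <- max(which(bounds[, 1] <= truth$start[r]))
    cs <- bounds[ci, 1]; ce <- bounds[ci, 2]
    truth$contig[r] <- names(contigs)[ci]
    truth$contig_start[r] <- truth$start[r] - cs + 1L
    truth$contig_end[r] <- min(truth$end[r], ce) - cs + 1L
    if (truth$end[r] > ce) {
      truth$cut[r] <- TRUE
      truth$expected_status[r] <- .expected_after_cut(
        elements[[truth$element_idx[r]]], ce - truth$start[r] + 1L, config)
    }
  }
  structure(list(contigs = contigs, truth = truth, elements = elements,
                 panel = elements[[1]]$panel),
            class = "planted_genome")
}

# Expected status of an element cut `keep_len` bp after its start (the
# remainder lies beyond a contig break): features that survive intact decide
# the call; anything less is inconclusive, since conservation cannot be
# evaluated at a contig end.
.expected_after_cut <- function(el, keep_len, config) {
  t <- el$truth
  orfs <- t$orfs
  if (!is.null(orfs) && nrow(orfs)) {
    orfs$intact[orfs$end > keep_len] <- FALSE
    orfs <- orfs[orfs$start <= keep_len, , drop = FALSE]
  }
  units <- t$repeat_units
  if (!is.null(units) && nrow(units)) {
    units <- units[units$end <= keep_len, , drop = FALSE]
    if (nrow(units)) {
      keep <- vapply(seq_len(nrow(units)), function(i) {
        partner <- paste0(substr(units$label[i], 1L, 1L),
                          if (substr(units$label[i], 2L, 2L) == "1") "2"
                          else "1")
        partner %in% units$label
      }, logical(1))
      units <- units[keep, , drop = FALSE]
    }
  }
  t$orfs <- orfs; t$repeat_units <- units; t$length <- keep_len
  st <- truth_status(t, config)
  if (st %in% c("putative_autonomous", "potentially_encoding")) st
  else "inconclusive"
}

#' Extract candidate loci with flanking sequence from a planted genome
#'
#' Copies whose flanked intervals overlap (tandem arrays) are merged into a
#' single locus, to be re-segmented by the pipeline.
#'
#' @param pg A `planted_genome`.
#' @param flank_bp Flanking sequence on each side (clipped at contig ends).
#' @return A [Biostrings::DNAStringSet] named by locus id, with a
#'   `locus_info` attribute recording each planted copy's locus and offset
#'   within it.
#' @export
extract_loci <- function(pg, flank_bp = 8000L) {
  truth <- pg$truth
  truth <- truth[order(truth$contig, truth$contig_start), , drop = FALSE]
  # merge flanked intervals per contig
  blocks <- list()
  cur <- NULL
  for (r in seq_len(nrow(truth))) {
    clen <- nchar(pg$contigs[[truth$contig[r]]])
    s <- max(1L, truth$contig_start[r] - flank_bp)
    e <- min(clen, truth$contig_end[r] + flank_bp)
    if (!is.null(cur) && cur$contig == truth$contig[r] && s <= cur$e + 1L) {
      cur$e <- max(cur$e, e)
      cur$rows <- c(cur$rows, r)
    } else {
      if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- list(contig = truth$contig[r], s = s, e = e, rows = r)
    }
  }
  if (!is.null(cur)) blocks[[length(blocks) + 1L]] <- cur
  seqs <- character(length(blocks))
  lid <- character(length(blocks))
  info <- list()
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    contig <- pg$contigs[[bl$contig]]
    seqs[b] <- substring(contig, bl$s, bl$e)
    lid[b] <- truth$copy_id[bl$rows[1]]
    for (r in bl$rows) {
      info[[length(info) + 1L]] <- data.frame(
        copy_id = truth$copy_id[r], locus_id = lid[b],
        element_offset = truth$contig_start[r] - bl$s + 1L,
        element_end = truth$contig_end[r] - bl$s + 1L,
        clipped_5 = (truth$contig_start[r] - bl$s) < flank_bp,
        clipped_3 = (bl$e - truth$contig_end[r]) < flank_bp,
        expected_status = truth$expected_status[r],
        stringsAsFactors = FALSE)
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- lid
  attr(out, "locus_info") <- do.call(rbind, info)
  out
}

#' Simulate a per-genome copy study with planted truth
#'
#' Generates a master element and a family of copies in the proportions of
#' a well-conserved genome: intact copies with SDRs (putative autonomous),
#' copies that kept their three ORFs but lost their terminal repeats
#' (potentially encoding), and copies additionally carrying a frameshift in
#' the RT/RH ORF (degenerate). All copies accumulate substitutions at
#' `sub_rate` from the master (ORF-preserving, so encoding status reflects
#' structure rather than chance stops), giving the copy family a realistic
#' divergence structure.
#'
#' @param n_autonomous,n_encoding,n_degenerate Copy counts per class.
#' @param sub_rate Per-copy substitution rate from the master.
#' @param spec Master [element_spec()].
#' @param config An [sdr_config()].
#' @param flank_bp Flank retained around each locus.
#' @param min_gap Background gap between planted copies (should exceed
#'   twice `flank_bp` so loci do not overlap neighbouring copies).
#' @param seed Integer seed.
#' @return List with `loci` (DNAStringSet), `panel`, `truth`, `genome`
#'   (the `planted_genome`), and `master`.
#' @export
simulate_copy_study <- function(n_autonomous = 7L, n_encoding = 5L,
                                n_degenerate = 3L, sub_rate = 0.025,
                                spec = element_spec(),
                                config = sdr_config(),
                                flank_bp = config$flank_bp,
                                min_gap = 2L * flank_bp + 500L,
                                seed = 1L) {
  with_seed(seed, {
    master <- make_element(spec, config = config)
    rt <- master$truth$orfs[master$truth$orfs$role == "rt_rh", ]
    copies <- list()
    for (i in seq_len(n_autonomous)) {
      copies[[length(copies) + 1L]] <- degrade(
        master, degradation_spec(sub_rate = sub_rate), config = config)
    }
    for (i in seq_len(n_encoding)) {
      el <- degrade(master, degradation_spec(sub_rate = sub_rate),
                    config = config)
      copies[[length(copies) + 1L]] <-
        strip_terminal_repeats(el, config = config)
    }
    for (i in seq_len(n_degenerate)) {
      el <- degrade(master, degradation_spec(sub_rate = sub_rate),
                    config = config)
      el <- strip_terminal_repeats(el, config = config)
      rt_now <- el$truth$orfs[el$truth$orfs$role == "rt_rh", ]
      fs_pos <- rt_now$start + floor(0.4 * (rt_now$end - rt_now$start))
      copies[[length(copies) + 1L]] <- degrade(
        el, degradation_spec(frameshift_positions = fs_pos),
        config = config)
    }
    n <- length(copies)
    pg <- plant_genome(copies,
                       background_len = (n + 1L) * min_gap + n * 1000L,
                       min_gap = min_gap, config = config)
    loci <- extract_loci(pg, flank_bp = flank_bp)
    list(loci = loci, panel = master$panel, truth = pg$truth,
         genome = pg, master = master)
  })
}
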