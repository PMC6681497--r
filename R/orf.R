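#' Translate a nucleotide sequence under the standard genetic code
#'
#' Codons containing ambiguity codes translate to `X` unless the translation
#' is unambiguous; the terminal stop, if present, is dropped. Internal stops
#' are reported as `*`.
#'
#' @param dna Character scalar over the IUPAC nucleotide alphabet; length must
#'   be a multiple of 3.
#' @return Character scalar amino-acid sequence.
#' @examples
#' translate_dna("ATGGCCTAA")
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) %% 3L != 0L)
    stop("sequence length must be a multiple of 3", call. = FALSE)
  if (nchar(dna) == 0L) return("")
  d <- tryCatch(Biostrings::DNAString(toupper(dna)),
                error = function(e) stop("non-nucleotide symbol in input: ",
                                         conditionMessage(e), call. = FALSE))
  p <- as.character(suppressWarnings(
    Biostrings::translate(d, if.fuzzy.codon = "solve")))
  sub("\\*$", "", p)
}

.revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Scan one strand of `s` (character scalar) for ATG-initiated, stop-terminated
# maximal ORFs. Returns codon-indexed hits per frame.
.scan_frames <- function(s, min_aa) {
  L <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3L
    if (n_codon < 2L) next
    starts <- seq.int(1L + frame, by = 3L, length.out = n_codon)
    codons <- substring(s, starts, starts + 2L)
    stop_i <- which(codons %in% .STOP_CODONS)
    atg_i <- which(codons == "ATG")
    if (!length(stop_i) || !length(atg_i)) next
    # index of the next stop at or after each ATG
    nxt <- stop_i[findInterval(atg_i, stop_i) + 1L]
    ok <- !is.na(nxt)
    atg_i <- atg_i[ok]; nxt <- nxt[ok]
    if (!length(atg_i)) next
    # maximal per stop: first ATG mapping to each stop
    first <- !duplicated(nxt)
    atg_i <- atg_i[first]; nxt <- nxt[first]
    len_aa <- nxt - atg_i
    keep <- len_aa >= min_aa
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      frame = frame,
      nt_start = starts[atg_i[keep]],
      nt_end = starts[nxt[keep]] + 2L,
      protein_len_aa = len_aa[keep])
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Find open reading frames in all six frames
#'
#' Reports every maximal ATG-initiated, stop-terminated ORF with protein
#' length at least `min_aa`, on both strands. Nested ATGs are collapsed to
#' the longest ORF per (frame, stop). Coordinates are 1-based inclusive on
#' the forward strand and include the stop codon; the reported protein
#' excludes it. ORFs spanning N runs carry an ambiguity flag.
#'
#' @param seq Character scalar over `{A,C,G,T,N}` (IUPAC codes tolerated).
#' @param min_aa Minimum protein length in amino acids.
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return A data frame with columns `orf_id`, `start`, `end`, `strand`,
#'   `frame`, `protein_len_aa`, `protein`, `has_ambiguity`.
#' @examples
#' find_orfs("ATGAAATAA", min_aa = 1)
#' @export
find_orfs <- function(seq, min_aa = 100L, both_strands = TRUE) {
  empty <- data.frame(orf_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      frame = integer(), protein_len_aa = integer(),
                      protein = character(), has_ambiguity = logical(),
                      stringsAsFactors = FALSE)
  if (is.na(seq) || nchar(seq) < 6L) return(empty)
  seq <- toupper(seq)
  L <- nchar(seq)
  res <- list()
  plus <- .scan_frames(seq, min_aa)
  if (!is.null(plus)) {
    plus$strand <- "+"
    plus$start <- plus$nt_start
    plus$end <- plus$nt_end
    res[[1L]] <- plus
  }
  if (both_strands) {
    rc <- .revcomp(seq)
    minus <- .scan_frames(rc, min_aa)
    if (!is.null(minus)) {
      minus$strand <- "-"
      minus$start <- L - minus$nt_end + 1L
      minus$end <- L - minus$nt_start + 1L
      res[[length(res) + 1L]] <- minus
    }
  }
  if (!length(res)) return(empty)
  df <- do.call(rbind, res)
  df <- df[order(df$start, df$end), , drop = FALSE]
  nt <- substring(seq, df$start, df$end)
  df$has_ambiguity <- grepl("[^ACGT]", nt)
  orf_nt <- ifelse(df$strand == "+", nt, vapply(nt, .revcomp, character(1)))
  # drop the stop codon before translating
  df$protein <- vapply(orf_nt, function(x)
    translate_dna(substr(x, 1L, nchar(x) - 3L)), character(1),
    USE.NAMES = FALSE)
  df$orf_id <- sprintf("orf%02d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("orf_id", "start", "end", "strand", "frame", "protein_len_aa",
         "protein", "has_ambiguity")]
}

#' Scan a protein for a motif
#'
#' Occurrences may overlap. Positions are 1-based.
#'
#' @param protein Amino-acid sequence (character scalar).
#' @param pattern A regular expression with a fixed-length match.
#' @param name Motif name to report.
#' @return Data frame with columns `name`, `aa_pos`, `matched_span`.
#' @export
scan_motif <- function(protein, pattern, name = "motif") {
  stopifnot(is.character(protein), length(protein) == 1L)
  hits <- gregexpr(paste0("(?=", pattern, ")"), protein, perl = TRUE)[[1]]
  if (hits[1] == -1L)
    return(data.frame(name = character(), aa_pos = integer(),
                      matched_span = character(), stringsAsFactors = FALSE))
  pos <- as.integer(hits)
  span <- vapply(pos, function(p) {
    m <- regexpr(paste0("^(", pattern, ")"), substring(protein, p),
                 perl = TRUE)
    substr(substring(protein, p), 1L, attr(m, "match.length"))
  }, character(1))
  data.frame(name = name, aa_pos = pos, matched_span = span,
             stringsAsFactors = FALSE)
}

#' Scan a protein for the CH-box zinc-knuckle motif
#'
#' The CH-box (CX2CX4HX4C) is a nucleocapsid-like zinc knuckle often carried
#' by Gag proteins of LTR retrotransposons and some YR retrotransposons.
#'
#' @param protein Amino-acid sequence (character scalar).
#' @return Data frame of hits as in [scan_motif()].
#' @examples
#' scan_chbox("CAACDEFGHIKLMC")
#' @export
scan_chbox <- function(protein) {
  scan_motif(protein, "C.{2}C.{4}H.{4}C", name = "CH_box")
}

.get_matrix <- function(matrix_name) {
  env <- new.env()
  ok <- tryCatch({
    utils::data(list = matrix_name, package = "Biostrings", envir = env)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(matrix_name, envir = env))
    stop("unknown substitution matrix: ", matrix_name, call. = FALSE)
  get(matrix_name, envir = env)
}

#' Optimal local protein alignment (Smith-Waterman, affine gaps)
#'
#' @param query,target Amino-acid sequences (character scalars).
#' @param matrix Substitution matrix name shipped with Biostrings
#'   (e.g. `"BLOSUM62"`).
#' @param gap_open,gap_extend Affine gap costs (positive).
#' @return List with `score`, `query_range`, `target_range`,
#'   `aligned_query`, `aligned_target`. An empty optimal alignment is
#'   reported as score 0 with `NA` ranges.
#' @examples
#' smith_waterman("MKV", "MKV")$score
#' @export
smith_waterman <- function(query, target, matrix = "BLOSUM62",
                           gap_open = 11, gap_extend = 1) {
  stopifnot(nchar(query) > 0L, nchar(target) > 0L)
  mat <- .get_matrix(matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend)
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(score = 0, query_range = c(NA_integer_, NA_integer_),
                target_range = c(NA_integer_, NA_integer_),
                aligned_query = "", aligned_target = ""))
  }
  list(score = sc,
       query_range = c(IRanges::start(Biostrings::pattern(pa)),
                       IRanges::end(Biostrings::pattern(pa))),
       target_range = c(IRanges::start(Biostrings::subject(pa)),
                        IRanges::end(Biostrings::subject(pa))),
       aligned_query = as.character(Biostrings::alignedPattern(pa)),
       aligned_target = as.character(Biostrings::alignedSubject(pa)))
}

# Parse "role=<role>" tags from panel FASTA headers.
panel_roles <- function(panel) {
  if (is.null(panel) || length(panel) == 0L) return(character())
  nm <- names(panel)
  m <- regmatches(nm, regexpr("role=[A-Za-z_]+", nm))
  if (length(m) != length(nm))
    stop("panel error: every panel record needs a 'role=' tag in its header",
         call. = FALSE)
  roles <- sub("^role=", "", m)
  bad <- setdiff(unique(roles), .ROLES)
  if (length(bad))
    stop("panel error: unknown role label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  roles
}

#' Assign functional roles to ORFs
#'
#' Each ORF receives the role of its best reference-panel hit above a score
#' floor (`evidence = "panel_alignment"`). An unassigned ORF immediately
#' upstream of, or overlapping, the YR ORF that meets the gag-like length
#' threshold is assigned gag-like positionally, mirroring the practice of
#' calling the first ORF by its position relative to ORF 2. A single ORF
#' whose panel hits span two or more role classes is flagged as a
#' single-ORF layout. Within a copy a role is kept only on its best-scoring
#' ORF; other ORFs with the same role are demoted to `unknown` (frameshift
#' linking, run afterwards, can restore them). An ORF is marked `encoding`
#' for its role only when its protein is strictly longer than the role's
#' `min_aa` threshold.
#'
#' @param orfs Data frame from [find_orfs()].
#' @param panel Optional [Biostrings::AAStringSet] of reference proteins with
#'   `role=` tags in headers.
#' @param config An [sdr_config()].
#' @return `orfs` with columns `role`, `role_evidence`, `panel_score`,
#'   `panel_target`, `panel_target_range_*`, `single_orf_layout`, `encoding`,
#'   `chbox_hits` added.
#' @export
assign_roles <- function(orfs, panel = NULL, config = sdr_config()) {
  n <- nrow(orfs)
  orfs$role <- rep("unknown", n)
  orfs$role_evidence <- rep("none", n)
  orfs$panel_score <- rep(NA_real_, n)
  orfs$panel_target <- rep(NA_character_, n)
  orfs$panel_target_start <- rep(NA_integer_, n)
  orfs$panel_target_end <- rep(NA_integer_, n)
  orfs$single_orf_layout <- rep(FALSE, n)
  orfs$chbox_hits <- rep(0L, n)
  orfs$encoding <- rep(FALSE, n)
  if (n == 0L) return(orfs)
  orfs$chbox_hits <- vapply(orfs$protein,
                            function(p) nrow(scan_chbox(p)), integer(1),
                            USE.NAMES = FALSE)
  roles <- panel_roles(panel)
  if (length(roles)) {
    for (i in seq_len(n)) {
      best <- NULL
      hit_roles <- character()
      for (j in seq_along(panel)) {
        al <- smith_waterman(orfs$protein[i], as.character(panel[[j]]))
        if (al$score >= config$min_panel_score) {
          hit_roles <- c(hit_roles, roles[j])
          if (is.null(best) || al$score > best$score) {
            best <- list(score = al$score, role = roles[j],
                         target = names(panel)[j],
                         trange = al$target_range)
          }
        }
      }
      if (!is.null(best)) {
        orfs$role[i] <- best$role
        orfs$role_evidence[i] <- "panel_alignment"
        orfs$panel_score[i] <- best$score
        orfs$panel_target[i] <- best$target
        orfs$panel_target_start[i] <- best$trange[1]
        orfs$panel_target_end[i] <- best$trange[2]
        if (length(unique(hit_roles)) >= 2L) orfs$single_orf_layout[i] <- TRUE
      }
    }
  } else if (n > 0L) {
    # No panel: fall back to ordering by size and position on one strand.
    orfs <- .assign_roles_positional(orfs, config)
  }
  # positional gag-like rule
  yr <- which(orfs$role == "yr")
  if (length(yr)) {
    y <- yr[which.max(orfs$panel_score[yr])]
    cand <- which(orfs$role == "unknown" &
                    orfs$strand == orfs$strand[y] &
                    orfs$protein_len_aa > config$min_aa[["gag_like"]] &
                    orfs$start < orfs$start[y] &
                    orfs$end >= orfs$start[y] - config$gag_gap_max_bp)
    if (length(cand)) {
      pick <- cand[which.max(orfs$end[cand])]
      orfs$role[pick] <- "gag_like"
      orfs$role_evidence[pick] <- "positional"
    }
  }
  # one role per copy unless frameshift-linked (linking happens later)
  for (r in .ROLES) {
    idx <- which(orfs$role == r)
    if (length(idx) > 1L) {
      sc <- orfs$panel_score[idx]
      sc[is.na(sc)] <- -Inf
      keep <- idx[order(-sc, -orfs$protein_len_aa[idx])][1]
      demote <- setdiff(idx, keep)
      orfs$role[demote] <- "unknown"
    }
  }
  orfs$encoding <- orfs$role %in% .ROLES &
    orfs$protein_len_aa > ifelse(orfs$role %in% .ROLES,
                                 config$min_aa[orfs$role], Inf)
  single <- which(orfs$single_orf_layout)
  if (length(single)) {
    orfs$encoding[single] <- orfs$protein_len_aa[single] >
      sum(config$min_aa)
  }
  orfs
}

# Panel-free fallback: pick the largest ORF cluster on one strand and assign
# roles by order and size.
.assign_roles_positional <- function(orfs, config) {
  for (str in c("+", "-")) {
    idx <- which(orfs$strand == str)
    if (length(idx) < 1L) next
    cand <- idx[orfs$protein_len_aa[idx] > config$min_aa[["rt_rh"]]]
    if (!length(cand)) next
    rt <- cand[which.max(orfs$protein_len_aa[cand])]
    orfs$role[rt] <- "rt_rh"; orfs$role_evidence[rt] <- "positional"
    upstream <- idx[orfs$start[idx] < orfs$start[rt] &
                      orfs$protein_len_aa[idx] > config$min_aa[["yr"]]]
    upstream <- setdiff(upstream, rt)
    if (length(upstream)) {
      y <- upstream[which.max(orfs$start[upstream])]
      orfs$role[y] <- "yr"; orfs$role_evidence[y] <- "positional"
    }
    break
  }
  orfs
}

#' Link frameshift-split ORF fragments
#'
#' Two same-strand ORFs in different frames, separated by at most
#' `frameshift_gap_bp`, whose reference-panel alignments cover adjacent and
#' minimally overlapping intervals of the same panel protein are linked as
#' one frameshifted gene. Linked fragments share the panel role but are not
#' potentially encoding for it.
#'
#' @param orfs Data frame from [assign_roles()].
#' @param panel Reference panel used for role assignment.
#' @param config An [sdr_config()].
#' @return `orfs` with columns `frameshift_partner` and `frameshift` added.
#' @export
detect_frameshift_pairs <- function(orfs, panel = NULL,
                                    config = sdr_config()) {
  n <- nrow(orfs)
  orfs$frameshift_partner <- rep(NA_character_, n)
  orfs$frameshift <- rep(FALSE, n)
  if (n < 2L || is.null(panel) || length(panel) == 0L) return(orfs)
  roles <- panel_roles(panel)
  # candidate hits: use stored best-panel alignments, recomputing for ORFs
  # whose best hit was demoted but may still support a fragment
  hit_of <- function(i) {
    if (!is.na(orfs$panel_target[i]))
      return(list(target = orfs$panel_target[i],
                  range = c(orfs$panel_target_start[i],
                            orfs$panel_target_end[i]),
                  score = orfs$panel_score[i]))
    best <- NULL
    for (j in seq_along(panel)) {
      al <- smith_waterman(orfs$protein[i], as.character(panel[[j]]))
      if (al$score >= config$min_panel_score &&
          (is.null(best) || al$score > best$score))
        best <- list(target = names(panel)[j], range = al$target_range,
                     score = al$score)
    }
    best
  }
  hits <- lapply(seq_len(n), hit_of)
  ord <- order(orfs$start)
  for (a_i in seq_along(ord)) {
    for (b_i in seq_along(ord)) {
      if (b_i <= a_i) next
      a <- ord[a_i]; b <- ord[b_i]
      if (orfs$strand[a] != orfs$strand[b]) next
      if (orfs$frame[a] == orfs$frame[b]) next
      gap <- orfs$start[b] - orfs$end[a] - 1L
      if (gap > config$frameshift_gap_bp) next
      ha <- hits[[a]]; hb <- hits[[b]]
      if (is.null(ha) || is.null(hb) || ha$target != hb$target) next
      ra <- ha$range; rb <- hb$range
      ov <- min(ra[2], rb[2]) - max(ra[1], rb[1]) + 1L
      short <- min(ra[2] - ra[1], rb[2] - rb[1]) + 1L
      if (ov > 0.5 * short) next     # fragments must cover distinct regions
      # genomic order must match panel order (strand-aware)
      upstream_first <- if (orfs$strand[a] == "+") ra[1] <= rb[1]
      else ra[1] >= rb[1]
      if (!upstream_first) next
      role <- roles[match(ha$target, names(panel))]
      orfs$frameshift_partner[a] <- orfs$orf_id[b]
      orfs$frameshift_partner[b] <- orfs$orf_id[a]
      orfs$frameshift[c(a, b)] <- TRUE
      orfs$role[c(a, b)] <- role
      orfs$encoding[c(a, b)] <- FALSE
    }
  }
  orfs
}
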