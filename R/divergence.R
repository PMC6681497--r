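#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch alignment under affine gap scoring, for nucleotide or
#' protein sequences. A gap of length g costs `gap_open + g * gap_extend`.
#'
#' @param a,b Sequences (character scalars) over one alphabet.
#' @param type `"dna"` or `"protein"` (guessed from the alphabet when
#'   missing).
#' @param match,mismatch Nucleotide scores (ignored for proteins).
#' @param matrix Protein substitution matrix name (ignored for DNA).
#' @param gap_open,gap_extend Affine gap costs (positive).
#' @return List with `score`, `a_aln`, `b_aln` (gapped strings).
#' @examples
#' global_align("ACGT", "ACT")
#' @export
global_align <- function(a, b, type = NULL, match = 2, mismatch = -2,
                         matrix = "BLOSUM62", gap_open = 10, gap_extend = 1) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  a <- toupper(a); b <- toupper(b)
  if (is.null(type)) {
    type <- if (grepl("[^ACGTUNRYSWKMBDHV-]", paste0(a, b))) "protein"
    else "dna"
  }
  is_dna_a <- !grepl("[^ACGTUNRYSWKMBDHV]", a)
  is_dna_b <- !grepl("[^ACGTUNRYSWKMBDHV]", b)
  if (type == "dna" && (!is_dna_a || !is_dna_b))
    stop("alphabet mismatch: non-nucleotide symbols in DNA alignment",
         call. = FALSE)
  if (type == "dna") {
    mat <- Biostrings::nucleotideSubstitutionMatrix(
      match = match, mismatch = mismatch, baseOnly = FALSE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
  } else {
    mat <- .get_matrix(matrix)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
  }
  list(score = Biostrings::score(pa),
       a_aln = as.character(Biostrings::alignedPattern(pa)),
       b_aln = as.character(Biostrings::alignedSubject(pa)))
}

# Columns masked by the confident-region policy: a column is masked when the
# gap fraction in the window of `window` columns centred on it exceeds
# `max_gap_frac`.
.masked_columns <- function(gapcol, window = 5L, max_gap_frac = 0.5) {
  n <- length(gapcol)
  if (!n) return(logical(0))
  half <- window %/% 2L
  cs <- cumsum(c(0L, as.integer(gapcol)))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  frac <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  frac > max_gap_frac
}

#' Percent identity of a pairwise alignment with confident-region masking
#'
#' Identity is matches over aligned columns after masking. Masking drops
#' columns in sliding windows whose gap fraction exceeds the policy
#' threshold, so poorly aligned (gap-rich) stretches do not contribute; an
#' unmasked gap column counts as a non-match.
#'
#' @param a_aln,b_aln Gapped aligned strings of equal length.
#' @param mask_policy List with `window` (columns) and `max_gap_frac`, or
#'   `NULL` to disable masking.
#' @return List with `identity_pct` (`NA` when no columns survive masking)
#'   and `aligned_length` (columns after masking).
#' @export
pairwise_identity <- function(a_aln, b_aln,
                              mask_policy = list(window = 5L,
                                                 max_gap_frac = 0.5)) {
  stopifnot(nchar(a_aln) == nchar(b_aln))
  ca <- strsplit(a_aln, "", fixed = TRUE)[[1]]
  cb <- strsplit(b_aln, "", fixed = TRUE)[[1]]
  gapcol <- ca == "-" | cb == "-"
  masked <- if (is.null(mask_policy)) rep(FALSE, length(ca))
  else .masked_columns(gapcol, mask_policy$window, mask_policy$max_gap_frac)
  keep <- !masked
  n_keep <- sum(keep)
  if (n_keep == 0L)
    return(list(identity_pct = NA_real_, aligned_length = 0L))
  matches <- sum(ca[keep] == cb[keep] & !gapcol[keep])
  list(identity_pct = 100 * matches / n_keep, aligned_length = n_keep)
}

#' Mean pairwise identity of a sequence set
#'
#' Aligns all pairs globally and averages masked identities, reporting the
#' number of sequences and the mean post-mask alignment length alongside the
#' mean, in the style of per-genome identity summaries.
#'
#' @param seqs Character vector (or `XStringSet`) of two or more sequences.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @param mask_policy See [pairwise_identity()].
#' @return List with `mean_identity_pct`, `n`, `mean_alignment_length`,
#'   `n_pairs`.
#' @export
mean_pairwise_identity <- function(seqs, level = c("nucleotide",
                                                   "amino_acid"),
                                   mask_policy = list(window = 5L,
                                                      max_gap_frac = 0.5)) {
  level <- match.arg(level)
  seqs <- as.character(seqs)
  if (length(seqs) < 2L)
    return(list(mean_identity_pct = NA_real_, n = length(seqs),
                mean_alignment_length = NA_real_, n_pairs = 0L))
  type <- if (level == "nucleotide") "dna" else "protein"
  prs <- combn(length(seqs), 2L)
  ids <- numeric(0); lens <- numeric(0)
  for (k in seq_len(ncol(prs))) {
    al <- global_align(seqs[prs[1, k]], seqs[prs[2, k]], type = type)
    pi <- pairwise_identity(al$a_aln, al$b_aln, mask_policy)
    if (!is.na(pi$identity_pct)) {
      ids <- c(ids, pi$identity_pct)
      lens <- c(lens, pi$aligned_length)
    }
  }
  if (!length(ids))
    return(list(mean_identity_pct = NA_real_, n = length(seqs),
                mean_alignment_length = NA_real_, n_pairs = 0L))
  list(mean_identity_pct = mean(ids), n = length(seqs),
       mean_alignment_length = mean(lens), n_pairs = length(ids))
}

#' Poisson-corrected evolutionary distance
#'
#' Multiple-hit correction `d = -ln(1 - p)` for an observed proportion of
#' differing sites `p`.
#'
#' @param p Proportion(s) of differing sites, in `[0, 1)`.
#' @return Distance(s) in substitutions per site.
#' @examples
#' poisson_distance(0.5)
#' @export
poisson_distance <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p >= 1))
    stop("p must lie in [0, 1)", call. = FALSE)
  -log(1 - p)
}

#' Pairwise p-distance matrix
#'
#' Proportion of differing sites per pair, from global alignments with
#' confident-region masking.
#'
#' @param seqs Named character vector (or `XStringSet`).
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @param mask_policy See [pairwise_identity()].
#' @return Symmetric numeric matrix with a zero diagonal.
#' @export
p_distance_matrix <- function(seqs, level = "nucleotide",
                              mask_policy = list(window = 5L,
                                                 max_gap_frac = 0.5)) {
  nms <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- nms
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- paste0("s", seq_len(n))
  D <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(D)
  type <- if (level == "nucleotide") "dna" else "protein"
  for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    al <- global_align(seqs[i], seqs[j], type = type)
    pi <- pairwise_identity(al$a_aln, al$b_aln, mask_policy)
    p <- if (is.na(pi$identity_pct)) NA_real_ else 1 - pi$identity_pct / 100
    D[i, j] <- D[j, i] <- p
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via [ape::nj()]); negative branch-length
#' estimates are clamped to zero and flagged. Two taxa yield the single
#' edge with the distance split evenly.
#'
#' @param D Symmetric distance matrix with labels and zero diagonal.
#' @return An [ape::phylo] tree; attribute `clamped` counts clamped edges.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D)) stop("distance matrix must be square",
                               call. = FALSE)
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric",
                                      call. = FALSE)
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero",
                              call. = FALSE)
  if (any(D < 0)) stop("distances must be non-negative", call. = FALSE)
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  if (nrow(D) < 2L) stop("need at least 2 taxa", call. = FALSE)
  if (nrow(D) == 2L) {
    tr <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);", rownames(D)[1],
                                        D[1, 2] / 2, rownames(D)[2],
                                        D[1, 2] / 2))
    attr(tr, "clamped") <- 0L
    return(tr)
  }
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  tr$edge.length[neg] <- 0
  attr(tr, "clamped") <- sum(neg)
  tr
}

# All candidate monophyletic leaf sets of an unrooted tree: both sides of
# every internal edge, plus singletons.
.tree_splits <- function(tree) {
  labs <- tree$tip.label
  n <- length(labs)
  sets <- lapply(seq_len(n), function(i) labs[i])
  if (n > 3L) {
    pp <- ape::prop.part(tree)
    for (cl in pp) {
      side <- labs[cl]
      if (length(side) > 1L && length(side) < n)
        sets[[length(sets) + 1L]] <- side
      comp <- setdiff(labs, side)
      if (length(comp) > 1L && length(comp) < n)
        sets[[length(sets) + 1L]] <- comp
    }
  }
  unique(sets)
}

#' Collapse redundant same-species sequences
#'
#' Every maximal monophyletic group whose members all share one species
#' label and whose maximum pairwise divergence is below `threshold` is
#' collapsed to a single representative (the longest sequence; ties broken
#' by input order). Groups containing two or more species are untouched, as
#' are same-species groups at or above the threshold.
#'
#' @param seqs Named character vector of sequences.
#' @param species Character vector of species labels, parallel to `seqs`.
#' @param D Pairwise distance matrix (p-distance by default policy) with
#'   rownames matching `names(seqs)`.
#' @param tree Optional precomputed [ape::phylo]; built by [nj_tree()] from
#'   `D` when missing (Poisson-corrected distances feed the tree when
#'   `corrected = TRUE`).
#' @param threshold Divergence below which a group collapses (strict).
#' @param corrected Apply the threshold to Poisson-corrected distances
#'   instead of raw p-distances.
#' @return Character vector of retained sequence names.
#' @export
redundancy_filter <- function(seqs, species, D, tree = NULL,
                              threshold = 0.35, corrected = FALSE) {
  if (is.null(names(seqs))) stop("seqs must be named", call. = FALSE)
  if (length(species) != length(seqs) || any(is.na(species)) ||
      any(!nzchar(species)))
    stop("every sequence needs a species label", call. = FALSE)
  names(species) <- names(seqs)
  D <- as.matrix(D)
  if (!all(names(seqs) %in% rownames(D)))
    stop("distance matrix must cover all sequences", call. = FALSE)
  if (is.null(tree)) {
    Dt <- if (corrected) {
      M <- D; M[] <- poisson_distance(pmin(D, 1 - 1e-12)); M
    } else D
    tree <- nj_tree(Dt[names(seqs), names(seqs)])
  }
  thr_D <- if (corrected) {
    M <- D; M[] <- poisson_distance(pmin(D, 1 - 1e-12)); M
  } else D
  sets <- .tree_splits(tree)
  qualifies <- vapply(sets, function(s) {
    if (length(unique(species[s])) != 1L) return(FALSE)
    if (length(s) == 1L) return(TRUE)
    max(thr_D[s, s]) < threshold
  }, logical(1))
  qsets <- sets[qualifies]
  qsets <- qsets[order(-lengths(qsets))]
  taken <- character(0)
  retained <- character(0)
  for (s in qsets) {
    if (any(s %in% taken)) next
    taken <- c(taken, s)
    rep_i <- s[order(-nchar(seqs[s]), match(s, names(seqs)))][1]
    retained <- c(retained, rep_i)
  }
  # anything not covered by a qualifying set is kept as-is
  retained <- c(retained, setdiff(names(seqs), taken))
  retained[order(match(retained, names(seqs)))]
}

#' Write a distance matrix as square TSV
#'
#' @param D Matrix with labels.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(D, path) {
  df <- data.frame(label = rownames(D), as.data.frame(D),
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
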