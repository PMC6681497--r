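# Independent reference implementations used as oracles. These are written
# from the definitions, not from the package internals.

orc_revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Codon-by-codon six-frame ORF scan.
orc_orfs <- function(seq, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else orc_revcomp(seq)
    L <- nchar(s)
    for (f in 0:2) {
      pos <- 1L + f
      orf_start <- NA_integer_
      while (pos + 2L <= L) {
        cod <- substr(s, pos, pos + 2L)
        if (is.na(orf_start) && cod == "ATG") orf_start <- pos
        if (cod %in% stops) {
          if (!is.na(orf_start)) {
            len <- (pos - orf_start) / 3L
            if (len >= min_aa) {
              a <- orf_start; b <- pos + 2L
              if (strand == "-") { tmp <- a; a <- L - b + 1L; b <- L - tmp + 1L }
              rows[[length(rows) + 1L]] <-
                data.frame(start = a, end = b, strand = strand,
                           protein_len_aa = len)
            }
          }
          orf_start <- NA_integer_
        }
        pos <- pos + 3L
      }
    }
  }
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), protein_len_aa = integer()))
  df <- do.call(rbind, rows)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Best-scoring interval of an integer vector by explicit double loop
# (leftmost end, then longest), then recursive removal — the segment
# decomposition definition, implemented independently.
orc_segments <- function(sc, min_score = 1) {
  n <- length(sc)
  out <- list()
  recurse <- function(from, to) {
    if (from > to) return(invisible(NULL))
    best_val <- -Inf; best_s <- NA; best_e <- NA
    for (e in from:to) {
      acc <- 0
      s_val <- -Inf; s_at <- NA
      for (s in e:from) {
        acc <- acc + sc[s]
        if (acc >= s_val) { s_val <- acc; s_at <- s }
      }
      if (s_val > best_val) { best_val <- s_val; best_s <- s_at; best_e <- e }
    }
    if (best_val < min_score) return(invisible(NULL))
    out[[length(out) + 1L]] <<- c(best_s, best_e, best_val)
    recurse(from, best_s - 1L)
    recurse(best_e + 1L, to)
  }
  recurse(1L, n)
  out
}

# Direct repeat pairs by exhaustive per-diagonal decomposition.
orc_repeat_pairs <- function(seq, min_len, f, pen) {
  L <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  rows <- list()
  if (L >= 2L * min_len) {
    for (d in 1:(L - 1L)) {
      n <- L - d
      if (n < 1L) next
      m <- (ch[1:n] == ch[(1 + d):(d + n)]) & ch[1:n] != "N"
      segs <- orc_segments(ifelse(m, 1, -pen),
                           min_score = min_len * (1 - (1 + pen) * f))
      for (sg in segs) {
        s <- sg[1]; e <- sg[2]
        len <- e - s + 1L
        if (len < min_len || len > d) next
        mis <- sum(!m[s:e])
        if (mis > f * len + 1e-9) next
        rows[[length(rows) + 1L]] <-
          data.frame(start1 = s, end1 = e, start2 = s + d, end2 = e + d)
      }
    }
  }
  if (!length(rows))
    return(data.frame(start1 = integer(), end1 = integer(),
                      start2 = integer(), end2 = integer()))
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$start1, df$start2), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# Affine-gap alignment score by dynamic programming written from the
# recurrences (gap of length g costs open + g * ext).
orc_align_score <- function(a, b, submat, open, ext, local = FALSE) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)   # gap in b (consume a)
  Y <- matrix(NEG, n + 1L, m + 1L)   # gap in a (consume b)
  M[1, 1] <- 0
  if (!local) {
    for (i in 2:(n + 1L)) X[i, 1] <- -open - (i - 1L) * ext
    for (j in 2:(m + 1L)) Y[1, j] <- -open - (j - 1L) * ext
  }
  best_local <- 0
  for (i in 2:(n + 1L)) {
    for (j in 2:(m + 1L)) {
      sub <- submat[A[i - 1L], B[j - 1L]]
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sub
      if (local) M[i, j] <- max(M[i, j], sub, 0)
      X[i, j] <- max(M[i - 1L, j] - open - ext, X[i - 1L, j] - ext)
      Y[i, j] <- max(M[i, j - 1L] - open - ext, Y[i, j - 1L] - ext)
      if (local) best_local <- max(best_local, M[i, j])
    }
  }
  if (local) best_local
  else max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate a copy of `unit` at `m` positions within [lo, hi], spaced at
# least 5 apart (the generator's planting convention).
mutate_spaced <- function(unit, m, lo = 9L, hi = length(unit) - 8L) {
  if (m > 0) {
    span <- hi - 5L * (m - 1L)
    x <- sort(sample(lo:span, m))
    for (p in x + 5L * (0:(m - 1L)))
      unit[p] <- sample(setdiff(c("A", "C", "G", "T"), unit[p]), 1)
  }
  unit
}

# Assemble flank1 + unit1 + mid + unit2 + flank2, forcing the `guard`
# columns flanking the pair to mismatch so the planted pair is a true
# maximal repeat (the generator's own convention).
plant_pair <- function(f1, u1, mid, u2, f2, guard = 8L) {
  f1 <- strsplit(f1, "")[[1]]; mid <- strsplit(mid, "")[[1]]
  f2 <- strsplit(f2, "")[[1]]
  n1 <- length(f1); nm <- length(mid)
  for (k in seq_len(guard)) {
    while (f1[n1 - k + 1L] == mid[nm - k + 1L])
      f1[n1 - k + 1L] <- sample(c("A", "C", "G", "T"), 1)
    while (mid[k] == f2[k])
      f2[k] <- sample(c("A", "C", "G", "T"), 1)
  }
  paste(c(f1, strsplit(u1, "")[[1]], mid, strsplit(u2, "")[[1]], f2),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}
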