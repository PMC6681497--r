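test_that("translate_dna follows the standard code and ambiguity rules", {
  expect_equal(translate_dna("ATG"), "M")
  expect_equal(translate_dna("ATGGCCTAA"), "MA")
  expect_equal(translate_dna("ATGANGGCC"), "MXA")
  expect_error(translate_dna("ATGQ"), "multiple of 3|non-nucleotide")
  expect_error(translate_dna("AT!GCC"), "non-nucleotide")
})

test_that("find_orfs reports maximal ATG-to-stop ORFs", {
  o <- find_orfs("ATGAAATAA", min_aa = 1)
  expect_equal(nrow(o), 1L)
  expect_equal(o$protein, "MK")
  expect_equal(o$protein_len_aa, 2L)
  expect_equal(o$frame, 0L)
  expect_equal(c(o$start, o$end), c(1L, 9L))
  # nested ATG collapses to the longest ORF per stop
  o2 <- find_orfs("ATGAAAATGAAATAA", min_aa = 1)
  expect_equal(o2$start[o2$strand == "+"], 1L)
  # no ATG anywhere -> empty
  expect_equal(nrow(find_orfs("CCCCCCCCCTAACCC", min_aa = 1)), 0L)
})

test_that("find_orfs equals a brute-force six-frame scan on random input", {
  set.seed(21)
  for (rep in 1:40) {
    s <- random_dna(300)
    got <- find_orfs(s, min_aa = 5)
    exp <- orc_orfs(s, min_aa = 5)
    got <- got[order(got$start, got$end, got$strand),
               c("start", "end", "strand", "protein_len_aa")]
    rownames(got) <- NULL
    expect_equal(got, exp, info = paste("replicate", rep))
  }
})

test_that("reverse complementing the input mirrors the ORF set", {
  set.seed(22)
  for (rep in 1:10) {
    s <- random_dna(400)
    L <- nchar(s)
    a <- find_orfs(s, min_aa = 5)
    b <- find_orfs(orc_revcomp(s), min_aa = 5)
    mirrored <- data.frame(start = L - b$end + 1L, end = L - b$start + 1L,
                           strand = ifelse(b$strand == "+", "-", "+"),
                           protein_len_aa = b$protein_len_aa)
    mirrored <- mirrored[order(mirrored$start, mirrored$end,
                               mirrored$strand), ]
    rownames(mirrored) <- NULL
    a2 <- a[order(a$start, a$end, a$strand),
            c("start", "end", "strand", "protein_len_aa")]
    rownames(a2) <- NULL
    expect_equal(a2, mirrored)
  }
})

test_that("CH-box scanning matches its definition with overlaps", {
  hit <- scan_chbox("CAACDEFGHIKLMC")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$aa_pos, 1L)
  expect_equal(nrow(scan_chbox("CAACDEFGHIKLMA")), 0L)
  # independent position-by-position oracle on random proteins
  set.seed(23)
  for (rep in 1:10) {
    p <- paste(sample(c("C", "H", "A", "G"), 1000, replace = TRUE,
                      prob = c(.3, .3, .2, .2)), collapse = "")
    got <- scan_chbox(p)$aa_pos
    ch <- strsplit(p, "")[[1]]
    exp <- which(vapply(seq_len(nchar(p) - 13L), function(i) {
      ch[i] == "C" && ch[i + 3L] == "C" && ch[i + 8L] == "H" &&
        ch[i + 13L] == "C"
    }, logical(1)))
    expect_equal(got, exp)
  }
})

test_that("smith_waterman scores match the matrix and a brute-force DP", {
  b62 <- sdrscan:::.get_matrix("BLOSUM62")
  expect_equal(smith_waterman("MKV", "MKV")$score,
               b62["M", "M"] + b62["K", "K"] + b62["V", "V"])
  empty <- smith_waterman("AAAA", "WWWW")
  expect_equal(empty$score, 0)
  expect_true(is.na(empty$query_range[1]))
  expect_error(smith_waterman("MKV", "MKV", matrix = "NOSUCH"), "unknown")
  set.seed(24)
  for (rep in 1:25) {
    a <- random_protein(6); b <- random_protein(6)
    got <- smith_waterman(a, b, gap_open = 11, gap_extend = 1)$score
    exp <- orc_align_score(a, b, b62, open = 11, ext = 1, local = TRUE)
    expect_equal(got, exp, info = paste(a, b))
  }
})

test_that("roles are assigned from the panel with positional gag fallback", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 31, config = cfg)
  orfs <- find_orfs(el$seq, cfg$orf_min_aa)
  ann <- assign_roles(orfs, el$panel, cfg)
  roles <- ann$role[ann$role %in% c("gag_like", "yr", "rt_rh")]
  ord <- ann[ann$role %in% c("gag_like", "yr", "rt_rh"), ]
  ord <- ord[order(ord$start), ]
  expect_equal(ord$role, c("gag_like", "yr", "rt_rh"))
  expect_true(all(ord$encoding))
  # without its gag panel entry, the gag ORF is still called positionally
  panel_no_gag <- el$panel[!grepl("gag", names(el$panel))]
  ann2 <- assign_roles(orfs, panel_no_gag, cfg)
  gag <- ann2[ann2$role == "gag_like", ]
  expect_equal(nrow(gag), 1L)
  expect_equal(gag$role_evidence, "positional")
  expect_equal(gag$start, ord$start[1])
  # no two ORFs share a role
  expect_false(any(duplicated(ann$role[ann$role %in%
                                         c("gag_like", "yr", "rt_rh")])))
})

test_that("a single ORF hitting several roles is flagged single-ORF layout", {
  cfg <- small_config()
  el <- make_element(small_spec(single_orf_layout = TRUE), seed = 32,
                     config = cfg)
  orfs <- assign_roles(find_orfs(el$seq, cfg$orf_min_aa), el$panel, cfg)
  expect_true(any(orfs$single_orf_layout))
  cp <- annotate_copy(el$seq, "s", el$panel, cfg)[[1]]
  expect_equal(cp$status, "putative_autonomous")
})

test_that("the gag-like protein carries a CH-box when planted", {
  cfg <- small_config()
  el <- make_element(small_spec(include_chbox = TRUE), seed = 33,
                     config = cfg)
  orfs <- assign_roles(find_orfs(el$seq, cfg$orf_min_aa), el$panel, cfg)
  gag <- orfs[orfs$role == "gag_like", ]
  expect_gte(gag$chbox_hits, 1L)
})

test_that("frameshift fragments are linked only across frames on one strand", {
  cfg <- small_config()
  spec <- small_spec()
  el <- make_element(spec, seed = 34, config = cfg)
  rt <- el$truth$orfs[el$truth$orfs$role == "rt_rh", ]
  # mid-ORF single-base deletion: downstream fragment shifts frame
  fs <- degrade(el, degradation_spec(
    frameshift_positions = rt$start + 300L), seed = 35, config = cfg)
  orfs <- find_orfs(fs$seq, 40L)
  orfs <- assign_roles(orfs, el$panel, cfg)
  orfs <- detect_frameshift_pairs(orfs, el$panel, cfg)
  if (any(orfs$frameshift)) {
    linked <- orfs[orfs$frameshift, ]
    expect_true(all(linked$role == "rt_rh"))
    expect_false(any(linked$encoding))
    expect_equal(length(unique(linked$strand)), 1L)
    expect_gte(length(unique(linked$frame)), 2L)
  }
  # two fragments in the same frame (premature stop) are never linked
  yr <- el$truth$orfs[el$truth$orfs$role == "yr", ]
  chars <- strsplit(el$seq, "")[[1]]
  stop_at <- yr$start + 150L - ((150L) %% 3L)   # in-frame position
  chars[stop_at:(stop_at + 2L)] <- c("T", "A", "A")
  orfs2 <- detect_frameshift_pairs(
    assign_roles(find_orfs(paste(chars, collapse = ""), 40L), el$panel, cfg),
    el$panel, cfg)
  same_frame_linked <- orfs2$frameshift &
    ave(orfs2$frame, orfs2$frameshift_partner, FUN = length) > 1
  frag <- orfs2[orfs2$frameshift, ]
  if (nrow(frag) >= 2L) {
    for (i in seq_len(nrow(frag))) {
      p <- frag$frameshift_partner[i]
      j <- which(orfs2$orf_id == p)
      expect_false(orfs2$frame[i] == orfs2$frame[j] &&
                     orfs2$strand[i] == orfs2$strand[j])
    }
  }
})
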