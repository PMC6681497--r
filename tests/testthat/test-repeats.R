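test_that("find_repeat_pairs resolves simple and planted duplications", {
  p <- find_repeat_pairs("ACGTACGT", seed_len = 4, min_repeat_len = 4,
                         low_complexity_filter = FALSE)
  expect_equal(nrow(p), 1L)
  expect_equal(unlist(p[1, 1:4], use.names = FALSE), c(1L, 4L, 5L, 8L))
  expect_equal(p$identity_pct, 100)
  # planted 60 bp duplicate inside random background (flank-guarded so the
  # plant is a true maximal repeat)
  set.seed(41)
  for (rep in 1:20) {
    unit <- random_dna(60)
    s <- plant_pair(random_dna(40), unit, random_dna(60), unit,
                    random_dna(40))
    p <- find_repeat_pairs(s, seed_len = 8, min_repeat_len = 50)
    expect_equal(nrow(p), 1L)
    expect_equal(p$length, 60L)
    expect_equal(unlist(p[1, 1:4], use.names = FALSE),
                 c(41L, 100L, 161L, 220L))
    # sequence shorter than two units -> empty
    expect_equal(nrow(find_repeat_pairs(random_dna(60), min_repeat_len = 50)),
                 0L)
  }
})

test_that("find_repeat_pairs equals the exhaustive oracle", {
  # structured, repeat-rich strings over a two-letter alphabet plus
  # random four-letter strings, small parameters with guaranteed seeding
  set.seed(42)
  cases <- character()
  for (n in c(10, 14, 18, 24, 30)) {
    cases <- c(cases,
               vapply(1:30, function(i)
                 paste(sample(c("A", "C"), n, replace = TRUE),
                       collapse = ""), character(1)),
               vapply(1:30, function(i) random_dna(n), character(1)))
  }
  cases <- c(cases, vapply(1:60, function(i) random_dna(40), character(1)))
  for (s in cases) {
    got <- find_repeat_pairs(s, seed_len = 3, min_repeat_len = 6,
                             max_mismatch_frac = 0.2, mismatch_penalty = 2,
                             low_complexity_filter = FALSE)
    exp <- orc_repeat_pairs(s, min_len = 6, f = 0.2, pen = 2)
    got <- got[, c("start1", "end1", "start2", "end2")]
    rownames(got) <- NULL
    expect_equal(got, exp, info = s)
  }
})

test_that("planted repeats at tolerated divergence are always recovered", {
  set.seed(43)
  for (rep in 1:60) {
    unit <- random_dna(60)
    u2 <- mutate_spaced(strsplit(unit, "")[[1]], 5)
    s <- plant_pair(random_dna(40), unit, random_dna(50),
                    paste(u2, collapse = ""), random_dna(40))
    p <- find_repeat_pairs(s, seed_len = 8, min_repeat_len = 50,
                           max_mismatch_frac = 0.1)
    expect_equal(nrow(p), 1L)
    expect_equal(p$length, 60L)
    expect_equal(p$mismatches, 5L)
  }
})

test_that("terminal repeats are labeled A then B with ties by quality", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 44, config = cfg)
  pr <- find_repeat_pairs(el$seq, cfg$seed_len, cfg$min_repeat_len)
  units <- label_terminal_repeats(pr, nchar(el$seq), cfg$terminal_window_bp)
  expect_setequal(units$label, c("A1", "A2", "B1", "B2"))
  tu <- el$truth$repeat_units
  for (lab in c("A1", "A2", "B1", "B2")) {
    expect_equal(units$start[units$label == lab],
                 tu$start[tu$label == lab])
    expect_equal(units$end[units$label == lab], tu$end[tu$label == lab])
  }
  # one terminal pair only -> A labels, no B
  one <- el
  u <- el$truth$repeat_units
  sub <- substring(el$seq, 1, u$end[u$label == "A2"])
  pr1 <- find_repeat_pairs(sub, cfg$seed_len, cfg$min_repeat_len)
  pr1 <- pr1[pr1$end2 <= nchar(sub), , drop = FALSE]
  # none when no pairs
  expect_equal(nrow(label_terminal_repeats(
    sdrscan:::.empty_pairs(), 1000L)), 0L)
})

test_that("architecture classes follow the ordered layout", {
  cfg <- small_config()
  for (arch in c("canonical_B1A2B2", "variant_B1B2A2", "A_pair_only")) {
    el <- make_element(small_spec(architecture = arch), seed = 45,
                       config = cfg)
    cp <- annotate_copy(el$seq, "x", el$panel, cfg)[[1]]
    expect_equal(cp$architecture$class, arch, info = arch)
  }
  el0 <- make_element(small_spec(architecture = "none"), seed = 46,
                      config = cfg)
  cp0 <- annotate_copy(el0$seq, "x", el0$panel, cfg)[[1]]
  expect_equal(cp0$architecture$class, "none")
  expect_equal(nrow(cp0$repeat_units), 0L)
})

test_that("an unusually distant repeat raises a distance flag", {
  cfg <- small_config(gap_warn_bp = 500L)
  el <- make_element(small_spec(utr3_bp = 900L), seed = 47, config = cfg)
  cp <- annotate_copy(el$seq, "x", el$panel, cfg)[[1]]
  expect_true("large_gap_3prime" %in% cp$architecture$distance_flags)
})

test_that("boundary calls use SDRs, falling back to the ORF span", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 48, config = cfg)
  cp <- annotate_copy(el$seq, "x", el$panel, cfg)[[1]]
  expect_equal(cp$boundaries$confidence, "sdr")
  expect_equal(cp$boundaries$start, 1L)
  expect_equal(cp$boundaries$end, el$truth$length)
  stripped <- strip_terminal_repeats(el, config = cfg)
  cp2 <- annotate_copy(stripped$seq, "x", el$panel, cfg)[[1]]
  expect_equal(cp2$boundaries$confidence, "orf_only")
  ro <- stripped$truth$orfs
  expect_equal(cp2$boundaries$start, min(ro$start))
  expect_equal(cp2$boundaries$end, max(ro$end))
})

test_that("repeat conservation gives the recent-insertion signal", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 49, config = cfg)
  cp <- annotate_copy(el$seq, "x", el$panel, cfg)[[1]]
  expect_true(cp$activity$recent_insertion_signal)
  el2 <- make_element(small_spec(identity_B = 96), seed = 50, config = cfg)
  cp2 <- annotate_copy(el2$seq, "x", el2$panel, cfg)[[1]]
  expect_false(cp2$activity$recent_insertion_signal)
  expect_lt(cp2$activity$pair_identities[["B"]], 100)
  expect_identical(activity_signal(sdrscan:::.empty_units()
                                   )$recent_insertion_signal, NA)
})

test_that("SIRE-like remnants match only the terminal-repeat region", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 51, config = cfg)
  u <- el$truth$repeat_units
  term <- substring(el$seq, u$start[u$label == "A2"],
                    u$end[u$label == "B2"])
  ro <- el$truth$orfs
  internal <- substring(el$seq, min(ro$start), max(ro$end))
  remnant <- paste0(random_dna(100), term, random_dna(100))
  det <- detect_sire_like(remnant, term, internal,
                          find_orfs(remnant, cfg$orf_min_aa))
  expect_true(det$sire_like)
  # the full element matches the internal region too -> not a remnant
  det2 <- detect_sire_like(el$seq, term, internal, NULL)
  expect_false(det2$sire_like)
  # random background matches nothing
  det3 <- detect_sire_like(random_dna(600), term, internal, NULL)
  expect_false(det3$sire_like)
  expect_warning(detect_sire_like(remnant, ""), "skipped")
})

test_that("head-to-tail arrays are split into one element per unit", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 52, config = cfg)
  pg <- plant_genome(list(el), background_len = 6000, tandem_counts = 2,
                     min_gap = 1500, seed = 53, config = cfg)
  loci <- extract_loci(pg, flank_bp = 600)
  expect_equal(length(loci), 1L)
  res <- run_pipeline(loci, el$panel, cfg)
  expect_equal(nrow(res$per_copy), 2L)
  expect_true(all(res$per_copy$status == "putative_autonomous"))
  info <- attr(loci, "locus_info")
  got <- res$per_copy[order(res$per_copy$element_start), ]
  expect_equal(got$element_start, info$element_offset)
  expect_equal(got$element_end, info$element_end)
  expect_true(got$element_end[1] < got$element_start[2])
})
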