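test_that("the generator realizes the requested full-size structure", {
  # full-size conditions: 492/338/948 aa ORFs, A = 173 bp and B = 219 bp
  # repeats at 100%/100%, canonical layout
  cfg <- sdr_config()
  el <- make_element(element_spec(), seed = 81, config = cfg)
  tu <- el$truth$repeat_units
  expect_equal(tu$length[tu$label == "A1"], 173L)
  expect_equal(tu$length[tu$label == "B1"], 219L)
  expect_true(all(tu$pair_identity == 100))
  cp <- annotate_copy(el$seq, "full", el$panel, cfg)[[1]]
  expect_equal(cp$architecture$class, "canonical_B1A2B2")
  lab <- cp$repeat_units
  expect_equal(lab$length[lab$label == "A1"], 173L)
  expect_equal(lab$length[lab$label == "B1"], 219L)
  expect_equal(lab$pair_identity[lab$label == "A1"], 100)
  expect_equal(lab$pair_identity[lab$label == "B1"], 100)
  expect_equal(cp$status, "putative_autonomous")
  ro <- cp$orfs[cp$orfs$role %in% c("gag_like", "yr", "rt_rh"), ]
  ro <- ro[order(ro$start), ]
  expect_equal(ro$protein_len_aa, c(492L, 338L, 948L))
  # the YR and RT/RH ORFs overlap
  expect_lt(ro$start[3], ro$end[2])
})

test_that("generator output is a pure function of spec and seed", {
  a <- make_element(small_spec(), seed = 82)
  b <- make_element(small_spec(), seed = 82)
  expect_identical(a$seq, b$seq)
  c <- make_element(small_spec(), seed = 83)
  expect_false(identical(a$seq, c$seq))
})

test_that("architecture 'none' leaves no terminal repeats", {
  cfg <- small_config()
  el <- make_element(small_spec(architecture = "none"), seed = 84,
                     config = cfg)
  pr <- find_repeat_pairs(el$seq, cfg$seed_len, cfg$min_repeat_len)
  expect_equal(nrow(pr), 0L)
  expect_equal(el$truth$expected_status, "potentially_encoding")
})

test_that("planted pair identity is realized exactly", {
  for (seed in 85:88) {
    el <- make_element(small_spec(len_A = 100L, identity_A = 95),
                       seed = seed)
    tu <- el$truth$repeat_units
    a1 <- substring(el$seq, tu$start[tu$label == "A1"],
                    tu$end[tu$label == "A1"])
    a2 <- substring(el$seq, tu$start[tu$label == "A2"],
                    tu$end[tu$label == "A2"])
    ham <- sum(strsplit(a1, "")[[1]] != strsplit(a2, "")[[1]])
    expect_lte(abs(ham - 5L), 1L)
  }
})

test_that("an infeasible overlap is a spec error", {
  expect_error(element_spec(orf_lengths_aa = c(gag_like = 120L, yr = 50L,
                                               rt_rh = 200L),
                            orf_overlap_bp = 160L), "overlap")
})

test_that("degradation: identity, substitution counts, truth updates", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 91, config = cfg)
  # all-zero spec leaves the sequence unchanged
  same <- degrade(el, degradation_spec(), seed = 92, config = cfg)
  expect_identical(same$seq, el$seq)
  # substitution count within the binomial 99% interval
  plain <- make_element(small_spec(architecture = "none"), seed = 93,
                        config = cfg)
  L <- nchar(plain$seq)
  mut <- degrade(plain, degradation_spec(sub_rate = 0.05,
                                         preserve_orfs = FALSE,
                                         preserve_repeats = FALSE),
                 seed = 94, config = cfg)
  nd <- sum(strsplit(plain$seq, "")[[1]] != strsplit(mut$seq, "")[[1]])
  ci <- qbinom(c(0.005, 0.995), L, 0.05)
  expect_gte(nd, ci[1]); expect_lte(nd, ci[2])
  # a single-base deletion inside the third ORF shifts the frame and the
  # expected status becomes degenerate, with the frameshift recorded
  rt <- el$truth$orfs[el$truth$orfs$role == "rt_rh", ]
  fs <- degrade(el, degradation_spec(
    frameshift_positions = rt$start + 101L), seed = 95, config = cfg)
  expect_true(fs$truth$orfs$frameshift[fs$truth$orfs$role == "rt_rh"])
  expect_equal(fs$truth$expected_status, "degenerate")
  expect_equal(nchar(fs$seq), nchar(el$seq) - 1L)
  # ORF-preserving substitutions never break the three-ORF layout
  enc <- degrade(el, degradation_spec(sub_rate = 0.04), seed = 96,
                 config = cfg)
  cp <- annotate_copy(enc$seq, "x", el$panel, cfg)[[1]]
  expect_equal(cp$status, "putative_autonomous")
})

test_that("planted genomes carry truth that the pipeline reproduces", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 101, config = cfg)
  enc <- strip_terminal_repeats(
    degrade(el, degradation_spec(sub_rate = 0.02), seed = 102,
            config = cfg), config = cfg)
  rt <- enc$truth$orfs[enc$truth$orfs$role == "rt_rh", ]
  deg <- degrade(enc, degradation_spec(
    frameshift_positions = rt$start + floor(0.4 * (rt$end - rt$start))),
    seed = 103, config = cfg)
  pg <- plant_genome(list(el, enc, deg), background_len = 12000,
                     min_gap = 1500, seed = 104, config = cfg)
  loci <- extract_loci(pg, flank_bp = 600)
  res <- run_pipeline(loci, el$panel, cfg)
  info <- attr(loci, "locus_info")
  got <- res$per_copy[match(info$copy_id, res$per_copy$copy_id), ]
  expect_equal(got$status, info$expected_status)
  # an element truncated by a contig end is inconclusive
  yr_mid <- el$truth$orfs$start[2] + 50L
  pg2 <- plant_genome(list(el), background_len = 6000, min_gap = 1500,
                      seed = 105,
                      contig_breaks = list(cut_element = 1, offset = yr_mid),
                      config = cfg)
  expect_equal(pg2$truth$expected_status[1], "inconclusive")
  res2 <- run_pipeline(extract_loci(pg2, flank_bp = 600), el$panel, cfg)
  expect_equal(res2$per_copy$status, "inconclusive")
  # placement must fail loudly when the background cannot host the copies
  expect_error(plant_genome(list(el), background_len = 100,
                            min_gap = 2000, seed = 106, config = cfg),
               "placement")
})

test_that("a telomeric hexamer context does not disturb boundary calls", {
  cfg <- small_config()
  el <- make_element(small_spec(), seed = 107, config = cfg)
  pg <- plant_genome(list(el), background_len = 6000, min_gap = 1500,
                     seed = 108, telomeric_idx = 1, config = cfg)
  loci <- extract_loci(pg, flank_bp = 600)
  res <- run_pipeline(loci, el$panel, cfg)
  info <- attr(loci, "locus_info")
  expect_equal(res$per_copy$status, "putative_autonomous")
  expect_equal(res$per_copy$element_start, info$element_offset)
  expect_equal(res$per_copy$element_end, info$element_end)
})
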