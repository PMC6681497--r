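test_that("global alignment handles identity, gaps, and alphabet errors", {
  al <- global_align("ACGTACGT", "ACGTACGT")
  expect_false(grepl("-", al$a_aln))
  expect_false(grepl("-", al$b_aln))
  al2 <- global_align("ACGT", "ACT")
  gaps <- sum(strsplit(al2$a_aln, "")[[1]] == "-") +
    sum(strsplit(al2$b_aln, "")[[1]] == "-")
  expect_equal(gaps, 1L)
  expect_error(global_align("ACGT", "PEFQ", type = "dna"), "alphabet")
})

test_that("global alignment scores equal a brute-force affine DP", {
  set.seed(71)
  dmat <- Biostrings::nucleotideSubstitutionMatrix(2, -2, baseOnly = TRUE)
  for (rep in 1:25) {
    a <- random_dna(sample(4:10, 1)); b <- random_dna(sample(4:10, 1))
    got <- global_align(a, b, type = "dna", match = 2, mismatch = -2,
                        gap_open = 10, gap_extend = 1)$score
    exp <- orc_align_score(a, b, dmat, open = 10, ext = 1, local = FALSE)
    expect_equal(got, exp, info = paste(a, b))
  }
})

test_that("identity with masking follows the confident-region policy", {
  a <- paste(rep("A", 100), collapse = "")
  pi <- pairwise_identity(a, a)
  expect_equal(pi$identity_pct, 100)
  expect_equal(pi$aligned_length, 100L)
  # one substitution in 20 aligned columns, no masking
  b <- paste0(paste(rep("A", 10), collapse = ""), "C",
              paste(rep("A", 9), collapse = ""))
  pi2 <- pairwise_identity(paste(rep("A", 20), collapse = ""), b,
                           mask_policy = NULL)
  expect_equal(pi2$identity_pct, 95)
  # gap-dense windows are masked out of the denominator
  a3 <- "AAAAA-----AAAAA"
  b3 <- "AAAAACCCCCAAAAA"
  pi3 <- pairwise_identity(a3, b3)
  expect_lt(pi3$aligned_length, 15L)
  expect_equal(pi3$identity_pct, 100)
  # symmetry
  set.seed(72)
  for (rep in 1:10) {
    x <- global_align(random_dna(50), random_dna(50), type = "dna")
    expect_equal(pairwise_identity(x$a_aln, x$b_aln),
                 pairwise_identity(x$b_aln, x$a_aln))
  }
  # all columns masked -> undefined identity
  pi4 <- pairwise_identity("---", "AAA")
  expect_true(is.na(pi4$identity_pct))
})

test_that("mean pairwise identity recovers planted divergence", {
  s <- random_dna(300)
  expect_equal(mean_pairwise_identity(c(s, s, s))$mean_identity_pct, 100)
  set.seed(73)
  base <- strsplit(random_dna(400), "")[[1]]
  seqs <- vapply(1:4, function(i) {
    v <- base
    pos <- sample(400, 20)          # 5% per copy
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }, character(1))
  mp <- mean_pairwise_identity(seqs)
  p_exp <- 2 * 0.05 * (1 - 0.05) + 2 * (0.05^2 / 3)
  expect_equal(mp$n, 4L)
  expect_lt(abs(mp$mean_identity_pct - 100 * (1 - p_exp)), 2)
  expect_true(is.na(mean_pairwise_identity("ACGT")$mean_identity_pct))
})

test_that("the Poisson correction matches its closed form", {
  expect_equal(poisson_distance(0), 0)
  expect_lt(abs(poisson_distance(0.5) - 0.6931471805599453), 1e-12)
  p <- seq(0, 0.95, by = 0.05)
  expect_true(all(poisson_distance(p) >= p))
  expect_true(all(diff(poisson_distance(p)) > 0))
  expect_error(poisson_distance(1), "0, 1")
  expect_error(poisson_distance(-0.1), "0, 1")
})

test_that("neighbor joining is exact on additive distances", {
  # two taxa: a single split edge
  t2 <- nj_tree(matrix(c(0, .4, .4, 0), 2,
                       dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(sort(t2$tip.label), c("a", "b"))
  expect_equal(unname(sum(t2$edge.length)), 0.4)
  set.seed(74)
  for (n in c(4, 5, 6, 8)) {
    for (rep in 1:10) {
      tr <- ape::rtree(n, rooted = FALSE)
      tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
      D <- ape::cophenetic.phylo(tr)
      got <- nj_tree(D[tr$tip.label, tr$tip.label])
      # additive-case exactness: the tree reproduces the distances
      D2 <- ape::cophenetic.phylo(got)[tr$tip.label, tr$tip.label]
      expect_lt(max(abs(D2 - D[tr$tip.label, tr$tip.label])), 1e-8)
      expect_equal(ape::dist.topo(got, tr), structure(0, names = "PH85"),
                   ignore_attr = TRUE)
    }
  }
  # label permutation does not change the topology
  tr <- ape::rtree(6, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.05, 1)
  D <- ape::cophenetic.phylo(tr)
  perm <- sample(rownames(D))
  got1 <- nj_tree(D)
  got2 <- nj_tree(D[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(got1, got2)), 0)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("the redundancy filter collapses same-species shallow clades", {
  # three same-species leaves at 0.2 plus two other species
  labs <- c("x1", "x2", "x3", "y1", "z1")
  species <- c("X", "X", "X", "Y", "Z")
  D <- matrix(0.8, 5, 5, dimnames = list(labs, labs))
  diag(D) <- 0
  D[1:3, 1:3] <- 0.2; diag(D) <- 0
  seqs <- setNames(c("AAAAA", "AAAAAA", "AAA", "CCCC", "GGGG"), labs)
  kept <- redundancy_filter(seqs, species, D, threshold = 0.35)
  expect_equal(sort(kept), c("x2", "y1", "z1"))  # longest representative
  # distance exactly at the threshold: both kept (strict less-than)
  D2 <- matrix(c(0, .35, .35, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  kept2 <- redundancy_filter(setNames(c("AAA", "CCC"), c("a", "b")),
                             c("S", "S"), D2, threshold = 0.35)
  expect_equal(sort(kept2), c("a", "b"))
  # mixed-species shallow clade untouched
  kept3 <- redundancy_filter(setNames(c("AAA", "CCC"), c("a", "b")),
                             c("S", "T"),
                             matrix(c(0, .1, .1, 0), 2,
                                    dimnames = list(c("a", "b"),
                                                    c("a", "b"))),
                             threshold = 0.35)
  expect_equal(sort(kept3), c("a", "b"))
  expect_error(redundancy_filter(setNames("A", "a"), NA, matrix(0, 1, 1)),
               "species")
})

test_that("the redundancy filter is idempotent", {
  set.seed(75)
  for (rep in 1:5) {
    n <- 12
    labs <- paste0("s", 1:n)
    species <- sample(c("A", "B", "C"), n, replace = TRUE)
    base <- list(A = random_dna(200), B = random_dna(200),
                 C = random_dna(200))
    seqs <- setNames(vapply(1:n, function(i) {
      v <- strsplit(base[[species[i]]], "")[[1]]
      pos <- sample(200, 15)
      for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
      paste(v, collapse = "")
    }, character(1)), labs)
    D <- p_distance_matrix(seqs)
    kept <- redundancy_filter(seqs, species, D, threshold = 0.35)
    D2 <- D[kept, kept, drop = FALSE]
    kept2 <- redundancy_filter(seqs[kept],
                               species[match(kept, labs)], D2,
                               threshold = 0.35)
    expect_equal(sort(kept2), sort(kept))
  }
})
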