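test_that("pairwise distances implement pairwise deletion and the models", {
  a <- "ACDEFGHIKL"
  expect_equal(pairwise_distance(a, a, "p")$distance, 0)
  expect_equal(pairwise_distance(a, a, "poisson")$distance, 0)
  expect_equal(pairwise_distance(a, a, "dayhoff")$distance, 0)

  b <- "ACDEFGHIWW"  # 2 mismatches over 10 columns
  pd <- pairwise_distance(a, b, "p")
  expect_equal(pd$distance, 0.2)
  expect_equal(pd$n_sites, 10L)

  # gapped columns are excluded per pair
  g1 <- "AC-EFGHIKL"
  g2 <- "ACDE-GHIWW"
  pd <- pairwise_distance(g1, g2, "p")
  expect_equal(pd$n_sites, 8L)
  expect_equal(pd$distance, 2 / 8)

  # all-gap overlap -> undefined flag
  pd <- pairwise_distance("--AA", "AA--", "p")
  expect_true(pd$undefined)
  expect_true(is.na(pd$distance))

  expect_error(pairwise_distance("AAA", "AAAA"), "length")
})

test_that("dayhoff distance matches a dense matrix-exponential oracle", {
  tmp <- get(".Dayhoff", environment(phangorn::pml))
  bf <- tmp$bf
  S <- matrix(0, 20, 20)
  S[lower.tri(S)] <- tmp$Q
  S <- S + t(S)
  Q <- S %*% diag(bf)
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(bf * diag(Q)))
  ident <- function(t) sum(bf * diag(as.matrix(Matrix::expm(Q * t))))
  oracle <- function(p) {
    lo <- 0; hi <- 30
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      if (ident(mid) > 1 - p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  a <- paste(rep("A", 20), collapse = "")
  for (k in c(2, 6, 10)) {
    b <- paste(c(rep("C", k), rep("A", 20 - k)), collapse = "")
    mine <- pairwise_distance(a, b, "dayhoff")$distance
    expect_equal(mine, oracle(k / 20), tolerance = 1e-6)
  }
})

test_that("model corrections are ordered dayhoff >= poisson >= p", {
  n <- 40L
  a <- paste(rep("A", n), collapse = "")
  for (p in c(0.05, 0.2, 0.4, 0.6)) {
    k <- round(n * p)
    b <- paste(c(rep("C", k), rep("A", n - k)), collapse = "")
    dp <- pairwise_distance(a, b, "p")$distance
    dpois <- pairwise_distance(a, b, "poisson")$distance
    dday <- pairwise_distance(a, b, "dayhoff")$distance
    expect_gte(dpois, dp)
    expect_gte(dday, dpois)
    expect_lte(dday, 2 * dpois)
  }
})

test_that("three taxa produce the closed-form star tree", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3, dimnames = list(c("A", "B", "C"),
                                                c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  expect_equal(tr$Nnode, 1L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], (3 + 4 - 5) / 2)
  expect_equal(lens[["B"]], (3 + 5 - 4) / 2)
  expect_equal(lens[["C"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("a four-taxon additive matrix yields the generating topology", {
  # tree ((A:1,B:2):1,(C:3,D:1):1) -> additive distances
  d <- matrix(c(0, 3, 6, 4,
                3, 0, 7, 5,
                6, 7, 0, 4,
                4, 5, 4, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_true(is_clade(tr, c("A", "B")))
  expect_true(is_clade(tr, c("C", "D")))
  # brute-force least-squares over the three unrooted quartets confirms
  # AB|CD is the best split: its four-point sums are 3+4 < 6+5 = 4+7
  expect_lt(d["A", "B"] + d["C", "D"],
            min(d["A", "C"] + d["B", "D"], d["A", "D"] + d["B", "C"]))
})

test_that("equal distances still give a valid non-negative tree", {
  n <- 5
  d <- matrix(1, n, n, dimnames = list(LETTERS[1:n], LETTERS[1:n]))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_equal(sort(tr$tip.label), LETTERS[1:n])
  expect_true(all(tr$edge.length >= 0))
  expect_identical(nj_tree(d)$edge, tr$edge)  # tie rule is deterministic
})

test_that("NJ recovers the topology of random additive matrices", {
  set.seed(29)
  for (rep in 1:8) {
    ntip <- sample(4:12, 1)
    true <- ape::rtree(ntip)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(true)
    mine <- nj_tree(d[sort(rownames(d)), sort(rownames(d))])
    expect_equal(phangorn::RF.dist(ape::unroot(true), mine), 0)
    # and matches the reference NJ implementation
    expect_equal(phangorn::RF.dist(ape::nj(as.dist(d)), mine), 0)
  }
})

test_that("bootstrap gives full support to a clean bipartition", {
  # two clades separated by many fixed differences, long alignment
  left <- paste(rep("A", 60), collapse = "")
  right <- paste(rep("W", 60), collapse = "")
  jitter <- function(s, at, to) {
    substr(s, at, at) <- to
    s
  }
  aln <- c(L1 = left, L2 = jitter(left, 1, "C"), L3 = jitter(left, 2, "C"),
           R1 = right, R2 = jitter(right, 1, "Y"), R3 = jitter(right, 2, "Y"))
  bt <- bootstrap_supports(aln, model = "p", replicates = 100, seed = 2)
  key <- paste(sort(c("R1", "R2", "R3")), collapse = "|")
  expect_true(key %in% names(bt$supports))
  expect_equal(unname(bt$supports[[key]]), 100)
  expect_equal(bt$n_used, 100L)

  # one replicate -> supports are 0 or 100
  b1 <- bootstrap_supports(aln, model = "p", replicates = 1, seed = 9)
  expect_true(all(b1$supports %in% c(0, 100)))

  # reproducibility under the seed
  b2 <- bootstrap_supports(aln, model = "p", replicates = 25, seed = 4)
  b3 <- bootstrap_supports(aln, model = "p", replicates = 25, seed = 4)
  expect_identical(b2$supports, b3$supports)
  expect_identical(write_newick(b2$tree), write_newick(b3$tree))
})

test_that("newick output round-trips byte-stably and carries supports", {
  d <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  txt <- write_newick(nj_tree(d))
  expect_match(txt, "^\\(.*A.*B.*C.*\\);$")
  expect_identical(write_newick(read_newick(txt)), txt)

  left <- paste(rep("A", 30), collapse = "")
  right <- paste(rep("W", 30), collapse = "")
  aln <- c(L1 = left, L2 = left, R1 = right, R2 = right)
  bt <- bootstrap_supports(aln, model = "p", replicates = 10, seed = 1)
  expect_match(write_newick(bt$tree), "\\)100")
  expect_false(grepl("100", write_newick(bt$tree, with_supports = FALSE)))
})

test_that("synthetic family panels are monophyletic in the NJ tree", {
  panel <- generate_panel(panel_spec(epsilon = 0.05, seed = 7))
  cores <- vapply(names(panel$sequences), function(id) {
    s <- panel$sequences[[id]]
    extract_core(assemble_architecture(scan_blocks(s, 1), s, seq_id = id))
  }, character(1))
  tr <- nj_tree(distance_matrix(cores, "dayhoff"))
  groups <- split(panel$truth$seq_id,
                  paste(panel$truth$family, panel$truth$subfamily))
  for (g in names(groups)) {
    expect_true(is_clade(tr, groups[[g]]), info = g)
  }
})
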