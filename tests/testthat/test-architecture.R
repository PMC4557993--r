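test_that("canonical matches assemble into the expected spans", {
  core <- canonical_core()
  arch <- assemble_architecture(scan_blocks(core, 0), core)
  expect_true(arch$complete)
  expect_equal(arch$fn2_1_span, c(1, 38))
  expect_equal(arch$linker_span, c(40, 42))
  expect_equal(arch$fn2_2_span, c(46, 87))
  expect_equal(arch$cter_extension, "")
  # spans are ordered and disjoint
  expect_lt(arch$fn2_1_span[2], arch$linker_span[1])
  expect_lt(arch$linker_span[2], arch$fn2_2_span[1])
  # 4-aa length asymmetry between the two domains
  expect_equal(diff(arch$fn2_2_span) - diff(arch$fn2_1_span), 4)
})

test_that("a single-domain hit yields an incomplete architecture", {
  core <- canonical_core()
  fn2_1_only <- substr(core, 1, 38)
  arch <- assemble_architecture(scan_blocks(fn2_1_only, 0), fn2_1_only)
  expect_false(arch$complete)
  expect_equal(arch$fn2_1_span, c(1, 38))
  expect_null(arch$fn2_2_span)
  expect_equal(nrow(arch$chain), 4L)
})

test_that("assembly is empty-safe, order-insensitive and idempotent", {
  core <- canonical_core()
  empty <- assemble_architecture(scan_blocks("AAAAAAAAAA", 0), "AAAAAAAAAA")
  expect_false(empty$complete)
  expect_equal(nrow(empty$chain), 0L)

  hits <- scan_blocks(core, 1)
  a1 <- assemble_architecture(hits, core)
  set.seed(3)
  a2 <- assemble_architecture(hits[sample(nrow(hits)), ], core)
  expect_identical(a1$chain, a2$chain)
  a3 <- assemble_architecture(a1$chain, core)
  expect_identical(a1$chain, a3$chain)
})

test_that("among competing Block I candidates the chain-compatible one wins", {
  core <- canonical_core()
  # prepend a decoy Block I instance too far upstream to chain with the rest
  decoy <- paste0("CVFPFEY", "GGGGGGGGGG")
  seq <- paste0(decoy, core)
  arch <- assemble_architecture(scan_blocks(seq, 0), seq)
  expect_true(arch$complete)
  # Block I of the chain is the one at the core anchor, not the decoy at 1
  expect_equal(arch$chain$start[arch$chain$block_id == "I"], 18)
  # brute-force check: chain gaps match canonical gaps exactly
  expect_equal(diff(arch$chain$start), diff(block_definitions()$canonical_start))
})

test_that("disulfide topology validates two bonds per complete domain", {
  core <- canonical_core()
  arch <- assemble_architecture(scan_blocks(core, 0), core)
  ds <- arch$disulfides
  expect_equal(sum(ds$domain == "FN2_1" & ds$status == "confirmed"), 2L)
  expect_equal(sum(ds$domain == "FN2_2" & ds$status == "confirmed"), 2L)
  expect_true(attr(ds, "valid"))

  # without a free cysteine in the VI->VII gap, pair 2 of FN2_2 is flagged
  # incomplete (a warning-level finding), not violated
  noc <- core
  substr(noc, 56, 56) <- "G"
  arch_noc <- assemble_architecture(scan_blocks(noc, 0), noc)
  fn2_2 <- arch_noc$disulfides[arch_noc$disulfides$domain == "FN2_2", ]
  expect_equal(sum(fn2_2$status == "confirmed"), 1L)
  expect_equal(sum(fn2_2$status == "incomplete"), 1L)
  expect_true(attr(arch_noc$disulfides, "valid"))

  # mutating the Block I cysteine breaks the first bond
  mut <- paste0("S", substr(core, 2, 87))
  arch_mut <- assemble_architecture(scan_blocks(mut, 1), mut)
  ds_mut <- check_disulfides(arch_mut, mut)
  expect_true(any(ds_mut$domain == "FN2_1" & ds_mut$status == "violated"))
  expect_false(attr(ds_mut, "valid"))

  # a gap cysteine completes the fourth pair (synthetic precursor has one)
  s <- synthetic_rsvp20_like_precursor()[[1]]
  full <- assemble_architecture(scan_blocks(s, 1), s)
  expect_equal(sum(full$disulfides$status == "confirmed"), 4L)
})

test_that("generated architectures keep ordered disjoint spans", {
  panel <- generate_panel(panel_spec(epsilon = 0.05, seed = 11))
  for (id in names(panel$sequences)) {
    s <- panel$sequences[[id]]
    a <- assemble_architecture(scan_blocks(s, 1), s, seq_id = id)
    if (!a$complete) next
    expect_lt(a$fn2_1_span[2], a$linker_span[1])
    expect_lt(a$linker_span[2], a$fn2_2_span[1])
  }
})
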