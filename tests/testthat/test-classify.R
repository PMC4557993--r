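test_that("fingerprint carriers are called BSPH1 / BSPH2, consensus is BSP", {
  # construct carriers directly from the generator at zero noise
  p1 <- generate_panel(panel_spec(counts = c(BSPH1 = 1), epsilon = 0, seed = 5))
  s <- p1$sequences[[1]]
  arch <- assemble_architecture(scan_blocks(s, 1), s)
  cl <- classify_family(arch)
  expect_equal(cl$family, "BSPH1")
  expect_equal(cl$score_BSPH1, 1.0)

  p2 <- generate_panel(panel_spec(counts = c(BSPH2 = 1), epsilon = 0, seed = 5))
  s <- p2$sequences[[1]]
  arch <- assemble_architecture(scan_blocks(s, 1), s)
  cl <- classify_family(arch)
  expect_equal(cl$family, "BSPH2")
  expect_equal(cl$score_BSPH2, 1.0)
  # the Block IX fingerprint and SP extension are visible in the evidence
  ev <- cl$evidence
  expect_true(ev$matched[ev$family == "BSPH2" & ev$component == "CTER"])

  core <- canonical_core()
  cl <- classify_family(assemble_architecture(scan_blocks(core, 0), core))
  expect_equal(cl$family, "BSP")

  # hand-built BSPH2: Block IX instance, DPP linker, SP extension
  expect_equal(bsptools:::fingerprint_component(
    "YNIDAKWKQC", "YNxDxKWKQC",
    block_definitions()$parsed[[9]])$matched, TRUE)
})

test_that("incomplete architectures are excluded from the superfamily", {
  half <- substr(canonical_core(), 1, 38)
  cl <- classify_family(assemble_architecture(scan_blocks(half, 0), half))
  expect_equal(cl$family, "not_BSP_superfamily")
})

test_that("fingerprint evidence scores never both reach 1", {
  # the BSPH1 and BSPH2 fingerprints conflict at shared blocks, so no
  # single chain can satisfy both perfectly; fuzz over generated panels
  set.seed(23)
  for (seed in c(2, 9)) {
    panel <- generate_panel(panel_spec(epsilon = 0.1, seed = seed))
    for (id in names(panel$sequences)) {
      s <- panel$sequences[[id]]
      cl <- classify_family(assemble_architecture(scan_blocks(s, 1), s))
      expect_false(cl$score_BSPH1 == 1 && cl$score_BSPH2 == 1)
    }
  }
})

test_that("subfamily assignment recovers generator truth by nearest core", {
  panel <- generate_panel(panel_spec(
    counts = c(BSP1 = 2, BSP2 = 2, BSP3 = 2, BSP5 = 2), epsilon = 0,
    seed = 13))
  refs <- generate_reference_panel(13)
  calls <- classify_panel(panel, refs)
  expect_equal(unname(calls[panel$truth$seq_id]),
               paste(panel$truth$family, panel$truth$subfamily))

  # under noise, every sequence whose architecture survives keeps its label
  noisy <- generate_panel(panel_spec(
    counts = c(BSP1 = 2, BSP2 = 2, BSP3 = 2, BSP5 = 2), epsilon = 0.05,
    seed = 13))
  calls <- classify_panel(noisy, refs)
  complete <- !grepl("not_BSP", calls)
  expect_gt(mean(complete), 0.5)
  expect_equal(unname(calls[noisy$truth$seq_id][complete]),
               paste(noisy$truth$family, noisy$truth$subfamily)[complete])
})

test_that("subfamily ties, floors and empty panels are handled", {
  core <- canonical_core()
  arch <- assemble_architecture(scan_blocks(core, 0), core)
  cl <- classify_family(arch)
  expect_equal(cl$family, "BSP")

  # tie: two references identical to the query -> alphabetical + flag
  refs <- data.frame(subfamily = c("BSP5", "BSP1"), core = c(core, core))
  got <- assign_subfamily(cl, core, refs)
  expect_equal(got$subfamily, "BSP1")
  expect_true(got$ambiguous_subfamily)

  # identity floor
  far <- paste(rep("K", 87), collapse = "")
  refs <- data.frame(subfamily = "BSP1", core = far)
  expect_equal(assign_subfamily(cl, core, refs, floor = 0.4)$subfamily, "none")

  expect_error(assign_subfamily(cl, core, refs[0, ]), "empty")
})

test_that("annotation reconciliation follows the family tokens", {
  expect_equal(reconcile_annotation("BSPH1", "BSPH2"), "misannotated")
  expect_equal(reconcile_annotation("BSPH1", "BSPH1"), "consistent")
  expect_equal(reconcile_annotation("", "BSPH2"), "novel")
  expect_equal(reconcile_annotation("RSVP14/BSP1", "BSP"), "consistent")
  expect_equal(reconcile_annotation("spneu", "BSP"), "unresolved")
  expect_equal(reconcile_annotation("BSPH1", "unclassified"), "unresolved")
  # token extraction details
  expect_equal(family_token("sp1/BSP1"), "BSP")
  expect_equal(family_token("BSP-30 kDa like"), "BSPH2")  # synonym table
  expect_equal(family_token("ELSPBP1"), "unknown")        # not a BSP gene
  expect_equal(family_token("LOC101107624"), "BSP")       # = BSP5c/RSVP22
  expect_equal(family_token(""), "")
})

test_that("the bundled nomenclature table reproduces the four renames", {
  ann <- nomenclature_table()
  rec <- reconcile_annotations(ann)
  mis <- rec$accession[rec$status == "misannotated"]
  expect_setequal(mis, c("M3XZ70", "G3VIB3", "H0Y1M6", "I3N753"))
  # every misannotation is the BSPH1 -> BSPH2 family-level rename
  expect_true(all(rec$existing_family[rec$status == "misannotated"] == "BSPH1"))
  expect_true(all(rec$call_family[rec$status == "misannotated"] == "BSPH2"))
  # rows with a database symbol that matches the proposal stay consistent
  expect_equal(rec$status[rec$accession == "P02784"], "consistent")
})
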