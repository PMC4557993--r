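test_that("protein concentration follows the corrected-absorbance formula", {
  expect_equal(protein_concentration(0, 0, 1), 0)
  # A280 equal to epsilon * 1e-5 gives 10 uM
  expect_equal(protein_concentration(0.45380, 0, 1), 1e-5)
  # independent hand arithmetic with the fluorophore correction
  expect_equal(protein_concentration(0.5, 1.0, 2), (0.5 - 0.11) * 2 / 45380)
  # custom extinction coefficient
  expect_equal(protein_concentration(1, 0, 1, epsilon = 50000), 2e-5)
  expect_warning(v <- protein_concentration(0.1, 2, 1), "negative")
  expect_lt(v, 0)
  expect_error(protein_concentration(-1, 0, 1))
})

test_that("FASTA input handles wrapping, gzip, ids and error cases", {
  seqs <- c(one = strrep("ACDEF", 20), two = strrep("WYKLM", 20))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(seqs, fa, width = 17)           # deliberately odd wrap
  got <- read_fasta(fa)
  expect_identical(got, seqs)

  # gzip round trip
  gz <- tempfile(fileext = ".fasta.gz")
  con <- gzfile(gz, "w")
  writeLines(c(">one some description", strrep("ACDEF", 20)), con)
  close(con)
  expect_identical(read_fasta(gz), c(one = strrep("ACDEF", 20)))

  # duplicate ids (after description stripping) are an error
  dup <- tempfile(fileext = ".fasta")
  writeLines(c(">a x", "AAA", ">a y", "CCC"), dup)
  expect_error(read_fasta(dup), "duplicate")

  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("configs validate, serialize and hash on parameters only", {
  cfg <- pipeline_config(seed = 5)
  expect_s3_class(cfg, "bsp_config")
  expect_error(pipeline_config(theta = 0), "theta")
  expect_error(pipeline_config(replicates = 0))
  # YAML round trip
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 5", "replicates: 10", "model: p"), yml)
  cfg2 <- read_config(yml)
  expect_equal(cfg2$seed, 5L)
  expect_equal(cfg2$model, "p")
  # hash ignores the output directory
  a <- pipeline_config(seed = 5, out_dir = tempfile())
  b <- pipeline_config(seed = 5, out_dir = tempfile())
  expect_identical(bsptools:::config_hash(a), bsptools:::config_hash(b))
  expect_false(identical(bsptools:::config_hash(a),
                         bsptools:::config_hash(pipeline_config(seed = 6))))
})

test_that("the pipeline runs end-to-end with perfect zero-noise recovery", {
  panel <- generate_panel(panel_spec(
    counts = c(BSP1 = 2, BSP3 = 2, BSP5 = 2, BSPH1 = 2, BSPH2 = 2),
    epsilon = 0, seed = 8))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(panel$sequences, fa)
  cfg <- pipeline_config(
    fasta = fa,
    neighborhoods = system.file("extdata", "neighborhoods_fixture.tsv",
                                package = "bsptools"),
    annotations = system.file("extdata", "nomenclature_proposed.tsv",
                              package = "bsptools"),
    out_dir = tempfile(), seed = 8, replicates = 20)
  res <- run_pipeline(cfg)

  expect_setequal(names(res$files),
                  c("scan.tsv", "architecture.tsv", "classification.tsv",
                    "tree.nwk", "distances.tsv", "patterns.tsv",
                    "discrepancies.tsv", "reconciliation.tsv"))
  # classification equals generator truth
  cls <- res$classification
  merged <- merge(cls, panel$truth, by = "seq_id")
  expect_true(all(merged$family.x == merged$family.y))
  bsp_rows <- merged$family.y == "BSP"
  expect_true(all(merged$subfamily.x[bsp_rows] == merged$subfamily.y[bsp_rows]))
  # every tabular output carries the provenance header
  for (f in setdiff(names(res$files), c("tree.nwk", "distances.tsv"))) {
    first <- readLines(res$files[[f]], n = 1)
    expect_match(first, "^# bsptools .*seed=8", info = f)
  }
})

test_that("identical config and seed reproduce identical artifacts", {
  panel <- generate_panel(panel_spec(counts = c(BSP1 = 2, BSPH1 = 2),
                                     epsilon = 0.05, seed = 21))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(panel$sequences, fa)
  run_once <- function() {
    cfg <- pipeline_config(fasta = fa, out_dir = tempfile(), seed = 21,
                           replicates = 10,
                           stages = c("scan", "classify", "phylo"))
    run_pipeline(cfg)
  }
  r1 <- run_once()
  r2 <- run_once()
  for (f in names(r1$files)) {
    expect_identical(readLines(r1$files[[f]]), readLines(r2$files[[f]]),
                     info = f)
  }
})

test_that("sequence stages demand a FASTA and reject malformed input", {
  expect_error(run_pipeline(pipeline_config(stages = "scan")), "FASTA")
  bad <- tempfile(fileext = ".fasta")
  writeLines(character(0), bad)
  expect_error(run_pipeline(pipeline_config(fasta = bad, stages = "scan",
                                            out_dir = tempfile())), "empty")
})
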