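test_that("a CAMI profiling file reads into ranked entries", {
  tree <- mini_tree()
  f <- write_cami(tempfile(fileext = ".profile"),
                  list(c("2", "superkingdom", "100.0"),
                       c("1224", "phylum", "100.0")))
  p <- read_profile(f, tree, tool_id = "toolA")
  expect_s3_class(p, "tax_profile")
  expect_equal(nrow(p), 2L)
  expect_setequal(p$rank, c("superkingdom", "phylum"))
  expect_equal(attr(p, "sample_id"), "S1")
  expect_equal(attr(p, "tool_id"), "toolA")
})

test_that("stale, off-ladder and duplicate rows are repaired on read", {
  tree <- deep_tree()
  # merged id 666 -> 1224; strain 10 -> species 9; duplicate species rows sum
  f <- write_cami(tempfile(fileext = ".profile"),
                  list(c("2", "superkingdom", "100"),
                       c("666", "phylum", "100"),
                       c("10", "strain", "40"),
                       c("9", "species", "30"),
                       c("11", "species", "30")))
  expect_warning(expect_warning(
    p <- read_profile(f, tree), "projected"), "summed")
  expect_equal(p$taxid[p$rank == "phylum"], 1224L)
  sp <- p[p$rank == "species", ]
  expect_equal(sp$abundance[sp$taxid == 9L], 70)
  expect_equal(sp$abundance[sp$taxid == 11L], 30)
})

test_that("malformed profiling input is fatal with context", {
  tree <- mini_tree()
  bad <- tempfile()
  writeLines(c("2\tsuperkingdom\t100"), bad)
  expect_error(read_profile(bad, tree), "missing '@@'")
  f <- write_cami(tempfile(), list(c("2", "superkingdom", "abc")))
  expect_error(read_profile(f, tree), "non-numeric PERCENTAGE")
  f2 <- write_cami(tempfile(), list(c("2", "superkingdom", "-5")))
  expect_error(read_profile(f2, tree), "negative PERCENTAGE")
})

test_that("0-1 scaled abundances are detected and rescaled", {
  tree <- mini_tree()
  f <- write_cami(tempfile(), list(c("2", "superkingdom", "0.6"),
                                   c("1224", "phylum", "0.6")))
  expect_warning(p <- read_profile(f, tree), "0-1 scaled")
  expect_equal(p$abundance, c(60, 60))
})

test_that("profile writing round-trips values and is byte-stable", {
  tree <- deep_tree()
  p <- prof(list("superkingdom", 2, 100), list("phylum", 1224, 100),
            list("species", 9, 60), list("species", 11, 40))
  f1 <- tempfile(); f2 <- tempfile()
  write_profile(p, f1, tree)
  back <- read_profile(f1, tree)
  expect_equal(back$taxid, p$taxid)
  expect_equal(back$abundance, p$abundance, tolerance = 1e-6)
  # species lines ordered by descending abundance
  lines <- readLines(f1)
  sp_lines <- grep("\tspecies\t", lines, value = TRUE)
  expect_match(sp_lines[1], "^9\t")
  expect_match(sp_lines[2], "^11\t")
  # TAXPATH rebuilt from the taxonomy
  expect_match(sp_lines[1], "2\\|1224\\|3\\|4\\|5\\|6\\|9")
  # second emission of a canonical file is byte-identical
  write_profile(back, f2, tree)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an empty profile writes headers only", {
  tree <- mini_tree()
  f <- tempfile()
  write_profile(tax_profile(sample_id = "E"), f, tree)
  lines <- readLines(f)
  expect_length(lines, 4L)
  p <- read_profile(f, tree)
  expect_equal(nrow(p), 0L)
})

test_that("plain and BioBoxes binning dialects both read", {
  tree <- deep_tree()
  f <- tempfile()
  writeLines(c("# comment", "r1\t100\t9", "r2\t80\t9"), f)
  b <- read_binning(f, tree)
  expect_equal(nrow(b), 2L)
  expect_equal(b$taxid, c(9L, 9L))
  expect_equal(sum(b$length), 180L)

  f2 <- tempfile()
  writeLines(c("@Version:0.9.4", "@@SEQUENCEID\tTAXID", "r1\t9", "r2\t11"), f2)
  b2 <- read_binning(f2, tree, default_length = 150L)
  expect_equal(b2$length, c(150L, 150L))

  f3 <- tempfile()
  writeLines(c("r1\t100\t9", "r2\t80\t424242"), f3)
  expect_warning(b3 <- read_binning(f3, tree), "1 assignment")
  expect_equal(nrow(b3), 1L)
})

test_that("binning duplicates and bad lengths are policed", {
  tree <- deep_tree()
  f <- tempfile()
  writeLines(c("r1\t100\t9", "r1\t80\t11"), f)
  expect_error(read_binning(f, tree), "duplicate sequence id")
  expect_warning(b <- read_binning(f, tree, keep_first = TRUE), "kept first")
  expect_equal(b$taxid, 9L)
  f2 <- tempfile()
  writeLines("r1\t0\t9", f2)
  expect_error(read_binning(f2, tree), "non-positive.*line 1")
})

test_that("database profiles are ancestor-closed with summed lengths", {
  tree <- deep_tree()
  f <- tempfile()
  writeLines(c("9\t3000000", "11\t1000000"), f)
  db <- read_database_profile(f, tree, tool_id = "toolA")
  # two species + genus..superkingdom closure = 2 + 6 taxa
  expect_equal(nrow(db), 8L)
  expect_equal(db$ref_length[db$taxid == 6L], 4e6)   # genus sums children
  expect_equal(db$ref_length[db$taxid == 2L], 4e6)
  expect_equal(db$ref_length[db$taxid == 9L], 3e6)
  # every fixed-rank ancestor of a present taxon is present
  for (tx in db$taxid) {
    lin <- lineage_at_ranks(tree, tx)
    expect_true(all(unname(lin) %in% db$taxid))
  }

  f1 <- tempfile()
  writeLines("9\t4000000", f1)
  db1 <- read_database_profile(f1, tree)
  expect_equal(nrow(db1), 7L)  # full 7-rank lineage of one species
  expect_true(all(db1$ref_length == 4e6))

  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(read_database_profile(empty, tree)), 0L)
})

test_that("database profile write/read round-trips the closure", {
  tree <- deep_tree()
  f <- tempfile()
  writeLines(c("9\t3000000", "11\t1000000"), f)
  db <- read_database_profile(f, tree, tool_id = "toolA")
  f2 <- tempfile()
  write_database_profile(db, f2, tree)
  db2 <- read_database_profile(f2, tree, tool_id = "toolA")
  expect_equal(as.data.frame(db2), as.data.frame(db))
})

test_that("accession maps build a database profile with summed lengths", {
  tree <- deep_tree()
  a2t <- tempfile(); a2l <- tempfile()
  writeLines(c("ACC1\t9", "ACC2\t9", "ACC3\t11", "ACC4\t9"), a2t)
  writeLines(c("ACC1\t1000000", "ACC2\t2000000", "ACC3\t500000"), a2l)
  expect_warning(db <- build_database_profile(a2t, a2l, tree), "only one map")
  expect_equal(db$ref_length[db$taxid == 9L], 3e6)
  expect_equal(db$ref_length[db$taxid == 6L], 3.5e6)

  a2l2 <- tempfile(); writeLines("OTHER\t5", a2l2)
  expect_error(build_database_profile(a2t, a2l2, tree), "no accession")
})

test_that("krona text export lists species with name lineages", {
  tree <- deep_tree()
  p <- prof(list("species", 9, 60), list("species", 11, 40))
  f <- tempfile()
  write_krona(p, f, tree)
  lines <- readLines(f)
  expect_length(lines, 2L)
  expect_match(lines[1], "^60\\.000000\tBacteria\t")
  expect_match(lines[1], "Escherichia coli$")
})
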