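test_that("the co-occurrence score matches its closed form everywhere", {
  for (i in 0:10) {
    for (j in 0:10) {
      expect_identical(score_taxon(i, j), (i + 1)^2 / (j + 1))
    }
  }
  # diagonal reduces to i + 1
  expect_equal(score_taxon(0:10, 0:10), 1:11)
  # strictly increasing in i at fixed j, strictly decreasing in j at fixed i
  for (j in 0:10) expect_true(all(diff(score_taxon(0:10, j)) > 0))
  for (i in 0:10) expect_true(all(diff(score_taxon(i, 0:10)) < 0))
  expect_equal(score_taxon(0, 0), 1)
  expect_equal(score_taxon(1, 5), 4 / 6)
  expect_error(score_taxon(-1, 0), ">= 0")
})

test_that("harmonic-mean integration damps outliers and matches closed form", {
  expect_equal(integrate_abundance(c(0.2, 0.2, 0.2)), 0.2)
  expect_equal(integrate_abundance(c(10, 40)), 16)
  v <- integrate_abundance(c(1, 100))
  expect_equal(v, 2 / (1 + 1 / 100))
  expect_lt(v, mean(c(1, 100)) / 10)
  withr::with_seed(8, {
    for (k in 1:1000) {
      x <- stats::runif(sample(1:6, 1), 1e-4, 100)
      expect_equal(integrate_abundance(x), length(x) / sum(1 / x),
                   tolerance = 1e-12)
    }
  })
  expect_error(integrate_abundance(numeric(0)))
  expect_error(integrate_abundance(c(1, 0)), "> 0")
})

test_that("entry collection counts occurrences and database presence independently", {
  mk <- function(id, ...) prof(..., tool_id = id)
  profs <- list(mk("t1", list("species", 9, 60), list("species", 11, 40)),
                mk("t2", list("species", 9, 100)),
                mk("t3", list("species", 9, 50), list("species", 11, 50)))
  dbt <- function(id, taxids) {
    d <- tibble::tibble(taxid = as.integer(taxids),
                        rank = rep("species", length(taxids)),
                        ref_length = NA_real_)
    attr(d, "tool_id") <- id
    d
  }
  dbs <- list(dbt("t1", c(9, 11)), dbt("t2", c(9, 11)), dbt("t3", 9))
  # t3 reports 11 although its own database lacks it: i counts, j does not
  expect_warning(e <- collect_entries(profs, dbs), "own database")
  expect_equal(e$i[e$taxid == 9], 3L)
  expect_equal(e$j[e$taxid == 9], 3L)
  expect_equal(e$i[e$taxid == 11], 2L)
  expect_equal(e$j[e$taxid == 11], 2L)

  expect_error(collect_entries(list(mk("t1"), mk("t1"))), "duplicate tool id")
  expect_warning(collect_entries(profs[1], list()), "contribute 0")
})

test_that("mode percentiles follow the power family and its ordering", {
  modes <- c("very-precise", "precise", "linear", "sensitive", "very-sensitive")
  # top bin keeps everything in every mode
  for (m in modes) expect_equal(mode_percentile(3, 4, m), 1)
  expect_equal(mode_percentile(1, 4, "linear"), 0.5)
  expect_equal(mode_percentile(0, 4, "very-precise"), 0.015625)
  expect_equal(mode_percentile(0, 4, "very-sensitive"), 0.25^(1 / 3))
  # keep fraction ordered from precise to sensitive in every bin,
  # and monotone non-decreasing along bins in every mode
  for (b in 0:3) {
    kf <- vapply(modes, function(m) mode_percentile(b, 4, m), numeric(1))
    expect_true(all(diff(kf) >= 0))
  }
  for (m in modes) {
    expect_true(all(diff(vapply(0:3, function(b) mode_percentile(b, 4, m),
                                numeric(1))) >= 0))
  }
  expect_error(mode_percentile(0, 4, "fast"), "unknown mode")
  expect_error(mode_percentile(4, 4, "linear"))
})

test_that("score bins divide the observed range with a closed top edge", {
  e <- tibble::tibble(rank = "species", taxid = 1:4, score = c(1, 2, 3, 4))
  expect_equal(assign_bins(e, 4)$bin, c(0L, 1L, 2L, 3L))
  # degenerate range: everything in the top bin
  e2 <- tibble::tibble(rank = "species", taxid = 1:3, score = c(2, 2, 2))
  expect_equal(assign_bins(e2, 4)$bin, c(3L, 3L, 3L))
  expect_equal(assign_bins(e, 1)$bin, rep(0L, 4))
  # ranks are binned independently
  e3 <- tibble::tibble(rank = c("species", "species", "genus", "genus"),
                       taxid = 1:4, score = c(1, 7, 1, 7))
  b3 <- assign_bins(e3, 2)
  expect_equal(b3$bin, c(0L, 1L, 0L, 1L))
  expect_error(assign_bins(e, 0), ">= 1")
})

test_that("bin filtering keeps top-abundance entries and honours the cutoff", {
  e <- tibble::tibble(rank = "species", taxid = 1:10, score = 5,
                      bin = 0L, integrated_abundance = 10:1)
  cfg <- merge_config(bins = 2, mode = "linear", cutoff = 0)
  kept <- filter_bins(e, cfg)  # bin0 of B=2, linear -> keep 1/2
  expect_equal(nrow(kept), 5L)
  expect_setequal(kept$integrated_abundance, 6:10)
  # keep-fraction 1 keeps everything
  e$bin <- 1L
  expect_equal(nrow(filter_bins(e, cfg)), 10L)
  # the absolute cutoff removes entries even from the top bin
  e2 <- tibble::tibble(rank = "species", taxid = 1:2, score = 5, bin = 3L,
                       integrated_abundance = c(50, 1e-6))
  expect_equal(filter_bins(e2, merge_config())$taxid, 1L)
  # ceiling guarantees non-empty bins keep at least one entry
  e3 <- tibble::tibble(rank = "species", taxid = 1:3, score = 1, bin = 0L,
                       integrated_abundance = c(3, 2, 1))
  k3 <- filter_bins(e3, merge_config(bins = 4, mode = "very-precise", cutoff = 0))
  expect_equal(k3$taxid, 1L)
})

test_that("merging one tool returns its normalized profile back", {
  p <- prof(list("species", 9, 60), list("species", 11, 20), tool_id = "solo")
  m <- suppressWarnings(
    merge_profiles(list(p), config = merge_config(bins = 1)))
  expect_equal(m$profile$abundance, c(75, 25))
  expect_equal(m$profile$taxid, c(9L, 11L))
})

test_that("a hand-traced two-tool merge behaves end to end", {
  tree <- deep_tree()
  # identical databases, disjoint reports -> equal scores, degenerate bin
  dbt <- function(id) {
    f <- tempfile(); writeLines(c("9\t1000", "11\t1000"), f)
    read_database_profile(f, tree, tool_id = id)
  }
  p1 <- prof(list("species", 9, 100), tool_id = "t1")
  p2 <- prof(list("species", 11, 100), tool_id = "t2")
  m <- merge_profiles(list(p1, p2), list(dbt("t1"), dbt("t2")),
                      merge_config(bins = 4, mode = "linear", cutoff = 0))
  det <- m$detail[m$detail$rank == "species", ]
  expect_equal(det$i, c(1L, 1L))
  expect_equal(det$j, c(2L, 2L))
  expect_equal(det$score, c(4 / 3, 4 / 3))
  expect_equal(det$bin, c(3L, 3L))   # degenerate range -> top bin
  expect_true(all(det$kept))
  expect_equal(m$profile$abundance[m$profile$rank == "species"], c(50, 50))
})

test_that("true co-occurring taxa survive while solitary false reports are cut", {
  tree <- generate_taxonomy(40, seed = 21)
  species <- species_of(tree)
  true_sp <- species[1:10]
  withr::with_seed(31, {
    true_ab <- stats::runif(10, 5, 15)
  })
  profs <- lapply(1:6, function(t) {
    fp <- species[10 + (t - 1) * 5 + 1:5]   # disjoint per tool
    rows <- c(lapply(seq_along(true_sp), function(k)
                list("species", true_sp[k], true_ab[k])),
              lapply(fp, function(s) list("species", s, 0.05)))
    normalize_profile(do.call(prof, c(rows, list(tool_id = sprintf("t%d", t)))))
  })
  dbs <- lapply(1:6, function(t) {
    fp <- species[10 + (t - 1) * 5 + 1:5]
    f <- tempfile()
    writeLines(sprintf("%d\t1000", c(true_sp, fp)), f)
    read_database_profile(f, tree, tool_id = sprintf("t%d", t))
  })
  m <- merge_profiles(profs, dbs, merge_config())
  det <- m$detail[m$detail$rank == "species", ]
  expect_equal(sort(unique(det$i[det$taxid %in% true_sp])), 6L)
  expect_equal(sort(unique(det$i[!det$taxid %in% true_sp])), 1L)
  # all true species are in the top bin and survive
  expect_true(all(det$bin[det$taxid %in% true_sp] == 3L))
  expect_true(all(det$kept[det$taxid %in% true_sp]))
  # solitary false species concentrate at the bottom of the score range
  expect_true(all(det$bin[!det$taxid %in% true_sp] == 0L))
  kept_fp <- sum(det$kept & !det$taxid %in% true_sp)
  expect_lte(kept_fp, ceiling(0.25 * 30))
  # precise mode removes them entirely on this fixture
  mp <- merge_profiles(profs, dbs, merge_config(mode = "very-precise"))
  dp <- mp$detail[mp$detail$rank == "species", ]
  expect_equal(sum(dp$kept & !dp$taxid %in% true_sp), 1L)  # ceiling floor
})

test_that("the final profile conserves mass and orders deterministically", {
  reps <- ensemble_replicates(3)
  for (ens in reps) {
    m <- suppressWarnings(merge_profiles(ens$profiles, ens$dbprofiles))
    sums <- tapply(m$profile$abundance, m$profile$rank, sum)
    expect_true(all(abs(sums - 100) <= 1e-9))
    for (rk in unique(m$profile$rank)) {
      sub <- m$profile[m$profile$rank == rk, ]
      expect_true(all(diff(sub$abundance) <= 1e-12))
    }
    # byte-reproducibility of the merge given identical inputs
    m2 <- suppressWarnings(merge_profiles(ens$profiles, ens$dbprofiles))
    expect_identical(as.data.frame(m$profile), as.data.frame(m2$profile))
  }
})

test_that("survivor sets nest from very-precise to very-sensitive", {
  modes <- c("very-precise", "precise", "linear", "sensitive", "very-sensitive")
  reps <- ensemble_replicates(3)
  for (ens in reps) {
    truth_sp <- ens$truth$taxid[ens$truth$rank == "species"]
    sets <- lapply(modes, function(md) {
      m <- suppressWarnings(
        merge_profiles(ens$profiles, ens$dbprofiles, merge_config(mode = md)))
      m$profile$taxid[m$profile$rank == "species"]
    })
    for (k in 1:4) expect_true(all(sets[[k]] %in% sets[[k + 1]]))
    sens <- vapply(sets, function(s) mean(truth_sp %in% s), numeric(1))
    expect_true(all(diff(sens) >= 0))
  }
})

test_that("tidy/glance/autoplot expose the merge detail", {
  ens <- ensemble_replicates(1)[[1]]
  m <- suppressWarnings(merge_profiles(ens$profiles, ens$dbprofiles))
  td <- tidy(m)
  expect_true(all(c("rank", "taxid", "i", "j", "score", "bin",
                    "integrated_abundance", "kept") %in% names(td)))
  expect_true(any(grepl("^ab_tool", names(td))))
  expect_equal(nrow(td), nrow(m$detail))
  gl <- glance(m)
  expect_equal(gl$rank, fixed_ranks())
  expect_true(all(gl$n_kept <= gl$n_reported))
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(m$profile), "ggplot")
})
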