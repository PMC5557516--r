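#' Specification of a synthetic classifier ensemble
#'
#' Parameters of the generator that emulates the regime an ensemble merge
#' faces in practice: several tools seeing overlapping but distinct slices
#' of a community (complementary true positives), incomplete reference
#' databases, multiplicative abundance noise, and a long tail of
#' low-abundance false positives that rarely co-occur between tools.
#'
#' @param n_species Number of species truly present (default 50).
#' @param n_tools Number of simulated classifiers (default 6).
#' @param db_coverage Probability a true species is in a tool's reference
#'   database (default 0.8).
#' @param tool_sensitivity Probability a present-and-covered species is
#'   reported by a tool (default 0.7).
#' @param fp_per_tool False species reported per tool (default 15).
#' @param abundance_meanlog,abundance_sdlog Log-normal parameters of the
#'   true species abundance distribution (defaults 0 and 1.5).
#' @param abundance_noise_cv Coefficient of variation of the multiplicative
#'   log-normal noise each tool applies to a true abundance (default 0.3).
#' @param shared_fp Stress flag: draw every tool's false positives from one
#'   shared pool so false co-occurrence becomes common (default FALSE; the
#'   default disjoint pools make false co-occurrence rare).
#' @param seed Integer seed driving the whole ensemble.
#' @return An `ensemble_spec` list.
#' @export
ensemble_spec <- function(n_species = 50L, n_tools = 6L, db_coverage = 0.8,
                          tool_sensitivity = 0.7, fp_per_tool = 15L,
                          abundance_meanlog = 0, abundance_sdlog = 1.5,
                          abundance_noise_cv = 0.3, shared_fp = FALSE,
                          seed = 1L) {
  stopifnot(n_species >= 1L, n_tools >= 1L, fp_per_tool >= 0L,
            db_coverage >= 0, db_coverage <= 1,
            tool_sensitivity >= 0, tool_sensitivity <= 1,
            abundance_noise_cv >= 0)
  structure(list(n_species = as.integer(n_species),
                 n_tools = as.integer(n_tools),
                 db_coverage = db_coverage,
                 tool_sensitivity = tool_sensitivity,
                 fp_per_tool = as.integer(fp_per_tool),
                 abundance_meanlog = abundance_meanlog,
                 abundance_sdlog = abundance_sdlog,
                 abundance_noise_cv = abundance_noise_cv,
                 shared_fp = shared_fp, seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Generate a random seven-rank taxonomy
#'
#' Builds a tree with `n_species` species leaves under the full
#' [fixed_ranks()] ladder: each species is attached to a uniformly chosen
#' genus, each genus to a family, and so on up to at most two superkingdoms
#' under the root. Every leaf's lineage therefore has all seven ranks. The
#' tree round-trips through [write_taxonomy_dump()] and [load_taxonomy()].
#'
#' @param n_species Number of species leaves.
#' @param seed Integer seed.
#' @return A `taxonomy`.
#' @export
generate_taxonomy <- function(n_species, seed = 1L) {
  stopifnot(n_species >= 1L)
  withr::with_seed(seed, {
    ranks <- fixed_ranks()
    # node counts shrink from species up; at least one node per rank
    counts <- integer(7L)
    counts[7L] <- n_species
    shrink <- c(2.5, 2, 2, 2, 2.5)  # species->genus ... class->phylum
    for (k in 6:2) {
      counts[k] <- max(1L, ceiling(counts[k + 1L] / shrink[k - 1L]))
    }
    counts[1L] <- min(2L, counts[2L])

    next_id <- 2L
    ids <- vector("list", 7L)
    for (k in 1:7) {
      ids[[k]] <- seq.int(next_id, length.out = counts[k])
      next_id <- next_id + counts[k]
    }
    parent <- c(stats::setNames(1L, "1"))
    rank <- c(stats::setNames("no rank", "1"))
    name <- c(stats::setNames("root", "1"))
    for (k in 1:7) {
      par <- if (k == 1L) rep(1L, counts[k]) else
        sample(ids[[k - 1L]], counts[k], replace = TRUE)
      parent <- c(parent, stats::setNames(par, ids[[k]]))
      rank <- c(rank, stats::setNames(rep(ranks[k], counts[k]), ids[[k]]))
      name <- c(name, stats::setNames(
        sprintf("%s_%d", ranks[k], seq_len(counts[k])), ids[[k]]))
    }
    new_taxonomy(parent, rank, name,
                 stats::setNames(integer(0), character(0)), 1L)
  })
}

species_of <- function(tree) {
  sort(as.integer(names(tree$rank)[tree$rank == "species"]))
}

# Roll species-level values up the fixed ranks by cumulative sums.
rollup_species <- function(taxids, values, tree) {
  rows <- map2(taxids, values, function(tx, v) {
    lin <- lineage_at_ranks(tree, tx)
    tibble(rank = names(lin), taxid = unname(lin), abundance = v)
  })
  bind_rows(rows) |>
    group_by(.data$rank, .data$taxid) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop")
}

#' Generate a ground-truth community profile
#'
#' Draws `n_species` species (a seeded sample of the tree's leaves), gives
#' them log-normal abundances, normalizes species to 100%, and rolls the
#' values up to every fixed rank by cumulative sums.
#'
#' @param spec An [ensemble_spec()].
#' @param tree A `taxonomy` with at least `spec$n_species` species.
#' @return A normalized [tax_profile()] with `tool_id = "gold_standard"`.
#' @export
generate_truth <- function(spec, tree) {
  sp <- species_of(tree)
  if (length(sp) < spec$n_species) {
    abort("taxonomy has fewer species than spec$n_species")
  }
  withr::with_seed(spec$seed, {
    chosen <- sort(sample(sp, spec$n_species))
    ab <- stats::rlnorm(spec$n_species, meanlog = spec$abundance_meanlog,
                        sdlog = spec$abundance_sdlog)
  })
  ab <- ab / sum(ab) * 100
  tax_profile(rollup_species(chosen, ab, tree), sample_id = "synthetic",
              tool_id = "gold_standard") |>
    normalize_profile()
}

# Off-truth species partitioned into per-tool false-positive pools.
fp_pool <- function(spec, truth_species, tree, tool_index) {
  off <- setdiff(species_of(tree), truth_species)
  if (length(off) == 0L || spec$fp_per_tool == 0L) return(integer(0))
  if (spec$shared_fp) return(off)
  blocks <- split(off, rep(seq_len(spec$n_tools), length.out = length(off)))
  blocks[[((tool_index - 1L) %% spec$n_tools) + 1L]]
}

#' Simulate one classifier's profile and database
#'
#' The tool's database covers each true species with probability
#' `db_coverage`, plus the tool's own false-positive pool. Among covered
#' true species, each is reported with probability `tool_sensitivity`, at
#' the true abundance perturbed by multiplicative log-normal noise
#' (`abundance_noise_cv`). `fp_per_tool` false species are added at low
#' abundances — uniform below the 10th percentile of the true species
#' abundances, matching the long tail of low-abundance false positives real
#' classifiers produce. The reported set is rolled up and normalized.
#'
#' @param spec An [ensemble_spec()].
#' @param truth A truth profile from [generate_truth()].
#' @param tool_index 1-based tool index (drives the tool's own seed and its
#'   disjoint false-positive pool).
#' @param tree The `taxonomy`.
#' @return List with `profile` (normalized [tax_profile()]) and `db`
#'   (`tax_db`, ancestor-closed, with synthetic reference lengths).
#' @export
simulate_tool <- function(spec, truth, tool_index, tree) {
  stopifnot(tool_index >= 1L, tool_index <= spec$n_tools)
  truth_sp <- filter(truth, .data$rank == "species")
  tool_id <- sprintf("tool%02d", tool_index)
  pool <- fp_pool(spec, truth_sp$taxid, tree, tool_index)

  withr::with_seed(spec$seed + 7919L * tool_index, {
    covered <- truth_sp$taxid[stats::runif(nrow(truth_sp)) < spec$db_coverage]
    db_species <- sort(union(covered, pool))
    ref_len <- round(stats::runif(length(db_species), 1e6, 5e6))

    reported <- covered[stats::runif(length(covered)) < spec$tool_sensitivity]
    true_ab <- truth_sp$abundance[match(reported, truth_sp$taxid)]
    if (spec$abundance_noise_cv > 0 && length(reported) > 0L) {
      s <- sqrt(log(1 + spec$abundance_noise_cv^2))
      true_ab <- true_ab * stats::rlnorm(length(reported), -s^2 / 2, s)
    }
    n_fp <- min(spec$fp_per_tool, length(pool))
    fps <- if (n_fp > 0L) sort(sample(pool, n_fp)) else integer(0)
    fp_ab <- if (n_fp > 0L) {
      q10 <- stats::quantile(truth_sp$abundance, 0.1, names = FALSE)
      stats::runif(n_fp, 0, q10)
    } else numeric(0)
  })

  taxids <- c(reported, fps)
  abunds <- c(true_ab, fp_ab)
  keep <- abunds > 0
  prof <- if (sum(keep) == 0L) {
    tax_profile(sample_id = "synthetic", tool_id = tool_id)
  } else {
    tax_profile(rollup_species(taxids[keep], abunds[keep], tree),
                sample_id = "synthetic", tool_id = tool_id) |>
      normalize_profile()
  }
  db <- new_db_profile(expand_db_ancestors(db_species, ref_len, tree), tool_id)
  list(profile = prof, db = db)
}

#' Simulate a full classifier ensemble
#'
#' Convenience wrapper: generates a taxonomy large enough to hold the truth
#' plus every tool's disjoint false-positive pool, the ground-truth profile,
#' and one (profile, database) pair per tool. Optionally writes every
#' artifact — taxonomy dumps, truth, per-tool profiles and database
#' profiles — in the formats the package readers accept.
#'
#' @param spec An [ensemble_spec()].
#' @param dir Optional output directory for the on-disk artifacts.
#' @return List with `tree`, `truth`, `profiles` (list), `dbprofiles`
#'   (list), and `paths` (if `dir` was given).
#' @export
simulate_ensemble <- function(spec = ensemble_spec(), dir = NULL) {
  n_total <- spec$n_species + max(1L, spec$n_tools * spec$fp_per_tool)
  tree <- generate_taxonomy(n_total, seed = spec$seed)
  truth <- generate_truth(spec, tree)
  sims <- map(seq_len(spec$n_tools), function(t)
    simulate_tool(spec, truth, t, tree))
  out <- list(tree = tree, truth = truth,
              profiles = map(sims, "profile"),
              dbprofiles = map(sims, "db"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    tax_paths <- write_taxonomy_dump(tree, file.path(dir, "taxonomy"))
    write_profile(truth, file.path(dir, "gold_standard.profile"), tree)
    prof_paths <- imap(out$profiles, function(p, k) {
      pth <- file.path(dir, sprintf("tool%02d.profile", k))
      write_profile(p, pth, tree)
      pth
    })
    db_paths <- imap(out$dbprofiles, function(d, k) {
      pth <- file.path(dir, sprintf("tool%02d.dbprofile", k))
      write_database_profile(d, pth, tree)
      pth
    })
    out$paths <- list(taxonomy = tax_paths,
                      truth = file.path(dir, "gold_standard.profile"),
                      profiles = prof_paths, dbprofiles = db_paths)
  }
  out
}

#' Simulate binning output for a profile
#'
#' Draws reads multinomially with probability proportional to species
#' abundance times reference length — the sampling model under which the
#' length-normalized estimator recovers the input abundances — and records
#' the synthetic reference lengths (uniform 1-5 Mb) in a database profile.
#'
#' @param profile A [tax_profile()] normalized at species rank.
#' @param n_reads Total number of reads to draw.
#' @param read_length Assigned length per read, bases.
#' @param tree The `taxonomy`.
#' @param seed Integer seed.
#' @param tool_id Tool identity for the outputs.
#' @return List with `binning` (`tax_binning`) and `db` (`tax_db`).
#' @export
simulate_binning <- function(profile, n_reads = 10000L, read_length = 100L,
                             tree, seed = 1L, tool_id = "sim_binner") {
  sp <- filter(profile, .data$rank == "species")
  if (nrow(sp) == 0L) abort("profile has no species entries")
  withr::with_seed(seed, {
    ref_len <- round(stats::runif(nrow(sp), 1e6, 5e6))
    p <- sp$abundance * ref_len
    counts <- as.integer(stats::rmultinom(1L, n_reads, p / sum(p)))
  })
  binning <- new_binning(
    tibble(sequence_id = sprintf("read_%07d", seq_len(n_reads)),
           length = as.integer(read_length),
           taxid = rep(sp$taxid, counts)),
    tool_id)
  db <- new_db_profile(expand_db_ancestors(sp$taxid, ref_len, tree), tool_id)
  list(binning = binning, db = db)
}
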