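#' Estimate a ranked abundance profile from binning output
#'
#' A binner classifies each read individually, so its output must be turned
#' into relative abundances before it can be merged with profiler output.
#' For every taxon with direct assignments the raw abundance is the summed
#' assigned length of its reads divided by the taxon's total reference
#' length in the tool's database — a length-normalized coverage proxy. Each
#' fixed rank then carries, for every taxon, the cumulative sum of its own
#' direct value and all descendants' direct values, so a genus inherits the
#' mass of its species. The result is un-normalized; pass it through
#' [normalize_profile()] before merging.
#'
#' Assignments to off-ladder nodes (strains) are projected to their deepest
#' fixed-rank ancestor first. Assignments to taxa absent from the database
#' profile are dropped with a counted warning — a tool cannot have classified
#' against a reference it lacks, so these are stale identifiers.
#'
#' @param binning A `tax_binning` from [read_binning()].
#' @param dbprofile The same tool's `tax_db` with reference lengths.
#' @param tree A `taxonomy`.
#' @return An un-normalized [tax_profile()].
#' @export
estimate_abundance <- function(binning, dbprofile, tree) {
  stopifnot(inherits(tree, "taxonomy"))
  tool_id <- attr(binning, "tool_id") %||% ""
  if (nrow(binning) == 0L) {
    return(tax_profile(tool_id = tool_id))
  }

  proj <- vapply(binning$taxid, function(tx) project_to_fixed(tree, tx),
                 integer(1))
  warn_count(sum(is.na(proj)),
             "assignment(s) to taxa with no fixed-rank ancestor dropped")
  keep <- !is.na(proj)
  binning <- binning[keep, , drop = FALSE]
  binning$taxid <- proj[keep]

  ref_len <- stats::setNames(dbprofile$ref_length, dbprofile$taxid)
  in_db <- as.character(binning$taxid) %in% names(ref_len)
  warn_count(sum(!in_db),
             "assignment(s) to taxa absent from the tool's database profile dropped")
  binning <- binning[in_db, , drop = FALSE]
  if (nrow(binning) == 0L) return(tax_profile(tool_id = tool_id))

  direct <- binning |>
    group_by(.data$taxid) |>
    summarise(bases = sum(as.numeric(.data$length)), .groups = "drop")
  lens <- unname(ref_len[as.character(direct$taxid)])
  if (anyNA(lens) || any(lens <= 0)) {
    abort("database profile has a missing or non-positive reference length for an assigned taxon")
  }
  direct$value <- direct$bases / lens

  # cumulative rule: a direct value contributes to the taxon itself and to
  # every fixed-rank ancestor
  rows <- map2(direct$taxid, direct$value, function(tx, v) {
    lin <- lineage_at_ranks(tree, tx)
    tibble(rank = names(lin), taxid = unname(lin), abundance = v)
  })
  prof <- bind_rows(rows) |>
    group_by(.data$rank, .data$taxid) |>
    summarise(abundance = sum(.data$abundance), .groups = "drop")
  tax_profile(prof, tool_id = tool_id)
}

#' Normalize a profile to 100% per rank
#'
#' Each fixed rank is scaled independently so its abundances sum to 100 —
#' necessary before merging because some tools account for unclassified
#' reads and others do not, making raw scales incomparable. Empty ranks stay
#' empty; an all-zero rank is left untouched with a warning. The operation
#' is idempotent and preserves within-rank abundance ratios.
#'
#' @param profile A [tax_profile()].
#' @return The normalized [tax_profile()].
#' @export
normalize_profile <- function(profile) {
  if (any(profile$abundance < 0)) abort("abundances must be >= 0")
  meta <- profile_meta(profile)
  out <- profile |>
    group_by(.data$rank) |>
    mutate(.s = sum(.data$abundance)) |>
    ungroup()
  zero <- unique(out$rank[out$.s == 0 & nrow(out) > 0])
  if (length(zero) > 0L) {
    warn(sprintf("rank(s) with zero total abundance left unscaled: %s",
                 paste(zero, collapse = ", ")))
  }
  out <- out |>
    mutate(abundance = ifelse(.data$.s > 0, .data$abundance * 100 / .data$.s,
                              .data$abundance)) |>
    select(-".s")
  tax_profile(out, sample_id = meta$sample_id, tool_id = meta$tool_id)
}

is_normalized <- function(profile, tol = 1e-6) {
  if (nrow(profile) == 0L) return(TRUE)
  sums <- profile |>
    group_by(.data$rank) |>
    summarise(s = sum(.data$abundance), .groups = "drop")
  all(abs(sums$s - 100) <= tol | sums$s == 0)
}

#' Sub-sample sequencing reads
#'
#' Uniform random sub-sampling of a read collection, with or without
#' replacement, or splitting a sample into `shards` equal disjoint parts and
#' returning shard `shard` — the scheme used to spread one sample across
#' several classifiers cheaply. Record order of the input is preserved in
#' the subset, and the draw is fully determined by `seed`.
#'
#' @param reads A vector-like read collection (character vector of record
#'   ids, a `Biostrings::XStringSet`, ...). Anything subsettable by integer
#'   index works.
#' @param fraction Fraction of reads to draw, in (0, 1]. Exactly
#'   `floor(fraction * length(reads))` reads are returned.
#' @param with_replacement Draw with replacement (duplicates allowed).
#' @param seed Integer seed; the same seed reproduces the same subset.
#' @param shards,shard Alternative to `fraction`: split into `shards` equal
#'   disjoint random parts and return part `shard` (1-based). Sizes differ by
#'   at most one read.
#' @return The selected subset, same class as `reads`.
#' @export
subsample_reads <- function(reads, fraction = NULL, with_replacement = FALSE,
                            seed = 1L, shards = NULL, shard = NULL) {
  n <- length(reads)
  if (!is.null(shards)) {
    if (is.null(shard) || shard < 1L || shard > shards) {
      abort("`shard` must be in 1..shards")
    }
    # seeded permutation cut into `shards` consecutive blocks (sizes differ
    # by at most one), then input order restored within the chosen block
    idx <- withr::with_seed(seed, sample.int(n))
    sizes <- tabulate(rep(seq_len(shards), length.out = n), shards)
    starts <- cumsum(c(0L, sizes))
    sel <- sort(idx[(starts[shard] + 1L):starts[shard + 1L]])
    return(reads[sel])
  }
  if (is.null(fraction) || fraction <= 0) abort("`fraction` must be in (0, 1]")
  if (fraction > 1 && !with_replacement) {
    abort("fraction > 1 requires with_replacement = TRUE")
  }
  k <- floor(fraction * n)
  if (k < 1L) abort("fraction * length(reads) must be >= 1")
  idx <- withr::with_seed(seed, sample.int(n, size = k,
                                           replace = with_replacement))
  reads[sort(idx)]
}

#' Sub-sample a FASTA/FASTQ file
#'
#' File-level wrapper around [subsample_reads()]: reads the records with
#' Biostrings, selects the subset, and writes it back in the same format
#' (detected from the file extension), preserving record order.
#'
#' @param input,output File paths; `.fq`/`.fastq` is treated as FASTQ,
#'   anything else as FASTA.
#' @inheritParams subsample_reads
#' @return Invisibly, `output`.
#' @export
subsample_fastx <- function(input, output, fraction = NULL,
                            with_replacement = FALSE, seed = 1L,
                            shards = NULL, shard = NULL) {
  rlang::check_installed("Biostrings")
  fastq <- grepl("\\.(fq|fastq)(\\.gz)?$", input, ignore.case = TRUE)
  if (fastq) {
    # Biostrings warns about dropped metadata columns on plain FASTQ input
    reads <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(input))
  } else {
    reads <- Biostrings::readDNAStringSet(input)
  }
  sub <- subsample_reads(reads, fraction = fraction,
                         with_replacement = with_replacement, seed = seed,
                         shards = shards, shard = shard)
  if (fastq) {
    Biostrings::writeQualityScaledXStringSet(sub, output)
  } else {
    Biostrings::writeXStringSet(sub, output)
  }
  invisible(output)
}
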