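# Independent oracle for the length-normalized abundance estimator: loop over
# individual reads, adding read_length / reference_length(assigned taxon) to
# the assigned taxon and every fixed-rank ancestor, one read at a time.
brute_force_estimate <- function(assignments, ref_lengths, tree) {
  acc <- list()
  for (k in seq_len(nrow(assignments))) {
    tx <- assignments$taxid[k]
    contrib <- assignments$length[k] / ref_lengths[[as.character(tx)]]
    lin <- lineage_at_ranks(tree, tx)
    for (r in names(lin)) {
      key <- paste(r, lin[[r]])
      acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + contrib
    }
  }
  acc
}

db_from_lengths <- function(ref_lengths, tree, tool_id = "bt") {
  f <- tempfile()
  writeLines(sprintf("%s\t%.0f", names(ref_lengths), unname(ref_lengths)), f)
  read_database_profile(f, tree, tool_id = tool_id)
}

bin_tbl <- function(taxids, lengths, tool_id = "bt") {
  b <- tibble::tibble(sequence_id = sprintf("r%04d", seq_along(taxids)),
                      length = as.integer(lengths), taxid = as.integer(taxids))
  attr(b, "tool_id") <- tool_id
  b
}

# Shared ensemble experiment for the scaled-down dominance checks: for each
# seed, the default-spec ensemble merged under every mode, with per-rank
# evaluations of the merged and single-tool profiles.
acceptance_runs <- local({
  cache <- NULL
  function(n = 20L) {
    if (!is.null(cache) && length(cache) >= n) return(cache[seq_len(n)])
    modes <- c("very-precise", "precise", "linear", "sensitive",
               "very-sensitive")
    cache <<- lapply(seq_len(n), function(s) {
      ens <- suppressWarnings(simulate_ensemble(ensemble_spec(seed = s)))
      truth_sp <- ens$truth$taxid[ens$truth$rank == "species"]
      merges <- lapply(modes, function(md) {
        suppressWarnings(merge_profiles(ens$profiles, ens$dbprofiles,
                                        merge_config(mode = md)))
      })
      names(merges) <- modes
      tool_evals <- lapply(ens$profiles, function(p)
        evaluate_profile(p, ens$truth))
      merged_eval <- evaluate_profile(merges[["linear"]]$profile, ens$truth)
      list(ens = ens, truth_sp = truth_sp, merges = merges,
           tool_evals = tool_evals, merged_eval = merged_eval)
    })
    cache
  }
})
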