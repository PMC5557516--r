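#' Evaluate a predicted profile against a gold standard
#'
#' Binary and quantitative comparison per rank. A predicted taxon present in
#' the truth is a true positive; predicted-only taxa are false positives and
#' truth-only taxa false negatives. Sensitivity is TP/(TP+FN), precision
#' TP/(TP+FP) (NA when nothing was predicted at a rank). The L1 norm is the
#' sum over the union of taxa of absolute abundance differences, with a
#' missing taxon counting as abundance 0; on normalized profiles it lies in
#' [0, 200].
#'
#' @param predicted,truth Normalized [tax_profile()]s resolved against the
#'   same taxonomy.
#' @return A tibble with one row per rank present in either profile:
#'   `rank`, `tp`, `fp`, `fn`, `sensitivity`, `precision`, `l1`.
#' @export
evaluate_profile <- function(predicted, truth) {
  if (!is_normalized(predicted) || !is_normalized(truth)) {
    abort("both profiles must be normalized to 100% per rank (normalize_profile())")
  }
  ranks <- intersect(fixed_ranks(),
                     union(unique(predicted$rank), unique(truth$rank)))
  rows <- map(ranks, function(rk) {
    p <- filter(predicted, .data$rank == rk)
    t <- filter(truth, .data$rank == rk)
    inter <- intersect(p$taxid, t$taxid)
    tp <- length(inter)
    fp <- length(setdiff(p$taxid, t$taxid))
    fn <- length(setdiff(t$taxid, p$taxid))
    uni <- union(p$taxid, t$taxid)
    pa <- stats::setNames(rep(0, length(uni)), uni)
    ta <- pa
    pa[as.character(p$taxid)] <- p$abundance
    ta[as.character(t$taxid)] <- t$abundance
    tibble(rank = rk, tp = tp, fp = fp, fn = fn,
           sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           l1 = sum(abs(pa - ta)))
  })
  bind_rows(rows) |> arrange(rank_factor(.data$rank))
}

#' Database-limited maximum sensitivity
#'
#' A taxon absent from every tool's reference database can never be
#' identified, so the attainable sensitivity is capped below 1. This helper
#' reports, per rank, the fraction of truth taxa present in the union of the
#' supplied database profiles — the ceiling against which observed
#' sensitivities should be read. It is a companion output, not a change to
#' the sensitivity definition, whose denominator stays the full truth set.
#'
#' @param truth A [tax_profile()] gold standard.
#' @param dbprofiles List of `tax_db` database profiles.
#' @return Tibble with `rank`, `n_truth`, `n_coverable`, `max_sensitivity`.
#' @export
max_sensitivity <- function(truth, dbprofiles) {
  db_union <- bind_rows(map(dbprofiles, function(d) {
    tibble(rank = d$rank, taxid = d$taxid)
  })) |> distinct()
  truth |>
    group_by(.data$rank) |>
    summarise(
      n_truth = dplyr::n(),
      n_coverable = sum(paste(.data$rank, .data$taxid) %in%
                          paste(db_union$rank, db_union$taxid)),
      .groups = "drop") |>
    mutate(max_sensitivity = .data$n_coverable / .data$n_truth) |>
    arrange(rank_factor(.data$rank))
}

#' Write a per-rank evaluation report
#'
#' @param eval_result A tibble from [evaluate_profile()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(eval_result, path) {
  utils::write.table(eval_result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
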