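#' Merge configuration
#'
#' Tunables of the ensemble merge. `bins` is the number of equal-width score
#' bins per rank (4 by default). `mode` selects the precision-sensitivity
#' trade-off of the per-bin percentile cutoff, from `very-precise` to
#' `very-sensitive` (`linear` by default). `cutoff` is the minimum integrated
#' abundance (percent) a taxon must reach regardless of its bin, tied to the
#' lowest-abundance organism expected in the sample (0.0001 by default).
#' `ranks` restricts processing to a subset of [fixed_ranks()].
#'
#' @param bins Positive integer number of score bins.
#' @param mode One of `"very-precise"`, `"precise"`, `"linear"`,
#'   `"sensitive"`, `"very-sensitive"`.
#' @param cutoff Minimum integrated abundance in percent.
#' @param ranks Ordered subset of [fixed_ranks()].
#' @return A `merge_config` list.
#' @export
merge_config <- function(bins = 4L, mode = "linear", cutoff = 1e-4,
                         ranks = fixed_ranks()) {
  if (bins < 1L) abort("`bins` must be >= 1")
  if (cutoff < 0) abort("`cutoff` must be >= 0")
  mode <- match.arg(mode, names(mode_exponents()))
  if (!all(ranks %in% fixed_ranks())) abort("`ranks` must be fixed ranks")
  structure(list(bins = as.integer(bins), mode = mode, cutoff = cutoff,
                 ranks = ranks), class = "merge_config")
}

#' Co-occurrence score of a taxon
#'
#' The merge scores each taxon by how often it was identified relative to
#' how often it could have been: `S = (i + 1)^2 / (j + 1)`, with `i` the
#' number of tools reporting the taxon at a rank and `j` the number of tool
#' databases containing it. The square purposely biases toward `i = j`: a
#' taxon identified every time it could be (even once) outranks one present
#' in many databases but rarely reported.
#'
#' @param i Integer count(s) of reporting tools.
#' @param j Integer count(s) of databases containing the taxon.
#' @return Numeric score(s), vectorized over `i` and `j`.
#' @export
#' @examples
#' score_taxon(3, 3)  # diagonal: i + 1
#' score_taxon(1, 5)  # widely available but rarely seen: low
score_taxon <- function(i, j) {
  if (any(i < 0) || any(j < 0)) abort("counts must be >= 0")
  (i + 1)^2 / (j + 1)
}

#' Integrate per-tool abundances by harmonic mean
#'
#' The merged abundance of a taxon is the harmonic mean of the normalized
#' abundances of the tools that reported it. The harmonic mean damps
#' outliers: one tool over-reporting a taxon a hundredfold barely moves the
#' integrated value, which tracks the general trend instead.
#'
#' @param values Numeric vector of positive percentages (one per reporting
#'   tool).
#' @return The harmonic mean.
#' @export
#' @examples
#' integrate_abundance(c(1, 100))  # ~1.98, far below the arithmetic 50.5
integrate_abundance <- function(values) {
  if (length(values) == 0L) abort("need at least one abundance")
  if (any(values <= 0)) abort("abundances must be > 0")
  length(values) / sum(1 / values)
}

#' Collect per-taxon merge state across tools
#'
#' For every rank, every taxon reported by at least one tool becomes one
#' entry holding its occurrence count `i` (tools reporting it), database
#' presence `j` (tool databases containing it), and the per-tool normalized
#' abundances. A taxon reported by a tool whose database profile lacks it
#' still counts toward `i` but not `j`; this is logged, since it indicates a
#' stale database profile.
#'
#' @param profiles List of normalized [tax_profile()]s, one per tool.
#' @param dbprofiles List of `tax_db` objects; matched to profiles by their
#'   `tool_id` attribute. A tool without a database profile contributes 0 to
#'   `j` everywhere (warned once).
#' @return Tibble with columns `rank`, `taxid`, `i`, `j` and list-column
#'   `tool_abundance` (named numeric vectors).
#' @export
collect_entries <- function(profiles, dbprofiles = list()) {
  tool_ids <- vapply(profiles, function(p) attr(p, "tool_id") %||% "",
                     character(1))
  if (anyDuplicated(tool_ids) > 0L) {
    abort(sprintf("duplicate tool id among profiles: '%s'",
                  tool_ids[duplicated(tool_ids)][1L]))
  }
  db_ids <- vapply(dbprofiles, function(d) attr(d, "tool_id") %||% "",
                   character(1))
  missing_db <- setdiff(tool_ids, db_ids)
  if (length(missing_db) > 0L) {
    warn(sprintf("no database profile for tool(s) %s; they contribute 0 to j",
                 paste(missing_db, collapse = ", ")))
  }

  long <- bind_rows(map(profiles, function(p) {
    tibble(tool = attr(p, "tool_id") %||% "", rank = p$rank, taxid = p$taxid,
           abundance = p$abundance)
  }))
  if (nrow(long) == 0L) {
    return(tibble(rank = character(0), taxid = integer(0), i = integer(0),
                  j = integer(0), tool_abundance = list()))
  }
  db_long <- bind_rows(map(dbprofiles, function(d) {
    tibble(rank = d$rank, taxid = d$taxid)
  }))

  entries <- long |>
    group_by(.data$rank, .data$taxid) |>
    summarise(i = dplyr::n_distinct(.data$tool),
              tool_abundance = list(stats::setNames(.data$abundance, .data$tool)),
              .groups = "drop")
  if (nrow(db_long) > 0L) {
    j_tbl <- db_long |>
      group_by(.data$rank, .data$taxid) |>
      summarise(j = dplyr::n(), .groups = "drop")
    entries <- left_join(entries, j_tbl, by = c("rank", "taxid"))
    entries$j[is.na(entries$j)] <- 0L
  } else {
    entries$j <- 0L
  }

  # a report by a tool whose own database profile lacks the taxon indicates
  # a stale database profile; it still counts toward i but not j
  if (length(db_ids) > 0L) {
    db_sets <- stats::setNames(
      map(dbprofiles, function(d) paste(d$rank, d$taxid)), db_ids)
    stale <- sum(map_int(seq_len(nrow(entries)), function(k) {
      key <- paste(entries$rank[k], entries$taxid[k])
      tools_k <- intersect(names(entries$tool_abundance[[k]]), db_ids)
      sum(vapply(tools_k, function(tl) !key %in% db_sets[[tl]], logical(1)))
    }))
    warn_count(stale, "report(s) of a taxon absent from the reporting tool's own database")
  }
  select(entries, "rank", "taxid", "i", "j", "tool_abundance")
}

mode_exponents <- function() {
  c("very-precise" = 3, "precise" = 2, "linear" = 1,
    "sensitive" = 1 / 2, "very-sensitive" = 1 / 3)
}

#' Per-bin keep fraction for a filtering mode
#'
#' The filtering step keeps only the top-abundance fraction of each score
#' bin. With `x = (bin_index + 1) / bins` the normalized bin position
#' (higher x = higher-score bin), the keep fraction is `x^e` with exponent 3,
#' 2, 1, 1/2, 1/3 for the modes very-precise through very-sensitive. Every
#' mode keeps the whole top bin; precise modes cut low-score bins hard,
#' sensitive modes keep most of them.
#'
#' @param bin_index 0-based bin index (vectorized).
#' @param bins Total number of bins.
#' @param mode Mode name, see [merge_config()].
#' @return Keep fraction(s) in (0, 1].
#' @export
mode_percentile <- function(bin_index, bins, mode = "linear") {
  exps <- mode_exponents()
  if (!mode %in% names(exps)) abort(sprintf("unknown mode '%s'", mode))
  if (any(bin_index < 0L) || any(bin_index >= bins)) {
    abort("bin_index must be in [0, bins)")
  }
  ((bin_index + 1) / bins)^exps[[mode]]
}

#' Assign score bins within each rank
#'
#' Bins are defined by equally dividing the per-rank score range into `bins`
#' intervals; an entry with score S gets
#' `min(floor((S - Smin) / width), bins - 1)`, so the top edge is closed.
#' When all scores at a rank are equal the range is degenerate and every
#' entry lands in the top bin — filtering then degrades gracefully to the
#' percentile-on-abundance rule.
#'
#' @param entries Tibble with `rank` and `score` columns.
#' @param bins Number of bins.
#' @return `entries` with an integer `bin` column (0-based).
#' @export
assign_bins <- function(entries, bins = 4L) {
  if (bins < 1L) abort("`bins` must be >= 1")
  entries |>
    group_by(.data$rank) |>
    mutate(bin = {
      smin <- min(.data$score); smax <- max(.data$score)
      if (smax == smin) {
        rep(bins - 1L, dplyr::n())
      } else {
        w <- (smax - smin) / bins
        pmin(as.integer(floor((.data$score - smin) / w)), bins - 1L)
      }
    }) |>
    ungroup()
}

#' Filter merge entries by abundance within score bins
#'
#' Entries below the absolute abundance cutoff are removed first, whatever
#' their bin. Then, within each (rank, bin), entries are ranked by descending
#' integrated abundance (ties broken by higher score, then lower taxid) and
#' the top `ceiling(keep_fraction * bin_size)` survive, so every non-empty
#' bin keeps at least one taxon.
#'
#' @param entries Tibble with `rank`, `taxid`, `score`, `bin`,
#'   `integrated_abundance` columns.
#' @param config A [merge_config()].
#' @return The surviving rows of `entries`.
#' @export
filter_bins <- function(entries, config = merge_config()) {
  entries |>
    filter(.data$integrated_abundance >= config$cutoff) |>
    group_by(.data$rank, .data$bin) |>
    arrange(desc(.data$integrated_abundance), desc(.data$score), .data$taxid,
            .by_group = TRUE) |>
    mutate(.keep_n = ceiling(mode_percentile(.data$bin[1L], config$bins,
                                             config$mode) * dplyr::n())) |>
    filter(row_number() <= .data$.keep_n) |>
    ungroup() |>
    select(-".keep_n")
}

#' Merge taxonomic profiles from several tools
#'
#' The ensemble core. Per rank, independently: input profiles are normalized
#' to 100%; each reported taxon is collected with its occurrence count `i`,
#' database presence `j`, co-occurrence score `S = (i+1)^2/(j+1)` and
#' harmonic-mean integrated abundance; taxa are placed into equal-width
#' score bins; each bin keeps only its top-abundance fraction according to
#' the mode; survivors are re-normalized to 100% and sorted by descending
#' abundance. The returned object carries both the final profile and the
#' full pre-filter detail (i, j, S, bin, per-tool abundances, kept flag).
#'
#' @param profiles List of [tax_profile()]s, one per tool (normalized or
#'   not).
#' @param dbprofiles List of `tax_db` database profiles.
#' @param config A [merge_config()].
#' @param sample_id Sample identity for the output profile.
#' @return A `tax_merge` object: list with `profile` (final
#'   [tax_profile()]), `detail` (tibble), and `config`.
#' @export
merge_profiles <- function(profiles, dbprofiles = list(),
                           config = merge_config(), sample_id = NULL) {
  if (length(profiles) == 0L) abort("need at least one profile")
  stopifnot(inherits(config, "merge_config"))
  sample_id <- sample_id %||% (attr(profiles[[1L]], "sample_id") %||% "")

  normalized <- map(profiles, normalize_profile)
  normalized <- map(normalized, function(p) {
    meta <- profile_meta(p)
    tax_profile(filter(p, .data$rank %in% config$ranks),
                sample_id = meta$sample_id, tool_id = meta$tool_id)
  })

  entries <- collect_entries(normalized, dbprofiles)
  if (nrow(entries) == 0L) {
    detail <- tibble(rank = character(0), taxid = integer(0), i = integer(0),
                     j = integer(0), score = numeric(0), bin = integer(0),
                     integrated_abundance = numeric(0), kept = logical(0),
                     tool_abundance = list())
    out <- list(profile = tax_profile(sample_id = sample_id,
                                      tool_id = "merged"),
                detail = detail, config = config)
    class(out) <- "tax_merge"
    return(out)
  }
  entries <- entries |>
    mutate(score = score_taxon(.data$i, .data$j),
           integrated_abundance = map_dbl(.data$tool_abundance,
                                          integrate_abundance)) |>
    assign_bins(bins = config$bins)

  kept <- filter_bins(entries, config)
  detail <- entries |>
    mutate(kept = paste(.data$rank, .data$taxid) %in%
             paste(kept$rank, kept$taxid)) |>
    select("rank", "taxid", "i", "j", "score", "bin",
           "integrated_abundance", "kept", "tool_abundance") |>
    arrange(rank_factor(.data$rank), desc(.data$integrated_abundance),
            .data$taxid)

  final <- kept |>
    rename(abundance = "integrated_abundance") |>
    select("rank", "taxid", "abundance") |>
    tax_profile(sample_id = sample_id, tool_id = "merged") |>
    normalize_profile()

  out <- list(profile = final, detail = detail, config = config)
  class(out) <- "tax_merge"
  out
}

#' @export
print.tax_merge <- function(x, ...) {
  cat(sprintf("<tax_merge> mode=%s bins=%d cutoff=%g: %d/%d taxa kept across %d rank(s)\n",
              x$config$mode, x$config$bins, x$config$cutoff,
              sum(x$detail$kept), nrow(x$detail),
              dplyr::n_distinct(x$detail$rank)))
  print(x$profile, ...)
  invisible(x)
}

#' Tidy a merged-profile object
#'
#' Returns the full per-taxon merge detail, one row per (rank, taxon)
#' reported by any tool: occurrence `i`, database presence `j`, score, bin,
#' harmonic-mean abundance, survival flag, and one `ab_<tool>` column per
#' tool with that tool's normalized abundance.
#'
#' @param x A `tax_merge` object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy tax_merge
#' @export
tidy.tax_merge <- function(x, ...) {
  det <- x$detail
  if (nrow(det) == 0L) return(select(det, -"tool_abundance"))
  tools <- sort(unique(unlist(map(det$tool_abundance, names))))
  wide <- map(tools, function(tl) {
    map_dbl(det$tool_abundance, function(v) {
      if (tl %in% names(v)) v[[tl]] else NA_real_
    })
  })
  names(wide) <- paste0("ab_", tools)
  bind_cols(select(det, -"tool_abundance"), as_tibble(wide))
}

#' Glance at a merged-profile object
#'
#' One row per rank: how many taxa entered, how many survived, and the
#' score-bin occupancy.
#'
#' @inheritParams tidy.tax_merge
#' @return A tibble with one row per rank.
#' @method glance tax_merge
#' @export
glance.tax_merge <- function(x, ...) {
  x$detail |>
    group_by(.data$rank) |>
    summarise(n_reported = dplyr::n(), n_kept = sum(.data$kept),
              mean_i = mean(.data$i), mean_j = mean(.data$j),
              .groups = "drop") |>
    arrange(rank_factor(.data$rank))
}

#' Plot the score/abundance landscape of a merge
#'
#' Scatter of integrated abundance (log scale) against co-occurrence score,
#' colored by survival, faceted by rank — the visual counterpart of the
#' bin-and-cut filtering rule.
#'
#' @param object A `tax_merge` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tax_merge
#' @export
autoplot.tax_merge <- function(object, ...) {
  det <- object$detail
  ggplot2::ggplot(det, ggplot2::aes(x = .data$score,
                                    y = .data$integrated_abundance,
                                    colour = .data$kept)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(ggplot2::vars(rank_factor(.data$rank))) +
    ggplot2::labs(x = "co-occurrence score S", y = "integrated abundance (%)",
                  colour = "kept") +
    ggplot2::theme_minimal()
}

#' Plot a ranked profile
#'
#' Horizontal bars of relative abundance per taxon, faceted by rank.
#'
#' @param object A [tax_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot tax_profile
#' @export
autoplot.tax_profile <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abundance,
                                   y = stats::reorder(factor(.data$taxid),
                                                      .data$abundance))) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(rank_factor(.data$rank)),
                        scales = "free_y") +
    ggplot2::labs(x = "relative abundance (%)", y = "taxid") +
    ggplot2::theme_minimal()
}
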