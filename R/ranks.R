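#' Canonical taxonomic ranks
#'
#' The seven ranks every profile is resolved to, ordered from broadest
#' (superkingdom) to narrowest (species). All per-rank operations in the
#' package iterate over this ordering; ranks outside it (strain, subspecies,
#' "no rank" clades) are either projected onto it or dropped at read time.
#'
#' @return Character vector of rank names, broadest first.
#' @export
#' @examples
#' fixed_ranks()
fixed_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

# Rank-name normalization: inputs from tools using the "domain" dialect are
# aliased to "superkingdom"; everything else is lower-cased verbatim.
normalize_rank <- function(rank) {
  rank <- tolower(trimws(rank))
  rank[rank == "domain"] <- "superkingdom"
  rank
}

# Index of a rank within fixed_ranks(); NA for ranks outside the ladder.
rank_index <- function(rank) {
  match(normalize_rank(rank), fixed_ranks())
}

# Order a rank column by the fixed ladder (factor keeps emitted files and
# grouped summaries in superkingdom -> species order).
rank_factor <- function(rank) {
  factor(rank, levels = fixed_ranks())
}
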