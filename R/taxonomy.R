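#' @importFrom stringr str_split fixed
NULL

# fixed 7-rank lineage convention used throughout
lineage_rank_names <- c("domain", "phylum", "class", "order", "family",
                        "genus", "species")

#' Split semicolon-delimited lineages into the fixed 7-rank convention
#'
#' Lineages shorter than seven ranks are right-padded as unassigned (`NA`);
#' blank rank labels are also treated as unassigned. An unassigned rank
#' never matches anything, including itself, when computing common prefixes.
#'
#' @param lineage Character vector of `;`-delimited lineage strings
#'   (domain;phylum;class;order;family;genus;species).
#' @return Character matrix with one row per lineage and seven columns.
#' @export
parse_lineage <- function(lineage) {
  parts <- str_split(lineage, fixed(";"))
  out <- matrix(NA_character_, nrow = length(parts), ncol = 7,
                dimnames = list(NULL, lineage_rank_names))
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- p[seq_len(min(length(p), 7))]
    p[!nzchar(p)] <- NA_character_
    out[i, seq_along(p)] <- p
  }
  out
}

# longest common lineage prefix of a rank matrix; unassigned terminates
.common_prefix <- function(ranks) {
  depth <- 0L
  for (j in seq_len(ncol(ranks))) {
    col <- ranks[, j]
    if (any(is.na(col)) || length(unique(col)) != 1) break
    depth <- j
  }
  if (depth == 0L) character(0) else ranks[1, seq_len(depth)]
}

# threshold filter + bitscore cap shared by the assignment modes;
# hits tied at the max_hits-th bitscore are all kept (input-order independent)
.qualify_hits <- function(hits, min_identity, min_coverage, max_hits, strict) {
  keep <- if (strict) {
    hits$percent_identity > min_identity & hits$query_coverage > min_coverage
  } else {
    hits$percent_identity >= min_identity & hits$query_coverage >= min_coverage
  }
  hits <- hits[keep, , drop = FALSE]
  hits |>
    group_by(.data$asv_id) |>
    arrange(dplyr::desc(.data$bitscore), .by_group = TRUE) |>
    filter(.data$bitscore >= dplyr::nth(.data$bitscore, min(max_hits, n()))) |>
    ungroup()
}

.assign_from_hits <- function(all_ids, qualified, method, min_identity, min_coverage) {
  assigned <- qualified |>
    group_by(.data$asv_id) |>
    summarise(lineage = paste(.common_prefix(parse_lineage(.data$lineage)),
                              collapse = ";"),
              n_hits = n(), .groups = "drop")
  tibble(asv_id = all_ids) |>
    left_join(assigned, by = "asv_id") |>
    mutate(lineage = tidyr::replace_na(.data$lineage, ""),
           n_hits = tidyr::replace_na(.data$n_hits, 0L),
           depth = ifelse(nzchar(.data$lineage),
                          lengths(str_split(.data$lineage, fixed(";"))), 0L),
           rank = ifelse(.data$depth > 0, lineage_rank_names[pmax(.data$depth, 1)],
                         NA_character_),
           method = method, min_identity = min_identity,
           min_coverage = min_coverage) |>
    select("asv_id", "lineage", "rank", "depth", "n_hits", "method",
           "min_identity", "min_coverage")
}

#' Lowest-common-ancestor taxonomy assignment
#'
#' For each ASV, hits below the identity/coverage thresholds are discarded,
#' at most `max_hits` best-bitscore hits are retained (ties at the cutoff
#' are all kept), and the assignment is the longest lineage prefix common
#' to every retained hit. An ASV with no qualifying hits is left
#' unassigned (empty lineage).
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @param min_identity,min_coverage Inclusive thresholds in percent.
#' @param max_hits Maximum hits retained per ASV (default 200, the number
#'   of alignments requested per query in a typical search).
#' @return Tibble with one row per ASV: `asv_id`, `lineage` (assigned
#'   prefix, possibly empty), `rank` (deepest assigned rank), `depth`,
#'   `n_hits`, `method`, and the thresholds used.
#' @export
lca_assign <- function(hits, min_identity = 0, min_coverage = 0, max_hits = 200) {
  validate_hit_table(hits)
  qualified <- .qualify_hits(hits, min_identity, min_coverage, max_hits,
                             strict = FALSE)
  .assign_from_hits(unique(hits$asv_id), qualified, "lca",
                    min_identity, min_coverage)
}

#' High-confidence taxonomy assignment
#'
#' Identical to [lca_assign()] but with strict (exclusive) threshold
#' comparisons: identity must exceed 99% and coverage must exceed the
#' preset (90% generally; 95% for vertebrate targets). A hit at exactly
#' 99.0% identity is excluded.
#'
#' @param hits Hit tibble.
#' @param min_identity Exclusive identity threshold (default 99).
#' @param coverage_preset `"general"` (coverage > 90) or `"vertebrate"`
#'   (coverage > 95); ignored when `min_coverage` is given.
#' @param min_coverage Optional explicit exclusive coverage threshold.
#' @param max_hits Maximum hits retained per ASV.
#' @return Assignment tibble as in [lca_assign()], `method =
#'   "high_confidence"`.
#' @export
high_confidence_assign <- function(hits, min_identity = 99,
                                   coverage_preset = c("general", "vertebrate"),
                                   min_coverage = NULL, max_hits = 200) {
  coverage_preset <- match.arg(coverage_preset)
  min_coverage <- min_coverage %||% switch(coverage_preset, general = 90,
                                           vertebrate = 95)
  validate_hit_table(hits)
  qualified <- .qualify_hits(hits, min_identity, min_coverage, max_hits,
                             strict = TRUE)
  .assign_from_hits(unique(hits$asv_id), qualified, "high_confidence",
                    min_identity, min_coverage)
}

#' Consensus functional annotation over alignment hits
#'
#' Each reference subject carries a categorical annotation (for example a
#' functional group). An ASV receives an annotation only when every
#' qualifying hit (identity > `min_identity`, coverage > `min_coverage`)
#' carries the identical annotation; any disagreement, or an empty
#' qualifying set, yields no annotation.
#'
#' @param hits Hit tibble; annotations are taken from an `annotation`
#'   column in `hits` or joined from `annotations`.
#' @param annotations Optional tibble (`subject_id`, `annotation`).
#' @param min_identity,min_coverage Exclusive thresholds in percent
#'   (defaults 85 and 90).
#' @return Tibble (`asv_id`, `annotation`, `n_hits`); `annotation` is `NA`
#'   without consensus.
#' @export
consensus_annotation <- function(hits, annotations = NULL, min_identity = 85,
                                 min_coverage = 90) {
  validate_hit_table(hits)
  if (!is.null(annotations)) {
    hits <- hits |>
      select(-dplyr::any_of("annotation")) |>
      left_join(annotations, by = "subject_id")
  }
  if (!"annotation" %in% names(hits)) {
    abort("no annotation column in hits and no annotations table supplied")
  }
  qualified <- .qualify_hits(hits, min_identity, min_coverage,
                             max_hits = Inf, strict = TRUE)
  consensus <- qualified |>
    group_by(.data$asv_id) |>
    summarise(annotation = if (dplyr::n_distinct(.data$annotation) == 1)
      .data$annotation[1] else NA_character_,
      n_hits = n(), .groups = "drop")
  tibble(asv_id = unique(hits$asv_id)) |>
    left_join(consensus, by = "asv_id") |>
    mutate(n_hits = tidyr::replace_na(.data$n_hits, 0L))
}

#' Merge ASV counts within replicates by assigned genus
#'
#' Counts of every ASV assigned to the given genus are summed within each
#' PCR replicate, so that per-replicate presence reflects the genus rather
#' than any single sequence variant. Reads of the genus are conserved.
#'
#' @param table Long-format ASV table (typically post-curation).
#' @param assignments Assignment tibble from [lca_assign()] or
#'   [high_confidence_assign()] covering every ASV in `table`.
#' @param genus Genus name, e.g. `"Gadus"` or `"Clupea"`.
#' @return Tibble (`replicate_id`, `taxon`, `count`) with one row per
#'   replicate present in `table` (zero counts included). Empty with a
#'   warning when no ASV is assigned to the genus.
#' @export
genus_merge <- function(table, assignments, genus) {
  validate_asv_table(table)
  missing_asv <- setdiff(unique(table$asv_id), assignments$asv_id)
  if (length(missing_asv) > 0) {
    abort(paste0("assignments missing for ASV(s): ",
                 paste(utils::head(missing_asv, 5), collapse = ", ")))
  }
  genus_col <- parse_lineage(assignments$lineage)[, "genus"]
  target_ids <- assignments$asv_id[!is.na(genus_col) & genus_col == genus]
  replicates <- unique(table$replicate_id)
  if (length(target_ids) == 0) {
    warn(paste0("no ASV assigned to genus ", genus))
    return(tibble(replicate_id = replicates, taxon = genus, count = 0))
  }
  table |>
    filter(.data$asv_id %in% target_ids) |>
    group_by(.data$replicate_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    tidyr::complete(replicate_id = replicates, fill = list(count = 0)) |>
    mutate(taxon = genus) |>
    select("replicate_id", "taxon", "count")
}
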