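#' Global alignment identity between two DNA sequences
#'
#' Needleman-Wunsch global alignment (match +1, mismatch -1, gap -2);
#' identity is the number of matching columns divided by the total number of
#' alignment columns (gaps included).
#'
#' @param a,b DNA strings.
#' @return Identity as a percentage in \[0, 100\].
#' @export
alignment_identity <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, baseOnly = TRUE,
                                                  mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 0, gapExtension = 2)
  columns <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / columns
}

# deterministic representative id for a set of merged ASVs: most abundant,
# ties broken lexicographically
.pick_id <- function(ids, totals) {
  ids[order(-totals, ids)][1]
}

# collapse rows with exactly identical sequences, summing counts within each
# replicate; representative asv_id chosen by .pick_id
.collapse_identical <- function(table, lane_label = NULL, orientation_label = NULL) {
  totals <- table |>
    group_by(.data$asv_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  id_map <- table |>
    distinct(.data$asv_id, .data$sequence) |>
    left_join(totals, by = "asv_id") |>
    group_by(.data$sequence) |>
    summarise(new_id = .pick_id(.data$asv_id, .data$total), .groups = "drop")
  lane_label <- lane_label %||% paste(sort(unique(table$lane)), collapse = "+")
  orientation_label <- orientation_label %||%
    (if (length(unique(table$orientation)) == 1) table$orientation[1] else "merged")
  table |>
    left_join(id_map, by = "sequence") |>
    group_by(.data$new_id, .data$sequence, .data$replicate_id) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    rename(asv_id = "new_id") |>
    mutate(lane = lane_label, orientation = orientation_label) |>
    select(all_of(.asv_cols))
}

#' Merge forward- and reverse-orientation ASV tables
#'
#' Two-pass demultiplexing of a library built with the amplicon in both
#' orientations yields two per-lane tables of the same molecules. The
#' reverse-orientation sequences are reverse-complemented and counts are
#' summed for exactly identical sequences within each replicate; the union
#' of replicates is preserved and total reads are conserved.
#'
#' @param table_fwd,table_rev Long-format ASV tables from the same lane.
#' @return Merged ASV table with `orientation = "merged"`.
#' @export
merge_orientations <- function(table_fwd, table_rev) {
  validate_asv_table(table_fwd)
  validate_asv_table(table_rev)
  lanes <- unique(c(table_fwd$lane, table_rev$lane))
  if (length(lanes) > 1) {
    shared <- intersect(table_fwd$replicate_id, table_rev$replicate_id)
    if (length(shared) > 0) {
      abort("replicate present in both orientations with conflicting lane metadata")
    }
    abort("orientation tables must come from the same lane")
  }
  rev_rc <- table_rev |>
    mutate(sequence = as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(.data$sequence))))
  out <- bind_rows(table_fwd, rev_rc) |>
    .collapse_identical(lane_label = lanes, orientation_label = "merged")
  stopifnot(total_reads(out) == total_reads(table_fwd) + total_reads(table_rev))
  out
}

#' Post-clustering error curation of an ASV table
#'
#' Merges likely erroneous "daughter" ASVs into more abundant, highly
#' similar, co-occurring "parent" ASVs, in the style of post-clustering
#' curation of amplicon tables. A daughter qualifies for a parent when
#' (i) the parent's total abundance exceeds the daughter's, (ii) global
#' alignment identity is at least `min_identity`, (iii) the parent is
#' present in at least `min_cooccurrence` of the replicates where the
#' daughter is present, and (iv) the minimum parent/daughter count ratio
#' over co-occurring replicates is at least `min_ratio`. Qualification is
#' decided on the input table; daughters are processed in ascending
#' total-abundance order and their counts flow to the ultimate surviving
#' parent (merge chains are followed), so reads are conserved exactly.
#'
#' When several parents qualify the one with the highest alignment identity
#' is chosen, ties broken by larger total abundance then lexicographic id.
#'
#' @param table Long-format ASV table with sequences.
#' @param min_identity Minimum percent identity (default 99).
#' @param min_ratio Minimum parent/daughter abundance ratio in co-occurring
#'   replicates (default 1).
#' @param min_cooccurrence Minimum fraction of daughter-positive replicates
#'   where the parent is also positive (default 0.95).
#' @return Curated ASV table; a no-op when no merge qualifies.
#' @export
lulu_curation <- function(table, min_identity = 99, min_ratio = 1,
                          min_cooccurrence = 0.95) {
  validate_asv_table(table)
  seqs <- table |> distinct(.data$asv_id, .data$sequence)
  if (nrow(seqs) < 2) return(table)
  counts <- table |>
    select("asv_id", "replicate_id", "count") |>
    tidyr::pivot_wider(names_from = "replicate_id", values_from = "count",
                       values_fill = 0)
  mat <- as.matrix(counts[, -1, drop = FALSE])
  rownames(mat) <- counts$asv_id
  totals <- rowSums(mat)
  ord <- names(sort(totals))  # ascending abundance; stable on ties by name

  parent_of <- character(0)
  for (d in ord) {
    cand <- names(totals)[totals > totals[[d]]]
    if (length(cand) == 0) next
    d_pos <- mat[d, ] > 0
    if (!any(d_pos)) next
    best <- NULL
    best_ident <- -Inf
    d_seq <- seqs$sequence[seqs$asv_id == d]
    for (p in cand[order(-totals[cand], cand)]) {
      co <- sum(mat[p, d_pos] > 0) / sum(d_pos)
      if (co < min_cooccurrence) next
      both <- d_pos & (mat[p, ] > 0)
      if (!any(both)) next
      ratio <- min(mat[p, both] / mat[d, both])
      if (ratio < min_ratio) next
      ident <- alignment_identity(seqs$sequence[seqs$asv_id == p], d_seq)
      if (ident >= min_identity && ident > best_ident) {
        best <- p
        best_ident <- ident
      }
    }
    if (!is.null(best)) parent_of[[d]] <- best
  }
  if (length(parent_of) == 0) return(table)

  # follow merge chains to the ultimate surviving parent
  resolve <- function(x) {
    while (x %in% names(parent_of)) x <- parent_of[[x]]
    x
  }
  dest <- vapply(names(totals), resolve, character(1))
  table |>
    mutate(dest = dest[.data$asv_id]) |>
    group_by(.data$dest, .data$replicate_id, .data$lane, .data$orientation) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    rename(asv_id = "dest") |>
    left_join(seqs, by = "asv_id") |>
    select(all_of(.asv_cols))
}

#' Remove singleton observations and single-replicate ASVs
#'
#' Per lane: observations (single ASV x replicate cells) with a count of 1
#' are set to zero, then ASVs left with non-zero counts in fewer than two
#' replicates of the lane are removed entirely. Idempotent.
#'
#' @param table Long-format ASV table.
#' @return Filtered table.
#' @export
filter_replicate_support <- function(table) {
  validate_asv_table(table)
  table |>
    mutate(count = ifelse(.data$count == 1, 0, .data$count)) |>
    group_by(.data$lane, .data$asv_id) |>
    filter(sum(.data$count > 0) >= 2) |>
    ungroup()
}

#' Zero sediment observations at or below the negative-control level
#'
#' For each ASV in each lane a contamination threshold tau is the arithmetic
#' mean of its counts over all negative-control replicates of the lane
#' (extraction, PCR and library negatives; zeros included in the mean).
#' By default every sediment observation with `count <= tau` is set to zero
#' ("at or below contamination level"). `literal = TRUE` instead zeroes
#' observations with `count > tau` — the printed form of the rule in the
#' source protocol, retained behind a flag because it removes the strongest
#' signal and is treated here as an erratum. Negative-control observations
#' are left untouched.
#'
#' @param table Long-format ASV table.
#' @param info Replicate metadata.
#' @param literal Use the literal "more than the mean is zeroed" reading
#'   (default `FALSE`).
#' @return List with `table` (filtered) and `thresholds` (tibble `lane`,
#'   `asv_id`, `tau`, `n_negatives`).
#' @export
negative_control_filter <- function(table, info, literal = FALSE) {
  validate_asv_table(table, info)
  validate_replicate_info(info)
  lanes <- unique(table$lane)
  neg <- info |> filter(.data$role != "sediment", .data$lane %in% lanes)
  n_neg <- neg |> dplyr::count(.data$lane, name = "n_negatives")
  missing_lanes <- setdiff(lanes, n_neg$lane)
  if (length(missing_lanes) > 0) {
    abort(paste0(
      "no negative-control replicates in lane(s) ",
      paste(missing_lanes, collapse = ", "),
      "; to run without contamination thresholding, omit this stage explicitly"))
  }
  neg_counts <- table |>
    inner_join(neg |> select("replicate_id"), by = "replicate_id") |>
    group_by(.data$lane, .data$asv_id) |>
    summarise(neg_total = sum(.data$count), .groups = "drop")
  thresholds <- table |>
    distinct(.data$lane, .data$asv_id) |>
    left_join(neg_counts, by = c("lane", "asv_id")) |>
    left_join(n_neg, by = "lane") |>
    mutate(neg_total = tidyr::replace_na(.data$neg_total, 0),
           tau = .data$neg_total / .data$n_negatives) |>
    select("lane", "asv_id", "tau", "n_negatives")
  sediment_ids <- info$replicate_id[info$role == "sediment"]
  out <- table |>
    left_join(thresholds |> select("lane", "asv_id", "tau"),
              by = c("lane", "asv_id")) |>
    mutate(zero = .data$replicate_id %in% sediment_ids &
             (if (literal) .data$count > .data$tau else .data$count <= .data$tau),
           count = ifelse(.data$zero, 0, .data$count)) |>
    select(all_of(.asv_cols))
  list(table = out, thresholds = thresholds)
}

#' Remove ASVs outside the expected amplicon length range
#'
#' ASVs with sequences shorter than `min_len` or longer than `max_len`
#' base pairs are removed; both bounds are inclusive (a 70-bp and a 170-bp
#' amplicon are retained at the defaults).
#'
#' @param table Long-format ASV table.
#' @param min_len,max_len Inclusive length bounds in base pairs (defaults
#'   70 and 170, the expected 18S V9 amplicon range without primers).
#' @return Filtered table.
#' @export
length_filter <- function(table, min_len = 70, max_len = 170) {
  if (min_len > max_len) abort("min_len must not exceed max_len")
  validate_asv_table(table)
  table |> filter(nchar(.data$sequence) >= min_len,
                  nchar(.data$sequence) <= max_len)
}

#' Combine per-lane ASV tables
#'
#' Counts are summed for exactly identical sequences across lanes within
#' each replicate; the union of replicates is preserved and reads are
#' conserved. With a single input table this is the identity.
#'
#' @param tables List of long-format ASV tables (one per lane), or a single
#'   table.
#' @param info Optional replicate metadata; when given, a replicate
#'   appearing with inconsistent sample metadata raises an error.
#' @return Combined ASV table.
#' @export
combine_lanes <- function(tables, info = NULL) {
  if (is.data.frame(tables)) tables <- list(tables)
  purrr::walk(tables, validate_asv_table)
  if (!is.null(info)) {
    key <- info |>
      distinct(.data$replicate_id, .data$sample_id, .data$core_id, .data$role)
    if (any(duplicated(key$replicate_id))) {
      abort("replicate_id appears with conflicting metadata across lanes")
    }
  }
  all_tbl <- bind_rows(tables)
  out <- .collapse_identical(all_tbl)
  stopifnot(total_reads(out) == total_reads(all_tbl))
  out
}

#' Run the full per-lane curation cascade
#'
#' Applies, per lane: orientation merging (when both orientations are
#' supplied), post-clustering error curation, singleton/replicate-support
#' filtering, negative-control thresholding, and amplicon length filtering;
#' the curated per-lane tables are then combined across lanes by summing
#' identical sequences. A per-stage audit (ASVs and reads in/out,
#' observations zeroed) is returned alongside the table.
#'
#' @param tables A list with one element per lane; each element is either a
#'   single ASV table or a list with elements `forward` and `reverse`.
#' @param info Replicate metadata covering every lane.
#' @param min_identity,min_ratio,min_cooccurrence Passed to
#'   [lulu_curation()].
#' @param min_len,max_len Passed to [length_filter()].
#' @param negative_filter Apply the negative-control stage (default `TRUE`;
#'   must be set to `FALSE` explicitly for lanes without negatives).
#' @param literal_negative_rule Passed to [negative_control_filter()].
#' @return List with `table` (combined curated table), `report` (per-stage
#'   audit tibble) and `thresholds` (per-lane per-ASV tau).
#' @export
curate <- function(tables, info, min_identity = 99, min_ratio = 1,
                   min_cooccurrence = 0.95, min_len = 70, max_len = 170,
                   negative_filter = TRUE, literal_negative_rule = FALSE) {
  validate_replicate_info(info)
  report <- list()
  thresholds <- list()
  audit <- function(stage, lane, before, after) {
    tibble(stage = stage, lane = lane,
           asvs_in = dplyr::n_distinct(before$asv_id[before$count > 0]),
           asvs_out = dplyr::n_distinct(after$asv_id[after$count > 0]),
           reads_in = total_reads(before), reads_out = total_reads(after),
           observations_zeroed = sum(before$count > 0) - sum(after$count > 0))
  }
  curated <- purrr::imap(tables, function(tbl, i) {
    if (!is.data.frame(tbl) && all(c("forward", "reverse") %in% names(tbl))) {
      merged <- merge_orientations(tbl$forward, tbl$reverse)
      lane <- unique(merged$lane)
      report[[length(report) + 1]] <<-
        audit("merge_orientations", lane, bind_rows(tbl$forward, tbl$reverse), merged)
      tbl <- merged
    }
    lane <- paste(unique(tbl$lane), collapse = "+")
    s1 <- lulu_curation(tbl, min_identity = min_identity, min_ratio = min_ratio,
                        min_cooccurrence = min_cooccurrence)
    report[[length(report) + 1]] <<- audit("lulu_curation", lane, tbl, s1)
    s2 <- filter_replicate_support(s1)
    report[[length(report) + 1]] <<- audit("filter_replicate_support", lane, s1, s2)
    if (negative_filter) {
      nc <- negative_control_filter(s2, info, literal = literal_negative_rule)
      report[[length(report) + 1]] <<- audit("negative_control_filter", lane, s2, nc$table)
      thresholds[[length(thresholds) + 1]] <<- nc$thresholds
      s3 <- nc$table
    } else {
      s3 <- s2
    }
    s4 <- length_filter(s3, min_len = min_len, max_len = max_len)
    report[[length(report) + 1]] <<- audit("length_filter", lane, s3, s4)
    s4
  })
  combined <- combine_lanes(unname(curated), info = info)
  report[[length(report) + 1]] <-
    audit("combine_lanes", "all", bind_rows(curated), combined)
  list(table = combined,
       report = bind_rows(report),
       thresholds = if (length(thresholds)) bind_rows(thresholds) else NULL)
}
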