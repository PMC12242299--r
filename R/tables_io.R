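#' @importFrom rlang .data abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   distinct left_join inner_join anti_join bind_rows n across all_of rename
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# Canonical long-format ASV table columns. Counts are one row per
# (asv_id, replicate_id) cell; the sequence travels with every row so that
# dplyr verbs never strand it.
.asv_cols <- c("asv_id", "sequence", "lane", "orientation", "replicate_id", "count")

.replicate_roles <- c("sediment", "extraction_negative", "pcr_negative", "library_negative")

#' Validate a long-format ASV count table
#'
#' Checks the structural invariants of an ASV table: non-negative integer
#' counts, exactly one sequence per ASV identifier, non-empty DNA sequences,
#' and (when replicate metadata is supplied) that every replicate in the
#' counts is described in the metadata.
#'
#' @param table Tibble with columns `asv_id`, `sequence`, `lane`,
#'   `orientation`, `replicate_id`, `count`.
#' @param info Optional replicate metadata tibble (see
#'   [read_replicate_info()]).
#' @return `table`, invisibly, if all invariants hold; otherwise an error.
#' @export
validate_asv_table <- function(table, info = NULL) {
  missing_cols <- setdiff(.asv_cols, names(table))
  if (length(missing_cols) > 0) {
    abort(paste0("ASV table is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(table$count < 0)) {
    abort("ASV table contains negative counts")
  }
  if (any(table$count != floor(table$count))) {
    abort("ASV table counts must be integers")
  }
  seq_per_id <- table |>
    distinct(.data$asv_id, .data$sequence) |>
    dplyr::count(.data$asv_id)
  if (any(seq_per_id$n > 1)) {
    bad <- seq_per_id$asv_id[seq_per_id$n > 1]
    abort(paste0("ASV id(s) mapped to more than one sequence: ",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  if (any(!nzchar(table$sequence))) {
    abort("ASV table contains empty sequences")
  }
  if (any(duplicated(table[, c("asv_id", "replicate_id")]))) {
    abort("duplicate (asv_id, replicate_id) cells in ASV table")
  }
  if (!is.null(info)) {
    orphans <- setdiff(unique(table$replicate_id), info$replicate_id)
    if (length(orphans) > 0) {
      abort(paste0("replicate(s) in counts absent from metadata: ",
                   paste(utils::head(orphans, 5), collapse = ", ")))
    }
  }
  invisible(table)
}

#' Validate replicate metadata
#'
#' @param info Tibble with columns `replicate_id`, `sample_id`, `core_id`,
#'   `depth_cm`, `replicate_index`, `role`, `lane`. `role` is one of
#'   `"sediment"`, `"extraction_negative"`, `"pcr_negative"`,
#'   `"library_negative"`. Negative controls may lack a depth; sediment
#'   replicates must carry one.
#' @return `info`, invisibly.
#' @export
validate_replicate_info <- function(info) {
  needed <- c("replicate_id", "sample_id", "core_id", "depth_cm",
              "replicate_index", "role", "lane")
  missing_cols <- setdiff(needed, names(info))
  if (length(missing_cols) > 0) {
    abort(paste0("replicate metadata missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(duplicated(info$replicate_id))) {
    abort("replicate_id values must be unique")
  }
  key <- info[, c("sample_id", "replicate_index", "lane")]
  if (any(duplicated(key))) {
    abort("(sample_id, replicate_index, lane) must be unique in replicate metadata")
  }
  bad_role <- setdiff(unique(info$role), .replicate_roles)
  if (length(bad_role) > 0) {
    abort(paste0("unknown replicate role(s): ", paste(bad_role, collapse = ", ")))
  }
  sed <- info$role == "sediment"
  if (any(sed & (is.na(info$depth_cm) | info$depth_cm < 0))) {
    abort("sediment replicates must have a non-negative depth_cm")
  }
  invisible(info)
}

#' Read an ASV count table and its replicate metadata
#'
#' Reads a wide tab-separated ASV table (columns `asv_id`, `sequence`, then
#' one column per PCR replicate) together with a replicate metadata table,
#' returning the counts in long format with the lane label joined from the
#' metadata. Lines starting with `#` are comments.
#'
#' @param path Path to the wide count TSV.
#' @param metadata_path Path to the replicate metadata TSV.
#' @param orientation Orientation label for this table, `"forward"` or
#'   `"reverse"` (per-orientation tables produced by two-pass
#'   demultiplexing), or `"merged"`.
#' @return A list with elements `table` (long tibble, see
#'   [validate_asv_table()]) and `info` (replicate metadata tibble).
#' @export
read_asv_table <- function(path, metadata_path, orientation = "forward") {
  info <- read_replicate_info(metadata_path)
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("asv_id", "sequence") %in% names(wide))) {
    abort("ASV table must start with asv_id and sequence columns")
  }
  if (any(duplicated(wide$asv_id))) {
    abort("duplicate asv_id rows in ASV table file")
  }
  rep_cols <- setdiff(names(wide), c("asv_id", "sequence"))
  long <- wide |>
    tidyr::pivot_longer(all_of(rep_cols), names_to = "replicate_id",
                        values_to = "count") |>
    mutate(count = as.numeric(.data$count))
  lane_map <- info |> select("replicate_id", "lane")
  orphans <- setdiff(unique(long$replicate_id), lane_map$replicate_id)
  if (length(orphans) > 0) {
    abort(paste0("replicate(s) in counts absent from metadata: ",
                 paste(utils::head(orphans, 5), collapse = ", ")))
  }
  table <- long |>
    left_join(lane_map, by = "replicate_id") |>
    mutate(orientation = orientation) |>
    select(all_of(.asv_cols))
  validate_asv_table(table, info)
  list(table = table, info = info)
}

#' Write an ASV count table as wide TSV
#'
#' Inverse of [read_asv_table()]: one row per ASV, one column per replicate,
#' integer counts. Round-trips bit-exactly.
#'
#' @param table Long-format ASV table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path) {
  validate_asv_table(table)
  wide <- table |>
    select("asv_id", "sequence", "replicate_id", "count") |>
    tidyr::pivot_wider(names_from = "replicate_id", values_from = "count",
                       values_fill = 0)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read replicate metadata
#'
#' @param path TSV with one row per PCR replicate; see
#'   [validate_replicate_info()] for the required columns.
#' @return Validated metadata tibble.
#' @export
read_replicate_info <- function(path) {
  info <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(
                            depth_cm = readr::col_double(),
                            replicate_index = readr::col_integer(),
                            .default = readr::col_character()
                          ))
  validate_replicate_info(as_tibble(info))
  as_tibble(info)
}

#' Write replicate metadata
#'
#' @param info Replicate metadata tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_replicate_info <- function(info, path) {
  validate_replicate_info(info)
  readr::write_tsv(info, path)
  invisible(path)
}

#' Read an alignment hit table
#'
#' Reads a BLAST-tabular-like TSV with one row per hit. The lineage is a
#' semicolon-delimited rank string (domain;phylum;class;order;family;genus;
#' species); shorter lineages are treated as unassigned at the missing
#' ranks. Hits are grouped by ASV and sorted by descending bitscore within
#' each ASV.
#'
#' @param path TSV with columns `asv_id`, `subject_id`, `lineage`,
#'   `percent_identity`, `query_coverage`, `bitscore`, and optionally
#'   `annotation` (a categorical functional label per subject).
#' @return Hit tibble sorted by (`asv_id`, descending `bitscore`).
#' @export
read_hit_table <- function(path) {
  hits <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  if (nrow(hits) == 0) {
    return(tibble(asv_id = character(), subject_id = character(),
                  lineage = character(), percent_identity = numeric(),
                  query_coverage = numeric(), bitscore = numeric()))
  }
  validate_hit_table(hits)
  hits |> arrange(.data$asv_id, dplyr::desc(.data$bitscore))
}

#' Validate an alignment hit table
#'
#' @param hits Hit tibble (see [read_hit_table()]).
#' @return `hits`, invisibly.
#' @export
validate_hit_table <- function(hits) {
  needed <- c("asv_id", "subject_id", "lineage", "percent_identity",
              "query_coverage", "bitscore")
  missing_cols <- setdiff(needed, names(hits))
  if (length(missing_cols) > 0) {
    abort(paste0("hit table missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    abort("percent_identity outside [0, 100]")
  }
  if (any(hits$query_coverage < 0 | hits$query_coverage > 100)) {
    abort("query_coverage outside [0, 100]")
  }
  if (any(!nzchar(hits$lineage))) {
    abort("hit table contains empty lineages")
  }
  invisible(hits)
}

#' Write a hit table
#' @param hits Hit tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  readr::write_tsv(hits, path)
  invisible(path)
}

#' Read a climate proxy series
#'
#' @param path CSV with columns `time` (astronomical calendar year CE;
#'   1315 BCE is -1314) and `value` (proxy units).
#' @param proxy_name Label recorded in the `proxy_name` column.
#' @return Tibble (`time`, `value`, `proxy_name`) sorted by time.
#' @export
read_climate_series <- function(path, proxy_name = "proxy") {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  if (!all(c("time", "value") %in% names(x))) {
    abort("climate series must have time and value columns")
  }
  if (any(!is.finite(x$value))) abort("climate series contains non-finite values")
  x |>
    mutate(proxy_name = proxy_name) |>
    arrange(.data$time)
}

#' Write a climate proxy series
#' @param series Climate series tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_climate_series <- function(series, path) {
  readr::write_csv(series, path)
  invisible(path)
}

#' Read dated horizons for age-depth modelling
#'
#' @param path CSV with columns `depth_cm`, `age_mean` (calendar year CE),
#'   `age_sd` (years) and `source` (`"radiocarbon"` or `"tephra"`).
#'   Calibration and any reservoir correction are assumed already applied
#'   to the input ages.
#' @return Tibble sorted by depth.
#' @export
read_age_points <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  needed <- c("depth_cm", "age_mean", "age_sd", "source")
  if (!all(needed %in% names(x))) {
    abort(paste0("horizon table must have columns: ", paste(needed, collapse = ", ")))
  }
  if (any(duplicated(x$depth_cm))) abort("horizon depths must be unique")
  if (any(x$age_sd < 0)) abort("age_sd must be non-negative")
  x |> arrange(.data$depth_cm)
}

#' Read an archaeofaunal assemblage table
#'
#' @param path CSV with columns `site`, `first_century`, `last_century`
#'   (century indices, e.g. 9 = 801-900 CE), `marine_nisp`,
#'   `terrestrial_nisp`, and optionally `region`.
#' @return Assemblage tibble.
#' @export
read_assemblages <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  needed <- c("site", "first_century", "last_century", "marine_nisp",
              "terrestrial_nisp")
  if (!all(needed %in% names(x))) {
    abort(paste0("assemblage table must have columns: ",
                 paste(needed, collapse = ", ")))
  }
  if (any(x$last_century < x$first_century)) {
    abort("last_century must be >= first_century")
  }
  if (any(x$marine_nisp < 0 | x$terrestrial_nisp < 0)) {
    abort("NISP counts must be non-negative")
  }
  if (any(x$marine_nisp + x$terrestrial_nisp == 0)) {
    abort("each assemblage must have at least one identified specimen")
  }
  as_tibble(x)
}

#' Write ASV sequences as FASTA
#'
#' @param table Long-format ASV table.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_asv_fasta <- function(table, path) {
  seqs <- table |> distinct(.data$asv_id, .data$sequence)
  dna <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs$asv_id))
  Biostrings::writeXStringSet(dna, path)
  invisible(path)
}

#' Read ASV sequences from FASTA
#'
#' @param path FASTA path.
#' @return Tibble (`asv_id`, `sequence`).
#' @export
read_asv_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  tibble(asv_id = names(dna), sequence = unname(as.character(dna)))
}

# total reads in a table; used throughout the curation audit
total_reads <- function(table) sum(table$count)
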