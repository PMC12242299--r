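# In-code fixtures shared across the suite. Everything is built
# programmatically; no data files are read.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# reverse complement written independently of Biostrings, for oracles
revcomp_chr <- function(s) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", s), ""),
         function(x) paste(rev(x), collapse = ""), character(1))
}

rand_dna <- function(n, len = 100) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# replicate metadata: n_samples sediment samples x R replicates in one lane,
# plus n_neg negative controls
tiny_info <- function(n_samples = 2, R = 3, lane = "L1", n_neg = 2,
                      core = "PC19", depth_step = 10) {
  sed <- tidyr::expand_grid(s = seq_len(n_samples), r = seq_len(R)) |>
    mutate(sample_id = sprintf("S%02d", s),
           replicate_id = sprintf("S%02d.%d", s, r),
           core_id = core, depth_cm = s * depth_step,
           replicate_index = r, role = "sediment", lane = lane) |>
    select(replicate_id, sample_id, core_id, depth_cm, replicate_index,
           role, lane)
  if (n_neg == 0) return(sed)
  neg <- tibble(replicate_id = sprintf("NEG%02d.1", seq_len(n_neg)),
                sample_id = sprintf("NEG%02d", seq_len(n_neg)),
                core_id = "control", depth_cm = NA_real_,
                replicate_index = 1L,
                role = rep(c("extraction_negative", "pcr_negative",
                             "library_negative"), length.out = n_neg),
                lane = lane)
  bind_rows(sed, neg)
}

# long ASV table from a count matrix (rows = ASVs, cols = replicate ids)
asv_tbl <- function(counts, sequences, lane = "L1", orientation = "merged",
                    keep_zeros = FALSE) {
  stopifnot(nrow(counts) == length(sequences))
  ids <- rownames(counts) %||% sprintf("A%02d", seq_len(nrow(counts)))
  out <- tibble(asv_id = rep(ids, times = ncol(counts)),
                sequence = rep(unname(sequences), times = ncol(counts)),
                lane = lane, orientation = orientation,
                replicate_id = rep(colnames(counts), each = nrow(counts)),
                count = as.numeric(counts))
  if (!keep_zeros) out <- out |> filter(count > 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small random experiment table over a tiny_info roster
random_asv_table <- function(info, n_asv = 10, lane = "L1", seed = 1,
                             max_count = 50, seq_len_bp = 100) {
  set.seed(seed)
  reps <- info$replicate_id[info$lane == lane]
  m <- matrix(rpois(n_asv * length(reps), lambda = max_count / 4),
              nrow = n_asv, dimnames = list(sprintf("A%02d", seq_len(n_asv)), reps))
  asv_tbl(m, rand_dna(n_asv, seq_len_bp), lane = lane)
}

# hit-table row builder
hit_rows <- function(asv_id, lineage, identity, coverage,
                     bitscore = NULL, subject = NULL, annotation = NULL) {
  n <- max(length(lineage), length(identity), length(coverage))
  out <- tibble(asv_id = asv_id,
                subject_id = subject %||% sprintf("ref%03d", seq_len(n)),
                lineage = rep_len(lineage, n),
                percent_identity = rep_len(identity, n),
                query_coverage = rep_len(coverage, n),
                bitscore = bitscore %||% (rep_len(identity, n) * 2))
  if (!is.null(annotation)) out$annotation <- rep_len(annotation, n)
  out
}
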