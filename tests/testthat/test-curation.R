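test_that("orientation merging reverse-complements and conserves reads", {
  info <- tiny_info(n_samples = 1, R = 2, n_neg = 0)
  reps <- info$replicate_id
  fwd <- asv_tbl(matrix(c(5, 0), 1, dimnames = list("F1", reps)),
                 "AAGT", orientation = "forward")
  rev <- asv_tbl(matrix(c(3, 0), 1, dimnames = list("R1", reps)),
                 "ACTT", orientation = "reverse")  # revcomp(ACTT) = AAGT
  merged <- merge_orientations(fwd, rev)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$count, 8)
  expect_equal(merged$sequence, "AAGT")

  # disjoint sequences: concatenation, totals conserved
  rev2 <- asv_tbl(matrix(c(2, 7), 1, dimnames = list("R2", reps)),
                  "GGGGC", orientation = "reverse")
  m2 <- merge_orientations(fwd, rev2)
  expect_equal(sort(unique(m2$sequence)), sort(c("AAGT", revcomp_chr("GGGGC"))))
  expect_equal(sum(m2$count), sum(fwd$count) + sum(rev2$count))
})

test_that("orientation merging equals a brute-force sequence-keyed sum", {
  set.seed(21)
  info <- tiny_info(n_samples = 2, R = 4, n_neg = 0)
  reps <- info$replicate_id
  seqs <- rand_dna(6, 40)
  fwd <- asv_tbl(matrix(rpois(6 * 8, 4), 6, dimnames = list(sprintf("F%d", 1:6), reps)),
                 seqs, orientation = "forward")
  # reverse table shares 3 molecules (revcomped) and has 3 novel ones
  rev_seqs <- c(revcomp_chr(seqs[1:3]), rand_dna(3, 40))
  rev <- asv_tbl(matrix(rpois(6 * 8, 4), 6, dimnames = list(sprintf("R%d", 1:6), reps)),
                 rev_seqs, orientation = "reverse")
  merged <- merge_orientations(fwd, rev)

  # oracle: hash-map keyed on (forward-orientation sequence, replicate)
  oracle <- new.env()
  add <- function(seq, rep, n) {
    key <- paste(seq, rep)
    assign(key, (if (exists(key, oracle)) get(key, oracle) else 0) + n, oracle)
  }
  purrr::pwalk(fwd[, c("sequence", "replicate_id", "count")],
               function(sequence, replicate_id, count) add(sequence, replicate_id, count))
  purrr::pwalk(rev[, c("sequence", "replicate_id", "count")],
               function(sequence, replicate_id, count)
                 add(revcomp_chr(sequence), replicate_id, count))
  got <- merged |> mutate(key = paste(sequence, replicate_id))
  for (k in ls(oracle)) {
    expect_equal(got$count[got$key == k], get(k, oracle), label = k)
  }
  expect_equal(nrow(got), length(ls(oracle)))

  # conflicting lane metadata is an error
  rev_conflict <- rev |> mutate(lane = "L9")
  expect_error(merge_orientations(fwd, rev_conflict), "lane")
})

test_that("error-daughter curation merges qualifying daughters only", {
  info <- tiny_info(n_samples = 1, R = 4, n_neg = 0)
  reps <- info$replicate_id
  parent_seq <- paste(rep("ACGT", 30), collapse = "")  # 120 bp
  daughter_seq <- sub("^ACGT", "ACTT", parent_seq)     # 1 mismatch -> 99.2%
  m <- matrix(c(100, 80, 120, 90,
                10, 8, 12, 9), nrow = 2, byrow = TRUE,
              dimnames = list(c("P", "D"), reps))
  tbl <- asv_tbl(m, c(parent_seq, daughter_seq))
  out <- lulu_curation(tbl)
  expect_equal(sort(unique(out$asv_id)), "P")
  expect_equal(sum(out$count), sum(tbl$count))
  expect_equal(out$count[order(out$replicate_id)], c(110, 88, 132, 99))

  # unrelated sequences at low identity: unchanged
  set.seed(3)
  tbl2 <- asv_tbl(matrix(c(50, 40, 30, 20, 5, 4, 3, 2), 2, byrow = TRUE,
                         dimnames = list(c("X", "Y"), reps)),
                  rand_dna(2, 120))
  expect_equal(lulu_curation(tbl2) |> arrange(asv_id, replicate_id),
               tbl2 |> arrange(asv_id, replicate_id))
})

test_that("error-daughter curation matches an exhaustive pairwise oracle", {
  # 20-ASV table with planted 1-mismatch daughters; equal-length sequences so
  # identity for the oracle is a plain Hamming computation
  set.seed(31)
  info <- tiny_info(n_samples = 3, R = 4, n_neg = 0)
  reps <- info$replicate_id
  n_parent <- 12
  parents <- rand_dna(n_parent, 120)
  ids <- sprintf("P%02d", seq_len(n_parent))
  counts <- matrix(rpois(n_parent * length(reps), 60), n_parent,
                   dimnames = list(ids, reps))
  # plant 8 daughters: subset of parent's replicates, ~5% abundance
  d_seq <- character(0); d_cnt <- NULL; d_ids <- character(0)
  for (j in 1:8) {
    p <- j
    s <- parents[p]
    pos <- sample(nchar(s), 1)
    substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(s, pos, pos))[1]
    cnt <- rbinom(length(reps), counts[p, ], 0.05)
    d_seq <- c(d_seq, s); d_cnt <- rbind(d_cnt, cnt)
    d_ids <- c(d_ids, sprintf("D%02d", j))
  }
  all_cnt <- rbind(counts, d_cnt)
  rownames(all_cnt) <- c(ids, d_ids)
  tbl <- asv_tbl(all_cnt, c(parents, d_seq))
  out <- lulu_curation(tbl)

  # oracle: evaluate every ordered pair on the input table
  mat <- all_cnt[rownames(all_cnt) %in% unique(tbl$asv_id), , drop = FALSE]
  totals <- rowSums(mat)
  seqs <- setNames(c(parents, d_seq), c(ids, d_ids))
  ham_identity <- function(a, b) {
    if (nchar(a) != nchar(b)) return(0)
    va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
    100 * mean(va == vb)
  }
  parent_of <- character(0)
  for (d in names(sort(totals))) {
    best <- NULL; best_ident <- -Inf
    d_pos <- mat[d, ] > 0
    if (!any(d_pos)) next
    for (p in names(totals)[totals > totals[[d]]]) {
      co <- sum(mat[p, d_pos] > 0) / sum(d_pos)
      if (co < 0.95) next
      both <- d_pos & mat[p, ] > 0
      if (!any(both) || min(mat[p, both] / mat[d, both]) < 1) next
      ident <- ham_identity(seqs[[p]], seqs[[d]])
      if (ident >= 99 && ident > best_ident) { best <- p; best_ident <- ident }
    }
    if (!is.null(best)) parent_of[[d]] <- best
  }
  resolve <- function(x) { while (x %in% names(parent_of)) x <- parent_of[[x]]; x }
  survivors <- sort(unique(vapply(names(totals), resolve, character(1))))
  expect_equal(sort(unique(out$asv_id)), survivors)
  expect_equal(sum(out$count), sum(tbl$count))
})

test_that("replicate-support filtering applies singleton and support rules in order", {
  info <- tiny_info(n_samples = 1, R = 4, n_neg = 0)
  reps <- info$replicate_id
  m <- matrix(c(1, 0, 0, 0,    # singleton + single replicate -> removed
                5, 3, 0, 0,    # retained unchanged
                7, 1, 0, 0),   # singleton zeroed, then 1 supporting rep -> removed
              nrow = 3, byrow = TRUE, dimnames = list(c("A", "B", "C"), reps))
  tbl <- asv_tbl(m, rand_dna(3, 90))
  out <- filter_replicate_support(tbl)
  expect_equal(sort(unique(out$asv_id)), "B")
  expect_equal(sum(out$count), 8)
})

test_that("negative-control thresholding zeroes at-or-below-mean observations", {
  info <- tiny_info(n_samples = 2, R = 2, n_neg = 2)
  sed <- info$replicate_id[info$role == "sediment"]
  neg <- info$replicate_id[info$role != "sediment"]
  m <- matrix(c(3, 8, 4, 9, 10, 0,   # ASV in negatives: tau = (10+0)/2 = 5
                6, 2, 7, 5, 0, 0),   # ASV absent from negatives: tau = 0
              nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c(sed, neg)))
  tbl <- asv_tbl(m, rand_dna(2, 90), keep_zeros = TRUE)
  res <- negative_control_filter(tbl, info)
  expect_equal(res$thresholds |> arrange(asv_id) |> pull(tau), c(5, 0))
  got <- res$table |> filter(replicate_id %in% sed) |>
    arrange(asv_id, replicate_id) |> pull(count)
  # A: 3 -> 0, 8 -> 8, 4 -> 0, 9 -> 9; B: tau = 0 so only exact zeros stay zero
  expect_equal(got, c(0, 8, 0, 9, 6, 2, 7, 5))
  # negative-control observations untouched
  expect_equal(res$table |> filter(replicate_id %in% neg) |> pull(count) |> sum(), 10)

  # literal reading zeroes the strong signal instead
  lit <- negative_control_filter(tbl, info, literal = TRUE)
  got_lit <- lit$table |> filter(replicate_id %in% sed, asv_id == "A") |>
    arrange(replicate_id) |> pull(count)
  expect_equal(got_lit, c(3, 0, 4, 0))

  # lane without negatives: instructive error
  info0 <- tiny_info(n_samples = 1, R = 2, n_neg = 0)
  tbl0 <- random_asv_table(info0, n_asv = 2, seed = 1)
  expect_error(negative_control_filter(tbl0, info0), "omit this stage")
})

test_that("simulated contamination is removed against generator truth", {
  cfg <- sim_config(seed = 17, n_samples = c(PC19 = 14L, GC01 = 6L),
                    n_noise_taxa = 10L, reads_per_replicate = 5000,
                    error_daughter_rate = 0, tag_jump_rate = 0)
  sim <- simulate_experiment(cfg)
  contam_ids <- sim$truth$asv_origin$asv_id[sim$truth$asv_origin$origin == "contaminant"]
  sed_reps <- sim$info$replicate_id[sim$info$role == "sediment"]
  before <- bind_rows(sim$tables) |>
    filter(asv_id %in% contam_ids, replicate_id %in% sed_reps) |>
    pull(count) |> sum()
  res <- curate(sim$tables, sim$info)
  after <- res$table |>
    filter(asv_id %in% contam_ids, replicate_id %in% sed_reps) |>
    pull(count) |> sum()
  expect_gt(before, 0)
  expect_gte(1 - after / before, 0.9)
})

test_that("length filtering uses inclusive 70 and 170 bp bounds", {
  info <- tiny_info(n_samples = 1, R = 2, n_neg = 0)
  reps <- info$replicate_id
  lens <- c(69, 70, 100, 170, 171)
  m <- matrix(5, length(lens), 2, dimnames = list(sprintf("A%d", lens), reps))
  tbl <- asv_tbl(m, vapply(lens, function(l) rand_dna(1, l), character(1)))
  out <- length_filter(tbl)
  expect_equal(sort(unique(out$asv_id)), c("A100", "A170", "A70"))
  expect_error(length_filter(tbl, min_len = 100, max_len = 90), "min_len")

  # survivor set equals the predicate oracle for a random mix
  set.seed(5)
  lens2 <- sample(50:200, 30, replace = TRUE)
  tbl2 <- asv_tbl(matrix(3, 30, 2, dimnames = list(sprintf("B%02d", 1:30), reps)),
                  vapply(lens2, function(l) rand_dna(1, l), character(1)))
  expect_equal(sort(unique(length_filter(tbl2)$asv_id)),
               sort(sprintf("B%02d", which(lens2 >= 70 & lens2 <= 170))))
})

test_that("lane combination sums identical sequences and inverts a lane split", {
  info3 <- tiny_info(n_samples = 1, R = 3, n_neg = 0)
  reps <- info3$replicate_id
  seqs <- rand_dna(1, 80)
  lanes <- purrr::map(c(5, 3, 2), function(k)
    asv_tbl(matrix(c(k, 0, 0), 1, dimnames = list("A01", reps)), seqs,
            lane = paste0("L", k)))
  comb <- combine_lanes(lanes)
  expect_equal(comb$count[comb$replicate_id == reps[1]], 10)

  # single-lane input is the identity
  one <- random_asv_table(info3, n_asv = 5, seed = 9)
  expect_equal(combine_lanes(list(one)) |> arrange(asv_id, replicate_id) |>
                 select(asv_id, sequence, replicate_id, count),
               one |> arrange(asv_id, replicate_id) |>
                 select(asv_id, sequence, replicate_id, count))

  # random split across lanes then combine recovers the original counts
  set.seed(13)
  orig <- random_asv_table(info3, n_asv = 8, seed = 13)
  split1 <- orig |> mutate(count = rbinom(n(), count, 0.5))
  split2 <- orig |> mutate(count = count - split1$count, lane = "L2")
  back <- combine_lanes(list(split1 |> filter(count > 0),
                             split2 |> filter(count > 0)))
  expect_equal(back |> arrange(asv_id, replicate_id) |>
                 select(asv_id, sequence, replicate_id, count),
               orig |> filter(count > 0) |> arrange(asv_id, replicate_id) |>
                 select(asv_id, sequence, replicate_id, count))
})

test_that("curation stages never increase reads and filters are idempotent", {
  cfg <- sim_config(seed = 5, n_samples = c(PC19 = 8L, GC01 = 4L),
                    n_noise_taxa = 10L, reads_per_replicate = 3000)
  sim <- simulate_experiment(cfg)
  res <- curate(sim$tables, sim$info)
  expect_true(all(res$report$reads_out <= res$report$reads_in))
  expect_true(all(res$report$asvs_out <= res$report$asvs_in))
  merge_stages <- res$report |>
    filter(stage %in% c("merge_orientations", "lulu_curation", "combine_lanes"))
  expect_equal(merge_stages$reads_out, merge_stages$reads_in)

  tbl <- sim$tables[[1]]
  norm <- function(x) x |> filter(count > 0) |> arrange(asv_id, replicate_id)
  f1 <- filter_replicate_support(tbl)
  expect_equal(norm(filter_replicate_support(f1)), norm(f1))
  n1 <- negative_control_filter(tbl, sim$info)$table
  expect_equal(norm(negative_control_filter(n1, sim$info)$table), norm(n1))
  l1 <- length_filter(tbl)
  expect_equal(norm(length_filter(l1)), norm(l1))
})

test_that("the pipeline's stage order is pinned (support before negatives)", {
  # adversarial fixture: sediment counts [5, 2], negatives [3, 1]. In the
  # pipeline order the singleton rule zeroes the stray negative read first,
  # lowering tau to 1.5 so both sediment observations survive (sum 7); with
  # the negative filter applied first, tau = 2 and the weaker sediment
  # observation is lost (sum 5).
  info <- tiny_info(n_samples = 1, R = 2, n_neg = 2)
  sed <- info$replicate_id[info$role == "sediment"]
  neg <- info$replicate_id[info$role != "sediment"]
  m <- matrix(c(5, 2, 3, 1), 1, dimnames = list("A", c(sed, neg)))
  tbl <- asv_tbl(m, rand_dna(1, 100), keep_zeros = TRUE)

  pipeline <- curate(list(tbl), info)
  expect_equal(pipeline$table |> filter(replicate_id %in% sed) |> pull(count) |> sum(), 7)

  scrambled <- filter_replicate_support(
    negative_control_filter(tbl, info)$table)
  expect_equal(scrambled |> filter(replicate_id %in% sed) |> pull(count) |> sum(), 5)
})

test_that("true ASVs are retained with high precision on simulated data", {
  cfg <- sim_config(seed = 23, n_samples = c(PC19 = 12L, GC01 = 6L),
                    n_noise_taxa = 15L, reads_per_replicate = 5000)
  sim <- simulate_experiment(cfg)
  res <- curate(sim$tables, sim$info)
  origin <- sim$truth$asv_origin
  sed_reps <- sim$info$replicate_id[sim$info$role == "sediment"]
  kept <- unique(res$table$asv_id[res$table$count > 0 &
                                    res$table$replicate_id %in% sed_reps])
  precision <- mean(origin$origin[origin$asv_id %in% kept] == "real")
  expect_gte(precision, 0.95)
})
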