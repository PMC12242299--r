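#' Default focal taxa for the sediment-core simulator
#'
#' Three focal taxa emulating the structure of a north-Atlantic shelf 18S
#' V9 dataset: a demersal gadid with climate-independent detection, a
#' pelagic clupeid whose detection probability increases with sea surface
#' temperature, and a dominant bloom-forming diatom present in nearly
#' every replicate.
#'
#' @return Tibble (`taxon`, `lineage`, `n_asvs`, `baseline`, `beta0`,
#'   `beta1`): `baseline` is log relative read abundance, `beta0` the
#'   detection logit intercept and `beta1` the detection logit slope on
#'   the standardised SST-like covariate.
#' @export
default_taxa_spec <- function() {
  tibble(
    taxon = c("Gadus morhua", "Clupea harengus", "Chaetoceros socialis"),
    lineage = c(
      "Eukaryota;Chordata;Actinopteri;Gadiformes;Gadidae;Gadus;Gadus morhua",
      "Eukaryota;Chordata;Actinopteri;Clupeiformes;Clupeidae;Clupea;Clupea harengus",
      "Eukaryota;Bacillariophyta;Bacillariophyceae;Chaetocerotales;Chaetocerotaceae;Chaetoceros;Chaetoceros socialis"),
    n_asvs = c(2L, 6L, 1L),
    baseline = c(2, 1.5, 6),
    beta0 = c(0.5, 0, 4),
    beta1 = c(0, 1.5, 0.3))
}

#' Simulation configuration for a synthetic sediment-core experiment
#'
#' The defaults emulate the design of a two-core replicated sedaDNA
#' metabarcoding study: 158 + 46 sediment samples, eight independently
#' processed PCR replicates per sample, a mean of 170 000 reads per
#' replicate, three sequencing lanes, and extraction/PCR/library negative
#' controls carrying near-zero reads relative to sediment replicates.
#'
#' @param seed Integer seed; every downstream draw is reproducible.
#' @param n_samples Named integer vector of sediment samples per core.
#' @param core_spans_cm Named list of `c(top, bottom)` sampled depth spans.
#' @param n_replicates PCR replicates per sample (default 8).
#' @param reads_per_replicate Mean reads per replicate (default 170000).
#' @param reads_dispersion Negative-binomial size parameter for replicate
#'   totals (default 4, giving a coefficient of variation near 0.5).
#' @param taxa Focal taxa tibble (see [default_taxa_spec()]).
#' @param n_noise_taxa Climate-independent background taxa (default 30).
#' @param core_offsets Named per-core detection logit offsets.
#' @param error_daughter_rate Probability that a real ASV spawns a
#'   1-mismatch error daughter (default 0.3).
#' @param daughter_fraction Per-read probability that a parent read is
#'   miscalled into its daughter (default 0.05; daughters are always rarer
#'   than parents and co-occur with them).
#' @param contamination_rate Mean contaminant reads per negative control
#'   (lambda_c, default 150, the order of magnitude seen in sequenced
#'   blanks).
#' @param sediment_contamination_rate Mean contaminant reads per sediment
#'   replicate (default `contamination_rate / 10`: template competition
#'   suppresses contaminant amplification in template-rich reactions).
#' @param leakage_rate Mean reads of each of the most abundant real ASVs
#'   leaking into every negative control (default 2).
#' @param tag_jump_rate Per-read probability of acquiring another
#'   replicate's tags within a lane (rho, default 0.001).
#' @param n_lanes Sequencing lanes (default 3).
#' @param negatives_per_lane Negative controls per lane (default 6).
#' @param dm_concentration Dirichlet-multinomial concentration for read
#'   allocation across ASVs within a replicate (default 50; smaller is
#'   more overdispersed).
#' @param horizons Named list of per-core dated-horizon tibbles
#'   (`depth_cm`, `age_mean`, `age_sd`, `source`).
#' @param amplicon_length_range Inclusive ASV length range in bp.
#' @param split_orientations Emit separate forward/reverse orientation
#'   tables per lane (default `FALSE`).
#' @param detection_only Skip read-level simulation and return only
#'   occupancy-level truth (fast path for detection-statistics studies).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_samples = c(PC19 = 158L, GC01 = 46L),
                       core_spans_cm = list(PC19 = c(23, 275), GC01 = c(2, 180)),
                       n_replicates = 8L,
                       reads_per_replicate = 170000,
                       reads_dispersion = 4,
                       taxa = default_taxa_spec(),
                       n_noise_taxa = 30L,
                       core_offsets = c(PC19 = 0, GC01 = 0.25),
                       error_daughter_rate = 0.3,
                       daughter_fraction = 0.05,
                       contamination_rate = 150,
                       sediment_contamination_rate = contamination_rate / 10,
                       leakage_rate = 2,
                       tag_jump_rate = 0.001,
                       n_lanes = 3L,
                       negatives_per_lane = 6L,
                       dm_concentration = 50,
                       horizons = NULL,
                       amplicon_length_range = c(100, 150),
                       split_orientations = FALSE,
                       detection_only = FALSE) {
  if (is.null(horizons)) {
    horizons <- list(
      PC19 = tibble(depth_cm = c(20, 60, 110, 160, 210, 275),
                    age_mean = c(1700, 1310, 890, 300, -420, -1314),
                    age_sd = c(30, 40, 15, 50, 60, 80),
                    source = c("radiocarbon", "radiocarbon", "tephra",
                               "radiocarbon", "radiocarbon", "radiocarbon")),
      GC01 = tibble(depth_cm = c(5, 60, 120, 180),
                    age_mean = c(1750, 1100, 150, -900),
                    age_sd = c(25, 40, 55, 70),
                    source = c("radiocarbon", "radiocarbon", "radiocarbon",
                               "radiocarbon")))
  }
  cfg <- list(seed = seed, n_samples = n_samples, core_spans_cm = core_spans_cm,
              n_replicates = as.integer(n_replicates),
              reads_per_replicate = reads_per_replicate,
              reads_dispersion = reads_dispersion, taxa = taxa,
              n_noise_taxa = as.integer(n_noise_taxa),
              core_offsets = core_offsets,
              error_daughter_rate = error_daughter_rate,
              daughter_fraction = daughter_fraction,
              contamination_rate = contamination_rate,
              sediment_contamination_rate = sediment_contamination_rate,
              leakage_rate = leakage_rate, tag_jump_rate = tag_jump_rate,
              n_lanes = as.integer(n_lanes),
              negatives_per_lane = as.integer(negatives_per_lane),
              dm_concentration = dm_concentration, horizons = horizons,
              amplicon_length_range = amplicon_length_range,
              split_orientations = split_orientations,
              detection_only = detection_only)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#' @param config A `sim_config`.
#' @return `config`, invisibly.
#' @export
validate_sim_config <- function(config) {
  if (nrow(config$taxa) + config$n_noise_taxa == 0) {
    abort("simulation requires at least one taxon")
  }
  if (is.null(names(config$n_samples)) ||
      !setequal(names(config$n_samples), names(config$horizons))) {
    abort("n_samples and horizons must be named by the same cores")
  }
  rates <- c(config$error_daughter_rate, config$daughter_fraction,
             config$tag_jump_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (config$contamination_rate < 0 || config$leakage_rate < 0 ||
      config$sediment_contamination_rate < 0) {
    abort("contamination and leakage rates must be non-negative")
  }
  if (config$n_replicates < 1) abort("at least one PCR replicate is required")
  invisible(config)
}

.random_dna <- function(n, len_range) {
  vapply(seq_len(n), function(i) {
    len <- sample(seq(len_range[1], len_range[2]), 1)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# single substitution at a random position, guaranteed to change the base
.mutate_one <- function(seq) {
  pos <- sample(nchar(seq), 1)
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
  paste0(substr(seq, 1, pos - 1), new, substr(seq, pos + 1, nchar(seq)))
}

.contaminant_taxa <- function() {
  tibble(
    taxon = c("Homo sapiens", "Malassezia restricta", "Cutibacterium acnes"),
    lineage = c(
      "Eukaryota;Chordata;Mammalia;Primates;Hominidae;Homo;Homo sapiens",
      "Eukaryota;Basidiomycota;Malasseziomycetes;Malasseziales;Malasseziaceae;Malassezia;Malassezia restricta",
      "Bacteria;Actinomycetota;Actinomycetes;Propionibacteriales;Propionibacteriaceae;Cutibacterium;Cutibacterium acnes"))
}

.annotation_from_lineage <- function(lineage) {
  phylum <- parse_lineage(lineage)[, "phylum"]
  dplyr::case_when(
    phylum == "Bacillariophyta" ~ "diatom",
    phylum == "Chordata" ~ "metazoa",
    phylum == "Basidiomycota" ~ "fungus",
    is.na(phylum) ~ "unknown",
    .default = "other_protist")
}

#' Simulate a replicated sediment-core metabarcoding experiment
#'
#' Generates a complete synthetic experiment with known truth: an SST-like
#' covariate series (cooling trend + centennial sinusoid + noise), per-core
#' age-depth structure from dated horizons, per sample x taxon detection
#' probabilities through a logit link on the standardised covariate,
#' Bernoulli replicate occupancy, Dirichlet-multinomial read allocation
#' over taxon-derived ASVs, 1-mismatch error-daughter ASVs, contaminant
#' reads in negatives (Poisson) and at a reduced rate in sediment
#' replicates, leakage of abundant real ASVs into negatives, and
#' within-lane tag jumps. All outputs are reproducible under the config
#' seed.
#'
#' @param config A [sim_config()].
#' @return A list:
#' \describe{
#'   \item{tables}{named list of per-lane long ASV tables (or per-lane
#'     `list(forward, reverse)` when `split_orientations`); `NULL` in
#'     detection-only mode}
#'   \item{info}{replicate metadata incl. negative controls}
#'   \item{climate}{SST-like covariate series (`time`, `value`)}
#'   \item{horizons}{the per-core dated-horizon tibbles}
#'   \item{ages}{true sample ages (deterministic interpolation of horizon
#'     means)}
#'   \item{hits}{synthetic alignment hit table with `annotation` column}
#'   \item{truth}{list: `detection` (per sample x taxon probability,
#'     occupancy and covariate), `asv_origin` (origin of every ASV:
#'     real / error_daughter / contaminant), `betas`, `replicate_totals`}
#'   \item{config}{the input configuration}
#' }
#' @export
simulate_experiment <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  cores <- names(config$n_samples)
  R <- config$n_replicates

  # --- samples, depths, true ages -----------------------------------------
  samples <- purrr::map_dfr(cores, function(core) {
    n <- config$n_samples[[core]]
    span <- config$core_spans_cm[[core]]
    hz <- config$horizons[[core]] |> arrange(.data$depth_cm)
    depth <- seq(span[1], span[2], length.out = n)
    tibble(core_id = core,
           sample_id = sprintf("%s_S%03d", core, seq_len(n)),
           depth_cm = depth,
           age = .interp_extrap(hz$depth_cm, hz$age_mean, depth))
  })

  # --- covariate series ----------------------------------------------------
  yrs <- seq(floor(min(samples$age)) - 25, ceiling(max(samples$age)) + 25)
  trend <- 8 - 1.5 * (yrs - min(yrs)) / diff(range(yrs))
  climate <- tibble(time = yrs,
                    value = trend + 0.5 * sin(2 * pi * yrs / 800) +
                      stats::rnorm(length(yrs), sd = 0.3),
                    proxy_name = "sst_mean")
  samples$sst <- stats::approx(climate$time, climate$value, xout = samples$age,
                               ties = "ordered")$y
  sst_z <- as.numeric(scale(samples$sst))

  # --- taxa ---------------------------------------------------------------
  focal <- config$taxa |> mutate(origin = "real")
  noise <- if (config$n_noise_taxa > 0) {
    k <- config$n_noise_taxa
    tibble(taxon = sprintf("Noise_taxon_%02d", seq_len(k)),
           lineage = sprintf(
             "Eukaryota;Phylum_%02d;Class_%02d;Order_%02d;Family_%02d;Genus_%02d;Species_%02d",
             (seq_len(k) - 1) %/% 5 + 1, (seq_len(k) - 1) %/% 5 + 1,
             (seq_len(k) - 1) %/% 2 + 1, (seq_len(k) - 1) %/% 2 + 1,
             seq_len(k), seq_len(k)),
           n_asvs = 1L,
           baseline = stats::rnorm(k, 0, 1),
           beta0 = stats::rnorm(k, 0.5, 1),
           beta1 = 0,
           origin = "real")
  } else NULL
  taxa <- bind_rows(focal, noise)

  # --- detection truth -----------------------------------------------------
  detection <- tidyr::expand_grid(samples, taxa |> select("taxon", "beta0", "beta1")) |>
    mutate(sst_z = sst_z[match(.data$sample_id, samples$sample_id)],
           p = stats::plogis(.data$beta0 +
                               config$core_offsets[.data$core_id] +
                               .data$beta1 * .data$sst_z))
  occ <- matrix(stats::rbinom(nrow(detection) * R, 1,
                              rep(detection$p, each = R)),
                ncol = R, byrow = TRUE)
  detection$n_occupied <- rowSums(occ)
  detection <- detection |>
    mutate(n_replicates = R, occupancy_proportion = .data$n_occupied / R)

  # --- replicate metadata --------------------------------------------------
  lanes <- sprintf("L%d", seq_len(config$n_lanes))
  info_sed <- tidyr::expand_grid(samples |> select("sample_id", "core_id", "depth_cm"),
                                 replicate_index = seq_len(R)) |>
    mutate(replicate_id = paste0(.data$sample_id, ".", .data$replicate_index),
           role = "sediment",
           lane = lanes[(.data$replicate_index - 1) %% config$n_lanes + 1]) |>
    select("replicate_id", "sample_id", "core_id", "depth_cm",
           "replicate_index", "role", "lane")
  neg_roles <- rep(c("extraction_negative", "pcr_negative", "pcr_negative",
                     "extraction_negative", "pcr_negative", "library_negative"),
                   length.out = config$negatives_per_lane)
  info_neg <- tidyr::expand_grid(lane = lanes,
                                 j = seq_len(config$negatives_per_lane)) |>
    mutate(sample_id = sprintf("NEG_%s_%02d", .data$lane, .data$j),
           replicate_id = paste0(.data$sample_id, ".1"),
           core_id = "control", depth_cm = NA_real_, replicate_index = 1L,
           role = neg_roles[.data$j]) |>
    select("replicate_id", "sample_id", "core_id", "depth_cm",
           "replicate_index", "role", "lane")
  info <- bind_rows(info_sed, info_neg)
  validate_replicate_info(info)

  betas <- taxa |> select("taxon", "beta0", "beta1")
  truth <- list(detection = detection |>
                  select("sample_id", "core_id", "depth_cm", "age", "sst",
                         "sst_z", "taxon", "p", "n_occupied", "n_replicates",
                         "occupancy_proportion"),
                betas = betas)
  base <- list(info = info, climate = climate, horizons = config$horizons,
               ages = samples |> select("sample_id", "core_id", "depth_cm", "age"),
               config = config)

  if (config$detection_only) {
    return(c(base, list(tables = NULL, hits = NULL, truth = truth)))
  }

  # --- ASVs ---------------------------------------------------------------
  contam <- .contaminant_taxa() |>
    mutate(n_asvs = 1L, baseline = 0, beta0 = -Inf, beta1 = 0,
           origin = "contaminant")
  asvs <- bind_rows(taxa, contam) |>
    mutate(share = purrr::map(.data$n_asvs, function(k) {
      g <- stats::rgamma(k, shape = 1.5)
      g / sum(g)
    })) |>
    tidyr::unnest("share") |>
    mutate(asv_id = sprintf("ASV_%04d", dplyr::row_number()),
           sequence = .random_dna(n(), config$amplicon_length_range),
           origin = .data$origin)
  real_asvs <- asvs |> filter(.data$origin == "real")
  contam_asvs <- asvs |> filter(.data$origin == "contaminant")

  # --- read allocation per sediment replicate -----------------------------
  occ_long <- tibble(sample_id = rep(detection$sample_id, each = R),
                     taxon = rep(detection$taxon, each = R),
                     replicate_index = rep(seq_len(R), nrow(detection)),
                     occupied = as.integer(t(occ)))
  rep_ids <- info_sed$replicate_id
  totals <- stats::rnbinom(length(rep_ids), mu = config$reads_per_replicate,
                           size = config$reads_dispersion)
  names(totals) <- rep_ids

  n_real <- nrow(real_asvs)
  alpha_base <- config$dm_concentration *
    exp(real_asvs$baseline) * real_asvs$share
  occ_key <- occ_long |>
    mutate(replicate_id = paste0(.data$sample_id, ".", .data$replicate_index))
  occ_by_rep <- split(setNames(occ_key$occupied, occ_key$taxon),
                      occ_key$replicate_id)

  count_mat <- matrix(0, nrow = nrow(asvs), ncol = length(rep_ids),
                      dimnames = list(asvs$asv_id, rep_ids))
  for (r in rep_ids) {
    occ_r <- occ_by_rep[[r]]
    open <- occ_r[real_asvs$taxon] > 0
    if (any(open) && totals[[r]] > 0) {
      g <- stats::rgamma(n_real, shape = alpha_base) * open
      if (sum(g) > 0) {
        count_mat[seq_len(n_real), r] <-
          stats::rmultinom(1, totals[[r]], g / sum(g))[, 1]
      }
    }
  }

  # --- contamination -------------------------------------------------------
  contam_w <- stats::rgamma(nrow(contam_asvs), shape = 2)
  contam_w <- contam_w / sum(contam_w)
  sed_rate <- config$sediment_contamination_rate * contam_w
  for (i in seq_len(nrow(contam_asvs))) {
    count_mat[contam_asvs$asv_id[i], ] <-
      count_mat[contam_asvs$asv_id[i], ] +
      stats::rpois(length(rep_ids), sed_rate[i])
  }
  neg_ids <- info_neg$replicate_id
  neg_mat <- matrix(0, nrow = nrow(asvs), ncol = length(neg_ids),
                    dimnames = list(asvs$asv_id, neg_ids))
  for (j in seq_along(neg_ids)) {
    tot <- stats::rpois(1, config$contamination_rate)
    if (tot > 0) {
      neg_mat[contam_asvs$asv_id, j] <- stats::rmultinom(1, tot, contam_w)[, 1]
    }
  }
  if (config$leakage_rate > 0 && n_real > 0) {
    top <- real_asvs$asv_id[order(-rowSums(count_mat[real_asvs$asv_id, ,
                                                     drop = FALSE]))][
      seq_len(min(3, n_real))]
    for (a in top) {
      neg_mat[a, ] <- neg_mat[a, ] + stats::rpois(length(neg_ids),
                                                  config$leakage_rate)
    }
  }
  count_mat <- cbind(count_mat, neg_mat)
  all_rep_ids <- colnames(count_mat)

  # --- error daughters -----------------------------------------------------
  daughter_rows <- list()
  parent_ids <- real_asvs$asv_id[
    stats::runif(n_real) < config$error_daughter_rate]
  for (pid in parent_ids) {
    d_counts <- stats::rbinom(ncol(count_mat), count_mat[pid, ],
                              config$daughter_fraction)
    if (sum(d_counts) == 0) next
    count_mat[pid, ] <- count_mat[pid, ] - d_counts
    did <- paste0(pid, "_d")
    daughter_rows[[did]] <- d_counts
    p_row <- asvs[asvs$asv_id == pid, ]
    asvs <- bind_rows(asvs, p_row |>
                        mutate(asv_id = did,
                               sequence = .mutate_one(p_row$sequence),
                               origin = "error_daughter"))
  }
  if (length(daughter_rows) > 0) {
    count_mat <- rbind(count_mat, do.call(rbind, daughter_rows))
    rownames(count_mat) <- asvs$asv_id
  }

  # --- tag jumps within lane ----------------------------------------------
  if (config$tag_jump_rate > 0) {
    lane_of <- setNames(info$lane, info$replicate_id)
    for (ln in lanes) {
      cols <- which(lane_of[all_rep_ids] == ln)
      if (length(cols) < 2) next
      sub <- count_mat[, cols, drop = FALSE]
      jumps <- matrix(stats::rbinom(length(sub), sub, config$tag_jump_rate),
                      nrow = nrow(sub))
      nz <- which(jumps > 0, arr.ind = TRUE)
      if (nrow(nz) > 0) {
        sub <- sub - jumps
        for (k in seq_len(nrow(nz))) {
          dest <- sample(setdiff(seq_along(cols), nz[k, 2]), 1)
          sub[nz[k, 1], dest] <- sub[nz[k, 1], dest] + jumps[nz[k, 1], nz[k, 2]]
        }
        count_mat[, cols] <- sub
      }
    }
  }

  # --- long tables per lane ------------------------------------------------
  long <- tibble(asv_id = rep(rownames(count_mat), times = ncol(count_mat)),
                 replicate_id = rep(colnames(count_mat), each = nrow(count_mat)),
                 count = as.numeric(count_mat)) |>
    filter(.data$count > 0) |>
    left_join(asvs |> select("asv_id", "sequence"), by = "asv_id") |>
    left_join(info |> select("replicate_id", "lane"), by = "replicate_id") |>
    mutate(orientation = "merged") |>
    select(all_of(.asv_cols))
  tables <- split(long, long$lane)
  if (config$split_orientations) {
    tables <- purrr::map(tables, function(tbl) {
      fwd_n <- stats::rbinom(nrow(tbl), tbl$count, 0.5)
      fwd <- tbl |> mutate(count = fwd_n, orientation = "forward") |>
        filter(.data$count > 0)
      rev <- tbl |>
        mutate(count = .data$count - fwd_n, orientation = "reverse",
               sequence = as.character(Biostrings::reverseComplement(
                 Biostrings::DNAStringSet(.data$sequence)))) |>
        filter(.data$count > 0)
      list(forward = fwd, reverse = rev)
    })
  }

  # --- synthetic hit table -------------------------------------------------
  hits <- purrr::map_dfr(seq_len(nrow(asvs)), function(i) {
    a <- asvs[i, ]
    lin <- parse_lineage(a$lineage)[1, ]
    drop_ident <- if (a$origin == "error_daughter")
      100 * 1 / nchar(a$sequence) else 0
    n1 <- sample(1:3, 1); n2 <- sample(1:3, 1); n3 <- sample(0:2, 1)
    species_hits <- tibble(
      asv_id = a$asv_id,
      subject_id = sprintf("%s_ref%d", gsub(" ", "_", a$taxon), seq_len(n1)),
      lineage = a$lineage,
      percent_identity = stats::runif(n1, 99.05, 100) - drop_ident,
      query_coverage = stats::runif(n1, 95.5, 100))
    congener <- paste(c(lin[1:6], paste(lin["genus"], "sp2")), collapse = ";")
    congener_hits <- tibble(
      asv_id = a$asv_id,
      subject_id = sprintf("%s_cong%d", gsub(" ", "_", a$taxon), seq_len(n2)),
      lineage = congener,
      percent_identity = stats::runif(n2, 95, 98.9),
      query_coverage = stats::runif(n2, 90, 100))
    fam <- paste(c(lin[1:5], paste0(lin["genus"], "ella"),
                   paste0(lin["genus"], "ella sp")), collapse = ";")
    family_hits <- if (n3 > 0) tibble(
      asv_id = a$asv_id,
      subject_id = sprintf("%s_fam%d", gsub(" ", "_", a$taxon), seq_len(n3)),
      lineage = fam,
      percent_identity = stats::runif(n3, 86, 94),
      query_coverage = stats::runif(n3, 85, 100)) else NULL
    bind_rows(species_hits, congener_hits, family_hits)
  }) |>
    mutate(percent_identity = pmin(.data$percent_identity, 100),
           bitscore = round(1.8 * .data$percent_identity +
                              0.2 * .data$query_coverage +
                              stats::runif(n(), 0, 2), 1),
           annotation = .annotation_from_lineage(.data$lineage)) |>
    arrange(.data$asv_id, dplyr::desc(.data$bitscore))

  truth$asv_origin <- asvs |>
    mutate(parent_id = ifelse(.data$origin == "error_daughter",
                              sub("_d$", "", .data$asv_id), NA_character_)) |>
    select("asv_id", "origin", "parent_id", "taxon", "lineage")
  truth$replicate_totals <- tibble(replicate_id = rep_ids,
                                   target_total = as.numeric(totals))

  c(base, list(tables = tables, hits = hits, truth = truth))
}

#' Expected read profile of simulated negative controls
#'
#' Draws negative-control read totals under the configured contamination
#' rate: plain `Poisson(lambda_c)` by default, or a heavy-tailed mixture
#' (most blanks near-empty, a small fraction carrying large read counts,
#' reproducing the mean >> median pattern seen in sequenced blanks).
#'
#' @param config A [sim_config()].
#' @param n_negatives Number of blank libraries to draw (default 300).
#' @param heavy_tail Use the mixture (default `FALSE`).
#' @param tail_fraction,tail_meanlog,tail_sdlog Mixture parameters: a
#'   `tail_fraction` of blanks draw lognormal totals.
#' @return List with `totals` (tibble `negative_id`, `reads`) and
#'   `summary` (mean, sd, median, IQR).
#' @export
simulate_negatives_profile <- function(config = sim_config(), n_negatives = 300,
                                       heavy_tail = FALSE, tail_fraction = 0.03,
                                       tail_meanlog = 7.5, tail_sdlog = 1.2) {
  set.seed(config$seed + 1L)
  lam <- config$contamination_rate
  reads <- if (heavy_tail) {
    tail <- stats::runif(n_negatives) < tail_fraction
    base <- stats::rpois(n_negatives, pmax(lam / 30, 1))
    big <- round(stats::rlnorm(n_negatives, tail_meanlog, tail_sdlog))
    ifelse(tail, big, base)
  } else {
    stats::rpois(n_negatives, lam)
  }
  totals <- tibble(negative_id = sprintf("NEG_%03d", seq_len(n_negatives)),
                   reads = reads)
  list(totals = totals,
       summary = tibble(mean = mean(reads), sd = stats::sd(reads),
                        median = stats::median(reads),
                        iqr = stats::IQR(reads)))
}
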