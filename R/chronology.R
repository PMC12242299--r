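#' Build a Monte-Carlo piecewise-linear age-depth model
#'
#' Each draw samples every dated horizon's calendar age from
#' `Normal(age_mean, age_sd)`, rejects draws in which age does not run
#' monotonically with depth (deeper horizons must stay older: for ages in
#' calendar years CE the year is non-increasing with depth; a series
#' supplied on an age-before-present scale, increasing with depth, is
#' honoured in that direction), and interpolates linearly between horizons
#' (linear extrapolation beyond the outermost horizons using the adjacent
#' segment's slope). Per-depth posterior means and central 95% intervals
#' are computed over the accepted draws. This is a deliberate
#' simplification of fully Bayesian accumulation-rate age models: no prior
#' is placed on sedimentation rate, so the model is suitable when only mean
#' ages per depth feed downstream analyses.
#'
#' @param points Tibble of dated horizons (`depth_cm`, `age_mean` in
#'   calendar years CE, `age_sd` in years, `source`); at least two rows.
#' @param n_draws Number of accepted Monte-Carlo draws (default 2000).
#' @param seed Integer seed; draws are reproducible under a fixed seed.
#' @param max_attempts_factor Rejection sampling is capped at
#'   `max_attempts_factor * n_draws` attempted draws (default 100).
#' @return An object of class `age_model`: list with `points` (sorted
#'   horizons), `draws` (accepted n_draws x n_points age matrix),
#'   `n_draws`, `seed`, `acceptance_rate`.
#' @export
build_age_model <- function(points, n_draws = 2000, seed = 1,
                            max_attempts_factor = 100) {
  if (nrow(points) < 2) abort("at least two dated horizons are required")
  if (any(!is.finite(points$age_sd)) || any(points$age_sd < 0)) {
    abort("age_sd must be finite and non-negative")
  }
  if (any(duplicated(points$depth_cm))) abort("horizon depths must be unique")
  points <- points |> arrange(.data$depth_cm)
  k <- nrow(points)
  # direction of time with depth, taken from the dated means themselves:
  # -1 for calendar years CE (deeper = smaller year), +1 for age-BP scales
  direction <- sign(points$age_mean[k] - points$age_mean[1])
  if (direction == 0) direction <- 1
  set.seed(seed)
  accepted <- matrix(NA_real_, nrow = n_draws, ncol = k)
  n_acc <- 0L
  attempts <- 0L
  max_attempts <- max_attempts_factor * n_draws
  inversion_count <- integer(k - 1)
  while (n_acc < n_draws && attempts < max_attempts) {
    batch <- min(n_draws, max_attempts - attempts)
    draws <- matrix(stats::rnorm(batch * k, mean = rep(points$age_mean, each = batch),
                                 sd = rep(points$age_sd, each = batch)),
                    nrow = batch, ncol = k)
    mono <- rep(TRUE, batch)
    for (j in seq_len(k - 1)) {
      ok <- direction * (draws[, j + 1] - draws[, j]) >= 0
      inversion_count[j] <- inversion_count[j] + sum(!ok)
      mono <- mono & ok
    }
    keep <- which(mono)
    if (length(keep) > 0) {
      take <- utils::head(keep, n_draws - n_acc)
      accepted[n_acc + seq_along(take), ] <- draws[take, , drop = FALSE]
      n_acc <- n_acc + length(take)
    }
    attempts <- attempts + batch
  }
  if (n_acc < n_draws) {
    worst <- which.max(inversion_count)
    abort(paste0(
      "rejection sampling exhausted after ", attempts, " attempts; ",
      "horizons at ", points$depth_cm[worst], " and ",
      points$depth_cm[worst + 1],
      " cm most often produced age reversals"))
  }
  structure(list(points = points, draws = accepted, n_draws = n_draws,
                 seed = seed, acceptance_rate = n_draws / attempts),
            class = "age_model")
}

# piecewise-linear interpolation with linear extrapolation at both ends
.interp_extrap <- function(x, y, xout) {
  n <- length(x)
  out <- stats::approx(x, y, xout = xout, rule = 2, ties = "ordered")$y
  lo <- xout < x[1]
  hi <- xout > x[n]
  if (any(lo)) {
    slope <- (y[2] - y[1]) / (x[2] - x[1])
    out[lo] <- y[1] + slope * (xout[lo] - x[1])
  }
  if (any(hi)) {
    slope <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
    out[hi] <- y[n] + slope * (xout[hi] - x[n])
  }
  out
}

#' Predict calendar ages at depths from an age model
#'
#' @param object An `age_model`.
#' @param depth_cm Numeric vector of depths.
#' @param level Central interval level (default 0.95).
#' @param ... Unused.
#' @return Tibble (`depth_cm`, `age_mean`, `age_lo`, `age_hi`).
#' @export
predict.age_model <- function(object, depth_cm, level = 0.95, ...) {
  x <- object$points$depth_cm
  ages <- apply(object$draws, 1, function(y) .interp_extrap(x, y, depth_cm))
  ages <- matrix(ages, nrow = length(depth_cm))
  a <- (1 - level) / 2
  tibble(depth_cm = depth_cm,
         age_mean = rowMeans(ages),
         age_lo = apply(ages, 1, stats::quantile, probs = a),
         age_hi = apply(ages, 1, stats::quantile, probs = 1 - a))
}

#' Attach mean calendar ages to sediment samples
#'
#' Samples are located at the midpoint of their sampled depth span: when
#' `info` carries `depth_top_cm` and `depth_bottom_cm` columns the midpoint
#' is used, otherwise `depth_cm` is taken as already centred. Depths beyond
#' 10% of the model's depth span outside the dated horizons trigger an
#' extrapolation warning.
#'
#' @param model An `age_model`.
#' @param info Replicate metadata (or any tibble with `sample_id` and
#'   depth columns); only sediment rows carry depths.
#' @param extrapolation_guard Fraction of the model depth span beyond which
#'   extrapolation is flagged (default 0.1).
#' @return Tibble (`sample_id`, `depth_cm`, `age_mean`, `age_lo`,
#'   `age_hi`), one row per sample, ordered by depth.
#' @export
assign_sample_ages <- function(model, info, extrapolation_guard = 0.1) {
  stopifnot(inherits(model, "age_model"))
  samples <- info
  if (all(c("depth_top_cm", "depth_bottom_cm") %in% names(info))) {
    samples <- samples |>
      mutate(depth_cm = (.data$depth_top_cm + .data$depth_bottom_cm) / 2)
  }
  if ("role" %in% names(samples)) {
    samples <- samples |> filter(.data$role == "sediment")
  }
  samples <- samples |>
    distinct(.data$sample_id, .data$depth_cm) |>
    filter(!is.na(.data$depth_cm))
  if (any(duplicated(samples$sample_id))) {
    abort("a sample_id maps to more than one depth")
  }
  rng <- range(model$points$depth_cm)
  guard <- extrapolation_guard * diff(rng)
  n_out <- sum(samples$depth_cm < rng[1] - guard | samples$depth_cm > rng[2] + guard)
  if (n_out > 0) {
    warn(paste0(n_out, " sample(s) lie beyond ", 100 * extrapolation_guard,
                "% of the model depth span; extrapolated ages are unreliable"))
  }
  pred <- predict(model, samples$depth_cm)
  dplyr::bind_cols(samples["sample_id"], pred) |> arrange(.data$depth_cm)
}

#' @export
print.age_model <- function(x, ...) {
  cat("Monte-Carlo piecewise-linear age-depth model\n")
  cat("  horizons:", nrow(x$points), "(",
      paste(range(x$points$depth_cm), collapse = "-"), "cm )\n")
  cat("  accepted draws:", x$n_draws,
      sprintf("(acceptance rate %.2f)\n", x$acceptance_rate))
  invisible(x)
}

#' Tidy the dated horizons of an age model
#'
#' @param x An `age_model`.
#' @param ... Unused.
#' @return One row per dated horizon with posterior summaries of its
#'   sampled age across accepted draws.
#' @export
tidy.age_model <- function(x, ...) {
  x$points |>
    mutate(post_mean = colMeans(x$draws),
           post_lo = apply(x$draws, 2, stats::quantile, probs = 0.025),
           post_hi = apply(x$draws, 2, stats::quantile, probs = 0.975))
}

#' One-row summary of an age model
#'
#' @param x An `age_model`.
#' @param ... Unused.
#' @return Tibble with horizon count, depth span, draw count and
#'   rejection-sampling acceptance rate.
#' @export
glance.age_model <- function(x, ...) {
  tibble(n_horizons = nrow(x$points),
         depth_min = min(x$points$depth_cm),
         depth_max = max(x$points$depth_cm),
         n_draws = x$n_draws,
         acceptance_rate = x$acceptance_rate)
}

#' Plot an age-depth model
#'
#' @param object An `age_model`.
#' @param n_grid Number of depths at which the envelope is evaluated.
#' @param ... Unused.
#' @return A ggplot: posterior mean age against depth with the 95%
#'   envelope and the dated horizons.
#' @export
autoplot.age_model <- function(object, n_grid = 200, ...) {
  grid <- seq(min(object$points$depth_cm), max(object$points$depth_cm),
              length.out = n_grid)
  pred <- predict(object, grid)
  ggplot2::ggplot(pred, ggplot2::aes(x = .data$depth_cm)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$age_lo, ymax = .data$age_hi),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$age_mean)) +
    ggplot2::geom_pointrange(
      data = tidy(object),
      ggplot2::aes(y = .data$age_mean,
                   ymin = .data$age_mean - 2 * .data$age_sd,
                   ymax = .data$age_mean + 2 * .data$age_sd,
                   shape = .data$source)) +
    ggplot2::labs(x = "Depth (cm)", y = "Calendar age (year CE)",
                  shape = "Horizon")
}
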