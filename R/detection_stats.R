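#' Mean relative proportion per ASV across a sample's PCR replicates
#'
#' Within each replicate, counts are normalised to sum to one; the
#' per-ASV proportions are then averaged over the sample's replicates
#' (replicates with zero total reads are excluded from the average), so the
#' result sums to one over ASVs within each sample.
#'
#' @param table Long-format ASV table.
#' @param info Replicate metadata linking replicates to samples.
#' @param sample_id Optional single sample; default computes every sediment
#'   sample with at least one non-empty replicate.
#' @return Tibble (`sample_id`, `asv_id`, `proportion`).
#' @export
mean_relative_proportion <- function(table, info, sample_id = NULL) {
  validate_asv_table(table, info)
  joined <- table |>
    inner_join(info |> select("replicate_id", "sample_id"), by = "replicate_id")
  if (!is.null(sample_id)) {
    joined <- joined |> filter(.data$sample_id %in% !!sample_id)
    if (nrow(joined) == 0 || sum(joined$count) == 0) {
      abort(paste0("all replicates of sample ", sample_id, " have zero reads"))
    }
  }
  joined |>
    group_by(.data$sample_id, .data$replicate_id) |>
    mutate(rep_total = sum(.data$count)) |>
    ungroup() |>
    filter(.data$rep_total > 0) |>
    mutate(rel = .data$count / .data$rep_total) |>
    group_by(.data$sample_id, .data$replicate_id) |>
    ungroup() |>
    group_by(.data$sample_id) |>
    mutate(n_rep = dplyr::n_distinct(.data$replicate_id)) |>
    group_by(.data$sample_id, .data$asv_id) |>
    summarise(proportion = sum(.data$rel) / .data$n_rep[1], .groups = "drop")
}

#' Pool rare ASVs into an "other" category
#'
#' ASVs whose mean relative proportion falls below `threshold` within a
#' sample are pooled into a single `"other"` row; totals are conserved.
#' This is a display convention for composition overviews and does not
#' feed back into filtering.
#'
#' @param proportions Output of [mean_relative_proportion()] (a
#'   `sample_id` column is optional).
#' @param threshold Pooling threshold on the proportion scale (default
#'   0.01, i.e. 1% of reads).
#' @return Tibble of the same shape with rare ASVs replaced by `"other"`.
#' @export
other_category <- function(proportions, threshold = 0.01) {
  grp <- intersect("sample_id", names(proportions))
  proportions |>
    mutate(asv_id = ifelse(.data$proportion < threshold, "other", .data$asv_id)) |>
    group_by(across(all_of(c(grp, "asv_id")))) |>
    summarise(proportion = sum(.data$proportion), .groups = "drop")
}

#' ASV richness from mean relative proportions
#'
#' @param proportions Output of [mean_relative_proportion()].
#' @return Tibble (`sample_id`, `richness`): the number of ASVs with a
#'   non-zero mean relative proportion per sample; or a single count when
#'   no `sample_id` column is present.
#' @export
asv_richness <- function(proportions) {
  if (!"sample_id" %in% names(proportions)) {
    return(sum(proportions$proportion > 0))
  }
  proportions |>
    group_by(.data$sample_id) |>
    summarise(richness = sum(.data$proportion > 0), .groups = "drop")
}

#' Detection proportion across PCR replicates
#'
#' A replicate is positive for a taxon when its merged (post-curation)
#' count exceeds zero; the detection proportion of a sample is the number
#' of positive replicates divided by the number of that sample's
#' replicates observed in the count table (replicates missing from the
#' table are excluded from numerator and denominator alike). No minimum
#' read count is imposed beyond curation.
#'
#' @param merged Genus-merged counts from [genus_merge()]
#'   (`replicate_id`, `taxon`, `count`).
#' @param info Replicate metadata.
#' @return Tibble (`sample_id`, `taxon`, `n_positive`, `n_replicates`,
#'   `proportion`), one row per sediment sample.
#' @export
detection_proportion <- function(merged, info) {
  validate_replicate_info(info)
  roster <- info |>
    filter(.data$role == "sediment") |>
    select("replicate_id", "sample_id") |>
    inner_join(merged, by = "replicate_id")
  if (nrow(roster) == 0) abort("replicate roster is empty")
  roster |>
    group_by(.data$sample_id, .data$taxon) |>
    summarise(n_positive = sum(.data$count > 0),
              n_replicates = n(),
              .groups = "drop") |>
    mutate(proportion = .data$n_positive / .data$n_replicates)
}

#' Attach calendar ages to a detection series
#'
#' @param series Output of [detection_proportion()].
#' @param ages Tibble (`sample_id`, `age_mean`) from
#'   [assign_sample_ages()].
#' @return `series` with an `age` column, samples without an age dropped.
#' @export
attach_ages <- function(series, ages) {
  series |>
    inner_join(ages |> select("sample_id", age = "age_mean"), by = "sample_id")
}

#' Regress detection proportion against an interpolated climate covariate
#'
#' The covariate is linearly interpolated to each sample's calendar age
#' (samples outside the covariate's span are dropped with a message) and
#' an ordinary least squares model is fitted. Without a grouping term the
#' model is `proportion ~ covariate`; with `group` (e.g. sediment core)
#' either separate intercepts (`proportion ~ covariate + group`) or full
#' interaction (`proportion ~ covariate * group`) can be requested, and
#' the interaction fit carries a slope-equality test (the F test of the
#' interaction terms).
#'
#' @param series Detection series with `age` and `proportion` columns (see
#'   [attach_ages()]).
#' @param covariate Climate series tibble (`time`, `value`).
#' @param group Optional name of a grouping column in `series`.
#' @param interaction With `group`, also fit group-specific slopes
#'   (default `TRUE`).
#' @return Object of class `detection_ols` wrapping the `lm` fit, with
#'   `r_squared`, `f_statistic` (`value`, `df1`, `df2`, `p_value`) against
#'   the intercept-only null, `slope_equality_p` (NA unless an interaction
#'   was fitted) and `n_dropped` (samples outside the covariate span).
#' @export
ols_detection_vs_covariate <- function(series, covariate, group = NULL,
                                       interaction = TRUE) {
  if (!all(c("age", "proportion") %in% names(series))) {
    abort("series must carry age and proportion columns")
  }
  covariate <- covariate |> arrange(.data$time)
  rng <- range(covariate$time)
  inside <- series$age >= rng[1] & series$age <= rng[2]
  if (any(!inside)) {
    inform(paste0(sum(!inside), " sample(s) outside the covariate span dropped"))
  }
  dat <- series[inside, , drop = FALSE] |>
    mutate(covariate_value = stats::approx(covariate$time, covariate$value,
                                           xout = .data$age,
                                           ties = "ordered")$y)
  if (nrow(dat) < 3) abort("too few samples within the covariate span")
  if (!is.null(group)) {
    dat$group <- factor(dat[[group]])
    form <- if (interaction) proportion ~ covariate_value * group
            else proportion ~ covariate_value + group
  } else {
    form <- proportion ~ covariate_value
  }
  fit <- stats::lm(form, data = dat)
  qrr <- qr(stats::model.matrix(fit))
  if (qrr$rank < ncol(stats::model.matrix(fit))) {
    bad <- colnames(stats::model.matrix(fit))[-seq_len(qrr$rank)]
    abort(paste0("rank-deficient design; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  fstat <- sm$fstatistic
  slope_p <- NA_real_
  if (!is.null(group) && interaction && nlevels(dat$group) > 1) {
    reduced <- stats::lm(proportion ~ covariate_value + group, data = dat)
    slope_p <- stats::anova(reduced, fit)[["Pr(>F)"]][2]
  }
  structure(list(
    fit = fit,
    data = dat,
    r_squared = unname(sm$r.squared),
    f_statistic = if (is.null(fstat)) {
      list(value = 0, df1 = NA, df2 = stats::df.residual(fit), p_value = NA)
    } else {
      list(value = unname(fstat["value"]), df1 = unname(fstat["numdf"]),
           df2 = unname(fstat["dendf"]),
           p_value = unname(stats::pf(fstat["value"], fstat["numdf"],
                                      fstat["dendf"], lower.tail = FALSE)))
    },
    slope_equality_p = slope_p,
    n_dropped = sum(!inside)
  ), class = "detection_ols")
}

#' @export
print.detection_ols <- function(x, ...) {
  cat("Detection-proportion OLS fit\n")
  print(stats::coef(x$fit))
  cat(sprintf("R-squared %.3f; F(%d, %d) = %.2f, p = %.3g\n",
              x$r_squared, x$f_statistic$df1, x$f_statistic$df2,
              x$f_statistic$value, x$f_statistic$p_value))
  if (!is.na(x$slope_equality_p)) {
    cat(sprintf("slope-equality test p = %.3g\n", x$slope_equality_p))
  }
  invisible(x)
}

#' Tidy a detection-proportion regression
#' @param x A `detection_ols` object.
#' @param ... Passed to the underlying `lm` tidier.
#' @return Coefficient-level tibble.
#' @export
tidy.detection_ols <- function(x, ...) broom::tidy(x$fit, ...)

#' One-row summary of a detection-proportion regression
#' @param x A `detection_ols` object.
#' @param ... Unused.
#' @return Tibble with R-squared, the overall F statistic and its degrees
#'   of freedom, the slope-equality p-value (when an interaction was
#'   fitted) and sample counts.
#' @export
glance.detection_ols <- function(x, ...) {
  tibble(r_squared = x$r_squared,
         f_value = x$f_statistic$value,
         df1 = x$f_statistic$df1,
         df2 = x$f_statistic$df2,
         p_value = x$f_statistic$p_value,
         slope_equality_p = x$slope_equality_p,
         n = nrow(x$data),
         n_dropped = x$n_dropped)
}

#' Plot a detection-proportion regression
#' @param object A `detection_ols` object.
#' @param ... Unused.
#' @return A ggplot of detection proportion against the covariate with the
#'   fitted line(s).
#' @export
autoplot.detection_ols <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$covariate_value,
                                         y = .data$proportion))
  if ("group" %in% names(dat)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::geom_line(ggplot2::aes(y = stats::fitted(object$fit),
                                      colour = .data$group))
  } else {
    p <- p + ggplot2::geom_point() +
      ggplot2::geom_line(ggplot2::aes(y = stats::fitted(object$fit)))
  }
  p + ggplot2::labs(x = "Covariate", y = "Detection proportion")
}

#' Low-pass smoothing of a climate proxy series
#'
#' First-order local regression (LOESS-style): at each time point a
#' weighted linear fit is taken over a fixed window of `window_years`,
#' with tricube weights on the time distance; windows are one-sided at the
#' series ends. A constant series is returned unchanged and a pure linear
#' trend is recovered exactly in the interior, while oscillations with
#' periods well below the window are strongly attenuated.
#'
#' @param series Climate series tibble (`time`, `value`).
#' @param window_years Full window width in years (default 100).
#' @return `series` with an added `smooth` column.
#' @export
lowpass_smooth <- function(series, window_years = 100) {
  if (nrow(series) < 5) abort("at least 5 points are required for smoothing")
  series <- series |> arrange(.data$time)
  span <- diff(range(series$time))
  if (window_years > span) {
    abort("smoothing window exceeds the series time span")
  }
  h <- window_years / 2
  t <- series$time
  v <- series$value
  smooth <- vapply(t, function(t0) {
    u <- abs(t - t0) / h
    w <- ifelse(u < 1, (1 - u^3)^3, 0)
    idx <- w > 0
    if (sum(idx) < 2) return(v[which.min(abs(t - t0))])
    x <- t[idx] - t0
    fit <- stats::lm.wfit(cbind(1, x), v[idx], w[idx])
    fit$coefficients[1]
  }, numeric(1))
  series |> mutate(smooth = smooth)
}

#' Plot a smoothed climate proxy series
#'
#' @param series Output of [lowpass_smooth()].
#' @return A ggplot with the raw series and its low-pass trend.
#' @export
plot_climate_series <- function(series) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(colour = "grey60")
  if ("smooth" %in% names(series)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$smooth), linewidth = 1)
  }
  p + ggplot2::labs(x = "Calendar year (CE)", y = "Proxy value")
}

#' Plot a detection-proportion time series
#'
#' @param series Detection series with `age` attached (see
#'   [attach_ages()]); an optional `core_id` column colours the points.
#' @return A ggplot of detection proportion over calendar age, one panel
#'   per taxon.
#' @export
plot_detection_series <- function(series) {
  aes <- if ("core_id" %in% names(series)) {
    ggplot2::aes(x = .data$age, y = .data$proportion, colour = .data$core_id)
  } else {
    ggplot2::aes(x = .data$age, y = .data$proportion)
  }
  ggplot2::ggplot(series, aes) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~taxon) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "Calendar year (CE)", y = "Proportion of positive PCR replicates")
}
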