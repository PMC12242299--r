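#' Temporal weight of an archaeofaunal assemblage
#'
#' Assemblages dated only to a broad span should not dominate century-scale
#' summaries, so each assemblage receives weight one divided by the number
#' of centuries it covers: an assemblage constrained to a single century
#' has weight 1, one spanning two centuries has weight 0.5, and so on. The
#' weights an assemblage contributes across its span sum to its full count
#' of one.
#'
#' @param assemblages Assemblage tibble (`site`, `first_century`,
#'   `last_century`, `marine_nisp`, `terrestrial_nisp`).
#' @return Numeric vector of per-assemblage weights.
#' @export
assemblage_weight <- function(assemblages) {
  if (any(assemblages$last_century < assemblages$first_century)) {
    abort("last_century must be >= first_century")
  }
  1 / (assemblages$last_century - assemblages$first_century + 1)
}

#' Weighted centennial marine-resource proportions
#'
#' For each century, a weighted average of per-assemblage marine
#' proportions (marine NISP over total NISP) is taken across every
#' assemblage whose dated span includes the century, with weights from
#' [assemblage_weight()]. Century n covers years (n-1)*100+1 to n*100 CE.
#' A century covered by no assemblage is returned with `NA` proportion and
#' zero weight.
#'
#' @param assemblages Assemblage tibble; an optional `region` column
#'   enables regional subsetting.
#' @param centuries Integer centuries to evaluate; defaults to the full
#'   range spanned by the assemblages.
#' @param region Optional region label to subset to (e.g. a sensitivity
#'   view restricted to sites near the sediment records).
#' @param pooled Pool weighted NISP sums across assemblages instead of
#'   weighting per-assemblage proportions (default `FALSE`: proportions
#'   are computed per assemblage before weighting).
#' @return Tibble (`century`, `proportion`, `total_weight`,
#'   `n_assemblages`).
#' @export
century_weighted_proportion <- function(assemblages, centuries = NULL,
                                        region = NULL, pooled = FALSE) {
  if (!is.null(region)) {
    if (!"region" %in% names(assemblages)) {
      abort("assemblage table has no region column")
    }
    assemblages <- assemblages |> filter(.data$region %in% !!region)
  }
  if (nrow(assemblages) == 0) abort("no assemblages to summarise")
  centuries <- centuries %||%
    seq(min(assemblages$first_century), max(assemblages$last_century))
  long <- assemblages |>
    mutate(weight = assemblage_weight(assemblages),
           p_marine = .data$marine_nisp /
             (.data$marine_nisp + .data$terrestrial_nisp)) |>
    mutate(century = purrr::map2(.data$first_century, .data$last_century, seq)) |>
    tidyr::unnest("century") |>
    filter(.data$century %in% centuries)
  out <- long |>
    group_by(.data$century) |>
    summarise(
      proportion = if (pooled) {
        sum(.data$weight * .data$marine_nisp) /
          sum(.data$weight * (.data$marine_nisp + .data$terrestrial_nisp))
      } else {
        sum(.data$weight * .data$p_marine) / sum(.data$weight)
      },
      total_weight = sum(.data$weight),
      n_assemblages = n(),
      .groups = "drop")
  tibble(century = centuries) |>
    left_join(out, by = "century") |>
    mutate(total_weight = tidyr::replace_na(.data$total_weight, 0),
           n_assemblages = tidyr::replace_na(.data$n_assemblages, 0L))
}

#' Plot centennial marine-resource proportions
#'
#' @param proportions Output of [century_weighted_proportion()].
#' @return A ggplot of the weighted marine proportion per century, bar
#'   height split between marine and terrestrial shares.
#' @export
plot_century_proportions <- function(proportions) {
  dat <- proportions |>
    filter(!is.na(.data$proportion)) |>
    tidyr::pivot_longer(cols = "proportion", values_to = "marine") |>
    mutate(terrestrial = 1 - .data$marine) |>
    tidyr::pivot_longer(cols = c("marine", "terrestrial"),
                        names_to = "origin", values_to = "share")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$century, y = .data$share,
                                    fill = .data$origin)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(marine = "#3B6FB6",
                                          terrestrial = "#8B5A2B")) +
    ggplot2::labs(x = "Century (CE)", y = "Weighted NISP proportion",
                  fill = NULL)
}
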