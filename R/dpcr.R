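#' Digital PCR well filters
#'
#' Inclusion ranges for digital-PCR wells: the mitochondrial target must not
#' approach partition saturation, the nuclear target must land in a window
#' where Poisson quantification is reliable, and the resulting copy-number
#' ratio must fall in the plausible biological range.
#'
#' @param nd1_pos_max Wells with this many or more ND1-positive partitions
#'   are excluded (default 30,000: "fewer than 30,000 positives").
#' @param rpph1_pos_min,rpph1_pos_max Inclusive range of RPPH1-positive
#'   partitions (default 5 to 2,000).
#' @param ratio_min,ratio_max Inclusive range of the ND1:RPPH1 copy ratio
#'   (default 15 to 300).
#' @return An object of class `dpcr_filter_params`.
#' @export
dpcr_filter_params <- function(nd1_pos_max = 30000,
                               rpph1_pos_min = 5, rpph1_pos_max = 2000,
                               ratio_min = 15, ratio_max = 300) {
  if (rpph1_pos_min >= rpph1_pos_max) abort("RPPH1 range must have min < max.")
  if (ratio_min >= ratio_max) abort("Ratio range must have min < max.")
  structure(list(nd1_pos_max = nd1_pos_max, rpph1_pos_min = rpph1_pos_min,
                 rpph1_pos_max = rpph1_pos_max, ratio_min = ratio_min,
                 ratio_max = ratio_max),
            class = "dpcr_filter_params")
}

#' Poisson quantification of digital PCR wells
#'
#' Converts positive-partition counts to concentrations by inverting the
#' Poisson occupancy model: with a fraction `f` of positive partitions the
#' mean copies per partition is \eqn{\lambda = -\ln(1 - f)}, total copies in
#' the well are \eqn{\lambda \times} partitions, and copies/ul divides by
#' the reaction volume. The copy-number ratio is ND1 copies/ul over RPPH1
#' copies/ul (volume cancels). Filters are applied in order, each well
#' receiving at most one first-failing reason: saturated partitions
#' (`SATURATED`, the occupancy is undefined), the ND1 positives ceiling
#' (`ND1_SATURATION_FILTER`), the RPPH1 positives range (`RPPH1_RANGE`),
#' then the ratio range (`RATIO_RANGE`).
#'
#' @param wells A tibble with `sample_id`, `positives_nd1`,
#'   `positives_rpph1`, `n_partitions` and optionally `plate_id` and
#'   `well_volume`.
#' @param params A [dpcr_filter_params()].
#' @param volume_ul Reaction volume in ul; required unless the table has a
#'   `well_volume` column.
#' @return A list: `estimates` (tibble with `copies_nd1_per_ul`,
#'   `copies_rpph1_per_ul`, `ratio` for wells passing all filters) and
#'   `exclusions` (well, reason).
#' @export
dpcr_quantify <- function(wells, params = dpcr_filter_params(),
                          volume_ul = NULL) {
  check_columns(wells, c("sample_id", "positives_nd1", "positives_rpph1",
                         "n_partitions"), "`wells`")
  stopifnot(inherits(params, "dpcr_filter_params"))
  if (!"well_volume" %in% names(wells)) {
    if (is.null(volume_ul)) {
      abort("Provide `volume_ul` or a `well_volume` column: the reaction volume is required to report copies/ul.")
    }
    wells$well_volume <- volume_ul
  }
  if (any(wells$positives_nd1 < 0 | wells$positives_nd1 > wells$n_partitions |
            wells$positives_rpph1 < 0 | wells$positives_rpph1 > wells$n_partitions)) {
    abort("Positive counts must lie in [0, n_partitions].")
  }
  x <- wells |> mutate(.reason = NA_character_)
  sat <- x$positives_nd1 == x$n_partitions | x$positives_rpph1 == x$n_partitions
  x$.reason[sat] <- "SATURATED"
  hit <- is.na(x$.reason) & x$positives_nd1 >= params$nd1_pos_max
  x$.reason[hit] <- "ND1_SATURATION_FILTER"
  hit <- is.na(x$.reason) & (x$positives_rpph1 < params$rpph1_pos_min |
                               x$positives_rpph1 > params$rpph1_pos_max)
  x$.reason[hit] <- "RPPH1_RANGE"

  lam <- function(pos, n) -log1p(-pos / n)
  x <- x |>
    mutate(
      lambda_nd1 = lam(.data$positives_nd1, .data$n_partitions),
      lambda_rpph1 = lam(.data$positives_rpph1, .data$n_partitions),
      copies_nd1_per_ul = .data$lambda_nd1 * .data$n_partitions / .data$well_volume,
      copies_rpph1_per_ul = .data$lambda_rpph1 * .data$n_partitions / .data$well_volume,
      ratio = .data$copies_nd1_per_ul / .data$copies_rpph1_per_ul
    )
  hit <- is.na(x$.reason) & (!is.finite(x$ratio) | x$ratio < params$ratio_min |
                               x$ratio > params$ratio_max)
  x$.reason[hit] <- "RATIO_RANGE"

  keep_cols <- intersect(c("sample_id", "plate_id", "copies_nd1_per_ul",
                           "copies_rpph1_per_ul", "ratio"), names(x))
  list(
    estimates = x |> filter(is.na(.data$.reason)) |> select(all_of(keep_cols)),
    exclusions = x |>
      filter(!is.na(.data$.reason)) |>
      select(any_of(c("sample_id", "plate_id")), reason = ".reason")
  )
}

#' Plate adjustment for digital PCR ratios
#'
#' Removes shrunken plate means from the dPCR copy-number ratio as a random
#' intercept (see [plate_adjust()]) while preserving the grand mean, so the
#' adjusted value remains an absolute copy-number measure.
#'
#' @param estimates A tibble with `ratio` and `plate_id` columns.
#' @return The input with an `adjusted_ratio` column appended.
#' @export
dpcr_plate_adjust <- function(estimates) {
  check_columns(estimates, c("ratio", "plate_id"), "`estimates`")
  estimates |>
    mutate(adjusted_ratio = plate_adjust(.data$ratio, .data$plate_id,
                                         preserve_mean = TRUE))
}
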