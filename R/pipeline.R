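#' Total family size
#'
#' The totality of Focal's living great-grandparents, grandparents, parents,
#' children, grandchildren, great-grandchildren, aunts/uncles, niblings
#' (nieces/nephews), siblings and cousins: the sum of expected counts over
#' all 10 reported kin categories, all kin ages and sexes (Focal herself is
#' not a member of her own network).
#'
#' @param net A `kin_network` or `kin_network_series`, or a tidy kin tibble
#'   (as from [tidy.kin_network()]) containing all 14 kin types.
#' @param focal_age Focal's age in years (class lower bound).
#' @param time Calendar year (needed for network series).
#' @return A single expected count.
#' @export
total_family_size <- function(net, focal_age, time = NULL) {
  codes <- kin_categories()$code
  if (is.data.frame(net)) {
    d <- net[net$focal_age == focal_age, ]
    if (!is.null(time)) d <- d[d$year == time, ]
    missing <- setdiff(codes, unique(d$kin_type))
    if (length(missing)) {
      stop("kin type(s) missing from network: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    return(sum(d$count))
  }
  stopifnot(inherits(net, "kin_network"))
  x <- age_to_class(focal_age, net$grid)
  missing <- setdiff(codes, names(net$arrays))
  if (length(missing)) {
    stop("kin type(s) missing from network: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sum(vapply(codes, function(tp) sum(kin_slab(net, tp, time)[, x]),
             numeric(1)))
}

#' Count-weighted mean age of kin
#'
#' The mean age of one kin population, weighting the midpoints of the age
#' classes (lower bound + step/2) by expected counts.
#'
#' @param arr Either a numeric vector of counts by age class, or a tibble
#'   with columns `kin_age` and `count` (as from [kin_counts()] or a
#'   filtered tidy network).
#' @param grid The [age_grid()] the counts live on (ignored for tibble
#'   input, which carries its own ages).
#' @return Mean kin age in years.
#' @export
#' @examples
#' mean_kin_age(c(1, 3, 0), age_grid(3, 5))  # (2.5 + 3 * 7.5) / 4 = 6.25
mean_kin_age <- function(arr, grid = NULL) {
  if (is.data.frame(arr)) {
    tot <- sum(arr$count)
    if (!(tot > 0)) stop("mean kin age undefined: zero total count",
                         call. = FALSE)
    ages <- sort(unique(arr$kin_age))
    step <- if (!is.null(grid)) grid$step_years else
      if (length(ages) > 1) min(diff(ages)) else 5

    return(sum((arr$kin_age + step / 2) * arr$count) / tot)
  }
  counts <- as.numeric(arr)
  if (is.null(grid)) grid <- age_grid(length(counts))
  if (length(counts) %% grid$n_classes == 0 &&
      length(counts) == 2 * grid$n_classes) {
    counts <- counts[seq_len(grid$n_classes)] +
      counts[grid$n_classes + seq_len(grid$n_classes)]
  }
  stopifnot(length(counts) == grid$n_classes)
  tot <- sum(counts)
  if (!(tot > 0)) stop("mean kin age undefined: zero total count",
                       call. = FALSE)
  sum(age_midpoints(grid) * counts) / tot
}

#' Median and 80% projection interval across an ensemble
#'
#' Summarises per-trajectory metric values by the ensemble median and the
#' 10th/90th percentiles (the 80% projection interval), using the standard
#' linear-interpolation quantile rule (type 7).
#'
#' @param df A data frame with one row per trajectory (and any grouping
#'   columns), or a bare numeric vector.
#' @param value Column holding the metric (tidy-eval), default `value`.
#' @param by Character vector of grouping columns; defaults to every column
#'   except the value and `trajectory`.
#' @return A tibble with columns `median`, `lo80`, `hi80` (plus the groups).
#' @export
summarize_ensemble <- function(df, value = "value", by = NULL) {
  if (is.numeric(df)) {
    if (!length(df)) stop("empty ensemble", call. = FALSE)
    q <- stats::quantile(df, c(0.1, 0.5, 0.9), type = 7, names = FALSE)
    return(tibble::tibble(median = q[2], lo80 = q[1], hi80 = q[3]))
  }
  stopifnot(is.data.frame(df), nrow(df) > 0)
  if (is.null(by)) by <- setdiff(names(df), c(value, "trajectory"))
  df |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      median = stats::quantile(.data[[value]], 0.5, type = 7, names = FALSE),
      lo80 = stats::quantile(.data[[value]], 0.1, type = 7, names = FALSE),
      hi80 = stats::quantile(.data[[value]], 0.9, type = 7, names = FALSE),
      .groups = "drop"
    )
}

#' Population-weighted regional aggregation
#'
#' Aggregates per-location metrics to regions: within each trajectory (and
#' any other grouping), the regional metric is the weighted mean of member
#' countries, with weights defaulting to the female population in Focal's
#' age class; the regional ensemble is then summarised by median and 80%
#' interval.
#'
#' @param df Per-location, per-trajectory metrics: needs columns `location`,
#'   `trajectory`, a value column, and a `weight` column.
#' @param region_map Data frame with columns `location`, `region`; every
#'   location must map to exactly one region.
#' @param value Name of the metric column, default `"value"`.
#' @param by Extra grouping columns shared by all locations (e.g. `year`,
#'   `focal_age`, `metric`).
#' @return A regional summary tibble (`region`, groups, `median`, `lo80`,
#'   `hi80`).
#' @export
aggregate_regions <- function(df, region_map, value = "value",
                              by = intersect(c("year", "focal_age", "metric"),
                                             names(df))) {
  stopifnot(all(c("location", "weight") %in% names(df)),
            all(c("location", "region") %in% names(region_map)))
  if (anyDuplicated(region_map$location)) {
    stop("each location must map to exactly one region", call. = FALSE)
  }
  unmapped <- setdiff(unique(df$location), region_map$location)
  if (length(unmapped)) {
    stop("unmapped location(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(df, region_map, by = "location")
  per_traj <- joined |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("region", "trajectory", by)))) |>
    dplyr::summarise(
      .total_w = sum(.data$weight),
      value = if (sum(.data$weight) > 0)
        sum(.data[[value]] * .data$weight) / sum(.data$weight) else NA_real_,
      .groups = "drop"
    )
  if (any(!(per_traj$.total_w > 0))) {
    stop("zero total weight in at least one region", call. = FALSE)
  }
  per_traj$.total_w <- NULL
  summarize_ensemble(per_traj, value = "value", by = c("region", by))
}
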