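# Derived whole-plant senescence and photosynthesis metrics.

#' Day of year from a calendar date
#'
#' @param year,month,day Gregorian date components.
#' @return Integer 1-based day of year, leap-year aware.
#' @export
#' @examples
#' date_to_doy(2020, 9, 30) # 274
date_to_doy <- function(year, month, day) {
  d <- tryCatch(as.Date(sprintf("%04d-%02d-%02d", year, month, day)),
                error = function(e) NA)
  if (is.na(d) || format(d, "%d") != sprintf("%02d", day) ||
      format(d, "%m") != sprintf("%02d", month))
    stop("invalid date: ", year, "-", month, "-", day)
  as.integer(format(d, "%j"))
}

#' Trapezoidal area under a series
#'
#' @param x Strictly increasing abscissae (days).
#' @param y Ordinates.
#' @return `sum((x[i+1]-x[i]) * (y[i]+y[i+1]) / 2)`.
#' @export
#' @examples
#' auc_trapezoid(c(0, 5, 10), c(2, 4, 0)) # 25
auc_trapezoid <- function(x, y) {
  if (length(x) < 2) stop("need at least 2 points for a trapezoid area")
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (any(diff(x) <= 0)) stop("x must be strictly increasing")
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Inverted relative SPAD senescence index
#'
#' Per tree and date, the product of leaf count and average SPAD is divided
#' by the tree's seasonal maximum of that product, subtracted from 1 in
#' absolute value:
#' `index(d) = | count(d) * spad(d) / max_i(count(i) * spad(i)) - 1 |`,
#' a senescence progression score in \[0, 1\] (0 at the greenest date, 1
#' once all leaves are lost). The maximum is taken over the tree's full
#' measurement set, before any modeling-window restriction.
#'
#' @param leaf_counts Tibble `tree_id`, `doy`, `count` (scheduled leaf
#'   counts).
#' @param spad Tibble `tree_id`, `doy`, `avg_spad` on the same dates.
#' @return A tibble `tree_id`, `doy`, `index`.
#' @export
inverted_spad_index <- function(leaf_counts, spad) {
  joined <- dplyr::inner_join(leaf_counts, spad, by = c("tree_id", "doy"))
  if (nrow(joined) == 0) stop("leaf counts and SPAD series share no dates")
  joined$product <- joined$count * joined$avg_spad
  out <- joined |>
    dplyr::group_by(.data$tree_id) |>
    dplyr::mutate(max_product = max(.data$product)) |>
    dplyr::ungroup()
  if (any(out$max_product <= 0)) {
    bad <- unique(out$tree_id[out$max_product <= 0])
    stop("index undefined (all count x SPAD products zero) for tree(s): ",
         paste(bad, collapse = ", "))
  }
  out$index <- abs(out$product / out$max_product - 1)
  out <- out[order(out$tree_id, out$doy),
             c("tree_id", "doy", "index")]
  tibble::as_tibble(out)
}

#' Restrict a senescence series to the modeling window
#'
#' Retains points at or after the cutoff day (default DOY 274, i.e. the last
#' nine of thirteen default campaigns).
#'
#' @param series Tibble with a `doy` column.
#' @param cutoff_doy Integer cutoff day of year.
#' @return The restricted series.
#' @export
restrict_to_modeling_window <- function(series, cutoff_doy = 274L) {
  out <- series[series$doy >= cutoff_doy, ]
  if (nrow(out) == 0) stop("no points at or after cutoff DOY ", cutoff_doy)
  out
}

#' Day of year of 50% senescence by threshold interpolation
#'
#' Finds the last adjacent pair of points straddling the threshold in the
#' increasing (senescing) direction and interpolates linearly between their
#' days; a point exactly at the threshold is its own crossing. Series that
#' never reach the threshold give `NA` (flagged, not an error).
#'
#' @param doy Ordered days of year.
#' @param index Senescence index values at those days.
#' @param threshold Crossing level, default 0.5.
#' @return A real-valued day of year, or `NA_real_` if never crossed.
#' @export
#' @examples
#' doy_50pct_senescence(c(240, 250), c(0.2125, 0.75)) # 245.35
doy_50pct_senescence <- function(doy, index, threshold = 0.5) {
  if (length(doy) < 2) stop("need at least 2 points to interpolate")
  stopifnot(length(doy) == length(index), all(diff(doy) > 0))
  if (max(index) < threshold) return(NA_real_)
  v1 <- head(index, -1); v2 <- tail(index, -1)
  crossing <- which(v1 < threshold & v2 >= threshold)
  if (length(crossing) == 0) {
    # threshold attained but never crossed from below inside the series
    # (e.g. already senesced at the first point): date of the first point of
    # the latest run of at-or-above-threshold values
    hits <- which(index >= threshold)
    starts <- hits[!(hits - 1L) %in% hits]
    return(doy[max(starts)])
  }
  i <- crossing[length(crossing)]
  d1 <- doy[i]; d2 <- doy[i + 1]
  x1 <- index[i]; x2 <- index[i + 1]
  d1 + (threshold - x1) / (x2 - x1) * (d2 - d1)
}

#' Total leaf-level autumn photosynthesis
#'
#' Trapezoidal area under a tree's QC-cleaned net-photosynthesis series,
#' with time in days (units umol m-2 s-1 x day; see the package vignette for
#' the time-base convention). An all-zero series returns 0.
#'
#' @param obs QC-cleaned, interval-day-assigned records for one tree
#'   (`doy`, `a_net`).
#' @return The area.
#' @export
total_autumn_photosynthesis <- function(obs) {
  obs <- obs[order(obs$doy), ]
  auc_trapezoid(obs$doy, obs$a_net)
}

#' Total relative tree-level carbon gain
#'
#' Each net-photosynthesis value is multiplied by the ratio of the
#' temporally closest leaf count to the pre-treatment leaf count (ties
#' between equidistant counts broken toward the earlier one), then
#' integrated by trapezoid. Corrects leaf-level rates for tree size and
#' defoliation.
#'
#' @param obs QC-cleaned records for one tree (`doy`, `a_net`).
#' @param leaf_counts Tibble `doy`, `count` for the same tree.
#' @param pretreatment_count Leaf count just before the first leaf removal;
#'   must be positive.
#' @return The area under the scaled series.
#' @export
total_relative_carbon_gain <- function(obs, leaf_counts, pretreatment_count) {
  if (length(pretreatment_count) != 1 || pretreatment_count <= 0)
    stop("pretreatment_count must be a single positive number")
  if (nrow(leaf_counts) == 0) stop("leaf_counts is empty")
  obs <- obs[order(obs$doy), ]
  closest <- vapply(obs$doy, function(d) {
    dist <- abs(leaf_counts$doy - d)
    cand <- which(dist == min(dist))
    leaf_counts$count[cand[which.min(leaf_counts$doy[cand])]]
  }, numeric(1))
  scaled <- obs$a_net * closest / pretreatment_count
  auc_trapezoid(obs$doy, scaled)
}

#' Relative organ counts
#'
#' Divides each count by the count just before the organ's first removal
#' event; the reference observation itself maps to 1 and regrowth can push
#' later ratios above 1.
#'
#' @param counts Count rows for one tree and organ (`doy`, `count`,
#'   `event_phase`).
#' @param first_removal_doy DOY of the organ's first removal event.
#' @return The counts with a `relative_count` column.
#' @export
relative_counts <- function(counts, first_removal_doy) {
  ref_row <- counts$doy == first_removal_doy & counts$event_phase == "pre"
  if (sum(ref_row) != 1)
    stop("need exactly one pre-removal observation at DOY ", first_removal_doy)
  ref <- counts$count[ref_row]
  if (ref == 0) stop("pre-removal reference count is zero")
  counts$relative_count <- counts$count / ref
  counts
}

#' Per-tree endpoint metrics for a whole dataset
#'
#' Runs the metric chain for every tree: QC-cleaned photosynthesis AUC,
#' relative carbon gain, and the DOY of 50% senescence from the inverted
#' SPAD index restricted to the modeling window.
#'
#' @param sim Dataset list (`trees`, `counts`, `spad`, `photosynthesis`)
#'   with photosynthesis either raw or already QC-processed.
#' @param config The [sim_config()] that produced the data (supplies the
#'   event calendar and schedules); required for the pre-treatment count
#'   reference.
#' @param cutoff_doy Modeling-window cutoff for the senescence series.
#' @return A tibble, one row per tree: `tree_id`, `total_autumn_photo`,
#'   `total_rel_carbon_gain`, `doy_50pct`, `doy_50pct_defined`, joined with
#'   the design columns.
#' @export
tree_metrics <- function(sim, config, cutoff_doy = 274L) {
  photo <- sim$photosynthesis
  if (!"qc_status" %in% names(photo)) {
    schedule <- measurement_schedule(config$photosynthesis_doys)
    photo <- qc_photosynthesis(photo, schedule)$observations
  }
  clean <- qc_kept(photo)

  leaf_sched <- sim$counts[sim$counts$organ == "leaf" &
                             sim$counts$event_phase == "none", ]
  leaf_pre <- sim$counts[sim$counts$organ == "leaf" &
                           sim$counts$event_phase == "pre" &
                           sim$counts$doy == config$event_doys$leaf_removal_1, ]
  index <- inverted_spad_index(
    leaf_sched[, c("tree_id", "doy", "count")], sim$spad
  )
  index_win <- restrict_to_modeling_window(index, cutoff_doy)

  ids <- sim$trees$tree_id
  clean_split <- split(clean[, c("doy", "a_net")], clean$tree_id)
  lc_split <- split(leaf_sched[, c("doy", "count")], leaf_sched$tree_id)
  iw_split <- split(index_win[, c("doy", "index")], index_win$tree_id)
  pre_map <- setNames(leaf_pre$count, leaf_pre$tree_id)

  n <- length(ids)
  total_photo <- total_gain <- d50 <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    obs <- clean_split[[ids[i]]]
    lc <- lc_split[[ids[i]]]
    pre <- pre_map[[ids[i]]]
    iw <- iw_split[[ids[i]]]
    if (!is.null(obs) && nrow(obs) >= 2) {
      total_photo[i] <- total_autumn_photosynthesis(obs)
      if (!is.null(pre) && !is.null(lc))
        total_gain[i] <- total_relative_carbon_gain(obs, lc, pre)
    }
    if (!is.null(iw) && nrow(iw) >= 2)
      d50[i] <- doy_50pct_senescence(iw$doy, iw$index)
  }
  metrics <- tibble::tibble(
    tree_id = ids,
    total_autumn_photo = total_photo,
    total_rel_carbon_gain = total_gain,
    doy_50pct = d50,
    doy_50pct_defined = !is.na(d50)
  )
  dplyr::left_join(sim$trees, metrics, by = "tree_id")
}
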