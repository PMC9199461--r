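# Quality control for leaf gas-exchange records.
#
# Fixed rule order: interval-day assignment -> leaf-area correction ->
# plausibility screen -> non-positive resolution. Every record ends in
# exactly one of the states kept / zeroed / dropped; dropped records stay in
# the table (flagged) so that counts are conserved and decisions auditable.

#' Build a measurement schedule from campaign first days
#'
#' Campaigns span several consecutive days; all measurements inside a
#' campaign are treated as comparable and assigned to its first day. Interval
#' ends default to the day before the next campaign starts (the final
#' campaign spans `final_length` days).
#'
#' @param first_doys Strictly increasing integer first days.
#' @param last_doys Optional matching vector of last days.
#' @param final_length Span in days of the final interval when `last_doys`
#'   is derived.
#' @return A tibble with `interval_index`, `first_doy`, `last_doy`.
#' @export
measurement_schedule <- function(first_doys, last_doys = NULL,
                                 final_length = 10L) {
  stopifnot(length(first_doys) >= 1, all(diff(first_doys) > 0))
  if (is.null(last_doys)) {
    last_doys <- c(first_doys[-1] - 1L,
                   first_doys[length(first_doys)] + final_length - 1L)
  }
  stopifnot(length(last_doys) == length(first_doys),
            all(last_doys >= first_doys))
  if (length(first_doys) > 1 &&
      any(first_doys[-1] <= last_doys[-length(last_doys)]))
    stop("measurement intervals must not overlap")
  tibble::tibble(interval_index = seq_along(first_doys),
                 first_doy = as.integer(first_doys),
                 last_doy = as.integer(last_doys))
}

#' Assign each observation to its measurement interval's first day
#'
#' @param observations Tibble with at least `tree_id` and `doy`.
#' @param schedule A [measurement_schedule()].
#' @return The observations with `doy` replaced by the interval's first day
#'   and an `interval_index` column set.
#' @export
assign_interval_day <- function(observations, schedule) {
  idx <- vapply(observations$doy, function(d) {
    hit <- which(schedule$first_doy <= d & d <= schedule$last_doy)
    if (length(hit) != 1) NA_integer_ else hit
  }, integer(1))
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("observation outside all measurement intervals: tree ",
         observations$tree_id[bad], ", doy ", observations$doy[bad])
  }
  observations$interval_index <- schedule$interval_index[idx]
  observations$doy <- schedule$first_doy[idx]
  observations
}

#' Re-express chamber-average photosynthesis per actual leaf area
#'
#' Leaves too small to fill the gas-exchange chamber yield a chamber-average
#' rate; dividing by the covered fraction converts it to the full-coverage
#' equivalent. Applied before any sign-based rule.
#'
#' @param a_net Net photosynthesis, umol m-2 s-1 (chamber basis).
#' @param covered_fraction Leaf area divided by chamber area, in (0, 1].
#' @return Corrected rates.
#' @export
#' @examples
#' correct_leaf_area(10, 0.5) # 20
correct_leaf_area <- function(a_net, covered_fraction) {
  if (any(covered_fraction <= 0 | covered_fraction > 1))
    stop("covered_fraction must be in (0, 1]")
  a_net / covered_fraction
}

#' Default plausibility rules
#'
#' Each rule is a predicate over the observation table returning `TRUE` for
#' records that pass. The single documented default: stomatal conductance
#' cannot be negative.
#'
#' @return A named list of predicate functions.
#' @export
qc_rules <- function() {
  list(negative_gsw = function(obs) obs$gsw >= 0)
}

#' Screen records against plausibility rules
#'
#' A record still in the `raw` state is dropped as soon as any rule fails,
#' with the failing rule's name recorded in `qc_reason`.
#'
#' @param observations Tibble of photosynthesis records.
#' @param rules Named list of predicates as in [qc_rules()]; an empty list
#'   keeps everything.
#' @return The observations with `qc_status`/`qc_reason` updated.
#' @export
screen_plausibility <- function(observations, rules = qc_rules()) {
  observations <- init_qc_columns(observations)
  raw <- observations$qc_status == "raw"
  for (nm in names(rules)) {
    fail <- raw & !rules[[nm]](observations)
    observations$qc_status[fail] <- "dropped"
    observations$qc_reason[fail] <- nm
    raw <- raw & !fail
  }
  observations
}

#' Resolve non-positive photosynthesis values
#'
#' Leafless trees record a true zero: their rates are set to 0 (`zeroed`).
#' A negative rate is biologically meaningful as zero only at season end: it
#' is zeroed if the record is from the final measurement interval or the
#' tree had lost all its leaves by the next interval, and dropped otherwise.
#' Non-negative rates are kept; an exact zero is kept, not routed through
#' the negative-value rule.
#'
#' @param observations Records after interval assignment (needs
#'   `interval_index` and `leafless_flag`).
#' @param tree_history Tibble `tree_id`, `interval_index`, `leafless` giving
#'   leafless status per tree and interval; defaults to the observations'
#'   own `leafless_flag`.
#' @return The observations with `qc_status`, `qc_reason` and `a_net`
#'   updated.
#' @export
resolve_nonpositive <- function(observations, tree_history = NULL) {
  observations <- init_qc_columns(observations)
  if (!"interval_index" %in% names(observations))
    stop("run assign_interval_day() before resolve_nonpositive()")
  if (is.null(tree_history)) {
    tree_history <- tibble::tibble(
      tree_id = observations$tree_id,
      interval_index = observations$interval_index,
      leafless = observations$leafless_flag
    )
  }
  missing <- setdiff(observations$tree_id, tree_history$tree_id)
  if (length(missing) > 0)
    stop("no leafless history for tree(s): ", paste(missing, collapse = ", "))
  last_interval <- max(tree_history$interval_index)
  leafless_key <- paste(tree_history$tree_id[tree_history$leafless],
                        tree_history$interval_index[tree_history$leafless])

  a <- observations$a_net
  status <- observations$qc_status
  reason <- observations$qc_reason
  raw <- status == "raw"

  leafless <- raw & observations$leafless_flag %in% TRUE
  a[leafless] <- 0
  status[leafless] <- "zeroed"
  reason[leafless] <- "leafless_zero"
  raw <- raw & !leafless

  neg <- raw & a < 0
  at_last <- neg & observations$interval_index == last_interval
  next_leafless <- neg & !at_last &
    paste(observations$tree_id, observations$interval_index + 1L) %in%
      leafless_key
  zero_neg <- at_last | next_leafless
  a[zero_neg] <- 0
  status[zero_neg] <- "zeroed"
  reason[at_last] <- "negative_last_interval"
  reason[next_leafless] <- "negative_leafless_next"
  drop_neg <- neg & !zero_neg
  status[drop_neg] <- "dropped"
  reason[drop_neg] <- "negative_dropped"

  keep <- raw & !neg
  status[keep] <- "kept"
  reason[keep] <- "ok"

  observations$a_net <- a
  observations$qc_status <- status
  observations$qc_reason <- reason
  observations
}

init_qc_columns <- function(observations) {
  if (!"qc_status" %in% names(observations))
    observations$qc_status <- "raw"
  if (!"qc_reason" %in% names(observations))
    observations$qc_reason <- NA_character_
  observations
}

#' Run the full photosynthesis QC chain
#'
#' Interval-day assignment, leaf-area correction, plausibility screen and
#' non-positive resolution, in that fixed order. Records already processed
#' (status other than `raw`) pass through untouched, so the chain is
#' idempotent.
#'
#' @param photo Photosynthesis records (`tree_id`, `doy`, `a_net`,
#'   `covered_fraction`, `gsw`, `leafless_flag`).
#' @param schedule A [measurement_schedule()]; defaults to one-day intervals
#'   at the distinct observed DOYs (synthetic data are already on first
#'   days).
#' @param rules Plausibility rules, see [qc_rules()].
#' @return A list with `observations` (all records, status-flagged, `a_net`
#'   area-corrected) and `log` (one row per record: tree, doy, action, rule).
#' @export
qc_photosynthesis <- function(photo, schedule = NULL, rules = qc_rules()) {
  photo <- init_qc_columns(photo)
  if (is.null(schedule))
    schedule <- measurement_schedule(sort(unique(photo$doy)))
  photo <- assign_interval_day(photo, schedule)
  raw <- photo$qc_status == "raw"
  photo$a_net[raw] <- correct_leaf_area(photo$a_net[raw],
                                        photo$covered_fraction[raw])
  photo <- screen_plausibility(photo, rules)
  photo <- resolve_nonpositive(photo)
  log <- tibble::tibble(
    tree_id = photo$tree_id, doy = photo$doy,
    action = photo$qc_status, rule = photo$qc_reason
  )
  list(observations = photo, log = log)
}

#' Records surviving QC (kept or zeroed)
#'
#' @param observations QC-processed records.
#' @return The subset with `qc_status` in `kept`/`zeroed`.
#' @export
qc_kept <- function(observations) {
  observations[observations$qc_status %in% c("kept", "zeroed"), ]
}
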