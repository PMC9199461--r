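# CSV schemas
#
# trees.csv          tree_id, treatment, leaf_removal_pct, bud_removal_pct,
#                    block_id, leaf_out_group
# counts.csv         tree_id, doy, organ, count, event_phase
# spad.csv           tree_id, doy, avg_spad
# photosynthesis.csv tree_id, doy, a_net_umol_m2_s, covered_fraction, gsw,
#                    leafless_flag
#
# All DOYs are integers; the calendar year is recorded in a '#' header
# comment on each file.

dataset_files <- c(trees = "trees.csv", counts = "counts.csv",
                   spad = "spad.csv", photosynthesis = "photosynthesis.csv")

#' Write a simulated (or observed) dataset as four CSV files
#'
#' @param sim A named list with tibbles `trees`, `counts`, `spad`,
#'   `photosynthesis`, as returned by [simulate_experiment()].
#' @param out_dir Output directory, created if needed.
#' @param overwrite Refuse to clobber existing files unless `TRUE`.
#' @param year Calendar year recorded in the file header comment.
#' @return Invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(sim, out_dir, overwrite = FALSE, year = 2020L) {
  stopifnot(all(names(dataset_files) %in% names(sim)))
  ids <- unique(sim$trees$tree_id)
  for (tab in c("counts", "spad", "photosynthesis")) {
    if (nrow(sim[[tab]]) > 0 && !all(sim[[tab]]$tree_id %in% ids))
      stop("tree_ids in '", tab, "' not present in the trees table")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, dataset_files)
  names(paths) <- names(dataset_files)
  if (!overwrite && any(file.exists(paths)))
    stop("output files exist; set overwrite = TRUE to replace them")

  photo <- sim$photosynthesis
  if ("a_net" %in% names(photo))
    photo <- dplyr::rename(photo, a_net_umol_m2_s = "a_net")
  tabs <- list(trees = sim$trees, counts = sim$counts, spad = sim$spad,
               photosynthesis = photo)
  for (nm in names(tabs)) {
    writeLines(sprintf("# year: %d", year), paths[[nm]])
    readr::write_csv(tabs[[nm]], paths[[nm]], append = TRUE, col_names = TRUE)
  }
  invisible(paths)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory holding the four CSV files.
#' @return A named list of tibbles `trees`, `counts`, `spad`,
#'   `photosynthesis` (photosynthesis rate column restored to `a_net`).
#' @export
read_dataset <- function(dir) {
  paths <- file.path(dir, dataset_files)
  names(paths) <- names(dataset_files)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("missing dataset files: ", paste(basename(missing), collapse = ", "))
  col_types <- list(
    trees = readr::cols(
      tree_id = readr::col_character(), treatment = readr::col_character(),
      leaf_removal_pct = readr::col_double(),
      bud_removal_pct = readr::col_double(),
      block_id = readr::col_integer(), leaf_out_group = readr::col_integer()
    ),
    counts = readr::cols(
      tree_id = readr::col_character(), doy = readr::col_integer(),
      organ = readr::col_character(), count = readr::col_integer(),
      event_phase = readr::col_character()
    ),
    spad = readr::cols(
      tree_id = readr::col_character(), doy = readr::col_integer(),
      avg_spad = readr::col_double()
    ),
    photosynthesis = readr::cols(
      tree_id = readr::col_character(), doy = readr::col_integer(),
      a_net_umol_m2_s = readr::col_double(),
      covered_fraction = readr::col_double(), gsw = readr::col_double(),
      leafless_flag = readr::col_logical()
    )
  )
  out <- lapply(names(paths), function(nm) {
    readr::read_csv(paths[[nm]], comment = "#", col_types = col_types[[nm]],
                    progress = FALSE)
  })
  names(out) <- names(paths)
  out$photosynthesis <- dplyr::rename(out$photosynthesis,
                                      a_net = "a_net_umol_m2_s")
  out
}
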