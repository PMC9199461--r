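#' The eight source--sink manipulation treatments
#'
#' One row per treatment: three leaf-removal intensities (25/50/75%), three
#' bud-removal intensities (25/50/75%), a combined 50% leaf + 50% bud removal,
#' and an untreated control.
#'
#' @return A tibble with columns `treatment`, `leaf_removal_pct`,
#'   `bud_removal_pct`.
#' @export
#' @examples
#' treatment_specs()
treatment_specs <- function() {
  tibble::tibble(
    treatment = c(
      "leaf_25", "leaf_50", "leaf_75",
      "bud_25", "bud_50", "bud_75",
      "leaf_bud_50", "control"
    ),
    leaf_removal_pct = c(25, 50, 75, 0, 0, 0, 50, 0),
    bud_removal_pct = c(0, 0, 0, 25, 50, 75, 50, 0)
  )
}

#' Generate the randomized-block experimental design
#'
#' Lays out 81 trees: ten per treatment plus an eleventh control, arranged in
#' ten blocks of one tree per treatment (one randomly chosen block carries the
#' extra control tree). Each tree belongs to one of five leaf-out groups,
#' which are spread across treatments as evenly as the arithmetic allows
#' (each group appears exactly twice per 10-tree treatment; the control's
#' eleventh tree draws one additional group at random).
#'
#' @param seed Integer seed; the same seed reproduces the identical design.
#' @return A tibble with one row per tree and columns `tree_id`, `treatment`,
#'   `leaf_removal_pct`, `bud_removal_pct`, `block_id`, `leaf_out_group`.
#' @export
#' @examples
#' d <- generate_design(seed = 1)
#' nrow(d)                       # 81
#' table(d$treatment)["control"] # 11
generate_design <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed == round(seed))
  specs <- treatment_specs()
  rng <- local_rng(seed)

  # blocks 1..10 each hold one tree per treatment; one block gets the spare control
  extra_block <- rng(sample.int(10, 1))
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    n <- if (specs$treatment[i] == "control") 11L else 10L
    blocks <- c(1:10, if (n == 11L) extra_block)
    tibble::tibble(
      treatment = specs$treatment[i],
      leaf_removal_pct = specs$leaf_removal_pct[i],
      bud_removal_pct = specs$bud_removal_pct[i],
      block_id = blocks
    )
  })
  design <- dplyr::bind_rows(rows)

  # leaf-out groups: each of the 5 groups twice per treatment, shuffled;
  # the eleventh control tree draws one extra group
  groups <- lapply(seq_len(nrow(specs)), function(i) {
    n <- if (specs$treatment[i] == "control") 11L else 10L
    g <- rep(1:5, 2)
    if (n == 11L) g <- c(g, rng(sample.int(5, 1)))
    rng(sample(g))
  })
  design$leaf_out_group <- unlist(groups)

  design <- design[order(design$treatment != "control", design$treatment,
                         design$block_id), ]
  design$tree_id <- sprintf("T%02d", seq_len(nrow(design)))
  design <- design[, c("tree_id", "treatment", "leaf_removal_pct",
                       "bud_removal_pct", "block_id", "leaf_out_group")]
  tibble::as_tibble(design)
}

# Run expressions under a private RNG stream without disturbing the caller's
# .Random.seed. Returns a function that evaluates its argument in that stream.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  function(expr) {
    outer <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(outer)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", outer, envir = globalenv())
      }
    })
    expr
  }
}
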