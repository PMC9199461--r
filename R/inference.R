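# Mixed-effects inference: REML fits via lme4/lmerTest, Type-II Wald
# chi-square tests via car::Anova, Nakagawa-Schielzeth R2, and model-based
# parametric bootstrap intervals via lme4::bootMer.

#' Specify a mixed model for a derived metric
#'
#' Removal percentages enter as continuous covariates (0-75); random terms
#' are intercepts per grouping factor. The endpoint models use block only;
#' the longitudinal senescence model adds day of year and a per-tree
#' intercept.
#'
#' @param response Response column name.
#' @param fixed Character vector of fixed-effect covariates.
#' @param interactions Character vector of interaction terms
#'   (e.g. `"leaf_removal_pct:bud_removal_pct"`).
#' @param random Character vector of random-intercept grouping factors.
#' @param transform Response transform: `"identity"`, `"log"` or `"sqrt"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(response,
                       fixed = c("leaf_removal_pct", "bud_removal_pct"),
                       interactions = "leaf_removal_pct:bud_removal_pct",
                       random = "block_id",
                       transform = c("identity", "log", "sqrt")) {
  transform <- match.arg(transform)
  stopifnot(is.character(response), length(response) == 1,
            length(random) >= 1)
  structure(list(response = response, fixed = fixed,
                 interactions = interactions, random = random,
                 transform = transform),
            class = "model_spec")
}

#' Longitudinal senescence-over-time model specification
#'
#' Day of year and both removal gradients with their pairwise interactions
#' as fixed effects; tree and block random intercepts.
#'
#' @param response Response column, default the senescence index.
#' @return A [model_spec()].
#' @export
longitudinal_spec <- function(response = "index") {
  model_spec(
    response,
    fixed = c("doy", "leaf_removal_pct", "bud_removal_pct"),
    interactions = c("leaf_removal_pct:bud_removal_pct",
                     "doy:leaf_removal_pct", "doy:bud_removal_pct"),
    random = c("block_id", "tree_id")
  )
}

spec_formula <- function(spec) {
  rhs <- c(spec$fixed, spec$interactions,
           sprintf("(1 | %s)", spec$random))
  if (length(c(spec$fixed, spec$interactions)) == 0) rhs <- c("1", rhs)
  as.formula(paste(".response ~", paste(rhs, collapse = " + ")))
}

apply_transform <- function(y, transform) {
  switch(transform,
         identity = y,
         log = { if (any(y <= 0)) stop("log transform needs positive response"); log(y) },
         sqrt = { if (any(y < 0)) stop("sqrt transform needs non-negative response"); sqrt(y) })
}

back_transform <- function(y, transform) {
  switch(transform, identity = y, log = exp(y), sqrt = y^2)
}

#' Fit a linear mixed-effects model (REML)
#'
#' Builds the design from a [model_spec()], applies the response transform,
#' and fits by restricted maximum likelihood with Satterthwaite degrees of
#' freedom for the coefficient table. Singular or non-converged fits are
#' returned flagged, never silently.
#'
#' @param spec A [model_spec()].
#' @param data Data frame with the spec's columns; rows with missing
#'   response are excluded.
#' @return An object of class `pheno_fit`: the `lmerMod` fit plus
#'   `coefficients`, `variance_components`, `r2_marginal`,
#'   `r2_conditional`, `converged`, `singular`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(c(spec$response, spec$fixed, spec$random),
                          names(data))
  if (length(missing_cols) > 0)
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "))
  data <- data[!is.na(data[[spec$response]]), , drop = FALSE]
  for (g in spec$random) {
    data[[g]] <- factor(data[[g]])
    if (nlevels(data[[g]]) < 2)
      stop("random factor '", g, "' needs at least 2 levels")
  }
  data$.response <- apply_transform(data[[spec$response]], spec$transform)

  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(spec_formula(spec), data = data, REML = TRUE)
  ))
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  singular <- lme4::isSingular(fit)
  # a boundary (singular) fit is a valid REML solution, not a failure
  real_problems <- msgs[!grepl("boundary \\(singular\\)", msgs)]
  converged <- length(real_problems) == 0

  ct <- coef(summary(fit))
  coefficients <- tibble::tibble(
    term = rownames(ct),
    estimate = ct[, "Estimate"],
    se = ct[, "Std. Error"],
    df = ct[, "df"],
    p = ct[, "Pr(>|t|)"]
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  variance_components <- tibble::tibble(
    group = vc$grp, variance = vc$vcov, sd = vc$sdcor
  )
  res <- structure(
    list(spec = spec, fit = fit, data = data,
         coefficients = coefficients,
         variance_components = variance_components,
         converged = converged, singular = singular,
         messages = msgs, n = nrow(data)),
    class = "pheno_fit"
  )
  r2 <- r2_mixed(res)
  res$r2_marginal <- r2[["marginal"]]
  res$r2_conditional <- r2[["conditional"]]
  res
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("<pheno_fit> ", x$spec$response,
      if (x$spec$transform != "identity") paste0(" (", x$spec$transform, ")"),
      ", n = ", x$n, "\n", sep = "")
  if (!x$converged) cat("  ** did not converge **\n")
  if (x$singular) cat("  ** singular fit **\n")
  print(as.data.frame(x$coefficients), digits = 4)
  cat(sprintf("  R2 marginal %.3f / conditional %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' Type-II Wald chi-square tests per model term
#'
#' @param result A [fit_lmm()] result.
#' @return A tibble `term`, `chisq`, `df`, `p`.
#' @export
effect_tests <- function(result) {
  stopifnot(inherits(result, "pheno_fit"))
  a <- car::Anova(result$fit, type = 2, test.statistic = "Chisq")
  tibble::tibble(term = rownames(a), chisq = a$Chisq, df = a$Df,
                 p = a[["Pr(>Chisq)"]])
}

interaction_order <- function(term) lengths(gregexpr(":", term, fixed = TRUE)) *
  (grepl(":", term, fixed = TRUE))

#' Prune non-significant interaction terms
#'
#' Highest-order interactions are tested first; the least significant
#' non-significant interaction is removed and the model refitted, repeating
#' until every remaining interaction is significant (or none remain). Main
#' effects are never pruned.
#'
#' @param spec A [model_spec()] containing interaction terms.
#' @param data Model data.
#' @param alpha Significance threshold, default 0.05.
#' @return A list: `spec` (reduced), `log` (tibble of pruning decisions),
#'   `fit` (the final [fit_lmm()] result).
#' @export
prune_interactions <- function(spec, data, alpha = 0.05) {
  log <- tibble::tibble(term = character(), p = numeric(),
                        action = character())
  repeat {
    fit <- fit_lmm(spec, data)
    if (length(spec$interactions) == 0) break
    tests <- effect_tests(fit)
    it <- tests[tests$term %in% spec$interactions, ]
    ord <- interaction_order(it$term)
    it <- it[ord == max(ord), ]
    worst <- it[which.max(it$p), ]
    if (worst$p <= alpha) {
      log <- dplyr::bind_rows(log, tibble::tibble(
        term = it$term, p = it$p, action = "kept"))
      break
    }
    log <- dplyr::bind_rows(log, tibble::tibble(
      term = worst$term, p = worst$p, action = "dropped"))
    spec$interactions <- setdiff(spec$interactions, worst$term)
  }
  list(spec = spec, log = log, fit = fit)
}

#' Marginal and conditional R-squared of a mixed model
#'
#' Variance-decomposition (Nakagawa-Schielzeth) R2: the marginal value is
#' the variance of the fixed-effect predictions over the total of fixed,
#' random-intercept and residual variances; the conditional value adds the
#' random-effect variances to the numerator.
#'
#' @param result A [fit_lmm()] result.
#' @return Named numeric vector `marginal`, `conditional`.
#' @export
r2_mixed <- function(result) {
  stopifnot(inherits(result, "pheno_fit"))
  fit <- result$fit
  var_fixed <- var(predict(fit, re.form = NA))
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_random <- sum(pmax(vc$vcov[vc$grp != "Residual"], 0))
  var_resid <- vc$vcov[vc$grp == "Residual"]
  total <- var_fixed + var_random + var_resid
  if (total <= 0) return(c(marginal = 0, conditional = 0))
  c(marginal = var_fixed / total,
    conditional = (var_fixed + var_random) / total)
}

#' Model-based parametric bootstrap confidence intervals for predictions
#'
#' Simulates responses from the fitted model, refits, and collects the
#' population-level prediction for each requested condition. The interval is
#' the point prediction plus/minus 1.96 times the bootstrap standard
#' deviation. Failed refits are dropped and counted; more than 10% failures
#' is an error.
#'
#' @param result A converged [fit_lmm()] result.
#' @param newdata Data frame of conditions to predict (fixed covariates).
#' @param n_sim Number of bootstrap simulations, default 1000.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return `newdata` with columns `fit`, `se_boot`, `lower95`, `upper95`
#'   (back-transformed to the response scale when a transform is in force)
#'   and an attribute `n_failed`.
#' @export
bootstrap_ci <- function(result, newdata, n_sim = 1000, seed = 1L) {
  stopifnot(inherits(result, "pheno_fit"))
  if (!result$converged)
    stop("refusing to bootstrap a non-converged fit")
  fit <- result$fit
  pred_fun <- function(m) predict(m, newdata = newdata, re.form = NA)
  boot <- suppressMessages(suppressWarnings(
    lme4::bootMer(fit, pred_fun, nsim = n_sim, seed = seed,
                  type = "parametric", use.u = FALSE)
  ))
  t_mat <- boot$t
  ok <- stats::complete.cases(t_mat)
  n_failed <- sum(!ok)
  if (n_failed > 0.1 * n_sim)
    stop(n_failed, " of ", n_sim, " bootstrap refits failed (> 10%)")
  point <- pred_fun(fit)
  se <- apply(t_mat[ok, , drop = FALSE], 2, sd)
  out <- newdata
  tr <- result$spec$transform
  out$fit <- back_transform(point, tr)
  out$se_boot <- se
  out$lower95 <- back_transform(point - 1.96 * se, tr)
  out$upper95 <- back_transform(point + 1.96 * se, tr)
  attr(out, "n_failed") <- n_failed
  out
}
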