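#' Split-plot mixed-model analysis of deviance
#'
#' Fits the standard split-plot linear mixed model for a two-treatment
#' multi-year genotype trial: fixed effects for year, treatment, genotype
#' and all their interactions; random intercepts for the block
#' (year-by-replicate) and for the main plot (block-by-treatment), the two
#' error strata of a split-plot layout where fertility is applied to whole
#' main plots and genotypes are randomised within them. Term significance
#' is summarised with Type II Wald chi-square tests.
#'
#' If the full random structure yields a singular fit, the model is refitted
#' with the block intercept only and the result is flagged
#' (`glance()$singular_refit`).
#'
#' @param data A [trial_dataset()] (or data frame with `genotype`, `year`,
#'   `treatment`, `rep` and the trait column).
#' @param trait Trait column to analyse.
#' @return An object of class `split_plot_fit`: use [tidy()] for the
#'   deviance table (terms Y, T, G, Y x T, Y x G, T x G, Y x T x G) and
#'   [glance()] for fit-level information. The underlying `lme4` fit is in
#'   `$model`.
#' @export
fit_split_plot <- function(data, trait) {
  stopifnot_scalar_string(trait, "trait")
  needed <- c("genotype", "year", "treatment", "rep", trait)
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing design column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "sfsi_design_error"
    )
  }
  d <- as_tibble(data) |>
    mutate(
      .y = .data[[trait]],
      year = factor(.data$year),
      treatment = factor(.data$treatment),
      genotype = factor(.data$genotype),
      block = interaction(.data$year, .data$rep, drop = TRUE),
      mainplot = interaction(.data$year, .data$rep, .data$treatment, drop = TRUE)
    ) |>
    filter(is.finite(.data$.y))

  full <- .y ~ year * treatment * genotype + (1 | block) + (1 | mainplot)
  fit <- suppressMessages(lme4::lmer(full, data = d))
  singular_refit <- FALSE
  if (lme4::isSingular(fit, tol = 1e-4)) {
    singular_refit <- TRUE
    fit <- suppressMessages(lme4::lmer(.y ~ year * treatment * genotype + (1 | block), data = d))
  }

  an <- car::Anova(fit, type = "II")
  term_map <- c(
    "year" = "Y", "treatment" = "T", "genotype" = "G",
    "year:treatment" = "Y x T", "year:genotype" = "Y x G",
    "treatment:genotype" = "T x G", "year:treatment:genotype" = "Y x T x G"
  )
  dev <- tibble(
    term = unname(term_map[rownames(an)]),
    chisq = an$Chisq,
    df = an$Df,
    p_value = an$`Pr(>Chisq)`
  )
  dev <- dev[match(term_map, dev$term), , drop = FALSE]
  dev$signif <- sig_codes(dev$p_value)

  structure(
    list(
      model = fit,
      deviance = dev,
      trait = trait,
      singular_refit = singular_refit,
      n_obs = nrow(d)
    ),
    class = "split_plot_fit"
  )
}

#' @export
print.split_plot_fit <- function(x, ...) {
  cat(sprintf(
    "# Split-plot mixed model for '%s' (%d obs%s)\n# Type II Wald chi-square tests:\n",
    x$trait, x$n_obs, if (x$singular_refit) "; singular fit, block-only random structure" else ""
  ))
  print(x$deviance, ...)
  invisible(x)
}

#' @rdname fit_split_plot
#' @param x A `split_plot_fit` object.
#' @param ... Unused.
#' @method tidy split_plot_fit
#' @export
tidy.split_plot_fit <- function(x, ...) x$deviance

#' @rdname fit_split_plot
#' @method glance split_plot_fit
#' @export
glance.split_plot_fit <- function(x, ...) {
  tibble(
    trait = x$trait,
    n_obs = x$n_obs,
    singular_refit = x$singular_refit,
    logLik = as.numeric(stats::logLik(x$model)),
    REML = lme4::isREML(x$model)
  )
}

#' Per-genotype low-vs-high treatment tests
#'
#' Two-sided Welch t-test of the low- against the high-input observations,
#' separately for each genotype, on the plot-level values. No
#' multiple-testing correction is applied across genotypes. Significance
#' uses the strict inequality `p < alpha`, so a p-value exactly at alpha is
#' not significant. Genotypes with fewer than 2 observations in either
#' treatment are flagged untestable rather than dropped.
#'
#' @inheritParams fit_split_plot
#' @param alpha Significance level (default 0.05).
#' @param treatment_labels Low/high labels; taken from the dataset when it
#'   is a `trial_dataset`.
#' @return A tibble with one row per genotype: `genotype`, `mean_lf`,
#'   `mean_hf`, `n_lf`, `n_hf`, `statistic`, `p_value`, `significant`,
#'   `testable`.
#' @export
genotype_treatment_tests <- function(data, trait, alpha = 0.05,
                                     treatment_labels = c(low = "LF", high = "HF")) {
  stopifnot_scalar_string(trait, "trait")
  if (inherits(data, "trial_dataset")) {
    treatment_labels <- attr(data, "treatment_labels")
  }
  low <- unname(treatment_labels[["low"]])
  high <- unname(treatment_labels[["high"]])

  as_tibble(data) |>
    dplyr::group_split(.data$genotype) |>
    purrr::map(function(d) {
      lf <- d[[trait]][d$treatment == low]
      hf <- d[[trait]][d$treatment == high]
      lf <- lf[!is.na(lf)]
      hf <- hf[!is.na(hf)]
      row <- tibble(
        genotype = d$genotype[1],
        mean_lf = if (length(lf)) mean(lf) else NA_real_,
        mean_hf = if (length(hf)) mean(hf) else NA_real_,
        n_lf = length(lf), n_hf = length(hf),
        statistic = NA_real_, p_value = NA_real_,
        significant = NA, testable = FALSE
      )
      if (length(lf) >= 2 && length(hf) >= 2 && (sd(lf) > 0 || sd(hf) > 0)) {
        tt <- stats::t.test(lf, hf, var.equal = FALSE, alternative = "two.sided")
        row$statistic <- unname(tt$statistic)
        row$p_value <- tt$p.value
        row$significant <- tt$p.value < alpha
        row$testable <- TRUE
      }
      row
    }) |>
    purrr::list_rbind() |>
    arrange(.data$genotype)
}

#' Dunnett many-to-one comparisons against the check
#'
#' Compares every genotype with the check variety within one treatment
#' level (typically the low-input stress plots), adjusting the many-to-one
#' family with the multivariate-t Dunnett method. Two-sided by default.
#' Significance codes follow the usual figure convention
#' (`***` p < 0.001, `**` < 0.01, `*` < 0.05, `+` < 0.1).
#'
#' With a single comparator the adjustment collapses and the adjusted
#' p-value equals the unadjusted two-sample p-value.
#'
#' @inheritParams genotype_treatment_tests
#' @param treatment Treatment level to compare within (default `"LF"`).
#' @param check_id Check genotype; defaults to the dataset's `check_id`.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return A tibble of class `dunnett_result`: `genotype`, `estimate`
#'   (genotype minus check, g plant^-1), `se`, `statistic`, `adj_p`,
#'   `signif`; attributes `check_id`, `treatment`, `alpha`.
#' @export
dunnett_vs_check <- function(data, trait, treatment = "LF", check_id = NULL,
                             alpha = 0.05, alternative = "two.sided") {
  stopifnot_scalar_string(trait, "trait")
  check_id <- check_id %||% attr(data, "check_id")
  if (is.null(check_id)) {
    abort("`check_id` is required for Dunnett comparisons.", class = "sfsi_config_error")
  }
  d <- as_tibble(data) |>
    filter(.data$treatment == !!treatment, !is.na(.data[[trait]]))
  if (!check_id %in% d$genotype) {
    abort(sprintf("Check '%s' has no observations under treatment '%s'.", check_id, treatment),
      class = "sfsi_config_error"
    )
  }
  if (dplyr::n_distinct(d$genotype) < 2) {
    abort("At least one comparator genotype is required.", class = "sfsi_design_error")
  }
  d$genotype <- stats::relevel(factor(d$genotype), ref = check_id)
  fit <- stats::lm(stats::reformulate("genotype", response = trait), data = d)
  glht_alt <- switch(alternative,
    two.sided = "two.sided", greater = "greater", less = "less",
    abort("`alternative` must be 'two.sided', 'greater' or 'less'.",
      class = "sfsi_config_error"
    )
  )
  comp <- multcomp::glht(fit,
    linfct = multcomp::mcp(genotype = "Dunnett"),
    alternative = glht_alt
  )
  # the multivariate-t integration is quasi-Monte-Carlo; pin its RNG state
  # locally so results are deterministic, and restore the caller's stream
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(20240501)
  sm <- summary(comp)
  out <- tibble(
    genotype = sub(" - .*$", "", names(sm$test$coefficients)),
    estimate = unname(sm$test$coefficients),
    se = unname(sm$test$sigma),
    statistic = unname(sm$test$tstat),
    adj_p = as.numeric(sm$test$pvalues)
  ) |>
    mutate(signif = sig_codes(.data$adj_p)) |>
    arrange(.data$genotype)

  structure(
    out,
    check_id = check_id,
    treatment = treatment,
    alpha = alpha,
    class = c("dunnett_result", class(tibble()))
  )
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf(
    "# Dunnett comparisons vs check '%s' under %s (family-wise adjusted p)\n",
    attr(x, "check_id"), attr(x, "treatment")
  ))
  print(as_tibble(x), ...)
  invisible(x)
}
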