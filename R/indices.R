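#' Percent reduction rate under low-input stress
#'
#' The relative trait loss of a genotype when grown under the low-fertility
#' treatment: `(x_hf - x_lf) / x_hf * 100`. A negative value means the
#' genotype performed better under stress and is reported as such, never
#' clipped.
#'
#' @param x_lf Mean trait value(s) under the low-input treatment
#'   (g plant^-1).
#' @param x_hf Mean trait value(s) under the high-input treatment; must be
#'   strictly positive.
#' @return Percent reduction, vectorised over the inputs.
#' @examples
#' reduction_rate(908.3, 1363.8) # 33.4
#' @export
reduction_rate <- function(x_lf, x_hf) {
  if (any(!is.finite(x_lf)) || any(!is.finite(x_hf))) {
    abort("Means must be finite to compute a reduction rate.", class = "sfsi_undefined_rate")
  }
  if (any(x_hf <= 0)) {
    abort("Reduction rate is undefined when the high-input mean is <= 0.",
      class = "sfsi_undefined_rate"
    )
  }
  (x_hf - x_lf) / x_hf * 100
}

#' Stress (soil fertility) intensity
#'
#' Population-level severity of the low-input stress:
#' `SI = 1 - Y_lf / Y_hf`, where `Y_lf` and `Y_hf` are the grand means of
#' the per-genotype means under the low and high treatments. Grand means
#' are unweighted means of genotype means, which reproduces the Mean row of
#' a published genotype-mean table; with unbalanced data this differs from
#' a raw plot-level mean.
#'
#' SI must be strictly positive for the susceptibility index to be defined:
#' a non-positive SI means the population was not stressed.
#'
#' @param means A `genotype_means` table (or data frame with `x_lf`,
#'   `x_hf`), with at least two genotypes.
#' @return The scalar SI, in (0, 1) for a stressed population.
#' @examples
#' stress_intensity(yam_trial_means("tuber_yield")) # ~0.519
#' @export
stress_intensity <- function(means) {
  if (!all(c("x_lf", "x_hf") %in% names(means))) {
    abort("`means` must have columns x_lf and x_hf.", class = "sfsi_schema_error")
  }
  if (nrow(means) < 2) {
    abort("Stress intensity needs at least 2 genotypes.", class = "sfsi_design_error")
  }
  y_hf <- mean(means$x_hf)
  if (!is.finite(y_hf) || y_hf <= 0) {
    abort("Grand high-input mean must be positive.", class = "sfsi_stress_orientation_error")
  }
  si <- 1 - mean(means$x_lf) / y_hf
  if (si <= 0) {
    abort(
      "Stress intensity is <= 0: the population mean did not drop under the low-input treatment, so the susceptibility index is undefined.",
      class = "sfsi_stress_orientation_error"
    )
  }
  si
}

#' Soil fertility susceptibility index table
#'
#' The central computation: for each genotype, the percent reduction PR and
#' the susceptibility index
#' `SFSI = (1 - x_lf/x_hf) / (1 - Y_lf/Y_hf) = (PR/100) / SI`,
#' a Fischer-Maurer-type index. SFSI < 1 marks a genotype losing
#' proportionally less than the population under stress (less susceptible),
#' SFSI > 1 proportionally more. Rows are sorted by ascending SFSI (ties
#' broken by genotype ID), the presentation order of published tables.
#'
#' Rows with a non-positive high-input mean cannot carry an index; they are
#' flagged, excluded from the grand means, and reported with a warning.
#'
#' @param means A `genotype_means` table ([genotype_treatment_means()] or
#'   [yam_trial_means()]).
#' @return A tibble of class `sfsi_table` with columns `genotype`, `x_lf`,
#'   `x_hf`, `pr_percent`, `sfsi`, and attributes `trait`, `si`, `y_lf_bar`,
#'   `y_hf_bar`, `mean_pr`, `mean_sfsi`, `check_id`, `flagged`. Use
#'   [glance()] for the population-level summary and [autoplot()] to plot.
#' @examples
#' idx <- sfsi_table(yam_trial_means("tuber_yield"))
#' idx
#' glance(idx)
#' @export
sfsi_table <- function(means) {
  if (!all(c("genotype", "x_lf", "x_hf") %in% names(means))) {
    abort("`means` must have columns genotype, x_lf and x_hf.", class = "sfsi_schema_error")
  }
  means <- as_tibble(means)
  bad <- !is.finite(means$x_hf) | means$x_hf <= 0
  flagged <- tibble(
    genotype = means$genotype[bad],
    reason = "non-positive high-input mean; no index computable"
  )
  if (any(bad)) {
    warn(
      sprintf(
        "%d genotype(s) flagged and excluded from the index table: %s.",
        sum(bad), paste(flagged$genotype, collapse = ", ")
      ),
      class = "sfsi_flagged_row_warning"
    )
    means <- means[!bad, , drop = FALSE]
  }

  si <- stress_intensity(means)
  out <- means |>
    mutate(
      pr_percent = reduction_rate(.data$x_lf, .data$x_hf),
      sfsi = .data$pr_percent / 100 / si
    ) |>
    select("genotype", "x_lf", "x_hf", "pr_percent", "sfsi") |>
    arrange(.data$sfsi, .data$genotype)

  structure(
    out,
    trait = attr(means, "trait"),
    check_id = attr(means, "check_id"),
    si = si,
    y_lf_bar = mean(means$x_lf),
    y_hf_bar = mean(means$x_hf),
    mean_pr = mean(out$pr_percent),
    mean_sfsi = mean(out$sfsi),
    flagged = flagged,
    class = c("sfsi_table", class(tibble()))
  )
}

#' @export
print.sfsi_table <- function(x, ...) {
  trait <- attr(x, "trait") %||% "trait"
  cat(sprintf(
    "# SFSI table: %s, %d genotypes\n# SI = %.3f (grand means %.1f LF / %.1f HF g plant^-1); mean PR = %.1f%%, mean SFSI = %.2f\n",
    trait, nrow(x), attr(x, "si"), attr(x, "y_lf_bar"), attr(x, "y_hf_bar"),
    attr(x, "mean_pr"), attr(x, "mean_sfsi")
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Classify genotypes as tolerant, intermediate or susceptible
#'
#' Labels each genotype relative to the check variety. The default rule:
#' *tolerant* iff its SFSI is strictly below the check's SFSI and (when
#' `tolerant_requires_low_pr` is set) its percent reduction is below the
#' table's mean PR -- low relative susceptibility combined with a low
#' absolute loss; *susceptible* iff SFSI >= `susceptible_sfsi_min`
#' (genotypes losing far more than the population average, typically strong
#' fertilizer responders); everything else *intermediate*. The check itself
#' is labelled `"check"`.
#'
#' @param idx An [sfsi_table()].
#' @param check_id Genotype ID of the check; defaults to the table's own
#'   `check_id` attribute.
#' @param susceptible_sfsi_min SFSI threshold at or above which a genotype
#'   is labelled susceptible (default 1.25).
#' @param tolerant_requires_low_pr Require PR below the table mean PR for
#'   the tolerant label (default `TRUE`).
#' @return A tibble of class `tolerance_report` with columns `genotype`,
#'   `pr_percent`, `sfsi`, `label`, and attributes `check_sfsi`,
#'   `thresholds`.
#' @examples
#' classify_tolerance(sfsi_table(yam_trial_means("tuber_yield")))
#' @export
classify_tolerance <- function(idx, check_id = NULL, susceptible_sfsi_min = 1.25,
                               tolerant_requires_low_pr = TRUE) {
  check_id <- check_id %||% attr(idx, "check_id")
  if (is.null(check_id) || !check_id %in% idx$genotype) {
    abort("A check genotype present in the table is required for classification.",
      class = "sfsi_config_error"
    )
  }
  check_sfsi <- idx$sfsi[idx$genotype == check_id]
  mean_pr <- attr(idx, "mean_pr") %||% mean(idx$pr_percent)

  pr_ok <- if (tolerant_requires_low_pr) idx$pr_percent < mean_pr else TRUE
  label <- dplyr::case_when(
    idx$genotype == check_id ~ "check",
    idx$sfsi >= susceptible_sfsi_min ~ "susceptible",
    idx$sfsi < check_sfsi & pr_ok ~ "tolerant",
    TRUE ~ "intermediate"
  )

  structure(
    tibble(
      genotype = idx$genotype,
      pr_percent = idx$pr_percent,
      sfsi = idx$sfsi,
      label = factor(label, levels = c("tolerant", "intermediate", "susceptible", "check"))
    ),
    check_id = check_id,
    check_sfsi = check_sfsi,
    thresholds = list(
      susceptible_sfsi_min = susceptible_sfsi_min,
      tolerant_requires_low_pr = tolerant_requires_low_pr,
      mean_pr = mean_pr
    ),
    class = c("tolerance_report", class(tibble()))
  )
}

#' @export
print.tolerance_report <- function(x, ...) {
  cat(sprintf(
    "# Tolerance classification vs check '%s' (check SFSI = %.2f)\n",
    attr(x, "check_id"), attr(x, "check_sfsi")
  ))
  print(as_tibble(x), ...)
  invisible(x)
}

#' Pearson correlation between per-genotype values
#'
#' Pearson's r with a two-sided p-value from the t distribution on n - 2
#' degrees of freedom, for paired per-genotype summaries (e.g. LF trait
#' means of two traits, or the SFSI columns of two traits).
#'
#' @param x,y Paired numeric vectors, n >= 3, finite, non-constant.
#' @return A one-row tibble with `r`, `p_value`, `n`, `df`.
#' @examples
#' tub <- sfsi_table(yam_trial_means("tuber_yield"))
#' sho <- sfsi_table(yam_trial_means("shoot_dry_weight"))
#' m <- match(tub$genotype, sho$genotype)
#' trait_correlation(tub$sfsi, sho$sfsi[m])
#' @export
trait_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must be paired vectors of equal length.", class = "sfsi_config_error")
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) {
    abort("At least 3 complete pairs are required.", class = "sfsi_design_error")
  }
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a zero-variance vector.",
      class = "sfsi_undefined_correlation"
    )
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  tibble(
    r = unname(ct$estimate),
    p_value = ct$p.value,
    n = n,
    df = unname(ct$parameter)
  )
}
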