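#' Broom-style tidiers for index tables and reports
#'
#' `tidy()` returns the per-genotype rows as a plain tibble; `glance()`
#' returns a one-row population-level summary.
#'
#' @param x An `sfsi_table`, `genotype_means`, `tolerance_report`,
#'   `dunnett_result` or `recovery_summary` object.
#' @param ... Unused.
#' @return A tibble.
#' @name sfsi-tidiers
NULL

#' @rdname sfsi-tidiers
#' @method tidy sfsi_table
#' @export
tidy.sfsi_table <- function(x, ...) as_tibble(x)

#' @rdname sfsi-tidiers
#' @method glance sfsi_table
#' @export
glance.sfsi_table <- function(x, ...) {
  tibble(
    trait = attr(x, "trait") %||% NA_character_,
    n_genotypes = nrow(x),
    y_lf_bar = attr(x, "y_lf_bar"),
    y_hf_bar = attr(x, "y_hf_bar"),
    si = attr(x, "si"),
    mean_pr = attr(x, "mean_pr"),
    mean_sfsi = attr(x, "mean_sfsi"),
    n_flagged = nrow(attr(x, "flagged"))
  )
}

#' @rdname sfsi-tidiers
#' @method tidy genotype_means
#' @export
tidy.genotype_means <- function(x, ...) as_tibble(x)

#' @rdname sfsi-tidiers
#' @method glance genotype_means
#' @export
glance.genotype_means <- function(x, ...) {
  tibble(
    trait = attr(x, "trait") %||% NA_character_,
    n_genotypes = nrow(x),
    n_excluded = nrow(excluded_genotypes(x))
  )
}

#' @rdname sfsi-tidiers
#' @method tidy tolerance_report
#' @export
tidy.tolerance_report <- function(x, ...) as_tibble(x)

#' @rdname sfsi-tidiers
#' @method glance tolerance_report
#' @export
glance.tolerance_report <- function(x, ...) {
  counts <- table(x$label)
  thr <- attr(x, "thresholds")
  tibble(
    check_id = attr(x, "check_id"),
    check_sfsi = attr(x, "check_sfsi"),
    susceptible_sfsi_min = thr$susceptible_sfsi_min,
    tolerant_requires_low_pr = thr$tolerant_requires_low_pr,
    n_tolerant = counts[["tolerant"]],
    n_intermediate = counts[["intermediate"]],
    n_susceptible = counts[["susceptible"]]
  )
}

#' @rdname sfsi-tidiers
#' @method tidy dunnett_result
#' @export
tidy.dunnett_result <- function(x, ...) as_tibble(x)

#' @rdname sfsi-tidiers
#' @method glance dunnett_result
#' @export
glance.dunnett_result <- function(x, ...) {
  tibble(
    check_id = attr(x, "check_id"),
    treatment = attr(x, "treatment"),
    alpha = attr(x, "alpha"),
    n_comparisons = nrow(x),
    n_significant = sum(x$adj_p < attr(x, "alpha"))
  )
}

#' @rdname sfsi-tidiers
#' @method tidy recovery_summary
#' @export
tidy.recovery_summary <- function(x, ...) as_tibble(x)

#' @rdname sfsi-tidiers
#' @method glance recovery_summary
#' @export
glance.recovery_summary <- function(x, ...) {
  tibble(
    n_sims = attr(x, "n_sims"),
    n_genotypes = nrow(x),
    overall_rmse = attr(x, "overall_rmse"),
    max_abs_bias = max(abs(x$bias))
  )
}
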