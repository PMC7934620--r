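#' Assemble and validate a plot-level trial dataset
#'
#' A trial dataset is a long tibble of subplot (or per-plant) observations
#' from a two-treatment fertility trial: one row per observational unit with
#' design columns `genotype`, `year`, `treatment`, `rep` (and optionally
#' `plant`), plus one numeric column per trait in g plant^-1. The
#' constructor validates the design (exactly the two declared treatment
#' levels, replicates >= 1, finite non-negative trait values) and attaches a
#' machine-readable validation report.
#'
#' @param records A data frame with the design columns and trait columns.
#' @param traits Character vector of trait column names. Defaults to every
#'   numeric column that is not a design column.
#' @param check_id Identifier of the check (reference) variety, or `NULL` if
#'   the trial has no check; check-relative operations require it. Must be
#'   present among the genotypes when supplied.
#' @param treatment_labels Named character vector `c(low = ..., high = ...)`
#'   declaring which treatment label is the low-input and which the
#'   high-input level. Orientation is never inferred from the data.
#' @return A tibble of class `trial_dataset` with attributes `traits`,
#'   `check_id`, `treatment_labels` and `validation` (a tibble of warnings,
#'   see [validation_report()]).
#' @seealso [read_trial_csv()], [genotype_treatment_means()]
#' @examples
#' rec <- expand.grid(
#'   genotype = c("G1", "G2"), year = 2018:2019,
#'   treatment = c("LF", "HF"), rep = 1:2, stringsAsFactors = FALSE
#' )
#' rec$tuber_yield <- 900 + seq_len(nrow(rec))
#' trial_dataset(rec, check_id = "G1")
#' @export
trial_dataset <- function(records, traits = NULL, check_id = NULL,
                          treatment_labels = c(low = "LF", high = "HF")) {
  records <- as_tibble(records)
  design_cols <- c("genotype", "year", "treatment", "rep", "plant")
  missing_cols <- setdiff(c("genotype", "year", "treatment", "rep"), names(records))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Missing required design column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "sfsi_schema_error"
    )
  }
  if (!all(c("low", "high") %in% names(treatment_labels))) {
    abort("`treatment_labels` must be a named vector with elements 'low' and 'high'.",
      class = "sfsi_config_error"
    )
  }
  treatment_labels <- treatment_labels[c("low", "high")]

  if (is.null(traits)) {
    traits <- names(records)[vapply(records, is.numeric, logical(1))]
    traits <- setdiff(traits, design_cols)
  }
  if (length(traits) == 0) {
    abort("No trait columns found or declared.", class = "sfsi_schema_error")
  }
  absent <- setdiff(traits, names(records))
  if (length(absent) > 0) {
    abort(sprintf("Declared trait column(s) not in data: %s.", paste(absent, collapse = ", ")),
      class = "sfsi_schema_error"
    )
  }

  levels_seen <- sort(unique(as.character(records$treatment)))
  if (length(levels_seen) != 2) {
    abort(
      sprintf(
        "Treatment column must have exactly 2 levels, found %d (%s).",
        length(levels_seen), paste(levels_seen, collapse = ", ")
      ),
      class = "sfsi_design_error"
    )
  }
  if (!setequal(levels_seen, unname(treatment_labels))) {
    abort(
      sprintf(
        "Treatment levels in data (%s) do not match declared labels (%s).",
        paste(levels_seen, collapse = ", "), paste(treatment_labels, collapse = ", ")
      ),
      class = "sfsi_design_error"
    )
  }

  records$genotype <- as.character(records$genotype)
  records$year <- as.integer(records$year)
  records$treatment <- as.character(records$treatment)
  records$rep <- as.integer(records$rep)
  if (any(is.na(records$rep)) || any(records$rep < 1)) {
    abort("Replicate identifiers must be integers >= 1.", class = "sfsi_design_error")
  }

  for (tr in traits) {
    v <- records[[tr]]
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad) > 0) {
      abort(
        sprintf(
          "Trait '%s' has %d non-finite or negative value(s) (first at row %d); trait values must be finite and >= 0 g plant^-1.",
          tr, length(bad), bad[1]
        ),
        class = "sfsi_validation_error"
      )
    }
  }

  if (!is.null(check_id) && !check_id %in% records$genotype) {
    abort(sprintf("check_id '%s' is not among the genotypes.", check_id),
      class = "sfsi_config_error"
    )
  }

  validation <- attr(records, "validation") %||%
    tibble(row = integer(), column = character(), issue = character())

  structure(
    records,
    traits = traits,
    check_id = check_id,
    treatment_labels = treatment_labels,
    validation = validation,
    class = c("trial_dataset", class(tibble())))
}

#' Read a plot-level trial CSV
#'
#' Reads a long-format CSV (UTF-8, header row, one row per subplot or
#' plant), maps its columns onto the canonical schema, parses trait values
#' and validates the design. Trait cells that cannot be parsed as numbers
#' are recorded as missing in the validation report -- never dropped
#' silently.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names (`genotype`, `year`, `treatment`, `rep`, optionally `plant` and
#'   trait names) to the column names used in the file, e.g.
#'   `c(genotype = "entry", rep = "block")`. Unmapped columns keep their
#'   file names.
#' @inheritParams trial_dataset
#' @return A [trial_dataset()].
#' @export
read_trial_csv <- function(path, schema = NULL, traits = NULL, check_id = NULL,
                           treatment_labels = c(low = "LF", high = "HF")) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "sfsi_schema_error")
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0 || ncol(raw) == 0) {
    abort(sprintf("File '%s' has no data rows.", path), class = "sfsi_schema_error")
  }

  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src) > 0) {
      abort(
        sprintf("Mapped column(s) absent from file: %s.", paste(missing_src, collapse = ", ")),
        class = "sfsi_schema_error"
      )
    }
    for (canonical in names(schema)) {
      names(raw)[names(raw) == schema[[canonical]]] <- canonical
    }
  }
  required <- c("genotype", "year", "treatment", "rep")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(
      sprintf("Missing mapped column(s): %s.", paste(missing_cols, collapse = ", ")),
      class = "sfsi_schema_error"
    )
  }

  design_cols <- intersect(c("genotype", "year", "treatment", "rep", "plant"), names(raw))
  trait_cols <- traits %||% setdiff(names(raw), design_cols)

  report <- tibble(row = integer(), column = character(), issue = character())
  for (tr in trait_cols) {
    txt <- raw[[tr]]
    num <- suppressWarnings(as.numeric(txt))
    unparseable <- which(is.na(num) & !is.na(txt) & !txt %in% c("", "NA", "NaN"))
    if (length(unparseable) > 0) {
      report <- bind_rows(report, tibble(
        row = unparseable, column = tr,
        issue = sprintf("unparseable trait value '%s' recorded as missing", txt[unparseable])
      ))
    }
    raw[[tr]] <- num
  }
  raw$year <- as.integer(raw$year)
  raw$rep <- as.integer(raw$rep)
  if ("plant" %in% names(raw)) raw$plant <- as.integer(raw$plant)
  attr(raw, "validation") <- report

  trial_dataset(raw,
    traits = trait_cols, check_id = check_id,
    treatment_labels = treatment_labels
  )
}

#' Write a trial dataset to CSV
#'
#' Writes the records in the canonical long format. Numeric trait values are
#' written with round-trip precision, so `read_trial_csv()` on the result
#' recovers the dataset exactly.
#'
#' @param ds A [trial_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(ds, path) {
  readr::write_csv(as_tibble(ds), path, progress = FALSE)
  invisible(path)
}

#' Validation report of a dataset or result
#'
#' Exclusions and data warnings accumulated while reading, validating or
#' summarising trial data, as a machine-readable tibble. An empty tibble
#' means a clean dataset.
#'
#' @param x A `trial_dataset` or `genotype_means` object.
#' @return A tibble of recorded issues.
#' @export
validation_report <- function(x) {
  attr(x, "validation") %||% tibble(row = integer(), column = character(), issue = character())
}

#' Per-genotype treatment means
#'
#' Computes, for one trait, the mean value of each genotype under the low
#' and high input treatments: the x_lf and x_hf that feed the reduction
#' rate and susceptibility index. Means are unweighted arithmetic means
#' pooled over all non-missing observations across years, replicates and
#' plants (with the balanced design of a standard two-year trial this
#' coincides with the mean of year means).
#'
#' A genotype with zero usable observations under either treatment is
#' excluded from the table and listed in the exclusion report (see
#' [excluded_genotypes()]); it is never imputed.
#'
#' @param data A [trial_dataset()], or any data frame with `genotype` and
#'   `treatment` columns plus the trait column.
#' @param trait Name of the trait column to summarise.
#' @param treatment_labels Low/high labels; taken from the dataset when it
#'   is a `trial_dataset`.
#' @return A tibble of class `genotype_means` with columns `genotype`,
#'   `x_lf`, `x_hf`, `n_lf`, `n_hf` and attributes `trait`, `check_id`,
#'   `excluded`.
#' @examples
#' d <- tibble::tibble(
#'   genotype = rep(c("A", "B"), each = 4),
#'   year = 2018L, rep = 1L,
#'   treatment = rep(c("LF", "LF", "HF", "HF"), 2),
#'   yield = c(800, 900, 1500, 1700, 500, 700, 1000, 1400)
#' )
#' genotype_treatment_means(d, "yield")
#' @export
genotype_treatment_means <- function(data, trait,
                                     treatment_labels = c(low = "LF", high = "HF")) {
  stopifnot_scalar_string(trait, "trait")
  if (inherits(data, "trial_dataset")) {
    treatment_labels <- attr(data, "treatment_labels")
    if (!trait %in% attr(data, "traits")) {
      abort(sprintf("Trait '%s' is not declared in the dataset.", trait),
        class = "sfsi_schema_error"
      )
    }
  }
  if (!trait %in% names(data)) {
    abort(sprintf("Trait column '%s' not found.", trait), class = "sfsi_schema_error")
  }

  low <- unname(treatment_labels[["low"]])
  high <- unname(treatment_labels[["high"]])

  per <- as_tibble(data) |>
    group_by(.data$genotype, .data$treatment) |>
    summarise(
      mean = mean(.data[[trait]], na.rm = TRUE),
      n = sum(!is.na(.data[[trait]])),
      .groups = "drop"
    )

  wide <- per |>
    tidyr::pivot_wider(
      names_from = "treatment",
      values_from = c("mean", "n"),
      values_fill = list(n = 0L)
    )
  for (col in paste0(c("mean_", "n_"), rep(c(low, high), each = 2))) {
    if (!col %in% names(wide)) wide[[col]] <- if (startsWith(col, "n_")) 0L else NA_real_
  }
  out <- tibble(
    genotype = wide$genotype,
    x_lf = wide[[paste0("mean_", low)]],
    x_hf = wide[[paste0("mean_", high)]],
    n_lf = wide[[paste0("n_", low)]],
    n_hf = wide[[paste0("n_", high)]]
  )

  unusable <- out$n_lf < 1 | out$n_hf < 1 | !is.finite(out$x_lf) | !is.finite(out$x_hf)
  excluded <- tibble(
    genotype = out$genotype[unusable],
    reason = dplyr::if_else(out$n_lf[unusable] < 1,
      "no usable observations under low treatment",
      "no usable observations under high treatment"
    )
  )
  if (nrow(excluded) > 0) {
    warn(
      sprintf(
        "%d genotype(s) excluded for lack of observations: %s.",
        nrow(excluded), paste(excluded$genotype, collapse = ", ")
      ),
      class = "sfsi_exclusion_warning"
    )
  }
  out <- out[!unusable, , drop = FALSE] |> arrange(.data$genotype)

  new_genotype_means(out,
    trait = trait,
    check_id = if (inherits(data, "trial_dataset")) attr(data, "check_id") else NULL,
    excluded = excluded
  )
}

new_genotype_means <- function(df, trait, check_id = NULL,
                               excluded = tibble(genotype = character(), reason = character())) {
  structure(
    as_tibble(df),
    trait = trait,
    check_id = check_id,
    excluded = excluded,
    class = c("genotype_means", class(tibble()))
  )
}

#' Genotypes excluded from a means table
#'
#' @param means A `genotype_means` object.
#' @return Tibble with columns `genotype` and `reason`.
#' @export
excluded_genotypes <- function(means) {
  attr(means, "excluded") %||% tibble(genotype = character(), reason = character())
}
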