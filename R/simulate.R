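#' Configure a synthetic split-plot fertility trial
#'
#' Defines the generating parameters of a two-treatment split-plot trial
#' with known genotype-level truth. The design mirrors a standard two-year
#' screening trial: fertility treatments on main plots, genotypes on
#' subplots, several plants per subplot, with additive year,
#' year-by-treatment, replicate (block), main-plot and residual effects on
#' the trait scale (all Gaussian). Effects are additive -- no log link --
#' so the implied true PR and SFSI stay analytic.
#'
#' Defaults reproduce the packaged yam trial's conditions: 21 genotypes
#' whose high-input means and reduction fractions are read from the
#' packaged tuber-yield table, 2 years x 2 replicates x 3 plants, and noise
#' standard deviations (residual 500, main plot 150, block 100 g plant^-1,
#' year effects +/-150, year-by-treatment +/-50) chosen so that
#' per-genotype low-vs-high Welch tests at n = 12 land in the range of
#' p-values typical of such trials.
#'
#' @param n_genotypes Number of genotypes; inferred from
#'   `genotype_hf_means` when that is given.
#' @param genotype_hf_means True mean trait value per genotype under the
#'   high-input treatment (g plant^-1, all > 0). Default: the packaged
#'   tuber-yield HF means.
#' @param reduction_fractions Per-genotype true fractional loss under low
#'   input, each < 1; true low mean is `(1 - fraction) * hf_mean`. Default:
#'   the packaged tuber-yield reductions.
#' @param genotype_ids Genotype labels; default the packaged IDs or
#'   `G01...`.
#' @param check_id Check variety label carried into the dataset.
#' @param trait Trait column name for the generated data.
#' @param year_effects Additive year effect per year (g plant^-1, applied
#'   to both treatments); length `n_years`. Defaults sum to zero so the
#'   configured genotype means are also the marginal expectations.
#' @param year_by_treatment_effects Additional effect of the high-input
#'   treatment in each year (g plant^-1); length `n_years`.
#' @param replicate_sd,mainplot_sd,residual_sd Standard deviations of the
#'   block (year x rep), main-plot (year x rep x treatment) and residual
#'   effects, all >= 0 g plant^-1.
#' @param n_years,n_reps,plants_per_subplot Design sizes, all >= 1.
#' @param treatment_labels Low/high treatment labels.
#' @param seed Integer seed of the root generator. Sub-streams per stratum
#'   are derived deterministically, so adding genotypes does not reshuffle
#'   the noise of existing ones.
#' @return A list of class `sim_config`.
#' @seealso [simulate_trial()], [sim_truth()], [recovery_experiment()]
#' @export
sim_config <- function(n_genotypes = NULL,
                       genotype_hf_means = NULL,
                       reduction_fractions = NULL,
                       genotype_ids = NULL,
                       check_id = NULL,
                       trait = "tuber_yield",
                       year_effects = c(150, -150),
                       year_by_treatment_effects = c(50, -50),
                       replicate_sd = 100,
                       mainplot_sd = 150,
                       residual_sd = 500,
                       n_years = 2,
                       n_reps = 2,
                       plants_per_subplot = 3,
                       treatment_labels = c(low = "LF", high = "HF"),
                       seed = 1L) {
  if (is.null(genotype_hf_means)) {
    if (is.null(n_genotypes)) {
      ref <- yam_trial_means("tuber_yield")
      genotype_hf_means <- ref$x_hf
      reduction_fractions <- reduction_fractions %||% (1 - ref$x_lf / ref$x_hf)
      genotype_ids <- genotype_ids %||% ref$genotype
      check_id <- check_id %||% attr(ref, "check_id")
    } else {
      genotype_hf_means <- seq(1100, 2600, length.out = n_genotypes)
      reduction_fractions <- reduction_fractions %||%
        seq(0.33, 0.70, length.out = n_genotypes)
    }
  }
  n_genotypes <- length(genotype_hf_means)
  if (is.null(reduction_fractions)) {
    reduction_fractions <- rep(0.5, n_genotypes)
  }
  if (length(reduction_fractions) != n_genotypes) {
    abort("`reduction_fractions` must match `genotype_hf_means` in length.",
      class = "sfsi_config_error"
    )
  }
  if (any(!is.finite(genotype_hf_means)) || any(genotype_hf_means <= 0)) {
    abort("All configured high-input means must be positive.", class = "sfsi_config_error")
  }
  if (any(reduction_fractions >= 1)) {
    abort("Reduction fractions must be < 1 (true low means must stay >= 0).",
      class = "sfsi_config_error"
    )
  }
  if (any(c(replicate_sd, mainplot_sd, residual_sd) < 0)) {
    abort("Noise standard deviations must be >= 0.", class = "sfsi_config_error")
  }
  if (any(c(n_years, n_reps, plants_per_subplot) < 1)) {
    abort("n_years, n_reps and plants_per_subplot must be >= 1.",
      class = "sfsi_config_error"
    )
  }
  recycle <- function(x, n) if (length(x) == 1) rep(x, n) else x
  year_effects <- recycle(year_effects, n_years)
  year_by_treatment_effects <- recycle(year_by_treatment_effects, n_years)
  if (length(year_effects) != n_years || length(year_by_treatment_effects) != n_years) {
    abort("Year effect vectors must have length n_years.", class = "sfsi_config_error")
  }
  genotype_ids <- genotype_ids %||% sprintf("G%02d", seq_len(n_genotypes))
  if (length(genotype_ids) != n_genotypes) {
    abort("`genotype_ids` must match the number of genotypes.", class = "sfsi_config_error")
  }

  structure(
    list(
      n_genotypes = n_genotypes,
      genotype_ids = genotype_ids,
      genotype_hf_means = genotype_hf_means,
      reduction_fractions = reduction_fractions,
      check_id = check_id,
      trait = trait,
      year_effects = year_effects,
      year_by_treatment_effects = year_by_treatment_effects,
      replicate_sd = replicate_sd,
      mainplot_sd = mainplot_sd,
      residual_sd = residual_sd,
      n_years = n_years,
      n_reps = n_reps,
      plants_per_subplot = plants_per_subplot,
      treatment_labels = treatment_labels,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Read a simulation configuration from YAML or JSON
#'
#' @param path A `.yml`/`.yaml` or `.json` file whose keys are
#'   [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "sfsi_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  args <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("Config must be a .yaml/.yml or .json file.", class = "sfsi_config_error")
  )
  unknown <- setdiff(names(args), names(formals(sim_config)))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s.", paste(unknown, collapse = ", ")),
      class = "sfsi_config_error"
    )
  }
  do.call(sim_config, args)
}

#' True per-genotype indices implied by a simulation configuration
#'
#' Computes analytically -- never from a simulated sample -- the true
#' genotype means under each treatment (configured means plus the average
#' year and year-by-treatment effects), the true percent reduction, the
#' population stress intensity and the true SFSI, via the same index
#' formulas used on observed data.
#'
#' @param cfg A [sim_config()].
#' @return A tibble with `genotype`, `x_lf`, `x_hf`, `pr_percent`, `sfsi`
#'   and attribute `si`.
#' @export
sim_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ye <- mean(cfg$year_effects)
  yte <- mean(cfg$year_by_treatment_effects)
  x_hf <- cfg$genotype_hf_means + ye + yte
  x_lf <- (1 - cfg$reduction_fractions) * cfg$genotype_hf_means + ye
  truth <- new_genotype_means(
    tibble(
      genotype = cfg$genotype_ids, x_lf = x_lf, x_hf = x_hf,
      n_lf = NA_integer_, n_hf = NA_integer_
    ),
    trait = cfg$trait, check_id = cfg$check_id
  )
  idx <- sfsi_table(truth)
  out <- as_tibble(idx) |> arrange(.data$genotype)
  attr(out, "si") <- attr(idx, "si")
  out
}

#' Simulate a split-plot fertility trial with known truth
#'
#' Generates plant-level observations under the model declared in the
#' configuration: genotype-by-treatment expectation, plus year,
#' year-by-treatment, block, main-plot and residual Gaussian effects.
#' Negative simulated values are clipped at zero (traits are masses) and
#' the clip count reported. The same seed always yields the identical
#' dataset.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `data` (a [trial_dataset()]), `truth`
#'   ([sim_truth()], or `NULL` for a null configuration whose stress
#'   intensity is zero, where no susceptibility truth is defined) and
#'   `n_clipped` (number of values clipped at zero).
#' @examples
#' sim <- simulate_trial(sim_config(n_genotypes = 4, seed = 7))
#' head(sim$data)
#' sim$truth
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  low <- unname(cfg$treatment_labels[["low"]])
  high <- unname(cfg$treatment_labels[["high"]])
  years <- seq_len(cfg$n_years)
  reps <- seq_len(cfg$n_reps)
  plants <- seq_len(cfg$plants_per_subplot)

  # block and main-plot random effects, each from its own sub-stream
  blocks <- tidyr::expand_grid(year = years, rep = reps)
  set.seed(substream_seed(cfg$seed, 1L))
  blocks$block_eff <- rnorm(nrow(blocks), 0, cfg$replicate_sd)
  mains <- tidyr::expand_grid(year = years, rep = reps, treatment = c(low, high))
  set.seed(substream_seed(cfg$seed, 2L))
  mains$mainplot_eff <- rnorm(nrow(mains), 0, cfg$mainplot_sd)

  per_genotype <- purrr::map(seq_len(cfg$n_genotypes), function(g) {
    grid <- tidyr::expand_grid(
      year = years, rep = reps, treatment = c(low, high), plant = plants
    )
    set.seed(substream_seed(cfg$seed, 100L + g))
    grid$resid <- rnorm(nrow(grid), 0, cfg$residual_sd)
    grid$genotype <- cfg$genotype_ids[g]
    hf_mu <- cfg$genotype_hf_means[g]
    grid$mu <- ifelse(grid$treatment == high, hf_mu,
      (1 - cfg$reduction_fractions[g]) * hf_mu
    ) +
      cfg$year_effects[grid$year] +
      ifelse(grid$treatment == high, cfg$year_by_treatment_effects[grid$year], 0)
    grid
  }) |>
    purrr::list_rbind() |>
    left_join(blocks, by = c("year", "rep")) |>
    left_join(mains, by = c("year", "rep", "treatment"))

  value <- per_genotype$mu + per_genotype$block_eff +
    per_genotype$mainplot_eff + per_genotype$resid
  n_clipped <- sum(value < 0)
  if (n_clipped > 0) {
    inform(sprintf("%d simulated value(s) clipped at 0 g plant^-1.", n_clipped))
  }
  value <- pmax(value, 0)

  records <- tibble(
    genotype = per_genotype$genotype,
    year = 2017L + per_genotype$year,
    treatment = per_genotype$treatment,
    rep = per_genotype$rep,
    plant = per_genotype$plant
  )
  records[[cfg$trait]] <- value

  list(
    data = trial_dataset(records,
      traits = cfg$trait, check_id = cfg$check_id,
      treatment_labels = cfg$treatment_labels
    ),
    truth = tryCatch(sim_truth(cfg),
      sfsi_stress_orientation_error = function(e) NULL
    ),
    n_clipped = n_clipped
  )
}

#' SFSI recovery experiment
#'
#' Repeatedly simulates a trial, runs the estimation pipeline (treatment
#' means then [sfsi_table()]) and compares the estimated SFSI of every
#' genotype to its analytic truth. Reports per-genotype bias and RMSE; with
#' more replicates or years at fixed noise the RMSE shrinks.
#'
#' @param cfg A [sim_config()]. Its own seed is ignored; per-simulation
#'   seeds are derived from `seed`.
#' @param n_sims Number of simulated trials (>= 1).
#' @param seed Root seed for the experiment.
#' @return A tibble of class `recovery_summary` with columns `genotype`,
#'   `true_sfsi`, `mean_estimate`, `bias`, `rmse`; attributes `n_sims` and
#'   `overall_rmse`.
#' @export
recovery_experiment <- function(cfg, n_sims = 200, seed = 1L) {
  stopifnot(inherits(cfg, "sim_config"), n_sims >= 1)
  truth <- sim_truth(cfg)

  est <- purrr::map(seq_len(n_sims), function(s) {
    cfg_s <- cfg
    cfg_s$seed <- substream_seed(seed, 1000L + s)
    sim <- simulate_trial(cfg_s)
    idx <- sfsi_table(genotype_treatment_means(sim$data, cfg$trait))
    tibble(sim = s, genotype = idx$genotype, estimate = idx$sfsi)
  }) |>
    purrr::list_rbind()

  out <- est |>
    group_by(.data$genotype) |>
    summarise(mean_estimate = mean(.data$estimate), .groups = "drop") |>
    left_join(
      est |>
        left_join(select(truth, "genotype", true_sfsi = "sfsi"), by = "genotype") |>
        group_by(.data$genotype) |>
        summarise(
          true_sfsi = .data$true_sfsi[1],
          bias = mean(.data$estimate - .data$true_sfsi),
          rmse = sqrt(mean((.data$estimate - .data$true_sfsi)^2)),
          .groups = "drop"
        ),
      by = "genotype"
    ) |>
    select("genotype", "true_sfsi", "mean_estimate", "bias", "rmse") |>
    arrange(.data$genotype)

  structure(
    out,
    n_sims = n_sims,
    overall_rmse = sqrt(mean(out$rmse^2)),
    class = c("recovery_summary", class(tibble()))
  )
}
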