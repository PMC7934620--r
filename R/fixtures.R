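# Checksums of the packaged reference tables, recorded at packaging time.
.yam_fixture_md5 <- c(
  tuber_yield = "1afaf3b4965d3ec20e2ca6fd59fc01e0",
  shoot_dry_weight = "a28ef9b8d2258f7a9e91524f709c8df1"
)

#' Packaged yam fertility-trial genotype means
#'
#' Genotype-mean trait values from a two-year split-plot evaluation of 21
#' white Guinea yam (*Dioscorea rotundata*) genotypes -- 20 advanced
#' breeding lines (R025..R141) and the local check variety (the landrace
#' Amula, labelled "Local variety") -- grown under low (no fertilizer,
#' nutrient-depleted soil) and high (NPK-fertilized) fertility at Ibadan,
#' Nigeria. Two traits are packaged: fresh tuber yield at harvest and shoot
#' dry weight at 150 days after planting, both in g plant^-1. Each mean
#' pools n = 12 observations (3 plants x 2 replicates x 2 years).
#'
#' The source tables also print per-genotype percent reduction (PR),
#' LF-vs-HF p-values and SFSI; these printed columns are attached as the
#' `printed` attribute so recomputed values can be compared against them
#' (see [reproduce_reference()]). Note that a few printed shoot SFSI cells
#' are internally inconsistent with their own printed PR; recomputation from
#' the LF/HF means is the authoritative path.
#'
#' @param trait `"tuber_yield"` or `"shoot_dry_weight"`.
#' @return A [genotype_treatment_means()]-style `genotype_means` tibble with
#'   21 rows, `check_id = "Local variety"`, and attribute `printed` (tibble
#'   of the published PR, p-value and SFSI columns).
#' @examples
#' yam_trial_means("tuber_yield")
#' @export
yam_trial_means <- function(trait = c("tuber_yield", "shoot_dry_weight")) {
  trait <- match.arg(trait)
  path <- system.file("extdata", sprintf("yam_%s_means.csv", trait),
    package = "sfsi", mustWork = TRUE
  )
  if (!identical(unname(tools::md5sum(path)), unname(.yam_fixture_md5[[trait]]))) {
    warn(sprintf("Checksum mismatch for packaged fixture '%s'.", trait),
      class = "sfsi_fixture_warning"
    )
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(
      genotype = readr::col_character(),
      .default = readr::col_double()
    ),
    progress = FALSE
  )
  out <- new_genotype_means(
    tibble(
      genotype = raw$genotype,
      x_lf = raw$lf_mean, x_hf = raw$hf_mean,
      n_lf = 12L, n_hf = 12L
    ),
    trait = trait, check_id = "Local variety"
  )
  attr(out, "printed") <- tibble(
    genotype = raw$genotype,
    pr = raw$pr_printed,
    p_value = raw$p_value_printed,
    sfsi = raw$sfsi_printed
  )
  out
}

#' Published summary values of the packaged yam trial
#'
#' Key figures reported for the packaged reference trial, used by
#' [reproduce_reference()] to check recomputation: overall percent
#' reduction per trait, the SFSI range and mean for tuber yield, the check
#' variety's SFSI per trait, the named tolerant and susceptible genotype
#' sets, and the three cross-trait Pearson correlations (shoot vs tuber
#' under LF and HF, and shoot SFSI vs tuber SFSI).
#'
#' @return A named list of reference values.
#' @export
yam_reference_values <- function() {
  list(
    overall_reduction_percent = c(tuber_yield = 51.9, shoot_dry_weight = 34.7),
    sfsi_range = list(
      tuber_yield = c(min = 0.64, max = 1.34),
      shoot_dry_weight = c(min = 0.60, max = 1.30)
    ),
    sfsi_mean = c(tuber_yield = 0.98, shoot_dry_weight = 0.99),
    check_sfsi = c(tuber_yield = 0.87, shoot_dry_weight = 0.88),
    tolerant = c("R034", "R041", "R050", "R052", "R060", "R100", "R125"),
    susceptible = c("R109", "R119", "R131"),
    correlations = c(lf_means = 0.69, hf_means = 0.75, sfsi = 0.71)
  )
}
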