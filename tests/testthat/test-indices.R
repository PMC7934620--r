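test_that("reduction rate matches published genotype rows and basic identities", {
  expect_equal(round_half_up(reduction_rate(908.3, 1363.8), 1), 33.4)
  expect_equal(round_half_up(reduction_rate(755.8, 2500.0), 1), 69.8)

  set.seed(1)
  x <- runif(20, 1, 5000)
  expect_equal(reduction_rate(x, x), rep(0, 20))
  # a genotype doing better under stress has a negative, unclipped rate
  expect_lt(reduction_rate(1200, 1000), 0)
  expect_error(reduction_rate(500, 0), class = "sfsi_undefined_rate")
})

test_that("stress intensity reproduces the published overall reductions", {
  expect_equal(round_half_up(100 * stress_intensity(yam_trial_means("tuber_yield")), 1), 51.9)
  expect_equal(round_half_up(100 * stress_intensity(yam_trial_means("shoot_dry_weight")), 1), 34.7)

  flat <- tibble::tibble(genotype = c("A", "B"), x_lf = c(10, 20), x_hf = c(10, 20))
  expect_error(stress_intensity(flat), class = "sfsi_stress_orientation_error")
  expect_error(stress_intensity(flat[1, ]), class = "sfsi_design_error")
})

test_that("SFSI table reproduces published index values and the check-cell recomputation", {
  tub <- sfsi_table(yam_trial_means("tuber_yield"))
  expect_equal(round_half_up(tub$sfsi[tub$genotype == "R125"], 2), 0.64)
  expect_equal(round_half_up(tub$sfsi[tub$genotype == "R119"], 2), 1.34)
  expect_equal(round_half_up(attr(tub, "mean_sfsi"), 2), 0.98)
  # ascending presentation order, ties broken by genotype ID
  expect_false(is.unsorted(tub$sfsi))
  r131 <- which(tub$genotype == "R131") # shares PR 68.3 with R109
  expect_equal(tub$genotype[r131 - 1], "R109")

  sho <- sfsi_table(yam_trial_means("shoot_dry_weight"))
  expect_equal(round_half_up(attr(sho, "mean_sfsi"), 2), 0.99)
  # the check's published cell (0.08) is a misprint: direct arithmetic from
  # the published LF/HF means is the oracle
  expected_check <- (1 - 104.1 / 150.4) / (1 - 103.3 / 158.2)
  check_sfsi <- sho$sfsi[sho$genotype == "Local variety"]
  # grand means printed to 1 dp bound the oracle's precision
  expect_lt(abs(check_sfsi - expected_check), 0.002)
  expect_equal(round_half_up(check_sfsi, 2), 0.89)

  # a genotype whose PR equals SI x 100 sits exactly at SFSI = 1
  si <- attr(tub, "si")
  tbl <- tibble::tibble(
    genotype = c("A", "B", "C"),
    x_hf = c(1000, 2000, 1500),
    x_lf = c(1000 * (1 - si), 2000 * 0.7, 1500 * 0.2)
  )
  # recalibrate: force the population SI, then give A exactly that reduction
  si2 <- stress_intensity(tbl)
  tbl$x_lf[1] <- 1000 * (1 - si2)
  # fixpoint iteration converges because A's weight in the mean is fixed
  for (i in 1:50) {
    si2 <- stress_intensity(tbl)
    tbl$x_lf[1] <- 1000 * (1 - si2)
  }
  out <- sfsi_table(tbl)
  expect_equal(out$sfsi[out$genotype == "A"], 1, tolerance = 1e-8)
})

test_that("rows with non-positive high-input means are flagged and excluded", {
  tbl <- random_means_table(6, seed = 11)
  tbl$x_hf[3] <- 0
  expect_warning(idx <- sfsi_table(tbl), class = "sfsi_flagged_row_warning")
  expect_equal(nrow(idx), 5)
  expect_equal(attr(idx, "flagged")$genotype, tbl$genotype[3])
})

test_that("index algebra holds on random tables: identity, scale invariance, monotonicity, oracle", {
  for (seed in 1:25) {
    tbl <- random_means_table(sample(5:30, 1), seed = seed)
    idx <- sfsi_table(tbl)
    si <- attr(idx, "si")

    # algebraic identity sfsi x si x 100 = pr
    expect_equal(idx$sfsi * si * 100, idx$pr_percent, tolerance = 1e-10)

    # independent scalar recomputation
    orc <- sfsi_oracle(tbl$x_lf, tbl$x_hf)
    i <- match(idx$genotype, tbl$genotype)
    expect_equal(si, orc$si, tolerance = 1e-12)
    expect_equal(idx$sfsi, orc$sfsi[i], tolerance = 1e-12)
    expect_equal(idx$pr_percent, orc$pr[i], tolerance = 1e-12)

    # multiplying every trait value by c > 0 changes nothing
    c0 <- runif(1, 0.1, 40)
    scaled <- dplyr::mutate(tbl, x_lf = x_lf * c0, x_hf = x_hf * c0)
    idx_s <- sfsi_table(scaled)
    expect_equal(idx_s$sfsi, idx$sfsi, tolerance = 1e-10)
    expect_equal(idx_s$pr_percent, idx$pr_percent, tolerance = 1e-10)
    expect_equal(attr(idx_s, "si"), si, tolerance = 1e-12)
  }

  # holding x_hf fixed, sfsi strictly decreases as x_lf increases
  tbl <- random_means_table(10, seed = 99)
  base <- sfsi_table(tbl)
  grid <- seq(0.5, 1.5, by = 0.1) * tbl$x_lf[4]
  vals <- vapply(grid, function(v) {
    t2 <- tbl
    t2$x_lf[4] <- v
    out <- sfsi_table(t2)
    out$sfsi[out$genotype == tbl$genotype[4]]
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("tolerance classification labels the published sets and degenerate cases", {
  rep_tub <- classify_tolerance(sfsi_table(yam_trial_means("tuber_yield")))
  expect_setequal(
    as.character(rep_tub$genotype[rep_tub$label == "tolerant"]),
    c("R034", "R041", "R050", "R052", "R060", "R100", "R125")
  )
  expect_setequal(
    as.character(rep_tub$genotype[rep_tub$label == "susceptible"]),
    c("R109", "R119", "R131")
  )
  expect_equal(sum(rep_tub$label == "check"), 1)
  # labels are exhaustive and mutually exclusive
  expect_false(any(is.na(rep_tub$label)))

  # every genotype identical to the check: nothing can be tolerant or susceptible
  flat <- tibble::tibble(
    genotype = c("CHK", "A", "B"),
    x_lf = c(600, 600, 600), x_hf = c(1100, 1100, 1100)
  )
  rep_flat <- classify_tolerance(sfsi_table(flat), check_id = "CHK")
  expect_true(all(rep_flat$label[rep_flat$genotype != "CHK"] == "intermediate"))

  expect_error(
    classify_tolerance(sfsi_table(flat), check_id = "nope"),
    class = "sfsi_config_error"
  )
})

test_that("Pearson correlation agrees with the first-principles oracle and handles edge cases", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- trait_correlation(x, y)
    orc <- pearson_oracle(x, y)
    expect_equal(got$r, orc$r, tolerance = 1e-12)
    expect_equal(got$p_value, orc$p, tolerance = 1e-10)
    expect_equal(got$df, n - 2)
  }
  set.seed(3)
  x <- rnorm(10)
  expect_equal(trait_correlation(x, x)$r, 1)
  expect_error(trait_correlation(x, rep(1, 10)), class = "sfsi_undefined_correlation")
  expect_error(trait_correlation(x[1:2], x[1:2]), class = "sfsi_design_error")
})
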