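test_that("division classification is definitional and order-symmetric", {
  expect_equal(as.character(classify_division("basal", "basal")), "SR")
  expect_equal(as.character(classify_division("suprabasal", "suprabasal")),
               "SD")
  expect_equal(as.character(classify_division("basal", "suprabasal")), "AD")
  expect_equal(as.character(classify_division("suprabasal", "basal")), "AD")
  # case-insensitive dialect
  expect_equal(as.character(classify_division("Basal", "BASAL")), "SR")
  expect_error(classify_division("basal", "apical"), "invalid")
  expect_error(classify_division(NA, "basal"), "invalid")
})

test_that("fate fractions match a brute-force tally on arbitrary tables", {
  for (seed in 1:3) {
    ev <- random_events(200, seed)
    f <- estimate_fate_fractions(ev)
    # independent recount
    n_SR <- n_AD <- n_SD <- 0
    for (i in seq_len(nrow(ev))) {
      nb <- (ev$daughter1_layer[i] == "basal") +
        (ev$daughter2_layer[i] == "basal")
      if (nb == 2) n_SR <- n_SR + 1
      else if (nb == 1) n_AD <- n_AD + 1
      else n_SD <- n_SD + 1
    }
    expect_equal(f$f_SR, n_SR / 200)
    expect_equal(f$f_AD, n_AD / 200)
    expect_equal(f$f_SD, n_SD / 200)
    expect_equal(f$n_events, 200L)
    expect_equal(f$f_SR + f$f_AD + f$f_SD, 1, tolerance = 1e-12)
  }
})

test_that("event filters subset correctly and empty selections error", {
  ev <- rbind(make_events(10, 0, 0, context = "clone_edge", week = 10),
              make_events(0, 0, 5, context = "clone_inner", week = 10),
              make_events(0, 8, 0, context = "clone_edge", week = 24))
  f <- estimate_fate_fractions(ev, context = "clone_edge", weeks = 10)
  expect_equal(f$n_events, 10L)
  expect_equal(f$f_SR, 1)
  f2 <- estimate_fate_fractions(ev, context = "clone_edge")
  expect_equal(f2$n_events, 18L)
  expect_error(estimate_fate_fractions(ev, context = "field"),
               "no division events")
  expect_error(estimate_fate_fractions(ev[0, ]), "no division events")
})

test_that("division-based renewal reproduces the measured anchor rates", {
  # oncogenic single cells: 48% SR, 10% SD -> r = 0.69
  hras <- renewal_rate_from_fractions(fate_fractions(0.48, 0.42, 0.10, 100))
  expect_equal(hras$rate, 0.69, tolerance = 1e-12)
  # control: 29/44/27 -> r = 0.51 (~0.5)
  ctrl <- renewal_rate_from_fractions(fate_fractions(0.29, 0.44, 0.27, 100))
  expect_equal(ctrl$rate, 0.51, tolerance = 1e-12)
  # boundary cases
  expect_equal(renewal_rate_from_fractions(fate_fractions(0, 1, 0, 10))$rate,
               0.5)
  expect_equal(renewal_rate_from_fractions(fate_fractions(1, 0, 0, 10))$rate,
               1.0)
  expect_equal(renewal_rate_from_fractions(fate_fractions(0, 0, 1, 10))$rate,
               0.0)
})

test_that("renewal rate is linear and bounded by the SR/SR+AD window", {
  set.seed(41)
  for (i in 1:20) {
    f <- as.numeric(stats::rmultinom(1, 100, runif(3))) / 100
    ff <- fate_fractions(f[1], f[2], f[3], 100)
    r <- renewal_rate_from_fractions(ff)$rate
    expect_gte(r, f[1] - 1e-12)
    expect_lte(r, f[1] + f[2] + 1e-12)
  }
  # r = 0.5 exactly when SR and SD balance
  expect_equal(renewal_rate_from_fractions(
    fate_fractions(0.23, 0.54, 0.23, 50))$rate, 0.5)
})

test_that("population renewal estimator matches a brute-force recount", {
  cells <- random_cells(300, seed = 7)
  est <- renewal_rate_population(cells)
  n_edu <- sum(cells$edu == 1)
  n_prog <- sum(cells$edu == 1 & cells$k10 == 0)
  expect_equal(est$rate, n_prog / n_edu)
  expect_equal(est$n, n_edu)
  expect_equal(est$method, "population_based")
  # all EdU+ cells undifferentiated
  all_prog <- random_cells(50, seed = 8, p_k10 = 0)
  expect_equal(renewal_rate_population(all_prog)$rate, 1.0)
  none <- random_cells(20, seed = 9, p_edu = 0)
  expect_error(renewal_rate_population(none), "EdU")
})

test_that("division-based and population-based estimators agree at scale", {
  # doublets generated at the control fractions: daughters staying basal
  # out of all daughters equals f_SR + f_AD/2 in expectation
  r0 <- 0.29 + 0.44 / 2
  ev <- sample_cfi_dataset(c(0.29, 0.44, 0.27), n_divisions = 10000,
                           seed = 303)
  cells <- data.frame(
    animal_id = "a1", clone_id = NA, cell_id = as.character(1:20000),
    x_um = 0, y_um = 0,
    layer = c(ev$daughter1_layer, ev$daughter2_layer), genotype = "WT",
    edu = 1L, brdu = 0L,
    k10 = as.integer(c(ev$daughter1_layer, ev$daughter2_layer) ==
                       "suprabasal"),
    stringsAsFactors = FALSE)
  pop <- renewal_rate_population(cells)$rate
  div <- renewal_rate_from_fractions(estimate_fate_fractions(ev))$rate
  expect_equal(pop, div, tolerance = 1e-12)  # identical by construction
  se <- sqrt(0.29 + 0.44 / 4 - r0^2) / sqrt(10000)
  expect_lt(abs(div - r0), 3 * se)
})

test_that("proliferation rate counts EdU+ basal cells within the clone", {
  cells <- hex_disc_clone(2)
  expect_equal(proliferation_rate(cells, "clone1"), 0)
  cells$edu <- 1L
  expect_equal(proliferation_rate(cells, "clone1"), 1)
  cells$edu <- rbinom(nrow(cells), 1, 0.5)
  expect_equal(proliferation_rate(cells, "clone1"),
               sum(cells$edu[cells$clone_id == "clone1" &
                               cells$layer == "basal"]) /
                 sum(cells$clone_id == "clone1" & cells$layer == "basal"))
  expect_error(proliferation_rate(cells, "nope"), "basal")
})

test_that("group comparison handles degenerate input and maps bands", {
  same <- compare_groups(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_equal(same$band, "n.s.")
  expect_error(compare_groups(c(1, 1), c(2, 2)), "zero variance")
  expect_error(compare_groups(0.5, c(0.4, 0.6)), "two animal-level")
  expect_equal(significance_band(c(0.2, 0.03, 0.005, 5e-4, 5e-5)),
               c("n.s.", "*", "**", "***", "****"))
  # agrees with stats::t.test
  a <- c(0.51, 0.49, 0.53); b <- c(0.68, 0.71, 0.66)
  expect_equal(compare_groups(a, b)$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value)
})

test_that("t-test p-values track an exhaustive permutation oracle", {
  set.seed(99)
  for (rep in 1:3) {
    a <- rnorm(5, 0.55, 0.05)
    b <- rnorm(5, 0.62, 0.05)
    p_t <- compare_groups(a, b)$p_value
    # exact permutation distribution of the mean difference
    v <- c(a, b)
    obs <- abs(mean(a) - mean(b))
    splits <- utils::combn(10, 5)
    stat <- apply(splits, 2, function(ix)
      abs(mean(v[ix]) - mean(v[-ix])))
    p_perm <- mean(stat >= obs - 1e-12)
    expect_lt(abs(p_t - p_perm), 0.15)
  }
})

test_that("bootstrap intervals are seeded, degenerate-safe and calibrated", {
  x <- rep(0.7, 30)
  ci <- bootstrap_ci(x, mean, n_boot = 200, seed = 1)
  expect_equal(unname(ci[1]), 0.7)
  expect_equal(unname(ci[2]), 0.7)
  y <- c(rep(1, 40), rep(0, 60))
  ci1 <- bootstrap_ci(y, mean, n_boot = 500, seed = 5)
  ci2 <- bootstrap_ci(y, mean, n_boot = 500, seed = 5)
  expect_identical(ci1, ci2)
  expect_warning(bootstrap_ci(y, mean, n_boot = 50, seed = 2), "unstable")
  # coverage of the 95% interval for a renewal-style proportion
  hits <- 0
  for (i in 1:200) {
    set.seed(1000 + i)
    draws <- sample(c(1, 0.5, 0), 100, replace = TRUE,
                    prob = c(0.29, 0.44, 0.27))
    ci <- bootstrap_ci(draws, mean, n_boot = 400, seed = 2000 + i)
    if (ci[1] <= 0.51 && 0.51 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.90)
  expect_lte(hits / 200, 0.99)
})

test_that("weeks snap to the 2-week collection grid with ties down", {
  expect_equal(bin_week(c(0, 1, 2, 3, 3.2, 9, 10.9)),
               c(0, 0, 2, 2, 4, 8, 10))
  expect_error(bin_week(-1), "non-negative")
})
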