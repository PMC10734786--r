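test_that("error_at_probability reproduces the symmetric normal bound", {
  ## closed form at zero mean: E = sd * z_{(1+p)/2}
  for (s in c(0.3, 0.45, 1.0)) {
    expect_equal(error_at_probability(difference_model(0, s), 0.85),
                 s * qnorm(0.925), tolerance = 1e-5)
  }
  ## worked example: exact bound 0.87099, conservative display 0.88
  e <- error_at_probability(difference_model(0.40, 0.45), 0.85)
  expect_equal(e, 0.8709902, tolerance = 1e-4)
  ## symmetric in the sign of the mean
  expect_equal(error_at_probability(difference_model(-0.40, 0.45), 0.85), e,
               tolerance = 1e-9)
  ## degenerate limit: all mass at the mean
  expect_equal(error_at_probability(difference_model(0.7, 0), 0.85), 0.7)
  expect_error(error_at_probability(difference_model(0, 1), 1.2), "probability")
})

test_that("Monte-Carlo draws confirm the 85% coverage of the bound", {
  set.seed(101)
  for (par in list(c(0.40, 0.45), c(1.2, 0.9), c(0, 0.7))) {
    E <- error_at_probability(difference_model(par[1], par[2]), 0.85)
    d <- rnorm(1e6, par[1], par[2])
    expect_lt(abs(mean(abs(d) <= E) - 0.85), 0.002)
  }
})

test_that("error bound is strictly monotone in SD and |mean|", {
  sds <- seq(0.1, 1.5, by = 0.1)
  e_sd <- vapply(sds, function(s)
    error_at_probability(difference_model(0.3, s), 0.85), numeric(1))
  expect_true(all(diff(e_sd) > 0))
  mus <- seq(0, 1.2, by = 0.1)
  e_mu <- vapply(mus, function(m)
    error_at_probability(difference_model(m, 0.5), 0.85), numeric(1))
  expect_true(all(diff(e_mu) > 0))
})

test_that("max_sd_for_error inverts the error bound", {
  ## closed form at zero mean
  expect_equal(max_sd_for_error(0, 1.0, 0.85), 1 / qnorm(0.925),
               tolerance = 1e-5)
  ## inverse of the worked example
  expect_equal(max_sd_for_error(0.40, 0.8709902, 0.85), 0.45, tolerance = 1e-3)
  ## inverse consistency over a grid
  for (mu in c(0, 0.2, 0.5, 0.9)) {
    for (E in c(1.0, 1.5)) {
      for (p in c(0.75, 0.85, 0.95)) {
        s <- max_sd_for_error(mu, E, p)
        expect_equal(error_at_probability(difference_model(mu, s), p), E,
                     tolerance = 1e-5)
      }
    }
  }
  ## feasibility boundary: mean just inside the bound forces SD toward 0
  expect_lt(max_sd_for_error(0.999, 1.0, 0.85), 0.001)
  expect_error(max_sd_for_error(1.0, 1.0, 0.85), "infeasible")
  expect_error(max_sd_for_error(1.4, 1.0, 0.85), "infeasible")
})

test_that("round_up_to_grid is conservative and idempotent on multiples", {
  expect_equal(round_up_to_grid(0.41), 0.45)
  expect_equal(round_up_to_grid(0.47), 0.50)
  expect_equal(round_up_to_grid(0.45), 0.45)
  expect_equal(round_up_to_grid(0), 0)
  ## rounded values are >= input and exact grid multiples
  vals <- seq(0, 2, by = 0.013)
  r <- round_up_to_grid(vals)
  expect_true(all(r >= vals - 1e-12))
  expect_true(all(abs(r / 0.05 - round(r / 0.05)) < 1e-9))
  expect_error(round_up_to_grid(-0.1), "non-negative")
})

test_that("grade_device applies rounding, the 85% bound and the thresholds", {
  g <- grade_device(difference_model(0.36, 0.44))
  expect_equal(g$rounded_mean, 0.40)
  expect_equal(g$rounded_sd, 0.45)
  expect_equal(g$error85_display, 0.88)
  expect_identical(g$grade, "good")

  g0 <- grade_device(difference_model(0, 0))
  expect_equal(g0$error85, 0)
  expect_identical(g0$grade, "good")

  ## exact bound for (1.2, 0.9) is 2.13 m/s, well past the 1.5 threshold
  gf <- grade_device(difference_model(1.2, 0.9))
  expect_identical(gf$grade, "fail")

  ## sign symmetry across a grid of models
  for (mu in seq(0.1, 1.3, by = 0.3)) {
    for (s in c(0.2, 0.6)) {
      expect_identical(grade_device(difference_model(mu, s))$grade,
                       grade_device(difference_model(-mu, s))$grade)
    }
  }
})

test_that("cutoff table is monotone, feasibility-marked and grade-consistent", {
  tab <- generate_cutoff_table(seq(0, 0.95, by = 0.05))
  expect_equal(nrow(tab), 20L)
  expect_true(all(diff(tab$max_sd_good) < 0))
  expect_true(all(diff(tab$max_sd_acceptable) < 0))
  expect_true(all(tab$good_feasible))

  ## infeasible mean rows are marked, not dropped
  tab2 <- generate_cutoff_table(c(0.5, 1.4))
  expect_true(is.na(tab2$max_sd_good[2]))
  expect_false(tab2$good_feasible[2])
  expect_true(tab2$acceptable_feasible[2])

  ## every 0.05-grid cell agrees with grade_device in both directions
  for (i in seq_len(nrow(tab))) {
    m <- tab$mean_diff[i]
    for (s in seq(0, 1.0, by = 0.05)) {
      table_good <- s <= tab$max_sd_good[i]
      expect_identical(grade_device(difference_model(m, s))$grade == "good",
                       table_good)
    }
  }
})

test_that("binomial sample-size calculus matches the design point", {
  expect_equal(margin_of_error(85, 0.85, 0.90), 6.370491, tolerance = 1e-5)
  expect_lte(margin_of_error(85, 0.85, 0.90), 7)
  expect_equal(assured_lower_bound(85, 0.85, 0.90), 78.62951, tolerance = 1e-5)
  expect_gte(assured_lower_bound(85, 0.85, 0.90), 78)

  ## worst case at p = 0.5
  expect_equal(margin_of_error(85, 0.5, 0.90), 8.920471, tolerance = 1e-5)
  ps <- seq(0.05, 0.95, by = 0.05)
  m <- vapply(ps, function(p) margin_of_error(85, p, 0.90), numeric(1))
  expect_equal(ps[which.max(m)], 0.5)

  ## 1/sqrt(n) scaling: quadrupling n halves the margin
  expect_equal(margin_of_error(340, 0.85, 0.90),
               margin_of_error(85, 0.85, 0.90) / 2, tolerance = 1e-10)
  ## consistency limit
  expect_lt(margin_of_error(1e8, 0.85, 0.90), 0.01)
  ## vanishing confidence returns the point estimate
  expect_equal(assured_lower_bound(85, 0.85, 1e-12), 85, tolerance = 1e-4)

  ## Wilson alternative is available and differs from Wald away from p = 0.5
  w <- margin_of_error(85, 0.85, 0.90, method = "wilson")
  expect_true(is.finite(w) && w > 0)
  expect_false(isTRUE(all.equal(w, margin_of_error(85, 0.85, 0.90))))
})

test_that("sample_size_plan ties the pieces together", {
  plan <- sample_size_plan()
  expect_equal(plan$lower_bound, 100 * 0.85 - plan$margin)
  expect_gte(plan$n_enroll, plan$n_analysis)
  expect_error(sample_size_plan(n_analysis = 85, n_enroll = 80), "at least")
})
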