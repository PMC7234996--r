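test_that("conventional screening applies KW per stratum", {
  tab <- make_table(sprintf("s%02d", 1:12),
                    ms_bmr = c(1, 2, 3, 4, 5, 6, 2, 2, 2, 2, 2, 2),
                    lifespan = c(rep(5, 6), rep(15, 6)),
                    keap1 = c(0, 0, 0, 1, 1, 1, 0, 0, 0, 1, 1, 1))
  asg <- assign_strata(tab, "max_lifespan", 10)
  # the ">=10" stratum is all-tied, so the degenerate-H warning is expected
  sc <- suppressWarnings(conventional_screen(tab, asg, "ms_bmr"))
  lo <- sc[sc$stratum == "<10", ]
  expect_equal(lo$H, 27 / 7)
  expect_true(lo$screened)                       # p = 0.0495 < 0.05
  hi <- sc[sc$stratum == ">=10", ]
  expect_equal(hi$H, 0)                          # identical distributions
  expect_false(hi$screened)

  # alpha = 0 screens nothing
  sc0 <- suppressWarnings(conventional_screen(tab, asg, "ms_bmr", alpha = 0))
  expect_false(any(sc0$screened, na.rm = TRUE))

  # a stratum missing a factor level is skipped with a message
  tab1 <- tab
  tab1$keap1_functional[7:12] <- 0L
  expect_message(sc1 <- conventional_screen(tab1, asg, "ms_bmr"), "skipped")
  expect_true(is.na(sc1$H[sc1$stratum == ">=10"]))
})

test_that("run_pi_kw validates its inputs", {
  sdat <- synth_comparative(n_tips = 20, clade_fraction = 0.5, seed = 42)
  expect_error(run_pi_kw(sdat$tree, sdat$table, n_sims = 50, seed = 1),
               "n_sims")
  tab2 <- sdat$table
  tab2$species[1] <- "not_a_tip"
  expect_error(run_pi_kw(sdat$tree, tab2, n_sims = 200, seed = 1),
               "not_a_tip")
  tab3 <- sdat$table
  tab3$keap1_functional <- 1L
  expect_error(run_pi_kw(sdat$tree, tab3, n_sims = 200, seed = 1),
               "both factor levels")
})

test_that("the PI null is exactly invariant to sigma2 and root state", {
  sdat <- synth_comparative(n_tips = 30, clade_fraction = 0.5, seed = 42)
  r1 <- run_pi_kw(sdat$tree, sdat$table, n_sims = 300, seed = 5,
                  sigma2 = 1, root_state = 0)
  r2 <- run_pi_kw(sdat$tree, sdat$table, n_sims = 300, seed = 5,
                  sigma2 = 100, root_state = 10)
  expect_identical(r1$null$h_values, r2$null$h_values)
  expect_identical(r1$threshold_95, r2$threshold_95)
})

test_that("run_pi_kw replays deterministically and is internally consistent", {
  sdat <- synth_comparative(n_tips = 40, clade_fraction = 0.4,
                            clade_shift = 1.5, seed = 42)
  r1 <- run_pi_kw(sdat$tree, sdat$table, n_sims = 400, seed = 9)
  r2 <- run_pi_kw(sdat$tree, sdat$table, n_sims = 400, seed = 9)
  expect_identical(r1[names(r1) != "null"], r2[names(r2) != "null"])
  expect_identical(r1$null$h_values, r2$null$h_values)

  # recomputation invariants of the result record
  expect_equal(r1$threshold_95, empirical_percentile(r1$null$h_values, 95))
  expect_equal(r1$empirical_p_add_one,
               empirical_p(r1$null$h_values, r1$observed_H))
  expect_equal(r1$empirical_p_raw,
               empirical_p(r1$null$h_values, r1$observed_H, "raw"))
  if (isTRUE(r1$significant)) expect_true(r1$screened)

  # per-stratum substreams: a stratum's null is the same whether the
  # stratum is analysed alone or alongside the others in the pipeline
  asg <- assign_strata(sdat$table, "max_lifespan", c(10, 20))
  pp <- suppressMessages(
    pikw_pipeline(sdat$tree, sdat$table, response = "ms_bmr",
                  stratify_by = "max_lifespan", bin_edges = c(10, 20),
                  n_sims = 200, seed = 3, pi_on = "all"))
  for (lab in names(pp$results)) {
    alone <- run_pi_kw(sdat$tree, sdat$table, asg, lab,
                       n_sims = 200, seed = 3)
    expect_identical(alone$null$h_values, pp$results[[lab]]$null$h_values)
  }
})

test_that("the pipeline stratifies, screens and reports coherently", {
  sdat <- synth_comparative(n_tips = 60, clade_fraction = 0.5,
                            clade_shift = 3, seed = 42)
  pp <- suppressMessages(
    pikw_pipeline(sdat$tree, sdat$table, response = "ms_bmr",
                  stratify_by = "max_lifespan", bin_edges = c(10, 30),
                  n_sims = 300, seed = 42, pi_on = "all"))
  sm <- pp$summary
  expect_true(all(c("stratum", "H", "chisq_p", "screened", "balance",
                    "threshold_95", "empirical_p", "significant")
                  %in% names(sm)))
  done <- !is.na(sm$significant)
  expect_true(any(done))
  expect_true(all(sm$significant[done] <=
                    (sm$screened[done] & sm$H[done] > sm$threshold_95[done])))
  # with a 3-SD clade shift at least one stratum should reject
  expect_true(any(sm$significant[done]))
  # results carry a full pikw_result per analysed stratum
  expect_true(all(vapply(pp$results, inherits, NA, "pikw_result")))
})

test_that("on a star tree the PI threshold matches exchangeable references", {
  star <- ape::stree(80, "star")
  star$edge.length <- rep(4, nrow(star$edge))
  g <- rep(c(0, 1), c(30, 50))
  h <- empirical_null_h(star, g, n_sims = 2000, seed = 42)
  thr <- empirical_percentile(h, 95)
  # chi-square(1) reference
  expect_lt(abs(thr - qchisq(0.95, 1)), 0.35)
  # label-permutation null on an exchangeable draw
  set.seed(42)
  y <- rnorm(80)
  hp <- vapply(1:2000, function(i) kruskal_wallis(y, sample(g))$H, 0)
  expect_lt(abs(thr - empirical_percentile(hp, 95)), 0.5)
})
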