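test_that("AARD follows its definition and is scale invariant", {
  expect_equal(aard(c(1, 2), c(1.1, 1.8)), 10)
  expect_equal(aard(c(3, 4, 5), c(3, 4, 5)), 0)
  obs <- c(2e-6, 3e-6, 4e-6); pred <- c(2.2e-6, 2.7e-6, 4.4e-6)
  expect_equal(aard(obs * 7, pred * 7), aard(obs, pred), tolerance = 1e-12)
  expect_error(aard(c(0, 1), c(1, 1)), "nonzero")
  expect_error(aard(1:3, 1:2), "equal-length")
})

test_that("scorecard reproduces its closed-form statistics", {
  obs <- c(1, 2, 3, 4, 5)
  s <- scorecard(obs, obs, Q = 2)
  expect_equal(unname(unlist(s[c("aard", "r2", "r_adj", "sse", "rmse")])),
               c(0, 1, 1, 0, 0))

  # construct data with R2 = 0.879 exactly, then check the printed
  # adjusted-R2 formula |R2 - Q(1-R2)/(N-Q-1)| by hand arithmetic
  set.seed(4)
  obs <- rnorm(24, 10, 2)
  sstot <- sum((obs - mean(obs))^2)
  pred <- obs; pred[1] <- obs[1] + sqrt(0.121 * sstot)
  s <- scorecard(obs, pred, Q = 2)
  expect_equal(s$r2, 0.879, tolerance = 1e-12)
  expect_equal(s$r_adj, abs(0.879 - 2 * (1 - 0.879) / (24 - 2 - 1)),
               tolerance = 1e-12)
  expect_equal(s$r_adj, 0.8675, tolerance = 1e-4)

  # SSE and the (no-1/N) RMSE are definitionally linked
  expect_equal(s$rmse^2, s$sse, tolerance = 1e-15)
  expect_equal(s$rmse_mean, sqrt(s$sse / 24), tolerance = 1e-15)

  expect_error(scorecard(1:3, 1:3, Q = 2), "N > Q")
})

test_that("multistart fitting is deterministic and never worse than OLS", {
  d <- reg_dataset()
  cfg <- fit_config(n_starts = 16, seed = 9)
  f1 <- fit_model("keshmiri", d, cfg)
  f2 <- fit_model("keshmiri", d, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$value, f2$value)

  ols <- unname(linear_fit("keshmiri", d))
  aard_ols <- aard(d$records$y2, predict_y2("keshmiri", ols, d))
  expect_lte(f1$value, aard_ols)

  # reported statistics recompute exactly from stored predictions
  s <- scorecard(f1$observed, f1$predicted, get_model("keshmiri")$n_indep)
  expect_equal(s$aard, f1$stats$aard, tolerance = 1e-12)
  expect_equal(s$sse, f1$stats$sse, tolerance = 1e-12)
  expect_equal(f1$value, f1$stats$aard, tolerance = 1e-12)
})

test_that("noise-free generated data are fitted to solver tolerance", {
  truth <- c(-27.2, 5.47, -4190)
  d <- generated_dataset("chrastil", truth)
  f <- fit_model("chrastil", d, fit_config(n_starts = 4, seed = 2))
  expect_lt(f$stats$aard, 1e-6)
  expect_rel_equal(unname(f$params), truth, 1e-6)
})

test_that("SSE objective is supported and minimized at the same solution", {
  d <- generated_dataset("kumar_johnston", c(-3.7, 0.0074, -4846))
  f <- fit_model("kumar_johnston", d, fit_config("sse", n_starts = 4, seed = 5))
  expect_lt(f$value, 1e-20)
  expect_equal(f$value, f$stats$sse, tolerance = 1e-15)
})

test_that("fit_report tabulates models, flags failures, averages by group", {
  d <- reg_dataset()
  cfg <- fit_config(n_starts = 2, seed = 3)
  rep <- fit_report(d, c("chrastil", "kumar_johnston", "gordillo"), cfg)
  expect_equal(nrow(rep$table), 3L)
  expect_true(all(rep$table$error == ""))
  expect_setequal(rep$group_means$group, c("II", "III"))
  gII <- mean(rep$table$AARD[rep$table$group == "II"])
  expect_equal(rep$group_means$mean_AARD[rep$group_means$group == "II"], gII)

  # a model with more parameters than records fails as a flagged row
  small <- scf_dataset(d$records[d$records$T_K %in% c(308, 318) &
                                   d$records$P_bar <= 180, ],
                       reg_solute(), co2_solvent())
  rep2 <- fit_report(small, c("chrastil", "belghait"), cfg)
  expect_equal(nrow(rep2$table), 2L)
  expect_true(is.na(rep2$table$AARD[rep2$table$model == "belghait"]))
  expect_match(rep2$table$error[rep2$table$model == "belghait"], "records")
  expect_false(is.na(rep2$table$AARD[rep2$table$model == "chrastil"]))

  rep0 <- fit_report(d, character(), cfg)
  expect_equal(nrow(rep0$table), 0L)
})
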