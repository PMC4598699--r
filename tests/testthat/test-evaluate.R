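test_that("parameter-corrected RMSE follows its definition", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4), p = 1), sqrt(1 / 2),
               tolerance = 1e-12)
  expect_equal(rmse(1:5, 1:5, p = 2), 0)
  # homogeneity: doubling residuals doubles the RMSE
  obs <- c(3, 5, 9, 11); pred <- c(2, 6, 8, 13)
  expect_equal(rmse(obs, obs + 2 * (pred - obs), 1),
               2 * rmse(obs, pred, 1), tolerance = 1e-12)
  expect_error(rmse(1:3, 1:3, p = 3), "n > p")
})

test_that("correlation statistics match an independent computation", {
  set.seed(1)
  obs <- rnorm(10); pred <- 2 * obs + rnorm(10, 0, 0.5)
  cs <- correlation_stats(obs, pred)
  # textbook product-moment formula, computed from scratch
  r_hand <- sum((obs - mean(obs)) * (pred - mean(pred))) /
    sqrt(sum((obs - mean(obs))^2) * sum((pred - mean(pred))^2))
  expect_equal(cs$r2, r_hand^2, tolerance = 1e-10)
  expect_equal(cs$r_y_yhat, 100 * abs(r_hand), tolerance = 1e-10)
  expect_equal(cs$sigma_yhat, sd(pred))

  expect_equal(correlation_stats(obs, obs)$r_y_yhat, 100)
  neg <- correlation_stats(obs, -obs)
  expect_equal(neg$r_y_yhat, 100)        # magnitude only ...
  expect_equal(neg$sign, -1)             # ... sign carried separately
  expect_error(correlation_stats(obs, rep(1, 10)), "variance")
  expect_error(correlation_stats(1:2, 1:2), "3 pairs")
})

test_that("Eq.-4 identity and the sigma criterion hold for training fits", {
  rec <- random_session_frame(400, seed = 30)
  set.seed(31)
  rec$yd_fat <- 250 + 7 * rec$q_fat * rec$milk + rnorm(400, 0, 30)
  rec$yd_milk <- 2 * rec$milk + rnorm(400, 0, 2)
  for (sp in list(preset_models("fat", "AM"),
                  preset_models("milk", "AM"))) {
    fit <- ampm_fit(sp, rec)
    s <- fit$stats
    expect_equal(s$rmse^2 * (s$n - s$p), s$sse, tolerance = 1e-9)
    # least-squares variance decomposition: sigma_yhat <= SD(observed)
    expect_true(sigma_check(s))
    # with an intercept, R2 from variance decomposition equals the squared
    # Pearson correlation of observed and fitted
    obs <- fitted(fit) + residuals(fit)
    r2_decomp <- 1 - s$sse / sum((obs - mean(obs))^2)
    expect_equal(s$r2, r2_decomp, tolerance = 1e-9)
  }
  expect_true(sigma_check(list(sigma_yhat = 3, sd_observed = 3)))
  expect_false(sigma_check(list(sigma_yhat = 3.1, sd_observed = 3)))
})

test_that("correlation table reproduces closed-form structure", {
  # degenerate: AM = PM for every record -> all correlations 100%
  base <- simulate_herds(tiny_config(seed = 40))
  for (t in c("fat", "sfa", "mufa", "ufa", "scfa", "mcfa", "lcfa", "c181"))
    base[[paste0("content_pm_", t)]] <- base[[paste0("content_am_", t)]]
  base$milk_pm <- base$milk_am
  v_eq <- make_validation_dataset(base)
  ct_eq <- correlation_table(v_eq)
  expect_equal(ct_eq$yield_am_pm, rep(100, 9), tolerance = 1e-9)
  expect_equal(ct_eq$content_am_daily[-1], rep(100, 8), tolerance = 1e-9)

  # independent equal-variance milkings: cor(AM, AM + PM) = 1/sqrt(2)
  set.seed(41)
  m <- 20000
  am <- rnorm(m); pm <- rnorm(m)
  df <- data.frame(milk_am = am, milk_pm = pm, milk_daily = am + pm)
  ct <- correlation_table(df, traits = "milk")
  expect_equal(ct$yield_am_daily, 100 / sqrt(2), tolerance = 0.02)

  # shared volume driver: yield correlations exceed content correlations
  truth <- simulate_herds(sim_config(n_herds = 8, cows_per_herd = 20,
                                     test_days_per_cow = 5, seed = 42))
  ctf <- correlation_table(make_validation_dataset(truth))
  fa_rows <- ctf$trait != "milk"
  expect_true(all(ctf$yield_am_daily[fa_rows] >
                  ctf$content_am_daily[fa_rows]))
  expect_error(correlation_table(df[1:2, ], traits = "milk"), "3 records")
})

test_that("validation report is consistent, order-free and serializable", {
  truth <- simulate_herds(tiny_config(seed = 50))
  v <- make_validation_dataset(truth)
  cal <- as_session_records(v, "AM")
  fit <- ampm_fit(preset_models("fat", "AM"), cal)
  rep1 <- validation_report(list(fat_AM = fit), list(calibration = cal))
  # on the training data the report reuses the fit-time statistics exactly
  expect_equal(rep1$rmse, fit$stats$rmse, tolerance = 1e-12)
  expect_equal(rep1$r_y_yhat, fit$stats$r_y_yhat, tolerance = 1e-12)
  expect_equal(rep1$sigma_yhat, fit$stats$sigma_yhat, tolerance = 1e-12)

  # permuting dataset rows leaves the report unchanged
  perm <- sample(nrow(cal))
  rep2 <- validation_report(list(fat_AM = fit), list(calibration = cal[perm, ]))
  expect_equal(rep2$rmse, rep1$rmse, tolerance = 1e-12)
  expect_equal(rep2$r_y_yhat, rep1$r_y_yhat, tolerance = 1e-12)

  # round-trip through CSV reproduces the report
  path <- tempfile(fileext = ".csv")
  write_table_csv(rep1, path)
  back <- read_table_csv(path)
  expect_equal(back$rmse, rep1$rmse, tolerance = 1e-12)

  # a missing model is reported as absent, not an error
  rep3 <- validation_report(list(fat_AM = fit, milk_AM = NULL),
                            list(calibration = cal))
  expect_true(any(is.na(rep3$rmse)))
  expect_equal(nrow(rep3), 2)
})

test_that("out-of-sample accuracy does not beat calibration accuracy on average", {
  gaps <- c()
  for (seed in 1:3) {
    truth <- simulate_herds(sim_config(n_herds = 8, cows_per_herd = 15,
                                       test_days_per_cow = 5, seed = seed))
    s <- make_s_dataset(truth)
    bt <- estimate_b_table(make_t_dataset(truth))
    split <- expected_split(s, bt)
    # split by cow (not herd) so both halves share the class levels
    half <- match(split$cow_id, sort(unique(split$cow_id))) %% 2L == 0L
    for (tr in c("milk", "fat")) {
      cal <- as_session_records(split[half, ], "AM")
      hold <- as_session_records(split[!half, ], "AM")
      fit <- ampm_fit(preset_models(tr, "AM"), cal)
      rep_ <- validation_report(list(m = fit),
                                list(calibration = cal, holdout = hold))
      gaps <- c(gaps, diff(rev(rep_$r_y_yhat)))  # calibration - holdout
    }
  }
  expect_gte(mean(gaps), 0)
})
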