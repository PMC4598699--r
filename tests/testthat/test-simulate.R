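test_that("symmetric configuration gives identical milkings", {
  cfg <- tiny_config(seed = 5, mi_hours = c(mean = 12, sd = 0),
                     dilution_slope = 0, noise_sd_content = 0,
                     noise_sd_milk = 0)
  truth <- simulate_herds(cfg)
  expect_equal(truth$milk_am, truth$milk_pm)
  for (t in c("fat", "sfa", "mufa", "ufa", "scfa", "mcfa", "lcfa", "c181"))
    expect_equal(truth[[paste0("content_am_", t)]],
                 truth[[paste0("content_pm_", t)]])
  expect_equal(truth$mi_am + truth$mi_pm, rep(24, nrow(truth)),
               tolerance = 1e-12)
})

test_that("a shorter interval before the AM milking lowers AM milk yield", {
  cfg <- sim_config(n_herds = 10, cows_per_herd = 25, test_days_per_cow = 5,
                    seed = 8, mi_hours = c(mean = 10, sd = 1))
  truth <- simulate_herds(cfg)
  expect_gte(nrow(truth), 1000)
  expect_lt(mean(truth$milk_am), mean(truth$milk_pm))
})

test_that("interval share drives yield up and fat content down (dilution)", {
  short <- simulate_herds(sim_config(n_herds = 10, cows_per_herd = 25,
                                     test_days_per_cow = 5, seed = 3,
                                     mi_hours = c(mean = 9.5, sd = 1)))
  long <- simulate_herds(sim_config(n_herds = 10, cows_per_herd = 25,
                                    test_days_per_cow = 5, seed = 3,
                                    mi_hours = c(mean = 13.5, sd = 1)))
  expect_gt(mean(long$milk_am), mean(short$milk_am))
  expect_lt(mean(long$content_am_fat), mean(short$content_am_fat))
})

test_that("identical config and seed reproduce the table exactly", {
  a <- simulate_herds(tiny_config(seed = 99))
  b <- simulate_herds(tiny_config(seed = 99))
  expect_identical(a, b)
  c <- simulate_herds(tiny_config(seed = 100))
  expect_false(identical(a, c))
})

test_that("FA groups partition fat content by construction", {
  truth <- simulate_herds(tiny_config(seed = 2))
  for (s in c("am", "pm")) {
    fat <- truth[[paste0("content_", s, "_fat")]]
    expect_equal(truth[[paste0("content_", s, "_sfa")]] +
                 truth[[paste0("content_", s, "_ufa")]], fat,
                 tolerance = 1e-12)
    expect_equal(truth[[paste0("content_", s, "_scfa")]] +
                 truth[[paste0("content_", s, "_mcfa")]] +
                 truth[[paste0("content_", s, "_lcfa")]], fat,
                 tolerance = 1e-12)
    expect_true(all(truth[[paste0("content_", s, "_mufa")]] <=
                    truth[[paste0("content_", s, "_ufa")]]))
  }
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(sim_config(n_herds = 0), "counts")
  expect_error(sim_config(noise_sd_milk = -1), "SDs")
  expect_error(sim_config(fa_fraction = c(sfa = 0.5, mufa = 0.29, ufa = 0.34,
                                          scfa = 0.09, mcfa = 0.51,
                                          lcfa = 0.40, c181 = 0.19)),
               "sfa \\+ ufa")
})

test_that("the composite scheme averages the two milkings exactly", {
  truth <- simulate_herds(tiny_config(seed = 4))
  s <- make_s_dataset(truth)
  expect_equal(s$milk_daily, truth$milk_am + truth$milk_pm)
  for (t in c("fat", "ufa", "c181")) {
    expect_equal(s[[paste0("content_5050_", t)]],
                 0.5 * truth[[paste0("content_am_", t)]] +
                 0.5 * truth[[paste0("content_pm_", t)]],
                 tolerance = 1e-15)
  }
  one <- truth[1, ]
  one$content_am_fat <- 4.0; one$content_pm_fat <- 5.0
  expect_equal(make_s_dataset(one)$content_5050_fat, 4.5)
})

test_that("alternate scheme exposes one session per visit, alternating", {
  truth <- simulate_herds(tiny_config(seed = 6, n_herds = 1,
                                      test_days_per_cow = 2))
  td <- make_t_dataset(truth)
  expect_true(all(td$session[td$test_day == 1] == "AM"))
  expect_true(all(td$session[td$test_day == 2] == "PM"))
  tdp <- make_t_dataset(truth, start_session = "PM")
  expect_true(all(tdp$session[tdp$test_day == 1] == "PM"))

  # emitted AM records carry the truth's AM fields verbatim
  am <- td[td$session == "AM", ]
  key <- paste(truth$cow_id, truth$test_day)
  idx <- match(paste(am$cow_id, am$test_day), key)
  expect_identical(am$milk, truth$milk_am[idx])
  expect_identical(am$content_fat, truth$content_am_fat[idx])
  expect_identical(am$content_lcfa, truth$content_am_lcfa[idx])

  empty <- make_t_dataset(truth[0, ])
  expect_equal(nrow(empty), 0)
  expect_true(all(c("session", "milk", "content_fat") %in% names(empty)))
})

test_that("validation scheme carries observed yields and computed dailies", {
  truth <- simulate_herds(tiny_config(seed = 7))
  v <- make_validation_dataset(truth)
  expect_equal(nrow(v), nrow(truth))
  expect_equal(v$milk_daily, truth$milk_am + truth$milk_pm)
  expect_equal(v$yield_daily_fat,
               10 * (truth$content_am_fat * truth$milk_am +
                     truth$content_pm_fat * truth$milk_pm),
               tolerance = 1e-12)
})

test_that("outlier filter drops records beyond mean +/- 3 SD, computed once", {
  # 5-point set: mean 20.8, SD ~ 44.03 -> the 100 is inside the 3 SD band
  d5 <- data.frame(x = c(1, 1, 1, 1, 100))
  expect_equal(apply_outlier_filter(d5, "x")$n_removed, 0)
  expect_lt(abs(100 - mean(d5$x)), 3 * sd(d5$x))  # oracle arithmetic

  d <- data.frame(x = c(rep(1, 50), 1e6))
  res <- apply_outlier_filter(d, "x")
  expect_equal(res$n_removed, 1)
  expect_equal(res$removed, 51L)

  # all-identical trait: SD = 0, the rule is vacuous
  expect_equal(apply_outlier_filter(data.frame(x = rep(3, 10)), "x")$n_removed,
               0)

  # Monte-Carlo: standard-normal tail beyond 3 SD ~ 2.7 per 1000
  set.seed(42)
  n <- 40000
  dn <- data.frame(x = rnorm(n))
  rate <- apply_outlier_filter(dn, "x")$n_removed / n * 1000
  se <- sqrt(0.0027 * 0.9973 / n) * 1000
  expect_lt(abs(rate - 2.7), 4 * se + 0.2)

  expect_error(apply_outlier_filter(d5[1, , drop = FALSE], "x"), "2 records")
  expect_error(apply_outlier_filter(d5, "nope"), "unknown columns")
})
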