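test_that("the model grammar round-trips and rejects bad tokens", {
  txt <- "a + b*(qFAT_AM*milk_AM*DIM) + c*(parity) + d*(milk_AM*parity)"
  sp <- parse_model(txt, "fat", "AM")
  expect_s3_class(sp, "ampm_spec")
  expect_length(sp$terms, 3)
  expect_equal(format_model(sp),
               "a + b*(milk_AM*qFAT_AM*DIM) + c*(parity) + d*(milk_AM*parity)")
  # typographic variant and 'month of test' wording parse too
  sp2 <- parse_model("a + b × (qC18:1 cis9_PM × milk_PM × month of test)",
                     "c181", "PM")
  expect_equal(sp2$terms[[1]]$covariates, c("milk", "q_c181"))
  expect_equal(sp2$terms[[1]]$classes, "month")

  expect_error(parse_model("a + b*(qFAT_PM*milk_PM)", "fat", "AM"), "session")
  expect_error(parse_model("a + b*(banana_AM)", "fat", "AM"), "parse")
  expect_error(ampm_term(character(), character()), "at least one")
  expect_error(ampm_spec("fat", "AM", list("parity", "parity")), "duplicate")
})

test_that("all shipped presets parse against their trait and session", {
  ps <- preset_models()
  expect_length(ps, 18)
  for (nm in names(ps)) {
    parts <- strsplit(nm, "_")[[1]]
    expect_equal(ps[[nm]]$trait, parts[1])
    expect_equal(ps[[nm]]$session, parts[2])
    expect_gte(length(ps[[nm]]$terms), 3)
  }
  expect_equal(preset_models("fat", "AM")$trait, "fat")
})

test_that("design columns are covariate products inside subclass cells", {
  rec <- data.frame(cow_id = "a", herd_id = "h",
                    dim = c(10, 20, 200, 210),
                    parity = c("1", "2", "3+", "1"),
                    month = c(1, 1, 2, 2),
                    milk = c(10, 11, 12, 13),
                    q_fat = c(4.0, 4.2, 4.4, 4.6))
  # indicator term: one column per occupied parity level
  d1 <- build_design(rec, ampm_spec("fat", "AM",
                                    list(ampm_term(character(), "parity"))))
  expect_equal(colnames(d1$X), c("(Intercept)", "parity[1]", "parity[2]",
                                 "parity[3+]"))
  expect_equal(unname(d1$X[, "parity[1]"]), c(1, 0, 0, 1))

  # covariate nested in classes: product inside the cell, 0 outside
  sp <- ampm_spec("fat", "AM", list(ampm_term(c("q_fat", "milk"), "dim")))
  d2 <- build_design(rec, sp)
  v <- rec$q_fat * rec$milk
  expect_equal(ncol(d2$X), 3)  # intercept + 2 occupied DIM cells
  expect_equal(unname(d2$X[, 2]), v * c(1, 1, 0, 0))  # (0,30]
  expect_equal(unname(d2$X[, 3]), v * c(0, 0, 1, 1))  # (180,210]

  # milk x parity: 3 columns, column j = milk * 1[parity = j]
  d3 <- build_design(rec, ampm_spec("fat", "AM",
                                    list(ampm_term("milk", "parity"))))
  expect_equal(unname(d3$X[, "milk_AM*parity[2]"]), c(0, 11, 0, 0))

  expect_error(
    build_design(rec[, -7], ampm_spec("fat", "AM", list(ampm_term("q_fat")))),
    "covariate")
})

test_that("least squares matches an independent normal-equations solve", {
  rec <- random_session_frame(50, seed = 13)
  set.seed(14)
  rec$yd_fat <- rnorm(50, 500, 80)
  sp <- ampm_spec("fat", "AM", list(ampm_term("milk"), ampm_term("q_fat"),
                                    ampm_term(c("q_fat", "milk"))))
  fit <- ampm_fit(sp, rec)
  X <- cbind(1, rec$milk, rec$q_fat, rec$q_fat * rec$milk)  # 50 x 4
  beta <- solve(crossprod(X), crossprod(X, rec$yd_fat))
  expect_equal(unname(coef(fit)), drop(beta), tolerance = 1e-8)
  expect_equal(fit$p, 4)
  expect_equal(fit$stats$sse, sum(residuals(fit)^2))
})

test_that("exact linear responses are recovered with zero residuals", {
  rec <- random_session_frame(40, seed = 2)
  rec$yd_fat <- 100 + 25 * rec$milk
  fit <- ampm_fit(ampm_spec("fat", "AM", list(ampm_term("milk"))), rec)
  expect_equal(unname(coef(fit)), c(100, 25), tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
})

test_that("duplicated information is aliased away deterministically", {
  rec <- random_session_frame(60, seed = 3)
  rec$q_sfa <- rec$q_fat          # q_sfa column duplicates q_fat
  set.seed(4)
  rec$yd_fat <- 50 + 10 * rec$q_fat + rnorm(60)
  sp2 <- ampm_spec("fat", "AM", list(ampm_term("q_fat"), ampm_term("q_sfa")))
  fit2 <- ampm_fit(sp2, rec)
  expect_equal(fit2$p, 2)                       # one column dropped
  expect_true(is.na(coef(fit2)[["qSFA_AM"]]))   # the later one
  fit1 <- ampm_fit(ampm_spec("fat", "AM", list(ampm_term("q_fat"))), rec)
  expect_equal(fitted(fit2), fitted(fit1), tolerance = 1e-10)
})

test_that("row order does not change the fit", {
  rec <- random_session_frame(120, seed = 5)
  set.seed(6)
  rec$yd_fat <- 400 + 8 * rec$q_fat * rec$milk + rnorm(120, 0, 15)
  sp <- preset_models("fat", "AM")
  f1 <- ampm_fit(sp, rec)
  perm <- sample(nrow(rec))
  f2 <- ampm_fit(sp, rec[perm, ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("prediction reproduces the linear predictor and guards levels", {
  rec <- random_session_frame(100, seed = 7)
  set.seed(8)
  rec$yd_fat <- 300 + 5 * rec$milk + rnorm(100, 0, 10)

  # intercept-only model predicts the training mean
  f0 <- ampm_fit(ampm_spec("fat", "AM", list()), rec)
  expect_equal(predict(f0, rec), rep(mean(rec$yd_fat), 100))

  # training records get the fitted values back
  sp <- ampm_spec("fat", "AM", list(ampm_term("milk", "parity")))
  fit <- ampm_fit(sp, rec)
  expect_equal(predict(fit, rec), fitted(fit), tolerance = 1e-10)

  # hand-computed predictor on a toy model with known coefficients
  b <- coef(fit)
  one <- rec[3, ]
  expect_equal(predict(fit, one),
               unname(b[["(Intercept)"]] +
                      b[[paste0("milk_AM*parity[", one$parity, "]")]] *
                      one$milk),
               tolerance = 1e-10)

  # unseen class level: error naming the level, no silent extrapolation
  rec_lo <- rec
  rec_lo$dim <- sample(5:30, 100, replace = TRUE)   # one DIM class only
  sp_d <- ampm_spec("fat", "AM", list(ampm_term("milk", "dim")))
  fit_d <- ampm_fit(sp_d, rec_lo)
  rec2 <- rec_lo[1, ]
  rec2$dim <- 200L
  expect_error(predict(fit_d, rec2), "unseen dim.*\\(180,210\\]")
})

test_that("adding a term never increases the calibration SSE", {
  rec <- random_session_frame(200, seed = 9)
  set.seed(10)
  rec$yd_fat <- 200 + 6 * rec$q_fat * rec$milk + 3 * rec$milk +
    rnorm(200, 0, 25)
  terms <- preset_models("fat", "AM")$terms
  sse <- numeric(0)
  for (k in 0:length(terms)) {
    f <- ampm_fit(ampm_spec("fat", "AM", terms[seq_len(k)]), rec)
    sse <- c(sse, f$stats$sse)
  }
  expect_true(all(diff(sse) <= 1e-8 * sse[1]))
})

test_that("forward stepwise finds a planted single-term signal", {
  found <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    calib <- random_session_frame(300, seed = seed)
    test <- random_session_frame(300, seed = seed + 1000)
    val <- random_session_frame(300, seed = seed + 2000)
    gen <- function(d) 100 + 12 * d$q_fat * d$milk + rnorm(nrow(d), 0, 20)
    calib$yd_fat <- gen(calib); test$yd_fat <- gen(test); val$yd_fat <- gen(val)
    sel <- stepwise_select("fat", "AM", calib, test, val)
    if (sel$trace$term[2] == "milk_AM*qFAT_AM") found <- found + 1L
    expect_true(all(diff(sel$trace$test_rmse) <= 0))
  }
  expect_gte(found, 9L)
})

test_that("stepwise stopping rule boundaries behave", {
  calib <- random_session_frame(150, seed = 20)
  set.seed(21)
  calib$yd_fat <- 100 + 10 * calib$milk + rnorm(150, 0, 5)
  test <- random_session_frame(150, seed = 22)
  test$yd_fat <- 100 + 10 * test$milk + rnorm(150, 0, 5)

  # infinite tolerance: no step is ever accepted
  sel_inf <- stepwise_select("fat", "AM", calib, test, test, tol = Inf)
  expect_length(sel_inf$spec$terms, 0)

  # zero-variance response: intercept-only model (candidates bring nothing)
  calib0 <- calib; calib0$yd_fat <- 7
  test0 <- test; test0$yd_fat <- 7
  sel0 <- stepwise_select("fat", "AM", calib0, test0, test0)
  expect_length(sel0$spec$terms, 0)
  expect_equal(predict(sel0$fit, test0), rep(7, 150))
})
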