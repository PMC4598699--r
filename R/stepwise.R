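#' Default candidate-term pool for stepwise selection
#'
#' Every term appearing in any shipped preset for the trait's session, plus
#' all single-factor terms and all two-way covariate-in-class terms built
#' from the session milk yield, the trait's session content, and the three
#' class factors.
#'
#' @param trait response trait (id or token).
#' @param session `"AM"` or `"PM"`.
#' @return a list of [ampm_term()] objects (no duplicates).
#' @export
default_pool <- function(trait, session) {
  tok <- resolve_trait(trait)
  session <- match_session(session)
  covs <- if (tok == "milk") list("milk") else
    list("milk", paste0("q_", tok), c(paste0("q_", tok), "milk"))
  classes <- list(character(), "dim", "parity", "month")
  pool <- list()
  for (cv in covs) for (cl in classes)
    pool[[length(pool) + 1L]] <- ampm_term(cv, cl)
  for (cl in c("dim", "parity", "month"))
    pool[[length(pool) + 1L]] <- ampm_term(character(), cl)
  # preset terms (may add deeper class crosses)
  for (nm in names(preset_strings())) {
    parts <- strsplit(nm, "_")[[1]]
    if (parts[1] == tok && parts[2] == session) {
      sp <- preset_models(parts[1], parts[2])
      pool <- c(pool, sp$terms)
    }
  }
  labs <- vapply(pool, label_term, character(1), session = session)
  pool[!duplicated(labs)]
}

#' Forward stepwise model selection against a held-out TEST set
#'
#' Starting from the intercept-only model, repeatedly adds the candidate term
#' that most reduces the TEST-set RMSE of daily-yield prediction, and stops
#' when the best addition no longer improves the TEST RMSE by more than a
#' relative tolerance. The third (VAL) dataset takes no part in the selection
#' and is only reported on, as an untouched external check.
#'
#' Candidates whose added design columns are entirely aliased (no new
#' estimable parameter) are skipped with a note in the trace.
#'
#' @param trait response trait (id or token).
#' @param session `"AM"` or `"PM"`.
#' @param calib,test,val session frames ([as_session_records()]): calibration
#'   (fitting), TEST (selection criterion) and VAL (reporting only).
#' @param pool candidate terms; defaults to [default_pool()].
#' @param tol relative TEST-RMSE improvement required to accept a step
#'   (default 1e-3). `tol = Inf` accepts nothing (intercept-only model).
#' @param max_steps optional cap on the number of accepted terms.
#' @return an object of class `"ampm_selection"`: `spec` (selected
#'   [ampm_spec()]), `fit` (final `"ampm_model"` on `calib`), `trace`
#'   (data.frame: step, term, test_rmse, accepted), `report` (statistics on
#'   the three datasets via [validation_report()]), `notes` (skipped
#'   candidates).
#' @export
stepwise_select <- function(trait, session, calib, test, val,
                            pool = NULL, tol = 1e-3, max_steps = Inf) {
  tok <- resolve_trait(trait)
  session <- match_session(session)
  if (is.null(pool)) pool <- default_pool(tok, session)
  if (!length(pool)) stop("empty candidate pool", call. = FALSE)
  ycol <- paste0("yd_", tok)
  y_test <- test[[ycol]]

  test_rmse_of <- function(fit) {
    pred <- predict(fit, test)
    rmse(y_test, pred, fit$p)
  }

  current <- ampm_spec(tok, session, list())
  fit <- ampm_fit(current, calib)
  cur_rmse <- test_rmse_of(fit)
  trace <- data.frame(step = 0L, term = "(Intercept)", test_rmse = cur_rmse,
                      accepted = TRUE, stringsAsFactors = FALSE)
  notes <- character(0)
  remaining <- pool
  step <- 0L
  while (length(remaining) && step < max_steps) {
    cand_rmse <- rep(NA_real_, length(remaining))
    cand_fit <- vector("list", length(remaining))
    for (i in seq_along(remaining)) {
      sp_try <- ampm_spec(tok, session, c(current$terms, remaining[i]))
      ft <- tryCatch(ampm_fit(sp_try, calib), error = function(e) e)
      if (inherits(ft, "error")) {
        notes <- c(notes, sprintf("skipped '%s': %s",
                                  label_term(remaining[[i]], session),
                                  conditionMessage(ft)))
        next
      }
      if (ft$p <= fit$p) {  # no new estimable parameter: rank collapse
        notes <- c(notes, sprintf("skipped '%s': adds no estimable parameter",
                                  label_term(remaining[[i]], session)))
        next
      }
      rr <- tryCatch(test_rmse_of(ft), error = function(e) e)
      if (inherits(rr, "error")) {
        notes <- c(notes, sprintf("skipped '%s': %s",
                                  label_term(remaining[[i]], session),
                                  conditionMessage(rr)))
        next
      }
      cand_fit[[i]] <- ft
      cand_rmse[i] <- rr
    }
    if (all(is.na(cand_rmse))) break
    best <- which.min(cand_rmse)
    improve <- (cur_rmse - cand_rmse[best]) / cur_rmse
    # absolute floor keeps floating-point jitter on a ~0 RMSE from counting
    # as an improvement (e.g. a constant response)
    eps_abs <- 1e-10 * (mean(abs(y_test)) + 1)
    if (!is.finite(improve) || improve <= tol ||
        cur_rmse - cand_rmse[best] <= eps_abs) break
    step <- step + 1L
    current <- ampm_spec(tok, session, c(current$terms, remaining[best]))
    fit <- cand_fit[[best]]
    cur_rmse <- cand_rmse[best]
    trace <- rbind(trace, data.frame(
      step = step, term = label_term(remaining[[best]], session),
      test_rmse = cur_rmse, accepted = TRUE, stringsAsFactors = FALSE))
    remaining <- remaining[-best]
  }

  report <- validation_report(
    stats::setNames(list(fit), paste0(tok, "_", session)),
    list(calibration = calib, test = test, validation = val))
  structure(list(spec = current, fit = fit, trace = trace, report = report,
                 notes = notes),
            class = "ampm_selection")
}

#' @export
print.ampm_selection <- function(x, ...) {
  cat("Forward stepwise selection (TEST-RMSE criterion)\n")
  cat("  selected:", format_model(x$spec), "\n")
  cat("  trace:\n")
  print(x$trace, row.names = FALSE)
  if (length(x$notes)) cat("  notes:", length(x$notes), "candidate(s) skipped\n")
  invisible(x)
}
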