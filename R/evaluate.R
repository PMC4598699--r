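#' Root mean squared error with parameter-count correction
#'
#' `RMSE = sqrt(SSE / (n - p))` where `SSE` is the sum of squared
#' observed-minus-predicted differences and `p` the number of estimated
#' parameters, intercept included.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @param p number of parameters (>= 1).
#' @return the RMSE, in response units.
#' @export
#' @examples
#' rmse(c(1, 2, 3), c(1, 2, 4), p = 1)  # sqrt(1/2)
rmse <- function(observed, predicted, p) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n <= p) stop("need n > p (n = ", n, ", p = ", p, ")", call. = FALSE)
  sqrt(sum((observed - predicted)^2) / (n - p))
}

#' Correlation-based accuracy statistics
#'
#' The coefficient of determination is computed as the squared Pearson
#' correlation between observed and predicted values, and the reported
#' correlation `R_y,yhat = 100 * sqrt(R2)` is therefore the absolute Pearson
#' correlation in percent; the sign is carried separately (a perfectly
#' anti-correlated predictor reports 100% with `sign = -1`).
#'
#' @param observed,predicted numeric vectors (>= 3 pairs, both with nonzero
#'   variance).
#' @return a list with `r2` (fraction), `r_y_yhat` (%), `sign` (+1/-1) and
#'   `sigma_yhat` (SD of the predictions).
#' @export
correlation_stats <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted))
  if (length(observed) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0)
    stop("zero variance in observed or predicted values", call. = FALSE)
  r <- stats::cor(observed, predicted)
  list(r2 = r^2, r_y_yhat = 100 * abs(r), sign = sign(r),
       sigma_yhat = stats::sd(predicted))
}

#' Assemble the goodness-of-fit statistics of a prediction
#'
#' @param observed,predicted numeric vectors.
#' @param p number of estimated parameters (intercept included).
#' @return an object of class `"ampm_fitstats"`: `n, p, sse, rmse, r2,
#'   r_y_yhat` (%), `sign`, `sigma_yhat`, `sd_observed`. Unlike
#'   [correlation_stats()], a degenerate case (constant observations or
#'   predictions, e.g. an intercept-only model) is tolerated here: the
#'   correlation fields come back `NA` rather than erroring, so that such
#'   fits still carry their RMSE.
#' @export
fit_stats <- function(observed, predicted, p) {
  cs <- tryCatch(correlation_stats(observed, predicted),
                 error = function(e) list(r2 = NA_real_,
                                          r_y_yhat = NA_real_,
                                          sign = NA_real_,
                                          sigma_yhat = stats::sd(predicted)))
  structure(list(n = length(observed), p = p,
                 sse = sum((observed - predicted)^2),
                 rmse = rmse(observed, predicted, p),
                 r2 = cs$r2, r_y_yhat = cs$r_y_yhat, sign = cs$sign,
                 sigma_yhat = cs$sigma_yhat,
                 sd_observed = stats::sd(observed)),
            class = "ampm_fitstats")
}

#' @export
print.ampm_fitstats <- function(x, ...) {
  cat(sprintf(paste0("n = %d, p = %d, RMSE = %.4g, R2 = %.4f, ",
                     "R_y,yhat = %.1f%%, sigma_yhat = %.4g, SD(obs) = %.4g\n"),
              x$n, x$p, x$rmse, x$r2, x$r_y_yhat, x$sigma_yhat,
              x$sd_observed))
  invisible(x)
}

#' Prediction-spread criterion
#'
#' A well-behaved daily-yield predictor should have a prediction SD close to,
#' but not above, the SD of the observed daily yields. Returns `TRUE` when
#' `sigma_yhat <= sd_observed` (boundary passes).
#'
#' @param stats an `"ampm_fitstats"` object (or any list with `sigma_yhat`
#'   and `sd_observed`).
#' @return logical.
#' @export
sigma_check <- function(stats) {
  isTRUE(stats$sigma_yhat <= stats$sd_observed)
}

#' AM/PM/daily correlation table
#'
#' Pearson correlations (in %) among morning, evening and daily values,
#' separately for contents (g/dL) and yields, computed from fully observed
#' two-milking records. Milk has no content columns; its yield correlations
#' use the AM/PM/daily kg.
#'
#' @param val_records table from [make_validation_dataset()] (>= 3 records).
#' @param traits traits to include (default all nine).
#' @return a data.frame with columns `trait`, `content_am_pm`,
#'   `content_am_daily`, `content_pm_daily`, `yield_am_pm`, `yield_am_daily`,
#'   `yield_pm_daily`, each in [-100, 100] (contents `NA` for milk).
#' @export
correlation_table <- function(val_records, traits = trait_catalog()$col) {
  if (nrow(val_records) < 3L) stop("need at least 3 records", call. = FALSE)
  pc <- function(a, b) 100 * stats::cor(a, b)
  rows <- lapply(traits, function(t) {
    tok <- resolve_trait(t)
    if (tok == "milk") {
      a <- val_records$milk_am; p <- val_records$milk_pm
      d <- val_records$milk_daily
      data.frame(trait = "milk",
                 content_am_pm = NA_real_, content_am_daily = NA_real_,
                 content_pm_daily = NA_real_,
                 yield_am_pm = pc(a, p), yield_am_daily = pc(a, d),
                 yield_pm_daily = pc(p, d))
    } else {
      ca <- val_records[[paste0("content_am_", tok)]]
      cp <- val_records[[paste0("content_pm_", tok)]]
      cd <- val_records[[paste0("content_daily_", tok)]]
      ya <- val_records[[paste0("yield_am_", tok)]]
      yp <- val_records[[paste0("yield_pm_", tok)]]
      yd <- val_records[[paste0("yield_daily_", tok)]]
      data.frame(trait = tok,
                 content_am_pm = pc(ca, cp), content_am_daily = pc(ca, cd),
                 content_pm_daily = pc(cp, cd),
                 yield_am_pm = pc(ya, yp), yield_am_daily = pc(ya, yd),
                 yield_pm_daily = pc(yp, yd))
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Calibration/validation statistics report
#'
#' For each fitted model and each dataset, computes the prediction-accuracy
#' triplet: SD of the predictions (`sigma_yhat`), RMSE (with the model's
#' parameter count) and `R_y,yhat` in percent. On the model's own training
#' data the values coincide with the fit-time statistics.
#'
#' @param models named list of `"ampm_model"` objects (names are free;
#'   a `NULL` element is reported as an absent model, not an error).
#' @param datasets named list of session frames ([as_session_records()]);
#'   each model is evaluated on every dataset.
#' @return a data.frame with columns `model, trait, session, dataset, n,
#'   sigma_yhat, rmse, r_y_yhat`.
#' @export
validation_report <- function(models, datasets) {
  stopifnot(length(names(datasets)) == length(datasets))
  rows <- list()
  for (nm in names(models)) {
    m <- models[[nm]]
    if (is.null(m)) {
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, trait = NA_character_, session = NA_character_,
        dataset = NA_character_, n = NA_integer_, sigma_yhat = NA_real_,
        rmse = NA_real_, r_y_yhat = NA_real_, stringsAsFactors = FALSE)
      next
    }
    for (ds in names(datasets)) {
      dat <- datasets[[ds]]
      obs <- dat[[paste0("yd_", m$spec$trait)]]
      pred <- predict(m, dat)
      # degenerate predictions (e.g. intercept-only models) keep their RMSE
      # but carry no correlation
      cs <- tryCatch(correlation_stats(obs, pred),
                     error = function(e) list(r_y_yhat = NA_real_,
                                              sigma_yhat = stats::sd(pred)))
      rows[[length(rows) + 1L]] <- data.frame(
        model = nm, trait = m$spec$trait, session = m$spec$session,
        dataset = ds, n = length(obs), sigma_yhat = cs$sigma_yhat,
        rmse = rmse(obs, pred, m$p), r_y_yhat = cs$r_y_yhat,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a validation report as aligned text
#'
#' @param report a data.frame from [validation_report()].
#' @return a character vector of lines (invisibly printed with `cat`).
#' @export
format_report <- function(report) {
  fr <- report
  for (cl in c("sigma_yhat", "rmse", "r_y_yhat"))
    fr[[cl]] <- sprintf("%.2f", report[[cl]])
  txt <- utils::capture.output(print(fr, row.names = FALSE))
  txt
}
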