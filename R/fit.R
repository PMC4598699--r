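#' Build the per-session modelling frame
#'
#' Turns a decomposed calibration table ([expected_split()]) or a fully
#' observed validation table ([make_validation_dataset()]) into the flat
#' frame the models are fitted on: one milking's milk yield and contents as
#' predictors, daily yields as responses.
#'
#' @param data a table with `content_am_*` / `content_pm_*`,
#'   `yield_daily_*`, and `milk_am` / `milk_pm` / `milk_daily` columns.
#' @param session `"AM"` or `"PM"`.
#' @return a data.frame with `cow_id, herd_id, dim, parity, month`,
#'   `milk` (kg at the session), `q_<t>` (g/dL at the session) and
#'   `yd_<t>` (daily yield: kg/day for milk, g/day otherwise).
#' @export
as_session_records <- function(data, session) {
  session <- match_session(session)
  sfx <- tolower(session)
  out <- data[c("cow_id", "herd_id", "dim", "parity", "month")]
  out$milk <- data[[paste0("milk_", sfx)]]
  out$yd_milk <- data$milk_daily
  for (t in fa_trait_cols()) {
    out[[paste0("q_", t)]] <- data[[paste0("content_", sfx, "_", t)]]
    out[[paste0("yd_", t)]] <- data[[paste0("yield_daily_", t)]]
  }
  rownames(out) <- NULL
  out
}

class_columns <- function(records) {
  list(dim = as.character(dim_class(records$dim)),
       parity = as.character(parity_class(records$parity)),
       month = as.character(as.integer(records$month)))
}

term_cell_ids <- function(term, cls) {
  do.call(paste, c(unname(cls[term$classes]), list(sep = ":")))
}

#' Build the design matrix of a model specification
#'
#' One intercept column, then per term: a single column holding the covariate
#' product when the term has no class factors; otherwise one column per
#' occupied subclass cell, equal to the covariate product inside the cell and
#' zero outside (plain indicator columns when the term has no covariates).
#' Unoccupied cells produce no column. Cells are ordered by their sorted cell
#' id, so the layout does not depend on row order.
#'
#' @param records a session frame from [as_session_records()].
#' @param spec an [ampm_spec()] model specification.
#' @return a list with `X` (numeric matrix, labelled columns), `labels`,
#'   `term_cells` (per term, the occupied cell ids), and `cls_levels` (the
#'   class levels observed, used to guard prediction).
#' @export
build_design <- function(records, spec) {
  n <- nrow(records)
  cls <- class_columns(records)
  needed <- unique(unlist(lapply(spec$terms, `[[`, "covariates")))
  miss <- setdiff(needed, names(records))
  if (length(miss))
    stop("records lack covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cols <- list("(Intercept)" = rep(1, n))
  term_cells <- vector("list", length(spec$terms))
  for (k in seq_along(spec$terms)) {
    term <- spec$terms[[k]]
    lab <- label_term(term, spec$session)
    v <- rep(1, n)
    for (cv in term$covariates) v <- v * records[[cv]]
    if (!length(term$classes)) {
      cols[[lab]] <- v
      term_cells[[k]] <- character(0)
    } else {
      ids <- term_cell_ids(term, cls)
      cells <- sort(unique(ids))
      for (cell in cells) cols[[paste0(lab, "[", cell, "]")]] <- v * (ids == cell)
      term_cells[[k]] <- cells
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  list(X = X, labels = names(cols), term_cells = term_cells,
       cls_levels = lapply(cls, function(x) sort(unique(x))))
}

#' Fit a daily-yield prediction model
#'
#' Least-squares fit of an [ampm_spec()] on a session frame, via a
#' rank-revealing pivoted QR ([stats::lm.fit()]). Aliased (linearly
#' dependent) columns are dropped deterministically — earlier columns are
#' kept — and their coefficients reported as `NA`; the parameter count `p`
#' counts the estimated (non-aliased) coefficients, intercept included.
#'
#' @param spec an [ampm_spec()].
#' @param data a session frame from [as_session_records()], or any data.frame
#'   carrying the spec's response `yd_<trait>` and covariate/class columns.
#' @return an object of class `"ampm_model"` with components `spec`,
#'   `coefficients` (named, `NA` = aliased), `n`, `p`, `fitted.values`,
#'   `residuals`, `stats` (an `"ampm_fitstats"`, see [fit_stats()]), and the
#'   design metadata needed by [predict.ampm_model()].
#' @seealso [predict.ampm_model()], [stepwise_select()], [preset_models()]
#' @export
#' @examples
#' truth <- simulate_herds(sim_config(n_herds = 4, cows_per_herd = 8,
#'                                    test_days_per_cow = 4, seed = 7))
#' cal <- as_session_records(make_validation_dataset(truth), "AM")
#' fit <- ampm_fit(ampm_spec("fat", "AM", list(
#'   ampm_term(c("q_fat", "milk"), character()))), cal)
#' summary(fit)
ampm_fit <- function(spec, data) {
  stopifnot(inherits(spec, "ampm_spec"))
  ycol <- paste0("yd_", spec$trait)
  if (is.null(data[[ycol]]))
    stop("data lack the response column ", ycol, call. = FALSE)
  y <- data[[ycol]]
  keep <- is.finite(y)
  data <- data[keep, , drop = FALSE]
  y <- y[keep]
  if (!length(y)) stop("no usable rows", call. = FALSE)
  des <- build_design(data, spec)
  if (nrow(des$X) < ncol(des$X))
    stop("fewer rows (", nrow(des$X), ") than design columns (",
         ncol(des$X), ")", call. = FALSE)
  fit <- stats::lm.fit(des$X, y)
  beta <- fit$coefficients
  p <- sum(!is.na(beta))
  beta0 <- ifelse(is.na(beta), 0, beta)
  fitted <- drop(des$X %*% beta0)
  obj <- structure(list(
    spec = spec,
    coefficients = beta,
    n = length(y),
    p = p,
    fitted.values = fitted,
    residuals = y - fitted,
    stats = fit_stats(y, fitted, p),
    labels = des$labels,
    term_cells = des$term_cells,
    cls_levels = des$cls_levels
  ), class = "ampm_model")
  obj
}

#' @export
print.ampm_model <- function(x, ...) {
  cat(sprintf("Daily %s yield predicted from the %s milking\n",
              x$spec$trait, x$spec$session))
  cat("  ", format_model(x$spec), "\n", sep = "")
  cat(sprintf("  n = %d, p = %d (of %d design columns)\n",
              x$n, x$p, length(x$coefficients)))
  s <- x$stats
  if (!is.null(s))
    cat(sprintf("  RMSE = %.4g, R_y,yhat = %.1f%%, sigma_yhat = %.4g\n",
                s$rmse, s$r_y_yhat, s$sigma_yhat))
  invisible(x)
}

#' @export
summary.ampm_model <- function(object, ...) {
  structure(list(model = object), class = "summary.ampm_model")
}

#' @export
print.summary.ampm_model <- function(x, ...) {
  m <- x$model
  print(m)
  s <- m$stats
  cat(sprintf("  SSE = %.6g, R2 = %.4f, SD(observed) = %.4g [sigma check: %s]\n",
              s$sse, s$r2, s$sd_observed,
              if (sigma_check(s)) "pass" else "FAIL"))
  est <- m$coefficients[!is.na(m$coefficients)]
  cat("  estimated coefficients (first 10):\n")
  print(utils::head(round(est, 6), 10))
  invisible(x)
}

#' @export
coef.ampm_model <- function(object, ...) object$coefficients

#' @export
fitted.ampm_model <- function(object, ...) object$fitted.values

#' @export
residuals.ampm_model <- function(object, ...) object$residuals

#' Predict daily yields from single-milking records
#'
#' Evaluates the fitted linear predictor on new session records. All class
#' levels appearing in the new records must have been seen in training;
#' an unseen level raises an error naming it (no silent extrapolation). A
#' seen-level combination (cell) that happened to be unoccupied in training
#' contributes zero for that term.
#'
#' @param object an `"ampm_model"`.
#' @param newdata a session frame ([as_session_records()]) for the model's
#'   session.
#' @param ... unused.
#' @return numeric vector of predicted daily yields.
#' @export
predict.ampm_model <- function(object, newdata, ...) {
  spec <- object$spec
  n <- nrow(newdata)
  cls <- class_columns(newdata)
  used_classes <- unique(unlist(lapply(spec$terms, `[[`, "classes")))
  for (cl in used_classes) {
    unseen <- setdiff(unique(cls[[cl]]), object$cls_levels[[cl]])
    if (length(unseen))
      stop("unseen ", cl, " level(s) in newdata: ",
           paste(unseen, collapse = ", "), call. = FALSE)
  }
  beta <- ifelse(is.na(object$coefficients), 0, object$coefficients)
  pred <- rep(beta[["(Intercept)"]], n)
  ci <- 1L
  for (k in seq_along(spec$terms)) {
    term <- spec$terms[[k]]
    v <- rep(1, n)
    for (cv in term$covariates) v <- v * newdata[[cv]]
    if (!length(term$classes)) {
      ci <- ci + 1L
      pred <- pred + beta[[ci]] * v
    } else {
      ids <- term_cell_ids(term, cls)
      for (cell in object$term_cells[[k]]) {
        ci <- ci + 1L
        if (beta[[ci]] != 0) {
          hit <- ids == cell
          if (any(hit)) pred[hit] <- pred[hit] + beta[[ci]] * v[hit]
        }
      }
    }
  }
  pred
}

#' Observed-versus-predicted plot for a fitted model
#'
#' @param x an `"ampm_model"`.
#' @param newdata optional session frame; defaults to the training fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ampm_model <- function(x, newdata = NULL, ...) {
  if (is.null(newdata)) {
    obs <- x$fitted.values + x$residuals
    pred <- x$fitted.values
  } else {
    obs <- newdata[[paste0("yd_", x$spec$trait)]]
    pred <- predict(x, newdata)
  }
  unit <- if (x$spec$trait == "milk") "kg/day" else "g/day"
  graphics::plot(obs, pred,
                 xlab = sprintf("observed daily yield (%s)", unit),
                 ylab = sprintf("predicted daily yield (%s)", unit),
                 main = sprintf("%s, %s milking", x$spec$trait, x$spec$session),
                 ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
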