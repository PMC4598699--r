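#' How much milking-interval variation do production traits explain?
#'
#' Fits five nested least-squares regressions of the milking interval (MI,
#' hours preceding the chosen milking) on increasingly rich sets of routinely
#' recorded production covariates:
#' \enumerate{
#'   \item daily milk yield;
#'   \item + the milking's milk yield;
#'   \item + the milking's fat content (g/dL);
#'   \item + DIM class;
#'   \item + parity class.
#' }
#' and reports each model's R-squared in percent, together with a partial
#' F-test of every added block. Nested least squares guarantees the R-squared
#' sequence is non-decreasing. A large jump when the milking's own yield
#' enters reflects the interval-share mechanism: the milk accumulated before
#' a milking is roughly proportional to the preceding interval.
#'
#' @param records a table from [make_validation_dataset()] (needs `mi_am` /
#'   `mi_pm`, `milk_daily`, session milk and session fat content) with >= 2
#'   distinct MI values.
#' @param session which milking's interval, yield and content to use
#'   (`"AM"` default).
#' @param alpha significance level of the partial F-tests (default 0.05).
#' @return an object of class `"ampm_mireport"`: a data.frame with columns
#'   `model` (label), `r2_percent`, `p_partial_f` (`NA` for the first model)
#'   and `significant`.
#' @export
mi_nested_regressions <- function(records, session = "AM", alpha = 0.05) {
  session <- match_session(session)
  sfx <- tolower(session)
  mi <- records[[paste0("mi_", sfx)]]
  if (is.null(mi)) stop("records lack the mi_", sfx, " column", call. = FALSE)
  if (length(unique(mi)) < 2L)
    stop("milking interval has no variance to explain", call. = FALSE)
  d <- data.frame(
    mi = mi,
    milk_daily = records$milk_daily,
    milk_session = records[[paste0("milk_", sfx)]],
    fat_session = records[[paste0("content_", sfx, "_fat")]],
    dim_cl = dim_class(records$dim),
    parity_cl = parity_class(records$parity))
  forms <- list(
    mi ~ milk_daily,
    mi ~ milk_daily + milk_session,
    mi ~ milk_daily + milk_session + fat_session,
    mi ~ milk_daily + milk_session + fat_session + dim_cl,
    mi ~ milk_daily + milk_session + fat_session + dim_cl + parity_cl)
  labels <- c(
    "milk daily yield",
    sprintf("+ milk (%s) yield", session),
    sprintf("+ fat (%s) content (g/dL of milk)", session),
    "+ DIM",
    "+ parity")
  fits <- lapply(forms, stats::lm, data = d)
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1)) * 100
  pval <- c(NA_real_, vapply(seq_len(4L), function(i) {
    a <- stats::anova(fits[[i]], fits[[i + 1L]])
    a[["Pr(>F)"]][2L]
  }, numeric(1)))
  out <- data.frame(model = labels, r2_percent = r2, p_partial_f = pval,
                    significant = !is.na(pval) & pval < alpha,
                    stringsAsFactors = FALSE)
  attr(out, "session") <- session
  class(out) <- c("ampm_mireport", "data.frame")
  out
}

#' @export
print.ampm_mireport <- function(x, ...) {
  cat(sprintf("Milking-interval variance explained (%s interval)\n",
              attr(x, "session")))
  df <- as.data.frame(x)
  df$r2_percent <- sprintf("%.2f", df$r2_percent)
  print(df[c("model", "r2_percent", "significant")], row.names = FALSE)
  invisible(x)
}
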