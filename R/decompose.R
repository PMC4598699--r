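#' Regress a trait's per-milking yield on the milking's milk yield
#'
#' Estimates the b-coefficient of the selection-index construction from
#' alternate (T-scheme) records: a through-origin least-squares regression of
#' the trait yield at a milking (content x milk x 10, in g) on the milk yield
#' at the same milking (kg). The slope is `b = sum(m*y) / sum(m^2)`, in g of
#' trait per kg of milk. No intercept is fitted: the construction uses
#' expected yields of the form `b x milk`, which a free intercept would break.
#'
#' @param t_records alternate-scheme table from [make_t_dataset()] (or any
#'   table with `session`, `milk` and `content_<trait>` columns).
#' @param trait a content-bearing trait (id or column token).
#' @param session `"AM"` or `"PM"`; only that session's records are used.
#' @return an object of class `"ampm_b"`: a list with `b` (slope, g/kg), `n`,
#'   `resid_sd` (g), `se` (slope standard error, g/kg), `trait`, `session`.
#' @export
#' @examples
#' tr <- data.frame(session = "AM", milk = c(10, 12, 15),
#'                  content_fat = c(420, 470, 610) / (c(10, 12, 15) * 10))
#' estimate_b(tr, "fat", "AM")$b  # 18990/469
estimate_b <- function(t_records, trait, session) {
  tok <- resolve_trait(trait, allow_milk = FALSE)
  session <- match_session(session)
  rec <- t_records[t_records$session == session, , drop = FALSE]
  if (nrow(rec) < 2L)
    stop("need >= 2 ", session, " records to estimate b", call. = FALSE)
  m <- rec$milk
  if (any(m <= 0)) stop("milk yields must be positive", call. = FALSE)
  y <- yield_from_content(rec[[paste0("content_", tok)]], m)
  sm2 <- sum(m^2)
  if (sm2 == 0) stop("sum of squared milk yields is zero", call. = FALSE)
  b <- sum(m * y) / sm2
  res <- y - b * m
  resid_sd <- sqrt(sum(res^2) / (length(y) - 1L))
  structure(list(b = b, n = length(y), resid_sd = resid_sd,
                 se = resid_sd / sqrt(sm2), trait = tok, session = session),
            class = "ampm_b")
}

#' @export
print.ampm_b <- function(x, ...) {
  cat(sprintf("b[%s, %s] = %.4f g/kg (n = %d, residual SD = %.2f g)\n",
              x$trait, x$session, x$b, x$n, x$resid_sd))
  invisible(x)
}

#' Estimate b-coefficients for all traits and both sessions
#'
#' @param t_records alternate-scheme table from [make_t_dataset()].
#' @param traits traits to cover (default: all content-bearing traits).
#' @return a data.frame with columns `trait`, `session`, `b`, `n`,
#'   `resid_sd`, `se`.
#' @seealso [estimate_b()]
#' @export
estimate_b_table <- function(t_records, traits = fa_trait_cols()) {
  rows <- lapply(traits, function(tr) {
    do.call(rbind, lapply(c("AM", "PM"), function(s) {
      e <- estimate_b(t_records, tr, s)
      data.frame(trait = e$trait, session = s, b = e$b, n = e$n,
                 resid_sd = e$resid_sd, se = e$se, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

b_lookup <- function(b_table, trait, session) {
  i <- which(b_table$trait == trait & b_table$session == session)
  if (length(i) != 1L)
    stop("no b-coefficient for trait '", trait, "', session ", session,
         call. = FALSE)
  b_table$b[i]
}

#' Decompose 50/50 composite records into expected AM/PM phenotypes
#'
#' Implements the selection-index combination: the observed composite content
#' (`0.5 x AM + 0.5 x PM` by construction of the sample) is blended with the
#' session-specific information carried by the b-coefficients to give expected
#' per-milking contents and yields plus expected daily yields.
#'
#' With `method = "offset"` (default) the through-origin slopes imply
#' per-session contents `q_s = b_s / 10` (g/dL); the composite content is
#' shifted by half their difference: `content_AM = content_5050 + d/2`,
#' `content_PM = content_5050 - d/2` with `d = q_AM - q_PM`. This is the
#' linear rule that uses only the composite observation and `b x milk`,
#' preserves the 50/50 identity exactly, and reproduces the predicted
#' between-session contrast. `method = "ratio"` instead allocates the
#' composite in proportion to the implied contents
#' (`content_AM = 2 c q_AM / (q_AM + q_PM)`), which also preserves the 50/50
#' identity but keeps the session ratio rather than the difference.
#'
#' Expected contents falling below `content_floor` are clipped, with the
#' partner session re-adjusted so `0.5 AM + 0.5 PM` still equals the
#' composite; a warning is raised if more than 1% of records are clipped for
#' any trait.
#'
#' @param s_records composite-scheme table from [make_s_dataset()].
#' @param b_table b-coefficients from [estimate_b_table()].
#' @param method `"offset"` (difference-preserving) or `"ratio"`.
#' @param content_floor positive floor (g/dL) for expected contents.
#' @return a data.frame ("51-trait" layout) with the identification columns,
#'   `milk_am, milk_pm, milk_daily`, and per trait `<t>`:
#'   `content_am_<t>, content_pm_<t>, content_daily_<t>` (g/dL) and
#'   `yield_am_<t>, yield_pm_<t>, yield_daily_<t>` (g). The number of clipped
#'   records per trait is attached as attribute `"n_clipped"`.
#' @export
expected_split <- function(s_records, b_table, method = c("offset", "ratio"),
                           content_floor = 0.001) {
  method <- match.arg(method)
  if (any(s_records$milk_am <= 0) || any(s_records$milk_pm <= 0))
    stop("milk yields must be positive", call. = FALSE)
  stopifnot(content_floor > 0)
  out <- s_records[c("cow_id", "herd_id", "parity", "dim", "month",
                     "milk_am", "milk_pm", "milk_daily")]
  n <- nrow(out)
  n_clipped <- integer(0)
  traits <- unique(b_table$trait)
  for (t in traits) {
    c50 <- s_records[[paste0("content_5050_", t)]]
    if (is.null(c50)) stop("missing column content_5050_", t, call. = FALSE)
    q_am <- b_lookup(b_table, t, "AM") / 10
    q_pm <- b_lookup(b_table, t, "PM") / 10
    if (method == "offset") {
      d <- q_am - q_pm
      c_am <- c50 + 0.5 * d
      c_pm <- c50 - 0.5 * d
    } else {
      w <- q_am + q_pm
      if (w <= 0) stop("implied contents must be positive for method='ratio'",
                       call. = FALSE)
      c_am <- 2 * c50 * q_am / w
      c_pm <- 2 * c50 * q_pm / w
    }
    clip_lo <- c_am < content_floor
    c_am[clip_lo] <- content_floor
    c_pm[clip_lo] <- 2 * c50[clip_lo] - content_floor
    clip_hi <- c_pm < content_floor
    c_pm[clip_hi] <- content_floor
    c_am[clip_hi] <- 2 * c50[clip_hi] - content_floor
    nc <- sum(clip_lo | clip_hi)
    n_clipped[t] <- nc
    if (nc > 0.01 * n)
      warning(sprintf("trait %s: %d of %d records clipped at the content floor",
                      t, nc, n), call. = FALSE)
    y_am <- yield_from_content(c_am, out$milk_am)
    y_pm <- yield_from_content(c_pm, out$milk_pm)
    out[[paste0("content_am_", t)]] <- c_am
    out[[paste0("content_pm_", t)]] <- c_pm
    out[[paste0("content_daily_", t)]] <- (y_am + y_pm) / (10 * out$milk_daily)
    out[[paste0("yield_am_", t)]] <- y_am
    out[[paste0("yield_pm_", t)]] <- y_pm
    out[[paste0("yield_daily_", t)]] <- y_am + y_pm
  }
  attr(out, "n_clipped") <- n_clipped
  rownames(out) <- NULL
  out
}

#' Expected daily yield of a trait
#'
#' The 24-h yield is the sum of the two per-milking yields; for milk it is the
#' sum of the two milkings' kg.
#'
#' @param split a table from [expected_split()] or
#'   [make_validation_dataset()].
#' @param trait a trait id or column token (`"milk"` allowed).
#' @return numeric vector: g/day (kg/day for milk).
#' @export
#' @examples
#' d <- data.frame(yield_am_c181 = 94.13, yield_pm_c181 = 120.85)
#' daily_yield(d, "C18:1cis9")  # 214.98
daily_yield <- function(split, trait) {
  tok <- resolve_trait(trait)
  if (tok == "milk") return(split$milk_am + split$milk_pm)
  split[[paste0("yield_am_", tok)]] + split[[paste0("yield_pm_", tok)]]
}
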