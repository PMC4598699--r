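#' Configuration for the synthetic test-day generator
#'
#' Builds and validates the parameter set of [simulate_herds()]. Defaults give
#' a desk-scale population of 40 herds x 30 cows x 8 monthly test days
#' (9,600 cow-days) with the structural features of routine milk recording:
#' a Wood lactation curve scaled by parity, a milking split driven by the
#' share of the 24-h day preceding each milking, a dilution effect (more milk
#' at a milking, lower fat content), fatty-acid contents as fractions of fat
#' with a seasonal swing on the unsaturated/long-chain side, and additive
#' measurement noise.
#'
#' @param n_herds,cows_per_herd,test_days_per_cow population size (counts >= 1).
#' @param seed integer seed; the generator is fully reproducible given the
#'   config (identical config => bit-identical tables).
#' @param lactation_curve named list with elements `"1"`, `"2"`, `"3+"`, each a
#'   numeric triplet `(scale, rise, decay)` of the Wood curve
#'   `scale * DIM^rise * exp(-decay * DIM)` (kg/day).
#' @param mi_hours length-2 numeric `(mean, sd)` of the interval (hours)
#'   preceding the AM milking; the two daily intervals sum to 24 h.
#' @param dilution_slope decrease in fat content (g/dL) per extra kg of milk
#'   at a milking, applied to each milking's deviation from the half-day mean.
#' @param season_amplitude amplitude (g/dL) of the calendar-month sinusoid
#'   added to the unsaturated / long-chain contents (peak in July).
#' @param fa_fraction named numeric vector of mean FA-group fractions of fat
#'   content, names `sfa, mufa, ufa, scfa, mcfa, lcfa, c181`; `sfa + ufa` and
#'   `scfa + mcfa + lcfa` must each equal 1 (tolerance 1e-9).
#' @param noise_sd_content measurement noise SD on fat content, g/dL (FA
#'   traits get proportionally scaled noise).
#' @param noise_sd_milk noise SD on milk at a milking, kg.
#' @param base_fat_content population mean fat content, g/dL.
#' @return an object of class `"sim_config"` (a validated list).
#' @seealso [simulate_herds()]
#' @export
sim_config <- function(n_herds = 40L,
                       cows_per_herd = 30L,
                       test_days_per_cow = 8L,
                       seed = 1L,
                       lactation_curve = list(
                         "1"  = c(scale = 14.8, rise = 0.20, decay = 0.0035),
                         "2"  = c(scale = 17.4, rise = 0.21, decay = 0.0042),
                         "3+" = c(scale = 18.2, rise = 0.22, decay = 0.0046)),
                       mi_hours = c(mean = 11.5, sd = 1.0),
                       dilution_slope = 0.15,
                       season_amplitude = 0.05,
                       fa_fraction = c(sfa = 0.66, mufa = 0.29, ufa = 0.34,
                                       scfa = 0.09, mcfa = 0.51, lcfa = 0.40,
                                       c181 = 0.19),
                       noise_sd_content = 0.15,
                       noise_sd_milk = 0.9,
                       base_fat_content = 4.3) {
  cfg <- list(n_herds = as.integer(n_herds),
              cows_per_herd = as.integer(cows_per_herd),
              test_days_per_cow = as.integer(test_days_per_cow),
              seed = as.integer(seed),
              lactation_curve = lactation_curve,
              mi_hours = unname(mi_hours),
              dilution_slope = dilution_slope,
              season_amplitude = season_amplitude,
              fa_fraction = fa_fraction,
              noise_sd_content = noise_sd_content,
              noise_sd_milk = noise_sd_milk,
              base_fat_content = base_fat_content)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' Read a generator configuration from a YAML file
#'
#' Any subset of the [sim_config()] arguments may appear as top-level keys;
#' missing keys keep their defaults. `lactation_curve` is given as a mapping
#' of parity class to a `[scale, rise, decay]` triplet, `mi_hours` as a
#' `[mean, sd]` pair, and `fa_fraction` as a mapping of trait token to
#' fraction.
#'
#' @param path YAML file path.
#' @return a validated `"sim_config"`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$mi_hours)) raw$mi_hours <- unlist(raw$mi_hours)
  if (!is.null(raw$fa_fraction)) raw$fa_fraction <- unlist(raw$fa_fraction)
  if (!is.null(raw$lactation_curve))
    raw$lactation_curve <- lapply(raw$lactation_curve, unlist)
  do.call(sim_config, raw)
}

validate_sim_config <- function(cfg) {
  counts <- c(cfg$n_herds, cfg$cows_per_herd, cfg$test_days_per_cow)
  if (any(is.na(counts)) || any(counts < 1L))
    stop("all population counts must be >= 1", call. = FALSE)
  if (!all(c("1", "2", "3+") %in% names(cfg$lactation_curve)))
    stop("lactation_curve needs elements '1', '2', '3+'", call. = FALSE)
  if (length(cfg$mi_hours) != 2L || cfg$mi_hours[2] < 0)
    stop("mi_hours must be (mean, sd) with sd >= 0", call. = FALSE)
  if (cfg$mi_hours[1] <= 0 || cfg$mi_hours[1] >= 24)
    stop("mean AM interval must lie in (0, 24) hours", call. = FALSE)
  sds <- c(cfg$noise_sd_content, cfg$noise_sd_milk)
  if (any(sds < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  fr <- cfg$fa_fraction
  need <- c("sfa", "mufa", "ufa", "scfa", "mcfa", "lcfa", "c181")
  if (!all(need %in% names(fr)))
    stop("fa_fraction needs names: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(fr <= 0) || any(fr >= 1))
    stop("FA fractions of fat must lie in (0, 1)", call. = FALSE)
  if (abs(fr[["sfa"]] + fr[["ufa"]] - 1) > 1e-9)
    stop("fa_fraction: sfa + ufa must equal 1", call. = FALSE)
  if (abs(fr[["scfa"]] + fr[["mcfa"]] + fr[["lcfa"]] - 1) > 1e-9)
    stop("fa_fraction: scfa + mcfa + lcfa must equal 1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic test-day generator configuration\n")
  cat(sprintf("  %d herds x %d cows x %d test days (%d cow-days), seed %d\n",
              x$n_herds, x$cows_per_herd, x$test_days_per_cow,
              x$n_herds * x$cows_per_herd * x$test_days_per_cow, x$seed))
  cat(sprintf("  AM interval %.1f +/- %.1f h; dilution %.3f g/dL per kg\n",
              x$mi_hours[1], x$mi_hours[2], x$dilution_slope))
  invisible(x)
}

wood_curve <- function(dim, pars) {
  pars[[1]] * dim^pars[[2]] * exp(-pars[[3]] * dim)
}

# value = base + N(0, sd); redraw the noise of rows at or below `floor`
# until all clear it or the retry cap trips
draw_above <- function(base, sd, floor, cap = 20L, what = "milk yield") {
  val <- base + rnorm(length(base), 0, sd)
  idx <- which(val <= floor)
  tries <- 0L
  while (length(idx) && tries < cap) {
    val[idx] <- base[idx] + rnorm(length(idx), 0, sd)
    idx <- which(val <= floor)
    tries <- tries + 1L
  }
  if (length(idx))
    stop("could not simulate a positive ", what, " after ", cap,
         " retries; check the configuration", call. = FALSE)
  val
}

#' Simulate ground-truth cow milking days
#'
#' Generates per-cow test-day records with both milkings fully observed:
#' milk yield and the contents of fat and the seven FA traits at the AM and
#' PM milking, plus the milking intervals, days in milk, parity and calendar
#' month. This is the ground truth from which the three observation schemes
#' ([make_s_dataset()], [make_t_dataset()], [make_validation_dataset()]) are
#' derived.
#'
#' Mechanics: daily milk follows a parity-scaled Wood curve in DIM plus a cow
#' effect; milk at a milking is the daily yield times that milking's share of
#' the 24-h day (its preceding interval / 24) plus noise; fat content at a
#' milking decreases by `dilution_slope` per kg of milk above the half-day
#' mean (the dilution effect); FA contents are fractions of the milking's fat
#' content, with a seasonal sinusoid moving fat from the saturated/medium
#' fractions to the unsaturated/long-chain fractions in summer. By
#' construction SFA + UFA and SCFA + MCFA + LCFA both sum exactly to the fat
#' content.
#'
#' @param config a [sim_config()] object.
#' @return a data.frame of class `"cow_milking_day"` with one row per cow x
#'   test day: `cow_id, herd_id, parity, dim, month, test_day, mi_am, mi_pm,
#'   milk_am, milk_pm` and `content_am_<t>, content_pm_<t>` for each
#'   content-bearing trait token `<t>` (see [trait_catalog()]).
#' @export
#' @examples
#' truth <- simulate_herds(sim_config(n_herds = 2, cows_per_herd = 3,
#'                                    test_days_per_cow = 2, seed = 42))
#' head(truth)
simulate_herds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  set.seed(config$seed)

  nh <- config$n_herds; nc <- config$cows_per_herd; nd <- config$test_days_per_cow
  n_cows <- nh * nc
  herd_id <- rep(sprintf("H%03d", seq_len(nh)), each = nc)
  cow_id <- sprintf("%s_C%03d", herd_id, rep(seq_len(nc), times = nh))
  herd_start_month <- sample.int(12L, nh, replace = TRUE)

  parity <- parity_class(sample(c("1", "2", "3+"), n_cows, replace = TRUE,
                                prob = c(0.35, 0.28, 0.37)))
  dim0 <- sample(5:120, n_cows, replace = TRUE)
  cow_milk_eff <- rnorm(n_cows, 0, 2.2)         # kg/day, cow-level
  cow_fat_eff <- rnorm(n_cows, 0, 0.35)         # g/dL, cow-level

  rows <- vector("list", nd)
  for (d in seq_len(nd)) {
    dim <- pmin(dim0 + 30L * (d - 1L), 365L)
    month <- ((herd_start_month[rep(seq_len(nh), each = nc)] - 1L + (d - 1L)) %% 12L) + 1L

    pars <- config$lactation_curve[as.character(parity)]
    daily <- mapply(function(dd, pp) wood_curve(dd, pp), dim, pars) +
      cow_milk_eff + rnorm(n_cows, 0, config$noise_sd_milk)
    daily <- pmax(daily, 2)  # floor on daily production (kg); dry-off excluded

    mi_am <- rnorm(n_cows, config$mi_hours[1], config$mi_hours[2])
    mi_am <- pmin(pmax(mi_am, 4), 20)
    mi_pm <- 24 - mi_am

    milk_am <- draw_above(daily * mi_am / 24, config$noise_sd_milk,
                          floor = 0.2, what = "milk yield at the AM milking")
    milk_pm <- draw_above(daily * mi_pm / 24, config$noise_sd_milk,
                          floor = 0.2, what = "milk yield at the PM milking")
    half <- (milk_am + milk_pm) / 2

    # cow-day fat content: cow effect + late-lactation rise + day noise
    fat_day <- config$base_fat_content + cow_fat_eff +
      0.0015 * (dim - 150) + rnorm(n_cows, 0, 0.5 * config$noise_sd_content)
    fat_am <- draw_above(fat_day - config$dilution_slope * (milk_am - half),
                         config$noise_sd_content, floor = 0.5,
                         what = "fat content")
    fat_pm <- draw_above(fat_day - config$dilution_slope * (milk_pm - half),
                         config$noise_sd_content, floor = 0.5,
                         what = "fat content")

    s_term <- config$season_amplitude * sin(2 * pi * (month - 4) / 12)
    fr <- config$fa_fraction
    sd0 <- 0.3 * config$noise_sd_content
    mk_fa <- function(fat_s) {
      ufa <- fat_s * fr[["ufa"]] + s_term + rnorm(n_cows, 0, sd0 * fr[["ufa"]])
      ufa <- pmin(pmax(ufa, 0.02), fat_s - 0.02)
      sfa <- fat_s - ufa
      mufa <- ufa * (fr[["mufa"]] / fr[["ufa"]]) +
        rnorm(n_cows, 0, sd0 * fr[["mufa"]])
      mufa <- pmin(pmax(mufa, 0.01), ufa)
      c181 <- mufa * (fr[["c181"]] / fr[["mufa"]]) +
        rnorm(n_cows, 0, sd0 * fr[["c181"]])
      c181 <- pmin(pmax(c181, 0.005), mufa)
      scfa <- fat_s * fr[["scfa"]] - 0.2 * s_term +
        rnorm(n_cows, 0, sd0 * fr[["scfa"]])
      scfa <- pmax(scfa, 0.005)
      lcfa <- fat_s * fr[["lcfa"]] + 1.2 * s_term +
        rnorm(n_cows, 0, sd0 * fr[["lcfa"]])
      lcfa <- pmin(pmax(lcfa, 0.01), fat_s - scfa - 0.01)
      mcfa <- fat_s - scfa - lcfa
      list(sfa = sfa, mufa = mufa, ufa = ufa, scfa = scfa,
           mcfa = mcfa, lcfa = lcfa, c181 = c181)
    }
    fa_am <- mk_fa(fat_am)
    fa_pm <- mk_fa(fat_pm)

    df <- data.frame(cow_id = cow_id, herd_id = herd_id, parity = parity,
                     dim = as.integer(dim), month = as.integer(month),
                     test_day = d, mi_am = mi_am, mi_pm = mi_pm,
                     milk_am = milk_am, milk_pm = milk_pm,
                     content_am_fat = fat_am, content_pm_fat = fat_pm,
                     stringsAsFactors = FALSE)
    for (t in names(fa_am)) {
      df[[paste0("content_am_", t)]] <- fa_am[[t]]
      df[[paste0("content_pm_", t)]] <- fa_pm[[t]]
    }
    rows[[d]] <- df
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$herd_id, out$cow_id, out$test_day), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cow_milking_day", "data.frame")
  out
}

#' Derive the S-scheme (50/50 composite) dataset
#'
#' Emulates routine recording where one composite sample per cow is made of
#' equal parts AM and PM milk: the observed content of every trait is the
#' midpoint `0.5 * content_AM + 0.5 * content_PM`, while AM, PM and 24-h milk
#' yields are all recorded.
#'
#' @param truth a table from [simulate_herds()].
#' @return a data.frame with `cow_id, herd_id, parity, dim, month, milk_am,
#'   milk_pm, milk_daily` and `content_5050_<t>` per content-bearing trait.
#' @export
make_s_dataset <- function(truth) {
  if (nrow(truth) == 0L) stop("truth table is empty", call. = FALSE)
  out <- truth[c("cow_id", "herd_id", "parity", "dim", "month",
                 "milk_am", "milk_pm")]
  out$milk_daily <- truth$milk_am + truth$milk_pm
  for (t in fa_trait_cols()) {
    out[[paste0("content_5050_", t)]] <-
      0.5 * truth[[paste0("content_am_", t)]] +
      0.5 * truth[[paste0("content_pm_", t)]]
  }
  rownames(out) <- NULL
  out
}

#' Derive the T-scheme (alternate single-milking) dataset
#'
#' Emulates alternate recording: at each herd visit exactly one milking is
#' sampled for every cow, and the sampled session alternates between
#' consecutive visits. Only that session's milk yield and contents appear in
#' the record.
#'
#' @param truth a table from [simulate_herds()].
#' @param start_session session sampled at the first visit (`"AM"` default).
#' @return a data.frame with `cow_id, herd_id, parity, dim, month, test_day,
#'   session, milk` and `content_<t>` columns. Empty `truth` gives an empty
#'   table with the same columns.
#' @export
make_t_dataset <- function(truth, start_session = "AM") {
  start_session <- match_session(start_session)
  sessions <- c("AM", "PM")
  off <- if (start_session == "AM") 0L else 1L
  ses <- sessions[((truth$test_day - 1L + off) %% 2L) + 1L]
  out <- data.frame(cow_id = truth$cow_id, herd_id = truth$herd_id,
                    parity = truth$parity, dim = truth$dim,
                    month = truth$month, test_day = truth$test_day,
                    session = ses, stringsAsFactors = FALSE)
  am <- ses == "AM"
  out$milk <- ifelse(am, truth$milk_am, truth$milk_pm)
  for (t in fa_trait_cols()) {
    out[[paste0("content_", t)]] <-
      ifelse(am, truth[[paste0("content_am_", t)]],
             truth[[paste0("content_pm_", t)]])
  }
  rownames(out) <- NULL
  out
}

#' Derive the fully observed validation dataset
#'
#' Emulates a validation campaign sampling two consecutive milkings: both
#' sessions' milk yields and contents are observed, and per-milking and daily
#' yields are computed (no expectation step). Milking intervals are carried
#' along for the milking-interval analysis.
#'
#' @param truth a table from [simulate_herds()].
#' @return a data.frame with identification and class columns, `mi_am, mi_pm`,
#'   `milk_am, milk_pm, milk_daily`, and per content-bearing trait `<t>` the
#'   columns `content_am_<t>, content_pm_<t>, content_daily_<t>` (g/dL) and
#'   `yield_am_<t>, yield_pm_<t>, yield_daily_<t>` (g), with
#'   `yield = content x milk x 10` and daily values summed over milkings.
#' @export
make_validation_dataset <- function(truth) {
  if (nrow(truth) == 0L) stop("truth table is empty", call. = FALSE)
  out <- truth[c("cow_id", "herd_id", "parity", "dim", "month",
                 "mi_am", "mi_pm", "milk_am", "milk_pm")]
  out$milk_daily <- truth$milk_am + truth$milk_pm
  for (t in fa_trait_cols()) {
    c_am <- truth[[paste0("content_am_", t)]]
    c_pm <- truth[[paste0("content_pm_", t)]]
    y_am <- yield_from_content(c_am, truth$milk_am)
    y_pm <- yield_from_content(c_pm, truth$milk_pm)
    out[[paste0("content_am_", t)]] <- c_am
    out[[paste0("content_pm_", t)]] <- c_pm
    out[[paste0("content_daily_", t)]] <- (y_am + y_pm) / (10 * out$milk_daily)
    out[[paste0("yield_am_", t)]] <- y_am
    out[[paste0("yield_pm_", t)]] <- y_pm
    out[[paste0("yield_daily_", t)]] <- y_am + y_pm
  }
  rownames(out) <- NULL
  out
}

#' Remove records outside mean +/- 3 SD
#'
#' Screens the listed trait columns and drops any record for which at least
#' one value falls outside `[mean - 3 SD, mean + 3 SD]`. Means and SDs are
#' computed once on the input table, before any removal. Columns with zero
#' SD trigger no removals (the rule is vacuous without variance).
#'
#' @param records a data.frame.
#' @param trait_cols character vector of numeric column names to screen.
#' @return a list with `records` (the kept rows), `n_removed`, and
#'   `removed` (integer row indices of the dropped records).
#' @export
#' @examples
#' d <- data.frame(x = c(rnorm(50), 100))
#' apply_outlier_filter(d, "x")$n_removed
apply_outlier_filter <- function(records, trait_cols) {
  if (nrow(records) < 2L) stop("need at least 2 records", call. = FALSE)
  missing_cols <- setdiff(trait_cols, names(records))
  if (length(missing_cols))
    stop("unknown columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  drop <- logical(nrow(records))
  for (cl in trait_cols) {
    v <- records[[cl]]
    m <- mean(v); s <- stats::sd(v)
    if (!is.finite(s) || s == 0) next
    drop <- drop | v < m - 3 * s | v > m + 3 * s
  }
  list(records = records[!drop, , drop = FALSE],
       n_removed = sum(drop),
       removed = which(drop))
}
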