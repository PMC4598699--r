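#' Write / read a pipeline table as CSV
#'
#' Plain-CSV interchange used for every pipeline artifact. Writing then
#' reading then writing again reproduces the file byte for byte.
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `read_table_csv` returns a data.frame; `write_table_csv` its
#'   path, invisibly.
#' @export
write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Published descriptive statistics of the three source datasets
#'
#' The package ships the printed descriptive-statistics tables (mean, SD,
#' min, max of contents and yields per trait x milking) of the three
#' milk-recording datasets behind this methodology: the Luxembourg 50/50
#' calibration records (`"calib"`), the Luxembourg two-milking validation
#' campaign (`"lux"`), and the Walloon expected records (`"wal"`). They are
#' used for arithmetic consistency checks ([fixture_checks()]) and give the
#' scale the synthetic generator aims at; milk rows carry kg/day in the yield
#' columns and no content.
#'
#' @return a data.frame with columns `dataset, trait, session, content_mean,
#'   content_sd, content_min, content_max, yield_mean, yield_sd, yield_min,
#'   yield_max`.
#' @export
reference_stats <- function() {
  path <- system.file("extdata", "reference_stats.csv", package = "ampmyield")
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Arithmetic consistency checks on the published tables
#'
#' Recomputes, from the packaged [reference_stats()] tables, the identities
#' the recording arithmetic imposes and compares them with the printed
#' values: the mean daily yield of every trait must equal the sum of the two
#' mean per-milking yields (daily records are per-record sums), and the mean
#' daily SFA content divided by the mean daily fat content must reproduce the
#' published saturated share of fat (65.9% for the calibration records,
#' 68.2% for the Walloon records). Tolerances only absorb the rounding of the
#' printed values.
#'
#' @return a data.frame of class `"ampm_fixture_checks"` with columns
#'   `check, dataset, trait, expected, computed, diff, tol, pass`.
#' @export
#' @examples
#' all(fixture_checks()$pass)
fixture_checks <- function() {
  rs <- reference_stats()
  rows <- list()
  add <- function(check, dataset, trait, expected, computed, tol) {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, dataset = dataset, trait = trait,
      expected = expected, computed = computed,
      diff = computed - expected, tol = tol,
      pass = abs(computed - expected) <= tol, stringsAsFactors = FALSE)
  }
  get_ <- function(ds, tr, ses, col) {
    rs[[col]][rs$dataset == ds & rs$trait == tr & rs$session == ses]
  }
  for (ds in unique(rs$dataset)) {
    for (tr in unique(rs$trait)) {
      am <- get_(ds, tr, "AM", "yield_mean")
      pm <- get_(ds, tr, "PM", "yield_mean")
      dy <- get_(ds, tr, "daily", "yield_mean")
      # printed means are rounded to 2 decimals; large-N averages can carry
      # a little extra rounding drift, hence the relative component
      add("daily yield = AM + PM", ds, tr, dy, am + pm,
          tol = max(0.05, 5e-4 * dy))
    }
  }
  sfa_share <- function(ds) {
    100 * get_(ds, "sfa", "daily", "content_mean") /
      get_(ds, "fat", "daily", "content_mean")
  }
  add("SFA share of fat (%)", "calib", "sfa", 65.9, sfa_share("calib"), 0.1)
  add("SFA share of fat (%)", "wal", "sfa", 68.2, sfa_share("wal"), 0.1)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ampm_fixture_checks", "data.frame")
  out
}

#' @export
print.ampm_fixture_checks <- function(x, ...) {
  df <- as.data.frame(x)
  df$expected <- sprintf("%.2f", df$expected)
  df$computed <- sprintf("%.2f", df$computed)
  df$diff <- sprintf("%+.3f", as.numeric(df$diff))
  print(df[c("check", "dataset", "trait", "expected", "computed", "diff",
             "pass")], row.names = FALSE)
  cat(sprintf("%d of %d checks pass\n", sum(x$pass), nrow(x)))
  invisible(x)
}

#' Pipeline configuration
#'
#' @param sim a [sim_config()] for on-the-fly simulation of the three
#'   observation schemes.
#' @param outdir output directory for the pipeline artifacts (created if
#'   missing).
#' @param models `"preset"` fits the shipped model forms directly;
#'   `"select"` runs [stepwise_select()] per trait x session (the simulated
#'   validation herds are split in half into TEST and VAL sets).
#' @param traits traits to model (default all nine).
#' @param sessions milkings to model (default both).
#' @param t_start_session first sampled session of the alternate scheme.
#' @param selection_tol relative TEST-RMSE tolerance of the stepwise search.
#' @return a list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            outdir = tempfile("ampm_run_"),
                            models = c("preset", "select"),
                            traits = trait_catalog()$col,
                            sessions = c("AM", "PM"),
                            t_start_session = "AM",
                            selection_tol = 1e-3) {
  structure(list(sim = sim, outdir = outdir, models = match.arg(models),
                 traits = vapply(traits, resolve_trait, character(1),
                                 USE.NAMES = FALSE),
                 sessions = vapply(sessions, match_session, character(1),
                                   USE.NAMES = FALSE),
                 t_start_session = match_session(t_start_session),
                 selection_tol = selection_tol),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Orchestrates the end-to-end sequence on simulated data: ground-truth
#' generation, derivation of the three observation schemes, the +/-3 SD
#' record filter on the composite dataset, b-coefficient estimation from the
#' alternate dataset, selection-index decomposition into the expected-AM/PM
#' calibration table, model fitting (presets or stepwise selection),
#' calibration/validation statistics, the AM/PM/daily correlation table, and
#' the milking-interval nested regressions. All artifacts are written as CSV
#' into `config$outdir` together with a `manifest.csv` recording the seed,
#' row counts and an md5 per file; rerunning with the same configuration
#' reproduces every file bit for bit.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage messages.
#' @return (invisibly) a list of class `"ampm_pipeline"` with the in-memory
#'   artifacts (`truth`, `b_table`, `split`, `models`, `report`,
#'   `correlations`, `mi`, `fixtures`, `manifest`, `files`, and `selection`
#'   traces when selection ran).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(config$outdir, name)
    write_table_csv(df, path)
    files[[name]] <<- path
  }

  stage <- "simulate"
  res <- tryCatch({
    truth <- simulate_herds(config$sim)
    say("simulate: %d cow-days", nrow(truth))
    s_raw <- make_s_dataset(truth)
    t_dat <- make_t_dataset(truth, config$t_start_session)
    val_dat <- make_validation_dataset(truth)

    stage <- "outlier filter"
    screen_cols <- c("milk_daily",
                     paste0("content_5050_", fa_trait_cols()))
    filt <- apply_outlier_filter(s_raw, screen_cols)
    s_dat <- filt$records
    say("outlier filter: removed %d of %d composite records",
        filt$n_removed, nrow(s_raw))

    stage <- "decompose"
    b_table <- estimate_b_table(t_dat)
    split <- expected_split(s_dat, b_table)
    say("decompose: b-coefficients from %d alternate records; %d records split",
        nrow(t_dat), nrow(split))

    stage <- "model fitting"
    calib <- lapply(stats::setNames(config$sessions, config$sessions),
                    function(s) as_session_records(split, s))
    val <- lapply(stats::setNames(config$sessions, config$sessions),
                  function(s) as_session_records(val_dat, s))
    models <- list()
    selections <- list()
    for (ses in config$sessions) {
      for (tr in config$traits) {
        nm <- paste0(tr, "_", ses)
        if (config$models == "preset") {
          models[[nm]] <- ampm_fit(preset_models(tr, ses), calib[[ses]])
        } else {
          herds <- sort(unique(val_dat$herd_id))
          test_h <- herds[seq_along(herds) %% 2L == 1L]
          sel <- stepwise_select(
            tr, ses, calib[[ses]],
            test = val[[ses]][val[[ses]]$herd_id %in% test_h, ],
            val = val[[ses]][!val[[ses]]$herd_id %in% test_h, ],
            tol = config$selection_tol)
          selections[[nm]] <- sel
          models[[nm]] <- sel$fit
        }
      }
    }
    say("model fitting: %d models (%s)", length(models), config$models)

    stage <- "evaluate"
    report <- do.call(rbind, lapply(config$sessions, function(ses) {
      ms <- models[grepl(paste0("_", ses, "$"), names(models))]
      validation_report(ms, list(calibration = calib[[ses]],
                                 validation = val[[ses]]))
    }))
    rownames(report) <- NULL
    cortab <- correlation_table(val_dat)

    stage <- "milking-interval analysis"
    mi <- lapply(stats::setNames(config$sessions, config$sessions),
                 function(s) mi_nested_regressions(val_dat, s))

    stage <- "fixture checks"
    fixtures <- fixture_checks()

    stage <- "write artifacts"
    emit(s_dat, "s_dataset.csv")
    emit(t_dat, "t_dataset.csv")
    emit(val_dat, "validation_dataset.csv")
    emit(split, "calibration_split.csv")
    emit(b_table, "b_coefficients.csv")
    emit(report, "validation_report.csv")
    writeLines(format_report(report),
               file.path(config$outdir, "validation_report.txt"))
    files[["validation_report.txt"]] <- file.path(config$outdir,
                                                  "validation_report.txt")
    emit(cortab, "correlation_table.csv")
    for (ses in names(mi))
      emit(as.data.frame(mi[[ses]]), sprintf("mi_analysis_%s.csv", ses))
    for (nm in names(selections))
      emit(selections[[nm]]$trace, sprintf("selection_trace_%s.csv", nm))
    emit(as.data.frame(fixtures), "fixture_checks.csv")

    manifest <- data.frame(
      key = c("package_version", "seed", "n_herds", "cows_per_herd",
              "test_days_per_cow", "models", "n_truth", "n_s_removed",
              "n_s_kept", "n_t", "n_validation",
              paste0("md5_", names(files))),
      value = c(as.character(utils::packageVersion("ampmyield")),
                config$sim$seed, config$sim$n_herds,
                config$sim$cows_per_herd, config$sim$test_days_per_cow,
                config$models, nrow(truth), filt$n_removed, nrow(s_dat),
                nrow(t_dat), nrow(val_dat),
                unname(tools::md5sum(unlist(files)))),
      stringsAsFactors = FALSE)
    emit(manifest, "manifest.csv")
    say("artifacts written to %s", config$outdir)

    list(truth = truth, s_dataset = s_dat, t_dataset = t_dat,
         validation = val_dat, n_removed = filt$n_removed,
         b_table = b_table, split = split, models = models,
         selection = selections, report = report, correlations = cortab,
         mi = mi, fixtures = fixtures, manifest = manifest, files = files)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "ampm_pipeline"
  invisible(res)
}

#' @export
print.ampm_pipeline <- function(x, ...) {
  cat("AM/PM daily-yield pipeline run\n")
  cat(sprintf("  %d truth rows, %d composite records kept (%d removed)\n",
              nrow(x$truth), nrow(x$s_dataset), x$n_removed))
  cat(sprintf("  %d fitted models; artifacts: %s\n", length(x$models),
              dirname(x$files[[1]])))
  invisible(x)
}
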