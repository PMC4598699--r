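#' Model terms: covariate products nested in class crosses
#'
#' A term of a daily-yield prediction model is the product of zero or more
#' session covariates (the session's milk yield `milk_AM`/`milk_PM`, and/or a
#' session content `q<TRAIT>_AM`/`_PM` in g/dL) nested in the cross of zero
#' or more class factors (DIM class, parity class, calendar month). With
#' classes present the term contributes one regression coefficient per
#' occupied subclass cell (separate slopes per cell); with no covariates it
#' contributes plain indicator columns; with no classes it is a single global
#' covariate column.
#'
#' @param covariates character vector among `"milk"`, `"q_<trait token>"`
#'   (e.g. `"q_fat"`); may be empty.
#' @param classes character vector among `"dim"`, `"parity"`, `"month"`;
#'   may be empty (but not simultaneously with `covariates`).
#' @return an object of class `"ampm_term"`.
#' @seealso [ampm_spec()], [parse_model()]
#' @export
ampm_term <- function(covariates = character(), classes = character()) {
  covariates <- as.character(covariates)
  classes <- as.character(classes)
  ok_cov <- c("milk", paste0("q_", fa_trait_cols()))
  bad <- setdiff(covariates, ok_cov)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- setdiff(classes, c("dim", "parity", "month"))
  if (length(bad))
    stop("unknown class factor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (!length(covariates) && !length(classes))
    stop("a term needs at least one covariate or class factor", call. = FALSE)
  if (anyDuplicated(covariates) || anyDuplicated(classes))
    stop("duplicated factor within a term", call. = FALSE)
  # canonical order => canonical labels
  covariates <- covariates[order(match(covariates, ok_cov))]
  classes <- classes[order(match(classes, c("dim", "parity", "month")))]
  structure(list(covariates = covariates, classes = classes),
            class = "ampm_term")
}

label_term <- function(term, session) {
  covs <- vapply(term$covariates, function(cv) {
    if (cv == "milk") paste0("milk_", session)
    else paste0("q", toupper(sub("^q_", "", cv)), "_", session)
  }, character(1))
  cls <- c(dim = "DIM", parity = "parity", month = "month")[term$classes]
  paste(c(covs, unname(cls)), collapse = "*")
}

#' Specification of a daily-yield prediction model
#'
#' A model predicts the 24-h yield of one trait from one milking's records.
#' It always contains an intercept plus the given [ampm_term()] terms.
#'
#' @param trait trait whose daily yield is the response (id or token;
#'   `"milk"` allowed).
#' @param session `"AM"` or `"PM"`: which milking's records feed the model.
#' @param terms list of [ampm_term()] objects, or strings parseable by
#'   [parse_model()]'s term grammar.
#' @return an object of class `"ampm_spec"`.
#' @export
#' @examples
#' sp <- ampm_spec("fat", "AM", list(
#'   ampm_term(c("q_fat", "milk"), "dim"),
#'   ampm_term(character(), "parity")))
#' print(sp)
ampm_spec <- function(trait, session, terms = list()) {
  tok <- resolve_trait(trait)
  session <- match_session(session)
  terms <- lapply(terms, function(tm) {
    if (inherits(tm, "ampm_term")) tm else parse_term(tm, session)
  })
  labs <- vapply(terms, label_term, character(1), session = session)
  if (anyDuplicated(labs))
    stop("duplicate terms: ", paste(labs[duplicated(labs)], collapse = ", "),
         call. = FALSE)
  structure(list(trait = tok, session = session, terms = terms),
            class = "ampm_spec")
}

#' @export
print.ampm_spec <- function(x, ...) {
  cat(sprintf("Daily %s yield from the %s milking:\n  %s\n",
              x$trait, x$session, format_model(x)))
  invisible(x)
}

#' Render a model specification in the text grammar
#'
#' @param spec an [ampm_spec()] object.
#' @return a single string such as
#'   `"a + b*(qFAT_AM*milk_AM*DIM) + c*(parity)"`: `a` is the intercept and
#'   successive letters tag the terms.
#' @export
format_model <- function(spec) {
  if (!length(spec$terms)) return("a")
  letters_ <- letters[seq_along(spec$terms) + 1L]
  rhs <- mapply(function(l, tm) {
    sprintf("%s*(%s)", l, label_term(tm, spec$session))
  }, letters_, spec$terms)
  paste(c("a", rhs), collapse = " + ")
}

# parse one term string, e.g. "qFAT_AM x milk_AM x DIM"
parse_term <- function(text, session) {
  s <- gsub("×", "*", text)
  s <- gsub("(?i)\\s+of\\s+test", "", s, perl = TRUE)
  s <- gsub("^\\s*\\(|\\)\\s*$", "", trimws(s))
  toks <- trimws(strsplit(s, "\\*")[[1]])
  toks <- toks[nzchar(toks)]
  covariates <- character(); classes <- character()
  for (tk in toks) {
    key <- gsub("[^a-z0-9_]", "", tolower(tk))
    if (key %in% c("dim", "cdim")) { classes <- c(classes, "dim"); next }
    if (key == "parity") { classes <- c(classes, "parity"); next }
    if (key %in% c("month", "monthoftest")) { classes <- c(classes, "month"); next }
    m <- regmatches(key, regexec("^(q?)([a-z0-9]+)_(am|pm)$", key))[[1]]
    if (!length(m))
      stop("cannot parse model token: '", tk, "'", call. = FALSE)
    if (toupper(m[4]) != session)
      stop("token '", tk, "' does not match the model session ", session,
           call. = FALSE)
    if (m[2] == "q") {
      covariates <- c(covariates, paste0("q_", resolve_trait(m[3], FALSE)))
    } else if (m[3] == "milk") {
      covariates <- c(covariates, "milk")
    } else {
      stop("cannot parse model token: '", tk, "'", call. = FALSE)
    }
  }
  ampm_term(covariates, classes)
}

#' Parse a model written in the text grammar
#'
#' Accepts strings in the style `"a + b*(qFAT_AM*milk_AM*DIM) + c*(parity) +
#' d*(milk_AM*parity)"`: a leading `a` denotes the intercept, each further
#' piece is an optional coefficient letter times a parenthesised product of
#' session covariates (`milk_AM`, `qSFA_PM`, ...) and class factors (`DIM`,
#' `parity`, `month of test`). The multiplication sign may be `*` or the
#' typographic x.
#'
#' @param text the model string.
#' @param trait response trait (id or token).
#' @param session `"AM"` or `"PM"`.
#' @return an [ampm_spec()] object.
#' @export
#' @examples
#' parse_model("a + b*(qFAT_AM*milk_AM*DIM) + c*(parity)", "fat", "AM")
parse_model <- function(text, trait, session) {
  session <- match_session(session)
  pieces <- trimws(strsplit(gsub("×", "*", text), "\\+")[[1]])
  pieces <- pieces[nzchar(pieces)]
  # drop the bare intercept letter and strip "<letter> *" coefficient tags
  pieces <- pieces[!grepl("^[a-z]$", pieces)]
  pieces <- sub("^[a-z]\\s*\\*\\s*", "", pieces)
  ampm_spec(trait, session, lapply(pieces, parse_term, session = session))
}

# shipped model forms: selected by stepwise search against held-out test and
# validation sets on large-scale milk-recording data; one form per
# trait x milking
preset_strings <- function() {
  list(
    milk_AM = "a + b*(DIM) + c*(month) + d*(milk_AM*DIM*parity*month)",
    milk_PM = "a + b*(DIM) + c*(month) + d*(milk_PM*DIM*parity*month)",
    fat_AM  = "a + b*(qFAT_AM*milk_AM*DIM) + c*(parity) + d*(milk_AM*parity) + e*(qFAT_AM*milk_AM*parity)",
    fat_PM  = "a + b*(milk_PM*DIM) + c*(qFAT_PM*milk_PM*DIM) + d*(parity) + e*(qFAT_PM*milk_PM*month)",
    sfa_AM  = "a + b*(qSFA_AM*milk_AM*DIM) + c*(parity) + d*(milk_AM*parity) + e*(milk_AM*month)",
    sfa_PM  = "a + b*(milk_PM*DIM) + c*(qSFA_PM*milk_PM*DIM) + d*(parity) + e*(month)",
    mufa_AM = "a + b*(milk_AM*DIM) + c*(milk_AM*parity) + d*(qMUFA_AM*milk_AM*DIM*parity) + e*(qMUFA_AM*milk_AM*month)",
    mufa_PM = "a + b*(milk_PM*DIM) + c*(parity) + d*(qMUFA_PM*milk_PM*DIM*parity) + e*(milk_PM*month)",
    ufa_AM  = "a + b*(milk_AM*DIM) + c*(qUFA_AM*milk_AM*DIM) + d*(parity) + e*(milk_AM*parity)",
    ufa_PM  = "a + b*(milk_PM*DIM) + c*(qUFA_PM*milk_PM*DIM*parity) + d*(milk_PM*month) + e*(qUFA_PM*DIM*parity*month)",
    scfa_AM = "a + b*(qSCFA_AM*milk_AM*DIM) + c*(parity) + d*(milk_AM*parity) + e*(month)",
    scfa_PM = "a + b*(qSCFA_PM*milk_PM*DIM) + c*(milk_PM*parity) + d*(milk_PM*month) + e*(qSCFA_PM*DIM*parity*month)",
    mcfa_AM = "a + b*(qMCFA_AM*milk_AM*DIM) + c*(parity) + d*(qMCFA_AM*milk_AM*month) + e*(qMCFA_AM*DIM*parity*month)",
    mcfa_PM = "a + b*(milk_PM*DIM) + c*(qMCFA_PM*milk_PM*DIM) + d*(milk_PM*parity) + e*(month) + f*(qMCFA_PM*DIM*parity*month)",
    lcfa_AM = "a + b*(milk_AM*DIM*parity) + c*(qLCFA_AM*milk_AM*DIM*parity) + d*(milk_AM*month) + e*(qLCFA_AM*milk_AM*month) + f*(qLCFA_AM*DIM*parity*month)",
    lcfa_PM = "a + b*(milk_PM*DIM) + c*(qLCFA_PM*milk_PM*DIM*parity) + d*(milk_PM*parity*month) + e*(qLCFA_PM*DIM*parity*month)",
    c181_AM = "a + b*(milk_AM*DIM) + c*(milk_AM*parity) + d*(qC181_AM*milk_AM*DIM*parity) + e*(qC181_AM*milk_AM*parity*month) + f*(qC181_AM*DIM*parity*month)",
    c181_PM = "a + b*(milk_PM*DIM) + c*(qC181_PM*milk_PM*DIM*parity) + d*(month) + e*(qC181_PM*milk_PM*month) + f*(qC181_PM*DIM*parity*month)"
  )
}

#' Shipped prediction-model presets
#'
#' The package ships one prediction-model form per trait x milking (18 in
#' all), the forms selected by stepwise search on large-scale milk-recording
#' data. Users can fit these forms directly with [ampm_fit()] without redoing
#' the selection.
#'
#' @param trait optional trait filter (id or token).
#' @param session optional session filter (`"AM"`/`"PM"`).
#' @return a named list of [ampm_spec()] objects (names like `"fat_AM"`),
#'   or a single spec when both filters are given.
#' @export
#' @examples
#' preset_models("fat", "AM")
preset_models <- function(trait = NULL, session = NULL) {
  ps <- preset_strings()
  specs <- lapply(names(ps), function(nm) {
    parts <- strsplit(nm, "_")[[1]]
    parse_model(ps[[nm]], parts[1], parts[2])
  })
  names(specs) <- names(ps)
  if (!is.null(trait)) {
    tok <- resolve_trait(trait)
    specs <- specs[grepl(paste0("^", tok, "_"), names(specs))]
  }
  if (!is.null(session)) {
    session <- match_session(session)
    specs <- specs[grepl(paste0("_", session, "$"), names(specs))]
  }
  if (length(specs) == 1L) specs[[1L]] else specs
}
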