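#' Save / load a fitted model as a labelled-coefficient CSV
#'
#' A fitted model is stored as a plain CSV of `(kind, label, value)` rows:
#' metadata (trait, session, the model string in the text grammar, n, p),
#' one row per design column with its coefficient (aliased columns store
#' `NA`), and the class levels seen in training. A model loaded back
#' predicts identically to the in-memory original; fit-time residual
#' information is not stored, so `fitted()`/`residuals()` are unavailable on
#' a loaded model.
#'
#' @param model an `"ampm_model"`.
#' @param path CSV file path.
#' @return `write_model_csv` the path, invisibly; `read_model_csv` an
#'   `"ampm_model"` usable with [predict.ampm_model()] and
#'   [validation_report()].
#' @export
write_model_csv <- function(model, path) {
  stopifnot(inherits(model, "ampm_model"))
  meta <- data.frame(
    kind = "meta",
    label = c("trait", "session", "model", "n", "p"),
    value = c(model$spec$trait, model$spec$session, format_model(model$spec),
              model$n, model$p),
    stringsAsFactors = FALSE)
  coefs <- data.frame(kind = "coef", label = names(model$coefficients),
                      value = as.character(model$coefficients),
                      stringsAsFactors = FALSE)
  lv <- do.call(rbind, lapply(names(model$cls_levels), function(cl) {
    data.frame(kind = paste0("level_", cl), label = model$cls_levels[[cl]],
               value = "", stringsAsFactors = FALSE)
  }))
  utils::write.csv(rbind(meta, coefs, lv), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model_csv
#' @export
read_model_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  meta <- d[d$kind == "meta", ]
  getm <- function(k) meta$value[meta$label == k]
  spec <- parse_model(getm("model"), getm("trait"), getm("session"))
  coefs <- d[d$kind == "coef", ]
  beta <- suppressWarnings(as.numeric(coefs$value))
  names(beta) <- coefs$label
  # recover the occupied training cells from the column labels, in order
  term_cells <- lapply(spec$terms, function(tm) {
    if (!length(tm$classes)) return(character(0))
    prefix <- paste0(label_term(tm, spec$session), "[")
    hits <- startsWith(coefs$label, prefix) & endsWith(coefs$label, "]")
    substr(coefs$label[hits], nchar(prefix) + 1L,
           nchar(coefs$label[hits]) - 1L)
  })
  cls_levels <- lapply(c(dim = "dim", parity = "parity", month = "month"),
                       function(cl) d$label[d$kind == paste0("level_", cl)])
  structure(list(spec = spec, coefficients = beta,
                 n = as.integer(getm("n")), p = as.integer(getm("p")),
                 fitted.values = NULL, residuals = NULL, stats = NULL,
                 labels = coefs$label, term_cells = term_cells,
                 cls_levels = cls_levels),
            class = "ampm_model")
}
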