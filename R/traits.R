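#' The nine recorded traits
#'
#' Catalogue of the traits handled by the package: milk yield, fat content and
#' seven fatty-acid (FA) traits (SFA, MUFA, UFA, SCFA, MCFA, LCFA and
#' C18:1 cis-9, i.e. oleic acid). Contents are concentrations in g/dL of milk;
#' yields are masses secreted per milking or per day (g; kg for milk).
#'
#' @return A data.frame with one row per trait and columns:
#'   \describe{
#'     \item{trait_id}{display identifier, e.g. `"C18:1cis9"`}
#'     \item{col}{column-safe token used in dataset column names, e.g. `"c181"`}
#'     \item{content_unit}{`"g/dL"` for all traits but milk (`NA`)}
#'     \item{yield_unit}{`"g/day"`; `"kg/day"` for milk}
#'   }
#' @export
#' @examples
#' trait_catalog()
trait_catalog <- function() {
  data.frame(
    trait_id = c("milk", "fat", "SFA", "MUFA", "UFA",
                 "SCFA", "MCFA", "LCFA", "C18:1cis9"),
    col = c("milk", "fat", "sfa", "mufa", "ufa",
            "scfa", "mcfa", "lcfa", "c181"),
    content_unit = c(NA, rep("g/dL", 8L)),
    yield_unit = c("kg/day", rep("g/day", 8L)),
    stringsAsFactors = FALSE
  )
}

# column tokens of the content-bearing (non-milk) traits
fa_trait_cols <- function() trait_catalog()$col[-1L]

#' Convert a content and a per-milking volume to a per-milking yield
#'
#' Uses the convention 1 kg milk = 1 L = 10 dL, so
#' yield (g) = content (g/dL) x milk (kg) x 10.
#'
#' @param content concentration in g/dL of milk.
#' @param milk_kg milk mass at the milking, kg.
#' @return yield in g per milking.
#' @export
#' @examples
#' yield_from_content(4.11, 12.79)  # ~ 525.7 g of fat
yield_from_content <- function(content, milk_kg) content * milk_kg * 10

#' Days-in-milk classes
#'
#' Groups days in milk (DIM) into 30-day classes up to day 300 plus one open
#' class (11 levels), the grouping used whenever DIM enters a model as a class
#' effect.
#'
#' @param dim integer vector of days in milk.
#' @return a factor with 11 levels `"(0,30]"` ... `"(300,Inf]"`.
#' @export
dim_class <- function(dim) {
  cut(dim, breaks = c(seq(0, 300, by = 30), Inf), right = TRUE)
}

#' Parity classes
#'
#' Lactation number grouped as first, second, and third-or-later parity.
#'
#' @param parity integer or character vector of lactation numbers.
#' @return a factor with levels `"1"`, `"2"`, `"3+"`.
#' @export
parity_class <- function(parity) {
  p <- as.character(parity)
  p[!p %in% c("1", "2")] <- "3+"
  factor(p, levels = c("1", "2", "3+"))
}

# internal: resolve a trait argument (trait_id or col token) to its col token
resolve_trait <- function(trait, allow_milk = TRUE) {
  cat_ <- trait_catalog()
  if (trait %in% cat_$col) {
    tok <- trait
  } else if (trait %in% cat_$trait_id) {
    tok <- cat_$col[match(trait, cat_$trait_id)]
  } else {
    # tolerate case / punctuation variants such as "C18:1 cis-9"
    key <- tolower(gsub("[^a-z0-9]", "", tolower(trait)))
    keys <- tolower(gsub("[^a-z0-9]", "", tolower(cat_$trait_id)))
    hit <- match(key, keys)
    if (is.na(hit)) stop("unknown trait: ", trait, call. = FALSE)
    tok <- cat_$col[hit]
  }
  if (!allow_milk && tok == "milk")
    stop("trait 'milk' has no content; a content-bearing trait is required",
         call. = FALSE)
  tok
}

match_session <- function(session) {
  match.arg(toupper(session), c("AM", "PM"))
}
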