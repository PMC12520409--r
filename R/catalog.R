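#' Default catalog of FFH risk factors
#'
#' The taxonomy of fall-from-height (FFH) accident risk factors used
#' throughout the package: 20 main categories grouped into five core
#' dimensions (A: illegal and unauthorized construction practices;
#' B: lack of effective safety management and supervision; C: hazardous
#' site environment and equipment; D: inadequate site security and
#' personal protection; E: occupational-safety risks of construction
#' workers), plus the binary accident outcome node `FFHA`.
#'
#' @return An object of class `factor_catalog`: a data frame with columns
#'   `id`, `label`, `core_category`, and an `outcome_id` attribute naming
#'   the accident outcome node (not itself a row of the table).
#' @examples
#' cat <- ffh_catalog()
#' nrow(cat)            # 20 risk factors
#' attr(cat, "outcome_id")
#' @export
ffh_catalog <- function() {
  factors <- data.frame(
    id = c("A1", "A2", "A3",
           "B1", "B2", "B3", "B4", "B5", "B6", "B7", "B8",
           "C1", "C2", "C3",
           "D1", "D2", "D3",
           "E1", "E2", "E3"),
    label = c(
      "Construction without proper construction qualification",
      "Illegal and unauthorized construction",
      "In violation of instructions, unauthorized construction",
      "Ineffective performance of duties by the site person in charge",
      "Inadequate project safety supervision and enforcement",
      "Inadequate supervision by administrative departments",
      "Inadequate safety system or unclear responsibility",
      "Communication and coordination problems",
      "Technical and design defects or deficiencies",
      "Inadequate elimination of safety hazards",
      "Inadequate response to emergencies",
      "Non-standard scaffolding",
      "Inadequate site lighting",
      "Defective work equipment and facilities",
      "Inadequate personal protection",
      "Failure to post safety warnings and signs",
      "Inadequate site safety protection",
      "Careless operation",
      "Low safety awareness of construction personnel",
      "Physical or psychological problems of construction personnel"),
    core_category = c(rep("A", 3), rep("B", 8), rep("C", 3),
                      rep("D", 3), rep("E", 3)),
    stringsAsFactors = FALSE
  )
  new_factor_catalog(factors, outcome_id = "FFHA")
}

new_factor_catalog <- function(factors, outcome_id) {
  stopifnot(is.data.frame(factors),
            all(c("id", "label", "core_category") %in% names(factors)))
  if (anyDuplicated(factors$id))
    stop("factor catalog ids must be unique", call. = FALSE)
  if (outcome_id %in% factors$id)
    stop("outcome id must not be a catalog factor", call. = FALSE)
  structure(factors, outcome_id = outcome_id,
            class = c("factor_catalog", "data.frame"))
}

#' Read or write a factor catalog as JSON
#'
#' The serialized form is a JSON object with an `outcome_id` string and a
#' `factors` array of `{id, label, core_category}` records.
#'
#' @param path File path.
#' @return `read_catalog()` returns a `factor_catalog`; `write_catalog()`
#'   returns `path` invisibly.
#' @export
read_catalog <- function(path) {
  obj <- jsonlite::fromJSON(path)
  new_factor_catalog(as.data.frame(obj$factors), outcome_id = obj$outcome_id)
}

#' @rdname read_catalog
#' @param catalog A `factor_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  jsonlite::write_json(
    list(outcome_id = attr(catalog, "outcome_id"),
         factors = as.data.frame(catalog)[, c("id", "label", "core_category")]),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @export
print.factor_catalog <- function(x, ...) {
  cat("FFH risk-factor catalog:", nrow(x), "factors, outcome",
      attr(x, "outcome_id"), "\n")
  print(as.data.frame(x), ...)
  invisible(x)
}
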