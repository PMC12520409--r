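#' Construct a binary incidence matrix of accident reports
#'
#' The incidence matrix is the empirical backbone of the pipeline: one row
#' per accident report, one 0/1 column per risk factor, recording whether
#' the factor was identified in the report. All counting, conditional
#' mutual information, and CPT estimation read from it.
#'
#' @param cells A numeric/integer matrix or data frame of 0/1 values with
#'   column names giving factor ids.
#' @param report_ids Character vector of unique report labels (defaults to
#'   existing row names, else zero-padded "001", "002", ...).
#' @param catalog Optional `factor_catalog`; when supplied every column
#'   must be a catalog factor.
#' @return An object of class `incidence_matrix`: an integer matrix with
#'   report ids as row names.
#' @examples
#' m <- incidence_matrix(rbind(c(1, 0), c(1, 1)),
#'                       report_ids = c("001", "002"))
#' colnames(m) <- NULL # not run; columns are named on construction
#' @export
incidence_matrix <- function(cells, report_ids = NULL, catalog = NULL) {
  cells <- as.matrix(cells)
  if (is.null(colnames(cells)) || anyDuplicated(colnames(cells)))
    stop("incidence matrix needs unique factor column names", call. = FALSE)
  if (is.null(report_ids)) {
    report_ids <- rownames(cells)
    if (is.null(report_ids))
      report_ids <- formatC(seq_len(nrow(cells)), width = 3, flag = "0")
  }
  report_ids <- as.character(report_ids)
  if (length(report_ids) != nrow(cells))
    stop("report_ids length must match the number of rows", call. = FALSE)
  if (anyDuplicated(report_ids))
    stop("duplicate report id: ",
         report_ids[anyDuplicated(report_ids)], call. = FALSE)
  bad <- which(!(cells %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(cells))
    stop(sprintf("non-binary cell at report '%s', factor '%s': %s",
                 report_ids[rc[1]], colnames(cells)[rc[2]],
                 format(cells[bad[1]])), call. = FALSE)
  }
  if (!is.null(catalog)) {
    unknown <- setdiff(colnames(cells), catalog$id)
    if (length(unknown))
      stop("unknown factor id(s) not in catalog: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  storage.mode(cells) <- "integer"
  rownames(cells) <- report_ids
  structure(cells, class = c("incidence_matrix", class(matrix())))
}

#' Read / write an incidence matrix CSV
#'
#' The CSV dialect is comma-separated UTF-8 with a first column `ID`
#' holding report labels (zero-padded labels such as "001" are preserved
#' verbatim) followed by one 0/1 column per factor. Any column order is
#' accepted as long as the factors are in the supplied catalog.
#'
#' @param path CSV file path.
#' @param catalog Optional `factor_catalog` used to validate column names.
#' @return `read_incidence()` returns an `incidence_matrix` with row order
#'   preserved; `write_incidence()` returns `path` invisibly.
#' @export
read_incidence <- function(path, catalog = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!ncol(df) || names(df)[1] != "ID")
    stop("incidence CSV must have a leading 'ID' column", call. = FALSE)
  ids <- df$ID
  cells <- df[, -1, drop = FALSE]
  vals <- suppressWarnings(
    matrix(as.numeric(as.matrix(cells)), nrow = nrow(cells),
           ncol = ncol(cells), dimnames = list(NULL, names(cells))))
  if (nrow(vals) && anyNA(vals)) {
    rc <- arrayInd(which(is.na(vals))[1], dim(vals))
    stop(sprintf("non-numeric cell at report '%s', factor '%s'",
                 ids[rc[1]], colnames(vals)[rc[2]]), call. = FALSE)
  }
  incidence_matrix(vals, report_ids = ids, catalog = catalog)
}

#' @rdname read_incidence
#' @param matrix An `incidence_matrix`.
#' @export
write_incidence <- function(matrix, path) {
  df <- data.frame(ID = rownames(matrix), unclass(matrix),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

check_factors <- function(matrix, factors) {
  missing <- setdiff(factors, colnames(matrix))
  if (length(missing))
    stop("unknown factor(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
}

#' Counting primitives over an incidence matrix
#'
#' `marginal_count()` counts reports in which a factor takes a given state;
#' `joint_count()` counts reports matching every (factor, state) pair of an
#' assignment. These are the empirical counts behind the smoothed
#' probability estimates and the conditional-mutual-information test.
#'
#' @param matrix An `incidence_matrix`.
#' @param factor A factor id present in the matrix.
#' @param state 0 or 1.
#' @return An integer count in `[0, nrow(matrix)]`.
#' @examples
#' m <- incidence_matrix(cbind(A1 = c(1, 1, 0), A2 = c(1, 0, 0)))
#' marginal_count(m, "A1", 1)         # 2
#' joint_count(m, c(A1 = 1, A2 = 1))  # 1
#' @export
marginal_count <- function(matrix, factor, state = 1L) {
  check_factors(matrix, factor)
  stopifnot(length(factor) == 1, state %in% c(0L, 1L))
  sum(matrix[, factor] == state)
}

#' @rdname marginal_count
#' @param assignment A named vector/list mapping factor ids to states.
#' @export
joint_count <- function(matrix, assignment) {
  assignment <- unlist(assignment)
  if (!length(assignment) || is.null(names(assignment)))
    stop("assignment must be a non-empty named vector", call. = FALSE)
  check_factors(matrix, names(assignment))
  stopifnot(all(assignment %in% c(0L, 1L)))
  if (!nrow(matrix)) return(0L)
  hit <- rep(TRUE, nrow(matrix))
  for (f in names(assignment)) hit <- hit & (matrix[, f] == assignment[[f]])
  sum(hit)
}

#' Split an incidence matrix into two ordered subsets
#'
#' Deterministic head/tail split preserving row order, as used to separate
#' preliminary coding samples from saturation-test samples (e.g. 368
#' reports into 258 + 110).
#'
#' @param matrix An `incidence_matrix`.
#' @param n_first Number of rows in the first subset, in `[0, N]`.
#' @return A list with elements `first` and `second`.
#' @export
split_samples <- function(matrix, n_first) {
  n <- nrow(matrix)
  if (length(n_first) != 1 || n_first < 0 || n_first > n || n_first %% 1 != 0)
    stop("n_first must be an integer in [0, ", n, "]", call. = FALSE)
  take <- seq_len(n_first)
  list(
    first  = incidence_matrix(matrix[take, , drop = FALSE],
                              report_ids = rownames(matrix)[take]),
    second = incidence_matrix(matrix[setdiff(seq_len(n), take), , drop = FALSE],
                              report_ids = rownames(matrix)[setdiff(seq_len(n), take)])
  )
}

#' The incidence rows printed in the source frequency table
#'
#' A 16-report excerpt of the full 368-report FFH incidence matrix (reports
#' 001-011 and 364-368) over all 20 risk factors, useful for examples and
#' as a small real-data fixture. The full matrix is not redistributed here.
#'
#' @return An `incidence_matrix` with 16 rows and 20 factor columns.
#' @export
ffh_incidence_excerpt <- function() {
  ids <- c("001", "002", "003", "004", "005", "006", "007", "008", "009",
           "010", "011", "364", "365", "366", "367", "368")
  rows <- rbind(
    c(1,0,1,1,1,0,0,0,0,1,0,0,0,1,1,0,0,0,1,0),
    c(0,0,1,1,1,0,0,1,0,1,0,0,0,1,0,0,0,0,0,0),
    c(1,0,0,0,1,0,1,0,1,1,0,0,0,0,1,0,1,1,0,0),
    c(1,1,0,1,1,0,0,0,0,1,0,0,0,0,1,0,1,1,0,0),
    c(0,0,1,0,1,0,1,0,0,0,0,0,0,0,1,0,0,1,1,0),
    c(0,0,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,1,1,0),
    c(1,1,1,0,0,1,0,0,0,1,0,0,0,0,1,0,1,1,0,0),
    c(0,0,1,0,1,0,1,0,0,0,0,0,0,0,1,0,1,0,0,0),
    c(1,1,0,0,1,1,0,0,0,0,0,0,0,0,1,0,1,1,0,0),
    c(1,1,0,0,1,1,0,0,0,0,0,1,0,1,0,0,1,1,1,1),
    c(1,1,0,0,1,0,0,0,1,0,0,1,0,1,1,0,0,0,0,0),
    c(0,0,1,1,1,0,0,0,0,0,0,0,0,0,0,0,0,0,1,0),
    c(0,0,0,1,0,0,1,1,0,0,0,0,0,0,0,0,0,1,1,0),
    c(0,0,0,0,1,0,0,0,0,0,0,0,0,0,1,0,1,0,1,0),
    c(0,0,0,0,0,0,0,0,0,0,0,0,0,1,0,1,0,1,1,0),
    c(0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,0,1,0,0,0))
  colnames(rows) <- ffh_catalog()$id
  incidence_matrix(rows, report_ids = ids, catalog = ffh_catalog())
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat("Incidence matrix:", nrow(x), "reports x", ncol(x), "factors\n")
  print(unclass(x), ...)
  invisible(x)
}
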