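#' Panel support scores for candidate causal links
#'
#' The published panel-level supports for the 25 candidate links whose
#' fusion results survive screening: the mean 0-10 questionnaire score of
#' each respondent panel, rescaled to a unit-interval support mass.
#' Source 1 is the expert panel (10+ years of construction experience);
#' source 2 the frontline panel (2+ years).
#'
#' @return A data frame with columns `from`, `to`, `m1` (expert support)
#'   and `m2` (frontline support).
#' @examples
#' fuse_edges(ffh_edge_support())
#' @export
ffh_edge_support <- function() {
  data.frame(
    from = c("B4", "B2", "B2", "B2", "B1", "B1", "B7", "B7", "B7", "D3",
             "D2", "B6", "B3", "A1", "B8", "B5", "A3", "C2", "D1", "C1",
             "C3", "E2", "E1", "E3", "A2"),
    to   = c("B2", "B1", "C3", "B7", "D1", "C3", "C3", "D3", "D2", "C3",
             "E2", "C1", "A1", "A3", "B5", "E1", "E1", "E1", "FFHA", "FFHA",
             "FFHA", "FFHA", "FFHA", "FFHA", "FFHA"),
    m1 = c(0.88, 0.84, 0.84, 0.91, 0.81, 0.68, 0.77, 0.77, 0.73, 0.77,
           0.67, 0.65, 0.85, 0.88, 0.76, 0.79, 0.90, 0.77, 0.84, 0.88,
           0.82, 0.84, 0.81, 0.77, 0.84),
    m2 = c(0.790, 0.807, 0.754, 0.832, 0.795, 0.771, 0.812, 0.802, 0.768,
           0.756, 0.727, 0.761, 0.778, 0.761, 0.737, 0.705, 0.761, 0.717,
           0.798, 0.761, 0.751, 0.766, 0.793, 0.744, 0.785),
    stringsAsFactors = FALSE
  )
}

#' Aggregate raw questionnaire scores into per-edge source supports
#'
#' Each respondent rates each candidate link on a 0-10 scale (0 = no
#' influence, 10 = the source factor must cause the target). Panel support
#' is the arithmetic mean score divided by 10, giving one unit-interval
#' mass per source.
#'
#' @param responses A data frame with columns `from`, `to`, `panel`
#'   (`"expert"` or `"frontline"`) and `score` (integers 0-10), e.g. from
#'   [read_responses()] or [simulate_questionnaires()].
#' @return A data frame with columns `from`, `to`, `m1`, `m2` (expert and
#'   frontline support), one row per candidate edge, in first-appearance
#'   order.
#' @export
aggregate_responses <- function(responses) {
  stopifnot(is.data.frame(responses),
            all(c("from", "to", "panel", "score") %in% names(responses)))
  if (!all(responses$panel %in% c("expert", "frontline")))
    stop("panel must be 'expert' or 'frontline'", call. = FALSE)
  if (!all(responses$score >= 0 & responses$score <= 10))
    stop("scores must lie in [0, 10]", call. = FALSE)
  key <- paste(responses$from, responses$to, sep = "\r")
  edges <- unique(key)
  out <- data.frame(
    from = responses$from[match(edges, key)],
    to   = responses$to[match(edges, key)],
    m1 = NA_real_, m2 = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_along(edges)) {
    sel <- key == edges[i]
    for (p in c("expert", "frontline")) {
      s <- responses$score[sel & responses$panel == p]
      if (!length(s))
        stop(sprintf("no %s responses for edge %s -> %s",
                     p, out$from[i], out$to[i]), call. = FALSE)
      out[[if (p == "expert") "m1" else "m2"]][i] <- mean(s) / 10
    }
  }
  out
}

#' Read raw questionnaire responses from CSV
#'
#' Expected columns: `edge_from`, `edge_to`, `panel`, `respondent_id`,
#' `score`.
#'
#' @param path CSV file path.
#' @return A data frame with columns `from`, `to`, `panel`, `respondent`,
#'   `score`.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("edge_from", "edge_to", "panel", "respondent_id", "score")
  if (!all(need %in% names(df)))
    stop("responses CSV must have columns: ",
         paste(need, collapse = ", "), call. = FALSE)
  data.frame(from = df$edge_from, to = df$edge_to, panel = df$panel,
             respondent = df$respondent_id, score = df$score,
             stringsAsFactors = FALSE)
}

#' Dempster's rule of combination on a two-element frame
#'
#' Combines two sources' support masses for the hypothesis "the causal
#' link exists" over the frame \{exists, not exists\}, with Bayesian mass
#' assignment (no mass on the frame itself): source i places `m_i` on
#' "exists" and `1 - m_i` on "not exists". The conflict coefficient is
#' `k = m1 (1 - m2) + (1 - m1) m2` and the fused mass
#' `m = m1 m2 / (1 - k)`. Under Bayesian masses belief and plausibility
#' coincide with the fused mass: `Bel = Pl = m`.
#'
#' @param m1,m2 Unit-interval support masses (vectorized).
#' @return A data frame with columns `m`, `k`, `Bel`, `Pl` in full
#'   precision and `m4`, `k4`, `Bel4`, `Pl4` rounded to 4 decimals
#'   (round-half-even) for comparison with published tables.
#' @examples
#' dempster_combine(0.88, 0.790)  # m = 0.9650, k = 0.2796
#' @export
dempster_combine <- function(m1, m2) {
  stopifnot(all(m1 >= 0 & m1 <= 1), all(m2 >= 0 & m2 <= 1))
  k <- m1 * (1 - m2) + (1 - m1) * m2
  if (any(k >= 1))
    stop("total conflict between sources (k = 1); fusion undefined",
         call. = FALSE)
  m <- m1 * m2 / (1 - k)
  data.frame(m = m, k = k, Bel = m, Pl = m,
             m4 = round(m, 4), k4 = round(k, 4),
             Bel4 = round(m, 4), Pl4 = round(m, 4))
}

#' Fuse per-edge panel supports with Dempster's rule
#'
#' @param support A data frame with columns `from`, `to`, `m1`, `m2`
#'   (e.g. from [aggregate_responses()] or [ffh_edge_support()]).
#' @return The input with fusion columns `m`, `k`, `Bel`, `Pl` (full
#'   precision) and their 4-decimal versions appended.
#' @export
fuse_edges <- function(support) {
  stopifnot(all(c("from", "to", "m1", "m2") %in% names(support)))
  cbind(support, dempster_combine(support$m1, support$m2))
}

#' Screen fused edges on belief and conflict
#'
#' Keeps a candidate link when both belief and plausibility reach
#' `bel_min` and the conflict coefficient stays strictly below `k_max`,
#' the published screening rule (Bel, Pl > 0.8 with k in [0, 0.5)).
#'
#' @param fused Output of [fuse_edges()].
#' @param bel_min Minimum belief/plausibility (default 0.8).
#' @param k_max Conflict ceiling, exclusive (default 0.5).
#' @return `fused` with a logical `kept` column; input order preserved.
#' @export
screen_edges <- function(fused, bel_min = 0.8, k_max = 0.5) {
  stopifnot(bel_min > 0, bel_min < 1, k_max > 0, k_max <= 1)
  fused$kept <- fused$Bel >= bel_min & fused$Pl >= bel_min & fused$k < k_max
  fused
}
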