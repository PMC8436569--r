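#' Probability ingredients of a rule's interestingness measures
#'
#' Collects every probability the measures need, over the window
#' transactions of `db`:
#'
#' * `p_a`, `p_b` — antecedent / consequent support under the active mode,
#'   divided by the window count. In paper mode a singleton's support is
#'   its occurrence count, so these may exceed 1; this is deliberate and
#'   is what reproduces published measure tables for this mining style.
#' * `p_ab` — window-containment count of the union over the window count
#'   (the union has size >= 2, so both modes agree).
#' * `p_a_window` — window-containment probability of the antecedent,
#'   used wherever the complement event "A absent" is involved.
#' * `p_not_a` — `1 - p_a_window`.
#' * `p_nota_b` — P(B without A), computed as `p_b - p_ab` rather than by
#'   direct counting, so that the occurrence basis of `p_b` carries
#'   through; in set mode the two definitions coincide.
#'
#' @param antecedent,consequent Disjoint itemsets (letter strings or
#'   letter vectors).
#' @param db A `transaction_db`.
#' @param mode `"paper"` or `"set"`.
#' @return An object of class `rule_probs`.
#' @export
rule_probabilities <- function(antecedent, consequent, db,
                               mode = c("paper", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "transaction_db"))
  a <- as_items(antecedent)
  b <- as_items(consequent)
  if (length(intersect(a, b)) > 0L) {
    stop_validation("antecedent and consequent overlap: %s",
                    paste(intersect(a, b), collapse = ""))
  }
  n <- db$n_windows
  if (n == 0L) stop_validation("empty transaction database")
  p_a <- support_count(a, db, mode) / n
  p_b <- support_count(b, db, mode) / n
  p_ab <- containment_count(sort(c(a, b)), db) / n
  p_a_window <- containment_count(a, db) / n
  structure(list(antecedent = paste(a, collapse = ""),
                 consequent = paste(b, collapse = ""),
                 p_a = p_a,
                 p_b = p_b,
                 p_ab = p_ab,
                 p_a_window = p_a_window,
                 p_not_a = 1 - p_a_window,
                 p_nota_b = p_b - p_ab,
                 n_windows = n,
                 mode = mode),
            class = "rule_probs")
}

#' Lift of a rule
#'
#' `P(AB) / (P(A) P(B))`: 1 at independence, above 1 for positive
#' correlation.
#'
#' @param p A `rule_probs` object from [rule_probabilities()].
#' @return Nonnegative real, or `NA` if `P(A)` or `P(B)` is zero.
#' @export
lift <- function(p) {
  stopifnot(inherits(p, "rule_probs"))
  if (p$p_a <= 0 || p$p_b <= 0) return(NA_real_)
  p$p_ab / (p$p_a * p$p_b)
}

#' Improve of a rule
#'
#' `P(B|A) - P(B)`, the additive analogue of lift. Computed and reported
#' but not used in the usefulness verdict (its sign always matches
#' bi-improve's).
#'
#' @inheritParams lift
#' @return Real, or `NA` if `P(A)` is zero.
#' @export
improve <- function(p) {
  stopifnot(inherits(p, "rule_probs"))
  if (p$p_a <= 0) return(NA_real_)
  p$p_ab / p$p_a - p$p_b
}

#' Bi-lift of a rule
#'
#' `lift(A -> B) / lift(not-A -> B)`, correcting lift's symmetry in A and
#' B. `lift(not-A -> B) = P(not-A and B) / (P(not-A) P(B))` uses the
#' complement probabilities of [rule_probabilities()]. When B never occurs
#' without A the measure is `Inf` (range is \[0, Inf\]; `Inf` counts as
#' passing the `> 1` usefulness clause); when A is in every window it is
#' undefined (`NA`).
#'
#' @inheritParams lift
#' @return Nonnegative real, `Inf`, or `NA`.
#' @export
bi_lift <- function(p) {
  stopifnot(inherits(p, "rule_probs"))
  l <- lift(p)
  if (is.na(l) || p$p_not_a <= 0) return(NA_real_)
  if (p$p_nota_b == 0) return(if (l > 0) Inf else NA_real_)
  l / (p$p_nota_b / (p$p_not_a * p$p_b))
}

#' Bi-improve of a rule
#'
#' `(P(AB) - P(A) P(B)) / P(not-A)`, correcting improve's sensitivity to
#' the antecedent's frequency.
#'
#' @inheritParams lift
#' @return Real, or `NA` when A is in every window.
#' @export
bi_improve <- function(p) {
  stopifnot(inherits(p, "rule_probs"))
  if (p$p_not_a <= 0) return(NA_real_)
  (p$p_ab - p$p_a * p$p_b) / p$p_not_a
}

#' Bi-confidence of a rule
#'
#' `(P(AB) - P(A) P(B)) / (P(A) (1 - P(A)))`, where the denominator always
#' uses the antecedent's window-containment probability (so it is a
#' variance-like term in \[0, 1/4\]). Positive values indicate positive
#' correlation; under set-mode counting the measure lies in \[-1, 1\].
#' Undefined (`NA`) when the antecedent is in no window or in all windows.
#'
#' @inheritParams lift
#' @return Real, or `NA`.
#' @export
bi_confidence <- function(p) {
  stopifnot(inherits(p, "rule_probs"))
  paw <- p$p_a_window
  if (paw <= 0 || paw >= 1) return(NA_real_)
  (p$p_ab - p$p_a * p$p_b) / (paw * (1 - paw))
}

#' Usefulness verdict for a rule
#'
#' A strong rule is useful iff all four clauses hold strictly:
#' lift > 1, bi-lift > 1, bi-improve > 0 and bi-confidence > 0. An
#' undefined (`NA`) measure fails its clause; `Inf` bi-lift passes. Rules
#' at exact independence (1, 1, 0, 0) are redundant.
#'
#' @param lift,bi_lift,bi_improve,bi_confidence Numeric vectors (recycled
#'   to a common length).
#' @return Character vector, `"useful"` or `"redundant"`.
#' @export
classify_rules <- function(lift, bi_lift, bi_improve, bi_confidence) {
  ok <- !is.na(lift) & lift > 1 &
    !is.na(bi_lift) & bi_lift > 1 &
    !is.na(bi_improve) & bi_improve > 0 &
    !is.na(bi_confidence) & bi_confidence > 0
  ifelse(ok, "useful", "redundant")
}

#' Compute interestingness measures and verdicts for a set of rules
#'
#' Evaluates lift, improve, bi-lift, bi-improve and bi-confidence for each
#' rule and classifies it as useful or redundant (see [classify_rules()]).
#'
#' @param rules Data frame with `antecedent` and `consequent` columns
#'   (typically the `accepted` partition from [filter_strong()]).
#' @param db The `transaction_db` the rules were mined from.
#' @param mode `"paper"` or `"set"`.
#' @return `rules` with added columns `lift`, `improve`, `bi_lift`,
#'   `bi_improve`, `bi_confidence`, `verdict`.
#' @examples
#' db <- partition_windows(read_fasta(hbb_fasta_path())[[1]])
#' p <- rule_probabilities("GT", "AN", db, "paper")
#' lift(p)           # 3.75
#' bi_lift(p)        # 12
#' @export
rule_metrics <- function(rules, db, mode = c("paper", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "transaction_db"))
  k <- nrow(rules)
  cols <- c("lift", "improve", "bi_lift", "bi_improve", "bi_confidence")
  for (cl in cols) rules[[cl]] <- numeric(k)
  for (i in seq_len(k)) {
    p <- rule_probabilities(rules$antecedent[i], rules$consequent[i],
                            db, mode)
    rules$lift[i] <- lift(p)
    rules$improve[i] <- improve(p)
    rules$bi_lift[i] <- bi_lift(p)
    rules$bi_improve[i] <- bi_improve(p)
    rules$bi_confidence[i] <- bi_confidence(p)
  }
  rules$verdict <- if (k > 0L) {
    classify_rules(rules$lift, rules$bi_lift,
                   rules$bi_improve, rules$bi_confidence)
  } else {
    character(0)
  }
  rules
}

# display formatting for measure columns: 3 decimals, half away from zero,
# non-finite values as "inf" / "NA"
format_metric <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "NA"
  out[is.infinite(x)] <- "inf"
  fin <- is.finite(x)
  out[fin] <- sprintf("%.3f", round_half_up(x[fin], 3))
  out
}

#' Write a rule-metrics table to TSV
#'
#' Columns: `antecedent`, `consequent`, `confidence_pct`, `lift`,
#' `bi_lift`, `bi_improve`, `bi_confidence`, `verdict`; useful rules
#' first, each block in descending bi-confidence order. Measures are
#' printed to 3 decimals; infinite bi-lift prints as `inf`.
#'
#' @param metrics Data frame from [rule_metrics()] (with a `confidence`
#'   column).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(metrics, path) {
  ord <- order(metrics$verdict != "useful",
               -ifelse(is.finite(metrics$bi_confidence),
                       metrics$bi_confidence, -Inf),
               metrics$antecedent, metrics$consequent)
  m <- metrics[ord, , drop = FALSE]
  df <- data.frame(
    antecedent = m$antecedent,
    consequent = m$consequent,
    confidence_pct = round_percent(m$confidence),
    lift = format_metric(m$lift),
    bi_lift = format_metric(m$bi_lift),
    bi_improve = format_metric(m$bi_improve),
    bi_confidence = format_metric(m$bi_confidence),
    verdict = m$verdict,
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}
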