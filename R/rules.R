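#' Enumerate all candidate association rules from frequent itemsets
#'
#' For every frequent itemset of size k >= 2, emits all 2^k - 2 nonempty
#' proper subsets as antecedents with the complement as consequent. Rules
#' are grouped by source itemset (itemsets in size-then-lexicographic
#' order) with antecedents in subset-enumeration order; both sides are
#' alphabetically sorted letter strings.
#'
#' @param table A `freq_itemsets` object from [apriori()].
#' @return Data frame with columns `itemset`, `antecedent`, `consequent`;
#'   zero rows if no itemset has size >= 2.
#' @examples
#' db <- partition_windows(read_fasta(hbb_fasta_path())[[1]])
#' rules <- enumerate_rules(apriori(db, minsup = 3))
#' nrow(rules)  # 698
#' @export
enumerate_rules <- function(table) {
  stopifnot(inherits(table, "freq_itemsets"))
  empty <- data.frame(itemset = character(0),
                      antecedent = character(0),
                      consequent = character(0),
                      stringsAsFactors = FALSE)
  df <- as.data.frame(table)
  df <- df[df$size >= 2L, , drop = FALSE]
  if (nrow(df) == 0L) return(empty)
  parts <- lapply(df$itemset, function(its) {
    letters <- strsplit(its, "", fixed = TRUE)[[1L]]
    k <- length(letters)
    masks <- seq_len(2L^k - 2L)
    ante <- character(length(masks))
    cons <- character(length(masks))
    for (m in masks) {
      sel <- bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) > 0L
      ante[m] <- paste(letters[sel], collapse = "")
      cons[m] <- paste(letters[!sel], collapse = "")
    }
    data.frame(itemset = its, antecedent = ante, consequent = cons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Attach support counts and confidence to candidate rules
#'
#' Confidence of A -> B is supp(A union B) / supp(A) under the active
#' counting mode: the union always has size >= 2 and is counted by window
#' containment, while a singleton antecedent's denominator is its
#' occurrence count in paper mode. Confidence is an exact ratio of integer
#' counts; [round_percent()] renders it for display.
#'
#' @param rules Data frame from [enumerate_rules()].
#' @param db The `transaction_db` the itemsets were mined from.
#' @param mode `"paper"` or `"set"`.
#' @return `rules` with added columns `supp_union`, `supp_antecedent`,
#'   `confidence`.
#' @export
rule_confidence <- function(rules, db, mode = c("paper", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "transaction_db"))
  if (nrow(rules) == 0L) {
    rules$supp_union <- integer(0)
    rules$supp_antecedent <- integer(0)
    rules$confidence <- numeric(0)
    return(rules)
  }
  rules$supp_union <- vapply(strsplit(rules$itemset, "", fixed = TRUE),
                             containment_count, integer(1L), db = db,
                             USE.NAMES = FALSE)
  rules$supp_antecedent <- vapply(rules$antecedent, support_count,
                                  integer(1L), db = db, mode = mode,
                                  USE.NAMES = FALSE)
  if (any(rules$supp_antecedent == 0L)) {
    bad <- rules$antecedent[rules$supp_antecedent == 0L][1L]
    stop_validation("confidence undefined: antecedent '%s' has zero support",
                    bad)
  }
  rules$confidence <- rules$supp_union / rules$supp_antecedent
  rules
}

#' Render a confidence (or any proportion) as a whole percentage
#'
#' Rounds half away from zero, matching the usual presentation of
#' confidence tables (3/7 -> 43).
#'
#' @param x Numeric vector of proportions in \[0, 1\].
#' @return Integer vector of percentages.
#' @export
round_percent <- function(x) {
  as.integer(round_half_up(100 * x))
}

#' Partition rules into strong (accepted) and rejected at a confidence
#' threshold
#'
#' A rule is accepted iff its confidence is greater than or equal to
#' `min_conf` (a rule at exactly the threshold passes). Input order is
#' preserved within each partition; the full table with a `status` column
#' is returned alongside.
#'
#' @param rules Data frame with a `confidence` column, from
#'   [rule_confidence()].
#' @param min_conf Minimum confidence in (0, 1\]; default 0.90.
#' @return List with elements `accepted`, `rejected` (disjoint row subsets
#'   of `rules`, each carrying `status`) and `all` (every rule with its
#'   `status`).
#' @export
filter_strong <- function(rules, min_conf = 0.90) {
  if (!is.numeric(min_conf) || length(min_conf) != 1L || is.na(min_conf) ||
      min_conf < 0 || min_conf > 1) {
    stop_validation("min_conf must be a number in [0, 1]")
  }
  if (is.null(rules$confidence)) {
    stop_validation("rules have no confidence column; run rule_confidence()")
  }
  status <- rep("rejected", nrow(rules))
  status[rules$confidence >= min_conf] <- "accepted"
  rules$status <- status
  accepted <- rules[rules$status == "accepted", , drop = FALSE]
  rejected <- rules[rules$status == "rejected", , drop = FALSE]
  rownames(accepted) <- NULL
  rownames(rejected) <- NULL
  list(accepted = accepted, rejected = rejected, all = rules)
}

#' Write a scored rule table to TSV
#'
#' Columns: `antecedent`, `consequent`, `support_count_union`,
#' `confidence_exact` (integer ratio, e.g. `3/7`), `confidence_pct`
#' (rounded whole percent) and `status`.
#'
#' @param rules Data frame from [filter_strong()]'s `all` element (or any
#'   frame with the needed columns).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(rules, path) {
  df <- data.frame(
    antecedent = rules$antecedent,
    consequent = rules$consequent,
    support_count_union = rules$supp_union,
    confidence_exact = sprintf("%d/%d", rules$supp_union,
                               rules$supp_antecedent),
    confidence_pct = round_percent(rules$confidence),
    status = rules$status,
    stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}
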