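# Itemsets are represented throughout as strings of strictly increasing
# letters ("AGT"). as_items() accepts either that form or a character
# vector of single letters.
as_items <- function(items) {
  if (length(items) == 1L && nchar(items) > 1L) {
    items <- strsplit(items, "", fixed = TRUE)[[1L]]
  }
  if (length(items) < 1L) stop_validation("itemset must be nonempty")
  if (!all(items %in% AA_ALPHABET)) {
    stop_validation("invalid amino-acid letter(s): %s",
                    paste(setdiff(items, AA_ALPHABET), collapse = ", "))
  }
  if (anyDuplicated(items)) {
    stop_validation("duplicate letters in itemset: %s",
                    paste(items, collapse = ""))
  }
  sort(items)
}

# windows whose distinct-letter set contains every item
containment_count <- function(items, db) {
  if (db$n_windows == 0L) return(0L)
  m <- db$set_matrix[, items, drop = FALSE]
  as.integer(sum(rowSums(m) == length(items)))
}

#' Support count of an itemset under a counting mode
#'
#' Two counting modes are provided. `"set"` is classical market-basket
#' support: the number of windows whose distinct-letter set contains the
#' itemset. `"paper"` differs only for 1-itemsets, whose support is the
#' total number of occurrences of the letter across all windows, counted
#' with multiplicity; itemsets of size 2 or more are counted by window
#' containment in both modes. The occurrence basis for singletons is what
#' reproduces published confidence tables for this mining style (e.g. a
#' singleton-antecedent rule's denominator is the letter's occurrence
#' count), so `"paper"` is the pipeline default.
#'
#' @param items An itemset: string of distinct letters (`"GT"`) or a
#'   character vector of single letters.
#' @param db A `transaction_db` from [partition_windows()].
#' @param mode `"paper"` or `"set"`.
#' @return Nonnegative integer support count.
#' @examples
#' db <- partition_windows(read_fasta(hbb_fasta_path())[[1]])
#' support_count("GT", db)            # 3 windows contain both G and T
#' support_count("A", db, "paper")    # 15 occurrences of A
#' support_count("A", db, "set")      # 10 windows contain A
#' @export
support_count <- function(items, db, mode = c("paper", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "transaction_db"))
  items <- as_items(items)
  if (db$n_windows == 0L) return(0L)
  if (mode == "paper" && length(items) == 1L) {
    return(unname(db$occurrences[items]))
  }
  containment_count(items, db)
}

#' Frequent 1-itemsets
#'
#' Single letters whose support count (per the active mode) meets the
#' minimum support count, sorted alphabetically.
#'
#' @inheritParams support_count
#' @param minsup Minimum support count (absolute, not a fraction);
#'   at least 1.
#' @return Data frame with columns `size`, `itemset`, `support_count`.
#' @export
frequent_singletons <- function(db, minsup, mode = c("paper", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "transaction_db"))
  check_minsup(minsup)
  supp <- if (mode == "paper") {
    db$occurrences
  } else {
    stats::setNames(as.integer(colSums(db$set_matrix)), AA_ALPHABET)
  }
  keep <- sort(names(supp)[supp >= minsup])
  data.frame(size = rep(1L, length(keep)),
             itemset = keep,
             support_count = unname(supp[keep]),
             stringsAsFactors = FALSE)
}

check_minsup <- function(minsup) {
  if (!is.numeric(minsup) || length(minsup) != 1L || is.na(minsup) ||
      minsup < 1 || minsup != floor(minsup)) {
    stop_validation("minsup must be an integer >= 1")
  }
}

#' Apriori candidate generation (prefix join)
#'
#' Joins every pair of (k-1)-itemsets sharing their first k-2 letters into
#' a size-k candidate. For k = 2 the shared prefix is empty, so all pairs
#' of frequent singletons join. Output is duplicate-free and sorted.
#'
#' @param prev_level Character vector of frequent (k-1)-itemsets, each a
#'   string of strictly increasing letters, all the same size.
#' @return Character vector of size-k candidate itemsets.
#' @examples
#' candidate_join(c("AG", "AK", "GK"))  # "AGK"
#' candidate_join(c("A", "G", "K"))     # "AG" "AK" "GK"
#' @export
candidate_join <- function(prev_level) {
  if (length(prev_level) < 2L) return(character(0))
  sizes <- nchar(prev_level)
  if (length(unique(sizes)) != 1L) {
    stop_validation("prev_level mixes itemset sizes: %s",
                    paste(sort(unique(sizes)), collapse = ", "))
  }
  k1 <- sizes[1L]
  prev <- sort(unique(prev_level))
  prefix <- substr(prev, 1L, k1 - 1L)
  last <- substr(prev, k1, k1)
  groups <- split(last, prefix)
  prefixes <- names(groups)
  joined <- lapply(seq_along(groups), function(g) {
    tails <- sort(groups[[g]])
    if (length(tails) < 2L) return(character(0))
    pairs <- utils::combn(tails, 2L)
    paste0(prefixes[g], pairs[1L, ], pairs[2L, ])
  })
  out <- unlist(joined, use.names = FALSE)
  sort(unique(out))
}

# downward-closure prune: keep candidates all of whose (k-1)-subsets are
# frequent
prune_closure <- function(candidates, prev_level) {
  if (length(candidates) == 0L) return(candidates)
  keep <- vapply(strsplit(candidates, "", fixed = TRUE), function(letters) {
    subs <- vapply(seq_along(letters),
                   function(i) paste(letters[-i], collapse = ""), "")
    all(subs %in% prev_level)
  }, logical(1L))
  candidates[keep]
}

#' Mine frequent amino-acid itemsets by levelwise Apriori
#'
#' Expands frequent itemsets level by level until a level yields none:
#' frequent singletons per the counting mode, then prefix-join candidate
#' generation and direct support counting at each size. Because paper-mode
#' level 1 uses the occurrence basis while higher levels use window
#' containment, the downward-closure candidate prune is applied only in
#' set mode (where it is sound); it never changes the final output, since
#' every candidate's support is counted anyway.
#'
#' @inheritParams frequent_singletons
#' @return An object of classes `freq_itemsets` and `data.frame` with
#'   columns `size`, `itemset`, `support_count`, ordered by size then
#'   lexicographically, and attributes `minsup`, `mode` and `n_windows`.
#' @examples
#' db <- partition_windows(read_fasta(hbb_fasta_path())[[1]])
#' fit <- apriori(db, minsup = 3, mode = "paper")
#' nrow(fit)           # 135 frequent itemsets
#' table(fit$size)     # 16 50 50 17 2
#' @export
apriori <- function(db, minsup = 3, mode = c("paper", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "transaction_db"))
  check_minsup(minsup)
  level <- frequent_singletons(db, minsup, mode)
  levels <- list(level)
  k <- 2L
  while (nrow(level) > 0L) {
    candidates <- candidate_join(level$itemset)
    if (mode == "set" && k > 2L) {
      candidates <- prune_closure(candidates, level$itemset)
    }
    if (length(candidates) == 0L) break
    supp <- vapply(strsplit(candidates, "", fixed = TRUE),
                   containment_count, integer(1L), db = db)
    keep <- supp >= minsup
    if (!any(keep)) break
    level <- data.frame(size = rep(k, sum(keep)),
                        itemset = candidates[keep],
                        support_count = as.integer(supp[keep]),
                        stringsAsFactors = FALSE)
    levels[[k]] <- level
    k <- k + 1L
  }
  out <- do.call(rbind, levels)
  rownames(out) <- NULL
  structure(out,
            minsup = as.integer(minsup),
            mode = mode,
            n_windows = db$n_windows,
            class = c("freq_itemsets", "data.frame"))
}

#' @export
print.freq_itemsets <- function(x, ...) {
  cat(sprintf(
    "<freq_itemsets> %d frequent itemset(s), minsup %d, mode '%s', %d window(s)\n",
    nrow(x), attr(x, "minsup"), attr(x, "mode"), attr(x, "n_windows")))
  if (nrow(x) > 0L) {
    counts <- table(x$size)
    cat("  per size:",
        paste(sprintf("%s-itemsets: %d", names(counts), counts),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a frequent-itemset table to TSV
#'
#' Columns: `size`, `itemset`, `support_count`, `support_fraction`
#' (support over the window count). Tab-separated, header row, LF endings.
#'
#' @param table A `freq_itemsets` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_itemsets <- function(table, path) {
  stopifnot(inherits(table, "freq_itemsets"))
  df <- as.data.frame(table)
  n <- attr(table, "n_windows")
  df$support_fraction <- if (n > 0L) df$support_count / n else NA_real_
  write_tsv(df, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
}
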