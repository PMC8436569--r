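# Shared fixtures and independent brute-force oracles. The oracles count
# directly over window letter-sets / occurrence tallies and never call the
# levelwise miner they are used to check.

hbb_seq <- function() read_fasta(hbb_fasta_path())[[1]]

hbb_db <- function() partition_windows(hbb_seq(), window_len = 10)

# a transaction database with zero windows (unreachable via partitioning,
# which requires a nonempty sequence)
empty_db <- function() {
  structure(list(windows = character(0),
                 sets = list(),
                 set_matrix = matrix(FALSE, nrow = 0,
                                     ncol = length(AA_ALPHABET),
                                     dimnames = list(NULL, AA_ALPHABET)),
                 occurrences = stats::setNames(integer(length(AA_ALPHABET)),
                                               AA_ALPHABET),
                 n_windows = 0L,
                 window_len = 10L,
                 source_id = "empty"),
            class = "transaction_db")
}

# direct scan: number of windows whose letter-set contains all items
oracle_support_set <- function(items, db) {
  sum(vapply(db$sets, function(s) all(items %in% s), logical(1)))
}

oracle_support <- function(items, db, mode) {
  if (mode == "paper" && length(items) == 1L) {
    tab <- table(unlist(strsplit(db$windows, "", fixed = TRUE)))
    return(as.integer(if (items %in% names(tab)) tab[[items]] else 0L))
  }
  oracle_support_set(items, db)
}

# exhaustive enumeration of all letter subsets, level by level, stopping
# at the first size with no frequent itemset (sound for sizes >= 2 by
# anti-monotonicity of window containment)
oracle_frequent <- function(db, minsup, mode) {
  present <- sort(unique(unlist(db$sets)))
  levels <- list()
  k <- 1L
  while (k <= length(present)) {
    combos <- utils::combn(present, k)
    supp <- apply(combos, 2L, function(it) oracle_support(it, db, mode))
    keep <- supp >= minsup
    if (!any(keep)) break
    levels[[k]] <- data.frame(
      size = k,
      itemset = apply(combos[, keep, drop = FALSE], 2L, paste,
                      collapse = ""),
      support_count = as.integer(supp[keep]),
      stringsAsFactors = FALSE)
    k <- k + 1L
  }
  out <- do.call(rbind, levels)
  if (is.null(out)) {
    out <- data.frame(size = integer(0), itemset = character(0),
                      support_count = integer(0))
  }
  rownames(out) <- NULL
  out
}

# all five measures from the explicit 2x2 window contingency table of
# (A present/absent) x (B present/absent); valid in set mode only
oracle_metrics_2x2 <- function(antecedent, consequent, db) {
  a_items <- strsplit(antecedent, "", fixed = TRUE)[[1L]]
  b_items <- strsplit(consequent, "", fixed = TRUE)[[1L]]
  in_a <- vapply(db$sets, function(s) all(a_items %in% s), logical(1))
  in_b <- vapply(db$sets, function(s) all(b_items %in% s), logical(1))
  n <- length(db$sets)
  n11 <- sum(in_a & in_b)
  n01 <- sum(!in_a & in_b)
  n0 <- sum(!in_a)
  pa <- mean(in_a)
  pb <- mean(in_b)
  pab <- n11 / n
  list(
    lift = pab / (pa * pb),
    improve = pab / pa - pb,
    # conditioning on "A absent" is undefined when A fills every window
    bi_lift = if (n0 == 0L) NA_real_ else if (n01 == 0L) Inf else
      (pab / (pa * pb)) / ((n01 / n) / ((n0 / n) * pb)),
    bi_improve = if (n0 == 0L) NA_real_ else (pab - pa * pb) / (n0 / n),
    bi_confidence = if (pa <= 0 || pa >= 1) NA_real_ else
      (pab - pa * pb) / (pa * (1 - pa)))
}

# view a freq_itemsets (or any data.frame) as a bare data.frame for
# identical() comparisons against oracle output
strip_fit <- function(x) {
  x <- as.data.frame(x)
  class(x) <- "data.frame"
  attr(x, "minsup") <- NULL
  attr(x, "mode") <- NULL
  attr(x, "n_windows") <- NULL
  rownames(x) <- NULL
  x
}

# deterministic small random fixtures for property tests
random_dbs <- function(n = 5L, len_range = c(40L, 80L), window_len = 10) {
  lapply(seq_len(n), function(i) {
    len <- len_range[1L] + (i * 7L) %% (len_range[2L] - len_range[1L] + 1L)
    partition_windows(random_protein(len, seed = 100L + i),
                      window_len = window_len)
  })
}
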