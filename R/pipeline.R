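#' Mine one protein sequence end to end
#'
#' Runs the full workflow on a single sequence: windowing, Apriori
#' frequent-itemset mining, rule enumeration, confidence filtering and
#' interestingness-based pruning. Pure (no file output); see
#' [run_pipeline()] for the FASTA-to-report driver.
#'
#' @param seq A [protein_seq()] (or plain residue string).
#' @param window_len Window length in residues (default 10).
#' @param minsup Minimum support count (default 3).
#' @param min_conf Minimum confidence for a strong rule (default 0.90).
#' @param mode Counting mode, `"paper"` (default) or `"set"`; see
#'   [support_count()].
#' @return An object of class `mining_report`: a list with the
#'   configuration, the per-stage counts (`n_windows`, `itemset_counts`,
#'   `n_itemsets`, `n_rules`, `n_strong`, `n_rejected`, `n_useful`,
#'   `n_redundant`) and the tables `itemsets`, `rules` (all candidates
#'   with status) and `metrics` (strong rules with measures and verdict).
#' @examples
#' hbb <- read_fasta(hbb_fasta_path())[[1]]
#' rep <- mine_protein(hbb)
#' rep$n_itemsets  # 135
#' rep$n_useful    # 59
#' @export
mine_protein <- function(seq, window_len = 10, minsup = 3,
                         min_conf = 0.90, mode = c("paper", "set")) {
  mode <- match.arg(mode)
  if (is.character(seq) && length(seq) == 1L) seq <- protein_seq("seq", seq)
  stopifnot(inherits(seq, "protein_seq"))
  db <- partition_windows(seq, window_len)
  fit <- apriori(db, minsup, mode)
  rules <- rule_confidence(enumerate_rules(fit), db, mode)
  parts <- filter_strong(rules, min_conf)
  metrics <- rule_metrics(parts$accepted, db, mode)
  counts <- table(factor(fit$size, levels = seq_len(max(fit$size, 1L))))
  structure(list(
    schema_version = "1.0",
    sequence_id = seq$id,
    sequence_length = seq$length,
    window_len = as.integer(window_len),
    minsup = as.integer(minsup),
    min_conf = min_conf,
    mode = mode,
    n_windows = db$n_windows,
    itemset_counts = stats::setNames(as.integer(counts), names(counts)),
    n_itemsets = nrow(fit),
    n_rules = nrow(rules),
    n_strong = nrow(parts$accepted),
    n_rejected = nrow(parts$rejected),
    n_useful = sum(metrics$verdict == "useful"),
    n_redundant = sum(metrics$verdict == "redundant"),
    itemsets = fit,
    rules = parts$all,
    metrics = metrics),
    class = "mining_report")
}

#' @export
print.mining_report <- function(x, ...) {
  cat(sprintf("<mining_report> %s (%d aa)\n", x$sequence_id,
              x$sequence_length))
  cat(sprintf("  window_len %d, minsup %d, min_conf %.2f, mode '%s'\n",
              x$window_len, x$minsup, x$min_conf, x$mode))
  cat(sprintf("  %d windows -> %d frequent itemsets -> %d rules\n",
              x$n_windows, x$n_itemsets, x$n_rules))
  cat(sprintf("  %d strong (%d rejected) -> %d useful, %d redundant\n",
              x$n_strong, x$n_rejected, x$n_useful, x$n_redundant))
  invisible(x)
}

#' Run the mining pipeline on a FASTA file
#'
#' Reads every record of `fasta_path`, mines each with [mine_protein()]
#' and optionally writes per-record artifacts (`itemsets.tsv`,
#' `rules.tsv`, `metrics.tsv`, `report.json`) under `out_dir` — directly
#' there for a single-record file, in per-record subdirectories otherwise.
#' Per-stage counts are logged to standard error.
#'
#' @inheritParams mine_protein
#' @param fasta_path Path to a FASTA file.
#' @param out_dir Output directory, or `NULL` (no files written).
#' @param strict Passed to [read_fasta()].
#' @param quiet Suppress progress messages.
#' @return A named list of `mining_report` objects, one per FASTA record,
#'   invisibly when `out_dir` is set.
#' @export
run_pipeline <- function(fasta_path, window_len = 10, minsup = 3,
                         min_conf = 0.90, mode = c("paper", "set"),
                         out_dir = NULL, strict = TRUE, quiet = FALSE) {
  mode <- match.arg(mode)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  seqs <- read_fasta(fasta_path, strict = strict)
  say("read %d record(s) from %s", length(seqs), fasta_path)
  reports <- lapply(seqs, function(s) {
    rep <- mine_protein(s, window_len = window_len, minsup = minsup,
                        min_conf = min_conf, mode = mode)
    say("%s: %d windows, %d itemsets, %d rules, %d strong, %d useful",
        rep$sequence_id, rep$n_windows, rep$n_itemsets, rep$n_rules,
        rep$n_strong, rep$n_useful)
    rep
  })
  if (!is.null(out_dir)) {
    for (rep in reports) {
      dir <- if (length(reports) == 1L) {
        out_dir
      } else {
        file.path(out_dir, gsub("[^A-Za-z0-9._-]", "_", rep$sequence_id))
      }
      write_report(rep, dir)
      say("%s: artifacts written to %s", rep$sequence_id, dir)
    }
    return(invisible(reports))
  }
  reports
}

#' Write a mining report's artifacts to a directory
#'
#' Produces `itemsets.tsv`, `rules.tsv`, `metrics.tsv` and `report.json`.
#' Outputs are deterministic: rerunning on the same input and
#' configuration reproduces the files byte for byte.
#'
#' @param report A `mining_report` from [mine_protein()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mining_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_itemsets(report$itemsets, file.path(dir, "itemsets.tsv"))
  write_rules(report$rules, file.path(dir, "rules.tsv"))
  write_metrics(report$metrics, file.path(dir, "metrics.tsv"))
  jsonlite::write_json(report_json(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

# JSON-safe view of a report: counts, config, and the strong rules with
# measures (Inf rendered as the string "inf")
report_json <- function(report) {
  m <- report$metrics
  rule_list <- lapply(seq_len(nrow(m)), function(i) {
    num <- function(x) if (is.na(x)) NULL else if (is.infinite(x)) "inf" else x
    list(antecedent = m$antecedent[i],
         consequent = m$consequent[i],
         confidence = m$confidence[i],
         confidence_pct = round_percent(m$confidence[i]),
         lift = num(m$lift[i]),
         improve = num(m$improve[i]),
         bi_lift = num(m$bi_lift[i]),
         bi_improve = num(m$bi_improve[i]),
         bi_confidence = num(m$bi_confidence[i]),
         verdict = m$verdict[i])
  })
  list(schema_version = report$schema_version,
       sequence_id = report$sequence_id,
       sequence_length = report$sequence_length,
       parameters = list(window_len = report$window_len,
                         minsup = report$minsup,
                         min_conf = report$min_conf,
                         mode = report$mode),
       n_windows = report$n_windows,
       itemset_counts = as.list(report$itemset_counts),
       n_itemsets = report$n_itemsets,
       n_rules = report$n_rules,
       n_strong = report$n_strong,
       n_rejected = report$n_rejected,
       n_useful = report$n_useful,
       n_redundant = report$n_redundant,
       strong_rules = rule_list)
}

#' Named mining presets for the five study proteins
#'
#' The minimum support count is chosen by sequence length: 3 for the
#' 147-residue hemoglobin beta chain, 5 for the long BRCA1 and CFTR
#' chains, 4 for the mid-length vasopressin V2 receptor and rhodopsin.
#' Window length 10 and confidence threshold 90% throughout.
#'
#' @return Data frame with columns `disease`, `protein`, `uniprot`,
#'   `length`, `window_len`, `minsup`, `min_conf`, `mode`.
#' @export
mining_presets <- function() {
  data.frame(
    disease = c("sickle cell anemia", "breast cancer", "cystic fibrosis",
                "nephrogenic diabetes insipidus", "retinitis pigmentosa 4"),
    protein = c("Hemoglobin subunit beta",
                "Breast cancer type 1 susceptibility protein",
                "Cystic fibrosis transmembrane conductance regulator",
                "Vasopressin V2 receptor", "Rhodopsin"),
    uniprot = c("P68871", "P38398", "P13569", "P30518", "P08100"),
    length = c(147L, 1863L, 1480L, 371L, 348L),
    window_len = 10L,
    minsup = c(3L, 5L, 5L, 4L, 4L),
    min_conf = 0.90,
    mode = "paper",
    stringsAsFactors = FALSE)
}

rule_keys <- function(metrics, verdict = NULL) {
  if (nrow(metrics) == 0L) return(character(0))
  m <- if (is.null(verdict)) metrics else
    metrics[metrics$verdict == verdict, , drop = FALSE]
  paste0(m$antecedent, "->", m$consequent)
}

#' Diff the rule sets of two mining runs of the same sequence
#'
#' Lists rules strong or useful in one run but not the other, supporting
#' audits of previously published rule lists against a rerun with
#' different parameters or counting mode.
#'
#' @param report_a,report_b `mining_report` objects for the same
#'   `sequence_id`.
#' @return An object of class `rule_diff`: list with character vectors
#'   `strong_only_a`, `strong_only_b`, `useful_only_a`, `useful_only_b`
#'   (rules as `"A->B"` strings) and the logical `identical`.
#' @export
compare_runs <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "mining_report"),
            inherits(report_b, "mining_report"))
  if (!identical(report_a$sequence_id, report_b$sequence_id)) {
    stop_validation("reports are for different sequences: '%s' vs '%s'",
                    report_a$sequence_id, report_b$sequence_id)
  }
  sa <- rule_keys(report_a$metrics)
  sb <- rule_keys(report_b$metrics)
  ua <- rule_keys(report_a$metrics, "useful")
  ub <- rule_keys(report_b$metrics, "useful")
  out <- list(sequence_id = report_a$sequence_id,
              strong_only_a = setdiff(sa, sb),
              strong_only_b = setdiff(sb, sa),
              useful_only_a = setdiff(ua, ub),
              useful_only_b = setdiff(ub, ua))
  out$identical <- all(lengths(out[c("strong_only_a", "strong_only_b",
                                     "useful_only_a", "useful_only_b")]) ==
                         0L)
  structure(out, class = "rule_diff")
}

#' @export
print.rule_diff <- function(x, ...) {
  cat(sprintf("<rule_diff> %s%s\n", x$sequence_id,
              if (x$identical) ": runs agree" else ""))
  for (nm in c("strong_only_a", "strong_only_b",
               "useful_only_a", "useful_only_b")) {
    if (length(x[[nm]]) > 0L) {
      cat(sprintf("  %s (%d): %s\n", nm, length(x[[nm]]),
                  paste(x[[nm]], collapse = ", ")))
    }
  }
  invisible(x)
}
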