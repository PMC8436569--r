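#' Construct a validated protein sequence
#'
#' Wraps an identifier and a residue string into a `protein_seq` object,
#' validating every character against the 20-letter amino-acid alphabet.
#' Non-standard codes (B, J, O, U, X, Z, `*`, gaps) either abort with an
#' error naming the first offending position (`strict = TRUE`, the default)
#' or are dropped with a warning (`strict = FALSE`).
#'
#' @param id Free-text identifier.
#' @param residues Residue string; whitespace is removed and letters are
#'   upper-cased before validation.
#' @param description Optional free-text description (carried, unused).
#' @param strict Reject (`TRUE`) or drop with a warning (`FALSE`)
#'   non-standard residues.
#' @return An object of class `protein_seq` with fields `id`,
#'   `description`, `residues` and `length`.
#' @export
protein_seq <- function(id, residues, description = "", strict = TRUE) {
  if (!is.character(residues) || length(residues) != 1L) {
    stop_validation("residues must be a single character string")
  }
  residues <- toupper(gsub("[[:space:]]", "", residues))
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad) > 0L) {
    if (strict) {
      stop_validation("record '%s': non-standard residue '%s' at position %d",
                      id, chars[bad[1L]], bad[1L])
    }
    warning(sprintf("record '%s': dropped %d non-standard residue(s)",
                    id, length(bad)))
    chars <- chars[-bad]
    residues <- paste(chars, collapse = "")
  }
  if (nchar(residues) < 1L) {
    stop_validation("record '%s' has an empty sequence", id)
  }
  structure(list(id = id,
                 description = description,
                 residues = residues,
                 length = nchar(residues)),
            class = "protein_seq")
}

#' @export
print.protein_seq <- function(x, ...) {
  cat(sprintf("<protein_seq> %s (%d aa)\n", x$id, x$length))
  head <- substr(x$residues, 1L, 60L)
  cat(" ", head, if (x$length > 60L) "..." else "", "\n", sep = "")
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' Parses a (possibly multi-record, line-wrapped) FASTA file into a list of
#' [protein_seq()] objects, preserving record order. The identifier is the
#' header text up to the first whitespace; the remainder is carried as the
#' description.
#'
#' @param path Path to a FASTA file.
#' @param strict Passed to [protein_seq()]: reject or drop non-standard
#'   residue codes.
#' @return A list of `protein_seq` objects, named by identifier.
#' @examples
#' seqs <- read_fasta(hbb_fasta_path())
#' seqs[[1]]$length  # 147
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop_io("FASTA file not found: %s", as.character(path)[1L])
  }
  records <- Biostrings::readBStringSet(path)
  if (length(records) == 0L) {
    stop_validation("no FASTA records found in %s", path)
  }
  headers <- names(records)
  seqs <- lapply(seq_along(records), function(i) {
    header <- headers[[i]]
    id <- sub("[[:space:]].*$", "", header)
    if (!nzchar(id)) id <- sprintf("record_%d", i)
    desc <- if (grepl("[[:space:]]", header)) {
      sub("^[^[:space:]]+[[:space:]]+", "", header)
    } else {
      ""
    }
    res <- as.character(records[[i]])
    if (nchar(gsub("[[:space:]]", "", res)) == 0L) {
      stop_validation("record '%s' (record %d) has an empty sequence", id, i)
    }
    protein_seq(id, res, description = desc, strict = strict)
  })
  names(seqs) <- vapply(seqs, `[[`, "", "id")
  seqs
}

#' Partition a protein sequence into fixed-length window transactions
#'
#' Cuts the sequence into consecutive, non-overlapping windows of
#' `window_len` residues. The trailing partial window is retained as a
#' transaction (the 147-residue hemoglobin beta chain yields 15 windows,
#' the last of length 7). Each window carries both its residue multiset
#' (letters with multiplicity) and its residue set (distinct letters); the
#' set drives containment counting, the multisets drive occurrence
#' counting.
#'
#' @param seq A [protein_seq()] object, or a plain residue string (wrapped
#'   with id `"seq"`).
#' @param window_len Window length in residues; positive integer,
#'   default 10.
#' @return An object of class `transaction_db` with fields `windows`
#'   (character vector of residue substrings), `sets` (list of sorted
#'   distinct-letter vectors), `set_matrix` (windows x 20 logical
#'   containment matrix), `occurrences` (per-letter occurrence totals
#'   across all windows), `n_windows`, `window_len` and `source_id`.
#' @examples
#' hbb <- read_fasta(hbb_fasta_path())[[1]]
#' db <- partition_windows(hbb, window_len = 10)
#' db$n_windows               # 15
#' nchar(db$windows[15])      # 7
#' @export
partition_windows <- function(seq, window_len = 10) {
  if (is.character(seq) && length(seq) == 1L) {
    seq <- protein_seq("seq", seq)
  }
  if (!inherits(seq, "protein_seq")) {
    stop_validation("seq must be a protein_seq or a residue string")
  }
  if (!is.numeric(window_len) || length(window_len) != 1L ||
      is.na(window_len) || window_len < 1 || window_len != floor(window_len)) {
    stop_validation("window_len must be a positive integer (got %s)",
                    paste(window_len, collapse = ","))
  }
  window_len <- as.integer(window_len)
  n <- seq$length
  starts <- seq.int(1L, n, by = window_len)
  ends <- pmin(starts + window_len - 1L, n)
  windows <- substring(seq$residues, starts, ends)
  letters <- strsplit(windows, "", fixed = TRUE)
  sets <- lapply(letters, function(x) sort(unique(x)))
  m <- matrix(FALSE, nrow = length(windows), ncol = length(AA_ALPHABET),
              dimnames = list(NULL, AA_ALPHABET))
  for (i in seq_along(sets)) m[i, sets[[i]]] <- TRUE
  occ <- table(factor(unlist(letters), levels = AA_ALPHABET))
  occ <- stats::setNames(as.integer(occ), AA_ALPHABET)
  structure(list(windows = windows,
                 sets = sets,
                 set_matrix = m,
                 occurrences = occ,
                 n_windows = length(windows),
                 window_len = window_len,
                 source_id = seq$id),
            class = "transaction_db")
}

#' Per-window residue multisets
#'
#' @param db A `transaction_db` from [partition_windows()].
#' @return A list (one element per window) of named integer vectors
#'   mapping each letter present in the window to its occurrence count.
#' @export
window_multisets <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  lapply(strsplit(db$windows, "", fixed = TRUE), function(x) {
    tab <- table(x)
    stats::setNames(as.integer(tab), names(tab))
  })
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("<transaction_db> %s: %d window(s) of nominal length %d\n",
              x$source_id, x$n_windows, x$window_len))
  invisible(x)
}

#' Generate a random protein sequence
#'
#' Draws residues i.i.d. from the 20-letter alphabet, uniformly by default
#' or with user-supplied weights. Deterministic for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param length Number of residues; positive integer.
#' @param seed Integer seed.
#' @param freqs Optional named numeric vector of nonnegative sampling
#'   weights for a subset of the alphabet (unnamed letters get weight 0);
#'   need not be normalized.
#' @param id Identifier for the generated record.
#' @return A [protein_seq()] object.
#' @examples
#' random_protein(20, seed = 7)
#' @export
random_protein <- function(length, seed, freqs = NULL,
                           id = sprintf("random_seed%d", seed)) {
  if (!is.numeric(length) || length(length) != 1L || is.na(length) ||
      length < 1 || length != floor(length)) {
    stop_validation("length must be a positive integer")
  }
  w <- rep(1, length(AA_ALPHABET))
  names(w) <- AA_ALPHABET
  if (!is.null(freqs)) {
    if (is.null(names(freqs)) || !all(names(freqs) %in% AA_ALPHABET)) {
      stop_validation("freqs must be named by amino-acid letters")
    }
    if (any(!is.finite(freqs)) || any(freqs < 0) || sum(freqs) <= 0) {
      stop_validation("freqs must be nonnegative weights, not all zero")
    }
    w[] <- 0
    w[names(freqs)] <- freqs
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  residues <- paste(sample(AA_ALPHABET, length, replace = TRUE, prob = w),
                    collapse = "")
  protein_seq(id, residues)
}
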