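test_that("bundled hemoglobin beta FASTA reads as one 147-residue record", {
  seqs <- read_fasta(hbb_fasta_path())
  expect_length(seqs, 1L)
  hbb <- seqs[[1]]
  expect_s3_class(hbb, "protein_seq")
  expect_identical(hbb$id, "P68871")
  expect_identical(hbb$length, 147L)
  expect_match(hbb$description, "Hemoglobin subunit beta")
  # the fixture is the concatenation of the five published 10/20/30-column
  # rows of the subsequence table
  rows <- c("MVHLTPEEKSAVTALWGKVNVDEVGGEALG",
            "RLLVVYPWTQRFFESFGDLSTPDAVMGNPK",
            "VKAHGKKVLGAFSDGLAHLDNLKGTFATLS",
            "ELHCDKLHVDPENFRLLGNVLVCVLAHHFG",
            "KEFTPPVQAAYQKVVAGVANALAHKYH")
  expect_identical(hbb$residues, paste(rows, collapse = ""))
})

test_that("FASTA parsing handles wrapping, case, order and minimal records", {
  path <- withr::local_tempfile(fileext = ".fasta")
  s1 <- random_protein(75, seed = 42, id = "rec1")
  wrapped <- gsub("(.{40})", "\\1\n", tolower(s1$residues))
  writeLines(c(">rec1 first generated record", wrapped, ">rec2", "M"), path)
  seqs <- read_fasta(path)
  expect_identical(names(seqs), c("rec1", "rec2"))
  expect_identical(seqs[["rec1"]]$residues, s1$residues)
  expect_identical(seqs[["rec1"]]$description, "first generated record")
  expect_identical(seqs[["rec2"]]$length, 1L)
  expect_identical(seqs[["rec2"]]$residues, "M")
})

test_that("FASTA errors: missing file, empty record, bad residues", {
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")),
               class = "aarules_io_error")

  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">ok", "MVH", ">empty", "", ">ok2", "MV"), path)
  expect_error(read_fasta(path), class = "aarules_validation_error")

  path2 <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">badseq", "MVXLT"), path2)
  expect_error(read_fasta(path2, strict = TRUE), "position 3",
               class = "aarules_validation_error")
  expect_warning(seqs <- read_fasta(path2, strict = FALSE),
                 "non-standard")
  expect_identical(seqs[["badseq"]]$residues, "MVLT")
})

test_that("windowing yields ceil(length/window_len) consecutive windows", {
  db <- hbb_db()
  expect_identical(db$n_windows, 15L)
  expect_identical(nchar(db$windows), c(rep(10L, 14), 7L))

  # exact fit leaves no empty tail window
  exact <- partition_windows(random_protein(10, seed = 1), window_len = 10)
  expect_identical(exact$n_windows, 1L)

  for (len in c(1L, 9L, 10L, 11L, 95L, 200L, 1000L)) {
    seq <- random_protein(len, seed = len)
    for (wl in c(1L, 3L, 7L, 10L, 20L)) {
      db <- partition_windows(seq, window_len = wl)
      expect_identical(db$n_windows, as.integer(ceiling(len / wl)))
      # concatenating windows reconstructs the input
      expect_identical(paste(db$windows, collapse = ""), seq$residues)
    }
  }
})

test_that("windows carry consistent residue multisets and sets", {
  seq <- protein_seq("hbb20", "MVHLTPEEKSAVTALWGKVN")
  db <- partition_windows(seq, window_len = 10)
  ms <- window_multisets(db)
  expect_identical(ms[[1]],
                   c(E = 2L, H = 1L, K = 1L, L = 1L, M = 1L, P = 1L,
                     S = 1L, T = 1L, V = 1L))
  expect_identical(ms[[2]],
                   c(A = 2L, G = 1L, K = 1L, L = 1L, N = 1L, T = 1L,
                     V = 2L, W = 1L))
  for (i in seq_along(ms)) {
    expect_identical(sum(ms[[i]]), nchar(db$windows[i]))
    expect_identical(sort(names(ms[[i]])), db$sets[[i]])
  }
})

test_that("windowing rejects invalid window lengths", {
  seq <- random_protein(20, seed = 2)
  expect_error(partition_windows(seq, window_len = 0),
               class = "aarules_validation_error")
  expect_error(partition_windows(seq, window_len = 2.5),
               class = "aarules_validation_error")
})

test_that("random proteins are deterministic, alphabet-bound and weighted", {
  a <- random_protein(50, seed = 7)
  b <- random_protein(50, seed = 7)
  expect_identical(a$residues, b$residues)
  expect_true(all(strsplit(a$residues, "")[[1]] %in% AA_ALPHABET))

  expect_identical(random_protein(5, seed = 3, freqs = c(A = 1))$residues,
                   "AAAAA")
  expect_error(random_protein(5, seed = 3, freqs = c(A = -1)),
               class = "aarules_validation_error")
  expect_error(random_protein(5, seed = 3, freqs = c(Z = 1)),
               class = "aarules_validation_error")

  # uniform draw: each letter within 5 binomial standard errors of 1/20
  big <- random_protein(10000, seed = 1)
  freq <- table(factor(strsplit(big$residues, "")[[1]],
                       levels = AA_ALPHABET)) / 10000
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_true(all(abs(freq - 0.05) <= 5 * se))
})

test_that("random_protein leaves the caller's RNG stream untouched", {
  set.seed(99)
  x1 <- runif(1)
  set.seed(99)
  invisible(random_protein(30, seed = 7))
  x2 <- runif(1)
  expect_identical(x1, x2)
})
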