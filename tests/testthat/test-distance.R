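# Alignment scoring, the two sequence metrics, and chunked matrices.

test_that("global alignment scores match a dynamic-programming oracle", {
  expect_equal(global_alignment_score("CASSL", "CASSL"), 30)
  expect_equal(global_alignment_score("C", "C"), 12)
  expect_equal(global_alignment_score("CASSL", "CASSV"), 26)

  withr::with_seed(11, {
    peps <- rand_peptides(30)
    for (k in seq_len(30)) {
      a <- sample(peps, 1); b <- sample(peps, 1)
      expect_equal(global_alignment_score(a, b), nw_score_oracle(a, b))
    }
  })
  expect_error(global_alignment_score("CAX", "CAS"), "canonical")
})

test_that("alignment scores and distances are symmetric", {
  withr::with_seed(12, {
    for (k in seq_len(100)) {
      ab <- rand_peptides(2)
      expect_identical(global_alignment_score(ab[1], ab[2]),
                       global_alignment_score(ab[2], ab[1]))
      expect_identical(blosum_distance(ab[1], ab[2]),
                       blosum_distance(ab[2], ab[1]))
    }
  })
})

test_that("the bundled BLOSUM45 table is pinned and matches the reference", {
  m <- blosum45_matrix()
  expect_identical(rlang::hash(m), "3535920bac5323bd19403b116f634a77")
  expect_identical(m, t(m))
  expect_true(all(diag(m) > 0))
  e <- new.env()
  utils::data("BLOSUM45", package = "Biostrings", envir = e)
  ref <- e$BLOSUM45[rownames(m), colnames(m)]
  expect_equal(unname(m), unname(ref), ignore_attr = TRUE)
})

test_that("alignment distance is normalised, zero on identity, bounded", {
  expect_identical(blosum_distance("CASSL", "CASSL"), 0)
  expect_equal(blosum_distance("CASSL", "CASSV"), 1 - 26 / 30)
  withr::with_seed(13, {
    for (k in seq_len(50)) {
      # equal lengths: the cross score cannot fall below minus the larger
      # self score, so the normalised distance stays within [0, 2]
      n <- sample(4:12, 1)
      a <- paste(rand_peptides(1, len = c(n, n)), collapse = "")
      b <- paste(rand_peptides(1, len = c(n, n)), collapse = "")
      d <- blosum_distance(a, b)
      expect_gte(d, 0)
      expect_lte(d, 2)
      # mixed lengths: gap costs against a weak self score can push the
      # normalised distance above 2, but it stays finite and non-negative
      ab <- rand_peptides(2, len = c(3, 10))
      dm <- blosum_distance(ab[1], ab[2])
      expect_gte(dm, 0)
      expect_true(is.finite(dm))
    }
  })
})

test_that("Atchley embedding averages per-residue factors", {
  tab <- atchley_factors()
  expect_equal(atchley_embed("A"), tab["A", ])
  expect_equal(atchley_embed("AA"), tab["A", ])
  withr::with_seed(14, {
    for (k in seq_len(20)) {
      p <- rand_peptides(1)
      res <- strsplit(p, "")[[1]]
      brute <- colSums(do.call(rbind, lapply(res, function(r) tab[r, ]))) /
        length(res)
      expect_equal(atchley_embed(p), brute)
    }
  })
  expect_error(atchley_embed(""), "non-empty")
})

test_that("Atchley distance is a pseudometric (non-injective, triangular)", {
  expect_identical(atchley_distance("CASSL", "CASSL"), 0)
  expect_identical(atchley_distance("A", "AA"), 0)
  withr::with_seed(15, {
    for (k in seq_len(100)) {
      abc <- rand_peptides(3, len = c(2, 8))
      dab <- atchley_distance(abc[1], abc[2])
      dbc <- atchley_distance(abc[2], abc[3])
      dac <- atchley_distance(abc[1], abc[3])
      expect_lte(dac, dab + dbc + 1e-12)
    }
  })
})

test_that("chunk partitioning covers the matrix with ceiling arithmetic", {
  rep3 <- make_test_repertoire(21, S = 3)
  ch <- compute_distance_chunks(rep3, "atchley", chunk_size = 100)
  expect_length(ch$chunks, 1)
  expect_equal(dim(ch$chunks[[1]]$values),
               c(length(rep3$sequences), length(rep3$sequences)))
  expect_true(all(diag(ch$chunks[[1]]$values) == 0))

  # 250 rows at chunk_size 100 -> 100/100/50; systematic distinct peptides
  aa <- rownames(blosum45_matrix())
  combos <- expand.grid(x = aa, y = aa, stringsAsFactors = FALSE)[1:250, ]
  rep250 <- tcr_repertoire(paste0("C", combos$x, combos$y, "F"),
                           rep(1 / 250, 250), "s250")
  ch250 <- compute_distance_chunks(rep250, "atchley", chunk_size = 100)
  expect_equal(vapply(ch250$chunks, `[[`, numeric(1), "row_count"),
               c(100, 100, 50))
  expect_equal(vapply(ch250$chunks, `[[`, numeric(1), "row_start"),
               c(0, 100, 200))
  expect_error(compute_distance_chunks(rep3, "atchley", chunk_size = 0),
               "chunk_size")
})

test_that("concatenated chunks equal a double-loop oracle for both metrics", {
  rep <- make_test_repertoire(22, S = 50)
  S <- length(rep$sequences)
  for (metric in c("blosum45", "atchley")) {
    got <- distance_matrix(compute_distance_chunks(rep, metric,
                                                   chunk_size = 16))
    pair_fun <- if (metric == "blosum45") blosum_distance else atchley_distance
    want <- matrix(0, S, S)
    for (i in seq_len(S)) {
      for (j in seq_len(S)) {
        if (i != j) want[i, j] <- pair_fun(rep$sequences[i],
                                           rep$sequences[j])
      }
    }
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(all(diag(got) == 0))
    expect_lt(max(abs(got - t(got))), 1e-9)
    expect_true(all(got >= 0))
  }
})

test_that("the matrix is invariant to chunk size and worker count", {
  rep <- make_test_repertoire(23, S = 30)
  S <- length(rep$sequences)
  ref <- distance_matrix(compute_distance_chunks(rep, "blosum45",
                                                 chunk_size = S))
  for (cs in c(1, 7, 100)) {
    expect_identical(
      distance_matrix(compute_distance_chunks(rep, "blosum45",
                                              chunk_size = cs)), ref)
  }
  expect_identical(
    distance_matrix(compute_distance_chunks(rep, "blosum45", chunk_size = 7,
                                            workers = 2)), ref)
})

test_that("chunks persist to TSV with a validating manifest", {
  rep <- make_test_repertoire(24, S = 17)
  ch <- compute_distance_chunks(rep, "atchley", chunk_size = 5)
  dir <- withr::local_tempdir()
  manifest <- write_distance_chunks(ch, dir)
  back <- read_distance_chunks(manifest)
  expect_equal(distance_matrix(back), distance_matrix(ch),
               tolerance = 1e-12)
  expect_identical(back$checksum, ch$checksum)
  expect_identical(back$metric, "atchley")

  # corrupting a chunk file is caught by the shape check
  files <- list.files(dir, pattern = "_chunk_5\\.tsv$", full.names = TRUE)
  writeLines(readLines(files[1])[-1], files[1])
  expect_error(read_distance_chunks(manifest), "shape")
})

test_that("precomputed dense matrices wrap into valid chunks", {
  mock <- make_uniform_mock(12, 0.3)
  ch <- as_distance_chunks(mock$dmat, mock$repertoire, chunk_size = 5)
  expect_length(ch$chunks, 3)
  expect_identical(distance_matrix(ch), mock$dmat)
  expect_error(as_distance_chunks(mock$dmat[-1, -1], mock$repertoire),
               "dimensions")
  bad <- mock$dmat; bad[1, 2] <- -1
  expect_error(as_distance_chunks(bad, mock$repertoire), "non-negative")
})
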