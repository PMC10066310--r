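# Hill diversities, similarity scaling, grid evaluation and serialization.

p325 <- c(0.5, 0.25, 0.25)

test_that("naive Hill numbers match their closed forms and limits", {
  expect_equal(naive_diversity(rep(1 / 100, 100), 0), 100)
  expect_equal(naive_diversity(rep(1 / 100, 100), 2), 100)
  expect_equal(naive_diversity(rep(1 / 100, 100), Inf), 100)
  expect_equal(naive_diversity(p325, Inf), 2)
  expect_equal(naive_diversity(p325, 2), 1 / 0.375)
  expect_equal(naive_diversity(p325, 1), exp(-sum(p325 * log(p325))))
  expect_equal(naive_diversity(p325, 0), 3)
  expect_error(naive_diversity(c(0.5, 0.4), 1), "sum to 1")

  # the q = 1 value is the continuous limit of the general formula
  expect_equal(naive_diversity(p325, 1 - 1e-7), naive_diversity(p325, 1),
               tolerance = 1e-5)
  withr::with_seed(31, {
    for (k in 1:10) {
      p <- rand_freqs(25)
      q <- runif(1, 0, 6)
      expect_equal(naive_diversity(p, q),
                   sum(p^q)^(1 / (1 - q)))  # direct formula, no log-space
      expect_gte(naive_diversity(p, q), 1)
      expect_lte(naive_diversity(p, q), 25 + 1e-9)
    }
  })
})

test_that("kernel-weighted abundances interpolate between 1 and p", {
  mock <- make_uniform_mock(2, 1)
  ch <- as_distance_chunks(mock$dmat, mock$repertoire)$chunks[[1]]
  p <- mock$repertoire$frequencies
  expect_equal(kernel_weighted_abundance(ch, p, 0), c(1, 1))
  expect_equal(kernel_weighted_abundance(ch, p, Inf), p)
  expect_equal(kernel_weighted_abundance(ch, p, log(2)), c(0.75, 0.75))
  expect_error(kernel_weighted_abundance(ch, p, -1), "lambda")
  expect_error(kernel_weighted_abundance(ch, c(p, 0.1), 1), "width")

  withr::with_seed(32, {
    rep <- make_test_repertoire(32, S = 20)
    chs <- compute_distance_chunks(rep, "atchley", chunk_size = 6)
    for (lam in c(0.1, 1, 8)) {
      zp <- unlist(lapply(chs$chunks, kernel_weighted_abundance,
                          freqs = rep$frequencies, lambda = lam))
      expect_true(all(zp >= rep$frequencies - 1e-12))
      expect_true(all(zp <= 1 + 1e-12))
    }
  })
})

test_that("similarity-scaled diversity hits its fixtures and limits", {
  # lambda = 0: all clones effectively identical, minimal diversity 1
  expect_equal(similarity_scaled_diversity(p325, rep(1, 3), 2), 1)
  expect_equal(similarity_scaled_diversity(p325, rep(1, 3), 0), 1)
  expect_equal(similarity_scaled_diversity(p325, rep(1, 3), Inf), 1)

  # two-clone fixture: p = (1/2, 1/2), d = 1, lambda = ln 2 -> zp = 3/4
  expect_equal(similarity_scaled_diversity(c(0.5, 0.5), c(0.75, 0.75), 2),
               4 / 3)

  # identity sentinel (zp = p) recovers the naive value at every grid q
  for (q in c(0, 1, 2, 3, 4, 5, 6, Inf)) {
    expect_equal(similarity_scaled_diversity(p325, p325, q),
                 naive_diversity(p325, q))
  }
  expect_error(similarity_scaled_diversity(p325, c(0.1, 1, 1), 2),
               "within")

  # q = 1 and q = infinity as numerical limits of the general formula
  withr::with_seed(33, {
    p <- rand_freqs(30)
    dmat <- as.matrix(stats::dist(matrix(runif(60), 30)))
    zp <- as.vector(exp(-2 * dmat) %*% p)
    expect_equal(similarity_scaled_diversity(p, zp, 1 + 1e-4),
                 similarity_scaled_diversity(p, zp, 1), tolerance = 1e-3)
    expect_equal(similarity_scaled_diversity(p, zp, 1 - 1e-4),
                 similarity_scaled_diversity(p, zp, 1), tolerance = 1e-3)
    d_inf <- similarity_scaled_diversity(p, zp, Inf)
    expect_equal(similarity_scaled_diversity(p, zp, 50), d_inf,
                 tolerance = 0.1)
    # and the approach is monotone in q
    expect_lt(abs(similarity_scaled_diversity(p, zp, 200) - d_inf),
              abs(similarity_scaled_diversity(p, zp, 50) - d_inf))
  })
})

test_that("parameter grids validate ordering and sentinels", {
  g <- parameter_grid()
  expect_length(g$q, 8)
  expect_length(g$lambda, 16)
  expect_true(g$include_identity)
  expect_error(parameter_grid(q = c(2, 1)), "ascending")
  expect_error(parameter_grid(lambda = c(-1, 0)), "non-negative")
  expect_error(parameter_grid(q = numeric(0)), "non-empty")
})

test_that("a single-clone repertoire has zero log-diversity everywhere", {
  rep <- tcr_repertoire("CASSL", 1, "solo")
  ch <- as_distance_chunks(matrix(0, 1, 1), rep)
  g <- diversity_grid(rep, ch)
  expect_true(all(g$log_values == 0))
})

test_that("the chunked grid equals a dense brute-force oracle", {
  rep <- make_test_repertoire(34, S = 50)
  ch <- compute_distance_chunks(rep, "blosum45", chunk_size = 13)
  g <- diversity_grid(rep, ch)
  want <- oracle_grid(rep$frequencies, distance_matrix(ch))
  expect_lt(max(abs(unname(g$log_values) - want)), 1e-9)
})

test_that("grids satisfy the q/lambda monotonicity and sandwich bounds", {
  for (seed in 41:60) {
    rep <- make_test_repertoire(seed, S = 25)
    ch <- compute_distance_chunks(rep, "atchley", chunk_size = 9)
    lv <- diversity_grid(rep, ch)$log_values
    S <- length(rep$sequences)
    # ln D >= 0, bounded by ln S; naive column bounds every lambda column
    expect_true(all(lv >= -1e-12))
    expect_true(all(lv <= log(S) + 1e-9))
    expect_true(all(lv <= lv[, "identity"] + 1e-9))
    # non-increasing in q (rows ordered by ascending q)
    expect_true(all(apply(lv, 2, function(col) all(diff(col) <= 1e-9))))
    # non-decreasing in lambda (identity column last)
    expect_true(all(apply(lv, 1, function(row) all(diff(row) >= -1e-9))))
    # lambda = 0 column is exactly zero
    expect_true(all(lv[, "0"] == 0))
  }
})

test_that("checksum mismatches between repertoire and chunks are caught", {
  rep <- make_test_repertoire(35, S = 10)
  other <- make_test_repertoire(36, S = 10)
  ch <- compute_distance_chunks(rep, "atchley")
  expect_error(diversity_grid(other, ch), "checksum")
})

test_that("small-lambda behaviour follows the perturbation expansion", {
  # ln D(q, lambda) ~ lambda * dbar, independent of q, for lambda dbar small
  for (d0 in c(0.1, 0.2)) {
    mock <- make_uniform_mock(100, d0)
    dbar <- oracle_dbar(mock$repertoire$frequencies, mock$dmat)
    expect_equal(dbar, d0 * (1 - 1 / 100))
    ch <- as_distance_chunks(mock$dmat, mock$repertoire)
    g <- diversity_grid(mock$repertoire, ch)
    for (lam in c(0.1, 0.2, 0.3, 0.4, 0.5)) {
      if (lam * dbar > 0.1) next
      col <- g$log_values[, as.character(lam)]
      expect_lt(max(abs(col - lam * dbar)) / (lam * dbar), 0.05)
      expect_lt(max(col) - min(col), 1e-6)  # q-independence for uniform mocks
    }
  }
  # heterogeneous frequencies and distances: the first-order term is
  # lambda * dbar; the curvature is set by the weighted second moment of the
  # distances, so lambda is placed where that second-order term is small
  rep <- make_test_repertoire(37, S = 30)
  ch <- compute_distance_chunks(rep, "blosum45")
  dmat <- distance_matrix(ch)
  dbar <- oracle_dbar(rep$frequencies, dmat)
  m2 <- as.numeric(t(rep$frequencies) %*% dmat^2 %*% rep$frequencies)
  lam <- 0.03 * dbar / m2
  g <- diversity_grid(rep, ch, parameter_grid(lambda = c(0, lam)))
  # finite q only: the q = inf (Berger-Parker) limit expands to
  # lambda * min_i (Dp)_i, not lambda * dbar, unless distances are constant
  col <- g$log_values[rownames(g$log_values) != "inf", as.character(lam)]
  expect_lt(max(abs(col - lam * dbar)) / (lam * dbar), 0.05)
})

test_that("the naive profile slope at q = 1 is -Var_p(ln p) / 2", {
  withr::with_seed(38, {
    for (k in 1:20) {
      p <- rand_freqs(40)
      lnp <- log(p)
      analytic <- -(sum(p * lnp^2) - sum(p * lnp)^2) / 2
      h <- 1e-4
      numeric_slope <- (log(naive_diversity(p, 1 + h)) -
                          log(naive_diversity(p, 1 - h))) / (2 * h)
      expect_equal(numeric_slope, analytic, tolerance = 1e-4)
    }
  })
  # slope magnitude grows with the ln-frequency variance of the distribution
  slopes <- vapply(c(0.25, 0.5, 1, 1.5), function(a) {
    p <- powerlaw_frequencies(200, a)
    h <- 1e-4
    abs(log(naive_diversity(p, 1 + h)) -
          log(naive_diversity(p, 1 - h))) / (2 * h)
  }, numeric(1))
  expect_true(all(diff(slopes) > 0))
})

test_that("diversity tables round-trip with sentinel tokens", {
  rep <- make_test_repertoire(39, S = 15)
  ch <- compute_distance_chunks(rep, "atchley")
  g <- diversity_grid(rep, ch)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_diversity_table(g, path)
  raw <- readLines(path)
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  expect_equal(nrow(df), 8 * 17)
  # sentinels serialized as literal tokens
  expect_true(any(grepl("\tidentity\t", raw)))
  expect_true(any(grepl("\tinf\t", raw)))
  expect_equal(df$D, exp(df$ln_D), tolerance = 1e-12)

  back <- read_diversity_table(path)
  expect_equal(back$log_values, g$log_values, tolerance = 1e-12)
  expect_identical(back$sample_id, g$sample_id)

  df$lambda[3] <- "mystery"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_diversity_table(path), "unknown lambda")
})
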