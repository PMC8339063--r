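test_that("trimming clips the stated flanks and filters bad sequences", {
  expect_equal(as.vector(trim_cdr3("CASSLAPGATNEKLFF")), "SLAPGATNEKL")
  expect_equal(as.vector(trim_cdr3("CASSLAPGATNEKLFF", 0L, 0L)),
               "CASSLAPGATNEKLFF")
  short <- trim_cdr3("CASSF")  # trimmed length 0
  expect_true(is.na(short[1]))
  expect_equal(attr(short, "exclusions")[["too_short"]], 1L)
  bad <- trim_cdr3(c("CASS*EQYFF", "CASSLAPGATNEKLFF", "CASSxLAPGATNEKLFF"))
  expect_equal(attr(bad, "exclusions")[["nonstandard"]], 2L)
  expect_equal(sum(is.na(bad)), 2L)
  expect_error(trim_cdr3("CASSLAPGATNEKLFF", clip_n = -1L), ">= 0")
})

test_that("a single residue encodes to Omega times its lifted vector", {
  x <- encode_cdr3("A", emb16, g6)
  expected <- g6$matrix %*% lift_vector(emb16$vectors["A", ], 6L)
  expect_equal(x, drop(expected))
})

test_that("encoding matches the explicit operator-product definition", {
  set.seed(21)
  for (L in c(5L, 8L, 13L)) {
    s <- random_trimmed(L)
    x <- encode_cdr3(s, emb16, g6)
    xm <- numeric(96)
    P <- diag(96)
    for (l in seq_len(L)) {
      P <- P %*% g6$matrix
      res <- substr(s, L - l + 1L, L - l + 1L)
      xm <- xm + drop(P %*% lift_vector(emb16$vectors[res, ], 6L))
    }
    expect_equal(x, xm)
    expect_equal(unname(encode_matrix(s, emb16, g6)[1, ]), x)
  }
})

test_that("identical sequences encode identically; residues must be standard", {
  s <- "SLAPGATNEKL"
  expect_equal(encode_cdr3(s, emb16, g6), encode_cdr3(s, emb16, g6))
  expect_equal(sum((encode_stacked(s, emb16) - encode_stacked(s, emb16))^2), 0)
  expect_error(encode_cdr3("SLAPX", emb16, g6), "absent from embedding")
})

test_that("one-mismatch squared distance equals the residue-pair distance", {
  set.seed(31)
  for (rep in 1:50) {
    L <- sample(5:14, 1)
    s1 <- strsplit(random_trimmed(L), "")[[1]]
    s2 <- s1
    p <- sample.int(L, 1)
    s2[p] <- sample(setdiff(AA_ALPHABET20, s1[p]), 1)
    x1 <- encode_cdr3(paste(s1, collapse = ""), emb16, g6)
    x2 <- encode_cdr3(paste(s2, collapse = ""), emb16, g6)
    ref <- sum((emb16$vectors[s1[p], ] - emb16$vectors[s2[p], ])^2)
    expect_equal(sum((x1 - x2)^2), ref, tolerance = 1e-12)
  }
})

test_that("mismatch isometry is exact off the period and deviates on it", {
  set.seed(41)
  n_exact <- 0L
  for (rep in 1:1000) {
    L <- sample(7:12, 1)
    s1 <- strsplit(random_trimmed(L), "")[[1]]
    s2 <- s1
    nm <- sample(1:2, 1)
    repeat {
      pos <- sort(sample.int(L, nm))
      if (nm == 1L || (pos[2] - pos[1]) %% 6L != 0L) break
    }
    for (p in pos) s2[p] <- sample(setdiff(AA_ALPHABET20, s1[p]), 1)
    x1 <- encode_cdr3(paste(s1, collapse = ""), emb16, g6)
    x2 <- encode_cdr3(paste(s2, collapse = ""), emb16, g6)
    ref <- sum(vapply(pos, function(p) {
      sum((emb16$vectors[s1[p], ] - emb16$vectors[s2[p], ])^2)
    }, numeric(1)))
    expect_lt(abs(sum((x1 - x2)^2) - ref), 1e-9)
    # stacked encoding agrees under the same condition
    y1 <- encode_stacked(paste(s1, collapse = ""), emb16)
    y2 <- encode_stacked(paste(s2, collapse = ""), emb16)
    expect_lt(abs(sum((y1 - y2)^2) - sum((x1 - x2)^2)), 1e-9)
    n_exact <- n_exact + 1L
  }
  expect_equal(n_exact, 1000L)

  # a violating pair (separation exactly 6) picks up a cross term
  s1 <- strsplit("SLAPGATNEKL", "")[[1]]
  s2 <- s1
  s2[2] <- "W"; s2[8] <- "C"
  x1 <- encode_cdr3(paste(s1, collapse = ""), emb16, g6)
  x2 <- encode_cdr3(paste(s2, collapse = ""), emb16, g6)
  ref <- sum((emb16$vectors["L", ] - emb16$vectors["W", ])^2) +
    sum((emb16$vectors["N", ] - emb16$vectors["C", ])^2)
  expect_gt(abs(sum((x1 - x2)^2) - ref), 1e-6)
})

test_that("stacked encoding stacks in sequence order with dimension k*r", {
  s <- "SLAPGA"
  y <- encode_stacked(s, emb16)
  expect_length(y, 6L * 16L)
  expect_equal(y[1:16], unname(emb16$vectors["S", ]))
  expect_equal(y[81:96], unname(emb16$vectors["A", ]))
})

test_that("non-identity-condition probabilities match exhaustive enumeration", {
  expect_equal(nic_violation_probability(16), 5 / 55)
  expect_equal(nic_violation_probability(14), 3 / 36)
  # L <= period: no pair can be period apart
  expect_equal(nic_violation_probability(11), 0)   # L = 6
  expect_equal(nic_violation_probability(10), 0)   # L = 5
  expect_error(nic_violation_probability(6), "length < 2")
  # independent oracle: brute count over explicit position pairs
  for (fl in 12:17) {
    L <- fl - 5L
    cnt <- 0L
    for (i in seq_len(L - 1L)) for (j in seq(i + 1L, L)) {
      if (j - i == 6L) cnt <- cnt + 1L
    }
    expect_equal(nic_violation_probability(fl), cnt / choose(L, 2))
  }
})
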