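test_that("carry-over reproduces the case analysis and signals degeneracy", {
  x <- seq_dna("GAAAA"); y <- seq_dna("TAAAC")
  st <- initial_state(x, y, 1)
  expect_equal(st$L, 4L); expect_equal(st$ties, 1L)
  co <- carry_over(st, x, y, 1)       # x_1='G' != y_1='T': Case 2
  expect_true(co$ok)
  expect_equal(co$L_max, 4L)          # 4 + lcp0 at offset 5 = 4 + 0
  expect_equal(co$ties, 2L)

  # Case 1: matching first characters lose one unit exactly
  x2 <- seq_dna("AACGTT"); y2 <- seq_dna("GGAACGTA")
  st2 <- initial_state(x2, y2, 0)     # L=5 at j=3, x_1='A' == y_3='A'
  expect_equal(st2$L, 5L)
  co2 <- carry_over(st2, x2, y2, 0)
  expect_equal(co2$L_max, 4L)
  expect_equal(co2$ties, 4L)

  # all ties at j == m: no image survives
  x3 <- seq_dna("CCAA"); y3 <- seq_dna("TTTC")
  st3 <- initial_state(x3, y3, 0)
  expect_equal(st3$ties, 4L)
  expect_false(carry_over(st3, x3, y3, 0)$ok)
})

test_that("candidate mask applies both per-symbol filters", {
  y <- seq_dna("ACGTACGT", "y")
  idx <- build_symbol_index(y)
  # x_i = 'A', anchor x_{i+L} = 'T', L = 2: r must not precede... r not 'A',
  # and y_{r+2} == 'T' -> r in {2, 6}
  x <- seq_dna("AGTT")                 # x_1='A', x_3='T', i=1, L=2
  expect_equal(candidate_mask(x, 1, 2, idx), c(2L, 6L))

  # anchor symbol absent from y: empty candidate set
  yy <- seq_dna("ACGAACGA", "yy")
  expect_equal(candidate_mask(x, 1, 2, build_symbol_index(yy)),
               integer(0))

  # subject made entirely of x_i: filter (a) removes everything
  yA <- seq_dna("AAAAAA", "ya")
  xa <- seq_dna("AAT")
  expect_equal(candidate_mask(xa, 1, 1, build_symbol_index(yA)),
               integer(0))

  # no anchor (i + L past the end of x): filter (a) only
  xs <- seq_dna("CA")
  expect_equal(candidate_mask(xs, 1, 5, idx), c(1L, 3L, 4L, 5L, 7L, 8L))
})

test_that("verification accepts exactly the oracle-confirmed candidates", {
  # c < L_max short-circuits without an extension
  x <- seq_dna("ACGTAAAA"); y <- seq_dna("ACGTTTTT")
  v <- verify_candidate(x, y, 1, i = 1, r = 5, L = 2, L_max = 10)
  expect_equal(v$verdict, "reject")
  expect_equal(v$pairs_examined, 0)
  expect_true(is.na(v$L_true))

  # randomized: accepted positions must be exactly those whose true
  # extension closes the optimistic gap
  set.seed(31)
  hidden_mismatch_seen <- FALSE
  for (rep in 1:150) {
    x <- rand_mm_seq(30); y <- rand_mm_seq(30)
    k <- sample(0:3, 1); i <- sample(1:(x$n - 1L), 1)
    st <- full_sweep(x, i, y, k)
    L <- st$best
    if (i + L > x$n) next
    L_max <- max(L - 1L, 0L)
    for (r in setdiff(seq_len(y$n - 1L), st$ties)) {
      v <- verify_candidate(x, y, k, i, r, L, L_max)
      truth <- oracle_lcpk(x$codes, i + 1L, y$codes, r + 1L, k)
      if (v$verdict %in% c("new_best", "tie")) {
        expect_equal(v$L_true, truth)      # accepted => genuine value
        expect_gte(truth, L_max)
      } else if (!is.na(v$L_true) && v$c > v$L_true) {
        hidden_mismatch_seen <- TRUE       # optimistic length not attained
        expect_lt(truth, v$c)
      }
    }
  }
  expect_true(hidden_mismatch_seen)
})

test_that("single exact steps match the oracle sweep", {
  x <- seq_dna("ACGT"); y <- seq_dna("TACG")
  st <- initial_state(x, y, 0)
  expect_equal(st$L, 3L); expect_equal(st$ties, 2L)
  st2 <- step_exact(st, x, y, 0)
  expect_equal(st2$i, 2L)
  expect_equal(st2$L, 2L)
  expect_equal(st2$ties, 3L)

  set.seed(32)
  for (rep in 1:120) {
    x <- rand_mm_seq(30, nsym = sample(c(2L, 4L), 1))
    y <- rand_mm_seq(30, nsym = length(x$alphabet$symbols))
    k <- sample(0:3, 1)
    st <- initial_state(x, y, k)
    for (i in 1:(x$n - 1L)) {
      st <- step_exact(st, x, y, k)
      o <- oracle_sweep(x$codes, i + 1L, y$codes, k)
      expect_equal(st$L, o$best)
      expect_equal(st$ties, o$ties)     # complete ascending tie list
    }
  }
})

test_that("exact mode equals the naive computation on random instances", {
  set.seed(33)
  for (rep in 1:200) {
    n <- sample(20:200, 1); m <- sample(20:200, 1)
    nsym <- sample(c(2L, 4L), 1)
    x <- rand_mm_seq(n, nsym, p_sentinel = sample(c(0, 0.03), 1))
    y <- rand_mm_seq(m, nsym, p_sentinel = sample(c(0, 0.03), 1))
    for (k in c(0L, 1L, 2L, 5L)) {
      ex <- maxcor_vector(x, y, k, "exact")
      nv <- naive_maxcor(x, y, k)
      expect_identical(ex$values, nv$values)
      expect_true(all(ex$values <= pmin(n - seq_len(n) + 1L, m)))
    }
  }
})

test_that("the optional whole-segment pre-filter never changes results", {
  set.seed(34)
  for (rep in 1:60) {
    x <- rand_mm_seq(150); y <- rand_mm_seq(150)
    k <- sample(0:5, 1)
    plain <- maxcor_vector(x, y, k, "exact")
    seg <- maxcor_vector(x, y, k, "exact", segment_filter = TRUE)
    expect_identical(plain$values, seg$values)
    rplain <- maxcor_vector(x, y, k, "relaxed")
    rseg <- maxcor_vector(x, y, k, "relaxed", segment_filter = TRUE)
    expect_identical(rplain$values, rseg$values)
  }
})

test_that("relaxed mode is dominated by exact and can genuinely diverge", {
  set.seed(35)
  diverged <- FALSE
  for (rep in 1:300) {
    x <- rand_mm_seq(60, nsym = 2L); y <- rand_mm_seq(60, nsym = 2L)
    k <- sample(1:4, 1)
    ex <- maxcor_vector(x, y, k, "exact")
    rl <- maxcor_vector(x, y, k, "relaxed")
    expect_true(all(rl$values <= ex$values))
    expect_lte(rl$stats$pairs_examined, ex$stats$pairs_examined)
    if (any(rl$values < ex$values)) {
      diverged <- TRUE
      # the oracle confirms exact, not relaxed, at the divergent suffix
      i <- which(rl$values < ex$values)[1L]
      expect_equal(ex$values[i], oracle_sweep(x$codes, i, y$codes, k)$best)
    }
  }
  expect_true(diverged)
})

test_that("filter exclusions never hide a strictly longer match", {
  set.seed(36)
  for (rep in 1:60) {
    x <- rand_mm_seq(40); y <- rand_mm_seq(40)
    k <- sample(0:3, 1)
    idx <- build_symbol_index(y)
    st <- initial_state(x, y, k)
    for (i in 1:(x$n - 1L)) {
      L <- st$L
      co <- carry_over(st, x, y, k)
      L_init <- if (co$ok) co$L_max else -1L
      cand <- if (i <= x$n - 1L) candidate_mask(x, i, L, idx) else integer(0)
      excluded <- setdiff(seq_len(y$n - 1L), cand)
      for (r in excluded) {
        truth <- oracle_lcpk(x$codes, i + 1L, y$codes, r + 1L, k)
        expect_lte(truth, max(L_init, L - 1L))
      }
      st <- step_exact(st, x, y, k)
    }
  }
})

test_that("per-suffix values are monotone in the mismatch budget", {
  set.seed(37)
  for (rep in 1:30) {
    x <- rand_mm_seq(100); y <- rand_mm_seq(100)
    prev <- rep(0L, 100)
    for (k in c(0L, 1L, 2L, 5L, 10L, 50L)) {
      v <- maxcor_vector(x, y, k, "exact")$values
      expect_true(all(v >= prev))
      prev <- v
    }
  }
})

test_that("degenerate and limit inputs behave as the definitions demand", {
  x <- rand_mm_seq(40)
  # self comparison at k=0: descending staircase
  expect_identical(maxcor_vector(x, x, 0)$values, 40:1)
  # unlimited budget: every suffix matches wherever it fits
  y <- rand_mm_seq(25)
  expect_identical(maxcor_vector(x, y, 100)$values,
                   pmin(40:1, 25L))
  expect_error(maxcor_vector(x, y, -1), "non-negative")
  one <- rand_mm_seq(1)
  expect_identical(maxcor_vector(one, one, 0)$values, 1L)
  # stats accounting
  mv <- maxcor_vector(x, y, 2)
  expect_equal(mv$stats$pairs_total, 40 * 25)
  expect_gte(mv$stats$percentage, 0)
  expect_lte(mv$stats$percentage, 100)
})
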