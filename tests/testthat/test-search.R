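test_that("random segmentations cover the arm with geometric lengths", {
  set.seed(1)
  expect_equal(random_segmentation(1), 1L)
  for (i in 1:50) {
    n <- sample(1:40, 1)
    lens <- random_segmentation(n, mean_len = 2)
    expect_true(all(lens >= 1L))
    expect_equal(sum(lens), n)
  }
  # law of large numbers on the untruncated draw
  set.seed(2)
  draws <- rgeom(100000, prob = 1 / 2) + 1
  expect_lt(abs(mean(draws) - 2) / 2, 0.01)
  # empirical mean of non-final lengths matches mean_len
  set.seed(3)
  lens <- random_segmentation(200000, mean_len = 3)
  expect_lt(abs(mean(head(lens, -1)) - 3) / 3, 0.02)
})

test_that("move enumeration matches hand counts and yields valid segmentations", {
  expect_equal(nrow(enumerate_moves(1L)), 0)
  mv <- enumerate_moves(c(2L, 2L))
  expect_equal(sum(mv$kind == "split"), 2)   # positions 1 and 3
  expect_equal(sum(mv$kind == "merge"), 1)
  expect_equal(sum(mv$kind == "shift"), 2)   # boundary 2 -> 1 or 3
  expect_equal(sort(mv$pos[mv$kind == "shift"]), c(1, 3))
  # every move yields a valid segmentation; apply-then-invert restores
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    lens <- random_segmentation(n)
    moves <- enumerate_moves(lens)
    for (j in seq_len(nrow(moves))) {
      mvj <- moves[j, ]
      after <- apply_move(lens, mvj)
      expect_true(all(after >= 1L))
      expect_equal(sum(after), n)
      back <- apply_move(after, invert_move(lens, mvj))
      expect_identical(back, as.integer(lens))
    }
  }
})

test_that("incremental move deltas equal full rescoring", {
  set.seed(21)
  sim <- simulate_dataset(15, 3, seed = 21)
  f <- sim$f; g <- sim$g
  lens <- random_segmentation(15)
  full <- function(l) {
    -2 * segmentation_loglik(sim$matrix, l, f, g) + (length(l) + 1) * log(45)
  }
  moves <- enumerate_moves(lens)
  for (j in seq_len(nrow(moves))) {
    mvj <- moves[j, ]
    delta <- move_delta_score(sim$matrix, lens, mvj, f, g)
    expect_equal(delta, full(apply_move(lens, mvj)) - full(lens),
                 tolerance = 1e-9)
  }
})

test_that("greedy descent leaves a local optimum unchanged", {
  sim <- simulate_dataset(30, 4, seed = 33)
  r1 <- greedy_descent(sim$matrix, random_segmentation(30), sim$f, sim$g)
  r2 <- greedy_descent(sim$matrix, r1$final$lengths, sim$f, sim$g)
  expect_equal(r2$n_iterations, 0)
  expect_identical(r2$final$lengths, r1$final$lengths)
  # and no enumerated move improves the final score
  moves <- enumerate_moves(r1$final$lengths)
  deltas <- vapply(seq_len(nrow(moves)), function(j) {
    move_delta_score(sim$matrix, r1$final$lengths, moves[j, ], sim$f, sim$g)
  }, numeric(1))
  expect_true(all(deltas >= -1e-9))
})

test_that("greedy score trace is strictly decreasing and matches full rescore", {
  sim <- simulate_dataset(40, 4, seed = 44)
  set.seed(4)
  r <- greedy_descent(sim$matrix, random_segmentation(40), sim$f, sim$g)
  expect_true(all(diff(r$trace) < 0))
  full_final <- -2 * segmentation_loglik(sim$matrix, r$final$lengths,
                                         sim$f, sim$g) +
    r$final$K * log(r$final$n_data)
  expect_equal(tail(r$trace, 1), full_final, tolerance = 1e-9)
  # every applied move's delta matches the trace steps
  expect_equal(diff(r$trace), r$moves$delta, tolerance = 1e-12)
})

test_that("greedy engine applies the same first move as the R move enumeration", {
  set.seed(55)
  for (i in 1:10) {
    sim <- simulate_dataset(12, 3, seed = 500 + i)
    lens <- random_segmentation(12)
    r <- greedy_descent(sim$matrix, lens, sim$f, sim$g, max_iter = 1)
    moves <- enumerate_moves(lens)
    if (nrow(moves) == 0) next
    deltas <- vapply(seq_len(nrow(moves)), function(j) {
      move_delta_score(sim$matrix, lens, moves[j, ], sim$f, sim$g)
    }, numeric(1))
    if (min(deltas) >= -1e-9) {
      expect_equal(r$n_iterations, 0)
    } else {
      best <- which.min(deltas)
      expect_identical(apply_move(lens, moves[best, ]),
                       as.integer(apply_move(lens, r$moves[1, ])))
    }
  }
})

test_that("zero-noise simulations are recovered exactly from any start", {
  sim <- simulate_dataset(30, 3, g = deviation_params(0), seed = 66)
  g_score <- deviation_params(0.05)
  set.seed(6)
  for (i in 1:5) {
    r <- greedy_descent(sim$matrix, random_segmentation(30), sim$f, g_score)
    expect_identical(segment_boundaries(r$final$lengths),
                     segment_boundaries(sim$truth))
  }
})

test_that("replicate runs are deterministic given the master seed", {
  sim <- simulate_dataset(25, 3, seed = 77)
  a <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 8,
                      master_seed = 123)
  b <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 8,
                      master_seed = 123)
  expect_identical(a$scores, b$scores)
  expect_identical(a$best$lengths, b$best$lengths)
  # single replicate: aggregate is that replicate's score
  one <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 1,
                        master_seed = 9)
  expect_equal(one$score, one$scores[1])
  # aggregators
  m <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 5,
                      master_seed = 5, aggregator = "median")
  expect_equal(m$score, median(m$scores))
  bst <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 5,
                        master_seed = 5, aggregator = "best")
  expect_equal(bst$score, min(bst$scores))
  mn <- run_replicates(sim$matrix, sim$f, sim$g, n_replicates = 5,
                       master_seed = 5, aggregator = "mean")
  expect_equal(mn$score, mean(mn$scores))
})

test_that("DP optimum equals brute-force enumeration and bounds greedy", {
  set.seed(10)
  for (i in 1:5) {
    sim <- simulate_dataset(10, 2, seed = 900 + i)
    dp <- dp_optimal_segmentation(sim$matrix, sim$f, sim$g)
    bf <- brute_force_optimum(sim$matrix, sim$f, sim$g)
    expect_equal(dp$score, bf$score, tolerance = 1e-8)
    expect_identical(dp$lengths, bf$lengths)
    r <- greedy_descent(sim$matrix, random_segmentation(10), sim$f, sim$g)
    expect_gte(r$final$score, dp$score - 1e-9)
  }
  # one-gene arm has exactly one segmentation
  one <- matrix(5.0, 1, 2)
  dp1 <- dp_optimal_segmentation(one, atlas_mixture(), deviation_params(0.6))
  expect_identical(dp1$lengths, 1L)
})

test_that("replicate agreement metrics match set arithmetic", {
  # build a scored segmentation whose BIC score is exactly `score`
  mk <- function(lengths, score) {
    K <- length(lengths) + 1
    bic_score((K * log(100) - score) / 2, lengths, n_data = 100)
  }
  # identical replicates agree fully
  same <- lapply(c(3, 5, 4), function(s) mk(c(2L, 3L, 5L), 10 + s))
  ag <- replicate_agreement(same)
  expect_equal(ag$shared_best_second, 1)
  expect_equal(ag$shared_best_worst, 1)
  expect_equal(ag$segments_majority_fraction, 1)
  # disjoint boundary sets share nothing
  disj <- list(mk(c(2L, 8L), 1), mk(c(5L, 5L), 2))
  ag2 <- replicate_agreement(disj)
  expect_equal(ag2$shared_best_second, 0)
  # hand-counted 5-replicate fixture
  reps <- list(
    mk(c(2L, 2L, 6L), 1),   # boundaries {2, 4} (best)
    mk(c(2L, 4L, 4L), 2),   # boundaries {2, 6}
    mk(c(2L, 2L, 6L), 3),   # boundaries {2, 4}
    mk(c(4L, 2L, 4L), 4),   # boundaries {4, 6}
    mk(c(1L, 9L), 5)        # boundaries {1}   (worst)
  )
  ag3 <- replicate_agreement(reps)
  expect_equal(ag3$shared_best_second, 0.5)   # {2,4} vs {2,6}
  expect_equal(ag3$shared_best_worst, 0)      # {2,4} vs {1}
  # distinct segments: 1-2 x3 (majority), 3-4 x2, 5-10 x2, 3-6, 7-10 x2,
  # 1-4, 5-6, 1-1, 2-10 -> 1 of 9 in more than half of the replicates
  expect_equal(ag3$segments_majority_fraction, 1 / 9)
})

test_that("sigma training is deterministic and finds the data scale", {
  sim <- simulate_dataset(80, 6, seed = 88)
  t1 <- train_sigma(sim$expr, sim$f, sigma_init = 1, n_replicates = 8,
                    master_seed = 42)
  t2 <- train_sigma(sim$expr, sim$f, sigma_init = 1, n_replicates = 8,
                    master_seed = 42)
  expect_identical(t1$sigma, t2$sigma)
  expect_identical(t1$objective, t2$objective)
  expect_lt(abs(t1$sigma - 0.6) / 0.6, 0.25)
  expect_true(t1$converged)
  # objective evaluated twice at the same sigma gives the same value
  ev <- t1$evaluations
  dup <- ev[duplicated(ev$sigma) | duplicated(ev$sigma, fromLast = TRUE), ]
  if (nrow(dup) > 1) {
    expect_true(all(tapply(dup$score, dup$sigma, function(v) {
      diff(range(v)) == 0
    })))
  }
})
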