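# Plug-in entropy / MI / interaction information, the Kendall
# transformation, discretization and categorical splitting.

test_that("entropy matches closed forms and the plug-in formula", {
  expect_identical(entropy(rep("a", 10)), 0)
  expect_equal(entropy(rep(c(0L, 1L), each = 5)), log(2), tolerance = 1e-12)

  # counts (1, 2, 3) over n = 6, evaluated by hand-summed frequencies
  x <- rep(c("a", "b", "c"), times = c(1, 2, 3))
  expect_equal(entropy(x),
               -(1 / 6) * log(1 / 6) - (2 / 6) * log(2 / 6) - (3 / 6) * log(3 / 6),
               tolerance = 1e-12)

  expect_error(entropy(integer(0)), "empty")
  expect_error(entropy(c(1, NA)), "missing")
})

test_that("mutual information matches closed forms on exact joint tables", {
  # product-form joint [[1,1],[1,1]]
  expect_identical(mutual_info(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)

  # I(X;X) = H(X) for uniform binary
  x <- c(0, 1, 0, 1)
  expect_equal(mutual_info(x, x), log(2), tolerance = 1e-12)

  # joint counts [[3,1],[1,3]]: hand-computed plug-in sum over 4 cells
  xv <- c(rep(0, 4), rep(1, 4))
  yv <- c(rep(0, 3), 1, 0, rep(1, 3))
  p <- c(3, 1, 1, 3) / 8
  expect_equal(mutual_info(xv, yv), sum(p * log(p / 0.25)), tolerance = 1e-12)

  expect_error(mutual_info(1:3, 1:4), "length")
})

test_that("mutual information is symmetric, non-negative, and ties to entropy", {
  set.seed(11)
  for (rep in 1:10) {
    x <- sample(letters[1:3], 40, replace = TRUE)
    y <- sample(1:4, 40, replace = TRUE)
    expect_equal(mutual_info(x, y), mutual_info(y, x), tolerance = 1e-12)
    expect_gte(mutual_info(x, y), 0)
    expect_equal(mutual_info(x, x), entropy(x), tolerance = 1e-12)
  }
})

test_that("interaction information separates synergy from redundancy", {
  # XOR: I(a;b) = 0, I(a;b|c) = log 2, ii = -log 2
  g <- expand.grid(a = 0:1, b = 0:1)
  a <- g$a; b <- g$b; c <- (a + b) %% 2
  ti <- interaction_info(a, b, c)
  expect_equal(ti$i_ab, 0, tolerance = 1e-12)
  expect_equal(ti$i_ab_given_c, log(2), tolerance = 1e-12)
  expect_equal(ti$ii, -log(2), tolerance = 1e-12)

  # deterministic copy chain: ii = log 2
  a <- c(0, 1, 0, 1)
  ti <- interaction_info(a, a, a)
  expect_equal(ti$i_ab, log(2), tolerance = 1e-12)
  expect_equal(ti$i_ab_given_c, 0, tolerance = 1e-12)
  expect_equal(ti$ii, log(2), tolerance = 1e-12)

  expect_error(interaction_info(1:3, 1:3, 1:4), "length")
})

test_that("interaction information on a noisy chain matches the exact distribution", {
  # a -> b -> c symmetric 0.1 flips; n = 1000 makes every cell integral,
  # so the plug-in estimate equals the population value computed from the
  # enumerated 8-cell distribution.
  fx <- noisy_chain3(0.1, 1000)
  s <- fx$sample
  p2 <- apply(fx$p3, c(1, 2), sum)
  expected <- p_mi(p2) - p_cmi(fx$p3)
  ti <- interaction_info(s$a, s$b, s$c)
  expect_equal(ti$ii, expected, tolerance = 1e-12)
  expect_gt(ti$ii, 0) # chains are redundant, not synergetic
})

test_that("interaction information is invariant under argument permutation", {
  set.seed(5)
  a <- sample(0:2, 60, replace = TRUE)
  b <- sample(0:1, 60, replace = TRUE)
  c <- (a + b + sample(0:1, 60, replace = TRUE)) %% 3
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  vals <- vapply(perms, function(p) {
    f <- list(a, b, c)[p]
    interaction_info(f[[1]], f[[2]], f[[3]])$ii
  }, numeric(1))
  expect_true(all(abs(vals - vals[1]) < 1e-12))
})

test_that("Kendall transformation enumerates ordered pairs lexicographically", {
  # x = (1,2,3): pairs (1,2),(1,3),(2,1),(2,3),(3,1),(3,2)
  k <- kendall_transform(c(1, 2, 3))
  expect_identical(as.character(k),
                   c("UP", "UP", "DOWN", "UP", "DOWN", "DOWN"))
  expect_length(k, 6L)

  expect_true(all(kendall_transform(rep(2.5, 4)) == "TIE"))

  # tied vector (1,1,2): pairs enumerate to 2 UP, 2 DOWN, 2 TIE
  k2 <- table(kendall_transform(c(1, 1, 2)))
  expect_identical(as.integer(k2[c("UP", "DOWN", "TIE")]), c(2L, 2L, 2L))

  expect_error(kendall_transform(factor(c("a", "b", "c"))), "split_categorical")
  expect_error(kendall_transform(1), "two observations")
})

test_that("Kendall transforms of one table stay aligned", {
  x <- c(3, 1, 2, 2)
  y <- c(10, 40, 20, 30)
  kx <- kendall_transform(x)
  ky <- kendall_transform(y)
  # token t of each transform refers to the same ordered (i, j) pair:
  # reconstruct pair indices and check a few positions explicitly
  n <- 4L
  i <- rep(1:n, each = n); j <- rep(1:n, n)
  keep <- i != j
  expect_identical(as.character(kx),
                   c("DOWN", "TIE", "UP")[sign(x[j[keep]] - x[i[keep]]) + 2])
  expect_identical(as.character(ky),
                   c("DOWN", "TIE", "UP")[sign(y[j[keep]] - y[i[keep]]) + 2])
})

test_that("estimate_mi dispatches and the KT estimator sees monotone structure", {
  x <- c(1, 2, 3, 4)
  # perfect monotone agreement: MI equals the token entropy
  expect_equal(estimate_mi(x, x, method = "kt"),
               entropy(kendall_transform(x)), tolerance = 1e-12)
  # anti-monotone is equally informative
  expect_equal(estimate_mi(x, rev(x), method = "kt"),
               estimate_mi(x, x, method = "kt"), tolerance = 1e-12)
  # mle on categorical inputs is plain plug-in MI
  f <- factor(c("a", "b", "a", "b"))
  g <- factor(c("u", "u", "v", "v"))
  expect_identical(estimate_mi(f, g, method = "mle"), mutual_info(f, g))
  expect_error(estimate_mi(x, x, method = "nope"))
})

test_that("KT-based MI is invariant under strictly monotone transforms", {
  set.seed(21)
  x <- rnorm(30)
  y <- x + rnorm(30)
  base <- estimate_mi(x, y, method = "kt")
  expect_identical(estimate_mi(exp(x), y, method = "kt"), base)
  expect_identical(estimate_mi(x, 3 * y - 100, method = "kt"), base)
  expect_identical(estimate_mi(atan(x), exp(y), method = "kt"), base)
})

test_that("plug-in MI of independent features decreases with sample size", {
  avg_mi <- function(n) {
    mean(vapply(1:5, function(s) {
      set.seed(1000 + s)
      mutual_info(rbinom(n, 1, 0.5), rbinom(n, 1, 0.5))
    }, numeric(1)))
  }
  m100 <- avg_mi(100); m1k <- avg_mi(1000); m10k <- avg_mi(10000)
  expect_gt(m100, m1k)
  expect_gt(m1k, m10k)
  expect_lt(m10k, 1e-3)
})

test_that("discretize bins by equal frequency with deterministic ties", {
  d <- discretize(1:10, bins = 2)
  expect_identical(as.integer(d), rep(1:2, each = 5))
  expect_identical(nlevels(discretize(rep(7, 20), bins = 5)), 1L)
  # never more categories than distinct values
  x3 <- rep(c(1.5, 2.5, 9), 10)
  expect_identical(nlevels(discretize(x3, bins = 10)), 3L)
  expect_error(discretize(1:10, bins = 1), "at least 2")
  # deterministic: same input, same binning
  set.seed(3); x <- rnorm(100)
  expect_identical(discretize(x, 10), discretize(x, 10))
})

test_that("split_categorical one-hot encodes and is invertible", {
  x <- factor(sample(c("red", "green", "blue"), 50, replace = TRUE))
  parts <- split_categorical(x, name = "col")
  expect_named(parts, paste0("col=", levels(x)))
  onehot <- vapply(parts, function(p) as.integer(as.character(p)), integer(50))
  expect_true(all(rowSums(onehot) == 1))
  # indicators determine the original up to labels
  rec <- levels(x)[apply(onehot, 1, which.max)]
  expect_identical(rec, as.character(x))
  expect_error(split_categorical(factor(c("a", "b"))), "at most two")
})
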