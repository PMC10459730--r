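test_that("Mann-Whitney U: statistic, exact p, and oracle agreement for n <= 8", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 2 / 6)
  expect_equal(r$method, "exact")

  # identical samples: p = 1
  expect_equal(mann_whitney_u(c(5, 5, 5), c(5, 5, 5))$p_value, 1)

  # all partitions with combined n <= 8, with and without ties
  set.seed(21)
  for (trial in 1:30) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    if (n1 + n2 > 8) next
    vals <- sample(1:5, n1 + n2, replace = TRUE)  # ties likely
    x <- vals[seq_len(n1)]; y <- vals[-seq_len(n1)]
    expect_equal(mann_whitney_u(x, y)$p_value, mw_bruteforce(x, y),
                 tolerance = 1e-12)
  }

  # exact vs normal approximation at n1 = n2 = 6
  set.seed(22)
  for (trial in 1:10) {
    x <- rnorm(6); y <- rnorm(6, 0.5)
    pe <- mann_whitney_u(x, y)$p_value
    pa <- mann_whitney_u(x, y, exact_limit = 0)$p_value
    expect_lt(abs(pe - pa), 0.02)
  }

  # sanity against the stats implementation (untied data, exact mode)
  set.seed(23)
  x <- rnorm(5); y <- rnorm(6, 1)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("IRIV classifies constructed variables as the construction dictates", {
  set.seed(31)
  n <- 60
  y <- rnorm(n)
  X <- cbind(y, matrix(rnorm(n * 5), n, 5))  # var 1 == y, rest pure noise

  cl <- iriv_classify(X, y, m = 40, seed = 1, n_latent = 4)
  expect_equal(cl$class[1], "strong")
  expect_lt(cl$DM[1], 0)

  # pure-noise variables are never strong, across seeds
  for (s in 2:6) {
    cl <- iriv_classify(X, y, m = 40, seed = s, n_latent = 4)
    expect_false(any(cl$class[-1] == "strong"))
  }

  # duplicated informative variable: redundancy may demote to weak but
  # must not flag as interfering
  Xd <- cbind(y + rnorm(n, 0, 0.05), y + rnorm(n, 0, 0.05),
              matrix(rnorm(n * 3), n, 3))
  for (s in 1:3) {
    cld <- iriv_classify(Xd, y, m = 40, seed = s, n_latent = 3)
    expect_false(any(cld$class[1:2] == "interfering"))
  }
  expect_error(iriv_classify(X, y, m = 15, seed = 1), "even")
})

test_that("IRIV iteration is an elimination-only fixed-point loop", {
  set.seed(41)
  n <- 60
  y <- rnorm(n)
  X <- cbind(y + rnorm(n, 0, 0.1), -y + rnorm(n, 0, 0.1),
             matrix(rnorm(n * 6), n, 6))

  it <- iriv_iterate(X, y, m = 40, seed = 2, n_latent = 4)
  # survivor counts non-increasing across rounds
  counts <- vapply(it$rounds, nrow, 1L)
  expect_true(all(diff(counts) <= 0))
  # informative pair survives
  expect_true(all(c(1, 2) %in% it$indices))

  # already all-informative input is a fixed point (single round)
  Xi <- cbind(y + rnorm(n, 0, 0.05), matrix(rnorm(n, 0, 1), n, 1) + y)
  it2 <- iriv_iterate(Xi, y, m = 40, seed = 3, n_latent = 2)
  expect_equal(it2$n_rounds, 1L)
  expect_equal(it2$indices, 1:2)
})

test_that("backward elimination removes an appended noise variable, never raises RMSEcv", {
  set.seed(51)
  n <- 80
  X <- matrix(rnorm(n * 4), n, 4)
  y <- X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, 0.1)
  Xn <- cbind(X[, 1:2], rnorm(n))   # informative pair + pure noise

  folds_seed <- 5
  # full-rank latent count: PLS = OLS per submodel, so the noise
  # variable only adds estimation variance and its removal must win
  before <- plsr_rmsecv(Xn, y, 3, seed = child_seed(folds_seed, "backelim_folds"))
  be <- backward_eliminate(Xn, y, 1:3, seed = folds_seed, n_latent = 3)
  expect_equal(be$indices, 1:2)
  expect_lte(be$rmsecv, before)

  # orthogonal all-informative set survives intact
  be2 <- backward_eliminate(X[, 1:2], y, 1:2, seed = 5, n_latent = 2)
  expect_equal(be2$indices, 1:2)
})

test_that("CARS-IRIV subsets are contained in the CARS subset", {
  d <- generate_planted_support(n_samples = 100, n_bands = 150, seed = 61)
  sub <- cars_iriv_select(d$X, d$y, N = 40, m = 40, seed = 9)
  cars <- attr(sub, "cars")
  expect_true(all(sub$indices %in% cars$indices))
  expect_lte(length(sub$indices), length(cars$indices))
  expect_identical(sub$source, "CARS-IRIV")
})
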