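test_that("discrete-gamma categories are mean-of-bin with unit mean", {
  # zero-variance limit
  g <- discrete_gamma_rates(1e6, 4)
  expect_true(all(abs(g$rates - 1) < 1e-2))
  # normalisation for arbitrary shapes
  for (shape in c(0.1, 0.5, 1, 3, 17)) {
    g <- discrete_gamma_rates(shape, 4)
    expect_equal(mean(g$rates), 1, tolerance = 1e-9)
    expect_true(all(diff(g$rates) >= 0))  # weakly increasing
  }
  # variance shrinks with shape
  v <- vapply(c(0.3, 1, 5, 50), function(s) var(discrete_gamma_rates(s, 4)$rates), 0)
  expect_true(all(diff(v) < 0))
  # quadrature oracle: bin means of Gamma(shape, shape) by numerical integration
  shape <- 0.5
  q <- qgamma(c(0.25, 0.5, 0.75), shape, rate = shape)
  edges <- c(0, q, Inf)
  oracle <- vapply(1:4, function(i) {
    4 * integrate(function(x) x * dgamma(x, shape, rate = shape),
                  edges[i], edges[i + 1], rel.tol = 1e-10)$value
  }, 0)
  expect_equal(discrete_gamma_rates(shape, 4)$rates, oracle, tolerance = 1e-6)
  # the engine's internal recomputation matches the R surface
  expect_equal(stratatips:::C_discrete_gamma(shape, 4),
               discrete_gamma_rates(shape, 4)$rates, tolerance = 1e-12)
  expect_error(discrete_gamma_rates(0, 4), "shape")
})

test_that("Mk transition probabilities follow the closed form", {
  expect_equal(mk_transition_prob(2, 0), diag(2))
  expect_true(all(abs(mk_transition_prob(3, 1e9) - 1/3) < 1e-9))
  p <- mk_transition_prob(2, 1)
  expect_equal(p[1, 1], 0.5 + 0.5 * exp(-2), tolerance = 1e-12)
  for (k in 2:5) {
    p <- mk_transition_prob(k, 0.37)
    expect_equal(rowSums(p), rep(1, k), tolerance = 1e-12)
    expect_equal(p[1, 2], p[2, 1])
  }
  expect_error(mk_transition_prob(2, -1), "t must be")
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(42)
  for (rep in 1:8) {
    ntip <- sample(2:4, 1)
    tree <- rand_dated_tree(ntip)
    k <- sample(2:3, 1)
    mat <- rand_matrix(tree$tip_labels, 3, k = k, missing_frac = 0.25)
    g <- discrete_gamma_rates(0.7, 4)
    br <- replace(exp(rnorm(2 * ntip - 1, 0, 0.3)), tree$root, NA)
    for (cond in c("none", "variable")) {
      a <- mk_log_likelihood(tree, mat, clock_rate = 0.4, branch_rates = br,
                             gamma = g, conditioning = cond)
      b <- brute_force_mk_loglik(tree, mat, clock_rate = 0.4,
                                 branch_rates = br, gamma_rates = g$rates,
                                 mkv = (cond == "variable"))
      expect_equal(a, b, tolerance = 1e-10)
    }
  }
})

test_that("two-tip limits: stationary root and exact Mkv value", {
  tr <- dated_tree(c(3L, 3L, NA), c(0, 0, 1), c("A", "B"))
  same <- suppressWarnings(character_matrix(
    matrix(c(0L, 0L), 2, 1, dimnames = list(c("A", "B"), NULL))))
  diff_ <- suppressWarnings(character_matrix(
    matrix(c(0L, 1L), 2, 1, dimnames = list(c("A", "B"), NULL))))
  # t -> 0: likelihood of a shared state -> stationary frequency 1/2
  expect_equal(mk_log_likelihood(tr, same, clock_rate = 1e-9), log(0.5),
               tolerance = 1e-6)
  # Mkv with different states: exactly 0.5 for every t > 0
  for (cr in c(1e-4, 0.05, 1, 50))
    expect_equal(exp(mk_log_likelihood(tr, diff_, clock_rate = cr,
                                       conditioning = "variable")),
                 0.5, tolerance = 1e-12)
  # Mkv likelihoods over all variable 2-tip binary patterns sum to 1
  pats <- list(c(0L, 1L), c(1L, 0L))
  tot <- sum(vapply(pats, function(p) {
    m <- suppressWarnings(character_matrix(
      matrix(p, 2, 1, dimnames = list(c("A", "B"), NULL))))
    exp(mk_log_likelihood(tr, m, clock_rate = 0.8, conditioning = "variable"))
  }, 0))
  expect_equal(tot, 1, tolerance = 1e-12)
  # unknown taxon rejected
  bad <- suppressWarnings(character_matrix(
    matrix(0:1, 2, 1, dimnames = list(c("A", "Z"), NULL))))
  expect_error(mk_log_likelihood(tr, bad), "absent from tree")
})

test_that("birth-death-sampling density matches the ODE oracle", {
  tr3 <- dated_tree(c(4L, 5L, 5L, NA, 4L), c(3, 1, 0, 10, 6),
                    c("f1", "f2", "x1"))
  for (par in list(c(0.3, 0.1, 0.05, 12), c(0.8, 0.4, 0.2, 11),
                   c(0.15, 0.02, 0.3, 20))) {
    a <- bdss_log_density(tr3, par[1], par[2], par[3], par[4])
    b <- ode_bdss_loglik(tr3, par[1], par[2], par[3], par[4])
    expect_equal(a, b, tolerance = 1e-8)
  }
  set.seed(5)
  tr6 <- rand_dated_tree(6, tip_ages = c(2, 1.5, 0, 0, 3, 0.7))
  expect_equal(bdss_log_density(tr6, 0.5, 0.2, 0.15, max(tr6$ages) + 2),
               ode_bdss_loglik(tr6, 0.5, 0.2, 0.15, max(tr6$ages) + 2),
               tolerance = 1e-8)
})

test_that("bdss density is exchangeable over tip labels at fixed node ages", {
  tr <- dated_tree(c(5L, 5L, 6L, 7L, 6L, 7L, NA),
                   c(2, 2.5, 1, 0, 4, 5, 6), c("a", "b", "c", "d"))
  perm <- tr
  perm$tip_labels <- c("d", "c", "b", "a")
  expect_equal(bdss_log_density(tr, 0.4, 0.1, 0.2, 8),
               bdss_log_density(perm, 0.4, 0.1, 0.2, 8))
})

test_that("bdss density preserves tree ordering under joint rescaling", {
  set.seed(13)
  # same fossil/extant composition so the rate-dimension factors cancel
  t1 <- rand_dated_tree(5, tip_ages = c(1.2, 0.4, 0, 2, 0.9))
  t2 <- rand_dated_tree(5, tip_ages = c(0.3, 1.6, 0, 0.8, 2.4))
  f <- function(tr, s) {
    tr$ages <- tr$ages * s
    bdss_log_density(tr, 0.5 / s, 0.2 / s, 0.1 / s, max(tr$ages) + 2 * s)
  }
  for (s in c(1, 10, 100))
    expect_equal(f(t1, s) > f(t2, s), f(t1, 1) > f(t2, 1))
  expect_error(bdss_log_density(t1, 0.5, 0.2, 0.1, max(t1$ages) - 0.01),
               "origin")
  expect_error(bdss_log_density(t1, -0.5, 0.2, 0.1, 10), "rates")
})

test_that("log_prior matches the closed-form hyperprior densities", {
  nn <- 5L
  mk_params <- function(...) {
    args <- list(...)
    defaults <- list(clock_rate = 0.0046, clock_sd = 0.5, gamma_shape = 5,
                     birth_rate = 0.14, death_rate = 0.1, sampling_rate = 0.03,
                     origin_age = 10,
                     branch_rates = replace(rep(1, nn), 4L, NA))
    do.call(model_params, utils::modifyList(defaults, args))
  }
  # below the clock-rate offset: zero prior mass
  expect_identical(log_prior(mk_params(clock_rate = 0.0015)), -Inf)
  expect_identical(log_prior(mk_params(gamma_shape = 10.5)), -Inf)
  # full closed form at a reference point
  p <- mk_params()
  manual <- (-log(0.003) - (0.0046 - 0.0016) / 0.003) +  # = -log(0.003) - 1
    dexp(0.5, 1, log = TRUE) +
    log(1 / 10) +
    dlnorm(0.14, log(0.14) - 0.9^2 / 2, 0.9, log = TRUE) +
    dexp(0.1, 10, log = TRUE) + dexp(0.03, 1 / 0.03, log = TRUE) +
    sum(dlnorm(rep(1, 4), -0.5^2 / 2, 0.5, log = TRUE))
  expect_equal(log_prior(p), manual, tolerance = 1e-12)
  # clock-rate term alone at offset + mean is -log(mean) - 1
  delta <- log_prior(mk_params(clock_rate = 0.0046)) -
    log_prior(mk_params(clock_rate = 0.0016))
  expect_equal(delta, -1, tolerance = 1e-12)
  # continuity on the interior: small parameter nudges move the density smoothly
  eps <- 1e-7
  d <- log_prior(mk_params(gamma_shape = 5 + eps)) - log_prior(p)
  expect_lt(abs(d), 1e-6)
})
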