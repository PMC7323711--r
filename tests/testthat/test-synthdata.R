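test_that("pure-birth simulation matches the Yule expectation", {
  set.seed(70)
  lam <- 0.9; t0 <- 2.5
  recipe <- simulation_recipe(birth_rate = lam, death_rate = 1e-12,
                              sampling_rate = 1e-12, origin_age = t0,
                              end_age = 0, rho = 1, min_tips = 2L,
                              target_tips = 50L)
  tips <- replicate(400, simulate_bdss_tree(recipe)$ntip)
  # N ~ Geometric(e^{-lam t0}); simulator conditions on N >= 2
  p1 <- exp(-lam * t0)
  cond_mean <- (exp(lam * t0) - p1) / (1 - p1)
  expect_equal(mean(tips), cond_mean, tolerance = 0.15)
})

test_that("tree simulation is deterministic per seed and respects the origin", {
  recipe <- simulation_recipe()
  set.seed(71); t1 <- simulate_bdss_tree(recipe)
  set.seed(71); t2 <- simulate_bdss_tree(recipe)
  expect_identical(t1, t2)
  expect_true(all(t1$ages < recipe$origin_age))
  expect_true(all(t1$ages[seq_len(t1$ntip)] >= recipe$end_age))
  expect_identical(tree_ok <- stratatips:::tree_violations(t1), character(0))
})

test_that("character simulation hits the Mk limits", {
  set.seed(72)
  tree <- rand_dated_tree(8, tip_ages = rep(0, 8), step = 1)
  # rate 0: every character constant
  r0 <- simulation_recipe(n_characters = 20, clock_rate = 0, missing_frac = 0)
  m0 <- simulate_mk_matrix(tree, r0, variable_only = FALSE)
  expect_true(all(apply(m0$data, 2, function(x) length(unique(x))) == 1L))
  # saturated branches: states approach iid uniform
  rbig <- simulation_recipe(n_characters = 400, clock_rate = 1e3,
                            prop_ternary = 0, missing_frac = 0)
  mbig <- simulate_mk_matrix(tree, rbig, variable_only = FALSE)
  freq0 <- mean(mbig$data == 0L)
  expect_equal(freq0, 0.5, tolerance = 0.05)
  # variable-only filtering leaves no constant characters
  rv <- simulation_recipe(n_characters = 50, clock_rate = 0.05, missing_frac = 0)
  mv <- simulate_mk_matrix(tree, rv, variable_only = TRUE)
  expect_true(all(apply(mv$data, 2, function(x) length(unique(x[!is.na(x)]))) > 1L))
})

test_that("the likelihood prefers the generating clock rate", {
  set.seed(73)
  tree <- rand_dated_tree(8, tip_ages = runif(8, 0, 2), step = 1)
  recipe <- simulation_recipe(n_characters = 30, clock_rate = 0.3,
                              prop_ternary = 0, gamma_shape = 1e6,
                              missing_frac = 0)
  wins <- 0L
  for (i in 1:100) {
    m <- simulate_mk_matrix(tree, recipe, variable_only = FALSE)
    l_true <- mk_log_likelihood(tree, m, clock_rate = 0.3)
    l_off <- mk_log_likelihood(tree, m, clock_rate = 3)
    wins <- wins + (l_true > l_off)
  }
  expect_gte(wins, 95L)
})

test_that("rejection sampler reproduces order-statistic closed forms", {
  set.seed(74)
  s1 <- fossil_site("A", "a", 410.8, 419.2)
  s2 <- fossil_site("B", "b", 410.8, 419.2)
  s3 <- fossil_site("C", "c", 410.8, 419.2)
  # no relations: exact uniforms
  m <- rejection_sample_site_ages(list(s1, s2), strat_sequence(), 10000)
  expect_lt(ks_distance(m[, "A"], qunif(stats::ppoints(10000), 410.8, 419.2)),
            0.02)
  # one relation: lower site is the max of two iid uniforms
  m <- rejection_sample_site_ages(list(s1, s2), strat_sequence("A", "B"), 10000)
  expect_equal(mean(m[, "A"]), 410.8 + 2 / 3 * 8.4, tolerance = 1.3e-4)
  expect_true(all(m[, "A"] >= m[, "B"]))
  # chain of three: middle site is the median order statistic, mean = midpoint
  m <- rejection_sample_site_ages(list(s1, s2, s3),
                                  strat_sequence(c("A", "B"), c("B", "C")),
                                  10000)
  expect_equal(mean(m[, "B"]), 415.0, tolerance = 1.3e-4)
  # incompatible bounds abort
  s4 <- fossil_site("D", "d", 400, 401)
  expect_error(rejection_sample_site_ages(list(s4, s1),
                                          strat_sequence("D", "A"), 100),
               "acceptance probability")
})

test_that("fixture datasets are reproducible and round-trip through io", {
  fx <- make_fixture_dataset(seed = 5, dir = file.path(tempdir(), "fxA"),
                             recipe = simulation_recipe(n_characters = 30,
                                                        target_tips = 10L),
                             site_size = 3L)
  m <- suppressWarnings(read_nexus_matrix(fx$matrix_path))
  expect_identical(m$data[fx$matrix$taxa, ], fx$matrix$data)
  st <- read_site_table(fx$sites_path)
  expect_equal(nrow(st$seq$relations), 1L)
  multi <- Filter(function(s) length(s$taxa) > 1, st$sites)
  expect_length(multi, 2L)
  expect_true(all(vapply(multi, function(s)
    s$min_age == 410.8 && s$max_age == 419.2, TRUE)))
  cfg <- read_config(fx$config_path)
  expect_s3_class(cfg, "analysis_config")
  # two seeds differ; one seed repeats exactly
  fx2 <- make_fixture_dataset(seed = 6, dir = file.path(tempdir(), "fxB"),
                              recipe = simulation_recipe(n_characters = 30,
                                                         target_tips = 10L),
                              site_size = 3L)
  expect_false(identical(fx$matrix$data, fx2$matrix$data))
  fx3 <- make_fixture_dataset(seed = 5, dir = file.path(tempdir(), "fxC"),
                              recipe = simulation_recipe(n_characters = 30,
                                                         target_tips = 10L),
                              site_size = 3L)
  expect_identical(fx$matrix$data, fx3$matrix$data)
  # within each multi-taxon site the true tip ages are exactly shared
  for (s in fx$sites[1:2]) {
    tips <- match(s$taxa, fx$tree$tip_labels)
    expect_equal(length(unique(fx$tree$ages[tips])), 1L)
  }
})

test_that("simulated root-age distribution matches the density oracle", {
  # among simulated 2-tip trees (1 fossil + 1 extant), the root age follows
  # the conditional density implied by the closed-form tree density
  set.seed(75)
  lam <- 0.4; mu <- 0.15; psi <- 0.25; t0 <- 4
  recipe <- simulation_recipe(birth_rate = lam, death_rate = mu,
                              sampling_rate = psi, origin_age = t0,
                              end_age = 0, rho = 1, min_tips = 2L,
                              target_tips = 3L)
  roots <- c()
  for (i in 1:7000) {
    tr <- tryCatch(simulate_bdss_tree(recipe, max_tries = 1),
                   error = function(e) NULL)
    if (is.null(tr) || tr$ntip != 2L) next
    ages <- tr$ages[1:2]
    if (sum(ages > 1e-9) == 1L)  # exactly one fossil, one extant tip
      roots <- c(roots, tr$ages[3])
  }
  expect_gt(length(roots), 200)
  # oracle CDF: integrate the closed-form density of (root age, fossil age)
  # over the fossil age at each root-age grid point
  grid <- seq(1e-3, t0 - 1e-3, length.out = 120)
  dens <- vapply(grid, function(x) {
    f <- function(y) vapply(y, function(yy) {
      tr <- dated_tree(c(3L, 3L, NA), c(yy, 0, x), c("f", "x"))
      exp(bdss_log_density(tr, lam, mu, psi, t0))
    }, 0)
    integrate(f, 0, x - 1e-6, rel.tol = 1e-8)$value
  }, 0)
  cdf <- cumsum(dens) / sum(dens)
  ks <- ks_distance(roots, grid[pmin(findInterval(runif(5000), cdf) + 1,
                                     length(grid))])
  expect_lt(ks, 0.08)
})
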