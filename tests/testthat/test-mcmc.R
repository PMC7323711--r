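tiny_fixture <- function(seed = 17) {
  make_fixture_dataset(seed = seed, dir = file.path(tempdir(), paste0("fx", seed)),
                       recipe = simulation_recipe(n_characters = 40,
                                                  target_tips = 10L),
                       site_size = 3L)
}

test_that("a zero-length chain logs exactly the initial state", {
  fx <- lochkovian_pair()
  cfg <- analysis_config(chain_length = 0, log_interval = 1, seed = 1,
                         prior_only = TRUE, fix_tree = TRUE)
  res <- run_chain(cfg, list(matrix = NULL, sites = fx$sites, seq = fx$seq,
                             tree = fx$tree))
  expect_equal(nrow(res$trace), 1L)
  expect_equal(res$trace$Sample, 0)
  expect_length(res$trees, 1L)
})

test_that("chains are bit-identical under the same seed", {
  fx <- tiny_fixture()
  cfg <- analysis_config(chain_length = 5e3, log_interval = 10, seed = 77)
  r1 <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
  r2 <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$trees[[length(r1$trees)]]$ages,
                   r2$trees[[length(r2$trees)]]$ages)
  cfg$seed <- 78L
  r3 <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
  expect_false(identical(r1$trace$posterior, r3$trace$posterior))
})

test_that("posterior equals likelihood plus prior in every row", {
  fx <- tiny_fixture()
  cfg <- analysis_config(chain_length = 1e4, log_interval = 20, seed = 31)
  res <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
  expect_true(all(abs(res$trace$posterior - res$trace$likelihood -
                        res$trace$prior) < 1e-8))
  # the logged prior at generation 0 matches the R-side density stack
  tree0 <- res$trees[[1]]
  params0 <- model_params(
    clock_rate = res$trace$clock_rate[1], clock_sd = res$trace$clock_sd[1],
    gamma_shape = res$trace$gamma_shape[1],
    birth_rate = res$trace$birth_rate[1], death_rate = res$trace$death_rate[1],
    sampling_rate = res$trace$sampling_rate[1],
    origin_age = res$trace$origin_age[1],
    branch_rates = replace(rep(1, 2 * tree0$ntip - 1), tree0$root, NA))
  site_terms <- sum(vapply(res$sites, function(s)
    if (s$max_age > s$min_age) -log(s$max_age - s$min_age) else 0, 0))
  manual <- log_prior(params0, cfg$priors) + site_terms +
    bdss_log_density(tree0, params0$birth_rate, params0$death_rate,
                     params0$sampling_rate, params0$origin_age)
  expect_equal(res$trace$prior[1], manual, tolerance = 1e-8)
  # the logged likelihood at generation 0 matches the R-side evaluation
  manual_l <- mk_log_likelihood(tree0, fx$matrix,
                                clock_rate = params0$clock_rate,
                                branch_rates = params0$branch_rates,
                                gamma = discrete_gamma_rates(params0$gamma_shape, 4),
                                conditioning = "variable")
  expect_equal(res$trace$likelihood[1], manual_l, tolerance = 1e-8)
})

test_that("every logged sample passes full state validation", {
  fx <- tiny_fixture(seed = 19)
  cfg <- analysis_config(chain_length = 2e4, log_interval = 100, seed = 42)
  res <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
  for (i in seq_along(res$trees)) {
    sites_i <- res$sites
    for (j in seq_along(sites_i))
      sites_i[[j]]$age <- res$trace[[paste0("age_", sites_i[[j]]$id)]][i]
    expect_identical(validate_state(res$trees[[i]], sites_i, res$seq),
                     character(0))
  }
})

test_that("acceptance bookkeeping is logged per operator", {
  fx <- tiny_fixture()
  cfg <- analysis_config(chain_length = 5e3, log_interval = 50, seed = 3)
  res <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites, seq = fx$seq))
  expect_true(all(c("operator", "proposed", "accepted", "rate") %in%
                    names(res$acceptance)))
  expect_gte(sum(res$acceptance$proposed), cfg$chain_length)
  expect_true(any(res$acceptance$accepted > 0))
})

test_that("prior-only sampling recovers the scalar hyperpriors", {
  fx <- tiny_fixture()
  cfg <- analysis_config(chain_length = 6e5, log_interval = 50, seed = 88,
                         prior_only = TRUE)
  res <- sample_prior(cfg, list(matrix = NULL, sites = fx$sites, seq = fx$seq,
                                tree = fx$tree))
  tr <- discard_burnin(res)$trace
  # gamma shape ~ Uniform(0, 10)
  expect_equal(mean(tr$gamma_shape), 5.0, tolerance = 0.1 / 5)
  expect_lt(ks_distance(tr$gamma_shape, qunif(stats::ppoints(5000), 0, 10)),
            0.05)
  # clock rate: offset exponential with zero mass below the offset
  expect_gte(min(tr$clock_rate), 0.0016)
  expect_equal(mean(tr$clock_rate), 0.0046, tolerance = 0.05)
  expect_lt(ks_distance(tr$clock_rate - 0.0016,
                        qexp(stats::ppoints(5000), 1 / 0.003)), 0.05)
  # clock sd ~ Exponential(mean 1)
  expect_lt(ks_distance(tr$clock_sd, qexp(stats::ppoints(5000), 1)), 0.05)
})

test_that("the sampled posterior matches a fine-grid oracle on a toy problem", {
  # 2 tips, 1 binary character, fixed tree: only the fossil tip age moves
  tree <- dated_tree(c(3L, 3L, NA), c(1.5, 0, 5), c("F", "X"))
  mat <- suppressWarnings(character_matrix(
    matrix(c(0L, 1L), 2, 1, dimnames = list(c("F", "X"), NULL))))
  sites <- list(fossil_site("F", "F", 0.5, 4.5, age = 1.5))
  cfg <- analysis_config(chain_length = 6e5, log_interval = 30, seed = 12,
                         fix_tree = TRUE, conditioning = "none",
                         priors = prior_config(clock_rate_mean = 0.8,
                                               clock_rate_offset = 0.2),
                         weights = c(scale_clock_rate = 0, scale_clock_sd = 0,
                                     scale_shape = 0, scale_birth = 0,
                                     scale_death = 0, scale_sampling = 0,
                                     rate_walk = 0))
  res <- run_chain(cfg, list(matrix = mat, sites = sites,
                             seq = strat_sequence(), tree = tree))
  x <- discard_burnin(res)$trace$age_F
  # oracle: posterior on the tip age by fine-grid quadrature of the same
  # likelihood (flat prior within bounds)
  grid <- seq(0.5, 4.5, length.out = 4001)
  loglik <- vapply(grid, function(a) {
    tr <- tree; tr$ages[1] <- a
    mk_log_likelihood(tr, mat, clock_rate = cfg$priors$clock_rate_offset +
                        cfg$priors$clock_rate_mean)
  }, 0)
  w <- exp(loglik - max(loglik)); cdf <- cumsum(w) / sum(w)
  ks <- max(abs(vapply(x, function(xx) cdf[findInterval(xx, grid)], 0) -
                  rank(x) / length(x)))
  expect_lt(ks, 0.05)
})

test_that("independent runs agree on site-age posteriors", {
  fx <- tiny_fixture(seed = 29)
  means <- ses <- numeric(3)
  for (i in 1:3) {
    cfg <- analysis_config(chain_length = 3e5, log_interval = 100,
                           seed = 100 + i)
    res <- run_chain(cfg, list(matrix = fx$matrix, sites = fx$sites,
                               seq = fx$seq))
    x <- discard_burnin(res)$trace$age_site_lower
    means[i] <- mean(x)
    ses[i] <- sd(x) / sqrt(max(ess(x), 1))
  }
  for (i in 1:2) for (j in (i + 1):3)
    expect_lt(abs(means[i] - means[j]), 2 * sqrt(ses[i]^2 + ses[j]^2) + 0.15)
})

test_that("an impossible initial state is reported, not sampled", {
  tree <- dated_tree(c(3L, 3L, NA), c(1.5, 0, 5), c("F", "X"))
  sites <- list(fossil_site("F", "F", 6, 8, age = 7))  # above the parent
  cfg <- analysis_config(chain_length = 100, log_interval = 10, seed = 1,
                         prior_only = TRUE)
  expect_error(run_chain(cfg, list(matrix = NULL, sites = sites,
                                   seq = strat_sequence(), tree = tree)),
               "zero-probability initial state")
})
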