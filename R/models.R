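# Model stack: discrete-gamma rate categories, Mk/Mkv likelihood,
# serially-sampled birth-death tree prior, hyperprior densities.

#' Discrete-gamma among-character rate categories
#'
#' Rates are the means of the `ncat` equal-probability bins of a
#' Gamma(shape, rate = shape) distribution (mean-of-bin discretisation), so
#' the category rates always average exactly 1. Computed via
#' [phangorn::discrete.gamma()]; the MCMC engine recomputes the same
#' quantities internally when the shape parameter moves.
#'
#' @param shape Gamma shape parameter (> 0).
#' @param ncat Number of categories (default 4).
#' @return A list with `shape`, `ncat`, `rates` (numeric, mean 1) and equal
#'   `weights`.
#' @export
discrete_gamma_rates <- function(shape, ncat = 4L) {
  if (!is.finite(shape) || shape <= 0) stop("shape must be > 0")
  if (ncat < 1) stop("ncat must be >= 1")
  rates <- if (ncat == 1L) 1.0 else as.numeric(phangorn::discrete.gamma(shape, ncat))
  rates <- rates / mean(rates)
  list(shape = shape, ncat = as.integer(ncat), rates = rates,
       weights = rep(1 / ncat, ncat))
}

#' Mk transition probability matrix
#'
#' Lewis Mk model with `k` symmetric states and unit mean rate:
#' `P_ii(t) = 1/k + ((k-1)/k) exp(-k t / (k-1))`, equal off-diagonals.
#'
#' @param k Number of states (>= 2).
#' @param t Branch length in expected substitutions (>= 0).
#' @return A `k x k` stochastic matrix.
#' @export
mk_transition_prob <- function(k, t) {
  if (k < 2) stop("k must be >= 2")
  if (t < 0) stop("t must be >= 0")
  e <- exp(-k * t / (k - 1))
  pii <- 1 / k + (k - 1) / k * e
  pij <- 1 / k - e / k
  m <- matrix(pij, k, k)
  diag(m) <- pii
  m
}

#' Mk / Mkv log-likelihood of a character matrix on a dated tree
#'
#' Felsenstein pruning with stationary (uniform) root frequencies, a
#' discrete-gamma rate mixture, and optional conditioning on characters being
#' variable (the Mkv ascertainment correction). Branch lengths in expected
#' substitutions are `branch_duration * clock_rate * branch multiplier`.
#' Missing states (`NA`) contribute partial likelihood 1 in every state. With
#' `conditioning = "variable"` each character's likelihood is divided by
#' one minus the probability of a constant pattern, computed with that
#' character's state count and the same branch lengths and rate mixture.
#'
#' @param tree A [dated_tree()].
#' @param matrix A [character_matrix()]; its taxa must all be tips of `tree`.
#' @param clock_rate Base clock rate (substitutions/character/Ma).
#' @param branch_rates Per-branch rate multipliers indexed by node id (`NA` or
#'   any value at the root); defaults to a strict clock (all 1).
#' @param gamma A list from [discrete_gamma_rates()]; default single rate 1.
#' @param conditioning `"none"` (Mk) or `"variable"` (Mkv).
#' @return The log-likelihood (a single real).
#' @export
mk_log_likelihood <- function(tree, matrix, clock_rate = 1,
                              branch_rates = NULL,
                              gamma = discrete_gamma_rates(1, 1L),
                              conditioning = c("none", "variable")) {
  conditioning <- match.arg(conditioning)
  nn <- 2L * tree$ntip - 1L
  if (is.null(branch_rates)) branch_rates <- rep(1, nn)
  missing_tax <- setdiff(matrix$taxa, tree$tip_labels)
  if (length(missing_tax))
    stop("taxa absent from tree: ", paste(missing_tax, collapse = ","))
  # reorder matrix rows to tree tip order
  dat <- matrix$data[match(tree$tip_labels, matrix$taxa), , drop = FALSE]
  br <- branch_rates
  br[tree$root] <- 1
  blen <- numeric(nn)
  nonroot <- which(!is.na(tree$parent))
  blen[nonroot] <- (tree$ages[tree$parent[nonroot]] - tree$ages[nonroot]) *
    clock_rate * br[nonroot]
  parent0 <- tree$parent - 1L
  parent0[tree$root] <- -1L
  C_mk_loglik(parent0, tree$ntip, blen, dat, matrix$k, gamma$rates,
              conditioning == "variable")
}

#' Serially-sampled birth-death log-density of a dated tree
#'
#' Density of a rooted dated tree under a birth-death process with
#' through-time sampling, conditioned on the origin age. Sampling removes the
#' lineage (so all samples are terminal tips, never ancestors): tips with
#' age above 0 are psi-samples, tips at age 0 are rho-samples with rho = 1.
#'
#' @param tree A [dated_tree()].
#' @param lambda,mu,psi Birth, death and fossil-sampling rates (> 0, per Ma).
#' @param origin_age Age of the origin (> root age).
#' @return The log-density (a single real).
#' @export
bdss_log_density <- function(tree, lambda, mu, psi, origin_age) {
  parent0 <- tree$parent - 1L
  parent0[tree$root] <- -1L
  C_bdss_loglik(parent0, tree$ntip, tree$ages, lambda, mu, psi, origin_age)
}

#' Default hyperprior configuration
#'
#' The defaults are the analysis settings of the motivating study: an
#' offset exponential on clock rate (mean 0.003, offset 0.0016), an
#' exponential (mean 1) on the relaxed-clock standard deviation, Uniform(0,10)
#' on the gamma shape, a lognormal with mean 0.14 in real space and sdlog 0.9
#' on birth rate, and exponentials with means 0.1 and 0.03 on death and
#' sampling rates.
#'
#' @param clock_rate_mean,clock_rate_offset,clock_sd_mean,shape_min,shape_max,birth_meanreal,birth_sdlog,death_mean,sampling_mean
#'   Hyperparameters; see Description for defaults.
#' @return An object of class `prior_config` (a named list).
#' @export
prior_config <- function(clock_rate_mean = 0.003, clock_rate_offset = 0.0016,
                         clock_sd_mean = 1, shape_min = 0, shape_max = 10,
                         birth_meanreal = 0.14, birth_sdlog = 0.9,
                         death_mean = 0.1, sampling_mean = 0.03) {
  p <- list(clock_rate_mean = clock_rate_mean,
            clock_rate_offset = clock_rate_offset,
            clock_sd_mean = clock_sd_mean,
            shape_min = shape_min, shape_max = shape_max,
            birth_meanreal = birth_meanreal, birth_sdlog = birth_sdlog,
            death_mean = death_mean, sampling_mean = sampling_mean)
  stopifnot(clock_rate_mean > 0, clock_rate_offset >= 0, clock_sd_mean > 0,
            shape_max > shape_min, birth_meanreal > 0, birth_sdlog > 0,
            death_mean > 0, sampling_mean > 0)
  structure(p, class = "prior_config")
}

# hyperparameters as the flat vector the engine expects
hyper_vector <- function(priors) {
  c(priors$clock_rate_mean, priors$clock_rate_offset, priors$clock_sd_mean,
    priors$shape_min, priors$shape_max, priors$birth_meanreal,
    priors$birth_sdlog, priors$death_mean, priors$sampling_mean)
}

#' Joint log-prior density of the model parameters
#'
#' Sum of the hyperprior log-densities of the scalar parameters plus the iid
#' lognormal density of the branch-rate multipliers (mean 1 in real space,
#' sdlog equal to `clock_sd`). Returns `-Inf` outside the support (e.g. clock
#' rate below its offset, shape outside its uniform range); the origin age
#' carries an improper uniform prior and contributes 0.
#'
#' @param params A [model_params()].
#' @param priors A [prior_config()].
#' @return Log-density (may be `-Inf`).
#' @export
log_prior <- function(params, priors = prior_config()) {
  p <- params
  if (p$clock_rate < priors$clock_rate_offset) return(-Inf)
  lp <- dexp(p$clock_rate - priors$clock_rate_offset,
             rate = 1 / priors$clock_rate_mean, log = TRUE)
  lp <- lp + dexp(p$clock_sd, rate = 1 / priors$clock_sd_mean, log = TRUE)
  if (p$gamma_shape < priors$shape_min || p$gamma_shape > priors$shape_max)
    return(-Inf)
  lp <- lp + dunif(p$gamma_shape, priors$shape_min, priors$shape_max, log = TRUE)
  mulog <- log(priors$birth_meanreal) - priors$birth_sdlog^2 / 2
  lp <- lp + dlnorm(p$birth_rate, mulog, priors$birth_sdlog, log = TRUE)
  lp <- lp + dexp(p$death_rate, rate = 1 / priors$death_mean, log = TRUE)
  lp <- lp + dexp(p$sampling_rate, rate = 1 / priors$sampling_mean, log = TRUE)
  br <- p$branch_rates[!is.na(p$branch_rates)]
  if (any(br <= 0)) return(-Inf)
  lp + sum(dlnorm(br, -p$clock_sd^2 / 2, p$clock_sd, log = TRUE))
}
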