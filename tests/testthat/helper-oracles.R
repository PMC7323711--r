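# Independent test oracles. These deliberately share no code with the
# package internals: the likelihood oracle enumerates ancestral states, the
# tree-prior oracle integrates the process ODEs numerically, and the
# site-age oracle is plain rejection sampling.

# Brute-force Mk/Mkv log-likelihood by full enumeration of node states
# (missing tips enumerated too), mixing over gamma categories.
brute_force_mk_loglik <- function(tree, mat, clock_rate = 1,
                                  branch_rates = NULL,
                                  gamma_rates = 1, mkv = FALSE) {
  nn <- 2L * tree$ntip - 1L
  if (is.null(branch_rates)) branch_rates <- rep(1, nn)
  nonroot <- which(!is.na(tree$parent))
  blen <- numeric(nn)
  blen[nonroot] <- (tree$ages[tree$parent[nonroot]] - tree$ages[nonroot]) *
    clock_rate * branch_rates[nonroot]
  dat <- mat$data[match(tree$tip_labels, mat$taxa), , drop = FALSE]

  lik_pattern <- function(obs, k, r) {
    # obs: per-tip state or NA; sum over all full assignments
    choices <- lapply(seq_len(nn), function(v) {
      if (v <= tree$ntip && !is.na(obs[v])) obs[v] else 0:(k - 1)
    })
    grid <- do.call(expand.grid, choices)
    total <- 0
    for (i in seq_len(nrow(grid))) {
      s <- as.integer(grid[i, ])
      p <- 1 / k
      for (v in nonroot) {
        P <- mk_transition_prob(k, blen[v] * r)
        p <- p * P[s[tree$parent[v]] + 1L, s[v] + 1L]
      }
      total <- total + p
    }
    total
  }

  lnL <- 0
  for (c_ in seq_len(ncol(dat))) {
    k <- mat$k[c_]
    L <- mean(vapply(gamma_rates, function(r)
      lik_pattern(dat[, c_], k, r), 0))
    if (mkv) {
      pconst <- mean(vapply(gamma_rates, function(r) {
        sum(vapply(0:(k - 1), function(s)
          lik_pattern(rep(s, tree$ntip), k, r), 0))
      }, 0))
      L <- L / (1 - pconst)
    }
    lnL <- lnL + log(L)
  }
  lnL
}

# Numerical oracle for the serially-sampled birth-death density: integrate
# p0 and log q along time with deSolve and assemble the tree density.
ode_bdss_loglik <- function(tree, lambda, mu, psi, origin_age) {
  rhs <- function(t, y, parms) {
    p0 <- y[1]
    list(c(mu - (lambda + mu + psi) * p0 + lambda * p0^2,
           -(lambda + mu + psi) + 2 * lambda * p0))
  }
  times <- sort(unique(c(0, tree$ages, origin_age)))
  sol <- deSolve::ode(c(p0 = 0, logq = 0), times, rhs, NULL,
                      rtol = 1e-12, atol = 1e-12)
  logq_at <- function(t) unname(sol[match(t, sol[, "time"]), "logq"])
  internal <- setdiff(seq_len(2L * tree$ntip - 1L), seq_len(tree$ntip))
  fossil <- which(tree$ages[seq_len(tree$ntip)] > 1e-12)
  logq_at(origin_age) +
    sum(log(lambda) + logq_at(tree$ages[internal])) +
    sum(log(psi) - logq_at(tree$ages[fossil]))
}

# random dated tree over given (or random) tip ages
rand_dated_tree <- function(ntip, tip_ages = NULL, step = 1) {
  if (is.null(tip_ages)) tip_ages <- runif(ntip, 0, 3)
  names(tip_ages) <- paste0("t", seq_len(ntip))
  random_start_tree(tip_ages, step = step)
}

# random character matrix with missing cells
rand_matrix <- function(taxa, nchar, k = 2L, missing_frac = 0.2) {
  dat <- matrix(sample.int(k, length(taxa) * nchar, replace = TRUE) - 1L,
                length(taxa), nchar, dimnames = list(taxa, NULL))
  dat[runif(length(dat)) < missing_frac] <- NA_integer_
  for (c_ in seq_len(nchar)) if (all(is.na(dat[, c_]))) dat[1, c_] <- 0L
  suppressWarnings(character_matrix(dat))
}

# small shared fixture: site pair on the Lochkovian window with a fixed,
# comfortably old tree (used for effective-prior runs)
lochkovian_pair <- function() {
  tip_ages <- c(A = 415, B = 415, C = 414, D = 414)
  tree <- random_start_tree(tip_ages, step = 40)
  list(tree = tree,
       sites = list(fossil_site("S_lower", c("A", "B"), 410.8, 419.2),
                    fossil_site("S_upper", c("C", "D"), 410.8, 419.2)),
       seq = strat_sequence("S_lower", "S_upper"))
}

ks_distance <- function(x, ref) {
  suppressWarnings(unname(stats::ks.test(x, ref)$statistic))
}
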