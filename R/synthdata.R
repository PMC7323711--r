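# Synthetic data: forward birth-death-sampling tree simulation, Mk character
# simulation, rejection-sampling oracle for ordered site ages, and on-disk
# fixture generation. The simulators are written independently of the
# likelihood/proposal code so they can serve as test oracles.

#' Simulation recipe
#'
#' @param birth_rate,death_rate,sampling_rate Per-lineage rates (per Ma).
#'   Sampling removes the lineage, so every fossil sample is a terminal tip.
#' @param origin_age Start of the process (Ma before present).
#' @param end_age Time at which the process is stopped (Ma; 0 = the present).
#'   Lineages alive at `end_age` are sampled with probability `rho`.
#' @param rho Extant-sampling probability at `end_age`.
#' @param min_tips,target_tips,max_tips Reject and resimulate trees with
#'   fewer than `min_tips` or more than `max_tips` sampled tips
#'   (`max_tips` defaults to `4 * target_tips`).
#' @param n_characters,prop_ternary Number of characters and the proportion
#'   with three states (the rest are binary).
#' @param gamma_shape,clock_rate Among-character rate shape and base clock
#'   rate (substitutions/character/Ma) for character simulation.
#' @param missing_frac Fraction of cells masked as missing.
#' @return A list of class `simulation_recipe`.
#' @export
simulation_recipe <- function(birth_rate = 0.35, death_rate = 0.05,
                              sampling_rate = 0.2, origin_age = 428,
                              end_age = 402, rho = 0, min_tips = 4L,
                              target_tips = 20L, max_tips = 2L * target_tips,
                              n_characters = 100L,
                              prop_ternary = 0.3, gamma_shape = 1,
                              clock_rate = 0.005, missing_frac = 0.1) {
  stopifnot(birth_rate > 0, death_rate >= 0, sampling_rate >= 0,
            origin_age > end_age, rho >= 0, rho <= 1, n_characters >= 1)
  structure(as.list(environment()), class = "simulation_recipe")
}

#' Simulate a dated tree under the serially-sampled birth-death process
#'
#' Forward simulation from one lineage at the origin: births at
#' `birth_rate`, deaths at `death_rate`, fossil sampling at `sampling_rate`
#' (the sampled lineage is removed and becomes a dated terminal tip).
#' Lineages alive at `end_age` are sampled with probability `rho`. The tree
#' is pruned to sampled lineages. Resimulates until the tip count is
#' acceptable.
#'
#' @param recipe A [simulation_recipe()].
#' @param max_tries Bounded retries before giving up.
#' @return A [dated_tree()] whose fossil tips have non-zero ages.
#' @export
simulate_bdss_tree <- function(recipe, max_tries = 200L) {
  for (try in seq_len(max_tries)) {
    tr <- sim_bdss_once(recipe)
    if (!is.null(tr) && tr$ntip >= recipe$min_tips &&
        tr$ntip <= recipe$max_tips)
      return(tr)
  }
  stop("could not reach an acceptable tip count in ", max_tries, " tries")
}

sim_bdss_once <- function(recipe) {
  lam <- recipe$birth_rate; mu <- recipe$death_rate; psi <- recipe$sampling_rate
  # event-driven forward simulation; node table grows as events happen
  parent <- integer(0); age <- numeric(0); type <- character(0)
  new_node <- function(p, a, ty) {
    parent[length(parent) + 1L] <<- p
    age[length(age) + 1L] <<- a
    type[length(type) + 1L] <<- ty
    length(parent)
  }
  root <- new_node(NA_integer_, recipe$origin_age, "pending")
  active <- root  # lineage ids currently alive, keyed by their future node
  repeat {
    k <- length(active)
    if (k == 0L) break
    # all active lineages share the current time = age of their pending node
    t_now <- age[active[1]]
    rate <- k * (lam + mu + psi)
    t_next <- t_now - rexp(1, rate)
    if (t_next <= recipe$end_age) {
      # stop: rho-sample survivors at end_age
      for (v in active) {
        age[v] <- recipe$end_age
        type[v] <- if (runif(1) < recipe$rho) "extant_sample" else "unsampled"
      }
      break
    }
    i <- sample.int(k, 1L)
    v <- active[i]
    age[active] <- t_next     # advance the clock on every pending node
    u <- runif(1, 0, lam + mu + psi)
    if (u < lam) {
      age[v] <- t_next; type[v] <- "birth"
      c1 <- new_node(v, t_next, "pending")
      c2 <- new_node(v, t_next, "pending")
      active <- c(active[-i], c1, c2)
    } else if (u < lam + mu) {
      age[v] <- t_next; type[v] <- "death"
      active <- active[-i]
    } else {
      age[v] <- t_next; type[v] <- "fossil_sample"
      active <- active[-i]
    }
    if (length(parent) > 200000L) return(NULL)  # runaway
  }
  sampled <- which(type %in% c("fossil_sample", "extant_sample"))
  if (length(sampled) < 2L) return(NULL)
  prune_to_sampled(parent, age, type, sampled)
}

# reduce the full event tree to the binary tree spanning the sampled tips
prune_to_sampled <- function(parent, age, type, sampled) {
  n_all <- length(parent)
  nsampled_desc <- integer(n_all)
  ord <- order(age[seq_len(n_all)])  # youngest first: children before parents
  is_sampled <- seq_len(n_all) %in% sampled
  for (v in ord) {
    nsampled_desc[v] <- nsampled_desc[v] + is_sampled[v]
    p <- parent[v]
    if (!is.na(p)) nsampled_desc[p] <- nsampled_desc[p] + (nsampled_desc[v] > 0)
  }
  # internal nodes of the pruned tree: birth events with sampled tips on
  # both sides; a binary tree over ntip sampled tips has exactly ntip-1
  internal <- which(vapply(seq_len(n_all), function(v) {
    if (type[v] != "birth") return(FALSE)
    kids <- which(parent == v)
    sum(nsampled_desc[kids] > 0) >= 2L
  }, TRUE))
  ntip <- length(sampled)
  if (length(internal) != ntip - 1L) return(NULL)
  # order internals so the root (oldest branching) gets id ntip+1
  internal <- internal[order(-age[internal])]
  old_ids <- c(sampled, internal)
  new_id <- setNames(seq_along(old_ids), old_ids)
  np <- rep(NA_integer_, length(old_ids))
  for (i in seq_along(old_ids)) {
    p <- parent[old_ids[i]]
    while (!is.na(p) && !(p %in% internal)) p <- parent[p]
    if (!is.na(p)) np[i] <- new_id[[as.character(p)]]
  }
  if (sum(is.na(np)) != 1L) return(NULL)
  ages_new <- age[old_ids]
  labs <- sprintf("t%02d_%s", seq_len(ntip),
                  ifelse(type[sampled] == "extant_sample", "x", "f"))
  out <- tryCatch(dated_tree(np, ages_new, labs), error = function(e) NULL)
  out
}

#' Simulate an Mk character matrix on a dated tree
#'
#' The root state is drawn from the uniform stationary distribution and
#' states evolve along branches under the Mk transition probabilities, with
#' per-character rates drawn uniformly from the discrete-gamma categories.
#' With `variable_only`, constant characters are resimulated, emulating the
#' ascertainment condition of Mkv data.
#'
#' @param tree A [dated_tree()].
#' @param recipe A [simulation_recipe()].
#' @param variable_only Resimulate characters that come out constant.
#' @return A [character_matrix()].
#' @export
simulate_mk_matrix <- function(tree, recipe, variable_only = TRUE) {
  nchr <- recipe$n_characters
  kvec <- c(rep(3L, round(nchr * recipe$prop_ternary)))
  kvec <- c(kvec, rep(2L, nchr - length(kvec)))
  gam <- discrete_gamma_rates(recipe$gamma_shape, 4L)
  nn <- 2L * tree$ntip - 1L
  preorder <- order(-tree$ages)  # parents before children on a clock tree
  preorder <- preorder[preorder != tree$root]
  dat <- matrix(NA_integer_, tree$ntip, nchr,
                dimnames = list(tree$tip_labels, NULL))
  for (c_ in seq_len(nchr)) {
    k <- kvec[c_]
    repeat {
      r <- sample(gam$rates, 1L)
      states <- integer(nn)
      states[tree$root] <- sample.int(k, 1L) - 1L
      for (v in preorder) {
        t_ <- branch_duration(tree, v) * recipe$clock_rate * r
        P <- mk_transition_prob(k, t_)
        states[v] <- sample.int(k, 1L, prob = P[states[tree$parent[v]] + 1L, ]) - 1L
      }
      tipstates <- states[seq_len(tree$ntip)]
      if (!variable_only || length(unique(tipstates)) > 1L) break
    }
    dat[, c_] <- tipstates
  }
  if (recipe$missing_frac > 0) {
    mask <- matrix(runif(length(dat)) < recipe$missing_frac, nrow(dat))
    # never blank out a whole character
    for (c_ in seq_len(nchr)) if (all(mask[, c_])) mask[1, c_] <- FALSE
    dat[mask] <- NA_integer_
  }
  suppressWarnings(character_matrix(dat))
}

#' Rejection-sampling oracle for ordered site ages
#'
#' Draws each site age iid uniformly within its own bounds and keeps the
#' joint draw iff every stratigraphic relation is satisfied (below >= above).
#' This is the target distribution of the ordered site-age proposal and
#' serves as its independent test oracle.
#'
#' @param sites List of [fossil_site()].
#' @param seq A [strat_sequence()].
#' @param n Number of accepted joint samples.
#' @return A numeric matrix `n x nsites` with site ids as column names.
#' @export
rejection_sample_site_ages <- function(sites, seq, n) {
  ids <- vapply(sites, `[[`, "", "id")
  lo <- vapply(sites, `[[`, 0, "min_age")
  hi <- vapply(sites, `[[`, 0, "max_age")
  rel <- seq$relations
  bi <- match(rel[, 1L], ids); ai <- match(rel[, 2L], ids)
  out <- matrix(NA_real_, n, length(ids), dimnames = list(NULL, ids))
  got <- 0L; tried <- 0L
  batch <- max(1000L, n)
  while (got < n) {
    m <- matrix(runif(batch * length(ids), rep(lo, each = batch),
                      rep(hi, each = batch)), batch)
    ok <- rep(TRUE, batch)
    for (r in seq_along(bi)) ok <- ok & (m[, bi[r]] >= m[, ai[r]])
    tried <- tried + batch
    acc <- which(ok)
    if (length(acc)) {
      take <- acc[seq_len(min(length(acc), n - got))]
      out[got + seq_along(take), ] <- m[take, , drop = FALSE]
      got <- got + length(take)
    }
    if (tried > 1e6 && got / tried < 1e-6)
      stop("acceptance probability below 1e-6; incompatible bounds")
  }
  out
}

#' Generate a complete on-disk fixture dataset
#'
#' A scenario modelled on the motivating empirical setting: a birth-death
#' tree of around `target_tips` fossil taxa, two multi-taxon fossil sites
#' with identical bounds spanning the Lochkovian window (410.8-419.2 Ma) in
#' an ordered two-site sequence, remaining taxa with independent age windows,
#' and an Mk character matrix simulated on the true tree. Within each
#' multi-taxon site the true tip ages are exactly shared.
#'
#' @param seed Integer seed; the fixture is deterministic given the seed.
#' @param dir Output directory (created if needed).
#' @param recipe A [simulation_recipe()].
#' @param site_size Number of taxa per multi-taxon site.
#' @return Invisibly, a list with the true `tree`, `matrix`, `sites`, `seq`,
#'   true site ages, and the paths written (`matrix_path`, `sites_path`,
#'   `config_path`).
#' @export
make_fixture_dataset <- function(seed = 1L, dir = tempfile("fixture"),
                                 recipe = simulation_recipe(min_tips = 14L,
                                                            max_tips = 30L),
                                 site_size = 4L) {
  set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  window <- c(410.8, 419.2)
  for (try in 1:100) {
    tree <- simulate_bdss_tree(recipe)
    # candidate fossil tips whose parent is old enough for a shared site age
    tips <- seq_len(tree$ntip)
    fossil <- tips[tree$ages[tips] > 0]
    prep <- assign_shared_site_ages(tree, fossil, window, site_size)
    if (!is.null(prep)) break
    prep <- NULL
  }
  if (is.null(prep)) stop("could not place two shared-age sites; adjust recipe")
  tree <- prep$tree
  mat <- simulate_mk_matrix(tree, recipe)
  sites <- list(
    fossil_site("site_lower", tree$tip_labels[prep$site1], window[1], window[2],
                age = prep$age1),
    fossil_site("site_upper", tree$tip_labels[prep$site2], window[1], window[2],
                age = prep$age2))
  seq_ <- strat_sequence(below = "site_lower", above = "site_upper")
  # remaining fossil tips: independent +-2 Ma windows around the true age
  rest <- setdiff(which(tree$ages[seq_len(tree$ntip)] > 0),
                  c(prep$site1, prep$site2))
  for (v in rest) {
    a <- tree$ages[v]
    sites <- c(sites, list(fossil_site(tree$tip_labels[v], tree$tip_labels[v],
                                       max(0, a - 2), a + 2, age = a)))
  }
  matrix_path <- file.path(dir, "matrix.nex")
  sites_path <- file.path(dir, "sites.tsv")
  config_path <- file.path(dir, "analysis.cfg")
  write_nexus_matrix(mat, matrix_path)
  write_site_table(sites, seq_, sites_path)
  cfg <- analysis_config(matrix = matrix_path, sites = sites_path,
                         out = file.path(dir, "run"), seed = seed)
  write_config(cfg, config_path)
  invisible(list(tree = tree, matrix = mat, sites = sites, seq = seq_,
                 true_ages = c(lower = prep$age1, upper = prep$age2),
                 matrix_path = matrix_path, sites_path = sites_path,
                 config_path = config_path))
}

# pick two disjoint groups of fossil tips and snap each group to a shared
# age inside the window (lower site older), keeping the tree valid
assign_shared_site_ages <- function(tree, fossil, window, site_size) {
  parent_age <- tree$ages[tree$parent[fossil]]
  a1 <- runif(1, window[1] + 0.45 * diff(window), window[2] - 0.05 * diff(window))
  a2 <- runif(1, window[1] + 0.05 * diff(window), a1)
  ok1 <- fossil[parent_age > a1 + 0.1]
  if (length(ok1) < site_size) return(NULL)
  site1 <- sample(ok1, site_size)
  ok2 <- setdiff(fossil[parent_age > a2 + 0.1], site1)
  if (length(ok2) < site_size) return(NULL)
  site2 <- sample(ok2, site_size)
  tree$ages[site1] <- a1
  tree$ages[site2] <- a2
  if (length(tree_violations(tree))) return(NULL)
  list(tree = tree, site1 = site1, site2 = site2, age1 = a1, age2 = a2)
}
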