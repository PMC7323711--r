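# MCMC proposals. The two fossil-site proposals are the distinctive machinery
# of the package: a joint uniform redraw of the shared age of all tips from
# one fossil site, and the same move with stratigraphic-ordering rejection.
# The chain engine (src/engine.cpp) applies these same definitions in its
# inner loop; the functions here are the documented single-step surface.

new_proposal <- function(type, changes = list(), log_hastings = 0,
                         hard_reject = FALSE) {
  structure(list(type = type, changes = changes,
                 log_hastings = log_hastings, hard_reject = hard_reject),
            class = "mcmc_proposal")
}

#' Jointly propose a new age for all fossils of one site
#'
#' Draws one age uniformly within the site's stratigraphic bounds and applies
#' it to every tip of the site simultaneously, so fossils from one locality
#' can never drift apart in age. The draw is symmetric (log-Hastings 0). The
#' proposal is hard-rejected when any tip's new age would reach or exceed its
#' parent's age.
#'
#' @param state A chain state: list with elements `tree` (a [dated_tree()])
#'   and `sites` (list of [fossil_site()]).
#' @param site_id Id of the site to update.
#' @return An `mcmc_proposal`: `type`, `changes` (with `site_id` and the
#'   proposed `age`), `log_hastings`, `hard_reject`.
#' @export
propose_linked_site_age <- function(state, site_id) {
  s <- site_by_id(state$sites, site_id)
  a <- if (s$max_age > s$min_age) runif(1, s$min_age, s$max_age) else s$min_age
  tips <- match(s$taxa, state$tree$tip_labels)
  parents <- state$tree$parent[tips]
  reject <- any(a >= state$tree$ages[parents])
  new_proposal("linked_site_age",
               changes = list(site_id = s$id, age = a),
               log_hastings = 0, hard_reject = reject)
}

#' Propose a site age under stratigraphic ordering
#'
#' As [propose_linked_site_age()], with additional rejection (prior
#' probability zero) when the proposed age would invert the stratigraphic
#' sequence: older than the current age of any site below it, or younger than
#' the current age of any site above it. Exact ties are allowed. The
#' acceptable window therefore depends on the current ages of the
#' neighbouring sites and moves as the chain runs, which is what induces the
#' non-uniform effective prior on the ages of ordered sites.
#'
#' @inheritParams propose_linked_site_age
#' @param seq A [strat_sequence()].
#' @return An `mcmc_proposal`.
#' @export
propose_ordered_site_age <- function(state, site_id, seq) {
  pr <- propose_linked_site_age(state, site_id)
  if (pr$hard_reject) return(pr)
  a <- pr$changes$age
  ids <- vapply(state$sites, `[[`, "", "id")
  age_of <- setNames(vapply(state$sites, `[[`, 0, "age"), ids)
  rel <- seq$relations
  for (i in seq_len(nrow(rel))) {
    lo <- rel[i, 1L]; hi <- rel[i, 2L]
    if (lo == site_id && a < age_of[[hi]]) pr$hard_reject <- TRUE
    if (hi == site_id && a > age_of[[lo]]) pr$hard_reject <- TRUE
  }
  pr$type <- "ordered_site_age"
  pr
}

#' Apply an accepted site-age proposal to a chain state
#'
#' @param state A chain state (list with `tree`, `sites`).
#' @param proposal An `mcmc_proposal` from one of the site-age proposal
#'   functions; must not be hard-rejected.
#' @return The updated state.
#' @export
apply_site_age <- function(state, proposal) {
  if (proposal$hard_reject) stop("cannot apply a hard-rejected proposal")
  a <- proposal$changes$age
  i <- which(vapply(state$sites, `[[`, "", "id") == proposal$changes$site_id)
  state$sites[[i]]$age <- a
  tips <- match(state$sites[[i]]$taxa, state$tree$tip_labels)
  state$tree$ages[tips] <- a
  state
}

site_by_id <- function(sites, id) {
  i <- which(vapply(sites, `[[`, "", "id") == id)
  if (!length(i)) stop("unknown site id: ", id)
  sites[[i]]
}

#' Uniform slide of an internal node age
#'
#' Proposes a new age uniformly between the node's oldest child and its
#' parent; the window does not depend on the current age, so the move is
#' symmetric (log-Hastings 0) and always respects the tree's age ordering.
#'
#' @param state A chain state.
#' @param node Internal, non-root node id; chosen uniformly at random when
#'   `NULL`.
#' @return An `mcmc_proposal` with the `node` and its proposed `age`.
#' @export
propose_node_slide <- function(state, node = NULL) {
  tr <- state$tree
  cand <- setdiff(seq.int(tr$ntip + 1L, 2L * tr$ntip - 1L), tr$root)
  if (!length(cand)) return(new_proposal("node_slide", hard_reject = TRUE))
  if (is.null(node)) node <- cand[sample.int(length(cand), 1L)]
  kids <- which(tr$parent == node)
  lo <- max(tr$ages[kids])
  hi <- tr$ages[tr$parent[node]]
  new_proposal("node_slide",
               changes = list(node = node, age = runif(1, lo, hi)),
               log_hastings = 0)
}

#' Multiplicative scale proposal
#'
#' Standard scale move: a factor `f` drawn uniformly on `[1/beta, beta]`,
#' proposal `x' = f x`, log-Hastings `-log f`. With `beta = 1` the move is
#' the identity.
#'
#' @param value Current (positive) value.
#' @param beta Scale bound (>= 1).
#' @return An `mcmc_proposal` with the proposed `value`.
#' @export
propose_scale <- function(value, beta = 1.25) {
  if (beta < 1) stop("beta must be >= 1")
  f <- if (beta == 1) 1 else runif(1, 1 / beta, beta)
  new_proposal("scale", changes = list(value = value * f),
               log_hastings = -log(f))
}

#' Draw one standard proposal at random
#'
#' Dispatches among the standard (non-site) moves used by the chain engine:
#' internal-node age slide, root-gap scale, narrow exchange, scale moves on
#' each scalar parameter, origin-gap scale, a log-scale random walk on one
#' branch-rate multiplier, a non-centered joint scale of the clock standard
#' deviation and all branch-rate multipliers (holding their standardized
#' latents fixed, which lets the chain traverse the sd-multiplier funnel),
#' a uniform redraw of the gamma shape over its bounded prior range, and an
#' additive random walk on the clock rate. Returned
#' proposals carry the components they would modify and their log-Hastings
#' ratios; they are not applied to the state.
#'
#' @param state A chain state: list with `tree` and `params`
#'   (a [model_params()]).
#' @return An `mcmc_proposal`.
#' @export
standard_proposals <- function(state) {
  scalars <- c("clock_rate", "clock_sd", "gamma_shape", "birth_rate",
               "death_rate", "sampling_rate")
  kinds <- c("node_slide", "root_scale", "narrow_exchange",
             paste0("scale_", scalars), "origin_scale", "rate_walk",
             "clock_sd_joint", "shape_uniform", "clock_rate_walk")
  kind <- kinds[sample.int(length(kinds), 1L)]
  tr <- state$tree
  if (kind == "node_slide") return(propose_node_slide(state))
  if (kind == "root_scale") {
    kids <- which(tr$parent == tr$root)
    mc <- max(tr$ages[kids])
    f <- exp(runif(1, -log(1.25), log(1.25)))
    age <- mc + f * (tr$ages[tr$root] - mc)
    reject <- !is.null(state$params) && age >= state$params$origin_age
    return(new_proposal("root_scale", changes = list(node = tr$root, age = age),
                        log_hastings = log(f), hard_reject = reject))
  }
  if (kind == "narrow_exchange") {
    cand <- setdiff(seq.int(tr$ntip + 1L, 2L * tr$ntip - 1L), tr$root)
    if (!length(cand)) return(new_proposal(kind, hard_reject = TRUE))
    P <- cand[sample.int(length(cand), 1L)]
    G <- tr$parent[P]
    sibs <- which(tr$parent == G)
    A <- sibs[sibs != P]
    kids <- which(tr$parent == P)
    C <- kids[sample.int(2L, 1L)]
    return(new_proposal("narrow_exchange",
                        changes = list(node = P, aunt = A, child = C),
                        log_hastings = 0,
                        hard_reject = tr$ages[A] >= tr$ages[P]))
  }
  if (kind == "origin_scale") {
    f <- exp(runif(1, -log(1.25), log(1.25)))
    age <- tr$ages[tr$root] + f * (state$params$origin_age - tr$ages[tr$root])
    return(new_proposal("origin_scale", changes = list(origin_age = age),
                        log_hastings = log(f)))
  }
  if (kind == "rate_walk") {
    cand <- setdiff(seq_len(2L * tr$ntip - 1L), tr$root)
    v <- cand[sample.int(length(cand), 1L)]
    u <- runif(1, -0.5, 0.5)
    return(new_proposal("rate_walk",
                        changes = list(node = v,
                                       value = state$params$branch_rates[v] * exp(u)),
                        log_hastings = u))
  }
  if (kind == "clock_sd_joint") {
    f <- exp(runif(1, -log(1.25), log(1.25)))
    sd <- state$params$clock_sd
    sd2 <- f * sd
    m <- state$params$branch_rates
    nonroot <- which(!is.na(m))
    z <- (log(m[nonroot]) + sd^2 / 2) / sd
    m2 <- m
    m2[nonroot] <- exp(sd2 * z - sd2^2 / 2)
    lj <- (length(nonroot) + 1) * log(f) +
      sum(log(m2[nonroot]) - log(m[nonroot]))
    return(new_proposal("clock_sd_joint",
                        changes = list(clock_sd = sd2, branch_rates = m2),
                        log_hastings = lj))
  }
  if (kind == "shape_uniform") {
    return(new_proposal("shape_uniform",
                        changes = list(param = "gamma_shape",
                                       value = runif(1, 0, 10)),
                        log_hastings = 0))
  }
  if (kind == "clock_rate_walk") {
    return(new_proposal("clock_rate_walk",
                        changes = list(param = "clock_rate",
                                       value = state$params$clock_rate +
                                         runif(1, -0.006, 0.006)),
                        log_hastings = 0))
  }
  nm <- sub("^scale_", "", kind)
  pr <- propose_scale(state$params[[nm]])
  pr$type <- kind
  pr$changes <- list(param = nm, value = pr$changes$value)
  pr
}
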