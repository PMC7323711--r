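# Metropolis-Hastings driver over the C++ engine: state initialisation,
# operator weighting, trace assembly, multi-run support.

# default standard operator weights, in engine order
std_weight_names <- c("node_slide", "root_scale", "narrow_exchange",
                      "scale_clock_rate", "scale_clock_sd", "scale_shape",
                      "scale_birth", "scale_death", "scale_sampling",
                      "origin_scale", "rate_walk", "clock_sd_joint",
                      "shape_uniform", "clock_rate_walk")

default_std_weights <- function(ntip) {
  w <- c(node_slide = max(1, ntip - 2), root_scale = 2,
         narrow_exchange = max(1, ntip - 2),
         scale_clock_rate = 2, scale_clock_sd = 2, scale_shape = 2,
         scale_birth = 1, scale_death = 1, scale_sampling = 1,
         origin_scale = 1, rate_walk = max(1, ntip),
         clock_sd_joint = 3, shape_uniform = 2, clock_rate_walk = 2)
  w[std_weight_names]
}

#' Expand sites so every taxon has one and unassigned taxa get their own
#'
#' Taxa not listed in any site are given an individual single-taxon site with
#' degenerate bounds at their current age (a fixed tip date). With
#' `unlink = TRUE`, multi-taxon sites are additionally exploded into
#' single-taxon sites sharing the original bounds — the "independent tip
#' ages" analysis mode.
#'
#' @param tree A [dated_tree()].
#' @param sites List of [fossil_site()].
#' @param unlink Explode multi-taxon sites into per-taxon sites.
#' @return A list of [fossil_site()] covering every tip exactly once.
#' @export
complete_sites <- function(tree, sites, unlink = FALSE) {
  if (unlink) {
    sites <- unlist(lapply(sites, function(s) {
      lapply(s$taxa, function(tx)
        fossil_site(if (length(s$taxa) > 1L) tx else s$id, tx,
                    s$min_age, s$max_age,
                    age = min(max(s$age, s$min_age), s$max_age)))
    }), recursive = FALSE)
  }
  assigned <- unlist(lapply(sites, `[[`, "taxa"))
  extra <- setdiff(tree$tip_labels, assigned)
  ages <- setNames(tree$ages[seq_len(tree$ntip)], tree$tip_labels)
  c(sites, lapply(extra, function(tx)
    fossil_site(tx, tx, ages[[tx]], ages[[tx]])))
}

# topological-depth initial ages: below-sites start older than above-sites
init_site_ages <- function(sites, seq) {
  ids <- vapply(sites, `[[`, "", "id")
  rel <- seq$relations
  depth_below <- setNames(rep(0L, length(ids)), ids)  # # sites below (longest chain)
  depth_above <- setNames(rep(0L, length(ids)), ids)
  changed <- TRUE; iter <- 0L
  while (changed && iter < length(ids) + 2L) {
    changed <- FALSE; iter <- iter + 1L
    for (i in seq_len(nrow(rel))) {
      lo <- rel[i, 1L]; hi <- rel[i, 2L]
      if (depth_below[[hi]] < depth_below[[lo]] + 1L) {
        depth_below[[hi]] <- depth_below[[lo]] + 1L; changed <- TRUE
      }
      if (depth_above[[lo]] < depth_above[[hi]] + 1L) {
        depth_above[[lo]] <- depth_above[[hi]] + 1L; changed <- TRUE
      }
    }
  }
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    if (s$max_age > s$min_age) {
      da <- depth_above[[s$id]]; db <- depth_below[[s$id]]
      frac <- (da + 1) / (da + db + 2)
      sites[[i]]$age <- s$min_age + frac * (s$max_age - s$min_age)
    }
  }
  sites
}

#' Build a random starting tree above given tip ages
#'
#' Sequentially joins random pairs of subtrees at an age above both of their
#' roots, yielding a valid serially-sampled starting topology for any set of
#' tip dates.
#'
#' @param tip_ages Named numeric vector (names = tip labels).
#' @param step Mean of the exponential gap added above each join (Ma).
#' @return A [dated_tree()].
#' @export
random_start_tree <- function(tip_ages, step = 2) {
  n <- length(tip_ages)
  if (n < 2L) stop("need at least 2 tips")
  nn <- 2L * n - 1L
  parent <- rep(NA_integer_, nn)
  ages <- c(as.numeric(tip_ages), rep(NA_real_, n - 1L))
  roots <- seq_len(n)                      # current subtree roots
  next_id <- 2L * n - 1L                   # fill internals from the top down,
  pending <- integer(0)                    # so the final join lands on n+1
  joins <- list()
  while (length(roots) > 1L) {
    pick <- sample.int(length(roots), 2L)
    a <- roots[pick[1]]; b <- roots[pick[2]]
    id <- if (length(roots) == 2L) n + 1L else next_id
    next_id <- next_id - 1L
    ages[id] <- max(ages[a], ages[b]) + rexp(1, 1 / step)
    parent[c(a, b)] <- id
    roots <- c(roots[-pick], id)
    pending <- c(pending, id)
  }
  dated_tree(parent, ages, names(tip_ages))
}

#' Run a Metropolis-Hastings tip-dating chain
#'
#' The chain samples tree topology, all node ages (tip ages through the
#' fossil-site proposals), the relaxed-clock parameters, the gamma shape and
#' the birth-death-sampling parameters. Acceptance probability is
#' `min(1, exp(delta log-posterior + log-Hastings))`; proposals flagged as
#' hard rejections (site ages violating a parent age or the stratigraphic
#' ordering) count as rejections. The state at generation 0 and at every
#' `log_interval` generations is logged. Fully reproducible from
#' `config$seed`.
#'
#' @param config An [analysis_config()].
#' @param data A list with elements `matrix` (a [character_matrix()]; may be
#'   `NULL` with `prior_only`), `sites` (list of [fossil_site()]), `seq`
#'   (a [strat_sequence()], optional) and optionally `tree` (a
#'   [dated_tree()] starting tree; one is built when absent).
#' @return A list of class `chain_result`: `trace` (data frame, one row per
#'   logged sample), `trees` (list of [dated_tree()] at the same samples),
#'   `acceptance` (per-operator proposed/accepted counts), `sites`, `seq`,
#'   `config`.
#' @export
run_chain <- function(config, data) {
  set.seed(config$seed)
  seq_ <- if (!is.null(data$seq)) data$seq else strat_sequence()
  # independent-tip-age mode dissolves multi-taxon sites, and with them any
  # ordering relations defined between sites
  if (!config$linked) seq_ <- strat_sequence()
  sites <- data$sites
  mat <- data$matrix

  # tree: supplied or constructed above the initial site ages
  if (is.null(data$tree)) {
    taxa <- if (!is.null(mat)) mat$taxa else unlist(lapply(sites, `[[`, "taxa"))
    tmp_sites <- init_site_ages(
      complete_sites(dated_tree_stub(taxa), sites, unlink = !config$linked), seq_)
    tip_ages <- setNames(rep(0, length(taxa)), taxa)
    for (s in tmp_sites) tip_ages[s$taxa] <- s$age
    tree <- random_start_tree(tip_ages)
  } else {
    tree <- data$tree
  }
  sites <- complete_sites(tree, sites, unlink = !config$linked)
  sites <- init_site_ages(sites, seq_)
  # synchronise tip ages with the initial site ages; when a supplied tree
  # cannot accommodate the default starting age, fall back to an age the
  # tree already satisfies
  for (i in seq_along(sites)) {
    s <- sites[[i]]
    tips <- match(s$taxa, tree$tip_labels)
    pa <- tree$ages[tree$parent[tips]]
    a <- s$age
    if (any(a >= pa)) {
      a <- min(max(min(tree$ages[tips]), s$min_age), s$max_age)
      if (any(a >= pa))
        stop("zero-probability initial state: site ", s$id,
             " admits no age below its taxa's parent ages within bounds")
    }
    sites[[i]]$age <- a
    tree$ages[tips] <- a
  }
  bad <- validate_state(tree, sites, seq_)
  if (length(bad))
    stop("zero-probability initial state: ", paste(bad, collapse = "; "))

  nn <- 2L * tree$ntip - 1L
  params <- model_params(
    clock_rate = config$priors$clock_rate_offset + config$priors$clock_rate_mean,
    clock_sd = 0.5, gamma_shape = 1,
    birth_rate = config$priors$birth_meanreal,
    death_rate = config$priors$death_mean,
    sampling_rate = config$priors$sampling_mean,
    origin_age = tree$ages[tree$root] + 4,
    branch_rates = replace(rep(1, nn), tree$root, NA))

  res <- engine_call(tree, sites, seq_, params, mat, config)
  ids <- vapply(sites, `[[`, "", "id")
  trace <- as.data.frame(res$trace)
  names(trace) <- c("Sample", "posterior", "likelihood", "prior",
                    "clock_rate", "clock_sd", "gamma_shape", "birth_rate",
                    "death_rate", "sampling_rate", "origin_age", "root_age",
                    paste0("age_", ids))
  opn <- c(paste0("site_", ids), std_weight_names)
  acc <- data.frame(operator = opn, proposed = res$proposed,
                    accepted = res$accepted)
  acc$rate <- ifelse(acc$proposed > 0, acc$accepted / acc$proposed, NA)
  if (config$chain_length > 0 && all(acc$accepted[acc$proposed > 0] == 0))
    warning("all operators have acceptance rate 0; the chain has not moved")
  trees <- unpack_trees(res, tree$tip_labels)
  structure(list(trace = trace, trees = trees, acceptance = acc,
                 sites = sites, seq = seq_, config = config),
            class = "chain_result")
}

# minimal tree-shaped object for taxon bookkeeping before the real tree exists
dated_tree_stub <- function(taxa) {
  list(ntip = length(taxa), tip_labels = taxa,
       ages = rep(0, 2L * length(taxa) - 1L),
       parent = rep(NA_integer_, 2L * length(taxa) - 1L))
}

engine_call <- function(tree, sites, seq_, params, mat, config) {
  ids <- vapply(sites, `[[`, "", "id")
  parent0 <- tree$parent - 1L
  parent0[tree$root] <- -1L
  site_tips <- lapply(sites, function(s) match(s$taxa, tree$tip_labels) - 1L)
  smin <- vapply(sites, `[[`, 0, "min_age")
  smax <- vapply(sites, `[[`, 0, "max_age")
  sage <- vapply(sites, `[[`, 0, "age")
  sw <- vapply(sites, function(s) length(s$taxa) * (s$max_age > s$min_age), 0)
  rel <- seq_$relations
  rb <- match(rel[, 1L], ids) - 1L
  ra <- match(rel[, 2L], ids) - 1L
  if (is.null(mat)) {
    dat <- matrix(NA_integer_, tree$ntip, 0L)
    kvec <- integer(0)
  } else {
    dat <- mat$data[match(tree$tip_labels, mat$taxa), , drop = FALSE]
    kvec <- mat$k
  }
  wts <- default_std_weights(tree$ntip)
  if (!is.null(config$weights)) {
    unknown <- setdiff(names(config$weights), std_weight_names)
    if (length(unknown)) stop("unknown operator weight: ", unknown[1])
    wts[names(config$weights)] <- config$weights
  }
  pv <- c(params$clock_rate, params$clock_sd, params$gamma_shape,
          params$birth_rate, params$death_rate, params$sampling_rate)
  attr(pv, "hyper") <- hyper_vector(config$priors)
  mult <- params$branch_rates
  mult[tree$root] <- 1
  C_engine_run(parent0, tree$ntip, tree$ages, mult, pv, params$origin_age,
               site_tips, smin, smax, sage, sw,
               as.integer(rb), as.integer(ra),
               dat, as.integer(kvec), config$ncat,
               config$conditioning == "variable", config$prior_only,
               config$fix_tree, unname(wts), 1.25, 0.5,
               as.numeric(config$chain_length), as.integer(config$log_interval))
}

unpack_trees <- function(res, tip_labels) {
  n <- nrow(res$parents)
  lapply(seq_len(n), function(i) {
    parent <- res$parents[i, ]
    parent[parent == 0L] <- NA_integer_
    dated_tree(parent, res$ages[i, ], tip_labels)
  })
}

#' Sample from the prior
#'
#' Identical machinery to [run_chain()] with the data likelihood replaced by
#' a constant, exposing the effective prior on tip dates and parameters.
#'
#' @inheritParams run_chain
#' @return A `chain_result`; see [run_chain()].
#' @export
sample_prior <- function(config, data) {
  config$prior_only <- TRUE
  run_chain(config, data)
}

#' Discard burn-in from a chain trace
#'
#' @param x A `chain_result` or a trace data frame.
#' @param burnin Fraction of samples to drop from the start (default: the
#'   run's configured burn-in).
#' @return An object of the same type with the initial samples removed.
#' @export
discard_burnin <- function(x, burnin = NULL) {
  if (inherits(x, "chain_result")) {
    if (is.null(burnin)) burnin <- x$config$burnin
    keep <- seq.int(floor(nrow(x$trace) * burnin) + 1L, nrow(x$trace))
    x$trace <- x$trace[keep, , drop = FALSE]
    x$trees <- x$trees[keep]
    return(x)
  }
  if (is.null(burnin)) burnin <- 0.10
  x[seq.int(floor(nrow(x) * burnin) + 1L, nrow(x)), , drop = FALSE]
}

#' @export
print.chain_result <- function(x, ...) {
  cat(sprintf("chain_result: %d logged samples, %d sites, %d tips\n",
              nrow(x$trace), length(x$sites), x$trees[[1]]$ntip))
  invisible(x)
}
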