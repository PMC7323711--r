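# Core state types: dated trees, character matrices, fossil sites,
# stratigraphic sequences and model parameters. Ages are in Ma before
# present and increase into the past; "younger" means numerically smaller.

#' Construct a dated phylogenetic tree
#'
#' A `dated_tree` is a rooted, strictly binary tree whose every node carries an
#' absolute age in Ma before present. Tips may have non-zero ages (fossils).
#' Node ids follow the `ape` convention: tips are `1..ntip`, the root is
#' `ntip + 1`, internal nodes are `ntip + 1 .. 2 * ntip - 1`.
#'
#' @param parent Integer vector of length `2 * ntip - 1`; `parent[i]` is the
#'   parent node id of node `i`, `NA` for the root.
#' @param ages Numeric vector of node ages (Ma before present), same length.
#' @param tip_labels Character vector of `ntip` unique, non-empty tip labels.
#' @return An object of class `dated_tree` with elements `ntip`, `parent`,
#'   `ages`, `tip_labels` and `root` (the root node id).
#' @examples
#' tr <- dated_tree(parent = c(5L, 5L, 4L, NA, 4L),
#'                  ages = c(415, 415, 410, 425, 420),
#'                  tip_labels = c("A", "B", "C"))
#' branch_duration(tr, 1L)
#' @export
dated_tree <- function(parent, ages, tip_labels) {
  tr <- structure(
    list(ntip = length(tip_labels), parent = as.integer(parent),
         ages = as.numeric(ages), tip_labels = as.character(tip_labels),
         root = which(is.na(parent))[1]),
    class = "dated_tree")
  bad <- tree_violations(tr)
  if (length(bad)) stop("invalid dated_tree: ", paste(bad, collapse = "; "))
  tr
}

# Violation descriptors for a candidate tree; character(0) when valid.
tree_violations <- function(tr) {
  out <- character(0)
  n <- tr$ntip
  nn <- 2L * n - 1L
  if (length(tr$parent) != nn || length(tr$ages) != nn)
    return("tree: parent/ages length must be 2*ntip-1")
  roots <- which(is.na(tr$parent))
  if (length(roots) != 1L)
    out <- c(out, sprintf("tree: expected exactly one root, found %d", length(roots)))
  if (anyNA(tr$ages) || any(tr$ages < 0))
    out <- c(out, "tree: ages must be real and >= 0")
  if (anyDuplicated(tr$tip_labels) || any(!nzchar(tr$tip_labels)))
    out <- c(out, "tree: tip labels must be unique and non-empty")
  kids <- tabulate(tr$parent[!is.na(tr$parent)], nbins = nn)
  if (any(kids[seq_len(n)] != 0L))
    out <- c(out, "tree: tips must have no children")
  internal <- setdiff(seq.int(n + 1L, nn), integer(0))
  if (n >= 2L && any(kids[internal] != 2L))
    out <- c(out, sprintf("tree: internal node(s) %s must have exactly 2 children",
                          paste(internal[kids[internal] != 2L], collapse = ",")))
  nonroot <- which(!is.na(tr$parent))
  bad_age <- nonroot[tr$ages[tr$parent[nonroot]] <= tr$ages[nonroot]]
  if (length(bad_age))
    out <- c(out, sprintf("tree: node(s) %s not strictly younger than parent",
                          paste(bad_age, collapse = ",")))
  # reachability: every node must reach the root (no cycles/orphans)
  if (length(roots) == 1L) {
    for (i in seq_len(nn)) {
      v <- i; steps <- 0L
      while (!is.na(tr$parent[v]) && steps <= nn) { v <- tr$parent[v]; steps <- steps + 1L }
      if (v != roots[1]) { out <- c(out, sprintf("tree: node %d unreachable from root", i)); break }
    }
  }
  out
}

#' Duration of the branch subtending a node
#'
#' @param tree A [dated_tree()].
#' @param node A node id (must not be the root).
#' @return Branch duration `age(parent) - age(node)` in Ma (> 0).
#' @export
branch_duration <- function(tree, node) {
  p <- tree$parent[node]
  if (any(is.na(p))) stop("root has no branch")
  tree$ages[p] - tree$ages[node]
}

#' Construct a discrete character matrix
#'
#' States are non-negative integers, `NA` is missing. The per-character state
#' count `k` is taken from the observed states only (`max + 1`) and forced to
#' at least 2, so that characters rendered invariant by missing data remain
#' valid binary characters under the Mk model.
#'
#' @param data Integer matrix, taxa in rows (rownames are taxon labels),
#'   characters in columns; `NA` encodes missing (`?`).
#' @param warn_invariant Warn about characters with fewer than two observed
#'   states (their `k` is forced to 2).
#' @return An object of class `character_matrix` with elements `taxa`, `data`
#'   and `k` (integer vector of per-character state counts).
#' @export
character_matrix <- function(data, warn_invariant = TRUE) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  if (is.null(rownames(data))) stop("data must have taxon rownames")
  if (anyDuplicated(rownames(data))) stop("duplicate taxon labels")
  if (any(data < 0L, na.rm = TRUE)) stop("states must be non-negative integers")
  nobs <- apply(data, 2L, function(x) sum(!is.na(x)))
  if (any(nobs == 0L))
    stop("character(s) ", paste(which(nobs == 0L), collapse = ","), " are all-missing")
  kmax <- apply(data, 2L, function(x) max(x, na.rm = TRUE)) + 1L
  ndistinct <- apply(data, 2L, function(x) length(unique(x[!is.na(x)])))
  if (warn_invariant && any(ndistinct < 2L))
    warning("character(s) ", paste(which(ndistinct < 2L), collapse = ","),
            " have fewer than 2 observed states; treating as binary (k = 2)")
  structure(list(taxa = rownames(data), data = data,
                 k = pmax(as.integer(kmax), 2L)),
            class = "character_matrix")
}

#' Construct a fossil site
#'
#' A fossil site is a set of fossil tips that share one age parameter, with
#' uniform age bounds. Taxa not assigned to any site are handled by giving
#' each its own single-taxon site, which makes an "independent tip ages"
#' analysis a special case of the site machinery.
#'
#' @param id Site identifier (character scalar).
#' @param taxa Character vector (length >= 1) of tip labels at the site.
#' @param min_age,max_age Uniform age bounds in Ma, `min_age <= max_age`.
#' @param age Current shared age; defaults to the bound midpoint.
#' @return An object of class `fossil_site`.
#' @export
fossil_site <- function(id, taxa, min_age, max_age, age = (min_age + max_age) / 2) {
  if (length(taxa) < 1L) stop("a fossil site needs at least one taxon")
  if (min_age > max_age) stop("min_age must not exceed max_age")
  if (age < min_age || age > max_age) stop("age must lie within [min_age, max_age]")
  structure(list(id = as.character(id), taxa = as.character(taxa),
                 min_age = min_age, max_age = max_age, age = age),
            class = "fossil_site")
}

#' Construct a stratigraphic sequence
#'
#' Ordered relations between fossil sites: a pair `(below, above)` states that
#' `below` is stratigraphically beneath `above`, hence at least as old. The
#' relation graph must be acyclic.
#'
#' @param below,above Character vectors of equal length with site ids.
#' @return An object of class `strat_sequence` holding a two-column character
#'   matrix `relations`.
#' @export
strat_sequence <- function(below = character(0), above = character(0)) {
  if (length(below) != length(above)) stop("below/above must have equal length")
  rel <- cbind(below = as.character(below), above = as.character(above))
  if (has_cycle(rel)) stop("cyclic stratigraphic sequence")
  structure(list(relations = rel), class = "strat_sequence")
}

# DFS cycle detection on the below -> above relation graph.
has_cycle <- function(rel) {
  if (nrow(rel) == 0L) return(FALSE)
  nodes <- unique(c(rel[, 1L], rel[, 2L]))
  state <- setNames(rep(0L, length(nodes)), nodes)  # 0 new, 1 open, 2 done
  adj <- split(rel[, 2L], factor(rel[, 1L], levels = nodes))
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  for (v in nodes) if (visit(v)) return(TRUE)
  FALSE
}

#' Construct the full set of free model parameters
#'
#' @param clock_rate Base clock rate (expected substitutions per character per
#'   Ma).
#' @param clock_sd Standard deviation (sdlog) of the lognormal branch-rate
#'   multipliers of the uncorrelated relaxed clock.
#' @param gamma_shape Shape of the discrete-gamma among-character rate
#'   distribution.
#' @param birth_rate,death_rate,sampling_rate Birth-death-sampling rates
#'   (per lineage per Ma).
#' @param origin_age Age of the origin of the process (Ma; must exceed the
#'   root age of the tree it is used with).
#' @param branch_rates Numeric vector of per-branch rate multipliers indexed
#'   by node id (`NA` at the root), all > 0.
#' @return An object of class `model_params`.
#' @export
model_params <- function(clock_rate, clock_sd, gamma_shape, birth_rate,
                         death_rate, sampling_rate, origin_age, branch_rates) {
  p <- structure(list(clock_rate = clock_rate, clock_sd = clock_sd,
                      gamma_shape = gamma_shape, birth_rate = birth_rate,
                      death_rate = death_rate, sampling_rate = sampling_rate,
                      origin_age = origin_age,
                      branch_rates = as.numeric(branch_rates)),
                 class = "model_params")
  bad <- params_violations(p)
  if (length(bad)) stop("invalid model_params: ", paste(bad, collapse = "; "))
  p
}

params_violations <- function(p) {
  out <- character(0)
  for (nm in c("clock_rate", "clock_sd", "gamma_shape", "birth_rate",
               "death_rate", "sampling_rate"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      out <- c(out, sprintf("params: %s must be > 0", nm))
  br <- p$branch_rates[!is.na(p$branch_rates)]
  if (any(!is.finite(br)) || any(br <= 0))
    out <- c(out, "params: branch-rate multipliers must be > 0")
  out
}

#' Validate a full chain state
#'
#' Diagnostic check of every structural invariant: tree shape and age ordering,
#' site bounds and membership, tip/site age synchrony, stratigraphic ordering,
#' and parameter positivity. Never throws; returns a character vector of
#' violation descriptors, empty when the state is valid.
#'
#' @param tree A [dated_tree()].
#' @param sites List of [fossil_site()] objects.
#' @param seq A [strat_sequence()] (optional).
#' @param params A [model_params()] (optional).
#' @return Character vector of violations; `character(0)` if valid.
#' @export
validate_state <- function(tree, sites, seq = strat_sequence(), params = NULL) {
  out <- tree_violations(tree)
  ids <- vapply(sites, `[[`, "", "id")
  if (anyDuplicated(ids)) out <- c(out, "sites: duplicate site ids")
  all_taxa <- unlist(lapply(sites, `[[`, "taxa"))
  if (anyDuplicated(all_taxa))
    out <- c(out, sprintf("sites: taxon %s in more than one site",
                          paste(unique(all_taxa[duplicated(all_taxa)]), collapse = ",")))
  age_of <- setNames(tree$ages[seq_len(tree$ntip)], tree$tip_labels)
  for (s in sites) {
    if (s$min_age > s$max_age)
      out <- c(out, sprintf("site %s: min_age > max_age", s$id))
    if (s$age < s$min_age || s$age > s$max_age)
      out <- c(out, sprintf("site %s: age outside bounds", s$id))
    missing <- setdiff(s$taxa, tree$tip_labels)
    if (length(missing)) {
      out <- c(out, sprintf("site %s: taxa not in tree: %s", s$id,
                            paste(missing, collapse = ",")))
      next
    }
    tip_ages <- age_of[s$taxa]
    if (any(abs(tip_ages - s$age) > 1e-9))
      out <- c(out, sprintf("site-age-desync: site %s tips not all at site age", s$id))
  }
  site_age <- setNames(vapply(sites, `[[`, 0, "age"), ids)
  rel <- seq$relations
  for (i in seq_len(nrow(rel))) {
    lo <- rel[i, 1L]; hi <- rel[i, 2L]
    if (!lo %in% ids || !hi %in% ids) {
      out <- c(out, sprintf("ordering: relation references unknown site %s",
                            if (lo %in% ids) hi else lo))
    } else if (site_age[[lo]] < site_age[[hi]]) {
      out <- c(out, sprintf("ordering: site %s (below) younger than site %s (above)", lo, hi))
    }
  }
  if (!is.null(params)) {
    out <- c(out, params_violations(params))
    if (is.finite(params$origin_age) && params$origin_age <= tree$ages[tree$root])
      out <- c(out, "params: origin_age must exceed root age")
  }
  out
}

#' Convert a dated tree to an ape \code{phylo} object
#'
#' Branch lengths are branch durations in Ma; the absolute age scale is
#' anchored by storing the root age in \code{root.edge}.
#'
#' @param tree A [dated_tree()].
#' @return An object of class `phylo`.
#' @export
as_phylo <- function(tree) {
  nonroot <- which(!is.na(tree$parent))
  phy <- list(edge = cbind(tree$parent[nonroot], nonroot),
              edge.length = tree$ages[tree$parent[nonroot]] - tree$ages[nonroot],
              tip.label = tree$tip_labels,
              Nnode = tree$ntip - 1L,
              root.edge = tree$ages[tree$root])
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Convert an ape \code{phylo} object to a dated tree
#'
#' @param phy A rooted, binary `phylo` with branch lengths in Ma.
#' @param root_age Absolute root age; defaults to `phy$root.edge` when present,
#'   otherwise chosen so the youngest tip sits at age 0.
#' @return A [dated_tree()].
#' @export
dated_tree_from_phylo <- function(phy, root_age = NULL) {
  if (!ape::is.binary(phy) || !ape::is.rooted(phy))
    stop("phy must be a rooted binary tree")
  depth <- ape::node.depth.edgelength(phy)
  if (is.null(root_age)) {
    root_age <- if (!is.null(phy$root.edge)) phy$root.edge else max(depth[seq_len(ape::Ntip(phy))])
  }
  nn <- ape::Ntip(phy) + phy$Nnode
  parent <- rep(NA_integer_, nn)
  parent[phy$edge[, 2L]] <- phy$edge[, 1L]
  dated_tree(parent = parent, ages = root_age - depth, tip_labels = phy$tip.label)
}

#' @export
print.dated_tree <- function(x, ...) {
  cat(sprintf("dated_tree: %d tips, root age %.4f Ma (tips %.4f-%.4f Ma)\n",
              x$ntip, x$ages[x$root],
              min(x$ages[seq_len(x$ntip)]), max(x$ages[seq_len(x$ntip)])))
  invisible(x)
}

#' @export
print.character_matrix <- function(x, ...) {
  cat(sprintf("character_matrix: %d taxa x %d characters, %d missing cells\n",
              nrow(x$data), ncol(x$data), sum(is.na(x$data))))
  invisible(x)
}

#' @export
print.fossil_site <- function(x, ...) {
  cat(sprintf("fossil_site %s: %d taxa, bounds [%.2f, %.2f] Ma, age %.4f\n",
              x$id, length(x$taxa), x$min_age, x$max_age, x$age))
  invisible(x)
}
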