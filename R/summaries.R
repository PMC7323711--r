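# Posterior summarization: HPD intervals, inter-site age comparisons,
# per-sample age spreads, ESS, majority-rule consensus.

#' Highest posterior density interval (Chen-Shao)
#'
#' The shortest interval containing `ceiling(level * n)` of the sorted
#' samples.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param level Credibility level in (0, 1]; default 0.95.
#' @return Named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (!length(samples)) stop("empty input")
  if (length(samples) < 2L) stop("need at least 2 samples")
  if (level <= 0 || level > 1) stop("level must be in (0, 1]")
  x <- sort(samples)
  n <- length(x)
  m <- min(n, ceiling(level * n))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- starts[which.min(widths)]
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Posterior probability that one age series is younger than another
#'
#' Fraction of paired samples in which `ages_a < ages_b`; exact ties count
#' one half.
#'
#' @param ages_a,ages_b Paired numeric series of equal length.
#' @return A fraction in `[0, 1]`.
#' @export
prob_younger <- function(ages_a, ages_b) {
  if (length(ages_a) != length(ages_b)) stop("length mismatch")
  mean((ages_a < ages_b) + 0.5 * (ages_a == ages_b))
}

#' Mean within-sample age spread of a set of taxa
#'
#' For taxa with independent age columns in a trace, the mean over samples of
#' `max - min` of their ages — the "average range" a fossil site's taxa are
#' spread over when their tip dates are unlinked. For linked-age runs the
#' spread is exactly 0.
#'
#' @param trace A trace data frame with one `age_<taxon>` column per taxon.
#' @param taxa Character vector of taxon (or site) names.
#' @return Mean age range in Ma.
#' @export
per_sample_age_range <- function(trace, taxa) {
  cols <- paste0("age_", taxa)
  missing <- setdiff(cols, names(trace))
  if (length(missing)) stop("unknown taxon column(s): ",
                            paste(missing, collapse = ","))
  if (length(cols) == 1L) return(0)
  m <- as.matrix(trace[, cols, drop = FALSE])
  mean(apply(m, 1L, max) - apply(m, 1L, min))
}

#' Majority-rule consensus tree with clade posterior frequencies
#'
#' Clades appearing in more than `threshold` of the input trees are retained
#' (via [ape::consensus()]); each internal node of the consensus is labelled
#' with its clade frequency. The output is strictly compatible by
#' construction and may contain polytomies.
#'
#' @param trees List of [dated_tree()] or `phylo` objects on one taxon set.
#' @param threshold Minimum clade frequency (default 0.5).
#' @return A `phylo` with node labels giving clade frequencies.
#' @export
majority_consensus <- function(trees, threshold = 0.5) {
  if (!length(trees)) stop("need at least 1 tree")
  phys <- lapply(trees, function(tr)
    if (inherits(tr, "phylo")) tr else as_phylo(tr))
  tax <- sort(phys[[1]]$tip.label)
  for (p in phys)
    if (!identical(sort(p$tip.label), tax)) stop("trees have differing taxon sets")
  class(phys) <- "multiPhylo"
  cons <- ape::consensus(phys, p = max(threshold, 0.5 + 1e-9), rooted = TRUE)
  pp <- ape::prop.part(phys)
  labs <- attr(pp, "labels")
  freq <- attr(pp, "number") / length(phys)
  part_key <- vapply(pp, function(idx) paste(sort(labs[idx]), collapse = "\r"), "")
  nt <- ape::Ntip(cons)
  node_lab <- character(cons$Nnode)
  for (i in seq_len(cons$Nnode)) {
    node <- nt + i
    tips <- cons$tip.label[tip_descendants(cons, node)]
    key <- paste(sort(tips), collapse = "\r")
    j <- match(key, part_key)
    node_lab[i] <- if (length(tips) == nt) format(1) else
      if (!is.na(j)) format(round(freq[j], 4)) else ""
  }
  cons$node.label <- node_lab
  cons
}

tip_descendants <- function(phy, node) {
  nt <- ape::Ntip(phy)
  if (node <= nt) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[1]; stack <- stack[-1]
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    out <- c(out, kids[kids <= nt])
    stack <- c(stack, kids[kids > nt])
  }
  out
}

#' Effective sample size
#'
#' `n / (1 + 2 * sum(rho_k))` with the sum over the initial positive sequence
#' of pairwise autocorrelation sums (Geyer's truncation).
#'
#' @param samples Numeric vector (>= 10 values).
#' @return Effective sample size; 0 (with a warning) for a constant series.
#' @export
ess <- function(samples) {
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples")
  if (var(samples) == 0) {
    warning("constant series; ESS reported as 0")
    return(0)
  }
  lag_max <- min(n - 1L, max(50L, floor(10 * log10(n))), 2000L)
  rho <- drop(acf(samples, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)[-1]
  npair <- floor(length(rho) / 2)
  s <- 0
  for (k in seq_len(npair)) {
    g <- rho[2 * k - 1] + rho[2 * k]
    if (g <= 0) break
    s <- s + g
  }
  n / (1 + 2 * s)
}

#' Summarize a posterior trace
#'
#' One row per numeric column: median, HPD bounds at `level`, ESS.
#'
#' @param trace Trace data frame (post burn-in).
#' @param level HPD level.
#' @return A data frame with columns `parameter`, `median`, `hpd_lower`,
#'   `hpd_upper`, `ess`.
#' @export
summarize_trace <- function(trace, level = 0.95) {
  cols <- setdiff(names(trace), "Sample")
  rows <- lapply(cols, function(nm) {
    x <- trace[[nm]]
    h <- if (length(unique(x)) > 1L) hpd_interval(x, level) else c(x[1], x[1])
    e <- if (length(x) >= 10L && var(x) > 0) ess(x) else NA
    data.frame(parameter = nm, median = median(x),
               hpd_lower = h[[1]], hpd_upper = h[[2]], ess = e)
  })
  do.call(rbind, rows)
}

#' Write a consensus tree with support values to NEXUS
#'
#' @param cons A `phylo` from [majority_consensus()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(cons, path) {
  ape::write.nexus(cons, file = path)
  invisible(path)
}
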