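# Readers/writers: NEXUS character matrices, tree logs, TSV site tables,
# TSV traces and the flat-text analysis config. Readers reject malformed
# input rather than coercing it.

#' Read a NEXUS morphological character matrix
#'
#' Parses a non-interleaved DATA or CHARACTERS block with standard
#' (discrete) data. Symbols are mapped to `0..k-1` in declared symbol order
#' (default `"0123456789"`); both `?` and the gap character map to missing.
#' Polymorphic codings like `{01}` are rejected.
#'
#' @param path Path to a NEXUS file.
#' @return A [character_matrix()].
#' @export
read_nexus_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  txt <- gsub("\\[[^]]*\\]", "", txt)  # strip comments
  if (!grepl("#NEXUS", txt, ignore.case = TRUE)) stop("not a NEXUS file")
  block <- regmatches(txt, regexpr(
    "(?is)BEGIN\\s+(DATA|CHARACTERS)\\s*;.*?END\\s*;", txt, perl = TRUE))
  if (!length(block)) stop("no DATA/CHARACTERS block found")
  block <- block[[1]]
  dims <- regmatches(block, regexpr("(?i)DIMENSIONS[^;]*;", block, perl = TRUE))
  ntax <- as.integer(sub(".*NTAX\\s*=\\s*(\\d+).*", "\\1", dims, ignore.case = TRUE))
  nchar_ <- as.integer(sub(".*NCHAR\\s*=\\s*(\\d+).*", "\\1", dims, ignore.case = TRUE))
  fmt <- regmatches(block, regexpr("(?i)FORMAT[^;]*;", block, perl = TRUE))
  symbols <- "0123456789"
  missing_ch <- "?"; gap_ch <- "-"
  if (length(fmt)) {
    fmt <- fmt[[1]]
    if (grepl("INTERLEAVE\\s*=\\s*YES", fmt, ignore.case = TRUE))
      stop("interleaved matrices are not supported")
    m <- regmatches(fmt, regexpr('(?i)SYMBOLS\\s*=\\s*"[^"]*"', fmt, perl = TRUE))
    if (length(m)) symbols <- gsub('.*"([^"]*)".*', "\\1", m)
    m <- regmatches(fmt, regexpr("(?i)MISSING\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(m)) missing_ch <- substr(m, nchar(m), nchar(m))
    m <- regmatches(fmt, regexpr("(?i)GAP\\s*=\\s*\\S", fmt, perl = TRUE))
    if (length(m)) gap_ch <- substr(m, nchar(m), nchar(m))
  }
  symbols <- gsub("\\s", "", symbols)
  mat_txt <- regmatches(block, regexpr("(?is)MATRIX(.*?);", block, perl = TRUE))
  if (!length(mat_txt)) stop("no MATRIX statement found")
  rows <- strsplit(sub("(?is)^MATRIX", "", mat_txt[[1]], perl = TRUE), "\n")[[1]]
  rows <- trimws(gsub(";", "", rows))
  rows <- rows[nzchar(rows)]
  taxa <- character(0)
  out <- list()
  for (r in rows) {
    # label may be quoted; otherwise first whitespace-delimited token
    if (startsWith(r, "'")) {
      lab <- sub("^'([^']*)'.*", "\\1", r)
      rest <- trimws(sub("^'[^']*'", "", r))
    } else {
      lab <- sub("\\s.*", "", r)
      rest <- trimws(sub("^\\S+", "", r))
    }
    chars <- gsub("\\s", "", rest)
    if (grepl("[{}()]", chars))
      stop("polymorphic state codings are not supported (taxon ", lab, ")")
    if (lab %in% taxa) stop("duplicate taxon label: ", lab)
    taxa <- c(taxa, lab)
    out[[lab]] <- strsplit(chars, "")[[1]]
  }
  if (length(taxa) != ntax) stop("NTAX=", ntax, " but found ", length(taxa), " taxa")
  lens <- lengths(out)
  if (any(lens != nchar_))
    stop("ragged rows: taxon ", taxa[which(lens != nchar_)[1]], " has ",
         lens[which(lens != nchar_)[1]], " characters, expected ", nchar_)
  sym <- strsplit(symbols, "")[[1]]
  dat <- matrix(NA_integer_, ntax, nchar_, dimnames = list(taxa, NULL))
  for (i in seq_along(taxa)) {
    v <- out[[taxa[i]]]
    idx <- match(v, sym) - 1L
    is_missing <- v %in% c(missing_ch, gap_ch)
    bad <- which(!is_missing & is.na(idx))
    if (length(bad))
      stop("undeclared symbol '", v[bad[1]], "' for taxon ", taxa[i],
           ", character ", bad[1])
    idx[is_missing] <- NA_integer_
    dat[i, ] <- idx
  }
  character_matrix(dat)
}

#' Write a character matrix to NEXUS
#'
#' @param matrix A [character_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_nexus_matrix <- function(matrix, path) {
  x <- apply(matrix$data, 1L, function(r) {
    r <- as.character(r); r[is.na(r)] <- "?"; r
  }, simplify = FALSE)
  names(x) <- matrix$taxa
  ape::write.nexus.data(x, file = path, format = "standard", interleaved = FALSE)
  invisible(path)
}

#' Read a fossil-site occurrence table
#'
#' Tab-separated with header `site  taxon  min_age  max_age  below  above`;
#' one row per taxon occurrence. `below`/`above` (optional, may be empty) name
#' the site immediately below/above this row's site in a stratigraphic
#' sequence.
#'
#' @param path Path to the TSV file.
#' @return A list with `sites` (list of [fossil_site()]) and `seq`
#'   (a [strat_sequence()]).
#' @export
read_site_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("site", "taxon", "min_age", "max_age")
  if (!all(need %in% names(df)))
    stop("site table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$taxon))
    stop("taxon ", df$taxon[duplicated(df$taxon)][1], " appears in two sites")
  sites <- lapply(split(df, df$site), function(d) {
    if (length(unique(d$min_age)) > 1L || length(unique(d$max_age)) > 1L)
      stop("site ", d$site[1], " has inconsistent age bounds")
    fossil_site(d$site[1], d$taxon, d$min_age[1], d$max_age[1])
  })
  ids <- vapply(sites, `[[`, "", "id")
  below <- character(0); above <- character(0)
  for (col in c("below", "above")) {
    if (!col %in% names(df)) next
    d <- unique(df[!is.na(df[[col]]), c("site", col)])
    for (i in seq_len(nrow(d))) {
      other <- d[[col]][i]
      if (!other %in% ids) stop("relation references undeclared site ", other)
      if (col == "below") { below <- c(below, other); above <- c(above, d$site[i]) }
      else { below <- c(below, d$site[i]); above <- c(above, other) }
    }
  }
  rel <- unique(cbind(below, above))
  list(sites = unname(sites),
       seq = strat_sequence(rel[, 1L], rel[, 2L]))
}

#' Write a fossil-site occurrence table
#'
#' @param sites List of [fossil_site()].
#' @param seq A [strat_sequence()] (optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, seq = strat_sequence(), path) {
  rel <- seq$relations
  rows <- lapply(sites, function(s) {
    below <- rel[rel[, "above"] == s$id, "below"]
    above <- rel[rel[, "below"] == s$id, "above"]
    data.frame(site = s$id, taxon = s$taxa, min_age = s$min_age,
               max_age = s$max_age,
               below = if (length(below)) below[1] else NA,
               above = if (length(above)) above[1] else NA,
               row.names = NULL)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write / read a parameter trace
#'
#' Tab-separated, one labelled column per logged quantity, first column
#' `Sample` (the generation index). Values survive a round trip to at least
#' 12 significant digits.
#'
#' @param trace A data frame whose first column is `Sample`.
#' @param path File path.
#' @return `write_trace`: `path` invisibly; `read_trace`: the data frame.
#' @export
write_trace <- function(trace, path) {
  if (names(trace)[1] != "Sample") stop("first trace column must be 'Sample'")
  fmt <- trace
  for (j in seq_along(fmt)) if (is.numeric(fmt[[j]]))
    fmt[[j]] <- sprintf("%.15g", fmt[[j]])
  write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  if (ncol(df) < 1L || names(df)[1] != "Sample")
    stop("malformed trace header: first column must be 'Sample'")
  df
}

#' Write / read a NEXUS tree log
#'
#' Trees are written as a NEXUS TREES block with a translate table; branch
#' lengths are branch durations in Ma and each tree's root age is stored as
#' its root edge, anchoring the absolute age scale so node ages are exactly
#' recoverable.
#'
#' @param trees List of [dated_tree()] sharing one taxon set.
#' @param path File path.
#' @return `write_tree_log`: `path` invisibly; `read_tree_log`: a list of
#'   [dated_tree()].
#' @export
write_tree_log <- function(trees, path) {
  if (!length(trees)) {
    writeLines(c("#NEXUS", "BEGIN TREES;", "END;"), path)
    return(invisible(path))
  }
  tax <- trees[[1]]$tip_labels
  for (tr in trees)
    if (!setequal(tr$tip_labels, tax)) stop("trees have mixed taxon sets")
  phys <- lapply(trees, as_phylo)
  class(phys) <- "multiPhylo"
  names(phys) <- if (!is.null(names(trees))) names(trees)
    else paste0("STATE_", seq_along(trees) - 1L)
  ape::write.nexus(phys, file = path, translate = TRUE)
  invisible(path)
}

#' @rdname write_tree_log
#' @export
read_tree_log <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*tree\\s+.*=", lines, ignore.case = TRUE)))
    return(list())
  phys <- ape::read.nexus(path)
  if (inherits(phys, "phylo")) phys <- list(phys)
  lapply(phys, dated_tree_from_phylo)
}

#' Analysis configuration
#'
#' All hyperprior defaults are those of [prior_config()]; chain defaults are a
#' 10% burn-in and logging every `chain_length / 1000` generations.
#'
#' @param matrix,sites,out Paths: character matrix (NEXUS), site table (TSV),
#'   output prefix. May be `NA` when running on in-memory objects.
#' @param chain_length Number of MCMC generations (>= 0).
#' @param log_interval Generations between logged samples (>= 1).
#' @param burnin Burn-in fraction in `[0, 1)`, applied at summary time.
#' @param seed Integer RNG seed.
#' @param prior_only Replace the data likelihood with a constant (sample the
#'   effective prior).
#' @param fix_tree Keep topology and internal-node ages fixed and omit the
#'   tree prior; site ages and scalar parameters still move. Used to inspect
#'   the operator-induced effective prior on site ages in isolation.
#' @param linked Use the site table as-is (`TRUE`) or explode every site into
#'   single-taxon sites with the same bounds (`FALSE`, independent tip ages).
#' @param conditioning `"variable"` (Mkv) or `"none"` (Mk).
#' @param ncat Number of discrete-gamma categories.
#' @param priors A [prior_config()].
#' @param weights Optional named numeric vector overriding standard operator
#'   weights (names as in [run_chain()]).
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(matrix = NA, sites = NA, out = NA,
                            chain_length = 1e5, log_interval = max(1, chain_length %/% 1000),
                            burnin = 0.10, seed = 1L, prior_only = FALSE,
                            fix_tree = FALSE, linked = TRUE,
                            conditioning = c("variable", "none"), ncat = 4L,
                            priors = prior_config(), weights = NULL) {
  conditioning <- match.arg(conditioning)
  if (chain_length < 0) stop("chain_length must be >= 0")
  if (log_interval < 1) stop("log_interval must be >= 1")
  if (burnin < 0 || burnin >= 1) stop("burnin must be in [0, 1)")
  structure(list(matrix = matrix, sites = sites, out = out,
                 chain_length = chain_length, log_interval = log_interval,
                 burnin = burnin, seed = as.integer(seed),
                 prior_only = prior_only, fix_tree = fix_tree, linked = linked,
                 conditioning = conditioning, ncat = as.integer(ncat),
                 priors = priors, weights = weights),
            class = "analysis_config")
}

#' Read / write an analysis config file
#'
#' Flat `key = value` text; unknown keys are an error. Keys are the arguments
#' of [analysis_config()] plus the hyperparameters of [prior_config()].
#'
#' @param path File path.
#' @return `read_config`: an [analysis_config()]; `write_config`: `path`
#'   invisibly.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  vals <- setNames(vapply(kv, `[[`, "", 2L), vapply(kv, `[[`, "", 1L))
  num_keys <- c("chain_length", "log_interval", "burnin", "seed", "ncat")
  lgl_keys <- c("prior_only", "fix_tree", "linked")
  chr_keys <- c("matrix", "sites", "out", "conditioning")
  prior_keys <- names(prior_config())
  args <- list(); pargs <- list()
  for (k in names(vals)) {
    v <- vals[[k]]
    if (k %in% num_keys) args[[k]] <- as.numeric(v)
    else if (k %in% lgl_keys) args[[k]] <- toupper(v) %in% c("TRUE", "YES", "1")
    else if (k %in% chr_keys) args[[k]] <- v
    else if (k %in% prior_keys) pargs[[k]] <- as.numeric(v)
    else stop("unknown config key: ", k)
  }
  args$priors <- do.call(prior_config, pargs)
  do.call(analysis_config, args)
}

#' @rdname read_config
#' @param config An [analysis_config()].
#' @export
write_config <- function(config, path) {
  flat <- config[setdiff(names(config), c("priors", "weights"))]
  flat <- flat[!vapply(flat, function(x) length(x) == 1 && is.na(x), TRUE)]
  lines <- c(sprintf("%s = %s", names(flat), vapply(flat, as.character, "")),
             sprintf("%s = %.15g", names(config$priors),
                     as.numeric(config$priors)))
  writeLines(lines, path)
  invisible(path)
}
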