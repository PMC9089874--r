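#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-delimited as
#' `set_id<TAB>description<TAB>gene1<TAB>gene2...`.  Duplicate members are
#' collapsed; sets with no members are dropped with a warning.
#'
#' @param path Path to a GMT file, or a character vector of GMT lines.
#' @return A list of gene sets, each a list with `set_id`, `name` and
#'   `members` (unique gene symbols).
#' @export
read_gmt <- function(path) {
  lines <- if (length(path) == 1L && !grepl("[\n\t]", path) && file.exists(path)) {
    readLines(path)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop(sprintf("GMT parse error at line %d: fewer than 2 columns", i),
           call. = FALSE)
    }
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    list(set_id = f[1], name = f[2], members = members)
  })
  empty <- vapply(sets, function(s) length(s$members) == 0L, logical(1))
  if (any(empty)) {
    warning(sprintf("dropping %d empty gene set(s)", sum(empty)))
  }
  sets[!empty]
}

#' Write gene sets in GMT format
#' @param sets A list of gene sets as returned by [read_gmt()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(sets, function(s) {
    paste(c(s$set_id, s$name, s$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Exact upper-tail hypergeometric p-value
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing
#' at least `k` members of a `K`-gene set in a size-`n` query drawn
#' without replacement from a size-`N` universe.  Exact (no normal
#' approximation).
#'
#' @param k Observed overlap.
#' @param K Gene-set size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return The one-sided over-representation p-value.
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  if (any(k < 0 | K < 0 | n < 0 | N < 0) || any(k > pmin(K, n)) ||
      any(K > N) || any(n > N)) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Q-values by the step-up rule: sort p ascending,
#' q(i) = min over j >= i of p(j) * m / j, capped at 1, returned in the
#' input order.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' One exact hypergeometric test per gene set against a fixed universe,
#' with Benjamini-Hochberg correction across sets.  Query genes outside
#' the universe are dropped with a warning; set members are intersected
#' with the universe before testing, and sets left empty are skipped.
#' Significance is declared at `q < alpha` (strict).
#'
#' @param query_genes Character vector of candidate genes.
#' @param gene_sets Gene-set list from [read_gmt()].
#' @param universe Background gene symbols.  A natural default for this
#'   pipeline is the genes bearing both RVIS and brain-expression
#'   annotations (the filtered search space).
#' @param alpha Significance level on the Q-value (default 0.05).
#' @return A data frame sorted by (q, p) with columns `set_id`, `name`,
#'   `k`, `K`, `n`, `N`, `p`, `q`, `coverage` (`"k/K"`), `significant`.
#' @export
enrich <- function(query_genes, gene_sets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0L) {
    stop("empty gene universe", call. = FALSE)
  }
  query <- unique(query_genes)
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(sprintf("%d query gene(s) outside the universe dropped",
                    length(outside)))
    query <- intersect(query, universe)
  }
  n <- length(query)
  N <- length(universe)
  rows <- lapply(gene_sets, function(s) {
    members <- intersect(s$members, universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(members, query))
    data.frame(set_id = s$set_id, name = s$name, k = k, K = K, n = n, N = N,
               p = hypergeom_pvalue(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set_id = character(), name = character(), k = integer(),
                      K = integer(), n = integer(), N = integer(),
                      p = numeric(), q = numeric(), coverage = character(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out$q <- bh_adjust(out$p)
  out$coverage <- paste0(out$k, "/", out$K)
  out$significant <- out$q < alpha
  out <- out[order(out$q, out$p), ]
  rownames(out) <- NULL
  out
}
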