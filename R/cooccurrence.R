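#' Deduplicate clock systems
#'
#' The taxonomic coverage of sequenced genomes is highly imbalanced (some
#' genera are sequenced far more densely than others), so co-occurrence
#' statistics are computed over *unique* factor combinations rather than
#' over strains. Rows of the presence matrix with identical factor
#' combinations are collapsed to one.
#'
#' @param pm Integer/logical presence matrix, rows = strains or systems,
#'   columns = factors (see [presence_matrix()]).
#' @return Presence matrix with unique rows, row names giving one
#'   representative strain per combination. Idempotent.
#' @export
dedup_systems <- function(pm) {
  if (is.null(dim(pm)) || nrow(pm) == 0) {
    warning("dedup_systems: empty input")
    return(pm)
  }
  key <- apply(pm != 0, 1, paste, collapse = "")
  out <- pm[!duplicated(key), , drop = FALSE]
  storage.mode(out) <- "integer"
  out
}

#' Right-sided Fisher's exact test for a 2x2 table
#'
#' Upper-tail hypergeometric probability P(X >= a) for the table
#' (a = both present, b = first only, c = second only, d = neither) with
#' all margins fixed. Computed with log-factorials (via `lchoose`) so the
#' tail sum is exact to near machine precision even for large cells.
#'
#' @param a,b,c,d Nonnegative integer cell counts.
#' @return The one-sided p-value for over-representation of joint presence.
#' @export
fisher_right <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("fisher_right: cells must be nonnegative integers")
  }
  m <- a + b        # margin of the first factor (present)
  k <- a + c        # margin of the second factor (present)
  n <- a + b + c + d
  kmax <- min(m, k)
  if (a > kmax) return(0)
  ks <- a:kmax
  logp <- lchoose(m, ks) + lchoose(n - m, k - ks) - lchoose(n, k)
  # sum on the log scale, largest term first, for numerical stability
  mx <- max(logp)
  min(1, exp(mx) * sum(exp(logp - mx)))
}

#' Benjamini-Hochberg adjustment with a significance call
#'
#' Step-up adjusted p-values (via `stats::p.adjust`) and the corresponding
#' significance flags at the requested false discovery rate.
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param fdr Accepted false discovery rate (default 0.01).
#' @return List with `p_adj` and logical `significant`.
#' @export
bh_adjust <- function(p, fdr = 0.01) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("bh_adjust: p-values must lie in [0, 1]")
  }
  p_adj <- stats::p.adjust(p, method = "BH")
  list(p_adj = p_adj, significant = !is.na(p_adj) & p_adj <= fdr)
}

#' Pairwise co-occurrence testing over unique clock systems
#'
#' For every unordered pair of factors, builds the 2x2 presence table over
#' the (deduplicated) systems and applies the right-sided Fisher's exact
#' test; p-values are then BH-corrected across all tested pairs. Factors
#' that are constant across systems (always present -- such as the
#' KaiC-family column guaranteed by the retention filter -- or always
#' absent) are excluded: their tables admit a single configuration and the
#' test is degenerate at p = 1.
#'
#' @param pm Presence matrix of unique systems (see [dedup_systems()]).
#' @param fdr False discovery rate for the significance call (default 0.01).
#' @return Data frame with one row per tested pair: `factor_i`, `factor_j`,
#'   `a`, `b`, `c`, `d`, `p_raw`, `p_adj`, `significant`.
#' @export
cooccurrence_test <- function(pm, fdr = 0.01) {
  pm <- pm != 0
  n <- nrow(pm)
  variable <- colnames(pm)[colSums(pm) > 0 & colSums(pm) < n]
  pairs <- if (length(variable) >= 2) utils::combn(variable, 2) else
    matrix(character(), nrow = 2)
  np <- ncol(pairs)
  res <- data.frame(
    factor_i = pairs[1, ], factor_j = pairs[2, ],
    a = rep(NA_integer_, np), b = rep(NA_integer_, np),
    c = rep(NA_integer_, np), d = rep(NA_integer_, np),
    p_raw = rep(NA_real_, np), stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(res))) {
    x <- pm[, res$factor_i[r]]
    y <- pm[, res$factor_j[r]]
    res$a[r] <- sum(x & y)
    res$b[r] <- sum(x & !y)
    res$c[r] <- sum(!x & y)
    res$d[r] <- sum(!x & !y)
    res$p_raw[r] <- fisher_right(res$a[r], res$b[r], res$c[r], res$d[r])
  }
  adj <- bh_adjust(res$p_raw, fdr = fdr)
  res$p_adj <- adj$p_adj
  res$significant <- adj$significant
  res
}

#' Symmetric adjusted-p matrix from pairwise results
#'
#' @param results Data frame from [cooccurrence_test()].
#' @return Symmetric numeric matrix of adjusted p-values with zero diagonal;
#'   untested (constant) factors are absent.
#' @export
p_adj_matrix <- function(results) {
  factors <- sort(unique(c(results$factor_i, results$factor_j)))
  m <- matrix(1, length(factors), length(factors),
              dimnames = list(factors, factors))
  m[cbind(results$factor_i, results$factor_j)] <- results$p_adj
  m[cbind(results$factor_j, results$factor_i)] <- results$p_adj
  diag(m) <- 0
  m
}

#' Cluster factors by their adjusted co-occurrence p-values
#'
#' Agglomerative hierarchical clustering with average linkage on the
#' adjusted p-values taken directly as distances (diagonal 0). Columns are
#' ordered lexicographically before clustering so that ties break
#' deterministically by factor label.
#'
#' @param m Symmetric adjusted-p matrix with zero diagonal
#'   (see [p_adj_matrix()]).
#' @return Character vector: the leaf ordering of the factors.
#' @export
cluster_factors <- function(m) {
  if (!isSymmetric(unname(m))) stop("cluster_factors: matrix not symmetric")
  if (any(diag(m) != 0)) stop("cluster_factors: diagonal must be zero")
  if (ncol(m) <= 2) return(colnames(m))
  ord <- order(colnames(m))
  m <- m[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m), method = "average")
  colnames(m)[hc$order]
}

#' Significance network of co-occurring factors
#'
#' Builds the graph whose edges are the factor pairs with adjusted p at or
#' below `alpha`; the edge weight is the adjusted p-value and each node
#' carries its degree.
#'
#' @param results Data frame from [cooccurrence_test()].
#' @param alpha Significance threshold on adjusted p (default 0.01).
#' @return List with `nodes` (data frame `factor`, `degree`), `edges`
#'   (data frame `from`, `to`, `p_adj`) and `graph` (an igraph object).
#' @export
build_network <- function(results, alpha = 0.01) {
  factors <- sort(unique(c(results$factor_i, results$factor_j)))
  sig <- results[!is.na(results$p_adj) & results$p_adj <= alpha, ,
                 drop = FALSE]
  edges <- data.frame(from = sig$factor_i, to = sig$factor_j,
                      p_adj = sig$p_adj, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = factors, stringsAsFactors = FALSE))
  if (nrow(edges)) igraph::E(g)$weight <- edges$p_adj
  deg <- igraph::degree(g)
  list(nodes = data.frame(factor = names(deg), degree = as.integer(deg),
                          stringsAsFactors = FALSE),
       edges = edges, graph = g)
}

#' Export a co-occurrence network
#'
#' Writes the edge list as TSV and, optionally, the graph as GraphML.
#'
#' @param network List from [build_network()].
#' @param edge_tsv Path for the edge-list TSV.
#' @param graphml Optional path for a GraphML export.
#' @export
write_network <- function(network, edge_tsv, graphml = NULL) {
  utils::write.table(network$edges, edge_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(graphml)) {
    igraph::write_graph(network$graph, graphml, format = "graphml")
  }
  invisible(edge_tsv)
}
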