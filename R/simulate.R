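#' Simulate proteome collections with planted homolog families
#'
#' Generates one proteome per taxon, each containing one or more members of
#' every query family plus random decoy proteins, together with the ground
#' truth needed for recovery tests of the reciprocal best-hit screen.
#' Family members are derived from their query by seeded point
#' substitutions until the target percent identity is reached; substituted
#' residues are drawn among the query residue's positive-scoring BLOSUM62
#' exchange partners (falling back to any other residue when none exists,
#' as for cysteine), which mimics accepted point mutations. Decoys are
#' random sequences drawn from the pooled amino-acid composition of the
#' queries, so they share composition but not homology.
#'
#' @param n_taxa Number of taxa (one proteome each).
#' @param families Data frame with columns `query_id`, `identity`
#'   (target percent identity, in \[20, 100\]) and `copies` (paralog count
#'   per taxon); an optional `prevalence` column gives the probability that
#'   a taxon carries the family at all (default 1, i.e. present
#'   everywhere).
#' @param n_decoys Decoy proteins per taxon.
#' @param seed Integer seed; identical seed and configuration give
#'   byte-identical output.
#' @param len_range Range of sequence lengths to draw from.
#' @param taxon_groups Taxon-group labels assigned cyclically to taxa.
#' @return List with `queries` (named character vector), `db` (named
#'   character vector of all simulated proteins), `meta` (id, organism,
#'   genus, taxon_group), and `truth` (data frame `member_id`, `query_id`,
#'   `organism`, `copy`, `target_identity`).
#' @export
simulate_proteomes <- function(n_taxa, families, n_decoys, seed,
                               len_range = c(90, 130),
                               taxon_groups = TAXON_GROUPS) {
  stopifnot(all(c("query_id", "identity", "copies") %in% names(families)))
  if (any(families$identity < 20 | families$identity > 100)) {
    stop("simulate_proteomes: identity must lie in [20, 100]")
  }
  if (is.null(families$prevalence)) families$prevalence <- 1
  set.seed(seed)
  submat <- clock_submat()
  lens <- seq(len_range[[1]], len_range[[2]])

  queries <- vapply(seq_len(nrow(families)), function(i) {
    paste(sample(AA_STANDARD, sample(lens, 1), replace = TRUE),
          collapse = "")
  }, character(1))
  names(queries) <- families$query_id
  comp <- table(factor(unlist(strsplit(queries, "")), levels = AA_STANDARD))
  comp <- as.numeric(comp) / sum(comp)

  db <- character()
  meta <- list()
  truth <- list()
  for (i in seq_len(n_taxa)) {
    organism <- sprintf("Genus%02d strain %d", i, i)
    group <- taxon_groups[[(i - 1) %% length(taxon_groups) + 1]]
    for (f in seq_len(nrow(families))) {
      qid <- families$query_id[[f]]
      if (stats::rbinom(1, 1, families$prevalence[[f]]) == 0) next
      for (cp in seq_len(families$copies[[f]])) {
        mid <- sprintf("%s_t%02d_c%d", qid, i, cp)
        db[[mid]] <- mutate_to_identity(queries[[qid]],
                                        families$identity[[f]], submat)
        meta[[mid]] <- data.frame(id = mid, organism = organism,
                                  genus = sprintf("Genus%02d", i),
                                  taxon_group = group,
                                  stringsAsFactors = FALSE)
        truth[[mid]] <- data.frame(member_id = mid, query_id = qid,
                                   organism = organism, copy = cp,
                                   target_identity = families$identity[[f]],
                                   stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(n_decoys)) {
      did <- sprintf("decoy_t%02d_%03d", i, j)
      db[[did]] <- paste(sample(AA_STANDARD, sample(lens, 1),
                                replace = TRUE, prob = comp),
                         collapse = "")
      meta[[did]] <- data.frame(id = did, organism = organism,
                                genus = sprintf("Genus%02d", i),
                                taxon_group = group,
                                stringsAsFactors = FALSE)
    }
  }
  list(queries = queries, db = db,
       meta = do.call(rbind, unname(meta)),
       truth = do.call(rbind, unname(truth)))
}

# Substitute exactly enough positions of `seq` to bring percent identity
# down to `identity`; substitutions prefer positive-scoring exchanges.
mutate_to_identity <- function(seq, identity, submat) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- round((1 - identity / 100) * length(chars))
  if (k == 0) return(seq)
  pos <- sample(length(chars), k)
  for (p in pos) {
    r <- chars[[p]]
    partners <- AA_STANDARD[submat[r, AA_STANDARD] > 0 & AA_STANDARD != r]
    if (!length(partners)) partners <- setdiff(AA_STANDARD, r)
    chars[[p]] <- if (length(partners) == 1) partners else sample(partners, 1)
  }
  paste(chars, collapse = "")
}

#' Write simulated proteomes as per-taxon FASTA plus sidecar metadata
#'
#' Emits exactly the formats the screen consumes: one multi-FASTA per
#' organism, a metadata sidecar TSV, a query FASTA, and the truth table.
#' The seed is recorded in a header comment of the sidecar and truth files
#' for provenance.
#'
#' @param sim Result of [simulate_proteomes()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the file headers.
#' @return Invisibly, the vector of written paths.
#' @export
write_proteomes <- function(sim, dir, seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (org in unique(sim$meta$organism)) {
    ids <- sim$meta$id[sim$meta$organism == org]
    slug <- gsub("\\s+", "_", org)
    p <- file.path(dir, paste0(slug, ".faa"))
    writeLines(paste0(">", ids, "\n", sim$db[ids]), p)
    paths <- c(paths, p)
  }
  qp <- file.path(dir, "queries.faa")
  writeLines(paste0(">", names(sim$queries), "\n", sim$queries), qp)
  mp <- file.path(dir, "meta.tsv")
  con <- file(mp, "w")
  writeLines(paste0("# seed: ", seed), con)
  utils::write.table(sim$meta, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  tp <- file.path(dir, "truth.tsv")
  con <- file(tp, "w")
  writeLines(paste0("# seed: ", seed), con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(c(paths, qp, mp, tp))
}

#' Simulate boolean clock-system presence matrices
#'
#' Columns are independent Bernoulli draws at the given prevalences, except
#' for planted factor pairs, which are drawn jointly from the 2x2
#' distribution with the specified odds ratio and the given marginals
#' (cell probabilities solved from the marginals and the odds ratio, cells
#' sampled by inverse CDF). This matches the null model of the
#' co-occurrence test -- pairwise independence across systems -- so planted
#' enrichments are the only violations.
#'
#' @param n_systems Number of systems (rows).
#' @param base_prevalence Named numeric vector of factor prevalences in
#'   (0, 1].
#' @param enriched_pairs Optional data frame `factor_i`, `factor_j`,
#'   `odds_ratio` (pairs must be disjoint).
#' @param seed Integer seed.
#' @return List with `matrix` (0/1 integer matrix, systems x factors) and
#'   `truth` (the generator settings).
#' @export
simulate_clock_systems <- function(n_systems, base_prevalence,
                                   enriched_pairs = NULL, seed) {
  p <- base_prevalence
  if (is.null(names(p)) || any(p <= 0 | p > 1)) {
    stop("simulate_clock_systems: prevalences must be named and in (0, 1]")
  }
  set.seed(seed)
  m <- matrix(0L, n_systems, length(p),
              dimnames = list(sprintf("sys%04d", seq_len(n_systems)),
                              names(p)))
  planted <- character()
  if (!is.null(enriched_pairs) && nrow(enriched_pairs)) {
    ids <- c(enriched_pairs$factor_i, enriched_pairs$factor_j)
    if (anyDuplicated(ids)) {
      stop("simulate_clock_systems: enriched pairs must be disjoint")
    }
    if (!all(ids %in% names(p))) {
      stop("simulate_clock_systems: enriched pair factor not in prevalences")
    }
    for (r in seq_len(nrow(enriched_pairs))) {
      fi <- enriched_pairs$factor_i[[r]]
      fj <- enriched_pairs$factor_j[[r]]
      cells <- joint_cell_probs(p[[fi]], p[[fj]],
                                enriched_pairs$odds_ratio[[r]])
      draw <- sample.int(4, n_systems, replace = TRUE, prob = cells)
      m[, fi] <- as.integer(draw %in% c(1L, 2L))
      m[, fj] <- as.integer(draw %in% c(1L, 3L))
      planted <- c(planted, fi, fj)
    }
  }
  for (f in setdiff(names(p), planted)) {
    m[, f] <- stats::rbinom(n_systems, 1, p[[f]])
  }
  list(matrix = m,
       truth = list(base_prevalence = p, enriched_pairs = enriched_pairs,
                    seed = seed))
}

# Cell probabilities (p11, p10, p01, p00) of a 2x2 Bernoulli pair with
# marginals pi, pj and odds ratio OR = p11 p00 / (p10 p01).
joint_cell_probs <- function(pi, pj, or) {
  if (or <= 0) stop("odds ratio must be positive")
  lo <- max(0, pi + pj - 1)
  hi <- min(pi, pj)
  if (or == 1) {
    p11 <- pi * pj
  } else {
    a <- or - 1
    b <- -(a * (pi + pj) + 1)
    cc <- or * pi * pj
    disc <- b^2 - 4 * a * cc
    if (disc < 0) stop("infeasible (marginal, odds ratio) combination")
    roots <- (-b + c(-1, 1) * sqrt(disc)) / (2 * a)
    ok <- roots >= lo - 1e-12 & roots <= hi + 1e-12
    if (!any(ok)) stop("infeasible (marginal, odds ratio) combination")
    p11 <- min(max(roots[ok][[1]], lo), hi)
  }
  c(p11, pi - p11, pj - p11, 1 - pi - pj + p11)
}

#' Simulate diurnal expression time series
#'
#' A stated fraction of genes oscillates: those genes follow
#' `b0 + b1 t + A cos(2 pi (t - phi) / period)` plus Gaussian noise, the
#' remainder only the linear trend plus noise. Defaults match a typical
#' diurnal microarray design: 12 samples every 4 h spanning 48 h, unit
#' amplitude, uniform phases, and noise with standard deviation 0.5 on the
#' (l2m-like) log2 scale.
#'
#' @param n_genes Number of genes.
#' @param frac_oscillating Fraction of genes with a planted sinusoid, in
#'   \[0, 1\].
#' @param period Oscillation period in hours (default 24).
#' @param timepoints Sampling times in hours (at least 6).
#' @param phase_dist,amp_dist,trend_slope_dist,baseline_dist Functions of n
#'   returning the planted parameters per gene.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed.
#' @return List with `time`, `values` (genes x timepoints matrix), and
#'   `truth` (data frame `gene_id`, `oscillating`, `phase`, `amplitude`,
#'   `slope`, `baseline`).
#' @export
simulate_expression <- function(n_genes, frac_oscillating, period = 24,
                                timepoints = seq(0, 44, by = 4),
                                phase_dist = function(n)
                                  stats::runif(n, 0, period),
                                amp_dist = function(n) rep(1, n),
                                trend_slope_dist = function(n)
                                  stats::rnorm(n, 0, 0.02),
                                baseline_dist = function(n) rep(0, n),
                                noise_sd = 0.5, seed = 1) {
  if (frac_oscillating < 0 || frac_oscillating > 1) {
    stop("simulate_expression: frac_oscillating must lie in [0, 1]")
  }
  if (length(timepoints) < 6) {
    stop("simulate_expression: need at least 6 timepoints")
  }
  set.seed(seed)
  n_osc <- round(frac_oscillating * n_genes)
  osc <- seq_len(n_genes) <= n_osc
  truth <- data.frame(
    gene_id = sprintf("gene%05d", seq_len(n_genes)),
    oscillating = osc,
    phase = ifelse(osc, phase_dist(n_genes), NA_real_),
    amplitude = ifelse(osc, amp_dist(n_genes), 0),
    slope = trend_slope_dist(n_genes),
    baseline = baseline_dist(n_genes),
    stringsAsFactors = FALSE
  )
  t <- timepoints
  vals <- vapply(seq_len(n_genes), function(g) {
    mu <- truth$baseline[[g]] + truth$slope[[g]] * t
    if (osc[[g]]) {
      mu <- mu + truth$amplitude[[g]] *
        cos(2 * pi * (t - truth$phase[[g]]) / period)
    }
    mu + stats::rnorm(length(t), 0, noise_sd)
  }, numeric(length(t)))
  values <- t(vals)
  dimnames(values) <- list(truth$gene_id, as.character(t))
  list(time = t, values = values, truth = truth)
}

#' Write an expression simulation as a TSV matrix plus truth table
#'
#' The matrix format is the one the rhythm stage consumes: first column
#' `gene_id`, remaining column names the timepoints in hours. The seed is
#' recorded in a header comment.
#'
#' @param sim Result of [simulate_expression()].
#' @param path Output TSV path; the truth table goes to
#'   `<path>.truth.tsv`.
#' @param seed Seed recorded in the header.
#' @return Invisibly, the matrix path.
#' @export
write_expression_tsv <- function(sim, path, seed = NA) {
  df <- data.frame(gene_id = rownames(sim$values), sim$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  writeLines(paste0("# seed: ", seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  con <- file(paste0(path, ".truth.tsv"), "w")
  writeLines(paste0("# seed: ", seed), con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  invisible(path)
}

#' Read an expression TSV matrix
#'
#' @param path TSV with first column `gene_id` and timepoint headers in
#'   hours; `#` lines are comments.
#' @return List with `time` and `values` as used by [rhythm_detect()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df[[1]]
  list(time = as.numeric(colnames(values)), values = values)
}
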