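#' l2m transform of an expression matrix
#'
#' Each value is expressed as log2 relative to its gene's arithmetic mean,
#' `log2(value / mean(gene))`, which centres profiles and makes amplitudes
#' comparable across genes. Rows that are entirely zero are dropped with a
#' warning. If the matrix contains zeros or negative values, the smallest
#' positive value of the matrix is added throughout before transforming
#' (logged as a warning).
#'
#' @param mat Numeric matrix, genes x timepoints, with gene ids as row
#'   names.
#' @return Transformed matrix of the same shape (minus dropped rows).
#' @export
l2m_transform <- function(mat) {
  stopifnot(is.matrix(mat))
  allzero <- rowSums(mat != 0) == 0
  if (any(allzero)) {
    warning("l2m_transform: dropping ", sum(allzero), " all-zero gene row(s)")
    mat <- mat[!allzero, , drop = FALSE]
  }
  if (any(mat <= 0)) {
    offset <- min(mat[mat > 0])
    warning("l2m_transform: nonpositive values; adding offset ",
            signif(offset, 4))
    mat <- mat + offset
  }
  log2(mat / rowMeans(mat))
}

#' Concatenate two replicate expression datasets
#'
#' Biological replicates sampled on their own time grids are pooled into a
#' single series per gene: the observations are the union of both
#' replicates, each keeping its own timepoint, and the harmonic regression
#' treats them as independent observations. Gene universes are intersected
#' with a warning when they differ.
#'
#' @param a,b Lists with elements `time` (numeric vector of hours) and
#'   `values` (genes x timepoints matrix with row names).
#' @return A list of the same shape with the pooled observations.
#' @export
concat_replicates <- function(a, b) {
  if (is.null(a) || length(a$time) == 0) return(b)
  if (is.null(b) || length(b$time) == 0) return(a)
  genes <- intersect(rownames(a$values), rownames(b$values))
  if (length(genes) < nrow(a$values) || length(genes) < nrow(b$values)) {
    warning("concat_replicates: gene sets differ; intersecting (",
            length(genes), " shared genes)")
  }
  list(time = c(a$time, b$time),
       values = cbind(a$values[genes, , drop = FALSE],
                      b$values[genes, , drop = FALSE]))
}

#' Savitzky-Golay smoothing of expression profiles
#'
#' Local least-squares polynomial smoothing, used to remove pseudo peaks
#' before oscillation detection. Polynomials of degree at most `polyorder`
#' pass through unchanged. Requires uniform sampling within the series;
#' with non-uniform timepoints the filter weights are wrong and the
#' function refuses to run (disable smoothing instead).
#'
#' @param mat Numeric matrix, genes x timepoints.
#' @param time Optional timepoint vector used to verify uniform sampling.
#' @param window Odd window length (default 5); must exceed `polyorder` and
#'   not exceed the series length.
#' @param polyorder Polynomial degree (default 2).
#' @return Smoothed matrix of the same shape.
#' @export
sg_smooth <- function(mat, time = NULL, window = 5, polyorder = 2) {
  stopifnot(is.matrix(mat))
  if (window %% 2 == 0) stop("sg_smooth: window must be odd")
  if (window <= polyorder) stop("sg_smooth: window must exceed polyorder")
  if (ncol(mat) < window) stop("sg_smooth: series shorter than window")
  if (!is.null(time)) {
    dt <- diff(time)
    if (length(dt) && diff(range(dt)) > 1e-8 * max(abs(dt))) {
      stop("sg_smooth: non-uniform sampling; run detection with ",
           "smoothing disabled")
    }
  }
  out <- t(apply(mat, 1, signal::sgolayfilt, p = polyorder, n = window))
  dimnames(out) <- dimnames(mat)
  out
}

#' Harmonic regression of a single expression series
#'
#' Fits the sinusoidal foreground model
#' `y = b0 + b1 t + c cos(wt) + d sin(wt)` (with `w = 2 pi / period`)
#' against the linear background `y = b0 + b1 t` by least squares. The
#' p-value is the F-test of the two harmonic coefficients (2 numerator
#' degrees of freedom); the amplitude is `A = sqrt(c^2 + d^2)` and the peak
#' phase is `phi = (period / 2 pi) atan2(d, c) mod period`, the time at
#' which the fitted cosine peaks.
#'
#' @param t Timepoints in hours (at least 6 observations; a warning is
#'   issued when they span less than one period).
#' @param y Expression values (same length as `t`).
#' @param period Oscillation period in hours (default 24).
#' @return List with `p`, `fstat`, `amplitude`, `phase`, and `ok` (FALSE
#'   when the design is rank deficient, in which case the estimates are
#'   NA).
#' @export
harmonic_fit <- function(t, y, period = 24) {
  n <- length(t)
  stopifnot(length(y) == n)
  if (n < 6) stop("harmonic_fit: need at least 6 observations")
  if (diff(range(t)) < period) {
    warning("harmonic_fit: timepoints span less than one period")
  }
  w <- 2 * pi / period
  X1 <- cbind(1, t, cos(w * t), sin(w * t))
  X0 <- X1[, 1:2, drop = FALSE]
  q1 <- qr(X1)
  if (q1$rank < 4) {
    return(list(p = NA_real_, fstat = NA_real_, amplitude = NA_real_,
                phase = NA_real_, ok = FALSE))
  }
  beta <- qr.coef(q1, y)
  r1 <- sum(qr.resid(q1, y)^2)
  r0 <- sum(qr.resid(qr(X0), y)^2)
  amp <- sqrt(beta[3]^2 + beta[4]^2)
  phase <- ((period / (2 * pi)) * atan2(beta[4], beta[3])) %% period
  df2 <- n - 4
  scale <- max(r0, sum(y^2), 1)
  num <- max(r0 - r1, 0)
  if (r1 <= 1e-12 * scale) {
    # (near-)perfect foreground fit: F degenerates
    if (num <= 1e-12 * scale) {
      fstat <- 0; p <- 1         # background already perfect (flat/linear)
    } else {
      fstat <- Inf; p <- 0       # exact sinusoid
    }
  } else {
    fstat <- (num / 2) / (r1 / df2)
    p <- stats::pf(fstat, 2, df2, lower.tail = FALSE)
  }
  list(p = p, fstat = fstat, amplitude = unname(amp),
       phase = unname(phase), ok = TRUE)
}

#' Detect diurnally oscillating genes in an expression matrix
#'
#' Fits the harmonic-regression model per gene and flags oscillators after
#' Benjamini-Hochberg correction. With `smooth = TRUE`, the peak phase and
#' amplitude descriptors are taken from the fit to the Savitzky-Golay
#' smoothed profile (removing pseudo peaks that distort these descriptors),
#' while the detection p-value is always computed from the unfiltered
#' series: smoothing shrinks and correlates the residual noise, which
#' invalidates the F-test's null distribution, so inference stays on the
#' raw data.
#'
#' @param mat Numeric matrix, genes x timepoints (typically l2m
#'   transformed), with gene ids as row names.
#' @param time Timepoints in hours (one per column).
#' @param period Oscillation period in hours (default 24).
#' @param smooth Apply [sg_smooth()] first (default TRUE).
#' @param window,polyorder Savitzky-Golay parameters.
#' @param q_max BH-adjusted significance threshold (default 0.05).
#' @return Data frame with one row per gene: `gene_id`, `p`, `q`, `phase`,
#'   `amplitude`, `oscillating`.
#' @export
rhythm_detect <- function(mat, time, period = 24, smooth = TRUE,
                          window = 5, polyorder = 2, q_max = 0.05) {
  stopifnot(is.matrix(mat), length(time) == ncol(mat))
  fits <- apply(mat, 1, function(y) harmonic_fit(time, y, period = period))
  desc <- fits
  if (smooth) {
    sm <- sg_smooth(mat, time = time, window = window,
                    polyorder = polyorder)
    desc <- apply(sm, 1, function(y) harmonic_fit(time, y, period = period))
  }
  res <- data.frame(
    gene_id = rownames(mat),
    p = vapply(fits, `[[`, numeric(1), "p"),
    phase = vapply(desc, `[[`, numeric(1), "phase"),
    amplitude = vapply(desc, `[[`, numeric(1), "amplitude"),
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  call_oscillators(res, q_max = q_max)
}

#' Flag significant oscillators
#'
#' Adds BH-adjusted q-values over the whole dataset and the oscillator
#' call `q <= q_max`.
#'
#' @param results Data frame with a `p` column (see [rhythm_detect()]).
#' @param q_max Significance threshold on q (default 0.05).
#' @return The input with columns `q` and `oscillating` added/updated.
#' @export
call_oscillators <- function(results, q_max = 0.05) {
  adj <- bh_adjust(results$p, fdr = q_max)
  results$q <- adj$p_adj
  results$oscillating <- adj$significant
  results[c("gene_id", "p", "q", "phase", "amplitude", "oscillating")]
}

circular_mean <- function(alpha) {
  atan2(mean(sin(alpha)), mean(cos(alpha)))
}

#' Circular correlation of two peak-phase programs
#'
#' The Jammalamadaka-SenGupta circular correlation coefficient between two
#' paired angular samples, applied to peak phases expressed in hours:
#' phases are converted to angles `alpha = 2 pi phi / period` and
#' `rho = sum sin(a - abar) sin(b - bbar) / sqrt(sum sin^2(a - abar) sum
#' sin^2(b - bbar))` with circular means `abar`, `bbar`. The p-value uses
#' the asymptotic normal statistic
#' `z = sqrt(n l20 l02 / l22) rho` with `ljk = mean(sin^j(a - abar)
#' sin^k(b - bbar))`.
#'
#' @param phases_a,phases_b Paired phase vectors in hours (length >= 3).
#' @param period Period in hours (default 24).
#' @return List with `rho_ccc` and `p`; both NA (with a warning) when
#'   either sample has zero circular variance.
#' @export
circular_correlation <- function(phases_a, phases_b, period = 24) {
  stopifnot(length(phases_a) == length(phases_b))
  n <- length(phases_a)
  if (n < 3) stop("circular_correlation: need at least 3 pairs")
  a <- 2 * pi * phases_a / period
  b <- 2 * pi * phases_b / period
  sa <- sin(a - circular_mean(a))
  sb <- sin(b - circular_mean(b))
  va <- sum(sa^2)
  vb <- sum(sb^2)
  if (va < 1e-12 || vb < 1e-12) {
    warning("circular_correlation: zero circular variance; undefined")
    return(list(rho_ccc = NA_real_, p = NA_real_))
  }
  rho <- sum(sa * sb) / sqrt(va * vb)
  l20 <- mean(sa^2)
  l02 <- mean(sb^2)
  l22 <- mean(sa^2 * sb^2)
  z <- sqrt(n * l20 * l02 / l22) * rho
  list(rho_ccc = rho, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare the diurnal programs of two datasets
#'
#' Restricts to genes (or homolog groups) oscillating in both datasets,
#' then compares peak phases by circular correlation and amplitudes by
#' Pearson correlation. Phase and amplitude are only meaningful descriptors
#' for significant oscillators, hence the restriction.
#'
#' @param res_a,res_b Per-gene result tables from [rhythm_detect()].
#' @param homolog_map Optional data frame `group_id`, `dataset`, `gene_id`
#'   relating gene ids across datasets; by default gene ids are matched
#'   directly (the identity map, appropriate for replicate pairs).
#' @param names_ab Dataset names, used for the `pair` label and for
#'   selecting rows of `homolog_map`.
#' @param period Period in hours for the phase comparison.
#' @return One-row data frame: `pair`, `n_shared`, `rho_ccc`, `p_ccc`,
#'   `rho_amp`, `p_amp`. When fewer than 3 shared oscillators exist the
#'   comparison is skipped with a warning and the statistics are NA.
#' @export
compare_datasets <- function(res_a, res_b, homolog_map = NULL,
                             names_ab = c("a", "b"), period = 24) {
  oa <- res_a[res_a$oscillating, , drop = FALSE]
  ob <- res_b[res_b$oscillating, , drop = FALSE]
  if (is.null(homolog_map)) {
    shared <- intersect(oa$gene_id, ob$gene_id)
    ia <- match(shared, oa$gene_id)
    ib <- match(shared, ob$gene_id)
  } else {
    ma <- homolog_map[homolog_map$dataset == names_ab[[1]], , drop = FALSE]
    mb <- homolog_map[homolog_map$dataset == names_ab[[2]], , drop = FALSE]
    ga <- ma$group_id[match(oa$gene_id, ma$gene_id)]
    gb <- mb$group_id[match(ob$gene_id, mb$gene_id)]
    shared <- intersect(ga[!is.na(ga)], gb[!is.na(gb)])
    ia <- match(shared, ga)
    ib <- match(shared, gb)
  }
  out <- data.frame(pair = paste(names_ab, collapse = " vs "),
                    n_shared = length(shared), rho_ccc = NA_real_,
                    p_ccc = NA_real_, rho_amp = NA_real_, p_amp = NA_real_,
                    stringsAsFactors = FALSE)
  if (length(shared) < 3) {
    warning("compare_datasets: fewer than 3 shared oscillators; skipped")
    return(out)
  }
  cc <- circular_correlation(oa$phase[ia], ob$phase[ib], period = period)
  ct <- stats::cor.test(oa$amplitude[ia], ob$amplitude[ib])
  out$rho_ccc <- cc$rho_ccc
  out$p_ccc <- cc$p
  out$rho_amp <- unname(ct$estimate)
  out$p_amp <- ct$p.value
  out
}

#' All pairwise dataset comparisons
#'
#' @param results_list Named list of per-gene result tables.
#' @param homolog_map Optional homolog map (see [compare_datasets()]).
#' @param period Period in hours.
#' @return Data frame with one row per dataset pair.
#' @export
compare_all <- function(results_list, homolog_map = NULL, period = 24) {
  nm <- names(results_list)
  stopifnot(!is.null(nm), length(nm) >= 2)
  pairs <- utils::combn(nm, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    compare_datasets(results_list[[pairs[1, k]]],
                     results_list[[pairs[2, k]]],
                     homolog_map = homolog_map,
                     names_ab = pairs[, k], period = period)
  }))
}

#' Core diurnal gene set
#'
#' Homolog groups (or shared gene ids) whose members oscillate
#' significantly in every dataset.
#'
#' @param results_list Named list of per-gene result tables.
#' @param homolog_map Optional homolog map `group_id`, `dataset`,
#'   `gene_id`; by default gene ids are matched directly across datasets.
#' @return Character vector of group ids (or gene ids) oscillating in all
#'   datasets.
#' @export
core_diurnal_set <- function(results_list, homolog_map = NULL) {
  stopifnot(length(results_list) >= 1)
  sets <- lapply(names(results_list), function(nm) {
    res <- results_list[[nm]]
    osc <- res$gene_id[res$oscillating]
    if (is.null(homolog_map)) return(osc)
    mm <- homolog_map[homolog_map$dataset == nm, , drop = FALSE]
    unique(mm$group_id[mm$gene_id %in% osc])
  })
  Reduce(intersect, sets)
}
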