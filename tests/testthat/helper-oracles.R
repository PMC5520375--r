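# Independent oracles used to cross-check the package's implementations.
# Each is a deliberately naive transcription of the underlying definition
# and shares no code with the functions it checks.

# Brute-force Gotoh dynamic programming for local alignment with affine
# gaps; a gap of length k costs gap_open + k * gap_extend.
sw_oracle <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(ca)
  m <- length(cb)
  H <- E <- F <- matrix(-Inf, n + 1, m + 1)
  H[1, ] <- 0
  H[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(E[i, j - 1], H[i, j - 1] - gap_open) - gap_extend
      F[i, j] <- max(F[i - 1, j], H[i - 1, j] - gap_open) - gap_extend
      H[i, j] <- max(0,
                     H[i - 1, j - 1] + submat[ca[i - 1], cb[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Right-tail hypergeometric probability by direct enumeration with choose().
fisher_enum_oracle <- function(a, b, c, d) {
  m <- a + b
  k <- a + c
  n <- a + b + c + d
  total <- 0
  for (x in a:min(m, k)) {
    total <- total + choose(m, x) * choose(n - m, k - x)
  }
  total / choose(n, k)
}

# Benjamini-Hochberg step-up, written out directly.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    adj[o[i]] <- val
    prev <- val
  }
  pmin(adj, 1)
}

# Jammalamadaka-SenGupta circular correlation as a plain loop.
ccc_oracle <- function(phases_a, phases_b, period = 24) {
  a <- 2 * pi * phases_a / period
  b <- 2 * pi * phases_b / period
  abar <- atan2(sum(sin(a)), sum(cos(a)))
  bbar <- atan2(sum(sin(b)), sum(cos(b)))
  num <- 0
  da <- 0
  db <- 0
  for (i in seq_along(a)) {
    num <- num + sin(a[i] - abar) * sin(b[i] - bbar)
    da <- da + sin(a[i] - abar)^2
    db <- db + sin(b[i] - bbar)^2
  }
  num / sqrt(da * db)
}

# Grid search over peak phase for the sinusoid-plus-trend model: for each
# candidate phase, ordinary least squares of y on (1, t, cos(w(t - phi)));
# returns the phase/amplitude pair with the smallest residual sum of
# squares. Grid resolution in hours.
grid_phase_oracle <- function(t, y, period = 24, step = 0.01) {
  w <- 2 * pi / period
  phis <- seq(0, period - step, by = step)
  best <- list(rss = Inf, phase = NA, amplitude = NA)
  for (phi in phis) {
    X <- cbind(1, t, cos(w * (t - phi)))
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    if (rss < best$rss) {
      best <- list(rss = rss, phase = phi, amplitude = fit$coefficients[3])
    }
  }
  if (best$amplitude < 0) {
    best$phase <- (best$phase + period / 2) %% period
    best$amplitude <- -best$amplitude
  }
  best
}

# Published Savitzky-Golay convolution coefficients for window 5, degree 2.
sg52_coef <- c(-3, 12, 17, 12, -3) / 35

# Circular absolute difference in hours.
phase_diff <- function(a, b, period = 24) {
  d <- abs(a - b) %% period
  pmin(d, period - d)
}

# Two expression datasets generated from one shared phase/amplitude
# program with independent noise -- a twin-study fixture.
twin_datasets <- function(n_genes = 150, noise_sd = 0.1, seed = 67) {
  set.seed(seed)
  phases <- runif(n_genes, 0, 24)
  amps <- runif(n_genes, 0.8, 1.5)
  t <- seq(0, 44, by = 4)
  mk <- function() {
    v <- t(vapply(seq_len(n_genes), function(g) {
      amps[g] * cos(2 * pi * (t - phases[g]) / 24) +
        rnorm(length(t), 0, noise_sd)
    }, numeric(length(t))))
    rownames(v) <- sprintf("g%03d", seq_len(n_genes))
    v
  }
  list(a = mk(), b = mk(), time = t, phases = phases)
}

# Random amino-acid sequence.
random_aa <- function(n) {
  paste(sample(clockmine::AA_STANDARD, n, replace = TRUE), collapse = "")
}

# A small synthetic RBH table with the columns the inventory layer needs.
make_rbh_row <- function(query_id, subject_id, organism,
                         taxon_group = "Cyanobacteria", genus = NULL,
                         bitscore = 100, evalue = 1e-30,
                         percent_similarity = 90, subtype = query_id) {
  data.frame(query_id = query_id, subject_id = subject_id,
             subject_organism = organism,
             subject_genus = if (is.null(genus))
               sub("\\s.*$", "", organism) else genus,
             subject_taxon_group = taxon_group, score = bitscore,
             bitscore = bitscore, evalue = evalue,
             percent_similarity = percent_similarity, aln_length = 100L,
             reverse_best_id = query_id, subtype = subtype,
             stringsAsFactors = FALSE)
}
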