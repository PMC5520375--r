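planted_rbh <- function() {
  rbind(
    make_rbh_row("KaiC1", "a_c1a", "Strain A"),
    make_rbh_row("KaiC1", "a_c1b", "Strain A"),
    make_rbh_row("KaiB1", "a_b1", "Strain A"),
    make_rbh_row("KaiC3", "b_c3", "Strain B", taxon_group = "Archaea"),
    make_rbh_row("RpaB", "c_rpab", "Strain C")  # no KaiC-family: dropped
  )
}

test_that("inventories count copies and apply the KaiC retention filter", {
  inv <- build_inventory(planted_rbh())
  expect_setequal(unique(inv$strain), c("Strain A", "Strain B"))
  a <- inv[inv$strain == "Strain A", ]
  expect_equal(a$copy_count[a$factor == "KaiC1"], 2L)
  expect_equal(a$copy_count[a$factor == "KaiB1"], 1L)
  expect_false("Strain C" %in% inv$strain)
})

test_that("the merge map collapses reference labels and rejects unknowns", {
  rows <- rbind(make_rbh_row("KaiC", "x_c", "Strain X"),
                make_rbh_row("KaiB", "x_b", "Strain X"))
  inv <- build_inventory(rows)
  expect_setequal(inv$factor, c("KaiC1", "KaiB1"))
  expect_error(build_inventory(rows, merge_map = c(Bogus = "KaiC1")),
               "unknown factor label")
})

test_that("inventory construction is idempotent and permutation-invariant", {
  rbh <- planted_rbh()
  inv1 <- build_inventory(rbh)
  set.seed(3)
  inv2 <- build_inventory(rbh[sample(nrow(rbh)), ])
  expect_equal(inv1, inv2)
})

test_that("every retained system contains a KaiC-family factor", {
  set.seed(21)
  orgs <- sprintf("Org %d", 1:12)
  rows <- do.call(rbind, lapply(orgs, function(o) {
    fs <- sample(c("KaiC1", "KaiC3", "KaiB1", "SasA", "RpaB"),
                 sample(1:4, 1))
    do.call(rbind, lapply(fs, function(f)
      make_rbh_row(f, paste0(gsub(" ", "", o), "_", f), o)))
  }))
  inv <- build_inventory(rows)
  for (s in unique(inv$strain)) {
    expect_true(any(inv$factor[inv$strain == s] %in% kaic_family()))
  }
})

test_that("genus means average similarity across a genus's genomes", {
  rows <- rbind(
    make_rbh_row("KaiC1", "s1_c", "Nostoc one", percent_similarity = 70),
    make_rbh_row("KaiC1", "s2_c", "Nostoc two", percent_similarity = 90),
    make_rbh_row("KaiA", "s1_a", "Nostoc one", percent_similarity = 80),
    make_rbh_row("KaiA", "s2_a", "Nostoc two", percent_similarity = 90)
  )
  gs <- genus_mean_similarity(rows)
  expect_equal(gs$mean_similarity[gs$factor == "KaiA"], 85)
  expect_equal(gs$mean_similarity[gs$factor == "KaiC1"], 80)
  expect_equal(unique(gs$n_genomes), 2L)
  # factors with no hit are absent, not zero
  expect_false("SasA" %in% gs$factor)
})

test_that("genus means equal an independent group-by oracle", {
  set.seed(31)
  rows <- do.call(rbind, lapply(1:40, function(i) {
    g <- sample(c("GenA", "GenB", "GenC"), 1)
    make_rbh_row(sample(c("KaiC1", "KaiB1", "CikA"), 1),
                 sprintf("p%03d", i), paste(g, "strain", i %% 5),
                 percent_similarity = runif(1, 40, 100))
  }))
  gs <- genus_mean_similarity(rows)
  # oracle restricted to retained strains (those with a KaiC-family hit)
  retained <- unique(rows$subject_organism[rows$subtype %in% kaic_family()])
  kept <- rows[rows$subject_organism %in% retained, ]
  oracle <- tapply(kept$percent_similarity,
                   paste(kept$subject_genus, kept$subtype), mean)
  got <- setNames(gs$mean_similarity, paste(gs$genus, gs$factor))
  # all oracle groups whose genus passed the KaiC filter must agree
  common <- intersect(names(oracle), names(got))
  expect_gt(length(common), 3)
  expect_equal(as.numeric(got[common]), as.numeric(oracle[common]))
  # values bounded by contributing hits
  expect_true(all(gs$mean_similarity >= min(rows$percent_similarity) -
                    1e-9))
  expect_true(all(gs$mean_similarity <= max(rows$percent_similarity) +
                    1e-9))
})

test_that("genera are ordered by taxon group then KaiC similarity", {
  rows <- rbind(
    make_rbh_row("KaiC1", "p1", "Low sp.", percent_similarity = 50),
    make_rbh_row("KaiC1", "p2", "High sp.", percent_similarity = 95),
    make_rbh_row("KaiC1", "p3", "Arch sp.", taxon_group = "Archaea",
                 percent_similarity = 99)
  )
  gs <- genus_mean_similarity(rows)
  lv <- levels(gs$genus)
  expect_equal(lv, c("High", "Low", "Arch"))
})

test_that("copy numbers above five are condensed", {
  inv <- build_inventory(rbind(
    do.call(rbind, lapply(1:7, function(i)
      make_rbh_row("KaiC1", sprintf("m%d", i), "Strain M"))),
    make_rbh_row("KaiB1", "m_b", "Strain M"),
    do.call(rbind, lapply(1:5, function(i)
      make_rbh_row("KaiC3", sprintf("n%d", i), "Strain N")))
  ))
  prof <- copy_number_profile(inv)
  expect_equal(prof["Strain M", "KaiC1"], ">5")
  expect_equal(prof["Strain M", "KaiB1"], "1")
  expect_equal(prof["Strain M", "KaiC3"], "0")
  expect_equal(prof["Strain N", "KaiC3"], "5")
})

test_that("length distributions give joint tables and stepwise CDFs", {
  recs <- data.frame(
    factor = c("KaiC1", "KaiA", "KaiB1", "KaiC1", "KaiB1"),
    subject_id = paste0("p", 1:5),
    organism = c("Ref", "Ref", "Ref", "Other", "Other"),
    taxon_group = "Cyanobacteria",
    length = c(519L, 284L, 102L, 500L, 250L),
    stringsAsFactors = FALSE
  )
  ld <- length_distribution(recs, c("KaiA", "KaiC1"))
  # only the organism with both factors enters the joint table
  expect_equal(nrow(ld$joint), 1)
  expect_equal(ld$joint$length_x, 284L)
  expect_equal(ld$joint$length_y, 519L)
  # single KaiA record: CDF is a unit step at its length
  expect_equal(ld$cdf$KaiA(283), 0)
  expect_equal(ld$cdf$KaiA(284), 1)

  # planted bimodal KaiB lengths show two CDF plateaus
  bim <- data.frame(factor = "KaiB1", subject_id = sprintf("b%d", 1:20),
                    organism = sprintf("o%d", 1:20),
                    taxon_group = "Cyanobacteria",
                    length = rep(c(102L, 250L), each = 10),
                    stringsAsFactors = FALSE)
  ld2 <- length_distribution(rbind(recs, bim), c("KaiB1", "KaiC1"))
  cdf <- ld2$cdf$KaiB1
  # histogram oracle: two modes at 102 and 250
  counts <- table(c(recs$length[recs$factor == "KaiB1"], bim$length))
  modes <- as.integer(names(counts)[counts >= 10])
  expect_equal(modes, c(102L, 250L))
  expect_equal(cdf(102) - cdf(101), 11 / 22)
  expect_equal(cdf(250) - cdf(249), 11 / 22)
  expect_equal(cdf(200), cdf(102))  # plateau between the modes
})

test_that("length records use merged labels and deduplicate subjects", {
  db <- c(x_c = strrep("A", 519), x_b = strrep("A", 102))
  rows <- rbind(make_rbh_row("KaiC", "x_c", "Strain X"),
                make_rbh_row("KaiC1", "x_c", "Strain X"),
                make_rbh_row("KaiB", "x_b", "Strain X"))
  rec <- length_records(rows, db)
  expect_equal(nrow(rec), 2)
  expect_setequal(rec$factor, c("KaiC1", "KaiB1"))
  expect_equal(sort(unname(rec$length)), c(102L, 519L))
})
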