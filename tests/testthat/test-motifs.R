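toy_msa <- function() {
  c(ref  = "MKGATGTGKTST",
    hom1 = "MKGATGTGKTST",
    hom2 = "MRGATGTGKTSA",
    hom3 = "M-GASGTGKTST")
}

test_that("reference mapping walks non-gap reference characters", {
  msa <- c(r = "AB-C", x = "ABDC")
  mp <- map_to_reference(sanitize_aa(msa) |> setNames(names(msa)), "r")
  expect_equal(mp, c(1L, 2L, NA, 3L))
  # gap-free reference maps to the identity
  msa2 <- toy_msa()
  mp2 <- map_to_reference(msa2, "ref")
  expect_equal(mp2, 1:12)
  expect_error(map_to_reference(msa2, "nope"), "absent")
})

test_that("reference mapping is a bijection onto 1..L (oracle check)", {
  set.seed(71)
  for (i in 1:20) {
    width <- sample(10:30, 1)
    seqs <- vapply(1:3, function(j) {
      chars <- sample(c(AA_STANDARD, "-"), width, replace = TRUE,
                      prob = c(rep(1, 20), 6))
      paste(chars, collapse = "")
    }, character(1))
    names(seqs) <- c("r", "s1", "s2")
    if (!grepl("[A-Z]", seqs[["r"]])) next
    mp <- map_to_reference(seqs, "r")
    # character-walking oracle
    ref <- strsplit(seqs[["r"]], "")[[1]]
    walk <- integer(0)
    count <- 0
    for (ch in ref) {
      count <- count + (ch != "-")
      walk <- c(walk, if (ch != "-") count else NA_integer_)
    }
    expect_equal(mp, walk)
    # bijection between non-gap columns and 1..L
    expect_equal(sort(mp[!is.na(mp)]), seq_len(sum(ref != "-")))
  }
})

test_that("column frequencies are exact relative counts summing to one", {
  msa <- c(r = "ASD", a = "ASD", b = "ASD", c = "ATD")
  mp <- map_to_reference(msa, "r")
  pfm <- column_frequencies(msa, mp, motif_window("site", 2))
  s_freq <- pfm$frequency[pfm$residue == "S"]
  t_freq <- pfm$frequency[pfm$residue == "T"]
  expect_equal(s_freq, 0.75)
  expect_equal(t_freq, 0.25)
  expect_equal(sum(pfm$frequency), 1, tolerance = 1e-9)
  dom <- attr(pfm, "dominant")
  expect_equal(dom$residue, "S")
  expect_equal(dom$frequency, 0.75)

  # two identical sequences: dominant frequency 1 everywhere
  msa2 <- c(r = "GKT", x = "GKT")
  pfm2 <- column_frequencies(msa2, map_to_reference(msa2, "r"),
                             motif_window("w", 1:3))
  expect_true(all(attr(pfm2, "dominant")$frequency == 1))
  expect_error(column_frequencies(msa2, map_to_reference(msa2, "r"),
                                  motif_window("w", 5)), "outside")
})

test_that("excluding a record and renormalising equals recomputation", {
  msa <- toy_msa()
  mp <- map_to_reference(msa, "ref")
  w <- motif_window("w", c(4, 5))
  no_ref <- column_frequencies(msa, mp, w, include_reference = FALSE,
                               reference_id = "ref")
  recomputed <- column_frequencies(msa[names(msa) != "ref"],
                                   map_to_reference(msa, "ref"), w)
  expect_equal(no_ref$frequency, recomputed$frequency)
})

test_that("per-column frequencies match planted mutation counts", {
  set.seed(73)
  base <- random_aa(30)
  n_rec <- 20
  mut_pos <- 11
  n_mut <- 6
  seqs <- vapply(1:n_rec, function(i) {
    chars <- strsplit(base, "")[[1]]
    if (i <= n_mut) chars[mut_pos] <- setdiff(AA_STANDARD,
                                              chars[mut_pos])[1]
    paste(chars, collapse = "")
  }, character(1))
  names(seqs) <- c("ref", sprintf("m%02d", 2:n_rec))
  mp <- map_to_reference(seqs, "ref")
  pfm <- column_frequencies(seqs, mp, motif_window("w", mut_pos))
  orig <- substr(base, mut_pos, mut_pos)
  expect_equal(pfm$frequency[pfm$residue == orig],
               (n_rec - n_mut) / n_rec)
})

test_that("motif reports score wildcard pattern matches", {
  msa <- toy_msa()
  mp <- map_to_reference(msa, "ref")
  w <- motif_window("walker_a", 3:10)
  rep1 <- motif_report(msa, mp, list(w),
                       patterns = c(walker_a = "GXXXXGKT"))
  # all four records carry the invariant anchors (X tolerates hom3's S)
  expect_equal(rep1$match_fraction, 1)
  expect_equal(rep1$consensus, "GATGTGKT")

  # a gap inside the window can never satisfy the pattern
  msa_gap <- c(r = "MKGATGTGKTST", g1 = "MKGAT--GKTST")
  repg <- motif_report(msa_gap, map_to_reference(msa_gap, "r"), list(w),
                       patterns = c(walker_a = "GXXXXGKT"))
  expect_equal(repg$match_fraction, 0.5)

  # mutating the invariant K in one of four sequences drops the fraction
  msa2 <- c(r = "GATGTGKT", a = "GATGTGKT", b = "GCCCCGKT",
            c = "GATGTGAT")
  rep2 <- motif_report(msa2, map_to_reference(msa2, "r"),
                       list(motif_window("walker_a", 1:8)),
                       patterns = c(walker_a = "GXXXXGKT"))
  expect_equal(rep2$match_fraction, 0.75)

  # record order must not matter
  rep3 <- motif_report(msa2[c(3, 1, 4, 2)],
                       map_to_reference(msa2[c(3, 1, 4, 2)], "r"),
                       list(motif_window("walker_a", 1:8)),
                       patterns = c(walker_a = "GXXXXGKT"))
  expect_equal(rep3$match_fraction, rep2$match_fraction)

  expect_error(motif_report(msa2, map_to_reference(msa2, "r"),
                            list(motif_window("walker_a", 1:5)),
                            patterns = c(walker_a = "GXXXXGKT")),
               "mismatch")
})

test_that("planted degenerate loops yield the planted match fraction", {
  set.seed(79)
  n <- 40
  good <- "GATGTGKT"
  degen <- "GQRSTGAT"
  frac_degen <- 0.3
  seqs <- vapply(1:n, function(i) {
    core <- if (i <= frac_degen * n) degen else good
    paste0(random_aa(5), core, random_aa(5))
  }, character(1))
  names(seqs) <- c("ref", sprintf("s%02d", 2:n))
  # make the reference carry the canonical motif
  seqs[["ref"]] <- paste0(substr(seqs[["ref"]], 1, 5), good,
                          substr(seqs[["ref"]], 14, 18))
  mp <- map_to_reference(seqs, "ref")
  rep <- motif_report(seqs, mp, list(motif_window("walker_a", 6:13)),
                      patterns = c(walker_a = "GXXXXGKT"))
  expect_equal(rep$match_fraction, 1 - frac_degen + 1 / n)
})

test_that("aligned FASTA round-trips through the MSA reader", {
  d <- withr::local_tempdir()
  p <- file.path(d, "aln.fasta")
  writeLines(c(">ref", "MKGAT-GKT", ">hom", "MRGATSGKT"), p)
  msa <- read_msa(p)
  expect_equal(length(msa), 2)
  expect_equal(unname(nchar(msa)), c(9, 9))
  expect_equal(unname(msa[["ref"]]), "MKGAT-GKT")
  expect_error(as_msa(c(a = "AB")), "at least 2")
  expect_error(as_msa(c(a = "AB", b = "ABC")), "equal length")
})

test_that("default KaiC windows anchor on named reference residues", {
  set.seed(83)
  ref <- paste0(random_aa(200), "GATGTGKT", random_aa(217),
                "T", random_aa(4), "ST", random_aa(80))
  # layout: walker A at 201..208, T at 426, S431 T432
  expect_equal(substr(ref, 426, 426), "T")
  expect_equal(substr(ref, 431, 432), "ST")
  w <- kaic_motif_windows(ref)
  expect_equal(w$phosphosites$positions, c(431L, 432L))
  expect_equal(w$T426$positions, 426L)
  expect_equal(w$walker_a$positions[1], 201L)
  pats <- attr(w, "patterns")
  expect_equal(unname(pats["walker_a"]), "GXXXXGKT")
  expect_null(locate_pattern("AAAA", "GXXXXGKT"))
})
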