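test_that("sequence normalization uppercases, maps T to U and names bad positions", {
  expect_equal(normalize_sequence("acgt"), "ACGU")
  expect_equal(normalize_sequence("UGAUGA"), "UGAUGA")
  expect_error(normalize_sequence("ACGX"), "position 4")
  expect_error(normalize_sequence("ACGN"), "position 4")
  expect_equal(normalize_sequence("ACGN", allow_n = TRUE), "ACGN")
  expect_error(normalize_sequence(""), "empty")
})

test_that("box scanning finds all occurrences with positional classes", {
  d <- scan_boxes("CUGA")
  expect_equal(nrow(d), 1L)
  expect_equal(d$start, 0L)
  expect_equal(d$end, 4L)
  expect_equal(d$position_class, "terminal_5p")

  s <- paste0("UGAUGA", strrep("A", 20), "CUGA", strrep("A", 20), "CUGA")
  expect_equal(nchar(s), 54L)
  b <- scan_boxes(s)
  cb <- b[b$box_type == "C", ]
  db <- b[b$box_type == "D", ]
  expect_equal(nrow(cb), 1L)
  expect_equal(cb$position_class, "terminal_5p")
  expect_equal(db$start, c(26L, 50L))
  expect_equal(db$end, c(30L, 54L))
  expect_equal(db$position_class, c("internal", "terminal_3p"))

  adj <- scan_boxes("CUGACUGA")
  expect_equal(adj$start, c(0L, 4L))
  expect_equal(adj$end, c(4L, 8L))
})

test_that("box scanning equals the naive substring oracle on random sequences", {
  set.seed(101)
  for (i in 1:200) {
    # enriched in motif letters so hits are common
    s <- random_rna(sample(20:120, 1), prob = c(0.2, 0.15, 0.3, 0.35))
    found <- scan_boxes(s)
    expect_equal(found$start[found$box_type == "C"],
                 brute_force_starts(s, "UGAUGA"))
    expect_equal(found$start[found$box_type == "D"],
                 brute_force_starts(s, "CUGA"))
  }
})

test_that("dinucleotide counting uses overlapping step-1 windows", {
  expect_equal(dinucleotide_counts("UGUG"), c(UG = 2L, CG = 0L))
  expect_equal(dinucleotide_counts("CGCG"), c(UG = 0L, CG = 2L))
  expect_equal(dinucleotide_counts("AAAA"), c(UG = 0L, CG = 0L))
  expect_warning(z <- dinucleotide_counts("A"), "shorter")
  expect_equal(z, c(UG = 0L, CG = 0L))
})

test_that("IQR bounds reproduce hand-computed and quartile-inverted values", {
  b <- length_outlier_bounds(c(48, 70, 75, 80, 88, 90, 120))
  expect_equal(b$q25, 72.5)
  expect_equal(b$q75, 89.0)
  expect_equal(b$iqr, 16.5)
  expect_equal(b$lower, 47.75)
  expect_equal(b$upper, 113.75)

  inv <- bounds_from_quartiles(70.995, 87.745)
  expect_equal(inv$lower, 45.87, tolerance = 1e-9)
  expect_equal(inv$upper, 112.87, tolerance = 1e-9)

  deg <- length_outlier_bounds(rep(77, 5))
  expect_equal(deg$lower, 77)
  expect_equal(deg$upper, 77)
  expect_error(length_outlier_bounds(c(1, 2, 3)), "at least 4")
})

test_that("IQR bounds are translation- and scale-equivariant", {
  set.seed(7)
  lens <- sample(48:237, 30, replace = TRUE)
  b <- length_outlier_bounds(lens)
  sh <- length_outlier_bounds(lens + 11)
  sc <- length_outlier_bounds(lens * 3)
  for (f in c("q25", "q75", "lower", "upper")) {
    expect_equal(sh[[f]], b[[f]] + 11)
    expect_equal(sc[[f]], b[[f]] * 3)
  }
  sweep_tab <- bounds_estimator_sweep(lens)
  expect_equal(nrow(sweep_tab), 9L)
  expect_true(all(sweep_tab$upper >= sweep_tab$q75))
})

test_that("outlier flagging respects fences, explicit thresholds and sides", {
  expect_length(flag_length_outliers(integer(),
                                     bounds_from_quartiles(50, 80)), 0L)
  lens <- c(48, 90, 114, 237)
  expect_equal(sum(flag_length_outliers(lens, threshold = 112.87)), 2L)
  b <- bounds_from_quartiles(70.995, 87.745)  # lower 45.87
  expect_equal(sum(flag_length_outliers(lens, b, side = "both") & lens < 48),
               0L)  # no short outliers when min length is 48
  expect_true(all(which(flag_length_outliers(lens, b)) == c(3L, 4L)))
})

test_that("K2P distance matches the closed form and handles saturation", {
  id <- k2p_distance("ACGUACGUAC", "ACGUACGUAC")
  expect_equal(id$distance, 0)
  expect_equal(id$p_transitions, 0)

  # one transition (A->G) and one transversion (A->U) in 10 sites
  a <- "ACGUACGUAC"
  b <- "GCGUACGUUC"
  r <- k2p_distance(a, b, aligner = "none")
  expect_equal(r$p_transitions, 0.1)
  expect_equal(r$q_transversions, 0.1)
  expect_equal(r$distance, -0.5 * log(1 - 0.3) - 0.25 * log(1 - 0.2),
               tolerance = 1e-12)
  expect_equal(r$distance, 0.2341234, tolerance = 1e-6)
  # symmetry
  expect_equal(k2p_distance(b, a, aligner = "none")$distance, r$distance)

  expect_error(k2p_distance("AAAAAAAAAA", "GGGGGAAAAA", aligner = "none"),
               class = "fluorosnc_saturation")
})

test_that("K2P agrees with ape's K80 distance on random equal-length pairs", {
  skip_if_not_installed("ape")
  set.seed(55)
  for (i in 1:25) {
    a <- random_rna(60)
    # mutate a little so distances stay in the defined domain
    b <- strsplit(a, "")[[1L]]
    idx <- sample(60, 6)
    b[idx] <- sample(c("A", "C", "G", "U"), 6, replace = TRUE)
    b <- paste(b, collapse = "")
    mine <- tryCatch(k2p_distance(a, b, aligner = "none")$distance,
                     fluorosnc_saturation = function(e) NA_real_)
    m <- rbind(strsplit(chartr("U", "T", a), "")[[1L]],
               strsplit(chartr("U", "T", b), "")[[1L]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(tolower(m)), model = "K80"))
    if (!is.na(mine)) expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("K2P exceeds the raw mismatch proportion for small divergence", {
  set.seed(66)
  a <- random_rna(200)
  b <- strsplit(a, "")[[1L]]
  idx <- sample(200, 12)
  b[idx] <- sample(c("A", "C", "G", "U"), 12, replace = TRUE)
  b <- paste(b, collapse = "")
  r <- k2p_distance(a, b, aligner = "none")
  mismatch <- r$p_transitions + r$q_transversions
  if (mismatch > 0) expect_gt(r$distance, mismatch)
})

test_that("global alignment lets K2P compare unequal-length sequences", {
  a <- "AAGCUUCGAAGGCAUCCGUA"
  b <- substr(a, 1, 16)        # same with 4 nt missing at the end
  r <- k2p_distance(a, b)
  expect_equal(r$distance, 0)
  expect_equal(r$sites_compared, 16L)
  # a mid-sequence transition survives alignment (gapping it out would cost
  # more than the mismatch under the -1/-2 scoring)
  b2 <- paste0(substr(b, 1, 4), "C", substr(b, 6, 16))  # U -> C at position 5
  r2 <- k2p_distance(a, b2)
  expect_equal(r2$p_transitions, 1 / 16)
  expect_gt(r2$distance, 0)
})

test_that("mean pairwise K2P averages defined pairs and reports saturated ones", {
  expect_equal(as.numeric(mean_pairwise_k2p(c("ACGUACGU", "ACGUACGU"))), 0)
  set.seed(77)
  seqs <- replicate(4, {
    a <- strsplit(random_rna(50), "")[[1L]]
    paste(a, collapse = "")
  })
  # permutation invariance
  m1 <- mean_pairwise_k2p(seqs)
  m2 <- mean_pairwise_k2p(rev(seqs))
  expect_equal(as.numeric(m1), as.numeric(m2), tolerance = 1e-12)
  expect_error(mean_pairwise_k2p("ACGU"), "at least 2")
  # saturated pairs (1-2 and 2-3 here) are excluded and counted
  sat <- c("AAAAAAAAAA", "GGGGGAAAAA", "AAAAAAAAAG")
  m3 <- mean_pairwise_k2p(sat, aligner = "none")
  expect_equal(attr(m3, "n_saturated"), 2L)
  expect_equal(attr(m3, "n_pairs"), 1L)
})

test_that("feature records recover the generator's planted truth", {
  set <- gen_snorna_set(8, 3, c_box_count_per_seq = 1,
                        d_box_counts = c(rep(1, 8), 2, 3, 4), seed = 13)
  feats <- snorna_features(setNames(set$sequence, set$id))
  expect_equal(feats$c_box_count, set$c_box_count)
  expect_equal(feats$d_box_count, set$d_box_count)
  expect_equal(feats$length, set$length)
  # UG/CG counts match a direct substring count
  expect_equal(feats$ug_count, vapply(set$sequence, function(s)
    length(brute_force_starts(s, "UG")), integer(1L)), ignore_attr = TRUE)
})

test_that("D-box multiplicity summary stratifies outliers by regulation", {
  rec <- data.frame(id = c("a", "b", "c", "d"),
                    d_box_count = c(3, 2, 1, 0),
                    is_length_outlier = TRUE,
                    direction = c("down", "down", "up", "up"))
  s <- dbox_regulation_summary(rec)
  expect_equal(unname(s$down_fraction[">=2"]), 1.0)
  expect_equal(unname(s$down_fraction["<2"]), 0.0)
  expect_equal(as.vector(s$table), c(2L, 0L, 0L, 2L))

  rec$direction[2] <- NA
  expect_error(dbox_regulation_summary(rec), "b")

  none <- data.frame(id = "x", d_box_count = 2, is_length_outlier = FALSE,
                     direction = "down")
  expect_warning(z <- dbox_regulation_summary(none), "no length outliers")
  expect_equal(sum(z$table), 0L)
})
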