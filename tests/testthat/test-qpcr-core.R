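test_that("ct export parsing keeps missingness explicit and rejects malformed input", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plate_id,well,sample_id,role,ct_fam,ct_cy5,ct_dfo",
    "P1,A01,S001,sample,24.1,25.3,23.0",
    "P1,A02,S001,sample,,25.1,23.1",
    "P1,A03,,water,,,"
  ), path)
  wells <- read_ct_export(path)
  expect_equal(nrow(wells), 3L)
  expect_equal(wells$ct_fam[1], 24.1)
  expect_equal(wells$ct_cy5[1], 25.3)
  expect_true(is.na(wells$ct_fam[2]))   # empty cell = no crossing, not 0/40
  expect_true(is.na(wells$sample_id[3]))

  dup <- rbind(wells, wells[1, ])
  expect_error(compute_delta_ct(dup), "duplicate")

  bad <- wells
  bad$ct_fam[1] <- 44
  expect_error(kircnv:::validate_well_table(bad), "\\(0, 40\\]")

  extra <- wells
  extra$ct_vic <- 20
  expect_error(kircnv:::validate_well_table(extra), "unknown Ct channel")
})

test_that("delta-Ct is the replicate median with per-channel missingness counts", {
  # constant replicates: dct = ref - gene = 1 for both genes
  w1 <- make_wells("S1", ct_fam = 24, ct_cy5 = 24, ct_dfo = 25)
  # per-well 3DS1 dct {1.0, 1.1, 1.2, 9.9} -> median 1.15
  w2 <- make_wells("S2", ct_fam = c(24, 23.9, 23.8, 15.1), ct_cy5 = 24,
                   ct_dfo = 25, well_offset = 24)
  # gene missing in 2 of 4 wells; available dcts {0.9, 1.1} -> 1.0
  w3 <- make_wells("S3", ct_fam = c(24.1, 23.9, NA, NA), ct_cy5 = 24,
                   ct_dfo = 25, well_offset = 48)
  dct <- compute_delta_ct(rbind_wells(w1, w2, w3))
  dct <- dct[order(dct$sample_id), ]
  expect_equal(dct$dct_3ds1, c(1.0, 1.15, 1.0))
  expect_equal(dct$dct_3dl1, rep(1.0, 3))
  expect_equal(dct$n_missing_3ds1, c(0L, 0L, 2L))
  expect_equal(dct$n_missing_ref, c(0L, 0L, 0L))

  # replicate order never matters
  shuffled <- rbind_wells(w3, w1, w2)
  shuffled <- shuffled[sample(nrow(shuffled)), ]
  dct2 <- compute_delta_ct(shuffled)
  expect_equal(dct2[order(dct2$sample_id), c("dct_3ds1", "dct_3dl1")],
               dct[, c("dct_3ds1", "dct_3dl1")], ignore_attr = TRUE)

  five <- rbind_wells(w1, make_wells("S1", ct_dfo = 25, n_wells = 1,
                                     well_offset = 90))
  expect_error(compute_delta_ct(five), "more than 4 replicate wells")
})

test_that("dye channels can be mapped either way round", {
  w <- make_wells("S1", ct_fam = 24.5, ct_cy5 = 23.5, ct_dfo = 25)
  a <- compute_delta_ct(w)
  b <- compute_delta_ct(w, dye_map = c(FAM = "KIR3DL1", CY5 = "KIR3DS1"))
  expect_equal(a$dct_3ds1, b$dct_3dl1)
  expect_equal(a$dct_3dl1, b$dct_3ds1)
  expect_error(compute_delta_ct(w, dye_map = c(FAM = "KIR3DS1")), "dye_map")
})

test_that("QC drops reference failures and plates with inflated noise", {
  base <- make_two_group_plates(n_per_group = 40, plates = c("P1", "P2", "P3"),
                                sd = 0.05, seed = 3)
  noisy <- make_two_group_plates(n_per_group = 40, plates = "P9",
                                 sd = 0.16, seed = 4)  # ~3x inflated noise
  ref_fail <- make_dct("BAD1", "P1", NA, NA, 4, 4, n_missing_ref = 4)
  qc <- qc_filter(rbind(base, noisy, ref_fail))

  expect_true("BAD1" %in% qc$dropped$sample_id)
  expect_equal(qc$dropped$rule[qc$dropped$sample_id == "BAD1"],
               "reference non-amplification")
  # the whole noisy plate goes, with the plate-outlier rule recorded
  expect_true(all(qc$dropped$rule[qc$dropped$plate_id == "P9"] == "plate outlier"))
  expect_false("P9" %in% qc$kept$plate_id)
  expect_true(all(c("P1", "P2", "P3") %in% qc$kept$plate_id))

  # reference missing in only 3 of 4 wells is kept
  part_fail <- make_dct("OK1", "P2", 1.0, 2.0, n_missing_ref = 3)
  qc2 <- qc_filter(rbind(base, part_fail))
  expect_true("OK1" %in% qc2$kept$sample_id)

  # monotone: adding a failing sample never changes other dispositions
  expect_equal(qc2$kept$sample_id,
               qc_filter(rbind(base, part_fail, ref_fail))$kept$sample_id[
                 qc_filter(rbind(base, part_fail, ref_fail))$kept$sample_id != "BAD1"])
})

test_that("hard-zero rule fires at three or more missing gene replicates", {
  rec <- make_dct(c("A", "B", "C"), "P1",
                  dct_3ds1 = c(NA, 1.0, NA), dct_3dl1 = c(2.0, 2.0, NA),
                  n_missing_3ds1 = c(3, 2, 4), n_missing_3dl1 = c(0, 0, 4))
  hz <- apply_hard_zero(rec)
  expect_equal(hz$hard_zero_3ds1, c(TRUE, FALSE, TRUE))
  expect_equal(hz$hard_zero_3dl1, c(FALSE, FALSE, TRUE))
  expect_true(is.na(hz$dct_3ds1[1]))
  expect_equal(hz$no_call, c(FALSE, FALSE, TRUE))  # 0-0 is not a callable group
})

test_that("anchor location matches the brute-force 1-D two-medoid oracle", {
  set.seed(11)
  x <- c(rnorm(25, 0.8, 0.05), rnorm(25, 1.9, 0.05))
  anc <- locate_anchor_groups(x)
  oracle <- brute_force_2medoid(x)
  expect_equal(unname(anc), c(oracle$m1, oracle$m2), tolerance = 1e-12)
  expect_equal(unname(anc[1]), 0.8, tolerance = 0.05)
  expect_equal(unname(anc[2]), 1.9, tolerance = 0.05)

  # equivariance under monotone affine maps
  anc2 <- locate_anchor_groups(2 * x + 3)
  expect_equal(unname(anc2), unname(2 * anc + 3), tolerance = 1e-12)

  # moderately separated random data still matches the global optimum cost
  y <- c(rnorm(30, 1, 0.25), rnorm(30, 2, 0.25))
  part <- kircnv:::kmedoids2(y)
  oracle_y <- brute_force_2medoid(y)
  pam_cost <- sum(vapply(1:2, function(g) {
    v <- part$x[part$cluster == g]
    min(vapply(v, function(m) sum(abs(v - m)), numeric(1)))
  }, numeric(1)))
  expect_equal(pam_cost, oracle_y$cost, tolerance = 1e-9)

  expect_error(locate_anchor_groups(rep(1, 20)), "no separation")
  expect_error(locate_anchor_groups(rnorm(8)), "too sparse")
})

test_that("normalization anchors medians at 1 and 2, clamps negatives, and is affine-invariant", {
  rec <- make_two_group_plates(n_per_group = 15, plates = c("P1", "P2"),
                               sd = 0.04, seed = 5)
  rec <- apply_hard_zero(rec)
  anchors <- anchor_plates(rec)
  norm <- normalize_plates(rec, anchors)

  # the anchor medians themselves land exactly on 1 and 2
  for (i in seq_len(nrow(anchors))) {
    a <- anchors[i, ]
    col <- paste0("dct_", tolower(a$gene), "_preclamp")
    raw_col <- paste0("dct_", tolower(a$gene))
    on_plate <- rec$plate_id == a$plate_id
    f <- function(x) 1 + (x - a$m1) / (a$m2 - a$m1)
    expect_equal(f(a$m1), 1, tolerance = 1e-12)
    expect_equal(f(a$m2), 2, tolerance = 1e-12)
    expect_equal(norm[[col]][on_plate], f(rec[[raw_col]][on_plate]),
                 tolerance = 1e-12)
  }

  # clamping: raw below the zero-copy boundary maps to exactly 0
  one <- make_dct(paste0("Z", 1:20), "P1",
                  dct_3ds1 = c(-0.35, rnorm(9, 0.8, 0.02), rnorm(10, 1.9, 0.02)),
                  dct_3dl1 = rep(c(1, 2), 10))
  one <- apply_hard_zero(one)
  n1 <- normalize_plates(one)
  expect_identical(n1$dct_3ds1[1], 0)
  expect_lt(n1$dct_3ds1_preclamp[1], 0)

  # per-plate affine distortion of the raw scale changes nothing pre-clamp
  distorted <- rec
  for (p in unique(rec$plate_id)) {
    a <- if (p == "P1") 2.0 else 0.7
    b <- if (p == "P1") 3.0 else -1.2
    i <- distorted$plate_id == p
    distorted$dct_3ds1[i] <- a * distorted$dct_3ds1[i] + b
    distorted$dct_3dl1[i] <- a * distorted$dct_3dl1[i] + b
  }
  norm_d <- normalize_plates(distorted)
  expect_equal(norm_d$dct_3ds1_preclamp, norm$dct_3ds1_preclamp, tolerance = 1e-9)
  expect_equal(norm_d$dct_3dl1_preclamp, norm$dct_3dl1_preclamp, tolerance = 1e-9)

  bad <- anchors
  bad$m2 <- bad$m1
  expect_error(normalize_plates(rec, bad), "m2 <= m1")
})

test_that("repeated samples collapse to the per-gene median with a reproducibility report", {
  rec <- make_dct(c("S1", "S1", "S2", "S3", "S3", "S3"),
                  c("A", "B", "A", "A", "B", "C"),
                  dct_3ds1 = c(1.02, 0.98, 1.5, 0.9, 1.0, 1.4),
                  dct_3dl1 = c(2.0, 2.1, 1.0, 2.0, 2.0, 2.0))
  rec <- apply_hard_zero(rec)
  rec$normalized <- TRUE
  rec$dct_3ds1_preclamp <- rec$dct_3ds1
  rec$dct_3dl1_preclamp <- rec$dct_3dl1
  merged <- merge_repeated_samples(rec)
  merged <- merged[order(merged$sample_id), ]
  expect_equal(nrow(merged), 3L)
  expect_equal(merged$dct_3ds1, c(1.00, 1.5, 1.0))
  expect_equal(merged$plate_id, c("multiple", "A", "multiple"))
  rr <- attr(merged, "reproducibility")
  expect_equal(rr$max_diff_3ds1[rr$sample_id == "S1"], 0.04)
})
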