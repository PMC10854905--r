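test_that("ONSASW arithmetic and invariants", {
  expect_equal(compute_onsasw(2.2, 2.2, 4.2, 4.2), 1.0)
  expect_equal(compute_onsasw(3, 3, 3, 3), 0)
  expect_error(compute_onsasw(4, 4, 3.9, 4.2), "sheath narrower than nerve")

  # mean-of-axes equals mean of per-axis half-differences (linearity)
  set.seed(1)
  for (i in 1:50) {
    ond <- runif(2, 1.5, 3.5)
    onsd <- ond + runif(2, 0, 2.5)
    a <- compute_onsasw(ond[1], ond[2], onsd[1], onsd[2])
    b <- mean(c((onsd[1] - ond[1]) / 2, (onsd[2] - ond[2]) / 2))
    expect_equal(a, b, tolerance = 1e-12)
    # adding c to both nerve and sheath leaves ONSASW unchanged
    cc <- runif(1, 0, 3)
    expect_equal(compute_onsasw(ond[1] + cc, ond[2] + cc,
                                onsd[1] + cc, onsd[2] + cc), a,
                 tolerance = 1e-12)
  }

  # monotonicity: wider sheath -> wider space; thicker nerve -> narrower
  base <- compute_onsasw(2.5, 2.6, 4.0, 4.1)
  expect_gt(compute_onsasw(2.5, 2.6, 4.3, 4.1), base)
  expect_lt(compute_onsasw(2.8, 2.6, 4.0, 4.1), base)
})

test_that("TLCPD is a signed difference", {
  expect_equal(as.numeric(compute_tlcpd(16, 10)), 6)
  expect_equal(as.numeric(compute_tlcpd(12, 12)), 0)
  neg <- compute_tlcpd(12, 15)
  expect_equal(as.numeric(neg), -3)
  expect_true(attr(neg, "negative"))
  expect_error(compute_tlcpd(-1, 5), "iop")
})

test_that("MRI measurement CSV loader validates rows", {
  good <- data.frame(subject = c("s1", "s1", "s2"), eye = "OD",
                     distance_mm = c(3, 9, 15),
                     ond_h_mm = c(2.5, 2.4, 2.3), ond_v_mm = c(2.6, 2.4, 2.2),
                     onsd_h_mm = c(4.4, 4.1, 3.8), onsd_v_mm = c(4.5, 4.0, 3.9))
  f <- tempfile(fileext = ".csv")
  write.csv(good, f, row.names = FALSE)
  rec <- load_mri_measurements(f)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$onsasw_mm[1],
               compute_onsasw(2.5, 2.6, 4.4, 4.5))

  bad <- good; bad$distance_mm[2] <- 5
  write.csv(bad, f, row.names = FALSE)
  expect_error(load_mri_measurements(f), "row 2.*stations 3, 9, 15")

  bad2 <- good; bad2$onsd_h_mm[3] <- 2.0
  write.csv(bad2, f, row.names = FALSE)
  expect_error(load_mri_measurements(f), "row 3.*sheath narrower")

  write.csv(good[0, ], f, row.names = FALSE)
  expect_warning(out <- load_mri_measurements(f), "empty")
  expect_equal(nrow(out), 0)

  write.csv(good[, -3], f, row.names = FALSE)
  expect_error(load_mri_measurements(f), "missing column")
})
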