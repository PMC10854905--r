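test_that("centerline of simple shapes", {
  g0 <- extract_centerline(matrix(0L, 20, 20))
  expect_equal(nrow(g0$nodes), 0)
  expect_equal(length(g0$edges), 0)

  # solid 100x5 bar: one edge, two endpoints, path length in [92, 100]
  m <- matrix(0L, 60, 200); m[30:34, 50:149] <- 1L
  g <- extract_centerline(m)
  expect_equal(length(g$edges), 1)
  expect_equal(sum(g$nodes$degree == 1), 2)
  expect_gte(g$edges[[1]]$length, 92)
  expect_lte(g$edges[[1]]$length, 100)
})

test_that("rendered trees yield exactly the truth bifurcations", {
  for (s in c(2, 8, 17)) {
    sc <- std_scene(seed = s)
    g <- extract_centerline(sc$rendering$vessel_mask)
    bif <- detect_bifurcations(g)
    expect_equal(nrow(bif), nrow(sc$truth$bifurcations))
    expect_equal(attr(bif, "n_crossings"), 0)
    # each detected bifurcation within a few px of a truth one
    for (i in seq_len(nrow(bif))) {
      d <- sqrt((sc$truth$bifurcations$x - bif$x[i])^2 +
                  (sc$truth$bifurcations$y - bif$y[i])^2)
      expect_lt(min(d), 8)
    }
  }
})

test_that("diameters: constant-width bar and 1-px line", {
  m <- matrix(0L, 60, 200); m[30:34, 50:149] <- 1L
  g <- extract_centerline(m)
  prof <- measure_diameters(m, g)
  expect_gt(nrow(prof), 50)
  expect_true(all(abs(prof$diameter_px - 5) <= 0.5))

  thin <- matrix(0L, 40, 120); thin[20, 10:110] <- 1L
  gt <- extract_centerline(thin)
  pt <- measure_diameters(thin, gt)
  expect_true(all(pt$diameter_px <= 2))
  expect_equal(median(pt$diameter_px), 1, tolerance = 0.25)
})

test_that("skipped points are tallied when the normal leaves the frame", {
  m <- matrix(1L, 30, 100)  # mask touching every border
  m[1:10, ] <- 0L; m[25:30, ] <- 0L
  g <- extract_centerline(m)
  prof <- measure_diameters(m, g, max_width = 10)
  expect_true(is.numeric(attr(prof, "n_skipped")))
})

test_that("annulus calibers: forced arithmetic and AVR identity", {
  # synthetic profile: arteries 6 px, veins 9 px, DD 100, all in annulus
  disc <- list(center = c(0, 0), diameter_px = 100)
  prof <- data.frame(
    edge = rep(1:2, each = 40),
    x = c(seq(100, 140, length.out = 40), seq(-100, -140, length.out = 40)),
    y = 0,
    diameter_px = rep(c(6, 9), each = 40),
    label = rep(c("artery", "vein"), each = 40))
  cal <- annulus_calibers(prof, disc)
  expect_equal(cal$rel_arteriolar, 0.06)
  expect_equal(cal$rel_venular, 0.09)
  expect_equal(cal$avr, 2 / 3)
  expect_true(cal$complete)
  expect_gte(min(cal$n_sections), 10)
  # identity AVR = relA / relV by construction
  expect_identical(cal$avr, cal$rel_arteriolar / cal$rel_venular)

  # equal calibers give AVR 1
  prof$diameter_px <- 7
  expect_equal(annulus_calibers(prof, disc)$avr, 1)

  # missing class flags incomplete, AVR undefined
  cal_a <- annulus_calibers(prof[prof$label == "artery", ], disc)
  expect_false(cal_a$complete)
  expect_true(is.na(cal_a$avr))
})

test_that("branching angles recover known geometry", {
  # orthogonal daughters drawn explicitly: +x and +y from a junction
  m <- matrix(0L, 100, 100)
  m[50, 10:50] <- 1L   # parent along x (row 50)
  m[50:90, 50] <- 1L   # daughter along +y
  m[50, 50:90] <- 1L   # daughter along +x
  # make the parent thicker so it is picked as parent by diameter
  m[48:52, 10:46] <- 1L
  g <- extract_centerline(m)
  bif <- detect_bifurcations(g)
  expect_equal(nrow(bif), 1)
  ba <- branching_angle(bif$id[1], g, vessel_mask = m)
  expect_equal(ba$angle_deg, 90, tolerance = 6)

  # rendered tree: recovered within 5 degrees of truth
  sc <- std_scene(seed = 13)
  g <- extract_centerline(sc$rendering$vessel_mask,
                          av_mask = sc$rendering$av_mask)
  prof <- measure_diameters(sc$rendering$vessel_mask, g)
  bif <- detect_bifurcations(g)
  errs <- vapply(seq_len(nrow(bif)), function(i) {
    ba <- branching_angle(bif$id[i], g, profile = prof)
    d2 <- (sc$truth$bifurcations$x - bif$x[i])^2 +
      (sc$truth$bifurcations$y - bif$y[i])^2
    abs(ba$angle_deg - sc$truth$bifurcations$angle_deg[which.min(d2)])
  }, numeric(1))
  expect_lt(mean(errs), 5)
})

test_that("quadrant assignment follows the laterality convention", {
  disc <- list(center = c(100, 100))
  # OD: nasal = image-right; point above and to image-left is sup. temporal
  expect_equal(assign_quadrant(c(80, 60), disc, "OD"), "superior temporal")
  # OS: mirrored; point below and image-left is inferior nasal
  expect_equal(assign_quadrant(c(80, 140), disc, "OS"), "inferior nasal")
  # flipping laterality flips nasal/temporal, preserves superior/inferior
  for (p in list(c(40, 20), c(150, 180), c(130, 40))) {
    qod <- strsplit(assign_quadrant(p, disc, "OD"), " ")[[1]]
    qos <- strsplit(assign_quadrant(p, disc, "OS"), " ")[[1]]
    expect_equal(qod[1], qos[1])
    expect_false(qod[2] == qos[2])
  }
  expect_error(assign_quadrant(c(100, 100), disc, "OD"), "undefined quadrant")
})

test_that("quadrant-stratified counts sum to the total bifurcation count", {
  sc <- std_scene(seed = 4)
  r <- sc$rendering
  g <- extract_centerline(r$vessel_mask, av_mask = r$av_mask)
  disc <- list(center = sc$truth$disc$center)
  qa <- quadrant_angles(g, disc, "OD", vessel_mask = r$vessel_mask)
  expect_equal(sum(qa$by_quadrant$n), nrow(detect_bifurcations(g)))
  expect_true(all(qa$angles$angle_deg > 0 & qa$angles$angle_deg < 180))
})
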