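test_that("tree generation honours the spec and is seeded", {
  s0 <- vessel_tree_spec(n_roots = 1, branching_depth = 0, seed = 4)
  t0 <- generate_vessel_tree(s0)
  expect_equal(nrow(t0$segments), 1)
  expect_equal(nrow(t0$bifurcations), 0)

  s7 <- vessel_tree_spec(seed = 7)
  expect_identical(generate_vessel_tree(s7), generate_vessel_tree(s7))

  expect_error(vessel_tree_spec(width_taper = 0), "width_taper")
  expect_error(vessel_tree_spec(angle_range_deg = c(-5, 90)), "angle_range_deg")
})

test_that("recorded angles respect the range and count 2^depth - 1 per root", {
  spec <- vessel_tree_spec(n_roots = 2, branching_depth = 3,
                           angle_range_deg = c(60, 90), seed = 11)
  tr <- generate_vessel_tree(spec)
  expect_true(all(tr$bifurcations$angle_deg >= 60 &
                    tr$bifurcations$angle_deg <= 90))
  # exhaustive traversal: walk the parent links and count internal nodes
  segs <- tr$segments
  children <- split(segs$id, segs$parent)
  count_bifs <- function(id) {
    kids <- children[[as.character(id)]]
    if (is.null(kids)) return(0L)
    1L + sum(vapply(kids, count_bifs, integer(1)))
  }
  roots <- segs$id[is.na(segs$parent)]
  per_root <- vapply(roots, count_bifs, integer(1))
  expect_equal(per_root, rep(2^3 - 1, 2))
  expect_equal(nrow(tr$bifurcations), sum(per_root))
  # every bifurcation sits at its parent segment's endpoint
  pseg <- segs[match(tr$bifurcations$parent_seg, segs$id), ]
  expect_equal(tr$bifurcations$x, pseg$x1)
  expect_equal(tr$bifurcations$y, pseg$y1)
})

test_that("rendering is faithful: masks partition and widths verify", {
  # empty truth renders background only
  empty <- structure(list(segments = NULL, bifurcations = NULL, disc = NULL,
                          image_size = 128L), class = "vessel_tree_truth")
  r0 <- render_fundus(empty, noise_sd = 0)
  expect_true(all(r0$vessel_mask == 0))

  sc <- std_scene()
  r <- sc$rendering
  # artery + vein pixels = vessel pixels, exactly
  expect_identical((r$av_mask > 0) * 1L, r$vessel_mask)
  expect_equal(sum(r$av_mask == 1) + sum(r$av_mask == 2), sum(r$vessel_mask))

  # distance-transform oracle: straight vessel of width 7
  tr <- sc$truth
  tr$segments <- data.frame(tree = 1L, id = 1L, parent = NA_integer_,
                            gen = 0L, x0 = 100, y0 = 256.3, x1 = 400,
                            y1 = 256.3, width_px = 7, label = "vein")
  tr$bifurcations <- tr$bifurcations[0, ]
  r7 <- render_fundus(tr, noise_sd = 0)
  dm <- EBImage::distmap(r7$vessel_mask)
  expect_equal(2 * max(dm) - 1, 7, tolerance = 0.5)

  # out-of-bounds segment is rejected with its id
  tr$segments$x1 <- 1e4
  expect_error(render_fundus(tr), "outside image bounds.*1")
})

test_that("rendered widths match truth within 0.5 px for widths >= 3", {
  sc <- std_scene(seed = 6)
  r <- sc$rendering
  g <- extract_centerline(r$vessel_mask)
  prof <- measure_diameters(r$vessel_mask, g)
  tw <- truth_width_at(prof, sc$truth)
  keep <- tw >= 3
  expect_gt(sum(keep), 100)
  expect_lt(mean(abs(prof$diameter_px[keep] - tw[keep])), 0.5)
})

test_that("cohort simulation: degenerate SDs, determinism, pairing", {
  spec0 <- cohort_spec(n_subjects = c(BRVO = 5L, CRVO = 4L), seed = 2)
  # zero SDs collapse every eye-level value onto its cell mean
  ev <- lapply(fundusgeom:::.eye_defaults, function(v) {
    v$sd <- rep(0, 4); v
  })
  co0 <- generate_cohort(cohort_spec(n_subjects = c(BRVO = 5L, CRVO = 4L),
                                     eye_vars = ev, seed = 2))
  crvo_aff <- co0[co0$group == "CRVO" & co0$eye_role == "affected", ]
  expect_true(all(crvo_aff$rel_ven_caliber == 0.095))
  expect_true(all(crvo_aff$iop_mmhg == 19.58))

  co <- generate_cohort(spec0)
  expect_identical(co, generate_cohort(spec0))
  expect_equal(nrow(co), 2 * 9)
  expect_true(validate_cohort(co))
  # BMI identity holds in every record
  expect_equal(co$bmi, co$weight_kg / co$height_m^2)
  # negative SD rejected
  ev_bad <- fundusgeom:::.eye_defaults
  ev_bad$iop_mmhg$sd[1] <- -1
  expect_error(cohort_spec(eye_vars = ev_bad), "SDs must be >= 0")
})

test_that("cohort moments recover the spec means at large n", {
  # 3-SE check on a representative set of columns over a few seeds
  cols <- c("rel_ven_caliber", "rel_art_caliber", "onsasw_3_mm", "oa_mm",
            "angle_it_artery_deg")
  for (seed in 1:3) {
    co <- generate_cohort(cohort_spec(n_subjects = c(BRVO = 5000L, CRVO = 5000L),
                                      seed = seed))
    for (cl in cols) {
      v <- fundusgeom:::.eye_defaults[[cl]]
      for (cell in 1:4) {
        g <- if (cell <= 2) "BRVO" else "CRVO"
        role <- if (cell %% 2 == 1) "affected" else "contralateral"
        x <- co[[cl]][co$group == g & co$eye_role == role]
        se <- v$sd[cell] / sqrt(length(x))
        expect_lt(abs(mean(x) - v$mean[cell]), 3.5 * se + 1e-12,
                  label = sprintf("%s %s %s seed %d", cl, g, role, seed))
      }
    }
  }
})
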