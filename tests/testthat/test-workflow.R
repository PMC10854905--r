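test_that("config validation: defaults, unknown keys, invariants", {
  cfg <- validate_config(list(seed = 5))
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$seed, 5)
  expect_equal(cfg$measure$zone, c(1.0, 1.5))
  expect_equal(cfg$n_images, 10)

  expect_error(validate_config(list(zoom = 2)), "unknown config key 'zoom'")
  expect_error(validate_config(list(measure = list(zone = c(1.5, 1.0)))),
               "zone")
  expect_error(validate_config(list(n_images = "many")), "numeric")

  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "n_images: 2", "measure:", "  backend: truth"), f)
  cfg2 <- validate_config(f)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$measure$backend, "truth")
})

test_that("pipeline runs end to end, writes a complete manifest, deterministic", {
  out1 <- tempfile("run1"); out2 <- tempfile("run2")
  base <- list(seed = 3, n_images = 2,
               cohort = list(n_subjects = c(BRVO = 25, CRVO = 25)))
  cfg <- validate_config(c(base, list(out_dir = out1)))
  rep1 <- run_pipeline(cfg)
  expect_false(rep1$failed)
  expect_true(all(file.exists(rep1$manifest)))
  expect_equal(nrow(rep1$geometry), 2)
  expect_s3_class(rep1$report, "comparison_report")

  # same config + seed => identical tabular outputs
  rep2 <- run_pipeline(validate_config(c(base, list(out_dir = out2))))
  expect_equal(rep1$config_hash, rep2$config_hash)
  h <- function(d, f) unname(tools::md5sum(file.path(d, f)))
  for (f in c("cohort.csv", "geometry.csv", "report_per_eye.csv")) {
    expect_equal(h(out1, f), h(out2, f), label = f)
  }
  unlink(c(out1, out2), recursive = TRUE)
})

test_that("derived seeds differ across stages and stay in integer range", {
  s <- vapply(c("simulate-image-1", "simulate-image-2", "render-1",
                "simulate-cohort"),
              function(l) fundusgeom:::derive_seed(42, l), numeric(1))
  expect_equal(length(unique(s)), 4)
  expect_true(all(s >= 0 & s < 2^31))
})
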