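test_that("cohort_spec validates its invariants", {
  expect_error(cohort_spec(n_images = 0), "n_images")
  expect_error(cohort_spec(vessel_density = 0.5), "vessel_density")
  expect_error(cohort_spec(width_mean = 0.5), "width_mean")
  expect_error(cohort_spec(image_size = c(32, 256)), "image_size")
})

test_that("vessel tree generation is deterministic and honours the zero case", {
  spec <- cohort_spec(image_size = c(128, 128), vessel_density = 0.1, seed = 5)
  m1 <- generate_vessel_tree(spec)
  m2 <- generate_vessel_tree(spec)
  expect_identical(as.integer(m1), as.integer(m2))

  z <- generate_vessel_tree(cohort_spec(vessel_density = 0, image_size = c(64, 64)))
  expect_equal(sum(z), 0)
  expect_false(attr(z, "density_warning"))
})

test_that("masks stay strictly inside the circular field", {
  spec <- cohort_spec(image_size = c(128, 128), vessel_density = 0.12, seed = 3)
  m <- generate_vessel_tree(spec)
  fov <- circular_fov(128, 128)
  expect_equal(sum(m == 1L & !fov), 0)
})

test_that("measured density tracks the target within 10%", {
  for (dens in c(0.05, 0.12, 0.2)) {
    spec <- cohort_spec(vessel_density = dens, seed = 11)
    m <- generate_vessel_tree(spec)
    expect_false(attr(m, "density_warning"))
    expect_lt(abs(attr(m, "density") - dens) / dens, 0.10)
  }
})

test_that("healthy cohorts are denser than pathological ones across seeds", {
  healthy <- cohort_spec("healthy", vessel_density = 0.12, branch_prob = 0.015,
                         image_size = c(128, 128))
  path <- cohort_spec("path", vessel_density = 0.07, branch_prob = 0.008,
                      image_size = c(128, 128))
  fh <- vapply(1:10, function(s)
    attr(generate_vessel_tree(healthy, seed = s), "density"), numeric(1))
  fp <- vapply(1:10, function(s)
    attr(generate_vessel_tree(path, seed = s), "density"), numeric(1))
  expect_gt(mean(fh), mean(fp))
})

test_that("render_fundus honours degenerate noise, shifts and clipping", {
  spec <- cohort_spec(image_size = c(64, 64), vessel_density = 0,
                      background_rgb_sd = c(0, 0, 0), noise_sd = 0)
  empty <- generate_vessel_tree(spec)
  img <- render_fundus(empty, spec, seed = 1)
  fov <- circular_fov(64, 64)
  expect_true(all(img[, , 2][fov] == spec$background_rgb_mean[2]))
  expect_true(all(img[, , 1][!fov] == 0))

  spec0 <- cohort_spec(image_size = c(64, 64), vessel_density = 0.05, seed = 2)
  specm10 <- cohort_spec(image_size = c(64, 64), vessel_density = 0.05,
                         green_shift = -10, seed = 2)
  mask <- generate_vessel_tree(spec0, seed = 9)
  g0 <- render_fundus(mask, spec0, seed = 4)
  gm <- render_fundus(mask, specm10, seed = 4)
  d <- mean(g0[, , 2][fov]) - mean(gm[, , 2][fov])
  expect_lt(abs(d - 10), 1)

  spec_ext <- cohort_spec(image_size = c(64, 64), vessel_density = 0.05,
                          green_shift = 200, blue_shift = -200, seed = 3)
  ext <- render_fundus(mask, spec_ext, seed = 5)
  expect_gte(min(ext), 0); expect_lte(max(ext), 255)

  expect_error(render_fundus(vessel_mask(matrix(0, 32, 32)), spec0), "dimensions")
})

test_that("vessels render darker than the background", {
  spec <- cohort_spec(image_size = c(128, 128), vessel_density = 0.1, seed = 6)
  m <- generate_vessel_tree(spec)
  img <- render_fundus(m, spec, seed = 7)
  fov <- circular_fov(128, 128)
  g <- img[, , 2]
  expect_lt(mean(g[m == 1L]), mean(g[m == 0L & fov]))
})

test_that("generate_cohort is seed-faithful and produces n samples", {
  spec <- load_preset("healthy", n_images = 3, image_size = c(128, 128))
  co <- generate_cohort(spec)
  expect_length(co, 3)
  expect_s3_class(co[[1]]$image, "fundus_image")
  expect_identical(dim(co[[1]]$mask), dim(co[[1]]$image)[1:2])

  co2 <- generate_cohort(spec)
  expect_identical(co[[2]]$image, co2[[2]]$image)      # pure function of spec

  spec_b <- load_preset("healthy", n_images = 3, image_size = c(128, 128),
                        seed = spec$seed + 1)
  co_b <- generate_cohort(spec_b)
  expect_false(identical(unclass(co[[1]]$image), unclass(co_b[[1]]$image)))

  # images within a cohort are mutually distinct (independent sub-streams)
  expect_false(identical(unclass(co[[1]]$image), unclass(co[[2]]$image)))
})

test_that("presets load, validate and can round-trip to disk", {
  h <- load_preset("healthy")
  p <- load_preset("pathological")
  expect_s3_class(h, "cohort_spec")
  expect_equal(h$n_images, 15L)
  expect_gt(h$vessel_density, p$vessel_density)
  expect_lt(p$green_shift, 0)
  expect_lt(p$blue_shift, 0)
  expect_equal(h$green_shift, 0)
  expect_error(load_preset("nonexistent"), "unknown preset")

  dir <- withr::local_tempdir()
  co <- generate_cohort(load_preset("healthy", n_images = 2,
                                    image_size = c(64, 64),
                                    vessel_density = 0.08))
  manifest <- save_cohort(co, dir)
  expect_true(all(file.exists(manifest$file)))
  expect_true(all(file.exists(manifest$mask_file)))
  back <- read_fundus_png(manifest$file[1], group = manifest$group[1])
  expect_equal(unclass(back)[, , 2], unclass(co[[1]]$image)[, , 2],
               ignore_attr = TRUE)
  mk <- read_mask_png(manifest$mask_file[1])
  expect_identical(as.integer(mk), as.integer(co[[1]]$mask))
})
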