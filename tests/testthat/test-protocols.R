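# shared inputs for the protocol tests, built once
make_pore_input <- function(seed = 11) {
  base <- generate_binary_phantom("boolean_balls", 48, r = 5, vv = 0.3,
                                  seed = seed)
  generate_gray_phantom(base, means = c(60, 180), sigma = 10, seed = seed + 1)
}

make_multiphase_input <- function() {
  sh <- c(48, 48, 32)
  g <- list(x = 0:47, y = 0:47, z = 0:31)
  mk <- function(cx) outer(outer((g$x - cx)^2, (g$y - 23.5)^2, "+"),
                           (g$z - 15.5)^2, "+") <= 100
  grains <- mk(15) | mk(31)                 # two touching bright grains
  lab <- array(1L, sh)
  lab[1:6, , ] <- 0L                        # darkest phase (air)
  lab[grains] <- 2L                         # bright phase (grains)
  lv <- label_volume(lab, compact = FALSE)
  list(gray = generate_gray_phantom(lv, means = c(20, 100, 220), sigma = 8,
                                    seed = 3),
       n_grains = 2L)
}

test_that("pore protocol runs all stages and reports the basic fields", {
  tmp <- withr::local_tempdir()
  cfg <- list(volume = make_pore_input(), median_width = 3, morph_width = 3,
              pruning = 5, n_directions = 64, out_dir = tmp)
  res <- run_pore_protocol(cfg)
  expect_named(res$report$basic, c("VV", "SV", "MV", "chi_v", "I", "EA"))
  expect_true(all(vapply(res$report$basic, is.finite, logical(1))))
  expect_gte(res$report$basic$VV, 0); expect_lte(res$report$basic$VV, 1)
  expect_true(file.exists(file.path(tmp, "report.json")))
  expect_true(file.exists(file.path(tmp, "blobs.csv")))
  expect_true(file.exists(file.path(tmp, "run.log")))
  expect_true(file.exists(file.path(tmp, "01_median.raw")))
  # parameters echoed in the log
  expect_true(any(grepl("median_width=3", readLines(file.path(tmp, "run.log")))))
})

test_that("pore protocol on two disjoint balls finds two blobs", {
  two <- fixture_two_balls(r = 8, gap = 24)
  gv <- generate_gray_phantom(two, means = c(40, 200), sigma = 0)
  res <- run_pore_protocol(list(volume = gv, median_width = 1, morph_width = 1,
                                n_directions = 32))
  expect_equal(nrow(res$blobs), 2)
})

test_that("identical pore configs give bit-identical reports", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  gv <- make_pore_input()
  cfg <- list(volume = gv, n_directions = 48, out_dir = d1)
  run_pore_protocol(cfg)
  cfg$out_dir <- d2
  run_pore_protocol(cfg)
  expect_identical(readLines(file.path(d1, "report.json")),
                   readLines(file.path(d2, "report.json")))
})

test_that("multiphase protocol separates touching grains", {
  inp <- make_multiphase_input()
  res <- run_multiphase_protocol(list(volume = inp$gray, k = 4, h = 2,
                                      phase_classes = 4))
  expect_equal(res$report$n_objects, inp$n_grains)
  # k = 4 on a 3-phase sample: two centroids collapse onto one physical
  # phase (their gap is far below the inter-phase gaps), revealing that
  # only three phases are present
  gaps <- diff(res$segmentation$centroids)
  expect_lt(min(gaps), 0.25 * max(gaps))
  expect_error(run_multiphase_protocol(list(volume = inp$gray, k = 1)), "k >= 2")
})

test_that("h larger than the maximum distance merges to one label per component", {
  ov <- fixture_two_balls(r = 10, gap = 16)   # one connected component
  gv <- generate_gray_phantom(ov, means = c(30, 220), sigma = 0)
  res <- run_multiphase_protocol(list(volume = gv, k = 2, phase_classes = 2,
                                      h = 999))
  expect_equal(res$report$n_objects, 1L)
  # while a small h separates the two overlapping balls
  res2 <- run_multiphase_protocol(list(volume = gv, k = 2, phase_classes = 2,
                                       h = 2))
  expect_equal(res2$report$n_objects, 2L)
})

test_that("morphometry protocol: scalar mode and volume mode", {
  res <- run_morphometry_protocol(list(BvTv = 0.1, BsBv = 32))
  expect_equal(res$report$TbTh, 0.0625)
  s <- generate_binary_phantom("slab_stack", c(32, 32, 64),
                               thickness = 8, period = 32)
  resv <- run_morphometry_protocol(list(volume = s))
  truth <- phantom_truth(s)
  expect_lte(abs(resv$report$TbTh / truth$TbTh_mm - 1), 0.10)
  expect_lte(abs(resv$report$TbSp / truth$TbSp_mm - 1), 0.10)
  full <- binary_volume(array(TRUE, c(8, 8, 8)))
  expect_equal(run_morphometry_protocol(list(volume = full))$report$BvTv, 1)
})

test_that("protocol config files parse and feed the pipelines", {
  tmp <- withr::local_tempdir()
  cfgfile <- file.path(tmp, "run.cfg")
  writeLines(c("# pore protocol", "median_width = 3", "pruning = 5",
               "closing = false", "voi_origin = 0,0,0", "voi_shape = 24,24,24"),
             cfgfile)
  cfg <- read_protocol_config(cfgfile)
  expect_equal(cfg$median_width, 3)
  expect_false(cfg$closing)
  expect_equal(cfg$voi_shape, c(24, 24, 24))
  cfg$volume <- make_pore_input()
  cfg$n_directions <- 32
  res <- run_pore_protocol(cfg)
  expect_equal(res$report$parameters$voi, "24x24x24")
  # stage failures name the stage
  bad <- list(volume = make_pore_input(), median_width = 2)
  expect_error(run_pore_protocol(bad), "stage 'median'")
})
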