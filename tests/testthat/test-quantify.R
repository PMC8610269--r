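# Mask logic and AQUA scoring on hand-built pixel grids and simulated cores.

fixed_params <- function(...) {
  segmentation_params(threshold_method = "fixed",
                      fixed_thresholds = c(dapi = 0.25, vimentin = 0.25,
                                           panck = 0.25), ...)
}

test_that("vimentin+panCK+ pixels are excluded from stroma (panCK wins)", {
  n <- 6
  dapi <- matrix(0, n, n); dapi[1, 1] <- 0.5
  vim <- matrix(0.5, n, n)          # vimentin everywhere
  panck <- matrix(0, n, n); panck[, 4:6] <- 0.5 # right half epithelial
  img <- grid_image(dapi, vim, panck)
  m <- build_compartment_masks(img, fixed_params())
  # double-positive pixels: epithelium, never stroma, never counted twice
  expect_true(all(m$epithelium[, 4:6]))
  expect_false(any(m$stroma[, 4:6]))
  expect_false(any(m$stroma & m$epithelium))
  # vimentin-only pixels near the nucleus remain stroma
  expect_true(m$stroma[1, 1])
})

test_that("stroma requires a DAPI-positive nucleus in reach", {
  n <- 6
  vim <- matrix(0.5, n, n)
  panck <- matrix(0, n, n); panck[6, 6] <- 0.5 # keep panck non-degenerate
  img <- grid_image(dapi = matrix(0, n, n), vimentin = vim, panck = panck)
  expect_warning(m <- build_compartment_masks(img, fixed_params()),
                 "dapi.*all zero")
  expect_false(any(m$stroma))

  # with a nucleus present, only pixels within the association radius count
  dapi <- matrix(0, 20, 20); dapi[1, 1] <- 0.5
  panck2 <- matrix(0, 20, 20); panck2[20, 1] <- 0.5
  img2 <- grid_image(dapi, matrix(0.5, 20, 20), panck2, n = 20)
  m2 <- build_compartment_masks(
    img2, segmentation_params(threshold_method = "fixed",
                              fixed_thresholds = c(dapi = 0.25,
                                                   vimentin = 0.25,
                                                   panck = 0.25),
                              nucleus_association_radius = 3))
  expect_true(m2$stroma[2, 2])
  expect_false(m2$stroma[20, 20])
})

test_that("min_region_px removes small components", {
  n <- 12
  dapi <- matrix(0.5, n, n)
  vim <- matrix(0, n, n)
  vim[1:4, 1:4] <- 0.5   # 16 px region
  vim[10, 10] <- 0.5     # 1 px speck
  panck <- matrix(0, n, n); panck[12, 12] <- 0.5
  img <- grid_image(dapi, vim, panck, n = n)
  m <- build_compartment_masks(img, fixed_params(min_region_px = 4))
  expect_true(all(m$stroma[1:4, 1:4]))
  expect_false(m$stroma[10, 10])
})

test_that("masks from noise-free simulated cores match ground truth", {
  sim <- noise_free_core(seed = 21)
  m <- build_compartment_masks(sim$image, fixed_params())
  expect_identical(m$stroma, sim$truth$stroma)
  expect_identical(m$epithelium, sim$truth$epithelium)
  # Otsu defaults find the same separation on clean bimodal channels
  m2 <- build_compartment_masks(sim$image)
  expect_identical(m2$stroma, sim$truth$stroma)
})

test_that("AQUA score equals its closed form on uniform intensity", {
  n <- 6
  mask <- matrix(FALSE, n, n); mask[2:4, 2:4] <- TRUE
  cav1 <- matrix(0, n, n); cav1[mask] <- 0.37
  img <- grid_image(matrix(0.5, n, n), matrix(0, n, n), matrix(0, n, n),
                    cav1 = cav1)
  s <- compute_aqua_score(img, list(stroma = mask), "stroma", scale = 1,
                          reference_exposure = 100)
  expect_equal(s$value, 0.37)
  expect_equal(s$area_px, 9L)
  # doubling every pixel intensity doubles the score
  img2 <- img; img2$channels$cav1 <- 2 * cav1
  expect_equal(compute_aqua_score(img2, list(stroma = mask), "stroma",
                                  scale = 1)$value, 2 * 0.37)
  # doubling the exposure at fixed intensities halves it
  img3 <- img; img3$exposure_ms[["cav1"]] <- 200
  expect_equal(compute_aqua_score(img3, list(stroma = mask), "stroma",
                                  scale = 1)$value, 0.37 / 2)
})

test_that("scores are exposure-invariant when intensities scale linearly", {
  mk <- function(e) generate_core_image(image_sim_config(
    noise_sd = 0, seed = 23,
    exposure_times = c(dapi = 100, vimentin = 100, panck = 100, cav1 = e)))
  generate_and_score <- function(e) {
    sim <- mk(e)
    compute_aqua_score(sim$image, sim$truth, "stroma")$value
  }
  expect_equal(generate_and_score(50), generate_and_score(100))
  expect_equal(generate_and_score(100), generate_and_score(200))
})

test_that("score responds correctly to mask changes", {
  n <- 6
  mask <- matrix(FALSE, n, n); mask[2:3, 2:3] <- TRUE
  cav1 <- matrix(0, n, n); cav1[mask] <- 0.4
  img <- grid_image(matrix(0.5, n, n), matrix(0, n, n), matrix(0, n, n),
                    cav1 = cav1)
  base <- compute_aqua_score(img, list(stroma = mask), "stroma",
                             scale = 1)$value
  # adding zero-intensity pixels strictly decreases the score
  bigger <- mask; bigger[5, 5] <- TRUE
  expect_lt(compute_aqua_score(img, list(stroma = bigger), "stroma",
                               scale = 1)$value, base)
  # adding pixels at the mask mean leaves it unchanged
  img2 <- img; img2$channels$cav1[5, 5] <- 0.4
  expect_equal(compute_aqua_score(img2, list(stroma = bigger), "stroma",
                                  scale = 1)$value, base)
})

test_that("an empty mask yields a missing score, not zero", {
  img <- grid_image(matrix(0.5, 6, 6), matrix(0, 6, 6), matrix(0, 6, 6))
  s <- compute_aqua_score(img, list(stroma = matrix(FALSE, 6, 6)), "stroma")
  expect_true(s$missing)
  expect_true(is.na(s$value))
  expect_equal(s$area_px, 0L)
})

test_that("noise-free scores recover true concentration exactly", {
  concs <- c(0.1, 0.3, 0.6, 1.0)
  scores <- vapply(seq_along(concs), function(i) {
    sim <- noise_free_core(stroma_conc = concs[i], seed = 30 + i)
    compute_aqua_score(sim$image, sim$truth, "stroma")$value
  }, numeric(1))
  # closed form: scale * conc * gain * reference_exposure = 500 * conc
  expect_equal(scores, 1000 * concs * 0.005 * 100)
})

test_that("duplicate cores aggregate by the mean of non-missing scores", {
  mk <- function(subject, scores) data.frame(
    subject_id = subject, core_id = paste0(subject, "_", seq_along(scores)),
    roi_class = "tumor_stroma", compartment = "stroma", score = scores,
    stringsAsFactors = FALSE)
  agg <- aggregate_duplicate_cores(mk("A", c(100, 200)))
  expect_equal(agg$score, 150)
  expect_equal(agg$n_cores, 2L)
  expect_equal(aggregate_duplicate_cores(mk("B", 152.6))$score, 152.6)
  # every missingness pattern of two cores
  pat <- list(c(100, NA), c(NA, 100), c(NA, NA))
  out <- lapply(pat, function(p) aggregate_duplicate_cores(mk("C", p)))
  expect_equal(out[[1]]$score, 100); expect_equal(out[[1]]$n_cores, 1L)
  expect_equal(out[[2]]$score, 100); expect_equal(out[[2]]$n_cores, 1L)
  expect_true(is.na(out[[3]]$score)); expect_equal(out[[3]]$n_cores, 0L)
})

test_that("median dichotomization labels ties at the median as high", {
  rec <- data.frame(subject_id = letters[1:4], score = c(1, 2, 3, 4))
  lab <- dichotomize_if(rec)
  expect_equal(lab$expression_level, c("low", "low", "high", "high"))
  # value exactly at the median is high
  rec2 <- data.frame(subject_id = letters[1:3], score = c(1, 2, 3))
  expect_equal(dichotomize_if(rec2)$expression_level[2], "high")
  # all equal values are all high (forced by the >= rule)
  rec3 <- data.frame(subject_id = letters[1:3], score = c(5, 5, 5))
  expect_true(all(dichotomize_if(rec3)$expression_level == "high"))
  # missing scores stay unlabelled; empty input errors
  rec4 <- data.frame(subject_id = letters[1:3], score = c(1, NA, 3))
  expect_true(is.na(dichotomize_if(rec4)$expression_level[2]))
  expect_error(dichotomize_if(data.frame(score = numeric())), "non-empty")
})
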