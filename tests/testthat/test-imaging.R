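test_that("organoid detection handles empty fields, clusters and area filters", {
  expect_equal(max(detect_organoids(matrix(0, 64, 64))), 0)

  # two well-separated nucleus clusters -> two organoids
  img <- matrix(0, 300, 300)
  for (ctr in list(c(70, 70), c(230, 230))) {
    for (off in list(c(-18, 0), c(18, 0), c(0, -18), c(0, 18), c(0, 0))) {
      d <- sqrt(outer((1:300 - ctr[1] - off[1])^2,
                      (1:300 - ctr[2] - off[2])^2, "+"))
      img[d <= 9] <- 0.6
    }
  }
  lab <- detect_organoids(img, blur_sigma = 10, min_area_px = 500)
  expect_equal(max(lab), 2)

  # a cluster below the minimum area is dropped
  lab2 <- detect_organoids(img, blur_sigma = 10, min_area_px = 1e6)
  expect_equal(max(lab2), 0)
})

test_that("nucleus segmentation recovers non-touching nuclei exactly", {
  fx <- hrp_image_fixture()
  expect_equal(max(fx$nuclei), max(fx$truth$nucleus_masks))
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
})

test_that("watershed splits touching nuclei with distinct cores", {
  img <- touching_nuclei_fixture()
  lab <- segment_nuclei(img, blur_sigma = 1, min_area_px = 30)
  expect_equal(max(lab), 2)
})

test_that("geodesic reconstruction recovers only marker-connected components", {
  mask <- matrix(FALSE, 40, 40)
  mask[5:15, 5:15] <- TRUE     # component 1
  mask[25:35, 25:35] <- TRUE   # component 2
  marker <- matrix(FALSE, 40, 40)
  marker[8, 8] <- TRUE
  rec <- geodesic_reconstruct(marker, mask)
  expect_true(all(rec[5:15, 5:15]))
  expect_false(any(rec[25:35, 25:35]))
  expect_equal(sum(rec), 11 * 11)
})

test_that("Cyclin A2 calling is accurate on generated fields", {
  fx <- hrp_image_fixture()
  called <- call_cyclinA2_positive(fx$image[, , 2], fx$nuclei)
  map <- match_segmentation_to_truth(fx$nuclei, fx$truth$nucleus_masks)
  called_truth <- map[called]
  truth_pos <- fx$truth$cyca2_positive_labels
  precision <- mean(called_truth %in% truth_pos)
  recall <- mean(truth_pos %in% called_truth)
  expect_gte(precision, 0.95)
  expect_gte(recall, 0.95)

  expect_identical(call_cyclinA2_positive(matrix(0, 40, 40),
                                          matrix(0L, 40, 40)), integer(0))
  expect_error(call_cyclinA2_positive(matrix(0, 10, 10), matrix(0L, 20, 20)),
               "shapes differ")
  expect_error(call_cyclinA2_positive(matrix(0, 10, 10), matrix(0L, 10, 10),
                                      sigma_small = 8, sigma_large = 2),
               "sigma_small")
})

test_that("marker overlapping exactly one of two nuclei marks only that one", {
  nuclei <- matrix(0L, 96, 96)
  nuclei[20:36, 20:36] <- 1L
  nuclei[60:76, 60:76] <- 2L
  fitc <- matrix(0.02, 96, 96)
  fitc[24:32, 24:32] <- 0.8  # bright blob on nucleus 1 only
  expect_identical(call_cyclinA2_positive(fitc, nuclei), 1L)
})

test_that("LoG focus detection finds bright spots and ignores dark ones", {
  expect_equal(nrow(detect_rad51_foci(matrix(0, 64, 64))), 0)

  img <- matrix(0.05, 64, 64)
  centers <- rbind(c(20, 20), c(20, 40), c(44, 30))
  for (i in 1:3) {
    d2 <- outer((1:64 - centers[i, 1])^2, (1:64 - centers[i, 2])^2, "+")
    img <- img + 0.5 * exp(-d2 / (2 * 2^2))
  }
  det <- detect_rad51_foci(img, sigma = 2, threshold = 0.05)
  expect_equal(nrow(det), 3)
  dmin <- apply(centers, 1, function(ctr)
    min(sqrt((det$row - ctr[1])^2 + (det$col - ctr[2])^2)))
  expect_true(all(dmin <= 2))

  inverted <- 0.6 - img  # dark spots on bright background
  expect_equal(nrow(detect_rad51_foci(inverted, 2, 0.05)), 0)
})

test_that("raising the LoG threshold never increases counts", {
  fx <- hrp_image_fixture()
  pos <- call_cyclinA2_positive(fx$image[, , 2], fx$nuclei)
  thresholds <- c(0.02, 0.05, 0.1, 0.2)
  counts <- sapply(thresholds, function(thr) {
    foci <- detect_rad51_foci(fx$image[, , 3], 2, thr)
    sum(count_foci_per_nucleus(foci, fx$nuclei, pos)$counts$focus_count)
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("focus assignment conserves detections and respects positivity", {
  fx <- hrp_image_fixture()
  pos <- call_cyclinA2_positive(fx$image[, , 2], fx$nuclei)
  foci <- detect_rad51_foci(fx$image[, , 3])
  res <- count_foci_per_nucleus(foci, fx$nuclei, pos)
  # conservation: every detection is assigned or excluded
  expect_equal(nrow(res$assignments), nrow(foci))
  expect_equal(sum(res$counts$focus_count),
               sum(!res$assignments$excluded))

  # background focus assigned to no nucleus
  bg <- which(fx$nuclei == 0, arr.ind = TRUE)[1, ]
  res_bg <- count_foci_per_nucleus(
    data.frame(row = bg[1], col = bg[2], response = 1), fx$nuclei, pos)
  expect_equal(res_bg$assignments$nucleus, 0L)
  expect_true(res_bg$assignments$excluded)

  # no positive nuclei -> all counts zero
  res_none <- count_foci_per_nucleus(foci, fx$nuclei, integer(0))
  expect_true(all(res_none$counts$focus_count == 0))
})

test_that("counts are unchanged by a common integer translation", {
  fx <- hrp_image_fixture()
  cfg <- recap_config()
  shift <- function(m, dr, dc) {
    out <- matrix(0, nrow(m), ncol(m))
    out[(1 + dr):nrow(m), (1 + dc):ncol(m)] <-
      m[1:(nrow(m) - dr), 1:(ncol(m) - dc)]
    out
  }
  img2 <- array(0, dim(fx$image))
  for (ch in 1:3) img2[, , ch] <- shift(fx$image[, , ch], 7, 11)
  t1 <- quantify_slide(fx$image, cfg)
  t2 <- quantify_slide(img2, cfg)
  expect_equal(sort(t1$focus_count), sort(t2$focus_count))
  expect_equal(sum(t1$cyca2_positive), sum(t2$cyca2_positive))
})

test_that("slide quantification validates inputs and is deterministic", {
  fx <- hrp_image_fixture()
  cfg <- recap_config()
  expect_identical(quantify_slide(fx$image, cfg), quantify_slide(fx$image, cfg))
  expect_error(quantify_slide(fx$image[, , 1:2], cfg), "array")
  expect_error(quantify_slide(list(dapi = fx$image[, , 1]), cfg), "channels")
  bad <- recap_config()
  bad$dog_sigma_small <- 9  # corrupt after construction
  expect_error(quantify_slide(fx$image, bad), "dog_sigma_small")
})

test_that("end-to-end counts track the regime mean on a generated slide", {
  fx <- hrp_image_fixture()
  cfg <- recap_config()
  slide <- quantify_slide(fx$image, cfg)
  sc <- score_quantification(slide, fx$nuclei, fx$truth)
  truth_mean <- mean(fx$truth$foci_per_nucleus[
    as.character(fx$truth$cyca2_positive_labels)])
  det_mean <- mean(slide$focus_count[slide$cyca2_positive])
  expect_lt(abs(det_mean - truth_mean) / max(truth_mean, 1), 0.2)
  expect_gte(sc$exact_fraction, 0.9)
})
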