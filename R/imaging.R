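#' @name recap-imaging
#' @title Automated RECAP image quantification
#' @description
#' The quantification chain mirrors the automated histo-imaging analysis of
#' the RECAP assay: organoids are isolated on the DAPI channel, nuclei
#' segmented within them, Cyclin A2-positive (proliferating) nuclei called
#' by a difference-of-Gaussians band-pass on the FITC channel followed by
#' geodesic reconstruction against the nucleus mask, RAD51 foci detected on
#' the CY3 channel as bright spots by a Laplacian-of-Gaussian filter, and
#' finally foci counted per nucleus, keeping only counts inside Cyclin
#' A2-positive nuclei for downstream scoring. Trained segmentation models
#' are deliberately not bundled; the classical Otsu/watershed chain is
#' deterministic and sufficient for the synthetic benchmarks, and each
#' stage accepts a drop-in replacement.
NULL

as_ebimage <- function(img) EBImage::Image(img)

# Robust background SD via the median absolute deviation of the image.
robust_bg_sd <- function(img) stats::mad(as.numeric(img))

#' Detect organoids on the DAPI channel
#'
#' Heavy Gaussian blur merges the nuclei of one organoid into a single
#' blob; Otsu thresholding, hole filling and a minimum-area filter yield
#' the labeled organoid map (background = 0).
#'
#' @param dapi single-channel matrix, values in [0, 1].
#' @param blur_sigma blur SD in px.
#' @param min_area_px smallest organoid kept.
#' @return integer label matrix.
#' @export
detect_organoids <- function(dapi, blur_sigma = 16, min_area_px = 2000) {
  stopifnot(is.matrix(dapi), all(dapi >= 0))
  if (all(dapi == 0)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  sm <- EBImage::gblur(as_ebimage(dapi), sigma = blur_sigma)
  thr <- EBImage::otsu(sm, range = c(0, max(sm)))
  bin <- EBImage::fillHull(sm > thr)
  lab <- EBImage::bwlabel(bin)
  drop_small_labels(as_label_matrix(lab), min_area_px)
}

# Relabel 1..n after dropping regions below min_area.
drop_small_labels <- function(lab, min_area) {
  if (max(lab) == 0) return(lab)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

as_label_matrix <- function(x) {
  m <- matrix(as.integer(round(EBImage::imageData(x))), dim(x)[1], dim(x)[2])
  m
}

#' Segment nuclei on the DAPI channel
#'
#' Gaussian smoothing, Otsu foreground, then a distance-transform watershed
#' to split touching nuclei; regions below \code{min_area_px} are removed
#' and labels compacted.
#'
#' @param dapi single-channel matrix in [0, 1].
#' @param blur_sigma smoothing SD in px.
#' @param min_area_px smallest nucleus kept.
#' @param tolerance watershed tolerance (object-merging depth).
#' @return integer label matrix.
#' @export
segment_nuclei <- function(dapi, blur_sigma = 2, min_area_px = 30,
                           tolerance = 1) {
  stopifnot(is.matrix(dapi))
  if (all(dapi == 0)) return(matrix(0L, nrow(dapi), ncol(dapi)))
  sm <- EBImage::gblur(as_ebimage(dapi), sigma = blur_sigma)
  thr <- EBImage::otsu(sm, range = c(0, max(sm)))
  bin <- sm > thr
  dmap <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dmap, tolerance = tolerance, ext = 1)
  drop_small_labels(as_label_matrix(lab), min_area_px)
}

#' Geodesic (morphological) reconstruction by dilation
#'
#' Iteratively dilates \code{marker} with a 3x3 structuring element
#' (8-connectivity) and clips to \code{mask} until stable: the result is
#' the union of the mask's connected components that touch the marker.
#'
#' @param marker,mask logical matrices of equal shape.
#' @return logical matrix.
#' @export
geodesic_reconstruct <- function(marker, mask) {
  stopifnot(identical(dim(marker), dim(mask)))
  rec <- marker & mask
  if (!any(rec)) return(rec)
  kern <- EBImage::makeBrush(3, shape = "box")
  repeat {
    grown <- EBImage::dilate(as_ebimage(rec * 1), kern) > 0.5
    grown <- grown & mask
    if (identical(as.vector(grown), as.vector(rec))) break
    rec <- grown
  }
  matrix(rec, nrow(mask), ncol(mask))
}

#' Call Cyclin A2-positive nuclei
#'
#' A difference of Gaussians band-pass on the FITC channel keeps the
#' positive pixels (small-sigma minus large-sigma blur > amplitude floor);
#' those pixels, intersected with the nucleus mask, seed a geodesic
#' reconstruction of the nucleus foreground, and any nucleus containing
#' reconstructed pixels is called positive. The amplitude floor (default
#' \code{floor_k} times the robust background SD of the band-pass image)
#' suppresses noise-only positives; at 0 the call reduces to the pure
#' difference criterion.
#'
#' @param fitc single-channel matrix.
#' @param nuclei integer label matrix from \code{\link{segment_nuclei}}.
#' @param sigma_small,sigma_large band-pass SDs in px (small < large).
#' @param floor_k amplitude floor in robust-SD units.
#' @return sorted integer vector of positive nucleus labels.
#' @export
call_cyclinA2_positive <- function(fitc, nuclei, sigma_small = 2,
                                   sigma_large = 8, floor_k = 2) {
  if (!identical(dim(fitc), dim(nuclei))) {
    stop("fitc and nucleus map shapes differ: ",
         paste(dim(fitc), collapse = "x"), " vs ",
         paste(dim(nuclei), collapse = "x"))
  }
  if (sigma_small >= sigma_large) stop("sigma_small must be < sigma_large")
  if (all(fitc == 0)) return(integer(0))
  g1 <- EBImage::gblur(as_ebimage(fitc), sigma = sigma_small)
  g2 <- EBImage::gblur(as_ebimage(fitc), sigma = sigma_large)
  dog <- matrix(g1 - g2, nrow(fitc), ncol(fitc))
  # the floor is expressed against the channel's robust background SD; the
  # band-passed image itself is nearly flat off-marker and would undershoot
  floor_amp <- floor_k * robust_bg_sd(fitc)
  # 1e-6 guards against FFT round-off reading as positive band-pass signal
  pos_px <- dog > max(1e-6, floor_amp)
  marker <- pos_px & (nuclei > 0)
  # reconstruction of the nucleus foreground from this marker recovers the
  # components touching it; on a label map those are exactly the labels
  # holding marker pixels, read off directly so touching nuclei split by
  # watershed cannot bleed into one another
  sort(unique(nuclei[marker]))
}

# Scale-normalized Laplacian-of-Gaussian kernel (negated: bright blobs give
# positive response).
log_kernel <- function(sigma) {
  w <- ceiling(3 * sigma)
  x <- -w:w
  g <- exp(-outer(x^2, x^2, "+") / (2 * sigma^2))
  g <- g / sum(g)
  r2 <- outer(x^2, x^2, "+")
  k <- -(r2 - 2 * sigma^2) / sigma^4 * g   # -Laplacian of the Gaussian
  k <- k - mean(k)                          # zero-DC: flat regions -> 0
  sigma^2 * k                               # scale normalization
}

#' Detect RAD51 foci by Laplacian-of-Gaussian filtering
#'
#' Convolves the CY3 channel with a scale-normalized LoG kernel (negated so
#' bright spots on dark background give positive response, matching the
#' assay's "bright foci on dark backgrounds" convention), then keeps local
#' maxima above \code{threshold} with non-maximum suppression at radius
#' \code{sigma}. Dark spots (inverted polarity) give negative response and
#' are never detected.
#'
#' @param cy3 single-channel matrix.
#' @param sigma spot scale in px.
#' @param threshold minimum response (scale-normalized units).
#' @return data.frame (row, col, response), one row per focus centroid.
#' @export
detect_rad51_foci <- function(cy3, sigma = 2, threshold = 0.05) {
  stopifnot(is.matrix(cy3), sigma > 0)
  resp <- matrix(EBImage::filter2(as_ebimage(cy3), log_kernel(sigma)),
                 nrow(cy3), ncol(cy3))
  r <- max(1L, ceiling(sigma))
  mx <- EBImage::dilate(as_ebimage(resp), EBImage::makeBrush(2L * r + 1L, "disc"))
  cand <- (abs(resp - matrix(mx, nrow(resp), ncol(resp))) < 1e-12) &
    (resp > threshold)
  if (!any(cand)) {
    return(data.frame(row = numeric(0), col = numeric(0), response = numeric(0)))
  }
  # plateaus of equal response collapse to one centroid per component
  comp <- as_label_matrix(EBImage::bwlabel(cand))
  idx <- which(comp > 0, arr.ind = TRUE)
  lab <- comp[comp > 0]
  out <- data.frame(
    row = as.numeric(tapply(idx[, 1], lab, mean)),
    col = as.numeric(tapply(idx[, 2], lab, mean)),
    response = as.numeric(tapply(resp[comp > 0], lab, max))
  )
  rownames(out) <- NULL
  out
}

#' Count foci per nucleus, restricted to Cyclin A2-positive nuclei
#'
#' Assigns each focus to the nucleus whose mask contains its (rounded)
#' centroid. Foci on background or inside Cyclin A2-negative nuclei are
#' kept in the assignment table but flagged excluded; the per-nucleus
#' counts cover every segmented nucleus (zeros included) with positivity
#' flags, so downstream scoring can keep only proliferating nuclei.
#'
#' @param foci data.frame from \code{\link{detect_rad51_foci}}.
#' @param nuclei integer label matrix.
#' @param positives integer vector of Cyclin A2-positive labels.
#' @return list: \code{counts} data.frame (nucleus, cyca2_positive,
#'   focus_count) and \code{assignments} data.frame (row, col, nucleus
#'   [0 = background], excluded).
#' @export
count_foci_per_nucleus <- function(foci, nuclei, positives) {
  n_lab <- max(nuclei)
  labels <- seq_len(n_lab)
  if (nrow(foci) == 0) {
    assignments <- data.frame(row = numeric(0), col = numeric(0),
                              nucleus = integer(0), excluded = logical(0))
  } else {
    ri <- pmin(pmax(round(foci$row), 1), nrow(nuclei))
    ci <- pmin(pmax(round(foci$col), 1), ncol(nuclei))
    hit <- nuclei[cbind(ri, ci)]
    assignments <- data.frame(row = foci$row, col = foci$col, nucleus = hit,
                              excluded = !(hit %in% positives) | hit == 0)
  }
  counts <- data.frame(
    nucleus = labels,
    cyca2_positive = labels %in% positives,
    focus_count = as.integer(tabulate(assignments$nucleus[!assignments$excluded],
                                      nbins = n_lab))
  )
  list(counts = counts, assignments = assignments)
}

#' Quantify one three-channel slide end to end
#'
#' Runs organoid detection, nucleus segmentation, Cyclin A2 calling, focus
#' detection and per-nucleus counting with the parameters of a
#' \code{\link{recap_config}}; nuclei are assigned to the organoid holding
#' the majority of their pixels (0 when outside all organoids).
#'
#' @param image rows x cols x 3 array, channels DAPI, FITC, CY3 (or a list
#'   with those names).
#' @param config a \code{\link{recap_config}}.
#' @param model,condition identifiers copied into the output rows.
#' @return data.frame (model, condition, organoid, nucleus, cyca2_positive,
#'   focus_count); attribute \code{assignments} holds the focus table.
#' @export
quantify_slide <- function(image, config = recap_config(),
                           model = "model", condition = "control") {
  if (is.list(image) && !is.array(image)) {
    need <- c("dapi", "fitc", "cy3")
    if (!all(need %in% names(image))) {
      stop("image list must have channels: ", paste(need, collapse = ", "))
    }
    dapi <- image$dapi; fitc <- image$fitc; cy3 <- image$cy3
  } else {
    if (length(dim(image)) != 3 || dim(image)[3] < 3) {
      stop("image must be a rows x cols x 3 array (DAPI, FITC, CY3)")
    }
    dapi <- image[, , 1]; fitc <- image[, , 2]; cy3 <- image[, , 3]
  }
  if (config$dog_sigma_small >= config$dog_sigma_large) {
    stop("invalid config: dog_sigma_small must be < dog_sigma_large")
  }
  organoids <- detect_organoids(dapi, config$organoid_blur_sigma,
                                config$organoid_min_area_px)
  nuclei <- segment_nuclei(dapi, config$nucleus_blur_sigma,
                           config$nucleus_min_area_px,
                           config$watershed_tolerance)
  positives <- call_cyclinA2_positive(fitc, nuclei, config$dog_sigma_small,
                                      config$dog_sigma_large,
                                      config$dog_floor_k)
  foci <- detect_rad51_foci(cy3, config$log_sigma, config$log_threshold)
  counted <- count_foci_per_nucleus(foci, nuclei, positives)

  n_lab <- max(nuclei)
  org_of <- integer(n_lab)
  if (n_lab > 0 && max(organoids) > 0) {
    px <- which(nuclei > 0)
    tab <- table(nuclei[px], organoids[px])
    org_of[as.integer(rownames(tab))] <-
      as.integer(colnames(tab))[apply(tab, 1, which.max)]
  }
  out <- data.frame(
    model = model, condition = condition,
    organoid = org_of[counted$counts$nucleus],
    counted$counts
  )
  attr(out, "assignments") <- counted$assignments
  out
}

#' Quantify every image of a synthetic cohort
#'
#' @param cohort output of \code{\link{gen_recap_cohort}}.
#' @param config a \code{\link{recap_config}}.
#' @return combined focus table over all models and conditions.
#' @export
quantify_cohort <- function(cohort, config = recap_config()) {
  rows <- list()
  for (id in names(cohort$models)) {
    mod <- cohort$models[[id]]
    for (cond in names(mod$images)) {
      rows[[length(rows) + 1L]] <-
        quantify_slide(mod$images[[cond]], config, model = id,
                       condition = cond)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Match segmented nuclei to ground-truth nuclei
#'
#' Maps each segmented nucleus label to the ground-truth label holding the
#' majority of its pixels (0 when mostly background), so detector output
#' can be scored against a generator's recorded truth even though label
#' numbering differs.
#'
#' @param nuclei segmented label matrix.
#' @param truth_masks ground-truth label matrix of equal shape.
#' @return integer vector: entry i is the truth label for segmented
#'   label i.
#' @export
match_segmentation_to_truth <- function(nuclei, truth_masks) {
  stopifnot(identical(dim(nuclei), dim(truth_masks)))
  n_lab <- max(nuclei)
  out <- integer(n_lab)
  for (i in seq_len(n_lab)) {
    tl <- truth_masks[nuclei == i]
    tab <- tabulate(tl + 1L)
    out[i] <- which.max(tab) - 1L
  }
  out
}

#' Score a quantified slide against its ground truth
#'
#' Matches segmented nuclei to ground-truth nuclei by majority overlap and
#' compares per-nucleus focus counts over ground-truth Cyclin A2-positive
#' nuclei, plus precision/recall of the positivity call.
#'
#' @param slide data.frame from \code{\link{quantify_slide}} (with the
#'   \code{nucleus} labels of the segmentation used).
#' @param nuclei the segmented label matrix used for the slide.
#' @param truth an \code{image_ground_truth}.
#' @return list: \code{per_nucleus} (truth label, truth count, detected
#'   count), \code{exact_fraction}, \code{mae}, \code{pos_precision},
#'   \code{pos_recall}, \code{n_matched}.
#' @export
score_quantification <- function(slide, nuclei, truth) {
  map <- match_segmentation_to_truth(nuclei, truth$nucleus_masks)
  seg_labels <- slide$nucleus
  truth_label <- map[seg_labels]
  keep <- truth_label > 0 & !duplicated(truth_label)
  df <- data.frame(truth_label = truth_label[keep],
                   detected = slide$focus_count[keep],
                   called_positive = slide$cyca2_positive[keep])
  df$truth_count <- truth$foci_per_nucleus[as.character(df$truth_label)]
  df$truth_positive <- df$truth_label %in% truth$cyca2_positive_labels
  pos <- df[df$truth_positive, ]
  called <- df$truth_label[df$called_positive]
  truth_pos <- truth$cyca2_positive_labels
  list(per_nucleus = df,
       exact_fraction = mean(pos$detected == pos$truth_count),
       mae = mean(abs(pos$detected - pos$truth_count)),
       pos_precision = if (length(called)) mean(called %in% truth_pos) else NA_real_,
       pos_recall = mean(truth_pos %in% called),
       n_matched = nrow(df))
}
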