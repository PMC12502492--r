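#' Describe an HRD or HRP focus-formation regime
#'
#' A regime encodes how a model behaves in the irradiation assay: the mean
#' RAD51 focus count per Cyclin A2-positive nucleus in each condition
#' (unirradiated control, 2 h and 24 h after 5 Gy), the fraction of
#' proliferating (Cyclin A2-positive) nuclei, and how many nuclei to render.
#' Homologous-recombination-proficient (HRP) models induce foci at 2 h and
#' partially resolve them by 24 h; deficient (HRD) models stay near their
#' basal level.
#'
#' @param name "HRD" or "HRP".
#' @param mean_foci named numeric of length 3 (control, post2h, post24h);
#'   defaults depend on \code{name}.
#' @param cyca2_fraction fraction of nuclei that are Cyclin A2 positive.
#' @param nucleus_count number of nuclei to render per image.
#' @return A list of class \code{recap_regime}.
#' @export
recap_regime <- function(name = c("HRP", "HRD"),
                         mean_foci = NULL,
                         cyca2_fraction = 0.6,
                         nucleus_count = 80) {
  name <- match.arg(name)
  if (is.null(mean_foci)) {
    mean_foci <- if (name == "HRP") {
      c(control = 1, post2h = 8, post24h = 3)
    } else {
      c(control = 1, post2h = 1.5, post24h = 1.5)
    }
  }
  stopifnot(
    all(c("control", "post2h", "post24h") %in% names(mean_foci)),
    all(mean_foci >= 0),
    cyca2_fraction > 0, cyca2_fraction <= 1,
    nucleus_count >= 1
  )
  if (name == "HRP" && mean_foci["post2h"] <= mean_foci["control"]) {
    stop("an HRP regime must induce foci: mean_foci['post2h'] > mean_foci['control']")
  }
  structure(
    list(name = name, mean_foci = mean_foci[c("control", "post2h", "post24h")],
         cyca2_fraction = cyca2_fraction, nucleus_count = nucleus_count),
    class = "recap_regime"
  )
}

# Dart-throwing placement of nucleus centers with pairwise exclusion.
# Returns matrix (row, col, rx, ry, theta); errors when the field is too
# crowded after `max_retry` rejected darts per nucleus.
place_nuclei <- function(n, shape, r_range = c(8, 13), gap = 2,
                         max_retry = 1000) {
  centers <- matrix(NA_real_, nrow = n, ncol = 5,
                    dimnames = list(NULL, c("row", "col", "rx", "ry", "theta")))
  for (i in seq_len(n)) {
    rx <- runif(1, r_range[1], r_range[2])
    ry <- runif(1, r_range[1], r_range[2])
    rmax <- max(rx, ry)
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      r0 <- runif(1, rmax + 2, shape[1] - rmax - 1)
      c0 <- runif(1, rmax + 2, shape[2] - rmax - 1)
      if (i == 1L) { ok <- TRUE } else {
        prev <- centers[seq_len(i - 1L), , drop = FALSE]
        d <- sqrt((prev[, "row"] - r0)^2 + (prev[, "col"] - c0)^2)
        ok <- all(d >= pmax(prev[, "rx"], prev[, "ry"]) + rmax + gap)
      }
      if (ok) { centers[i, ] <- c(r0, c0, rx, ry, runif(1, 0, pi)); break }
    }
    if (!ok) {
      stop("nucleus placement failed after ", max_retry,
           " retries: field of ", shape[1], "x", shape[2],
           " px cannot hold ", n, " nuclei")
    }
  }
  centers
}

# Rasterize one rotated ellipse into the label map (in place semantics via
# returned matrix).
fill_ellipse <- function(labels, label, row0, col0, rx, ry, theta) {
  rmax <- ceiling(max(rx, ry))
  rows <- max(1, floor(row0 - rmax)):min(nrow(labels), ceiling(row0 + rmax))
  cols <- max(1, floor(col0 - rmax)):min(ncol(labels), ceiling(col0 + rmax))
  dr <- outer(rows - row0, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - col0)
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  inside <- (u / rx)^2 + (v / ry)^2 <= 1
  sub <- labels[rows, cols]
  sub[inside & sub == 0] <- label
  labels[rows, cols] <- sub
  labels
}

# Add an isotropic Gaussian spot of given peak amplitude at (row0, col0).
add_spot <- function(img, row0, col0, sigma, amplitude) {
  w <- ceiling(4 * sigma)
  rows <- max(1, round(row0) - w):min(nrow(img), round(row0) + w)
  cols <- max(1, round(col0) - w):min(ncol(img), round(col0) + w)
  dr <- outer(rows - row0, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - col0)
  img[rows, cols] <- img[rows, cols] +
    amplitude * exp(-(dr^2 + dc^2) / (2 * sigma^2))
  img
}

#' Render a synthetic three-channel immunofluorescence image
#'
#' Generates a DAPI/FITC/CY3 field emulating a stained organoid section:
#' elliptical nuclei on a dark background (DAPI), elevated signal inside
#' Cyclin A2-positive nuclei (FITC), and punctate RAD51-like foci rendered
#' as isotropic Gaussian spots inside nuclei (CY3), with per-nucleus focus
#' counts drawn Poisson with the regime's condition mean. Every rendered
#' structure is recorded in the returned ground truth, so downstream
#' detectors can be scored exactly.
#'
#' Foci are placed by dart-throwing inside the nucleus with a minimum
#' spacing of \code{3 * spot_sigma}; when a crowded nucleus cannot hold
#' its Poisson draw the rendered (and recorded) count is the number of
#' spots actually placed.
#'
#' @param regime a \code{\link{recap_regime}}.
#' @param condition "control", "post2h" or "post24h".
#' @param shape integer (rows, cols) of the field.
#' @param seed integer seed; identical seeds give identical output.
#' @param spot_sigma Gaussian spot radius in px.
#' @param noise_sd additive Gaussian background noise SD (0 = noiseless).
#' @param snr spot peak amplitude expressed in units of \code{noise_sd}
#'   (when \code{noise_sd} is 0 the amplitude falls back to 0.5).
#' @param pixel_size_um physical pixel size recorded in the ground truth.
#' @return list with \code{image} (rows x cols x 3 array, channels DAPI,
#'   FITC, CY3 in [0,1]) and \code{truth} (class \code{image_ground_truth}:
#'   \code{nucleus_masks} label matrix, \code{cyca2_positive_labels},
#'   \code{foci_per_nucleus} named integer vector, \code{foci_xy} matrix of
#'   centers with nucleus label, \code{condition}, \code{pixel_size_um}).
#' @export
gen_recap_image <- function(regime, condition = c("control", "post2h", "post24h"),
                            shape = c(384L, 384L), seed = 1L,
                            spot_sigma = 2, noise_sd = 0.0625, snr = 8,
                            pixel_size_um = 0.325) {
  condition <- match.arg(condition)
  stopifnot(inherits(regime, "recap_regime"), length(shape) == 2)
  set.seed(seed)
  n <- regime$nucleus_count
  centers <- place_nuclei(n, shape)

  labels <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(n)) {
    labels <- fill_ellipse(labels, i, centers[i, "row"], centers[i, "col"],
                           centers[i, "rx"], centers[i, "ry"],
                           centers[i, "theta"])
  }

  n_pos <- max(1L, round(regime$cyca2_fraction * n))
  if (regime$cyca2_fraction >= 1) n_pos <- n
  pos_labels <- sort(sample.int(n, n_pos))

  amplitude <- if (noise_sd > 0) snr * noise_sd else 0.5
  mu <- unname(regime$mean_foci[condition])

  dapi <- matrix(0, shape[1], shape[2])
  fitc <- matrix(0, shape[1], shape[2])
  cy3 <- matrix(0, shape[1], shape[2])
  foci_counts <- integer(n)
  foci_list <- list()

  min_sep <- 3 * spot_sigma  # Rayleigh-style spacing so spots stay resolvable
  for (i in seq_len(n)) {
    px <- which(labels == i, arr.ind = TRUE)
    dapi[px] <- 0.55 + runif(1, -0.08, 0.08)
    fitc[px] <- if (i %in% pos_labels) 0.5 + runif(1, -0.06, 0.06) else 0.03
    k <- rpois(1, mu)
    placed <- matrix(numeric(0), ncol = 2)
    if (k > 0) {
      # keep spots off the rim so their mass stays inside the mask
      core <- px[sqrt((px[, 1] - centers[i, "row"])^2 +
                        (px[, 2] - centers[i, "col"])^2) <=
                   max(1, min(centers[i, c("rx", "ry")]) - spot_sigma), ,
                 drop = FALSE]
      if (nrow(core) == 0) core <- px
      for (s in seq_len(k)) {
        ok <- FALSE
        for (try in seq_len(50)) {
          cand <- core[sample.int(nrow(core), 1), ]
          if (nrow(placed) == 0 ||
              all(sqrt((placed[, 1] - cand[1])^2 +
                         (placed[, 2] - cand[2])^2) >= min_sep)) {
            placed <- rbind(placed, cand)
            ok <- TRUE
            break
          }
        }
        if (!ok) break  # nucleus is full; truth records what was rendered
      }
      if (nrow(placed) > 0) {
        for (s in seq_len(nrow(placed))) {
          cy3 <- add_spot(cy3, placed[s, 1], placed[s, 2], spot_sigma, amplitude)
        }
      }
    }
    foci_counts[i] <- nrow(placed)
    if (nrow(placed) > 0) {
      foci_list[[length(foci_list) + 1L]] <-
        cbind(row = placed[, 1], col = placed[, 2], nucleus = i)
    }
  }

  # autofluorescence-like baselines keep additive noise off the clip floor
  cy3 <- cy3 + 0.03
  fitc <- fitc + 0.08
  if (noise_sd > 0) {
    dapi <- dapi + matrix(rnorm(prod(shape), 0, 0.02), shape[1], shape[2])
    fitc <- fitc + matrix(rnorm(prod(shape), 0, 0.02), shape[1], shape[2])
    cy3 <- cy3 + matrix(rnorm(prod(shape), 0, noise_sd), shape[1], shape[2])
  }
  clip01 <- function(m) { m[m < 0] <- 0; m[m > 1] <- 1; m }
  img <- array(0, c(shape[1], shape[2], 3),
               dimnames = list(NULL, NULL, c("dapi", "fitc", "cy3")))
  img[, , 1] <- clip01(dapi)
  img[, , 2] <- clip01(fitc)
  img[, , 3] <- clip01(cy3)

  foci_xy <- if (length(foci_list)) do.call(rbind, foci_list) else
    matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("row", "col", "nucleus")))
  truth <- structure(
    list(nucleus_masks = labels,
         cyca2_positive_labels = pos_labels,
         foci_per_nucleus = setNames(foci_counts, seq_len(n)),
         foci_xy = foci_xy,
         condition = condition,
         pixel_size_um = pixel_size_um),
    class = "image_ground_truth"
  )
  list(image = img, truth = truth)
}

#' Generate a multi-model RECAP imaging cohort with ground truth
#'
#' Draws \code{n_hrd} HRD and \code{n_hrp} HRP models, renders one image
#' per model and condition (control, 2 h, 24 h post 5 Gy) and assembles the
#' ground-truth focus table. Per-model condition means receive a small
#' lognormal jitter around the regime defaults so models are not clones;
#' the jitter is small enough that the radio-induced gap of every HRP
#' model exceeds that of every HRD model.
#'
#' @param n_hrd,n_hrp numbers of HRD / HRP models (sum must be >= 1).
#' @param seed integer master seed.
#' @param nucleus_count nuclei per image.
#' @param shape image shape in px.
#' @param noise_sd,snr passed to \code{\link{gen_recap_image}}.
#' @param cyca2_fraction fraction of Cyclin A2-positive nuclei.
#' @return list with \code{models} (named list; each has \code{label},
#'   \code{regime}, \code{images} and \code{truths} per condition),
#'   \code{truth_table} (data.frame: model, condition, nucleus,
#'   cyca2_positive, focus_count) and \code{labels} (named character
#'   vector of ground-truth HRD/HRP per model).
#' @export
gen_recap_cohort <- function(n_hrd, n_hrp, seed = 1L,
                             nucleus_count = 80, shape = c(384L, 384L),
                             noise_sd = 0.0625, snr = 8,
                             cyca2_fraction = 0.6) {
  stopifnot(n_hrd >= 0, n_hrp >= 0, n_hrd + n_hrp >= 1)
  set.seed(seed)
  specs <- c(rep("HRD", n_hrd), rep("HRP", n_hrp))
  ids <- sprintf("M%02d", seq_along(specs))
  conditions <- c("control", "post2h", "post24h")
  models <- vector("list", length(specs))
  names(models) <- ids
  rows <- list()
  for (m in seq_along(specs)) {
    base <- recap_regime(specs[m], cyca2_fraction = cyca2_fraction,
                         nucleus_count = nucleus_count)
    jitter <- exp(rnorm(3, 0, 0.08))
    mf <- base$mean_foci * jitter
    if (specs[m] == "HRD") {
      # keep the induced gap small and bounded for deficient models
      mf["post2h"] <- mf["control"] + runif(1, 0, 0.5)
      mf["post24h"] <- mf["post2h"]
    }
    regime <- recap_regime(specs[m], mean_foci = mf,
                           cyca2_fraction = cyca2_fraction,
                           nucleus_count = nucleus_count)
    img_seeds <- sample.int(.Machine$integer.max, length(conditions))
    images <- truths <- vector("list", length(conditions))
    names(images) <- names(truths) <- conditions
    for (ci in seq_along(conditions)) {
      out <- gen_recap_image(regime, conditions[ci], shape = shape,
                             seed = img_seeds[ci], noise_sd = noise_sd,
                             snr = snr)
      images[[ci]] <- out$image
      truths[[ci]] <- out$truth
      tt <- out$truth
      rows[[length(rows) + 1L]] <- data.frame(
        model = ids[m], condition = conditions[ci],
        nucleus = as.integer(names(tt$foci_per_nucleus)),
        cyca2_positive = as.integer(names(tt$foci_per_nucleus)) %in%
          tt$cyca2_positive_labels,
        focus_count = as.integer(tt$foci_per_nucleus)
      )
    }
    models[[m]] <- list(label = specs[m], regime = regime,
                        images = images, truths = truths)
  }
  list(models = models,
       truth_table = do.call(rbind, rows),
       labels = setNames(specs, ids))
}
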