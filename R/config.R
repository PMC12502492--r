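#' Default pipeline configuration
#'
#' Collects every tunable constant of the pipeline in one list. The scoring
#' cutoffs default to the values calibrated in the source study: plate QC
#' z-score minimum 0.4, genomic instability score (GIS) threshold 0.48 with
#' a +/- 0.25 indeterminate margin (so the HRDmid band is [0.23, 0.73]),
#' RECAP PC1 cutoff -0.5, variant allele frequency floor 0.05, and the
#' 6-month platinum-sensitivity rule on the platinum-free interval (PFI).
#' Imaging parameters (Gaussian sigmas, detection thresholds, minimum areas)
#' are stated defaults for the classical segmentation chain; they carry no
#' claim of matching any particular acquisition setup and should be tuned
#' per assay.
#'
#' @param ... named overrides of any default entry; unknown names error.
#' @return A named list of class \code{recap_config}.
#' @examples
#' cfg <- recap_config()
#' cfg$gis_threshold + cfg$gis_margin   # upper edge of the HRDmid band
#' @export
recap_config <- function(...) {
  cfg <- list(
    # imaging: organoid detection
    organoid_blur_sigma = 16,
    organoid_min_area_px = 2000,
    # imaging: nucleus segmentation
    nucleus_blur_sigma = 2,
    nucleus_min_area_px = 30,
    watershed_tolerance = 1,
    # imaging: Cyclin A2 positivity (difference of Gaussians)
    dog_sigma_small = 2,
    dog_sigma_large = 8,
    dog_floor_k = 2,          # amplitude floor = k * robust background SD
    # imaging: RAD51 focus detection (Laplacian of Gaussian)
    log_sigma = 2,
    log_threshold = 0.05,     # scale-normalized response units
    # scoring
    min_nuclei = 20,
    gmm_components = 1,
    recap_cutoff = -0.5,
    # drug response
    qc_min = 0.4,
    auc_scale = "log10",      # integration variable: "log10" or "linear"
    # HR integration
    gis_threshold = 0.48,
    gis_margin = 0.25,
    vaf_min = 0.05,
    pfi_sensitive_months = 6,
    # expression concordance
    nmf_ranks = 2:18,
    nmf_max_iter = 2000,
    nmf_tol = 1e-5,
    signature_pct = 5,
    # seeds, one per stochastic stage
    seed_synth = 1L,
    seed_nmf = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config entries: ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  if (cfg$dog_sigma_small >= cfg$dog_sigma_large) {
    stop("dog_sigma_small must be < dog_sigma_large")
  }
  if (cfg$gis_margin <= 0 || cfg$gis_threshold <= 0 || cfg$gis_threshold >= 1) {
    stop("gis_threshold must lie in (0,1) and gis_margin be positive")
  }
  class(cfg) <- c("recap_config", "list")
  cfg
}

#' Long-term organoid establishment rate from cohort counts
#'
#' The establishment success rate of long-term PDTO lines: the number of
#' samples that expanded beyond eight passages and regrew after thawing,
#' divided by the number of samples put in culture, as a percentage.
#'
#' @param established number of established long-term lines.
#' @param attempted number of samples cultured.
#' @return Percentage in [0, 100].
#' @examples
#' establishment_rate(31, 224)
#' @export
establishment_rate <- function(established, attempted) {
  stopifnot(attempted > 0, established >= 0, established <= attempted)
  100 * established / attempted
}
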