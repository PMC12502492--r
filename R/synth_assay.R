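#' Specify a synthetic viability plate
#'
#' Describes a drug-treatment plate with negative controls (vehicle),
#' positive controls (a staurosporine-like kill control) and treated wells
#' following a four-parameter logistic of dose, with multiplicative
#' Gaussian noise of coefficient of variation \code{noise_cv}.
#'
#' @param doses_uM strictly increasing dose grid, micromolar.
#' @param true_ic50_uM dose at the curve midpoint.
#' @param hill Hill slope of the generating curve.
#' @param n_negative,n_positive,n_treated_per_dose well counts.
#' @param neg_mean,pos_mean expected raw signals of the control groups
#'   (positive far below negative for an exploitable assay).
#' @param top,bottom asymptotic viability fractions of the curve.
#' @param noise_cv multiplicative noise CV, must be < 1.
#' @param seed integer seed.
#' @return list of class \code{plate_spec}.
#' @export
plate_spec <- function(doses_uM = 10^seq(-1, 2, length.out = 8),
                       true_ic50_uM = 10, hill = 1,
                       n_negative = 6, n_positive = 6, n_treated_per_dose = 3,
                       neg_mean = 100, pos_mean = 5,
                       top = 1, bottom = 0,
                       noise_cv = 0.05, seed = 1L) {
  stopifnot(
    all(diff(doses_uM) > 0), all(doses_uM > 0), true_ic50_uM > 0,
    n_negative >= 1, n_positive >= 1, n_treated_per_dose >= 1,
    neg_mean > pos_mean, noise_cv >= 0, noise_cv < 1
  )
  structure(as.list(environment()), class = "plate_spec")
}

# 4PL viability at dose d (GraphPad parameterization on log10 dose).
logistic4 <- function(d, top, bottom, ic50, hill) {
  bottom + (top - bottom) / (1 + 10^((log10(ic50) - log10(d)) * -hill))
}

#' Generate a viability plate table
#'
#' Draws raw signals for every well of a \code{\link{plate_spec}}: control
#' wells Gaussian around their group mean with SD \code{cv * mean},
#' treated wells at \code{neg_mean} times the generating logistic with
#' multiplicative noise. The generating curve parameters ride along as
#' attributes so recovery can be scored.
#'
#' @param spec a \code{\link{plate_spec}}.
#' @return data.frame (well, role, dose_uM, signal) with attribute
#'   \code{truth} holding the generating parameters.
#' @export
gen_viability_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  set.seed(spec$seed)
  neg <- rnorm(spec$n_negative, spec$neg_mean, spec$noise_cv * spec$neg_mean)
  pos <- rnorm(spec$n_positive, spec$pos_mean, spec$noise_cv * spec$pos_mean)
  rows <- list(
    data.frame(well = sprintf("N%02d", seq_along(neg)), role = "neg",
               dose_uM = NA_real_, signal = neg),
    data.frame(well = sprintf("P%02d", seq_along(pos)), role = "pos",
               dose_uM = NA_real_, signal = pos)
  )
  w <- 0L
  for (d in spec$doses_uM) {
    mu <- spec$neg_mean *
      logistic4(d, spec$top, spec$bottom, spec$true_ic50_uM, spec$hill)
    eps <- if (spec$noise_cv > 0) rnorm(spec$n_treated_per_dose, 1, spec$noise_cv) else
      rep(1, spec$n_treated_per_dose)
    rows[[length(rows) + 1L]] <- data.frame(
      well = sprintf("T%03d", w + seq_len(spec$n_treated_per_dose)),
      role = "treated", dose_uM = d, signal = mu * eps
    )
    w <- w + spec$n_treated_per_dose
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL
  attr(plate, "truth") <- spec[c("true_ic50_uM", "hill", "top", "bottom",
                                 "neg_mean", "pos_mean")]
  plate
}

#' Specify a paired tumor/organoid expression cohort
#'
#' \code{k_true} shared non-negative transcriptional programs plus one
#' tumor-only "stromal" program of amplitude \code{stroma_weight}; counts
#' drawn from a Gamma-Poisson (negative binomial) mixture with dispersion
#' \code{noise_dispersion} (variance = mu + dispersion * mu^2).
#'
#' @param n_genes,n_pairs matrix dimensions (samples = 2 * n_pairs).
#' @param k_true number of shared latent programs (>= 2).
#' @param stroma_weight amplitude of the tumor-only program (0 = none).
#'   The stromal program concentrates its weight on a dedicated gene
#'   block, so small exposure amplitudes already separate tumors from
#'   organoids; the default is calibrated so tumor/organoid pair
#'   R-squared lands in the low-0.6s, the level reported for real
#'   stroma-containing tumor biopsies against their organoids.
#' @param noise_dispersion NB dispersion, > 0 (0.2 emulates patient-sample
#'   variability and yields tumor/organoid pair R-squared near 0.7).
#' @param pair_jitter_sd lognormal SD of the within-pair exposure jitter.
#' @param seed integer seed.
#' @return list of class \code{paired_expression_spec}.
#' @export
paired_expression_spec <- function(n_genes = 2000, n_pairs = 15, k_true = 4,
                                   stroma_weight = 0.02,
                                   noise_dispersion = 0.2,
                                   pair_jitter_sd = 0.3, seed = 1L) {
  stopifnot(k_true >= 2, k_true < 2 * n_pairs, n_genes > 10,
            stroma_weight >= 0, noise_dispersion > 0)
  structure(as.list(environment()), class = "paired_expression_spec")
}

#' Generate a paired tumor/PDTO count matrix
#'
#' Each pair shares one dominant program (plus a low uniform load on the
#' others); tumor columns additionally load the stromal program. Counts
#' are negative-binomial via a Gamma-Poisson mixture.
#'
#' @param spec a \code{\link{paired_expression_spec}}.
#' @return list: \code{counts} (genes x samples integer matrix, columns
#'   "T01..", "O01.."), \code{pairing} (data.frame tumor, pdto),
#'   \code{programs} (genes x (k_true [+1]) true program matrix),
#'   \code{exposures} (true program x sample loads).
#' @export
gen_paired_expression <- function(spec) {
  stopifnot(inherits(spec, "paired_expression_spec"))
  set.seed(spec$seed)
  g <- spec$n_genes; k <- spec$k_true; p <- spec$n_pairs
  # sparse-ish non-negative programs: each has a dedicated high-weight block
  programs <- matrix(rgamma(g * k, shape = 0.3, rate = 1), g, k)
  block <- split(seq_len(g), cut(seq_len(g), k + 1, labels = FALSE))
  for (j in seq_len(k)) {
    programs[block[[j]], j] <- programs[block[[j]], j] + rgamma(length(block[[j]]), 4, 0.5)
  }
  stroma <- matrix(rgamma(g, shape = 0.3, rate = 1), g, 1)
  stroma[block[[k + 1]], 1] <- stroma[block[[k + 1]], 1] +
    rgamma(length(block[[k + 1]]), 4, 0.5)

  tumor_ids <- sprintf("T%02d", seq_len(p))
  pdto_ids <- sprintf("O%02d", seq_len(p))
  expo <- matrix(0, k + 1, 2 * p,
                 dimnames = list(c(paste0("prog", seq_len(k)), "stroma"),
                                 c(tumor_ids, pdto_ids)))
  dominant <- rep_len(seq_len(k), p)
  for (i in seq_len(p)) {
    base <- runif(k, 0.05, 0.25)
    base[dominant[i]] <- runif(1, 0.8, 1.2)
    # both members deviate from the pair's latent profile
    expo[seq_len(k), i] <- base * exp(rnorm(k, 0, spec$pair_jitter_sd))
    expo[seq_len(k), p + i] <- base * exp(rnorm(k, 0, spec$pair_jitter_sd))
    expo["stroma", i] <- spec$stroma_weight
  }
  mu <- cbind(programs, stroma) %*% expo * 20 + 0.1
  disp <- spec$noise_dispersion
  lambda <- matrix(rgamma(length(mu), shape = 1 / disp, rate = 1 / disp),
                   nrow(mu)) * mu
  counts <- matrix(rpois(length(lambda), lambda), nrow(mu),
                   dimnames = list(sprintf("g%04d", seq_len(g)), colnames(expo)))
  list(counts = counts,
       pairing = data.frame(tumor = tumor_ids, pdto = pdto_ids),
       programs = cbind(programs, stroma = stroma),
       exposures = expo)
}

#' Generate a survival cohort with exponential event times
#'
#' Platinum-free intervals are drawn exponential with the stated median
#' per group (rate = log(2) / median). Censoring is independent of the
#' event process: each subject gets an exponential censoring time with
#' rate chosen so the expected censored fraction equals
#' \code{censor_frac}, and the observed time is the earlier of the two.
#'
#' @param group_medians_months named positive numeric, one median per group.
#' @param n_per_group subjects per group.
#' @param censor_frac fraction censored, in [0, 1).
#' @param seed integer seed.
#' @return data.frame (patient, group, pfi_months, event).
#' @export
gen_survival_cohort <- function(group_medians_months, n_per_group,
                                censor_frac = 0, seed = 1L) {
  stopifnot(all(group_medians_months > 0), n_per_group >= 1,
            censor_frac >= 0, censor_frac < 1)
  set.seed(seed)
  rows <- lapply(names(group_medians_months), function(gname) {
    rate_t <- log(2) / group_medians_months[[gname]]
    t <- rexp(n_per_group, rate = rate_t)
    event <- rep(TRUE, n_per_group)
    if (censor_frac > 0) {
      # independent censoring: P(C < T) = rate_c / (rate_c + rate_t)
      rate_c <- rate_t * censor_frac / (1 - censor_frac)
      cens <- rexp(n_per_group, rate = rate_c)
      event <- t <= cens
      t <- pmin(t, cens)
    }
    data.frame(patient = paste0(gname, "_", seq_len(n_per_group)),
               group = gname, pfi_months = t, event = event)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a toy variant table with keep/drop ground truth
#'
#' Mixes variant allele frequencies above and below the 5% reporting floor
#' with oncogenic / inactivating / benign annotations; the ground-truth
#' \code{keep_truth} column applies the reporting rule (VAF >= 0.05 and
#' oncogenic or inactivating).
#'
#' @param seed integer seed.
#' @param n number of variant rows.
#' @return data.frame (gene, vaf, oncogenic, inactivating, keep_truth).
#' @export
gen_variant_table <- function(seed = 1L, n = 24) {
  set.seed(seed)
  hr_genes <- c("BRCA1", "BRCA2", "ATM", "BARD1", "BRIP1", "CDK12", "CHEK1",
                "CHEK2", "FANCL", "PALB2", "PPP2R2A", "RAD51B", "RAD51C",
                "RAD51D", "RAD54L", "TP53")
  vaf <- round(c(0.049, 0.05, runif(n - 2, 0.005, 0.9)), 4)
  oncogenic <- c(TRUE, TRUE, runif(n - 2) < 0.4)
  inactivating <- c(FALSE, FALSE, runif(n - 2) < 0.3)
  data.frame(
    gene = sample(hr_genes, n, replace = TRUE),
    vaf = vaf, oncogenic = oncogenic, inactivating = inactivating,
    keep_truth = vaf >= 0.05 & (oncogenic | inactivating)
  )
}
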