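#' Plate quality-control z-score
#'
#' The screening QC statistic computed from negative (vehicle) and positive
#' (staurosporine-like kill) control wells:
#' \deqn{z = 1 - \frac{3\,SD_{neg} + 3\,SD_{pos}}{\bar{x}_{neg} - \bar{x}_{pos}}}
#' A plate is exploitable when z >= \code{qc_min} (default 0.4); assays
#' below that are discarded. The score is invariant to rescaling all
#' signals by a positive constant.
#'
#' @param neg_wells,pos_wells numeric signal vectors (>= 2 wells each).
#' @param qc_min exploitability cutoff.
#' @return list: \code{z_score}, \code{exploitable}, \code{neg_mean},
#'   \code{neg_sd}, \code{pos_mean}, \code{pos_sd}.
#' @export
qc_zscore <- function(neg_wells, pos_wells, qc_min = 0.4) {
  stopifnot(length(neg_wells) >= 2, length(pos_wells) >= 2)
  nm <- mean(neg_wells); pm <- mean(pos_wells)
  if (nm <= pm) {
    stop("degenerate assay: negative-control mean (", signif(nm, 4),
         ") must exceed positive-control mean (", signif(pm, 4), ")")
  }
  ns <- sd(neg_wells); ps <- sd(pos_wells)
  z <- 1 - (3 * ns + 3 * ps) / (nm - pm)
  list(z_score = z, exploitable = z >= qc_min,
       neg_mean = nm, neg_sd = ns, pos_mean = pm, pos_sd = ps)
}

#' Normalize well signals to the negative-control mean
#'
#' @param plate data.frame with columns role ("neg"/"pos"/"treated") and
#'   signal; treated rows must carry dose_uM.
#' @return the plate with a \code{viability} column (signal / mean of
#'   negative controls).
#' @export
normalize_viability <- function(plate) {
  stopifnot(all(c("role", "signal") %in% names(plate)))
  neg <- plate$signal[plate$role == "neg"]
  if (length(neg) < 1) stop("no negative-control wells on plate")
  ctrl <- mean(neg)
  if (ctrl == 0) stop("negative-control mean is zero; cannot normalize")
  plate$viability <- plate$signal / ctrl
  plate
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of viability against log10 dose:
#' \code{v = bottom + (top - bottom) / (1 + 10^((log10(d) - log10(ic50)) * hill))}
#' with \code{hill > 0} meaning viability falls with dose. The reported
#' IC50 is relative: the dose at the midpoint of the fitted asymptotes.
#' When the fit fails or the curve is flat over the tested range the IC50
#' is \code{NA} with a diagnostic message in \code{note}.
#'
#' @param doses_uM positive doses (>= 4 distinct values).
#' @param viabilities viability fractions, same length.
#' @return list: \code{ic50_uM}, \code{top}, \code{bottom}, \code{hill},
#'   \code{converged}, \code{note}.
#' @export
fit_dose_response <- function(doses_uM, viabilities) {
  stopifnot(length(doses_uM) == length(viabilities))
  if (any(doses_uM <= 0)) stop("doses must be positive (log scale)")
  if (length(unique(doses_uM)) < 4) stop("need >= 4 distinct doses")
  # average replicates per dose before fitting
  agg <- aggregate(v ~ d, data.frame(d = doses_uM, v = viabilities), mean)
  d <- agg$d; v <- agg$v
  if (max(v) - min(v) < 0.05) {
    return(list(ic50_uM = NA_real_, top = mean(v), bottom = mean(v),
                hill = NA_real_, converged = FALSE,
                note = "flat response over tested range (resistant beyond range)"))
  }
  x <- log10(d)
  start <- list(top = max(v), bottom = min(v),
                logic50 = x[which.min(abs(v - (max(v) + min(v)) / 2))],
                hill = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      v ~ bottom + (top - bottom) / (1 + 10^((x - logic50) * hill)),
      data = data.frame(x = x, v = v), start = start,
      lower = c(top = -Inf, bottom = -Inf, logic50 = min(x) - 3, hill = 0.05),
      upper = c(top = Inf, bottom = Inf, logic50 = max(x) + 3, hill = 20),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(ic50_uM = NA_real_, top = NA_real_, bottom = NA_real_,
                hill = NA_real_, converged = FALSE,
                note = "nonlinear least squares failed"))
  }
  cf <- stats::coef(fit)
  ic50 <- 10^cf[["logic50"]]
  note <- ""
  if (ic50 > max(d) * 100 || ic50 < min(d) / 100) {
    note <- "midpoint extrapolated far outside tested range"
  }
  list(ic50_uM = ic50, top = cf[["top"]], bottom = cf[["bottom"]],
       hill = cf[["hill"]], converged = TRUE, note = note)
}

#' Area under the viability curve
#'
#' Trapezoidal area of viability (as a percentage) against log10 dose by
#' default; a linear-dose variant is available for sensitivity analysis.
#' Additive over contiguous dose sub-intervals.
#'
#' @param doses_uM strictly increasing doses.
#' @param viabilities viability fractions (1 = 100\%).
#' @param scale "log10" (default) or "linear" integration variable.
#' @return scalar AUC in percent x dose-axis units.
#' @export
compute_auc <- function(doses_uM, viabilities, scale = c("log10", "linear")) {
  scale <- match.arg(scale)
  stopifnot(length(doses_uM) == length(viabilities))
  if (length(doses_uM) < 2) stop("AUC needs at least 2 dose points")
  if (is.unsorted(doses_uM, strictly = TRUE)) stop("doses must be sorted ascending")
  x <- if (scale == "log10") log10(doses_uM) else doses_uM
  y <- 100 * viabilities
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

#' Panel-normalized AUC z-scores
#'
#' Centers and scales the per-model AUCs of one drug across the panel
#' (sample SD, n - 1): the output has mean 0 and SD 1 by construction.
#' Models with z below 0 are on the sensitive side of the panel, above 0
#' on the resistant side.
#'
#' @param aucs named numeric vector of per-model AUCs (>= 3 models).
#' @return named numeric vector of z-scores.
#' @export
normalize_auc_zscores <- function(aucs) {
  if (length(aucs) < 3) stop("need >= 3 models to normalize a panel")
  s <- sd(aucs)
  if (s == 0) stop("panel AUC standard deviation is zero")
  (aucs - mean(aucs)) / s
}

#' Sensitivity call from a normalized AUC z-score
#'
#' @param z numeric z-scores.
#' @return character vector: "sensitive" (z < 0) or "resistant" (z >= 0).
#' @export
call_sensitivity <- function(z) ifelse(z < 0, "sensitive", "resistant")

#' Pairwise Spearman correlation between drugs
#'
#' Rank correlations (with p-values) between all drug columns of a
#' models x drugs z-score matrix; exact p for n <= 9 complete pairs
#' without ties, t-approximation otherwise. Constant columns give NA with
#' a warning.
#'
#' @param z_matrix numeric matrix, rows = models, columns = drugs.
#' @return list of matrices \code{r} and \code{p} (drugs x drugs).
#' @export
correlate_drugs <- function(z_matrix) {
  stopifnot(is.matrix(z_matrix), ncol(z_matrix) >= 2)
  nd <- ncol(z_matrix)
  r <- p <- matrix(NA_real_, nd, nd,
                   dimnames = list(colnames(z_matrix), colnames(z_matrix)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(nd - 1)) {
    for (j in (i + 1):nd) {
      ok <- complete.cases(z_matrix[, c(i, j)])
      if (sum(ok) < 5) stop("need >= 5 complete pairs for drugs ",
                            i, " and ", j)
      x <- z_matrix[ok, i]; y <- z_matrix[ok, j]
      if (sd(x) == 0 || sd(y) == 0) {
        warning("constant drug column; correlation undefined")
        next
      }
      exact <- sum(ok) <= 9 && !anyDuplicated(x) && !anyDuplicated(y)
      ct <- suppressWarnings(
        cor.test(x, y, method = "spearman", exact = exact))
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  list(r = r, p = p)
}

#' Summarize a drug panel: QC, curves, AUC and z-scores
#'
#' Runs plate QC, viability normalization, curve fitting and AUC per
#' model, then panel z-scores and sensitivity calls across models.
#'
#' @param plates named list of plate data.frames (one per model) as made
#'   by \code{\link{gen_viability_plate}}.
#' @param drug drug name recorded in the output.
#' @param config a \code{\link{recap_config}}.
#' @return data.frame (model, drug, qc_z, exploitable, ic50_uM, auc,
#'   auc_zscore, call).
#' @export
summarize_drug_panel <- function(plates, drug = "drug",
                                 config = recap_config()) {
  rows <- lapply(names(plates), function(id) {
    plate <- normalize_viability(plates[[id]])
    qc <- qc_zscore(plate$signal[plate$role == "neg"],
                    plate$signal[plate$role == "pos"],
                    qc_min = config$qc_min)
    tr <- plate[plate$role == "treated", ]
    agg <- aggregate(viability ~ dose_uM, tr, mean)
    fit <- fit_dose_response(tr$dose_uM, tr$viability)
    data.frame(model = id, drug = drug, qc_z = qc$z_score,
               exploitable = qc$exploitable, ic50_uM = fit$ic50_uM,
               auc = compute_auc(agg$dose_uM, agg$viability,
                                 scale = config$auc_scale))
  })
  out <- do.call(rbind, rows)
  out$auc_zscore <- normalize_auc_zscores(setNames(out$auc, out$model))
  out$call <- call_sensitivity(out$auc_zscore)
  rownames(out) <- NULL
  out
}
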