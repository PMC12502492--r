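#' Band a genomic instability score into HRP / HRDmid / HRD
#'
#' The GIS is a logistic-model score in [0, 1] tending to 0 for
#' HR-proficient and 1 for HR-deficient tumors, with a decision threshold
#' of 0.48 calibrated on FFPE tissue. Because that calibration does not
#' directly transfer to organoids, scores within \code{margin} (default
#' 0.25) of the threshold fall in an indeterminate HRDmid band: HRP below
#' 0.23, HRDmid on the closed interval [0.23, 0.73], HRD above 0.73.
#'
#' @param score numeric GIS value(s) in [0, 1].
#' @param threshold decision threshold.
#' @param margin half-width of the indeterminate band.
#' @return character vector of bands.
#' @export
classify_gis <- function(score, threshold = 0.48, margin = 0.25) {
  if (any(!is.finite(score)) || any(score < 0) || any(score > 1)) {
    stop("GIS scores must lie in [0, 1]")
  }
  lo <- threshold - margin
  hi <- threshold + margin
  ifelse(score < lo, "HRP", ifelse(score <= hi, "HRDmid", "HRD"))
}

#' Collapse a GIS band to a binary HR status
#'
#' For analyses needing a two-way status, HRDmid models fall back on the
#' FFPE threshold itself: HRD when score >= threshold, HRP otherwise.
#'
#' @inheritParams classify_gis
#' @return character vector, "HRD" or "HRP".
#' @export
gis_binary_status <- function(score, threshold = 0.48) {
  if (any(score < 0) || any(score > 1)) stop("GIS scores must lie in [0, 1]")
  ifelse(score >= threshold, "HRD", "HRP")
}

#' Filter variants by the reporting rule
#'
#' Keeps variants with allele frequency at or above \code{vaf_min}
#' (default 5\%, boundary inclusive) that are annotated oncogenic or
#' predicted inactivating; every row receives \code{kept} and a
#' \code{drop_reason}. Idempotent and order-independent.
#'
#' @param records data.frame with columns vaf, oncogenic, inactivating.
#' @param vaf_min allele-frequency floor.
#' @return the table with \code{kept} logical and \code{drop_reason}
#'   character columns.
#' @export
filter_variants <- function(records, vaf_min = 0.05) {
  stopifnot(all(c("vaf", "oncogenic", "inactivating") %in% names(records)))
  low <- records$vaf < vaf_min
  benign <- !(records$oncogenic | records$inactivating)
  records$kept <- !low & !benign
  records$drop_reason <- ifelse(records$kept, "",
                                ifelse(low, "vaf_below_threshold",
                                       "not_oncogenic_or_inactivating"))
  records
}

#' Cross-tabulate RECAP status against GIS band
#'
#' Builds the contingency table of the functional (RECAP) call against the
#' genomic (GIS) band over shared models and lists the reclassified
#' models: genomically proficient (GIS HRP) but functionally deficient
#' (RECAP HRD).
#'
#' @param recap_status named character vector (model -> "HRD"/"HRP").
#' @param gis_band named character vector (model -> band).
#' @return list: \code{table} (RECAP x GIS counts), \code{reclassified}
#'   (character vector of GIS-HRP/RECAP-HRD models), \code{models} used.
#' @export
concordance_table <- function(recap_status, gis_band) {
  shared <- intersect(names(recap_status), names(gis_band))
  if (length(shared) == 0) stop("no shared model ids between RECAP and GIS")
  r <- factor(recap_status[shared], levels = c("HRD", "HRP"))
  g <- factor(gis_band[shared], levels = intersect(c("HRP", "HRDmid", "HRD"),
                                                   unique(gis_band[shared])))
  tab <- table(RECAP = r, GIS = g)
  reclassified <- shared[recap_status[shared] == "HRD" &
                           gis_band[shared] == "HRP"]
  list(table = tab, reclassified = reclassified, models = shared)
}

#' Kaplan-Meier estimate with the assay's median rule
#'
#' Product-limit estimator (via \code{survival::survfit}); the reported
#' median is the smallest event time where the survivor function falls to
#' 0.5 or below, \code{NA} when it never does.
#'
#' @param pfi_months event/censoring times.
#' @param event logical event indicator (FALSE = censored).
#' @return list: \code{time}, \code{surv}, \code{n_risk} step function
#'   vectors and \code{median}.
#' @export
km_estimate <- function(pfi_months, event) {
  stopifnot(length(pfi_months) == length(event))
  if (!any(event)) {
    fit <- survival::survfit(survival::Surv(pfi_months, event) ~ 1)
    return(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                median = NA_real_))
  }
  fit <- survival::survfit(survival::Surv(pfi_months, event) ~ 1)
  below <- which(fit$surv <= 0.5 & fit$n.event > 0)
  med <- if (length(below)) fit$time[min(below)] else NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk, median = med)
}

#' Two-group log-rank test
#'
#' Standard O - E test over pooled event times, 1 df, via
#' \code{survival::survdiff}.
#'
#' @param time,event,group aligned vectors; \code{group} has two levels.
#' @return list: \code{chisq}, \code{p}.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  stopifnot(nlevels(droplevels(group)) == 2)
  if (!any(event)) stop("log-rank needs at least one event")
  sd0 <- survival::survdiff(survival::Surv(time, event) ~ group)
  p <- pchisq(sd0$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd0$chisq), p = p)
}

#' Gehan-Breslow-Wilcoxon test
#'
#' Weighted log-rank with weight equal to the number at risk at each
#' event time, emphasizing early differences. Without censoring the score
#' statistic reduces to Gehan's generalized Wilcoxon pairwise scoring.
#'
#' @param time,event,group aligned vectors; two groups.
#' @return list: \code{chisq}, \code{p}, \code{score} (weighted O - E of
#'   the first group level).
#' @export
gehan_breslow_wilcoxon <- function(time, event, group) {
  group <- droplevels(as.factor(group))
  stopifnot(nlevels(group) == 2)
  if (!any(event)) stop("test needs at least one event")
  g1 <- levels(group)[1]
  times <- sort(unique(time[event]))
  num <- 0; varsum <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event & time == t)
    d1 <- sum(event & time == t & group == g1)
    if (n < 1 || d < 1) next
    e1 <- d * n1 / n
    v <- if (n > 1) d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1) else 0
    num <- num + n * (d1 - e1)
    varsum <- varsum + n^2 * v
  }
  chisq <- if (varsum > 0) num^2 / varsum else 0
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE),
       score = num)
}

#' Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Two-sided unpaired test; exact p by enumeration when the combined
#' sample has at most \code{exact_max} observations without ties, normal
#' approximation with tie correction otherwise.
#'
#' @param x,y numeric samples.
#' @param exact_max size cutover for the exact distribution.
#' @return list: \code{U} (statistic for \code{x}), \code{p}.
#' @export
mann_whitney <- function(x, y, exact_max = 12) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= exact_max && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = !exact,
                alternative = "two.sided"))
  list(U = unname(wt$statistic), p = min(1, wt$p.value))
}

#' Platinum-sensitivity label from the PFI
#'
#' @param pfi_months platinum-free interval in months.
#' @param cutoff_months sensitivity rule (default 6: PFI >= 6 months is
#'   platinum-sensitive).
#' @return character vector "sensitive"/"resistant".
#' @export
platinum_sensitive <- function(pfi_months, cutoff_months = 6) {
  ifelse(pfi_months >= cutoff_months, "sensitive", "resistant")
}

#' Copy-number profile similarity
#'
#' Pearson correlation between two equal-length binned copy-number
#' profiles, dropping bins missing in either profile. This is an explicit
#' stand-in metric: bounded in [-1, 1], 1 for identical profiles.
#'
#' @param profileA,profileB numeric per-bin vectors.
#' @return scalar similarity.
#' @export
cnv_similarity <- function(profileA, profileB) {
  if (length(profileA) != length(profileB)) {
    stop("profiles must have equal length")
  }
  ok <- is.finite(profileA) & is.finite(profileB)
  if (sum(ok) < 3) stop("fewer than 3 shared finite bins")
  cor(profileA[ok], profileB[ok])
}
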