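#' Run the full synthetic-cohort pipeline
#'
#' End-to-end composition over a synthetic cohort with known ground truth:
#' image generation, RECAP quantification and HRD/HRP classification, a
#' drug-screen panel with QC and normalized AUC z-scores, GIS banding and
#' concordance against the functional call, survival comparison between
#' status groups, and NMF tumor/organoid concordance. Every stage is
#' seeded from the config so two runs with the same config are identical.
#'
#' @param config a \code{\link{recap_config}}.
#' @param n_hrd,n_hrp cohort composition.
#' @param nucleus_count nuclei per image.
#' @param n_pairs tumor/organoid expression pairs.
#' @param n_genes genes in the expression matrix.
#' @param ks NMF candidate ranks (kept small by default to bound runtime).
#' @param n_per_group subjects per survival group.
#' @param gis_discordant number of models planted as GIS-HRP but
#'   functionally HRD (the "reclassified" set).
#' @return named list (the report bundle) with per-stage results and a
#'   provenance block.
#' @export
run_full <- function(config = recap_config(), n_hrd = 3, n_hrp = 3,
                     nucleus_count = 60, n_pairs = 6, n_genes = 800,
                     ks = 2:6, n_per_group = 40, gis_discordant = 0) {
  seed <- config$seed_synth
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }

  cohort <- stage("synth", gen_recap_cohort(n_hrd, n_hrp, seed = seed,
                                            nucleus_count = nucleus_count))
  foci <- stage("imaging", quantify_cohort(cohort, config))
  indices <- stage("scoring", recap_indices(foci, config))
  classed <- stage("scoring", classify_recap(indices, config$recap_cutoff))
  recap_status <- setNames(classed$status, classed$model)

  # drug screen: one plate per model; HRD models get lower midpoints
  plates <- stage("drugs", {
    lapply(seq_along(cohort$labels), function(i) {
      hrd <- cohort$labels[i] == "HRD"
      gen_viability_plate(plate_spec(
        true_ic50_uM = if (hrd) 3 else 30,
        seed = seed + 1000L + i))
    }) |> setNames(names(cohort$labels))
  })
  drug_summary <- stage("drugs", summarize_drug_panel(plates, "carboplatin",
                                                      config))

  # GIS scores: concordant with truth except planted discordant models
  gis <- stage("gis", {
    set.seed(seed + 5L)
    truth <- cohort$labels
    score <- ifelse(truth == "HRD", runif(length(truth), 0.78, 0.95),
                    runif(length(truth), 0.03, 0.20))
    if (gis_discordant > 0) {
      hrd_ids <- names(truth)[truth == "HRD"]
      plant <- head(hrd_ids, gis_discordant)
      score[plant] <- runif(length(plant), 0.03, 0.20)
    }
    data.frame(model = names(truth), score = unname(score),
               band = classify_gis(unname(score), config$gis_threshold,
                                   config$gis_margin))
  })
  concordance <- stage("concordance",
                       concordance_table(recap_status,
                                         setNames(gis$band, gis$model)))

  surv <- stage("survival", {
    cohort_surv <- gen_survival_cohort(
      c(HRD = 16.79, HRP = 4.40), n_per_group = n_per_group,
      censor_frac = 0.1, seed = seed + 9L)
    by_group <- split(cohort_surv, cohort_surv$group)
    kms <- lapply(by_group, function(df) km_estimate(df$pfi_months, df$event))
    lr <- logrank_test(cohort_surv$pfi_months, cohort_surv$event,
                       cohort_surv$group)
    gbw <- gehan_breslow_wilcoxon(cohort_surv$pfi_months, cohort_surv$event,
                                  cohort_surv$group)
    list(median_by_group = vapply(kms, `[[`, numeric(1), "median"),
         logrank = lr, gehan_breslow = gbw)
  })

  expr <- stage("expression", {
    spec <- paired_expression_spec(n_genes = n_genes, n_pairs = n_pairs,
                                   seed = seed + 21L)
    sim <- gen_paired_expression(spec)
    sel <- select_rank(sim$counts, sim$pairing, ks = ks,
                       seed = config$seed_nmf)
    vst <- vst_transform(sim$counts)
    r2 <- vapply(seq_len(nrow(sim$pairing)), function(i) {
      paired_gene_correlation(vst[, sim$pairing$tumor[i]],
                              vst[, sim$pairing$pdto[i]])$r_squared
    }, numeric(1))
    list(chosen_k = sel$chosen_k,
         distance_by_k = as.list(sel$distance_by_k),
         mean_pair_r_squared = mean(r2))
  })

  report <- list(
    provenance = list(
      package_version = as.character(utils::packageVersion("recaplab")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seeds = list(synth = config$seed_synth, nmf = config$seed_nmf),
      config_hash = unname(tools::md5sum(local({
        f <- tempfile(); jsonlite::write_json(unclass(config), f,
                                              auto_unbox = TRUE, digits = NA)
        f
      })))
    ),
    cohort_labels = as.list(cohort$labels),
    recap = list(indices = indices, classification = classed,
                 accuracy = mean(recap_status[names(cohort$labels)] ==
                                   cohort$labels)),
    drugs = drug_summary,
    gis = gis,
    concordance = list(table = as.data.frame(concordance$table),
                       reclassified = concordance$reclassified),
    survival = surv,
    expression = expr
  )
  report
}
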