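test_that("GIS banding follows the threshold and closed HRDmid interval", {
  expect_equal(classify_gis(0.10), "HRP")
  expect_equal(classify_gis(0.48), "HRDmid")
  expect_equal(classify_gis(0.23), "HRDmid")
  expect_equal(classify_gis(0.73), "HRDmid")
  expect_equal(classify_gis(0.2299999), "HRP")
  expect_equal(classify_gis(0.7300001), "HRD")
  expect_error(classify_gis(1.2), "\\[0, 1\\]")

  # monotone: higher score never maps to a less-deficient band
  scores <- sort(runif(50))
  bands <- factor(classify_gis(scores), levels = c("HRP", "HRDmid", "HRD"),
                  ordered = TRUE)
  expect_true(all(diff(as.integer(bands)) >= 0))

  expect_equal(gis_binary_status(c(0.47, 0.48)), c("HRP", "HRD"))
})

test_that("variant filtering applies the reporting rule exactly", {
  toy <- data.frame(
    gene = c("BRCA1", "BRCA2", "TP53", "ATM", "CHEK2", "PALB2"),
    vaf = c(0.05, 0.049, 0.30, 0.40, 0.04, 0.80),
    oncogenic = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    inactivating = c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  )
  out <- filter_variants(toy)
  expect_identical(out$kept, c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(sum(out$kept), 3)
  expect_equal(out$drop_reason[2], "vaf_below_threshold")
  expect_equal(out$drop_reason[4], "not_oncogenic_or_inactivating")

  # idempotent and order-independent
  again <- filter_variants(out)
  expect_identical(again$kept, out$kept)
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_identical(filter_variants(toy[perm, ])$kept, out$kept[perm])
})

test_that("concordance table counts agreement and lists reclassified models", {
  recap <- setNames(rep(c("HRD", "HRP"), c(8, 13)), sprintf("M%02d", 1:21))
  gis <- setNames(rep(c("HRD", "HRP"), c(5, 16)), sprintf("M%02d", 1:21))
  # models 6-8: RECAP HRD but GIS HRP -> reclassified
  cc <- concordance_table(recap, gis)
  expect_equal(sort(cc$reclassified), c("M06", "M07", "M08"))
  expect_equal(unname(cc$table["HRD", "HRD"]), 5)
  expect_equal(unname(cc$table["HRP", "HRP"]), 13)

  same <- setNames(c("HRD", "HRP"), c("a", "b"))
  cc2 <- concordance_table(same, same)
  expect_equal(unname(cc2$table["HRD", "HRD"]), 1)
  expect_equal(unname(cc2$table["HRP", "HRP"]), 1)
  expect_equal(unname(cc2$table["HRD", "HRP"]), 0)
  expect_equal(unname(cc2$table["HRP", "HRD"]), 0)

  expect_error(concordance_table(setNames("HRD", "x"), setNames("HRP", "y")),
               "no shared")
})

test_that("Kaplan-Meier estimates match the empirical survivor function", {
  # single subject
  km1 <- km_estimate(5, TRUE)
  expect_equal(km1$median, 5)

  # no censoring, times 1..9: S(t_i) = (9 - i)/9, median 5
  km9 <- km_estimate(1:9, rep(TRUE, 9))
  expect_equal(km9$surv, (9 - (1:9)) / 9)
  expect_equal(km9$median, 5)

  # all censored -> undefined median
  kmc <- km_estimate(c(3, 6, 9), c(FALSE, FALSE, FALSE))
  expect_true(is.na(kmc$median))
})

test_that("log-rank behaves on identical groups and matches a hand oracle", {
  lr0 <- logrank_test(rep(c(1, 2, 3), 2), rep(TRUE, 6),
                      rep(c("A", "B"), each = 3))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # toy: A events at 1,2; B events at 3,4 — hand O-E computation:
  # t=1: n=4, nA=2, E=0.5, V=0.25; t=2: n=3, nA=1, E=1/3, V=2/9
  # t=3: n=2, nA=0, E=0;  t=4: n=1, nA=0, E=0
  # U = (1-0.5)+(1-1/3) = 7/6; Var = 0.25+2/9 = 17/36; chisq = U^2/Var
  lr <- logrank_test(c(1, 2, 3, 4), rep(TRUE, 4), c("A", "A", "B", "B"))
  expect_equal(lr$chisq, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)

  # label swap leaves p unchanged
  lr_sw <- logrank_test(c(1, 2, 3, 4), rep(TRUE, 4), c("B", "B", "A", "A"))
  expect_equal(lr_sw$p, lr$p)
})

test_that("Gehan-Breslow-Wilcoxon matches pairwise scoring and early weights", {
  set.seed(12)
  x <- round(rexp(8, 0.2), 3); y <- round(rexp(7, 0.1), 3)
  tm <- c(x, y); ev <- rep(TRUE, 15); gr <- rep(c("A", "B"), c(8, 7))
  g <- gehan_breslow_wilcoxon(tm, ev, gr)
  # brute-force Gehan scoring over all pairs (no censoring): wins - losses
  W <- sum(outer(x, y, ">")) - sum(outer(x, y, "<"))
  expect_equal(g$score, -W)

  # identical groups -> p = 1
  g0 <- gehan_breslow_wilcoxon(rep(c(1, 2, 3), 2), rep(TRUE, 6),
                               rep(c("A", "B"), each = 3))
  expect_equal(g0$p, 1)

  # early separation: GBW statistic at least the log-rank statistic
  tm2 <- c(1, 1.5, 2, 8, 9, 10, 5, 6, 7, 7.5, 8.5, 9.5)
  gr2 <- rep(c("A", "B"), each = 6)
  ev2 <- rep(TRUE, 12)
  gbw2 <- gehan_breslow_wilcoxon(tm2, ev2, gr2)
  lr2 <- logrank_test(tm2, ev2, gr2)
  expect_gte(gbw2$chisq, lr2$chisq)
})

test_that("Mann-Whitney exact p equals complete enumeration", {
  # identical multisets: U = n^2/2
  mw0 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw0$U, 4.5)

  # full separation: exact p = 2 / choose(n, k)
  mw1 <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_equal(mw1$U, 9)
  expect_equal(mw1$p, 2 / choose(6, 3))

  # 3 vs 3: p equals brute force over all 20 label arrangements
  x <- c(1.3, 4.1, 6.2); y <- c(2.5, 3.7, 9.9)
  mw <- mann_whitney(x, y)
  pool <- c(x, y)
  combs <- utils::combn(6, 3)
  u_obs <- sum(outer(x, y, ">"))
  u_all <- apply(combs, 2, function(ix) {
    xx <- pool[ix]; yy <- pool[-ix]
    sum(outer(xx, yy, ">"))
  })
  # two-sided exact p: distance from the null center
  p_exact <- mean(abs(u_all - 4.5) >= abs(u_obs - 4.5) - 1e-12)
  expect_equal(mw$p, p_exact)
})

test_that("platinum sensitivity uses the inclusive 6-month rule", {
  expect_identical(platinum_sensitive(c(5.9, 6, 6.1)),
                   c("resistant", "sensitive", "sensitive"))
})

test_that("copy-number similarity behaves as a bounded correlation", {
  p1 <- c(1, 2, 3, 2, 1, 0, -1)
  expect_equal(cnv_similarity(p1, p1), 1)
  expect_equal(cnv_similarity(p1 - mean(p1), -(p1 - mean(p1))), -1)

  # profiles sharing 80% of segments are more similar than sharing 20%
  set.seed(30)
  base <- rep(sample(c(-1, 0, 1, 2), 25, replace = TRUE), each = 8)
  mutate_frac <- function(p, frac) {
    segs <- matrix(seq_along(p), nrow = 8)
    idx <- sample(ncol(segs), round(frac * ncol(segs)))
    p[as.vector(segs[, idx])] <- sample(c(-1, 0, 1, 2), length(idx) * 8,
                                        replace = TRUE)
    p
  }
  s80 <- cnv_similarity(base, mutate_frac(base, 0.2))
  s20 <- cnv_similarity(base, mutate_frac(base, 0.8))
  expect_gt(s80, s20)
  expect_error(cnv_similarity(1:4, 1:5), "equal length")
})
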