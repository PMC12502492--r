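test_that("the stabilizing transform normalizes depth and flattens variance", {
  set.seed(5)
  mu <- rgamma(400, 2, 0.05)
  counts <- sapply(1:8, function(j) rpois(400, mu * sample(c(0.5, 1, 2), 1)))
  rownames(counts) <- paste0("g", 1:400)
  colnames(counts) <- paste0("s", 1:8)

  v <- vst_transform(counts)
  # a zero count transforms to exactly zero
  eq <- matrix(5L, 50, 4, dimnames = list(paste0("g", 1:50), paste0("s", 1:4)))
  eq[1, 1] <- 0L
  veq <- vst_transform(eq)
  expect_equal(unname(veq[1, 1]), 0)

  # a sample with doubled library (proportional counts) normalizes onto
  # its template: transformed columns coincide
  prop <- matrix(rpois(200 * 4, rgamma(200, 2, 0.1)), 200, 4,
                 dimnames = list(paste0("g", 1:200), paste0("s", 1:4)))
  prop[, 2] <- prop[, 1] * 2L
  prop <- prop[rowSums(prop) > 0, ]
  vp <- vst_transform(prop)
  expect_equal(unname(vp[, 2]), unname(vp[, 1]), tolerance = 1e-8)
  expect_equal(unname(attr(vp, "size_factors")[2] /
                        attr(vp, "size_factors")[1]), 2, tolerance = 1e-8)

  # mean-variance slope shrinks after the transform (NB data)
  spec <- paired_expression_spec(n_genes = 800, n_pairs = 6, seed = 2)
  sim <- gen_paired_expression(spec)
  raw <- sim$counts[rowSums(sim$counts) > 0, ]
  slope <- function(m) {
    mu <- rowMeans(m); va <- apply(m, 1, var)
    ok <- mu > 0 & va > 0
    unname(coef(lm(log(va[ok]) ~ log(mu[ok])))[2])
  }
  expect_lt(abs(slope(vst_transform(sim$counts)) - 0),
            abs(slope(raw) - 0) - 0.3)

  zero_sample <- matrix(c(1, 2, 0, 0), 2,
                        dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(vst_transform(zero_sample), "zero total")
})

test_that("NMF factorizes exactly factorizable matrices and is deterministic", {
  set.seed(4)
  w <- matrix(rgamma(60, 2, 1), 60, 1)
  h <- matrix(rgamma(8, 2, 1), 1, 8)
  m <- w %*% h
  fit <- fit_nmf(m, 1, seed = 1)
  expect_lt(fit$error, 1e-6)

  f1 <- fit_nmf(m, 2, seed = 9)
  f2 <- fit_nmf(m, 2, seed = 9)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)

  expect_error(fit_nmf(m, 9, seed = 1), "not exceed")
})

test_that("the NMF objective never increases across iterations", {
  set.seed(6)
  m <- matrix(rgamma(300, 1, 1), 30, 10)
  for (k in c(2, 4)) {
    fit <- fit_nmf(m, k, seed = 3)
    expect_true(all(diff(fit$error_trace) <= 1e-12))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  }
})

test_that("reconstruction error improves at the planted rank", {
  spec <- paired_expression_spec(n_genes = 600, n_pairs = 6, k_true = 3,
                                 stroma_weight = 0, seed = 7)
  sim <- gen_paired_expression(spec)
  v <- vst_transform(sim$counts)[, sim$pairing$pdto]
  e1 <- fit_nmf(v, 1, seed = 1)$error
  e3 <- fit_nmf(v, 3, seed = 1)$error
  e5 <- fit_nmf(v, 5, seed = 1)$error
  expect_lt(e3, e1 * 0.9)
  expect_lte(e5, e3 + 1e-6)
})

test_that("LCD projection reproduces training exposures on exact-rank data", {
  set.seed(11)
  W <- matrix(rgamma(200 * 3, 2, 1), 200, 3,
              dimnames = list(paste0("g", 1:200), paste0("f", 1:3)))
  H <- matrix(rgamma(3 * 10, 2, 1), 3, 10,
              dimnames = list(colnames(W), paste0("s", 1:10)))
  M <- W %*% H
  H_hat <- project_lcd(W, M)
  expect_equal(unname(H_hat), unname(H), tolerance = 1e-6)
  expect_true(all(H_hat >= 0))

  # all-zero sample projects to zero exposures
  M0 <- cbind(M, zero = 0)
  expect_equal(unname(project_lcd(W, M0)[, "zero"]), rep(0, 3))

  # gene mismatch is reported
  expect_error(project_lcd(W, M[1:100, ]), "absent")
})

test_that("training-matrix projection error is no worse than the fitted H", {
  spec <- paired_expression_spec(n_genes = 500, n_pairs = 5, k_true = 3,
                                 stroma_weight = 0, seed = 13)
  sim <- gen_paired_expression(spec)
  v <- vst_transform(sim$counts)[, sim$pairing$pdto]
  fit <- fit_nmf(v, 3, seed = 1)
  H_proj <- project_lcd(fit$W, v)
  err_fit <- norm(v - fit$W %*% fit$H, "F")
  err_proj <- norm(v - fit$W %*% H_proj, "F")
  expect_lte(err_proj, err_fit + 1e-8)
})

test_that("the PCA embedding is deterministic and resolves planted clusters", {
  set.seed(15)
  expo <- cbind(matrix(rep(c(5, 1), 8) + rnorm(16, 0, 0.1), 2),
                matrix(rep(c(1, 5), 8) + rnorm(16, 0, 0.1), 2))
  colnames(expo) <- paste0("s", 1:16)
  co <- embed_exposures(expo)
  expect_equal(dim(co), c(16L, 2L))

  # duplicated samples land on identical coordinates
  dup <- expo[, c(1, 1, 2, 3)]
  colnames(dup) <- paste0("d", 1:4)
  cd <- embed_exposures(dup)
  expect_equal(cd[1, ], cd[2, ])

  # silhouette of the two planted clusters
  lab <- rep(1:2, each = 8)
  d <- as.matrix(dist(co))
  sil <- sapply(1:16, function(i) {
    a <- mean(d[i, lab == lab[i]][-which(which(lab == lab[i]) == i)])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  })
  expect_gt(mean(sil), 0.5)
})

test_that("rank selection recovers structure and beats random re-pairings", {
  spec <- paired_expression_spec(n_genes = 1000, n_pairs = 8, k_true = 3,
                                 stroma_weight = 0, seed = 3)
  sim <- gen_paired_expression(spec)
  sel <- select_rank(sim$counts, sim$pairing, ks = 2:6, seed = 1)
  expect_true(sel$chosen_k %in% 2:6)
  expect_equal(unname(sel$distance_by_k[as.character(sel$chosen_k)]),
               min(sel$distance_by_k))

  # column-order invariance of the selection curve
  perm <- sample(colnames(sim$counts))
  sel2 <- select_rank(sim$counts[, perm], sim$pairing, ks = 2:6, seed = 1)
  expect_equal(sel2$distance_by_k, sel$distance_by_k, tolerance = 1e-8)

  # single pair degenerates gracefully: the criterion is that pair's
  # embedding distance
  p1 <- sim$pairing[1, ]
  sel1 <- select_rank(sim$counts, p1, ks = 1, seed = 1)
  expect_length(sel1$distance_by_k, 1)
  d1 <- sqrt(sum((sel1$embedding[p1$tumor, ] - sel1$embedding[p1$pdto, ])^2))
  expect_equal(unname(sel1$distance_by_k), d1)

  # unpaired sample errors
  bad <- sim$pairing
  bad$tumor[1] <- "missing_sample"
  expect_error(select_rank(sim$counts, bad, ks = 3), "missing")
})

test_that("signature gene lists have the right size and find planted markers", {
  set.seed(17)
  W <- matrix(rgamma(100 * 2, 1, 1), 100, 2,
              dimnames = list(paste0("g", 1:100), c("f1", "f2")))
  W[1:3, 1] <- W[1:3, 1] + 10 * max(W)
  top <- signature_top_genes(W, pct = 5)
  expect_length(top$f1, 5)
  expect_true(all(c("g1", "g2", "g3") %in% top$f1))

  all_genes <- signature_top_genes(W, pct = 100)
  expect_length(all_genes$f2, 100)
  expect_identical(all_genes$f2, rownames(W)[order(W[, 2], decreasing = TRUE)])
})

test_that("paired correlations behave at the identity and independence limits", {
  x <- rnorm(200)
  expect_equal(paired_gene_correlation(x, x)$r_squared, 1)

  withr::with_seed(19, {
    a <- rnorm(10000); b <- rnorm(10000)
  })
  expect_lt(abs(paired_gene_correlation(a, b)$r), 0.05)
})

test_that("generated pairs match by embedding proximity", {
  spec <- paired_expression_spec(n_genes = 1200, n_pairs = 10, k_true = 4,
                                 stroma_weight = 0, pair_jitter_sd = 0.15,
                                 seed = 23)
  sim <- gen_paired_expression(spec)
  sel <- select_rank(sim$counts, sim$pairing, ks = 4, seed = 1)
  # match in the full relative-exposure space the criterion uses
  rel <- sweep(sel$exposures, 2, pmax(colSums(sel$exposures), 1e-12), "/")
  matched <- match_pairs_by_distance(t(rel), sim$pairing$tumor,
                                     sim$pairing$pdto)
  acc <- mean(matched$matched_pdto == sim$pairing$pdto)
  expect_gte(acc, 0.9)
})
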