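#' Variance-stabilizing log transform of a count matrix
#'
#' Divides each sample by its median-of-ratios size factor (the DESeq
#' estimator) and takes log2(x + 1). Genes with all-zero counts are
#' dropped (recorded in the \code{dropped_genes} attribute). This is a
#' size-factor log transform standing in for an exact variance-stabilizing
#' transformation; it removes depth differences and flattens the
#' mean-variance trend enough for non-negative factorization.
#'
#' @param counts non-negative integer matrix, genes x samples.
#' @return transformed matrix with attributes \code{size_factors} and
#'   \code{dropped_genes}.
#' @export
vst_transform <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (any(colSums(counts) == 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  }
  zero <- rowSums(counts) == 0
  dropped <- rownames(counts)[zero]
  counts <- counts[!zero, , drop = FALSE]
  sf <- DESeq2::estimateSizeFactorsForMatrix(counts)
  out <- log2(sweep(counts, 2, sf, "/") + 1)
  attr(out, "size_factors") <- sf
  attr(out, "dropped_genes") <- dropped
  out
}

#' Non-negative matrix factorization by multiplicative updates
#'
#' Lee-Seung multiplicative updates minimizing the Frobenius
#' reconstruction error, with seeded uniform non-negative initialization.
#' The objective is non-increasing at every iteration; iteration stops
#' when the relative error change falls below \code{tol} or after
#' \code{max_iter} updates. Negative input entries (possible after a
#' stabilizing transform) are clipped to zero with a message.
#'
#' @param mat genes x samples matrix (non-negative after clipping).
#' @param k factorization rank, < min(dim(mat)).
#' @param seed integer seed for the random initialization.
#' @param max_iter,tol stopping rule.
#' @return list of class \code{factor_model}: \code{W} (genes x k),
#'   \code{H} (k x samples), \code{error} (final relative Frobenius
#'   error), \code{error_trace}, \code{k}, \code{iterations}.
#' @export
fit_nmf <- function(mat, k, seed = 1L, max_iter = 2000, tol = 1e-5) {
  stopifnot(is.matrix(mat), k >= 1)
  if (k > min(dim(mat))) {
    stop("rank k = ", k, " must not exceed min(dim) = ", min(dim(mat)))
  }
  if (any(mat < 0)) {
    message("clipping ", sum(mat < 0), " negative entries to 0 before NMF")
    mat[mat < 0] <- 0
  }
  set.seed(seed)
  g <- nrow(mat); s <- ncol(mat)
  scale0 <- sqrt(mean(mat) / k)
  W <- matrix(runif(g * k, 0, 1), g, k) * scale0 + 1e-9
  H <- matrix(runif(k * s, 0, 1), k, s) * scale0 + 1e-9
  normM <- norm(mat, "F")
  eps <- .Machine$double.eps
  err_trace <- numeric(0)
  err_old <- Inf
  it <- 0L
  for (it in seq_len(max_iter)) {
    H <- H * (crossprod(W, mat) / (crossprod(W, W %*% H) + eps))
    W <- W * (mat %*% t(H)) / (W %*% tcrossprod(H, H) + eps)
    err <- norm(mat - W %*% H, "F") / normM
    err_trace <- c(err_trace, err)
    if (is.finite(err_old) && abs(err_old - err) < tol * max(err_old, eps)) break
    err_old <- err
  }
  dimnames(W) <- list(rownames(mat), paste0("factor", seq_len(k)))
  dimnames(H) <- list(colnames(W), colnames(mat))
  structure(list(W = W, H = H, error = err_trace[length(err_trace)],
                 error_trace = err_trace, k = k, iterations = it),
            class = "factor_model")
}

#' Project samples onto learned NMF programs (linear combination
#' decomposition)
#'
#' Non-negative least squares of each sample's expression profile onto the
#' columns of \code{W}: the organoid-trained programs are held fixed and
#' every sample (tumor and organoid) receives non-negative exposures.
#'
#' @param W genes x k non-negative program matrix (rownames = genes).
#' @param mat genes x samples matrix to project (rownames = genes).
#' @return k x samples exposure matrix, all entries >= 0.
#' @export
project_lcd <- function(W, mat) {
  stopifnot(is.matrix(W), is.matrix(mat))
  if (!is.null(rownames(W)) && !is.null(rownames(mat))) {
    missing <- setdiff(rownames(W), rownames(mat))
    if (length(missing)) {
      stop("genes in W absent from matrix: ",
           paste(head(missing, 5), collapse = ", "),
           if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
    }
    mat <- mat[rownames(W), , drop = FALSE]
  } else if (nrow(W) != nrow(mat)) {
    stop("gene dimension mismatch: ", nrow(W), " vs ", nrow(mat))
  }
  mat[mat < 0] <- 0
  H <- vapply(seq_len(ncol(mat)), function(j) {
    if (all(mat[, j] == 0)) return(rep(0, ncol(W)))
    pracma::lsqnonneg(W, mat[, j])$x
  }, numeric(ncol(W)))
  H <- matrix(H, ncol(W), ncol(mat),
              dimnames = list(colnames(W), colnames(mat)))
  H
}

#' Embed sample exposures in two dimensions
#'
#' Deterministic PCA of the samples x programs exposure matrix (centered,
#' unscaled), returning the first two component scores. PCA is the default
#' because it is reproducible bit-for-bit; a stochastic neighborhood
#' embedding can be slotted in where exploratory figures need it.
#'
#' @param exposures k x samples matrix from \code{\link{project_lcd}}.
#' @param method only "pca" is shipped.
#' @return samples x 2 coordinate matrix.
#' @export
embed_exposures <- function(exposures, method = "pca") {
  method <- match.arg(method, "pca")
  X <- t(exposures)
  if (nrow(X) < 3) stop("embedding needs >= 3 samples")
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  coords <- pc$x[, seq_len(min(2, ncol(pc$x))), drop = FALSE]
  if (ncol(coords) == 1) coords <- cbind(coords, 0)
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Choose the NMF rank that minimizes paired-sample distance
#'
#' For each candidate rank: fit NMF on the organoid (PDTO) columns only,
#' project the programs onto all samples, convert exposures to relative
#' contributions (each sample's exposures sum to 1) and score how close
#' each tumor sits to its own organoid. The score per pair is the
#' symmetric neighbor rank: the number of other organoids closer to the
#' tumor than its partner, plus the number of other tumors closer to the
#' organoid than its partner, with Euclidean distances taken in the full
#' relative-exposure space. Summed over pairs this is a scale-free paired
#' distance: it plays the role neighborhood preservation plays when the
#' same criterion is run on a stochastic neighborhood embedding, and it
#' does not contract as the rank shrinks the way raw embedding distances
#' do (those always favor the smallest tested rank regardless of the
#' data). The chosen rank minimizes the sum (smallest rank on ties); the
#' full per-rank table is returned so the curve can be inspected. With a
#' single pair no other samples exist to rank against, and the criterion
#' falls back to the pair's raw embedding distance.
#'
#' @param counts genes x samples count matrix (columns must include every
#'   tumor and organoid named in \code{pairing}).
#' @param pairing data.frame with columns \code{tumor} and \code{pdto}.
#' @param ks candidate ranks.
#' @param seed seed forwarded to every NMF fit.
#' @param max_iter,tol NMF stopping rule.
#' @return list of class \code{rank_selection}: \code{chosen_k},
#'   \code{distance_by_k} (named numeric), \code{fits} is omitted to keep
#'   the object light, \code{embedding} (coordinates at the chosen rank),
#'   \code{exposures} (at the chosen rank).
#' @export
select_rank <- function(counts, pairing, ks = 2:18, seed = 1L,
                        max_iter = 2000, tol = 1e-6) {
  stopifnot(all(c("tumor", "pdto") %in% names(pairing)))
  missing <- setdiff(c(pairing$tumor, pairing$pdto), colnames(counts))
  if (length(missing)) {
    stop("unpaired/missing samples in count matrix: ",
         paste(missing, collapse = ", "))
  }
  vst <- vst_transform(counts)
  pdto_mat <- vst[, pairing$pdto, drop = FALSE]
  ks <- ks[ks <= min(dim(pdto_mat))]
  if (length(ks) == 0) stop("no feasible rank within min(dim) of PDTO matrix")
  dist_by_k <- setNames(numeric(length(ks)), ks)
  best <- NULL
  n_pairs <- nrow(pairing)
  for (i in seq_along(ks)) {
    k <- ks[i]
    fit <- fit_nmf(pdto_mat, k, seed = seed, max_iter = max_iter, tol = tol)
    expo <- project_lcd(fit$W, vst)
    rel <- sweep(expo, 2, pmax(colSums(expo), 1e-12), "/")
    coords <- embed_exposures(rel)
    if (n_pairs == 1) {
      dist_by_k[i] <- sqrt(sum((coords[pairing$tumor, ] -
                                  coords[pairing$pdto, ])^2))
    } else {
      D <- as.matrix(dist(t(rel)))
      dist_by_k[i] <- sum(vapply(seq_len(n_pairs), function(p) {
        tu <- pairing$tumor[p]; od <- pairing$pdto[p]
        sum(D[tu, pairing$pdto] < D[tu, od]) +
          sum(D[od, pairing$tumor] < D[od, tu])
      }, numeric(1)))
    }
    if (is.null(best) || dist_by_k[i] < best$distance) {
      best <- list(k = k, distance = dist_by_k[i], coords = coords,
                   exposures = expo, W = fit$W)
    }
  }
  structure(list(chosen_k = best$k, distance_by_k = dist_by_k,
                 embedding = best$coords, exposures = best$exposures,
                 W = best$W),
            class = "rank_selection")
}

#' Top contributing genes per NMF signature
#'
#' For each program (column of W), the genes in the top \code{pct} percent
#' of that program's weight distribution, in descending weight order.
#'
#' @param W genes x k weight matrix with rownames.
#' @param pct percentage of genes to keep per factor, in (0, 100].
#' @return named list of character vectors, one per factor.
#' @export
signature_top_genes <- function(W, pct = 5) {
  stopifnot(is.matrix(W), pct > 0, pct <= 100)
  if (is.null(rownames(W))) rownames(W) <- paste0("g", seq_len(nrow(W)))
  n_top <- max(1L, floor(nrow(W) * pct / 100))
  out <- lapply(seq_len(ncol(W)), function(j) {
    ord <- order(W[, j], decreasing = TRUE)
    rownames(W)[ord[seq_len(n_top)]]
  })
  names(out) <- colnames(W)
  out
}

#' Tumor/organoid expression correlation of one pair
#'
#' Pearson correlation (and its square) between the transformed expression
#' profiles of a tumor sample and its paired organoid.
#'
#' @param tumor_col,pdto_col aligned numeric expression vectors.
#' @return list: \code{r}, \code{r_squared}.
#' @export
paired_gene_correlation <- function(tumor_col, pdto_col) {
  stopifnot(length(tumor_col) == length(pdto_col))
  r <- cor(tumor_col, pdto_col)
  list(r = r, r_squared = r^2)
}

#' Match samples by embedding proximity
#'
#' Greedy minimum-distance matching of tumors to organoids in an
#' embedding; used to score how often the concordance pipeline pairs each
#' tumor with its own organoid.
#'
#' @param coords samples x 2 coordinate matrix (rownames = sample ids).
#' @param tumors,pdtos id vectors.
#' @return data.frame (tumor, matched_pdto).
#' @export
match_pairs_by_distance <- function(coords, tumors, pdtos) {
  d <- as.matrix(dist(coords))[tumors, pdtos, drop = FALSE]
  matched <- character(length(tumors))
  names(matched) <- tumors
  avail <- pdtos
  ord <- tumors[order(apply(d, 1, min))]
  for (t in ord) {
    j <- avail[which.min(d[t, avail])]
    matched[t] <- j
    avail <- setdiff(avail, j)
  }
  data.frame(tumor = tumors, matched_pdto = matched[tumors])
}
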