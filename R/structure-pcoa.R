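#' Euclidean genotype distance matrix with pairwise-deletion scaling
#'
#' Genotypes are encoded as 0/1/2 copies of `allele_b`. For a sample pair
#' with `M` mutually non-missing sites out of `P` total, the distance is
#' \deqn{d = \sqrt{(P / M) \sum (g_1 - g_2)^2},}
#' the pairwise-deletion convention that keeps distances comparable across
#' pairs with different amounts of missing data (with no missing data,
#' `M = P` and the scaling vanishes).
#'
#' @param table a `snp_table` with at least 2 samples.
#' @return Symmetric numeric matrix with zero diagonal, samples as dimnames.
#' @export
euclidean_distance_matrix <- function(table) {
  G <- t(table$geno)  # samples x sites
  if (nrow(G) < 2L) stop("need >=2 samples for a distance matrix")
  P <- ncol(G)
  W <- !is.na(G)
  A <- G
  A[!W] <- 0L
  storage.mode(A) <- "double"
  storage.mode(W) <- "double"
  # sum over mutually non-missing sites of (a_i - a_j)^2
  S2 <- A^2
  cross <- tcrossprod(A)
  ss <- S2 %*% t(W) + W %*% t(S2) - 2 * cross
  M <- tcrossprod(W)
  if (any(M[upper.tri(M)] == 0)) {
    ij <- which(M == 0 & upper.tri(M), arr.ind = TRUE)[1L, ]
    stop("no mutually non-missing sites for pair ",
         rownames(G)[ij[1L]], " / ", rownames(G)[ij[2L]])
  }
  d <- (P / M) * ss
  d[d < 0] <- 0  # guard tiny negatives from floating-point cancellation
  d <- sqrt(d)
  diag(d) <- 0
  dimnames(d) <- list(rownames(G), rownames(G))
  (d + t(d)) / 2
}

#' Principal coordinates analysis (classical MDS)
#'
#' Double-centers -D^2/2, eigendecomposes, and scales eigenvectors by the
#' square roots of the positive eigenvalues. When all positive eigenvalues
#' are kept, inter-sample Euclidean distances among the coordinates
#' reproduce the input distances (for a Euclidean-embeddable D). Negative
#' eigenvalues are reported but never used for coordinates.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param axes number of axes requested (capped at the number of positive
#'   eigenvalues).
#' @return A `pcoa_result`: `points` (samples x axes), `eig` (all
#'   eigenvalues, non-increasing), `percent` (percent of positive-eigenvalue
#'   variance per returned axis), `n_positive`, `negative_eig`.
#' @export
pcoa_embed <- function(d, axes = 2L) {
  if (axes < 1L) stop("axes must be >= 1")
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d))) || any(diag(d) != 0)) {
    stop("d must be symmetric with zero diagonal")
  }
  n <- nrow(d)
  B <- -0.5 * d^2
  B <- sweep(B, 1L, rowMeans(B))
  B <- sweep(B, 2L, colMeans(B))
  e <- eigen(B, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  if (!length(pos)) stop("no positive eigenvalues: degenerate distance matrix")
  k <- min(axes, length(pos))
  pts <- e$vectors[, pos[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(k)]]), k)
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("Axis", seq_len(k))
  structure(list(points = pts,
                 eig = e$values,
                 percent = 100 * e$values[pos[seq_len(k)]] /
                   sum(e$values[pos]),
                 n_positive = length(pos),
                 negative_eig = e$values[e$values < -tol]),
            class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("pcoa_result: %d samples, %d axes (%s%% of variance)\n",
              nrow(x$points), ncol(x$points),
              paste(sprintf("%.1f", x$percent), collapse = " + ")))
  invisible(x)
}

#' Per-population mean observed heterozygosity
#'
#' For each sample, the fraction of its non-missing sites with a
#' heterozygous call; per population, the mean over its ingroup samples.
#' Samples with zero non-missing sites are excluded with a warning.
#'
#' @param table a `snp_table`.
#' @param info a `sample_info` data.frame.
#' @return Named numeric vector (population -> mean heterozygosity in
#'   [0, 1]).
#' @export
population_heterozygosity <- function(table, info) {
  ing <- info[info$role == "ingroup" & info$sample_id %in% sample_ids(table), ,
              drop = FALSE]
  g <- table$geno[, ing$sample_id, drop = FALSE]
  nonmiss <- colSums(!is.na(g))
  if (any(nonmiss == 0L)) {
    warning("excluding sample(s) with zero non-missing sites: ",
            paste(ing$sample_id[nonmiss == 0L], collapse = ", "))
  }
  het <- colSums(g == 1L, na.rm = TRUE) / nonmiss
  keep <- nonmiss > 0L
  tapply(het[keep], ing$population_id[keep], mean)[unique(ing$population_id)]
}

#' K-means grouping on PCoA axes
#'
#' Optional helper standing in for visual group assignment: runs k-means on
#' the requested PCoA axes. `k` is user-set; no clustering is baked into the
#' pipeline.
#'
#' @param embedding a `pcoa_result`.
#' @param k number of groups.
#' @param axes which axes to cluster on (default 1:2).
#' @param seed integer seed.
#' @return Named integer vector of group labels per sample.
#' @export
assign_groups_kmeans <- function(embedding, k, axes = 1:2, seed = 1L) {
  axes <- axes[axes <= ncol(embedding$points)]
  set.seed(as.integer(seed))
  km <- stats::kmeans(embedding$points[, axes, drop = FALSE], centers = k,
                      nstart = 20L)
  stats::setNames(km$cluster, rownames(embedding$points))
}
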