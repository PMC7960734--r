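#' Genotype principal components for ancestry inference
#'
#' Standard population-structure PCA: each SNP dosage column is centered by
#' twice its allele frequency and scaled by `sqrt(2 f (1 - f))` (the
#' binomial standard deviation under Hardy–Weinberg), missing values are set
#' to the column mean (0 after centering), and the subject-by-subject
#' covariance is eigendecomposed. Monomorphic SNPs are dropped with a
#' message. Each eigenvector's sign is fixed by making its
#' largest-magnitude entry positive, so results are deterministic.
#'
#' @param genotypes A [genotype_matrix()].
#' @param n_components Number of leading components to return (default 10).
#' @return List of class `ancestry_pca`: `scores` (tibble `subject_id`,
#'   `PC1`, ...), `explained` (proportion of variance per component),
#'   `n_snps_used`.
#' @export
ancestry_pca <- function(genotypes, n_components = 10) {
  assert_that(inherits(genotypes, "genotype_matrix"), "genotypes must be a genotype_matrix")
  dos <- genotypes$dosage
  assert_that(nrow(dos) >= 2, "need >= 2 subjects")
  f <- colMeans(dos, na.rm = TRUE) / 2
  poly <- f > 0 & f < 1 & apply(dos, 2, function(v) var(v, na.rm = TRUE) > 0)
  n_dropped <- sum(!poly)
  if (n_dropped > 0) message(sprintf("dropped %d monomorphic SNP(s)", n_dropped))
  assert_that(sum(poly) >= 2, "need >= 2 polymorphic SNPs")
  dos <- dos[, poly, drop = FALSE]
  f <- f[poly]
  X <- sweep(dos, 2, 2 * f)
  X <- sweep(X, 2, sqrt(2 * f * (1 - f)), "/")
  X[is.na(X)] <- 0
  K <- tcrossprod(X) / ncol(X)
  eg <- eigen(K, symmetric = TRUE)
  n_components <- min(n_components, nrow(dos) - 1L)
  vec <- eg$vectors[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(ncol(vec))) {
    if (vec[which.max(abs(vec[, j])), j] < 0) vec[, j] <- -vec[, j]
  }
  pos <- pmax(eg$values, 0)
  # scale eigenvectors by sqrt(eigenvalue): proper PC scores, so axes carry
  # their share of variance (matters for distance-based clustering)
  vec <- sweep(vec, 2, sqrt(pos[seq_len(n_components)]), "*")
  scores <- tibble::as_tibble(vec, .name_repair = ~ paste0("PC", seq_len(n_components)))
  scores <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(dos)), scores)
  structure(list(scores = scores,
                 explained = pos[seq_len(n_components)] / sum(pos),
                 n_snps_used = sum(poly)),
            class = "ancestry_pca")
}

#' Assign genetic ancestry groups from principal components
#'
#' Clusters subjects into two groups by k-means on the first two genotype
#' PCs, with a deterministic k-means++ initialization driven by `seed`.
#' Cluster labels are mapped to ancestry names by the majority of
#' self-reported ancestry within each cluster (ties broken toward the larger
#' cluster). If the two clusters are poorly separated (between-cluster sum
#' of squares below half the total), the assignment is flagged with a
#' warning — the cohort may hold a single population.
#'
#' @param pcs An [ancestry_pca()] result.
#' @param self_report Tibble with `subject_id` and `ancestry` (self-reported
#'   labels, e.g. `"EA"` / `"AA"`).
#' @param k Number of clusters; only `k = 2` is supported.
#' @param seed Seed for the k-means++ initialization.
#' @return Tibble: `subject_id`, `ancestry_genetic`, `cluster`.
#' @export
assign_ancestry <- function(pcs, self_report, k = 2, seed = 1) {
  assert_that(inherits(pcs, "ancestry_pca"), "pcs must come from ancestry_pca()")
  assert_that(k == 2, "only k = 2 is supported")
  X <- as.matrix(pcs$scores[, c("PC1", "PC2")])
  centers <- with_seed(substream_seed(seed, "kmeanspp"), kmeanspp_init(X, k))
  km <- kmeans(X, centers = centers, iter.max = 100)
  if (km$betweenss / km$totss < 0.5) {
    warning("clusters poorly separated; cohort may contain a single population")
  }
  sr <- tibble::as_tibble(self_report)
  assert_that(all(c("subject_id", "ancestry") %in% names(sr)),
              "self_report needs subject_id and ancestry columns")
  sr <- sr[match(pcs$scores$subject_id, sr$subject_id), ]
  labs <- sort(unique(sr$ancestry))
  # majority vote per cluster; ties toward the larger cluster's majority
  map <- character(k)
  if (length(labs) == 1) {
    map[] <- labs
  } else {
    ord <- order(-tabulate(km$cluster, k)) # larger cluster decided first
    for (cl in ord) {
      tab <- sort(table(sr$ancestry[km$cluster == cl]), decreasing = TRUE)
      pick <- names(tab)[1]
      if (any(map != "") && pick %in% map) {
        pick <- setdiff(labs, map)[1] # remaining label
      }
      map[cl] <- pick
    }
  }
  tibble::tibble(subject_id = pcs$scores$subject_id,
                 ancestry_genetic = map[km$cluster],
                 cluster = km$cluster)
}

# k-means++ seeding: first center uniform, subsequent centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1, ] <- X[sample.int(n, 1), ]
  d2 <- rowSums((X - matrix(centers[1, ], n, ncol(X), byrow = TRUE))^2)
  for (j in 2:k) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- X[sample.int(n, 1, prob = probs), ]
    dj <- rowSums((X - matrix(centers[j, ], n, ncol(X), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  centers
}
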