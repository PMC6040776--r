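#' Z-score standardization of expression rows
#'
#' Each miRNA row is centered and scaled to sample standard deviation 1.
#' Constant rows are dropped with a warning (they carry no pattern).
#'
#' @param mat numeric matrix (miRNA x library), e.g. the TPM layer.
#' @return standardized matrix with `center` and `scale` attributes holding
#'   the per-row mean and sd of the retained rows.
#' @export
zscore <- function(mat) {
  stopifnot(is.matrix(mat), ncol(mat) >= 2)
  sds <- apply(mat, 1, stats::sd)
  drop <- sds == 0 | is.na(sds)
  if (all(drop)) stop("all rows are constant; nothing to standardize")
  if (any(drop)) {
    warning(sum(drop), " constant row(s) dropped before standardization")
  }
  m <- mat[!drop, , drop = FALSE]
  ctr <- rowMeans(m)
  scl <- sds[!drop]
  z <- sweep(sweep(m, 1, ctr), 1, scl, "/")
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Principal component analysis of libraries
#'
#' Libraries are the observations and miRNAs the variables; scores come from
#' the eigendecomposition of the covariance of the (z-scored) data, components
#' ordered by decreasing variance. Signs are fixed so each component's
#' largest-magnitude loading is positive, making results reproducible.
#'
#' @param z standardized matrix from [zscore()] (miRNA x library).
#' @return list with `scores` (library x component), `var_fraction`,
#'   `rotation` (loadings).
#' @export
pca_libraries <- function(z) {
  if (ncol(z) < 2) stop("need at least 2 libraries")
  pr <- stats::prcomp(t(z), center = TRUE, scale. = FALSE)
  for (j in seq_len(ncol(pr$rotation))) {
    i <- which.max(abs(pr$rotation[, j]))
    if (pr$rotation[i, j] < 0) {
      pr$rotation[, j] <- -pr$rotation[, j]
      pr$x[, j] <- -pr$x[, j]
    }
  }
  list(scores = pr$x,
       var_fraction = pr$sdev^2 / sum(pr$sdev^2),
       rotation = pr$rotation)
}

#' Hierarchical clustering of libraries
#'
#' Agglomerative clustering of the library columns under the distance
#' 1 - Pearson correlation with average linkage. Merges are deterministic:
#' distance ties are broken by the lexicographically smallest pair of cluster
#' labels (a cluster is labelled by its smallest member library id).
#'
#' @param z standardized matrix from [zscore()] (miRNA x library).
#' @return an object of class `hclust` (merge, height, order, labels).
#' @export
hcluster_libraries <- function(z) {
  D <- 1 - stats::cor(z)
  labels <- colnames(z)
  n <- length(labels)
  # active cluster bookkeeping
  size <- rep(1L, n)
  id <- -(1:n)                      # hclust merge encoding
  lab <- labels                     # tie-break label = smallest member id
  active <- rep(TRUE, n)
  d <- D
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  members <- as.list(seq_len(n))
  for (step in seq_len(n - 1L)) {
    best <- NULL; best_d <- Inf; best_key <- NULL
    act <- which(active)
    for (ii in seq_along(act)) for (jj in seq_len(ii - 1L)) {
      i <- act[ii]; j <- act[jj]
      dij <- d[i, j]
      key <- sort(c(lab[i], lab[j]))
      better <- dij < best_d - 1e-12 ||
        (abs(dij - best_d) <= 1e-12 &&
           (is.null(best_key) || key[1] < best_key[1] ||
              (key[1] == best_key[1] && key[2] < best_key[2])))
      if (better) {
        best <- c(i, j); best_d <- dij; best_key <- key
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # average-linkage update into slot i
    for (k in act) {
      if (k == i || k == j) next
      dnew <- (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
      d[i, k] <- dnew; d[k, i] <- dnew
    }
    size[i] <- size[i] + size[j]
    id[i] <- step
    lab[i] <- min(lab[i], lab[j])
    members[[i]] <- c(members[[i]], members[[j]])
    active[j] <- FALSE
  }
  # leaf order by recursive tree walk
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  structure(list(merge = merge, height = height,
                 order = walk(n - 1L), labels = labels,
                 method = "average", dist.method = "1-pearson",
                 call = match.call()),
            class = "hclust")
}
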