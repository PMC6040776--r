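#' Audic-Claverie point probability for a tag count pair
#'
#' Probability of observing `y` counts for a tag in a library of `N2` total
#' clean reads given `x` counts in a library of `N1` reads:
#' \deqn{p(y|x) = (N2/N1)^y \frac{(x+y)!}{x!\,y!} (1 + N2/N1)^{-(x+y+1)}}
#' computed in log space via log-gamma. Summed over y = 0, 1, 2, ... the
#' distribution is exactly normalized.
#'
#' @param x,y non-negative integer counts (vectorized).
#' @param n1,n2 positive library totals.
#' @param log return the log probability.
#' @return numeric vector of (log) probabilities.
#' @export
ac_point_probability <- function(x, y, n1, n2, log = FALSE) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library totals must be positive")
  r <- n2 / n1
  lp <- y * base::log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
  if (log) lp else exp(lp)
}

#' Audic-Claverie tail p-values
#'
#' Lower tail C(y <= y_obs | x) by direct summation, upper tail
#' D(y >= y_obs | x) in complement form (1 minus the sum up to y_obs - 1,
#' avoiding the infinite sum), and the two-sided value as the doubled minimum
#' tail capped at 1. Both tails include the observed point, so
#' `p_lower + p_upper - p(y_obs|x) = 1`.
#'
#' @param x count in the reference library.
#' @param y_obs observed count in the compared library.
#' @param n1,n2 total clean reads of the two libraries.
#' @return list with `p_lower`, `p_upper`, `p_two_sided`.
#' @export
ac_tail_pvalues <- function(x, y_obs, n1, n2) {
  if (length(x) != 1L || length(y_obs) != 1L) {
    stop("ac_tail_pvalues is scalar; use screen_de() for tables")
  }
  if (x < 0 || y_obs < 0) stop("counts must be non-negative")
  p <- ac_point_probability(x, 0:y_obs, n1, n2)
  csum <- cumsum(p)
  p_lower <- min(1, csum[y_obs + 1])
  p_upper <- if (y_obs == 0) 1 else 1 - csum[y_obs]
  if (y_obs > 0 && p_upper < 1e-9) {
    # complement form loses precision once the upper tail is tiny; sum the
    # tail directly (terms decay geometrically above the mode)
    span <- 0:(20L * as.integer(ceiling(sqrt(y_obs + 10))) + 200L)
    p_upper <- sum(ac_point_probability(x, y_obs + span, n1, n2))
  }
  p_upper <- min(1, max(p_upper, 0))
  list(p_lower = p_lower, p_upper = p_upper,
       p_two_sided = min(1, 2 * min(p_lower, p_upper)))
}

# comparison frame builder: breed mode pairs the two breeds at each stage,
# stage mode pairs neighboring stages within each breed.
build_comparisons <- function(meta, mode) {
  stages <- sort(unique(meta$stage))
  breeds <- sort(unique(meta$breed))
  lib_of <- function(b, s) {
    id <- meta$library_id[meta$breed == b & meta$stage == s]
    if (length(id) != 1L) stop("comparison references missing library: ",
                               b, s)
    id
  }
  if (mode == "breed") {
    do.call(rbind, lapply(stages, function(s) data.frame(
      label = sprintf("%s%d-vs-%s%d", breeds[1], s, breeds[2], s),
      lib_a = lib_of(breeds[1], s), lib_b = lib_of(breeds[2], s),
      group = as.character(s), stringsAsFactors = FALSE)))
  } else {
    do.call(rbind, lapply(breeds, function(b) {
      do.call(rbind, lapply(seq_len(length(stages) - 1L), function(k) {
        data.frame(
          label = sprintf("%s %d-vs-%d", b, stages[k], stages[k + 1]),
          lib_a = lib_of(b, stages[k]), lib_b = lib_of(b, stages[k + 1]),
          group = b, stringsAsFactors = FALSE)
      }))
    }))
  }
}

#' Screen differentially expressed miRNAs
#'
#' Runs the Audic-Claverie exact test plus the fold-change rule on every
#' miRNA of a (filtered) expression matrix. A miRNA is DE in a comparison iff
#' `|log2(tpm_b/tpm_a)| > log2(fold_threshold)` (strict) and the two-sided
#' p-value is below `p_threshold` (strict). Breed mode runs the same-stage
#' between-breed comparisons; stage mode runs the neighbor-stage comparisons
#' within each breed.
#'
#' @param expr a TPM-normalized (typically filtered) `mir_expr`.
#' @param mode `"breed"` or `"stage"`.
#' @param fold_threshold fold-change gate (default 2).
#' @param p_threshold p-value gate (default 0.05).
#' @return data.frame with one row per (miRNA, comparison): counts, totals,
#'   TPM values, log2 ratio, tail p-values, `is_de` and `direction`.
#' @export
screen_de <- function(expr, mode = c("breed", "stage"), fold_threshold = 2,
                      p_threshold = 0.05) {
  stopifnot(inherits(expr, "mir_expr"))
  if (is.null(expr$tpm)) stop("TPM layer not populated; run tpm_normalize()")
  mode <- match.arg(mode)
  comps <- build_comparisons(expr$meta, mode)
  N <- stats::setNames(expr$meta$total_reads, expr$meta$library_id)
  rows <- list()
  for (ci in seq_len(nrow(comps))) {
    a <- comps$lib_a[ci]; b <- comps$lib_b[ci]
    x <- expr$counts[, a]; y <- expr$counts[, b]
    tpm_a <- expr$tpm[, a]; tpm_b <- expr$tpm[, b]
    pv <- vapply(seq_along(x), function(i) {
      t <- ac_tail_pvalues(x[i], y[i], N[a], N[b])
      c(t$p_lower, t$p_upper, t$p_two_sided)
    }, numeric(3))
    log2_ratio <- log2(tpm_b / tpm_a)
    is_de <- abs(log2_ratio) > log2(fold_threshold) & pv[3, ] < p_threshold
    rows[[ci]] <- data.frame(
      mirna_id = rownames(expr$counts), comparison = comps$label[ci],
      mode = mode, group = comps$group[ci],
      x = x, y = y, n1 = N[a], n2 = N[b],
      tpm_a = tpm_a, tpm_b = tpm_b, log2_ratio = log2_ratio,
      p_lower = pv[1, ], p_upper = pv[2, ], p_two_sided = pv[3, ],
      is_de = is_de,
      direction = ifelse(log2_ratio > 0, "up", "down"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize stage-DE screens across the two breeds
#'
#' Reports the per-breed stage-DE unions, their intersection, and the
#' up-/down-regulated tallies per comparison.
#'
#' @param stage_de data.frame from `screen_de(mode = "stage")`.
#' @return list with `sets` (per-breed DE miRNA id vectors), `n_per_breed`,
#'   `shared` (ids in both breeds), `n_shared`, and `per_comparison`
#'   (comparison, up, down counts).
#' @export
de_set_algebra <- function(stage_de) {
  de <- stage_de[stage_de$is_de, , drop = FALSE]
  breeds <- sort(unique(stage_de$group))
  sets <- lapply(breeds, function(b)
    sort(unique(de$mirna_id[de$group == b])))
  names(sets) <- breeds
  shared <- Reduce(intersect, sets)
  per_comp <- do.call(rbind, lapply(unique(stage_de$comparison), function(cc) {
    d <- de[de$comparison == cc, , drop = FALSE]
    data.frame(comparison = cc,
               up = sum(d$direction == "up"),
               down = sum(d$direction == "down"),
               stringsAsFactors = FALSE)
  }))
  list(sets = sets,
       n_per_breed = vapply(sets, length, 0L),
       shared = shared, n_shared = length(shared),
       per_comparison = per_comp)
}
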