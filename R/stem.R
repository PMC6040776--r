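# Correlation between profile/trajectory vectors with the flat-vector
# convention: a constant vector has undefined Pearson correlation, which is
# defined here as 0 (so distance to the flat profile is 1) — except that two
# constant vectors match directly (correlation 1).
profile_cor <- function(a, b) {
  ca <- stats::sd(a) == 0
  cb <- stats::sd(b) == 0
  if (ca && cb) return(1)
  if (ca || cb) return(0)
  stats::cor(a, b)
}

#' Enumerate candidate model profiles
#'
#' All step sequences of length `T - 1` over \{-c, 0, +c\} cumulatively
#' summed from 0: the 3^(T-1) temporal shapes with at most one unit of change
#' between consecutive time points.
#'
#' @param T number of time points (stages).
#' @param c unit change (default 1).
#' @return list with `profiles` (3^(T-1) x T value matrix) and `steps`
#'   (3^(T-1) x T-1 step matrix).
#' @export
stem_enumerate <- function(T, c = 1) {
  stopifnot(T >= 2, c >= 1)
  steps <- as.matrix(expand.grid(rep(list(c(-c, 0, c)), T - 1L),
                                 KEEP.OUT.ATTRS = FALSE))
  colnames(steps) <- NULL
  profiles <- t(apply(cbind(0, steps), 1, cumsum))
  list(profiles = profiles, steps = steps)
}

# lexicographic order index over step rows (-c < 0 < +c position by position)
step_order_key <- function(steps) {
  do.call(order, lapply(seq_len(ncol(steps)), function(j) steps[, j]))
}

#' Select representative model profiles
#'
#' Deterministic greedy max-min selection from the enumerated candidates:
#' start from the profile with the largest absolute total change (ties broken
#' by the lexicographically smallest step sequence), then repeatedly add the
#' candidate maximizing its minimum distance (1 - Pearson correlation, with
#' the flat-profile convention of [stem_enumerate()] internals) to the
#' selected set, same tie-break. With the default unit change the first
#' selected profile (id 0) is the monotone decline.
#'
#' @param candidates output of [stem_enumerate()].
#' @param m number of profiles to retain (default 20).
#' @return list with `profiles` (m x T matrix, rownames `profile id`),
#'   `steps`, and `ids` (0-based profile ids in selection order).
#' @export
stem_select <- function(candidates, m = 20L) {
  profiles <- candidates$profiles
  steps <- candidates$steps
  n <- nrow(profiles)
  if (m > n) stop("m exceeds the number of candidate profiles")
  # pairwise candidate distances
  dmat <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(i)) {
    d <- 1 - profile_cor(profiles[i, ], profiles[j, ])
    dmat[i, j] <- d; dmat[j, i] <- d
  }
  lex <- integer(n)
  lex[step_order_key(steps)] <- seq_len(n)  # rank in lexicographic step order
  total <- abs(profiles[, ncol(profiles)])
  cand <- which(total == max(total))
  selected <- cand[which.min(lex[cand])]
  while (length(selected) < m) {
    remaining <- setdiff(seq_len(n), selected)
    mind <- vapply(remaining, function(r) min(dmat[r, selected]), 0)
    cand <- remaining[mind == max(mind)]
    selected <- c(selected, cand[which.min(lex[cand])])
  }
  sel <- profiles[selected, , drop = FALSE]
  rownames(sel) <- sprintf("profile-%d", seq_len(m) - 1L)
  list(profiles = sel, steps = steps[selected, , drop = FALSE],
       ids = seq_len(m) - 1L)
}

# trajectory transform: log2 ratio to the first time point
stem_transform <- function(tpm5) {
  log2(sweep(tpm5, 1, tpm5[, 1], "/"))
}

#' Assign miRNA trajectories to model profiles
#'
#' Each miRNA's 5-stage trajectory (log2 TPM ratio to the first stage, on the
#' revised TPM scale) is assigned to the profile with maximal Pearson
#' correlation; ties go to the lower profile id. Constant trajectories map to
#' the flat profile directly (when it is among the selected profiles).
#'
#' @param tpm5 miRNA x stage TPM matrix for one breed (see `stage_matrix`).
#' @param profiles output of [stem_select()].
#' @return data.frame: mirna_id, profile (id), correlation.
#' @export
stem_assign <- function(tpm5, profiles) {
  traj <- stem_transform(tpm5)
  pm <- profiles$profiles
  assign_one <- function(v) {
    cors <- vapply(seq_len(nrow(pm)), function(r) profile_cor(v, pm[r, ]), 0)
    which.max(cors)   # first maximum = lowest profile id
  }
  idx <- apply(traj, 1, assign_one)
  cors <- vapply(seq_along(idx), function(i)
    profile_cor(traj[i, ], pm[idx[i], ]), 0)
  data.frame(mirna_id = rownames(tpm5),
             profile = profiles$ids[idx],
             correlation = cors,
             stringsAsFactors = FALSE)
}

# all permutations of seq_len(n), deterministic order
all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    for (p in sub) out[[length(out) + 1L]] <- c(k, rest[p])
  }
  out
}

#' Profile significance by exact stage-label permutation
#'
#' The expected number of trajectories per profile is computed by exact
#' enumeration over all T! permutations of the stage labels (re-transforming
#' and re-assigning every miRNA under each permutation; no sampling, so the
#' result is deterministic). The per-profile p-value is the binomial tail
#' P(X >= observed) with n = number of miRNAs and p = expected / n,
#' Bonferroni-corrected across the m profiles; profiles with corrected
#' p < `alpha` are flagged significant.
#'
#' @param tpm5 miRNA x stage TPM matrix for one breed.
#' @param profiles output of [stem_select()].
#' @param assignments output of [stem_assign()] on the same matrix.
#' @param alpha significance level (default 0.05).
#' @return data.frame: profile, observed, expected, p_value, p_adj,
#'   significant, plus the profile value vectors as a string column.
#' @export
stem_significance <- function(tpm5, profiles, assignments, alpha = 0.05) {
  m <- nrow(profiles$profiles)
  n <- nrow(tpm5)
  obs <- tabulate(match(assignments$profile, profiles$ids), nbins = m)
  perms <- all_permutations(ncol(tpm5))
  tot <- numeric(m)
  for (p in perms) {
    a <- stem_assign(tpm5[, p, drop = FALSE], profiles)
    tot <- tot + tabulate(match(a$profile, profiles$ids), nbins = m)
  }
  expected <- tot / length(perms)
  pv <- vapply(seq_len(m), function(k) {
    stats::pbinom(obs[k] - 1L, n, min(1, expected[k] / n),
                  lower.tail = FALSE)
  }, 0)
  p_adj <- pmin(1, pv * m)
  data.frame(profile = profiles$ids,
             values = apply(profiles$profiles, 1, paste, collapse = ","),
             observed = obs, expected = expected,
             p_value = pv, p_adj = p_adj,
             significant = p_adj < alpha,
             stringsAsFactors = FALSE)
}

#' Run the full model-profile clustering for one breed
#'
#' Convenience wrapper: enumerate, select `m` profiles, assign and test.
#'
#' @param expr a TPM-normalized (filtered) `mir_expr`.
#' @param breed breed label.
#' @param m maximum number of model profiles (default 20).
#' @param unit_change maximum unit change between time points (default 1).
#' @param alpha significance level (default 0.05).
#' @return list with `profiles`, `assignments`, `significance`.
#' @export
stem_cluster <- function(expr, breed, m = 20L, unit_change = 1,
                         alpha = 0.05) {
  tpm5 <- stage_matrix(expr, breed)
  cand <- stem_enumerate(ncol(tpm5), unit_change)
  prof <- stem_select(cand, m)
  assign <- stem_assign(tpm5, prof)
  signif <- stem_significance(tpm5, prof, assign, alpha)
  list(profiles = prof, assignments = assign, significance = signif)
}
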