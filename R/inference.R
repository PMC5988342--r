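#' Two-sided Wilcoxon rank-sum test
#'
#' Thin wrapper around [stats::wilcox.test()] returning just the two-sided
#' p-value. The exact distribution is used whenever there are no ties (all
#' sample sizes used here are small); with ties the normal approximation is
#' used without continuity correction, so identical samples give p = 1.
#'
#' @param a,b Non-empty numeric samples.
#' @return Two-sided p-value.
#' @examples
#' rank_sum_test(c(1, 2, 3), c(101, 102, 103)) # 0.1 (exact)
#' @export
rank_sum_test <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  suppressWarnings(wilcox.test(a, b, correct = FALSE))$p.value
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (the standard convention); if every
#' difference is zero the samples are identical and p = 1 by convention.
#'
#' @param paired_differences Numeric vector of paired differences.
#' @return Two-sided p-value.
#' @examples
#' sign_rank_test(c(1, 2, 3, 4, 5)) # 0.0625 (exact, 2/2^5)
#' @export
sign_rank_test <- function(paired_differences) {
  d <- paired_differences[paired_differences != 0]
  if (length(d) == 0) return(1)
  suppressWarnings(wilcox.test(d, correct = FALSE))$p.value
}

#' Power of the two-sided one-sample z-test
#'
#' Exact two-sided power `Phi(e - z) + Phi(-e - z)` with
#' `e = effect * sqrt(n) / sd` and `z = qnorm(1 - alpha / 2)`; at zero effect
#' the power equals `alpha`.
#'
#' @param effect True mean under the alternative.
#' @param n Sample size.
#' @param sd Known standard deviation.
#' @param alpha Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
ztest_power <- function(effect, n, sd = 1, alpha = 0.05) {
  stopifnot(n >= 2, sd > 0, alpha > 0, alpha < 1)
  z <- qnorm(1 - alpha / 2)
  e <- effect * sqrt(n) / sd
  pnorm(e - z) + pnorm(-e - z)
}

#' Minimal detectable effect of the one-sample z-test
#'
#' Solves for the effect size at which the two-sided one-sample z-test with
#' known `sd` reaches the target power; the round-trip
#' `ztest_power(effect, ...)` returns the target power to numerical
#' precision. For the study design this is evaluated at n = 28, the number of
#' unique stimulus pairs among 8 stimuli.
#'
#' @param n Sample size.
#' @param sd Known standard deviation (same units as the effect).
#' @param alpha Two-sided significance level.
#' @param power Target power, must exceed `alpha` (the power at zero effect).
#' @return Minimal detectable effect, in the units of `sd`.
#' @examples
#' minimal_detectable_effect(n = 28) # ~ (qnorm(.975) + qnorm(.8)) / sqrt(28)
#' @export
minimal_detectable_effect <- function(n = 28, sd = 1, alpha = 0.05, power = 0.8) {
  stopifnot(n >= 2, sd > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  if (power <= alpha) {
    abort("target power not reachable: it must exceed `alpha` (the power at zero effect)",
          class = "attnspace_domain_error")
  }
  upper <- sd * (qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n) * 4 + sd
  uniroot(function(e) ztest_power(e, n, sd, alpha) - power,
          c(0, upper), tol = 1e-14)$root
}

# ---------------------------------------------------------------------------
# shuffle-split bootstrap for the stress between two conditions

# fast internal pipeline: passive matrix P (cells x 8, no constant rows),
# overlap passive x (cells x 3), attention overlap means y -> MDS points
boot_mds_points <- function(P, x, y, k) {
  g <- rowSums(x * y) / rowSums(x^2)
  D <- 1 - cor(P * g)
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  kk <- min(k, sum(e$values > 0))
  X <- matrix(0, n, k)
  if (kk > 0) {
    X[, seq_len(kk)] <- e$vectors[, seq_len(kk), drop = FALSE] %*%
      diag(sqrt(e$values[seq_len(kk)]), kk)
  }
  X
}

boot_pair_stress <- function(P, xa, xb, ya, yb, k, allow_scaling = TRUE) {
  A <- boot_mds_points(P, xa, ya, k)
  B <- boot_mds_points(P, xb, yb, k)
  procrustes_align(A, B, allow_scaling = allow_scaling)$stress
}

# arm descriptors: per-(cell, overlap column) trial-rate vectors plus the
# passive regressor appropriate to the arm
boot_arm <- function(prep, task) {
  n <- length(prep$cell_ids)
  if (task %in% attention_tasks()) {
    key <- tibble::tibble(cell_id = rep(prep$cell_ids, 3),
                          stim = as.vector(prep$overlap),
                          col = rep(1:3, each = n))
    tr <- prep$attention_trials[prep$attention_trials$task == task, ]
    x <- prep$overlap_passive
  } else if (identical(task, "passive")) {
    key <- tibble::tibble(cell_id = rep(prep$cell_ids, 3),
                          stim = as.vector(prep$nearest_passive_stim),
                          col = rep(1:3, each = n))
    tr <- prep$passive_trials
    x <- matrix(prep$passive8[cbind(rep(seq_len(n), 3),
                                    match(as.vector(prep$nearest_passive_stim),
                                          prep$stim_levels))], n, 3)
  } else {
    abort(paste0("unknown condition: ", task), class = "attnspace_label_error")
  }
  d <- dplyr::inner_join(tr, key, by = c("cell_id", "stim"))
  d$key <- match(paste(d$cell_id, d$col), paste(key$cell_id, key$col))
  rates <- split(d$rate_hz, factor(d$key, levels = seq_len(nrow(key))))
  if (any(lengths(rates) < 2)) {
    abort("fewer than 2 trials in some (cell, stimulus, condition)",
          class = "attnspace_domain_error")
  }
  list(x = x, rates = rates, n = n,
       means = matrix(vapply(rates, mean, numeric(1)), n, 3))
}

#' Shuffle-split bootstrap test for the stress between two conditions
#'
#' Tests the null hypothesis that two task conditions draw from the same
#' trial distribution, against the alternative that their representation
#' spaces differ. Trials of the two conditions are pooled within each
#' (cell, stimulus) pair, shuffled, and split into two pseudo-conditions with
#' the original trial counts; the full analysis (gain fit through the origin,
#' gain-scaled population matrices, correlation distances, classical MDS,
#' full Procrustes alignment) is run on each pseudo-condition and the stress
#' between the two results recorded. The p-value is the fraction of
#' resampled stress values strictly greater than the observed stress (so the
#' smallest reportable p is `1 / n_boot`). Gain factors are re-estimated
#' inside every iteration.
#'
#' @param trials Trial tibble covering both conditions (plus the passive
#'   baseline the pipeline scales).
#' @param task_a,task_b The two conditions: attention-task labels, or
#'   `"passive"` for the passive baseline of the decode space. `task_a` is
#'   configuration 1 of the (asymmetric) stress.
#' @param area,decode_space Which population and stimulus space to analyze.
#' @param n_boot Number of shuffle-split iterations (the full-scale analysis
#'   uses 10,000; reduce for exploration).
#' @param seed Integer seed for the resampling stream.
#' @param k Embedding dimension.
#' @param ecc_band Optional inclusive eccentricity band.
#' @param allow_scaling Scaling aspect of the Procrustes alignment (`TRUE`
#'   when comparing warping beyond magnification).
#' @return An object of class `attn_boot`: list with `observed_stress`,
#'   `null_stresses`, `p_value`, `n_boot`, `seed` and labels.
#' @export
bootstrap_stress_test <- function(trials, task_a, task_b, area, decode_space,
                                  n_boot = 10000, seed = 1, k = 2,
                                  ecc_band = NULL, allow_scaling = TRUE) {
  stopifnot(n_boot >= 1)
  prep <- prep_decode_data(trials, area = area, decode_space = decode_space,
                           ecc_band = ecc_band)
  boot_from_prep(prep, task_a, task_b, n_boot = n_boot, seed = seed, k = k,
                 allow_scaling = allow_scaling)
}

boot_from_prep <- function(prep, task_a, task_b, n_boot, seed, k = 2,
                           allow_scaling = TRUE) {
  # fixed passive matrix: drop constant rows once (they break Pearson)
  const <- apply(prep$passive8, 1, function(r) sd(r) == 0)
  keep <- which(!const)
  P <- prep$passive8[keep, , drop = FALSE]

  armA <- boot_arm(prep, task_a)
  armB <- boot_arm(prep, task_b)
  sub3 <- function(m) m[keep, , drop = FALSE]
  idx3 <- as.vector(outer(keep, (0:2) * length(prep$cell_ids), `+`))

  observed <- boot_pair_stress(P, sub3(armA$x), sub3(armB$x),
                               sub3(armA$means), sub3(armB$means),
                               k, allow_scaling)

  pooled <- purrr::map2(armA$rates[idx3], armB$rates[idx3], c)
  nA <- lengths(armA$rates[idx3])
  tot <- vapply(pooled, sum, numeric(1))
  m <- lengths(pooled)
  nkey <- length(pooled)
  nr <- nrow(P)

  null_stresses <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      sums_a <- vapply(seq_len(nkey), function(i) {
        sum(pooled[[i]][sample.int(m[i], nA[i])])
      }, numeric(1))
      ya <- matrix(sums_a / nA, nr, 3)
      yb <- matrix((tot - sums_a) / (m - nA), nr, 3)
      boot_pair_stress(P, sub3(armA$x), sub3(armB$x), ya, yb, k, allow_scaling)
    }, numeric(1))
  })

  structure(
    list(observed_stress = observed, null_stresses = null_stresses,
         p_value = mean(null_stresses > observed),
         n_boot = n_boot, seed = seed,
         task_a = task_a, task_b = task_b,
         area = prep$area, decode_space = prep$decode_space),
    class = "attn_boot"
  )
}

#' @export
print.attn_boot <- function(x, ...) {
  cat(sprintf("<attn_boot> %s vs %s (%s, %s space)\n",
              x$task_a, x$task_b, x$area, x$decode_space))
  cat(sprintf("  observed stress %.4f; p = %.4f (%d shuffle-split iterations)\n",
              x$observed_stress, x$p_value, x$n_boot))
  invisible(x)
}
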