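#' Extract muscle synergies by non-negative matrix factorization
#'
#' Factorizes a non-negative muscles x time matrix `M` as `W %*% C + eps`
#' with multiplicative updates minimizing the squared Euclidean (Frobenius)
#' error, the classic Lee-Seung scheme.  The factorization is run from
#' `n_restarts` seeded random initializations and the lowest-residual
#' solution is kept; weighting columns are then scaled to unit norm with the
#' compensating scale absorbed into the activation rows.
#'
#' @param M Non-negative numeric matrix, muscles x time.
#' @param n_synergies Number of synergies `N`, `1 <= N <= nrow(M)`.
#' @param seed Integer seed; the factorization is deterministic given it.
#' @param max_iter Iteration cap per restart (default 1000).
#' @param tol Relative-residual-change stopping tolerance (default 1e-6).
#' @param n_restarts Random restarts (default 20).
#' @return A `synergy_set`: list with `W` (muscles x N, unit-norm columns),
#'   `C` (N x T), `n_synergies`, `residual` (Frobenius), `vaf_global`,
#'   `residual_trace` of the winning restart, and `seed`.
#' @export
nmf <- function(M, n_synergies, seed = 1L, max_iter = 1000L, tol = 1e-6,
                n_restarts = 20L) {
  M <- as.matrix(M)
  if (any(M < 0)) stop("NMF input must be non-negative")
  n_m <- nrow(M)
  if (n_synergies < 1L || n_synergies > n_m)
    stop(sprintf("n_synergies = %d outside 1..%d", n_synergies, n_m))
  best <- NULL
  scale0 <- mean(M)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    W0 <- matrix(runif(n_m * n_synergies), n_m) * scale0
    C0 <- matrix(runif(n_synergies * ncol(M)), n_synergies) * scale0
    fit <- nmf_mu_cpp(M, W0, C0, max_iter, tol, FALSE, 1e-12)
    if (is.null(best) || utils::tail(fit$residuals, 1L) < best$residual) {
      best <- list(W = fit$W, C = fit$C,
                   residual = utils::tail(fit$residuals, 1L),
                   residual_trace = fit$residuals,
                   iterations = fit$iterations)
    }
  }
  nz <- normalize_synergy(best$W, best$C)
  rownames(nz$W) <- rownames(M)
  structure(list(W = nz$W, C = nz$C, n_synergies = n_synergies,
                 residual = best$residual,
                 residual_trace = best$residual_trace,
                 vaf_global = vaf(M, nz$W %*% nz$C, "global"),
                 seed = seed),
            class = "synergy_set")
}

#' @export
print.synergy_set <- function(x, ...) {
  cat(sprintf("<synergy_set> %d synergies, %d muscles x %d time steps, global VAF %.2f%%\n",
              x$n_synergies, nrow(x$W), ncol(x$C), x$vaf_global))
  invisible(x)
}

#' Refit activations with fixed weightings
#'
#' Held-out update used in cross-validation: only the activation matrix `C`
#' is iterated (multiplicative update), the weightings `W` stay fixed.
#'
#' @param M_test Non-negative muscles x time matrix.
#' @param W_fixed Muscles x N weighting matrix.
#' @param seed Seed for the random `C` initialization.
#' @param max_iter,tol As in [nmf()].
#' @return N x time activation matrix `C` (non-negative).
#' @export
update_activations_fixed_w <- function(M_test, W_fixed, seed = 1L,
                                       max_iter = 1000L, tol = 1e-6) {
  M_test <- as.matrix(M_test)
  if (any(M_test < 0)) stop("NMF input must be non-negative")
  if (nrow(W_fixed) != nrow(M_test))
    stop("W_fixed rows must match M_test rows")
  set.seed(seed)
  C0 <- matrix(runif(ncol(W_fixed) * ncol(M_test)), ncol(W_fixed)) * mean(M_test)
  fit <- nmf_mu_cpp(M_test, W_fixed, C0, max_iter, tol, TRUE, 1e-12)
  fit$C
}

#' Variability accounted for (VAF)
#'
#' `100 * (1 - SS_residual / SS_original)` with *uncentered* sums of squares
#' (no mean subtraction), over the whole matrix (`global`) or per muscle row
#' (`per_muscle`).
#'
#' @param original,reconstructed Equal-shape numeric matrices.
#' @param scope `"global"` or `"per_muscle"`.
#' @return A percentage (global) or named vector of percentages (per
#'   muscle).  Always `<= 100`.
#' @export
vaf <- function(original, reconstructed, scope = c("global", "per_muscle")) {
  scope <- match.arg(scope)
  original <- as.matrix(original); reconstructed <- as.matrix(reconstructed)
  if (!all(dim(original) == dim(reconstructed)))
    stop("original and reconstructed must have identical shapes")
  res2 <- (original - reconstructed)^2
  if (scope == "global") {
    ss_o <- sum(original^2)
    if (ss_o == 0) stop("VAF undefined: original matrix is all zero")
    100 * (1 - sum(res2) / ss_o)
  } else {
    ss_o <- rowSums(original^2)
    if (any(ss_o == 0)) stop("VAF undefined: all-zero muscle row")
    out <- 100 * (1 - rowSums(res2) / ss_o)
    names(out) <- rownames(original)
    out
  }
}

#' Cross-validated VAF over candidate synergy numbers
#'
#' For each repetition, the gait cycles (blocks of `points_per_cycle`
#' columns) are split at random into a training and a test set (default
#' 60/40, i.e. 18/12 of 30 cycles).  Weightings are fit on the training
#' cycles; activations are refit on the test cycles with weightings fixed;
#' global and per-muscle VAF are scored on the held-out reconstruction.
#' Means and 95% confidence intervals (t distribution, `n_repeats - 1` df)
#' are tabulated per candidate `N`.
#'
#' @param M Muscles x T matrix (`T` a multiple of `points_per_cycle`), or an
#'   `emg_matrix`.
#' @param n_range Contiguous candidate synergy numbers (default `1:nrow(M)`).
#' @param n_repeats Cross-validation repetitions (default 10).
#' @param train_frac Training fraction of cycles (default 0.6).
#' @param seed Master seed; splits and restarts derive from it.
#' @param n_restarts Restarts per training fit (default 3).
#' @param max_iter,tol Convergence controls for the inner fits.
#' @param points_per_cycle Columns per gait cycle (default 100).
#' @return A `vaf_table`: list with `global` (repetitions x N matrix),
#'   `muscle` (repetitions x muscles x N array), `summary` data frame
#'   (per N: mean/CI of global VAF and the minimum across muscles of the
#'   per-muscle CI lower bounds), `n_train`, `n_test`.
#' @export
cross_validated_vaf <- function(M, n_range = NULL, n_repeats = 10L,
                                train_frac = 0.6, seed = 1L, n_restarts = 3L,
                                max_iter = 500L, tol = 1e-5,
                                points_per_cycle = 100L) {
  if (inherits(M, "emg_matrix")) M <- M$values
  M <- as.matrix(M)
  if (is.null(n_range)) n_range <- seq_len(nrow(M))
  if (n_repeats < 2L) stop("n_repeats must be >= 2 to form a confidence interval")
  if (ncol(M) %% points_per_cycle != 0L)
    stop("columns must form whole cycles")
  n_cycles <- ncol(M) %/% points_per_cycle
  n_train <- round(train_frac * n_cycles)
  n_test <- n_cycles - n_train
  cyc_cols <- function(cycles)
    as.vector(vapply(cycles, function(k)
      ((k - 1L) * points_per_cycle + 1L):(k * points_per_cycle),
      integer(points_per_cycle)))
  glob <- matrix(NA_real_, n_repeats, length(n_range),
                 dimnames = list(NULL, paste0("N", n_range)))
  musc <- array(NA_real_, c(n_repeats, nrow(M), length(n_range)),
                dimnames = list(NULL, rownames(M), paste0("N", n_range)))
  for (rep_i in seq_len(n_repeats)) {
    set.seed(seed * 1000L + rep_i)
    train_cycles <- sort(sample(n_cycles, n_train))
    test_cycles <- setdiff(seq_len(n_cycles), train_cycles)
    M_train <- M[, cyc_cols(train_cycles), drop = FALSE]
    M_test <- M[, cyc_cols(test_cycles), drop = FALSE]
    for (ni in seq_along(n_range)) {
      fit <- nmf(M_train, n_range[ni], seed = seed * 1000L + rep_i * 37L + ni,
                 max_iter = max_iter, tol = tol, n_restarts = n_restarts)
      C_test <- update_activations_fixed_w(M_test, fit$W,
                                           seed = seed * 1000L + rep_i * 37L + ni,
                                           max_iter = max_iter, tol = tol)
      recon <- fit$W %*% C_test
      glob[rep_i, ni] <- vaf(M_test, recon, "global")
      musc[rep_i, , ni] <- vaf(M_test, recon, "per_muscle")
    }
  }
  ci <- function(v) {
    m <- mean(v); half <- stats::qt(0.975, length(v) - 1L) * stats::sd(v) / sqrt(length(v))
    c(mean = m, lower = m - half, upper = m + half)
  }
  summ <- do.call(rbind, lapply(seq_along(n_range), function(ni) {
    g <- ci(glob[, ni])
    mus_lower <- apply(musc[, , ni, drop = FALSE], 2L, function(v) ci(as.numeric(v))["lower"])
    data.frame(n_synergies = n_range[ni], global_mean = g["mean"],
               global_lower = g["lower"], global_upper = g["upper"],
               muscle_lower_min = min(mus_lower), row.names = NULL)
  }))
  structure(list(global = glob, muscle = musc, summary = summ,
                 n_range = n_range, n_repeats = n_repeats,
                 n_train = n_train, n_test = n_test),
            class = "vaf_table")
}

#' @export
print.vaf_table <- function(x, ...) {
  cat(sprintf("<vaf_table> N in %d..%d, %d repetitions, %d train / %d test cycles\n",
              min(x$n_range), max(x$n_range), x$n_repeats, x$n_train, x$n_test))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Select the number of synergies from a VAF table
#'
#' The smallest candidate `N` whose global-VAF 95% CI lower bound exceeds
#' `global_threshold` *and* whose per-muscle CI lower bounds all exceed
#' `muscle_threshold` ("exceeds" read as strict `>`).
#'
#' @param table A `vaf_table` from [cross_validated_vaf()].
#' @param global_threshold,muscle_threshold Percent thresholds (90 and 75).
#' @return The selected integer `N`.
#' @export
select_num_synergies <- function(table, global_threshold = 90,
                                 muscle_threshold = 75) {
  stopifnot(inherits(table, "vaf_table"))
  s <- table$summary
  ok <- s$global_lower > global_threshold & s$muscle_lower_min > muscle_threshold
  if (!any(ok)) {
    cond <- structure(class = c("synstab_no_selection", "error", "condition"),
                      list(message = "no synergy number satisfies the VAF thresholds",
                           call = sys.call(), table = table))
    stop(cond)
  }
  s$n_synergies[which(ok)[1L]]
}

#' Row-wise shuffle control
#'
#' Independently permutes each muscle row over all time columns, preserving
#' every row's values, range and variance while destroying between-muscle
#' structure.  The VAF of synergies extracted from the shuffled matrix is
#' the chance baseline against which the real VAF is compared.
#'
#' @param M Muscles x T matrix or `emg_matrix`.
#' @param seed Integer seed.
#' @return Shuffled matrix, same shape.
#' @export
shuffle_control <- function(M, seed = 1L) {
  if (inherits(M, "emg_matrix")) M <- M$values
  M <- as.matrix(M)
  set.seed(seed)
  out <- t(apply(M, 1L, sample))
  dimnames(out) <- dimnames(M)
  out
}

#' Scale weighting columns to unit norm
#'
#' Each column of `W` is divided by its Euclidean norm and the matching row
#' of `C` multiplied by it, so the product `W %*% C` is unchanged.
#'
#' @param W Muscles x N matrix with no zero column.
#' @param C N x T matrix.
#' @return List with `W` (unit-norm columns) and `C` (rescaled).
#' @export
normalize_synergy <- function(W, C) {
  norms <- sqrt(colSums(W^2))
  if (any(norms == 0)) stop("degenerate synergy: zero weighting column")
  list(W = sweep(W, 2L, norms, "/"), C = sweep(C, 1L, norms, "*"))
}

#' Cosine similarity of two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return `sum(u*v) / (||u|| ||v||)`; in `[0, 1]` for non-negative inputs.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for a zero vector")
  sum(u * v) / (nu * nv)
}

#' Critical similarity threshold at a given significance level
#'
#' The two-tailed critical value of the Pearson correlation coefficient at
#' significance `alpha` with `df` degrees of freedom,
#' `r = t / sqrt(t^2 + df)` with `t = qt(1 - alpha/2, df)`.  At
#' `alpha = 0.01`, `df = 10` this is 0.708 (rounding to 0.71), the
#' conventional cutoff for sorting 12-muscle synergy weightings.
#'
#' @param alpha Two-tailed significance level (default 0.01).
#' @param df Degrees of freedom (default `12 - 2 = 10` for 12 muscles).
#' @return The critical correlation (not rounded).
#' @export
critical_similarity_threshold <- function(alpha = 0.01, df = 10L) {
  t_crit <- stats::qt(1 - alpha / 2, df)
  t_crit / sqrt(t_crit^2 + df)
}

# mean activation waveform over cycles: N x points_per_cycle
.mean_waveform <- function(C, points_per_cycle = 100L) {
  t(apply(C, 1L, function(row)
    rowMeans(matrix(row, nrow = points_per_cycle))))
}

.pair_similarity <- function(Wa, Ca_wave, Wb, Cb_wave, i, j, method) {
  score <- function(u, v) {
    # empty reference groups (all-zero means) can occur in stage 2
    if (all(u == 0) || all(v == 0)) return(-Inf)
    if (method == "pearson") stats::cor(u, v) else cosine_similarity(u, v)
  }
  c(w = score(Wa[, i], Wb[, j]), c = score(Ca_wave[i, ], Cb_wave[j, ]))
}

# Greedy one-to-one matching of one trial's synergies to reference columns.
# A pair is admissible when the W *or* the C similarity clears the
# threshold; pairs are taken in decreasing order of their better score, so
# a conflicting lower-scoring pair is re-queued onto its next-best option.
.match_one <- function(W, C_wave, W_ref, C_ref_wave, threshold, method) {
  n <- ncol(W); n_ref <- ncol(W_ref)
  simw <- matrix(NA_real_, n, n_ref); simc <- matrix(NA_real_, n, n_ref)
  for (i in seq_len(n)) for (j in seq_len(n_ref)) {
    s <- .pair_similarity(W, C_wave, W_ref, C_ref_wave, i, j, method)
    simw[i, j] <- s["w"]; simc[i, j] <- s["c"]
  }
  best <- pmax(simw, simc)
  admissible <- simw > threshold | simc > threshold
  assign <- rep(NA_integer_, n); score <- rep(NA_real_, n)
  taken <- rep(FALSE, n_ref)
  ord <- order(best, decreasing = TRUE)
  for (idx in ord) {
    i <- (idx - 1L) %% n + 1L; j <- (idx - 1L) %/% n + 1L
    if (!isTRUE(admissible[i, j]) || !is.na(assign[i]) || taken[j]) next
    assign[i] <- j; score[i] <- best[i, j]; taken[j] <- TRUE
  }
  list(group = assign, similarity = score)
}

#' Sort synergies across trials by cosine similarity
#'
#' Two-stage functional sorting.  Stage 1 matches every trial's synergies to
#' those of a reference trial (the first, by default): a pair is a match
#' when the cosine similarity of the weightings *or* of the cycle-averaged
#' activation waveforms exceeds `threshold`; conflicts keep the
#' highest-similarity pair and re-queue the loser.  Stage 2 averages the
#' matched groups and re-matches every synergy against the group means with
#' the same rule.  Synergies that never clear the threshold are flagged
#' unmatched, not forced into a group.
#'
#' @param trial_sets List of `synergy_set` objects sharing the muscle order.
#' @param threshold Similarity threshold (default 0.71, the critical Pearson
#'   r at alpha = 0.01 with 10 df; see [critical_similarity_threshold()]).
#' @param method `"cosine"` (default) or `"pearson"` for the score.
#' @param reference Index of the reference trial (default 1).
#' @param points_per_cycle Columns per cycle in `C` (default 100).
#' @return A `synergy_grouping`: data frame with `trial`, `synergy`,
#'   `group` (NA when unmatched), `similarity`, `unmatched`; plus the group
#'   mean weightings/waveforms as attributes `"W_mean"` and `"C_mean"`.
#' @export
match_synergies <- function(trial_sets, threshold = 0.71,
                            method = c("cosine", "pearson"), reference = 1L,
                            points_per_cycle = 100L) {
  method <- match.arg(method)
  stopifnot(length(trial_sets) >= 1L)
  n_muscles <- vapply(trial_sets, function(s) nrow(s$W), integer(1L))
  if (length(unique(n_muscles)) != 1L)
    stop("all trials must share the same muscle count/order")
  Ws <- lapply(trial_sets, `[[`, "W")
  waves <- lapply(trial_sets, function(s) .mean_waveform(s$C, points_per_cycle))
  W_ref <- Ws[[reference]]; C_ref <- waves[[reference]]
  stage1 <- lapply(seq_along(trial_sets), function(t)
    .match_one(Ws[[t]], waves[[t]], W_ref, C_ref, threshold, method))
  n_groups <- ncol(W_ref)
  # group means from stage-1 assignments
  W_mean <- matrix(0, nrow(W_ref), n_groups); C_mean <- matrix(0, n_groups, ncol(C_ref))
  counts <- rep(0L, n_groups)
  for (t in seq_along(trial_sets)) {
    g <- stage1[[t]]$group
    for (i in seq_along(g)) if (!is.na(g[i])) {
      W_mean[, g[i]] <- W_mean[, g[i]] + Ws[[t]][, i]
      C_mean[g[i], ] <- C_mean[g[i], ] + waves[[t]][i, ]
      counts[g[i]] <- counts[g[i]] + 1L
    }
  }
  nonempty <- counts > 0L
  W_mean[, nonempty] <- sweep(W_mean[, nonempty, drop = FALSE], 2L, counts[nonempty], "/")
  C_mean[nonempty, ] <- sweep(C_mean[nonempty, , drop = FALSE], 1L, counts[nonempty], "/")
  # stage 2: re-match everything against the group means
  rows <- do.call(rbind, lapply(seq_along(trial_sets), function(t) {
    m <- .match_one(Ws[[t]], waves[[t]], W_mean, C_mean, threshold, method)
    data.frame(trial = t, synergy = seq_along(m$group), group = m$group,
               similarity = m$similarity, unmatched = is.na(m$group))
  }))
  structure(rows, class = c("synergy_grouping", "data.frame"),
            W_mean = W_mean, C_mean = C_mean, threshold = threshold,
            method = method)
}
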