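#' Poincare sections at each percent of the gait cycle
#'
#' Samples the delay-embedded state of an activation once per stride at
#' each of the 100 gait phases, giving 100 Poincare sections.  Stride `k`'s
#' state at phase `p` starts at sample `(k-1)*100 + p`; strides whose
#' embedding window `(d-1)*tau` runs past the end of the series are dropped
#' from the affected sections only.
#'
#' @param x Numeric activation series on the 100-points-per-cycle grid.
#' @param tau,d Embedding delay and dimension.
#' @param points_per_cycle Samples per stride (default 100).
#' @return A list of 100 `poincare_section` objects; each holds `phase`,
#'   `states` (strides x d, rownames = stride index), `fixed_point`
#'   (column means).
#' @export
build_sections <- function(x, tau, d, points_per_cycle = 100L) {
  x <- as.numeric(x)
  n <- length(x)
  n_strides <- n %/% points_per_cycle
  span <- (d - 1L) * tau
  sections <- vector("list", points_per_cycle)
  for (p in seq_len(points_per_cycle)) {
    starts <- (seq_len(n_strides) - 1L) * points_per_cycle + p
    usable <- which(starts + span <= n)
    if (length(usable) < d + 1L)
      stop(sprintf("insufficient strides: %d usable at phase %d%%, need >= %d",
                   length(usable), p, d + 1L))
    states <- t(vapply(starts[usable], function(s) x[s + (0:(d - 1L)) * tau],
                       numeric(d)))
    rownames(states) <- usable
    sections[[p]] <- structure(list(phase = p, states = states,
                                    fixed_point = colMeans(states)),
                               class = "poincare_section")
  }
  sections
}

# Moore-Penrose pseudoinverse via SVD (least-norm least-squares solve).
.pinv <- function(X, tol = NULL) {
  s <- svd(X)
  if (is.null(tol)) tol <- max(dim(X)) * max(s$d) * .Machine$double.eps
  pos <- s$d > tol
  if (!any(pos)) return(list(pinv = matrix(0, ncol(X), nrow(X)), rank = 0L))
  list(pinv = s$v[, pos, drop = FALSE] %*%
         (t(s$u[, pos, drop = FALSE]) / s$d[pos]),
       rank = sum(pos))
}

#' Linearized Poincare-map Jacobian at one section
#'
#' Fits `S[k+1] - S* ~ J (S[k] - S*)` by least squares over all
#' consecutive-stride pairs present in the section, with `S*` the mean
#' state (the fixed point of the limit cycle).  Rank-deficient deviation
#' sets fall back to the least-norm (pseudoinverse) solution with a flag.
#'
#' @param section A `poincare_section` (or any list with a `states` matrix
#'   whose rownames are stride indices).
#' @param fixed_point Optional known fixed point `S*`; by default the mean
#'   state (the average-trajectory rule).  Supplying the true fixed point
#'   is useful for simulated systems whose transient mean differs from it.
#' @return List with `J` (d x d), `fixed_point`, `n_pairs`,
#'   `rank_deficient` flag.
#' @export
fit_jacobian <- function(section, fixed_point = NULL) {
  states <- as.matrix(section$states)
  d <- ncol(states)
  if (nrow(states) < d + 1L)
    stop(sprintf("need >= %d strides to fit a %dx%d Jacobian, have %d",
                 d + 1L, d, d, nrow(states)))
  s_star <- if (is.null(fixed_point)) colMeans(states) else fixed_point
  strides <- as.integer(rownames(states))
  if (is.null(strides) || anyNA(strides)) strides <- seq_len(nrow(states))
  consec <- which(diff(strides) == 1L)
  if (length(consec) < d)
    stop(sprintf("need >= %d consecutive-stride pairs, have %d", d, length(consec)))
  X <- sweep(states[consec, , drop = FALSE], 2L, s_star)        # S_k - S*
  Y <- sweep(states[consec + 1L, , drop = FALSE], 2L, s_star)   # S_{k+1} - S*
  p <- .pinv(X)
  rank_deficient <- p$rank < d
  if (rank_deficient)
    warning(sprintf("rank-deficient deviations (rank %d < %d): least-norm Jacobian",
                    p$rank, d))
  J <- t(p$pinv %*% Y)   # Y ~ X B with J = t(B)
  list(J = J, fixed_point = s_star, n_pairs = length(consec),
       rank_deficient = rank_deficient)
}

#' Maximum Floquet multiplier magnitude of a Jacobian
#'
#' The Floquet multipliers are the (complex) eigenvalues of the Poincare-map
#' Jacobian; the orbit is stable when all magnitudes are below 1.
#'
#' @param J Square numeric matrix.
#' @return The maximum eigenvalue modulus (spectral radius).
#' @export
max_floquet_multiplier <- function(J) {
  J <- as.matrix(J)
  if (nrow(J) != ncol(J)) stop("Jacobian must be square")
  max(Mod(eigen(J, only.values = TRUE)$values))
}

#' Summarize per-section Floquet multipliers for one trial
#'
#' @param magnitudes Maximum multiplier magnitude at each section
#'   (typically 100 values, one per percent of the gait cycle).
#' @param policy Summary statistic driving the stability verdict:
#'   `"mean"` (default) or `"max"` across sections.
#' @return A `floquet_result`: list with `mean`, `max`, `n_sections`,
#'   `policy`, `stable` (`TRUE` iff the policy statistic < 1).
#' @export
floquet_summary <- function(magnitudes, policy = c("mean", "max")) {
  policy <- match.arg(policy)
  magnitudes <- as.numeric(magnitudes)
  if (any(magnitudes < 0)) stop("multiplier magnitudes must be >= 0")
  m <- mean(magnitudes); mx <- max(magnitudes)
  structure(list(mean = m, max = mx, n_sections = length(magnitudes),
                 policy = policy, stable = (if (policy == "mean") m else mx) < 1),
            class = "floquet_result")
}

#' @export
print.floquet_result <- function(x, ...) {
  cat(sprintf("<floquet_result> FM mean %.3f, max %.3f over %d sections; %s (%s policy)\n",
              x$mean, x$max, x$n_sections,
              ifelse(x$stable, "orbitally stable", "orbitally unstable"), x$policy))
  invisible(x)
}

#' Orbital-stability analysis of a scalar activation series
#'
#' Builds the 100 Poincare sections from the delay embedding, fits each
#' section's linearized map and summarizes the maximum multiplier
#' magnitudes.
#'
#' @param x Activation series on the 100-points-per-cycle grid.
#' @param tau,d Embedding parameters.
#' @param points_per_cycle Samples per stride (default 100).
#' @param policy Summary policy, see [floquet_summary()].
#' @return A `floquet_result` with the per-section `magnitudes` and
#'   rank-deficiency `flags` attached.
#' @export
floquet_analysis <- function(x, tau, d, points_per_cycle = 100L,
                             policy = "mean") {
  sections <- build_sections(x, tau, d, points_per_cycle)
  # rank deficiency is reported through the per-section flags, not warnings
  fits <- lapply(sections, function(s)
    withCallingHandlers(fit_jacobian(s),
                        warning = function(w) {
                          if (grepl("rank-deficient", conditionMessage(w)))
                            invokeRestart("muffleWarning")
                        }))
  mags <- vapply(fits, function(f) max_floquet_multiplier(f$J), numeric(1L))
  res <- floquet_summary(mags, policy)
  res$magnitudes <- mags
  res$flags <- vapply(fits, `[[`, logical(1L), "rank_deficient")
  res$tau <- tau; res$d <- d
  res
}
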