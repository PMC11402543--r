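# Binary STAPLE (Simultaneous Truth And Performance Level Estimation):
# expectation-maximization estimation of a probabilistic ground-truth
# segmentation together with per-rater sensitivity p_j and specificity q_j.

#' STAPLE fusion parameters
#'
#' @param threshold Posterior probability threshold tau in (0, 1] used when
#'   converting the ground-truth estimate to a binary GTV; 0.95 by default,
#'   the value used for all fused target volumes in this pipeline.
#' @param max_iterations Maximum number of EM iterations.
#' @param tolerance Convergence tolerance: the EM loop stops once the mean
#'   absolute change of the posterior field between iterations falls below it.
#' @param prior_mode `"global_fraction"` sets the foreground prior gamma to
#'   the mean foreground fraction over observers (held fixed across
#'   iterations); `"fixed"` uses `fixed_prior`.
#' @param fixed_prior Prior probability in (0, 1), used when
#'   `prior_mode = "fixed"`.
#' @return A `staple_params` list.
#' @export
staple_params <- function(threshold = 0.95, max_iterations = 200L,
                          tolerance = 1e-7,
                          prior_mode = c("global_fraction", "fixed"),
                          fixed_prior = NULL) {
  prior_mode <- match.arg(prior_mode)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1)
    stop("`threshold` must lie in (0, 1]", call. = FALSE)
  if (tolerance <= 0) stop("`tolerance` must be positive", call. = FALSE)
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  if (prior_mode == "fixed") {
    if (is.null(fixed_prior) || fixed_prior <= 0 || fixed_prior >= 1)
      stop("`fixed_prior` must lie in (0, 1) when prior_mode = 'fixed'",
           call. = FALSE)
  }
  structure(list(threshold = threshold,
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, prior_mode = prior_mode,
                 fixed_prior = fixed_prior),
            class = "staple_params")
}

#' Binary STAPLE expectation-maximization
#'
#' Estimates the posterior probability field \eqn{W_i = P(T_i = 1 | d)} of the
#' unknown true segmentation from the binary decisions \eqn{d_{ij}} of J
#' observers, together with each observer's sensitivity \eqn{p_j} and
#' specificity \eqn{q_j}.
#'
#' E-step, per voxel i:
#' \deqn{a_i = \gamma \prod_j p_j^{d_{ij}} (1-p_j)^{1-d_{ij}},\quad
#'       b_i = (1-\gamma) \prod_j (1-q_j)^{d_{ij}} q_j^{1-d_{ij}},\quad
#'       W_i = a_i / (a_i + b_i).}
#' M-step: \eqn{p_j = \sum_i W_i d_{ij} / \sum_i W_i},
#' \eqn{q_j = \sum_i (1-W_i)(1-d_{ij}) / \sum_i (1-W_i)}.
#'
#' W is initialized to the voxelwise mean of the observer decisions and the
#' first step is an M-step. The prior gamma is held fixed across iterations
#' (see [staple_params()]); p and q are clamped to `[1e-6, 1 - 1e-6]` after
#' each M-step to avoid degeneracies in unanimous regions. Iteration stops
#' when the mean absolute change in W drops below `tolerance` or after
#' `max_iterations`.
#'
#' @param observer_masks Non-empty list of [binary_mask()] objects on one
#'   grid, one per observer.
#' @param params A [staple_params()] object.
#' @return A `staple_result`: list with `posterior` (probability array on the
#'   grid), `sensitivity`, `specificity` (per-observer vectors), `prior`,
#'   `iterations_run`, `converged`, `grid`, `params`.
#' @references Warfield, Zou and Wells, IEEE TMI 23(7), 2004.
#' @export
staple_em <- function(observer_masks, params = staple_params()) {
  if (!is.list(observer_masks) || length(observer_masks) == 0L)
    stop("`observer_masks` must be a non-empty list", call. = FALSE)
  ref <- observer_masks[[1L]]
  for (m in observer_masks[-1L]) stop_if_grid_mismatch(ref, m, "observer masks")
  J <- length(observer_masks)
  V <- prod(ref$grid$shape)
  D <- vapply(observer_masks, function(m) as.numeric(m$values), numeric(V))
  dim(D) <- c(V, J)

  gamma <- switch(params$prior_mode,
                  global_fraction = mean(D),
                  fixed = params$fixed_prior)
  if (params$prior_mode == "global_fraction" && gamma == 0)
    stop("all observer masks are empty: global-fraction prior is degenerate",
         call. = FALSE)
  gamma <- min(max(gamma, 1e-6), 1 - 1e-6)

  clamp <- function(x) pmin(pmax(x, 1e-6), 1 - 1e-6)
  W <- rowMeans(D)
  Dc <- 1 - D
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(params$max_iterations)) {
    # M-step from the current posterior
    sW <- sum(W); sWc <- sum(1 - W)
    p <- clamp(as.numeric(crossprod(D, W)) / max(sW, .Machine$double.xmin))
    q <- clamp(as.numeric(crossprod(Dc, 1 - W)) / max(sWc, .Machine$double.xmin))
    # E-step
    loga <- log(gamma) + D %*% log(p) + Dc %*% log1p(-p)
    logb <- log1p(-gamma) + D %*% log1p(-q) + Dc %*% log(q)
    W_new <- as.numeric(1 / (1 + exp(logb - loga)))
    delta <- mean(abs(W_new - W))
    W <- W_new
    iters <- it
    if (delta < params$tolerance) { converged <- TRUE; break }
  }
  obs_names <- names(observer_masks)
  if (is.null(obs_names)) obs_names <- paste0("observer", seq_len(J))
  names(p) <- names(q) <- obs_names
  posterior <- array(W, dim = ref$grid$shape)
  structure(list(posterior = posterior, sensitivity = p, specificity = q,
                 prior = gamma, iterations_run = iters, converged = converged,
                 grid = ref$grid, params = params),
            class = "staple_result")
}

#' @export
print.staple_result <- function(x, ...) {
  cat(sprintf(
    "<staple_result> %d observers, %d iterations (%s), prior %.4f\n",
    length(x$sensitivity), x$iterations_run,
    if (x$converged) "converged" else "not converged", x$prior))
  cat("  sensitivity:", paste(sprintf("%.3f", x$sensitivity), collapse = " "), "\n")
  cat("  specificity:", paste(sprintf("%.3f", x$specificity), collapse = " "), "\n")
  invisible(x)
}

#' Threshold a STAPLE posterior into a binary mask
#'
#' Foreground where the posterior ground-truth probability is `>= tau`
#' (inclusive, so a unanimous consensus survives tau = 1).
#'
#' @param result A `staple_result` from [staple_em()].
#' @param tau Probability threshold in (0, 1].
#' @return A [binary_mask()] on the result's grid.
#' @export
threshold_posterior <- function(result, tau = 0.95) {
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau > 1)
    stop("`tau` must lie in (0, 1]", call. = FALSE)
  binary_mask(result$posterior >= tau, result$grid)
}
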