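# Multivariate Gaussian hidden Markov model for latent seizure-risk
# states: log-space forward-backward inference (the recursions live in
# compiled code), Baum-Welch EM with k-means initialization and restarts,
# identifiability relabeling, AIC state-count selection, posterior and
# Viterbi decoding, and rank-sum validation of the decoded states.

# Per-state Gaussian log-densities, T x K.
.gaussian_logdens <- function(X, means, covariances) {
  T_ <- nrow(X); K <- nrow(means); d <- ncol(X)
  out <- matrix(0, T_, K)
  for (k in seq_len(K)) {
    R <- tryCatch(chol(covariances[[k]]), error = function(e)
      rns_stop("singular state covariance after regularization",
               "rns_numerical_error"))
    ct <- t(X) - means[k, ]
    z <- backsolve(R, ct, transpose = TRUE)
    out[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(R))) +
                          colSums(z^2))
  }
  out
}

.seg_codes <- function(segments, T_) {
  if (is.null(segments)) rep(1L, T_)
  else as.integer(factor(segments, levels = unique(segments)))
}

#' Number of free parameters of a K-state Gaussian HMM
#'
#' `(K-1)` initial probabilities, `K(K-1)` transition parameters, `K d`
#' means and `K d(d+1)/2` covariance parameters (full covariances).
#'
#' @param K number of states; @param d observation dimension.
#' @return Integer parameter count.
#' @export
hmm_n_params <- function(K, d) {
  as.integer((K - 1) + K * (K - 1) + K * d + K * d * (d + 1) / 2)
}

#' Log-space forward-backward inference
#'
#' Computes the total log-likelihood, per-hour smoothed posteriors and
#' expected transition counts. All recursions run in log space, so
#' sequences of 1e5 hours do not underflow. The forward recursion restarts
#' from the initial distribution at each segment boundary, so no transition
#' is scored across a recording gap.
#'
#' @param model a `gaussian_hmm` (or a list with `initial_probs`,
#'   `transition_matrix`, `means`, `covariances`).
#' @param observations numeric matrix, T x d.
#' @param segments optional length-T segment labels.
#' @return List with `log_likelihood`, `posterior` (T x K), `xi_sum`
#'   (K x K expected transition counts) and `gamma_start` (summed posterior
#'   at segment starts).
#' @export
log_forward_backward <- function(model, observations, segments = NULL) {
  X <- as.matrix(observations)
  if (ncol(X) != ncol(model$means))
    rns_stop("observation dimension does not match the model",
             "rns_dimension_error")
  ld <- .gaussian_logdens(X, model$means, model$covariances)
  fb <- hmm_fb_cpp(ld, log(model$transition_matrix),
                   log(model$initial_probs), .seg_codes(segments, nrow(X)))
  list(log_likelihood = fb$log_likelihood, posterior = fb$gamma,
       xi_sum = fb$xi_sum, gamma_start = fb$gamma_start)
}

#' Viterbi path
#'
#' Most probable joint state sequence (per segment), 1-based labels.
#'
#' @inheritParams log_forward_backward
#' @return Integer vector of length T.
#' @export
viterbi_path <- function(model, observations, segments = NULL) {
  X <- as.matrix(observations)
  ld <- .gaussian_logdens(X, model$means, model$covariances)
  hmm_viterbi_cpp(ld, log(model$transition_matrix),
                  log(model$initial_probs), .seg_codes(segments, nrow(X)))
}

.make_hmm <- function(K, initial_probs, transition_matrix, means,
                      covariances, log_likelihood, converged, n_iter,
                      ll_trace, seed) {
  d <- ncol(means)
  np <- hmm_n_params(K, d)
  structure(list(K = K, d = d,
                 initial_probs = initial_probs,
                 transition_matrix = transition_matrix,
                 means = means, covariances = covariances,
                 log_likelihood = log_likelihood,
                 n_params = np,
                 aic = 2 * np - 2 * log_likelihood,
                 converged = converged, n_iter = n_iter,
                 ll_trace = ll_trace, seed = seed),
            class = "gaussian_hmm")
}

# One EM run from a given initialization.
.em_run <- function(X, K, seg, init, tol, max_iter, reg) {
  means <- init$means
  covariances <- init$covariances
  A <- init$A
  pi0 <- init$pi0
  d <- ncol(X)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0
  regI <- diag(reg, d)
  fb <- NULL
  for (iter in seq_len(max_iter)) {
    ld <- .gaussian_logdens(X, means, covariances)
    fb <- hmm_fb_cpp(ld, log(A), log(pi0), seg)
    ll <- fb$log_likelihood
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    g <- fb$gamma
    Nk <- colSums(g)
    means <- sweep(crossprod(g, X), 1, Nk, "/")
    for (k in seq_len(K)) {
      ctr <- sweep(X, 2, means[k, ])
      covariances[[k]] <- crossprod(ctr * sqrt(g[, k]), ctr * sqrt(g[, k])) /
        Nk[k] + regI
    }
    A <- fb$xi_sum / pmax(rowSums(fb$xi_sum), .Machine$double.eps)
    A <- pmax(A, 1e-12)
    A <- A / rowSums(A)
    pi0 <- pmax(fb$gamma_start / sum(fb$gamma_start), 1e-12)
    pi0 <- pi0 / sum(pi0)
  }
  list(means = means, covariances = covariances, A = A, pi0 = pi0,
       log_likelihood = ll_trace[length(ll_trace)], ll_trace = ll_trace,
       converged = converged, n_iter = iter)
}

#' Fit a K-state multivariate Gaussian HMM by EM
#'
#' Baum-Welch from `n_restarts` initializations (k-means centres for the
#' state means, pooled covariance, uniform chain; restarts beyond the
#' first jitter the means), returning the restart with the highest
#' log-likelihood. Covariances are regularized by adding
#' `1e-6 * mean feature variance` to the diagonal. The per-iteration
#' log-likelihood is nondecreasing (EM guarantee) and is retained in
#' `ll_trace`.
#'
#' @param observations numeric matrix, T x d (T >= 10 K).
#' @param K number of states.
#' @param n_restarts number of EM initializations (default 5).
#' @param seed integer seed (k-means and jitter draws).
#' @param tol stop when the log-likelihood improves by less than this
#'   (default 1e-4).
#' @param max_iter maximum EM iterations per restart (default 100).
#' @param segments optional length-T segment labels; the chain restarts at
#'   each boundary.
#' @return Object of class `gaussian_hmm`.
#' @export
fit_gaussian_hmm <- function(observations, K, n_restarts = 5, seed = 1,
                             tol = 1e-4, max_iter = 100, segments = NULL) {
  X <- as.matrix(observations)
  T_ <- nrow(X); d <- ncol(X)
  if (T_ < 10 * K)
    rns_stop("need at least 10 K observations to fit the HMM",
             "rns_config_error")
  seg <- .seg_codes(segments, T_)
  reg <- 1e-6 * mean(apply(X, 2, var))
  if (!is.finite(reg) || reg <= 0) reg <- 1e-8
  pooled <- cov(X) + diag(reg, d)
  col_sd <- apply(X, 2, sd)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    km <- tryCatch(kmeans(X, centers = K, nstart = 3),
                   error = function(e) NULL)
    means <- if (is.null(km)) X[sample(T_, K), , drop = FALSE] else
      km$centers
    if (r > 1)
      means <- means + matrix(rnorm(K * d, 0, 0.2) *
                                rep(col_sd, each = K), K, d)
    init <- list(means = means,
                 covariances = rep(list(pooled), K),
                 A = matrix(1 / K, K, K),
                 pi0 = rep(1 / K, K))
    run <- .em_run(X, K, seg, init, tol, max_iter, reg)
    if (is.null(best) || run$log_likelihood > best$log_likelihood)
      best <- run
  }
  if (!best$converged)
    warning("EM did not converge within max_iter; returning best restart")
  .make_hmm(K, best$pi0, best$A, best$means, best$covariances,
            best$log_likelihood, best$converged, best$n_iter,
            best$ll_trace, seed)
}

#' Relabel HMM states for identifiability
#'
#' Two-state models: state 2 (high risk) is the state with the largest mean
#' LE count per decoded hour; state 1 is the remaining state. Three-state
#' models: state 3 by largest mean LE, state 2 by the greatest mean shifted
#' phase (unweighted over all bands) among the remaining two, state 1 the
#' remainder. Exact ties are broken by the larger mean IEA count (logged).
#' All model fields are permuted consistently; the permuted model's
#' likelihood is unchanged.
#'
#' @param model a `gaussian_hmm`.
#' @param decoded_states integer state labels (pre-relabeling) per hour.
#' @param le_counts hourly LE counts, aligned to `decoded_states`.
#' @param shifted_phases matrix of shifted band phases (needed for K = 3).
#' @param iea_counts hourly IEA counts (tie-break; optional).
#' @return The relabeled `gaussian_hmm`, with attribute `"permutation"`
#'   (`perm[new] = old`).
#' @export
relabel_states <- function(model, decoded_states, le_counts,
                           shifted_phases = NULL, iea_counts = NULL) {
  K <- model$K
  stopifnot(length(decoded_states) == length(le_counts))
  mean_by_state <- function(x) {
    vapply(seq_len(K), function(k) {
      h <- decoded_states == k
      if (!any(h)) -Inf else mean(x[h])
    }, 0)
  }
  mean_le <- mean_by_state(le_counts)
  tie_stat <- if (is.null(iea_counts)) rep(0, K) else
    mean_by_state(iea_counts)
  ord_le <- order(mean_le, tie_stat)
  if (any(duplicated(mean_le[is.finite(mean_le)])))
    message("tie in mean LE broken by mean IEA")
  if (K == 2) {
    perm <- ord_le  # perm[new] = old; largest mean LE last (state 2)
  } else if (K == 3) {
    high <- ord_le[K]
    rest <- setdiff(seq_len(K), high)
    if (is.null(shifted_phases))
      rns_stop("shifted_phases required to relabel a 3-state model",
               "rns_config_error")
    mp <- vapply(rest, function(k) {
      h <- decoded_states == k
      if (!any(h)) -Inf else mean(shifted_phases[h, , drop = FALSE])
    }, 0)
    o <- order(mp, tie_stat[rest])
    perm <- c(rest[o[1]], rest[o[2]], high)
  } else {
    perm <- seq_len(K)
  }
  out <- model
  out$initial_probs <- model$initial_probs[perm]
  out$transition_matrix <- model$transition_matrix[perm, perm, drop = FALSE]
  out$means <- model$means[perm, , drop = FALSE]
  out$covariances <- model$covariances[perm]
  attr(out, "permutation") <- perm
  out
}

#' Select the number of states by AIC
#'
#' Per patient: the K with the smaller AIC. Cohort scope: the K minimizing
#' the sum of per-patient AICs. The full AIC table is returned.
#'
#' @param fits either a list of `gaussian_hmm` fits named by K (per-patient
#'   scope) or a list of such lists, one element per patient (cohort
#'   scope).
#' @param scope `"patient"` or `"cohort"`.
#' @return List with `K` (chosen state count) and `aic_table` (data.frame).
#' @export
select_state_count <- function(fits, scope = c("patient", "cohort")) {
  scope <- match.arg(scope)
  if (scope == "patient") fits <- list(fits)
  Ks <- sort(unique(unlist(lapply(fits, names))))
  tab <- lapply(seq_along(fits), function(i) {
    aics <- vapply(Ks, function(k) {
      f <- fits[[i]][[k]]
      if (is.null(f)) rns_stop(sprintf("missing fit for K = %s", k),
                               "rns_config_error")
      f$aic
    }, 0)
    data.frame(patient = i, K = as.integer(Ks), aic = aics)
  })
  tab <- do.call(rbind, tab)
  totals <- tapply(tab$aic, tab$K, sum)
  list(K = as.integer(names(totals)[which.min(totals)]),
       aic_table = tab, total_aic = totals)
}

#' Decode risk states by smoothed posterior
#'
#' Per-hour posterior decoding (argmax of the forward-backward smoothed
#' posterior), returning the state sequence with the full posterior matrix.
#'
#' @param model a relabeled `gaussian_hmm`.
#' @param observations T x d feature matrix.
#' @param segments optional segment labels.
#' @param hours optional hour indices (defaults to 1..T).
#' @return List of class `risk_state_sequence` with `hours`, `state`
#'   (integer; K = high risk) and `posterior` (T x K).
#' @export
decode_states <- function(model, observations, segments = NULL,
                          hours = NULL) {
  fb <- log_forward_backward(model, observations, segments)
  st <- max.col(fb$posterior, ties.method = "first")
  structure(list(hours = if (is.null(hours)) seq_len(nrow(fb$posterior))
                 else hours,
                 state = st, posterior = fb$posterior,
                 log_likelihood = fb$log_likelihood),
            class = "risk_state_sequence")
}

#' Validate decoded risk states against hourly counts
#'
#' Two-sided Wilcoxon rank-sum tests comparing hourly LE and IEA counts
#' between the decoded low- and high-risk states at the 0.05 level; the
#' validation passes when the high-risk state has the greater mean of each
#' count and both tests are significant.
#'
#' @param states a `risk_state_sequence` (two-state, relabeled) or integer
#'   vector of 1/2 labels.
#' @param le_counts,iea_counts hourly counts aligned to the states.
#' @param alpha significance level (default 0.05).
#' @param min_hours fewer decoded hours than this in either state marks the
#'   report unreliable (default 10).
#' @return List of class `state_validation_report`.
#' @export
validate_risk_states <- function(states, le_counts, iea_counts,
                                 alpha = 0.05, min_hours = 10) {
  st <- if (inherits(states, "risk_state_sequence")) states$state else states
  stopifnot(length(st) == length(le_counts),
            length(st) == length(iea_counts))
  n_by <- table(factor(st, levels = 1:2))
  unreliable <- any(n_by < min_hours)
  mean_le <- tapply(le_counts, factor(st, levels = 1:2), mean)
  mean_iea <- tapply(iea_counts, factor(st, levels = 1:2), mean)
  p_le <- p_iea <- NA_real_
  if (!unreliable) {
    p_le <- suppressWarnings(
      wilcox.test(le_counts[st == 1], le_counts[st == 2])$p.value)
    p_iea <- suppressWarnings(
      wilcox.test(iea_counts[st == 1], iea_counts[st == 2])$p.value)
  }
  passed <- !unreliable && !is.na(p_le) && !is.na(p_iea) &&
    p_le < alpha && p_iea < alpha &&
    isTRUE(mean_le[2] > mean_le[1]) && isTRUE(mean_iea[2] > mean_iea[1])
  structure(list(mean_le_per_hour = mean_le, mean_iea_per_hour = mean_iea,
                 rank_sum_p_le = p_le, rank_sum_p_iea = p_iea,
                 alpha = alpha, n_hours_by_state = as.vector(n_by),
                 unreliable = unreliable, passed = passed),
            class = "state_validation_report")
}

#' Serialize a fitted HMM to JSON
#'
#' @param model a `gaussian_hmm`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_hmm_json <- function(model, path) {
  obj <- list(K = model$K, d = model$d,
              initial_probs = model$initial_probs,
              transition_matrix = model$transition_matrix,
              means = model$means,
              covariances = model$covariances,
              log_likelihood = model$log_likelihood,
              n_params = model$n_params, aic = model$aic,
              converged = model$converged, n_iter = model$n_iter,
              seed = model$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
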