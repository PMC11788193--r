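# Independent oracles and small fixture builders, kept deliberately naive:
# exhaustive path enumeration for HMM inference, closed-form contingency
# odds ratios, and a tiny multivariate-normal sampler.

# Multivariate normal draws via Cholesky (no package dependency).
rmvn <- function(n, mean, sigma) {
  d <- length(mean)
  z <- matrix(rnorm(n * d), n, d)
  sweep(z %*% chol(sigma), 2, mean, "+")
}

mvn_logdens_naive <- function(x, mean, sigma) {
  d <- length(mean)
  -0.5 * (d * log(2 * pi) + determinant(sigma)$modulus[1] +
            mahalanobis(matrix(x, 1), mean, sigma))
}

# All K^T state paths.
all_paths <- function(T_, K) {
  as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
}

# Brute-force log-likelihood, smoothed posteriors and best path by
# enumerating every state sequence.
enumerate_hmm <- function(model, X) {
  T_ <- nrow(X); K <- model$K
  paths <- all_paths(T_, K)
  ld <- sapply(seq_len(K), function(k)
    sapply(seq_len(T_), function(t)
      mvn_logdens_naive(X[t, ], model$means[k, ], model$covariances[[k]])))
  logjoint <- apply(paths, 1, function(p) {
    lp <- log(model$initial_probs[p[1]]) + ld[1, p[1]]
    for (t in seq_len(T_ - 1)) {
      lp <- lp + log(model$transition_matrix[p[t], p[t + 1]]) +
        ld[t + 1, p[t + 1]]
    }
    lp
  })
  m <- max(logjoint)
  ll <- m + log(sum(exp(logjoint - m)))
  w <- exp(logjoint - ll)
  post <- matrix(0, T_, K)
  for (t in seq_len(T_))
    for (k in seq_len(K))
      post[t, k] <- sum(w[paths[, t] == k])
  list(log_likelihood = ll, posterior = post,
       viterbi = paths[which.max(logjoint), ])
}

# A random valid Gaussian HMM for oracle tests.
random_hmm <- function(K, d, seed) {
  set.seed(seed)
  A <- matrix(runif(K * K, 0.2, 1), K)
  A <- A / rowSums(A)
  p0 <- runif(K, 0.2, 1)
  covs <- lapply(seq_len(K), function(k) {
    M <- matrix(rnorm(d * d, 0, 0.3), d)
    crossprod(M) + diag(d)
  })
  list(K = K, d = d, initial_probs = p0 / sum(p0), transition_matrix = A,
       means = matrix(rnorm(K * d, 0, 2), K), covariances = covs)
}

# Clean two-state data: latent chain from the synthetic-data module's
# logistic chain machinery (no cycles, no stimulation effects), Gaussian
# emissions with configurable mean separation (in within-state sd units).
sim_two_state_gaussian <- function(T_, d, sep = 4, dwell = c(60, 60),
                                   seed = 1) {
  cfg <- simulation_config(n_patients = 1, hours_per_patient = T_,
                           state_dwell_low = dwell[1],
                           state_dwell_high = dwell[2],
                           phase_coupling = 0, seed = seed)
  comp <- matrix(0, T_, length(cfg$cycle_periods))
  cats <- categorize_stim_params(numeric(T_), numeric(T_), numeric(T_),
                                 numeric(T_))
  chain <- simulate_state_chain(cfg, comp, cats, seed = seed)
  st <- chain$states
  set.seed(seed + 1)
  mu <- rbind(rep(0, d), rep(sep, d))
  X <- matrix(rnorm(T_ * d), T_, d) + mu[st, ]
  list(X = X, states = st,
       true_A = matrix(c(1 - 1 / dwell[1], 1 / dwell[1],
                         1 / dwell[2], 1 - 1 / dwell[2]), 2, byrow = TRUE))
}

# Closed-form log odds ratio of a 2x2 table.
logodds_2x2 <- function(x, y) {
  n11 <- sum(x == 1 & y == 1); n10 <- sum(x == 1 & y == 0)
  n01 <- sum(x == 0 & y == 1); n00 <- sum(x == 0 & y == 0)
  log((n11 * n00) / (n10 * n01))
}

# Small raw record table for preprocessing/design tests.
make_records <- function(n, patient_id = "P1", segment_id = "S1",
                         hour_start = 1, cd = 0.5, fq = 200, pw = 160,
                         bd = 100, detections = 5, stim = TRUE,
                         montage = "monopolar_leadtolead",
                         location = "mesiotemporal") {
  data.frame(patient_id = patient_id, epoch_id = segment_id,
             segment_id = segment_id,
             hour_index = seq(hour_start, length.out = n),
             iea_count = 40L, le_count = 0L,
             n_therapy_detections = detections,
             charge_density = cd, frequency = fq, pulse_width = pw,
             burst_duration = bd, stim_enabled = stim,
             montage = montage, location = location)
}
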