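# Shared fixtures: small, fast generator configurations.

# one participant, defaults otherwise
quick_config <- function(..., seed = 101L) {
  generator_config(n_participants = 1, seed = seed, ...)
}

# torque-direction matrix with clean one-axis rows, handy for arithmetic
unit_directions <- function(ab = c(4, 0, 0, 0), er = c(0, 0, 3, 0)) {
  m <- rbind(EF = c(0, 0, 0, 5), AB = ab, ER = er, HAB = c(0, 4, 0, 0),
             EE = c(0, 0, 0, -5), AD = c(-4, 0, 0, 0), IR = c(0, 0, -3, 0),
             HAD = c(0, -4, 0, 0))
  colnames(m) <- torque_dof_names()
  m
}

# brute-force Gaussian classifier with pooled covariance: the independent
# oracle for LDA predictions. Recomputes means/covariance from scratch and
# evaluates full log-densities with solve(), no shared code path.
oracle_gaussian_predict <- function(xtrain, g, xtest, lambda = 0) {
  classes <- sort(unique(g))
  K <- length(classes)
  D <- ncol(xtrain)
  mus <- lapply(classes, function(cl) colMeans(xtrain[g == cl, , drop = FALSE]))
  S <- matrix(0, D, D)
  for (k in seq_len(K)) {
    xc <- sweep(xtrain[g == classes[k], , drop = FALSE], 2, mus[[k]])
    S <- S + t(xc) %*% xc
  }
  S <- S / (nrow(xtrain) - K) + diag(lambda, D)
  Sinv <- solve(S)
  logdet <- determinant(S, logarithm = TRUE)$modulus
  apply(xtest, 1, function(x) {
    ll <- vapply(seq_len(K), function(k) {
      d <- x - mus[[k]]
      -0.5 * logdet - 0.5 * drop(t(d) %*% Sinv %*% d) + log(1 / K)
    }, 0)
    classes[which.max(ll)]
  })
}

# brute-force segmentation oracle: per-sample boolean scan + run-length walk
oracle_segments <- function(primary, mvt, threshold = 0.2) {
  above <- primary > threshold * mvt
  starts <- integer(0); ends <- integer(0)
  in_run <- FALSE
  for (i in seq_along(above)) {
    if (above[i] && !in_run) { starts <- c(starts, i); in_run <- TRUE }
    if (!above[i] && in_run) { ends <- c(ends, i - 1L); in_run <- FALSE }
  }
  if (in_run) ends <- c(ends, length(above))
  data.frame(start = starts, end = ends)
}

# cache cohort evaluations shared between property and acceptance tests
cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(key, maker) {
  if (is.null(cohort_cache[[key]])) cohort_cache[[key]] <- maker()
  cohort_cache[[key]]
}

eval_coupling_cohort <- function(coupling, feature_sets, n = 2,
                                 seed = 211L, label = "", ...) {
  key <- paste(coupling, paste(feature_sets, collapse = "+"), n, seed,
               label, sep = "|")
  cached_cohort(key, function() {
    cfg <- generator_config(n_participants = n, synergy_coupling = coupling,
                            seed = seed, ...)
    evaluate_cohort(generate_dataset(cfg), feature_sets = feature_sets)
  })
}
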