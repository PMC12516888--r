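# Independent oracles used by the property and acceptance tests. These are
# deliberately written as plain loops, separate from the package
# implementations they check.

# Fuzzy C-means fixed-point oracle: alternate membership and centroid
# updates from a given start until the objective stabilizes.
fcm_oracle <- function(X, init, m, tol = 1e-7, max_iter = 500) {
  k <- nrow(init)
  n <- nrow(X)
  C <- init
  sqd <- function(C) {
    D <- matrix(0, k, n)
    for (i in 1:k) for (j in 1:n) D[i, j] <- sum((X[j, ] - C[i, ])^2)
    D
  }
  J_prev <- Inf
  trace <- numeric(0)
  for (it in 1:max_iter) {
    D <- sqd(C)
    U <- matrix(0, k, n)
    for (j in 1:n) {
      if (any(D[, j] < 1e-24)) {
        hits <- which(D[, j] < 1e-24)
        U[hits, j] <- 1 / length(hits)
      } else {
        for (i in 1:k) U[i, j] <- 1 / sum((D[i, j] / D[, j])^(1 / (m - 1)))
      }
    }
    for (i in 1:k) {
      w <- U[i, ]^m
      C[i, ] <- colSums(X * w) / sum(w)
    }
    J <- sum(U^m * sqd(C))
    trace <- c(trace, J)
    if (is.finite(J_prev) && abs(J_prev - J) < tol) break
    J_prev <- J
  }
  list(U = U, centers = C, objective = J, trace = trace)
}

# Fine-grid oracle for the ARDS flag: sample the LOCF value of both series
# on a dense time grid and measure the longest run where the joint
# condition holds.
ards_oracle <- function(pf, peep, start, duration_h = 24, min_span_h = 8,
                        dt = 0.01) {
  if (nrow(pf) == 0 || nrow(peep) == 0) return(NA_real_)
  grid <- seq(start, start + duration_h - dt, by = dt)
  locf_at <- function(times, values, t) {
    o <- order(times)
    idx <- findInterval(t, times[o])
    ifelse(idx == 0, NA_real_, values[o][pmax(idx, 1)])
  }
  v1 <- locf_at(pf$time_h, pf$value, grid)
  v2 <- locf_at(peep$time_h, peep$value, grid)
  ok <- !is.na(v1) & !is.na(v2) & v1 <= 300 & v2 >= 5
  r <- rle(ok)
  runs <- r$lengths[r$values] * dt
  if (length(runs) == 0) return(0)
  as.numeric(max(runs) >= min_span_h - dt / 2)
}

# random step series on a half-hour grid for flag-rule fuzzing
random_step_series <- function(n_samples, lo, hi, start = 0, end = 24) {
  times <- sort(sample(seq(start, end, by = 0.5), n_samples))
  data.frame(time_h = times, value = runif(n_samples, lo, hi))
}

# Shapley permutation-average oracle: enumerate all orderings, average
# marginal contributions with interventional (background-mean) values.
shapley_perm_oracle <- function(f, x, background) {
  k <- length(x)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  val <- function(members) {
    M <- background
    if (length(members)) M[, members] <- rep(x[members], each = nrow(M))
    mean(f(M))
  }
  phi <- setNames(numeric(k), names(x))
  all_p <- perms(seq_len(k))
  for (p in all_p) {
    members <- integer(0)
    prev <- val(members)
    for (i in p) {
      members <- c(members, i)
      cur <- val(members)
      phi[i] <- phi[i] + (cur - prev) / length(all_p)
      prev <- cur
    }
  }
  phi
}

# small helpers shared across model tests
tiny_spec <- function() {
  boosted_tree_spec(grid = data.frame(max_depth = 2L, eta = 0.1),
                    nrounds = 100L, early_stopping_rounds = 10L)
}

make_planted_cohort <- function(seed, n = 800L) {
  sim <- simulate_corpus(corpus_sim_config(seed = seed))
  sem <- fit_semantic_clusters(
    sim$corpus, fcm_config(seed = seed, n_restarts = 3L))
  pats <- simulate_patients(
    patient_sim_config(n_patients = n, seed = seed), sim$truth)
  list(sim = sim, sem = sem, X = pats$features, y = pats$labels,
       truth = pats$truth)
}
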