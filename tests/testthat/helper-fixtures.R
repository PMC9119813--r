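# Shared fixtures, built in code.

# Scaled-down generator config for fast end-to-end tests.
small_config <- function(n = 2000, seed = 1) {
  default_generator_config(n_patients = n, seed = seed)
}

# Single-ethnicity, single-subgroup config with near-degenerate spread.
degenerate_config <- function(n = 200, sd = 1e-9) {
  cfg <- default_generator_config(n_patients = n)
  cfg$ethnicity_mix <- c(white = 1, south_asian = 0, black = 0, mixed_other = 0)
  prof <- cfg$profiles[cfg$profiles$ethnicity == "white" &
                         cfg$profiles$subgroup == "MARD", ]
  prof$share <- 1
  prof$age_sd <- prof$hba1c_sd <- prof$bmi_sd <- sd
  other <- cfg$profiles[cfg$profiles$ethnicity != "white", ]
  cfg$profiles <- rbind(prof, other)
  cfg
}

# Small three-class indicator sample with known, well-separated parameters.
toy_indicators <- function(n = 600, seed = 42, sep = 6) {
  set.seed(seed)
  k <- sample(1:2, n, replace = TRUE, prob = c(0.6, 0.4))
  age <- rnorm(n, c(50, 50 + sep * 10)[k], 10)
  hba1c <- rnorm(n, c(7, 7)[k], 1)
  bmi <- rnorm(n, c(28, 28)[k], 4)
  sex <- rbinom(n, 1, c(0.5, 0.5)[k])
  list(X = cbind(age = age, hba1c = hba1c, bmi = bmi, sex_male = sex),
       truth = k)
}

# Direct (loop-based) mixture log-likelihood used as an independent check;
# deliberately shares no code with the package's vectorised implementation.
direct_loglik <- function(X, weights, means, sds, p_male) {
  ll <- 0
  for (i in seq_len(nrow(X))) {
    li <- 0
    for (k in seq_along(weights)) {
      fk <- weights[k] *
        dnorm(X[i, "age"], means[k, 1], sds[k, 1]) *
        dnorm(X[i, "hba1c"], means[k, 2], sds[k, 2]) *
        dnorm(X[i, "bmi"], means[k, 3], sds[k, 3]) *
        dbinom(X[i, "sex_male"], 1, p_male[k])
      li <- li + fk
    }
    ll <- ll + log(li)
  }
  ll
}

# Independent maximiser of the same floored likelihood via multi-start
# general-purpose optimisation (the brute-force oracle for tiny instances):
# Nelder-Mead exploration from partition-moment and random starts, then
# quasi-Newton polish of the leading candidates.
oracle_max_loglik <- function(X, K, n_starts = 10, seed = 1) {
  cont <- X[, c("age", "hba1c", "bmi"), drop = FALSE]
  sd_floor <- sqrt(1e-4 * apply(cont, 2, var))
  obj <- function(theta) {
    w <- exp(theta[1:K]); w <- w / sum(w)
    means <- matrix(theta[K + 1:(3 * K)], K, 3)
    sds <- matrix(sd_floor, K, 3, byrow = TRUE) +
      exp(matrix(theta[4 * K + 1:(3 * K)], K, 3))
    p <- plogis(theta[7 * K + 1:K])
    -direct_loglik(X, w, means, sds, p)
  }
  moment_start <- function(part) {
    mu0 <- sapply(1:3, function(j) tapply(cont[, j], part, mean))
    s0 <- sapply(1:3, function(j) {
      v <- tapply(cont[, j], part, sd)
      v[is.na(v) | v < 0.05] <- 0.05
      v
    })
    p0 <- tapply(X[, "sex_male"], part, mean)
    c(rep(0, K), as.numeric(mu0), as.numeric(log(s0)),
      qlogis(pmin(pmax(p0, 0.05), 0.95)))
  }
  set.seed(seed)
  rng <- apply(cont, 2, range)
  starts <- list()
  for (s in 1:3) {
    km <- tryCatch(kmeans(scale(cont), K, nstart = 5), error = function(e) NULL)
    if (!is.null(km) && min(table(km$cluster)) >= 2) {
      starts[[length(starts) + 1]] <- moment_start(km$cluster)
    }
    part <- sample(rep_len(seq_len(K), nrow(X)))
    starts[[length(starts) + 1]] <- moment_start(part)
  }
  for (s in seq_len(n_starts)) {
    mu0 <- sapply(1:3, function(j) runif(K, rng[1, j], rng[2, j]))
    starts[[length(starts) + 1]] <-
      c(rnorm(K, 0, 0.5), as.numeric(mu0),
        log(pmax(apply(cont, 2, sd), 0.1))[rep(1:3, each = K)] +
          rnorm(3 * K, 0, 0.3),
        rnorm(K, 0, 0.5))
  }
  cand <- lapply(starts, function(theta0) {
    tryCatch(optim(theta0, obj, method = "Nelder-Mead",
                   control = list(maxit = 1000, reltol = 1e-10)),
             error = function(e) list(value = Inf, par = theta0))
  })
  vals <- vapply(cand, function(f) f$value, numeric(1))
  best <- -Inf
  for (i in order(vals)[seq_len(min(3, length(vals)))]) {
    polish <- tryCatch(
      optim(cand[[i]]$par, obj, method = "BFGS",
            control = list(maxit = 300, reltol = 1e-14)),
      error = function(e) cand[[i]])
    polish2 <- tryCatch(
      optim(polish$par, obj, method = "Nelder-Mead",
            control = list(maxit = 2000, reltol = 1e-13)),
      error = function(e) polish)
    best <- max(best, -polish$value, -polish2$value)
  }
  best
}

# Breslow partial log-likelihood for a single binary covariate, written
# directly from the definition (grid-search oracle for Cox fits).
breslow_pll <- function(beta, time, event, z) {
  ll <- 0
  for (i in which(event == 1)) {
    at_risk <- time >= time[i]
    ll <- ll + beta * z[i] - log(sum(exp(beta * z[at_risk])))
  }
  ll
}
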