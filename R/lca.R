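LCA_CONTINUOUS <- c("age", "hba1c", "bmi")
LCA_BINARY <- "sex_male"

#' Build the latent-class indicator matrix from a baseline table
#'
#' Extracts the four diagnosis-time indicators (age in years, HbA1c in NGSP
#' percent, BMI in kg/m2, male sex as 0/1) used to derive diabetes
#' subgroups.  Values outside plausible physiological bounds (age 18-110,
#' HbA1c 3.5-20, BMI 13-80) trigger a warning.
#'
#' @param baseline baseline table from [build_baseline_table()], or any
#'   data.frame with columns `age`, `hba1c_pct` (or `hba1c`), `bmi`,
#'   `sex_male`.
#' @return numeric matrix with columns `age`, `hba1c`, `bmi`, `sex_male`;
#'   rownames are patient ids when available.
#' @export
indicator_matrix <- function(baseline) {
  hba <- baseline[["hba1c_pct"]] %||% baseline[["hba1c"]]
  X <- cbind(age = as.numeric(baseline$age), hba1c = as.numeric(hba),
             bmi = as.numeric(baseline$bmi),
             sex_male = as.numeric(baseline$sex_male))
  if (!is.null(baseline$id)) rownames(X) <- baseline$id
  bounds <- rbind(age = c(18, 110), hba1c = c(3.5, 20), bmi = c(13, 80))
  for (j in rownames(bounds)) {
    out_of_range <- !is.na(X[, j]) & (X[, j] < bounds[j, 1] | X[, j] > bounds[j, 2])
    if (any(out_of_range)) {
      warning(sum(out_of_range), " ", j, " value(s) outside plausible bounds")
    }
  }
  X
}

# Class-conditional log density of each row under each class (no weights).
# Continuous indicators are independent Gaussians; sex is Bernoulli.
lca_log_density <- function(model, X, cols = colnames(X)) {
  n <- nrow(X)
  K <- model$K
  logf <- matrix(0, n, K)
  for (j in intersect(LCA_CONTINUOUS, cols)) {
    for (k in seq_len(K)) {
      logf[, k] <- logf[, k] +
        stats::dnorm(X[, j], model$means[k, j], model$sds[k, j], log = TRUE)
    }
  }
  if (LCA_BINARY %in% cols) {
    s <- X[, LCA_BINARY]
    for (k in seq_len(K)) {
      p <- min(max(model$p_male[k], 1e-12), 1 - 1e-12)
      logf[, k] <- logf[, k] + s * log(p) + (1 - s) * log1p(-p)
    }
  }
  logf
}

row_log_sum_exp <- function(m) {
  mx <- m[, 1]
  for (k in seq_len(ncol(m))[-1]) mx <- pmax(mx, m[, k])
  mx + log(rowSums(exp(m - mx)))
}

#' Fit the mixed-indicator latent-class model by EM
#'
#' Maximises the observed-data log-likelihood of a K-class mixture in which,
#' within each class, age, HbA1c and BMI are independent Gaussians and sex is
#' Bernoulli (local independence).  The E-step computes responsibilities in
#' log space; the M-step updates weights, class means/SDs (with a variance
#' floor of 1e-4 times each column's marginal variance) and class male
#' probabilities.  Each restart initialises from a k-means partition of the
#' standardised continuous indicators under a derived seed; the restart with
#' the best converged log-likelihood wins, ties resolving to the earliest
#' restart.
#'
#' @param X indicator matrix from [indicator_matrix()]; rows with any
#'   missing indicator are dropped from fitting (complete-case).
#' @param K number of classes (>= 1).
#' @param seed integer master seed for the restarts.
#' @param restarts number of seeded initialisations.
#' @param tol relative log-likelihood change declaring convergence.
#' @param max_iter maximum EM iterations per restart.
#' @return object of class `lca_model`: `K`, `weights`, `means` (K x 3),
#'   `sds`, `p_male`, `loglik`, `n_parameters` (= 8K - 1), `n_used`,
#'   `converged`, `n_restarts`, `best_restart`, `ll_trace`.
#' @export
fit_lca <- function(X, K, seed = 1, restarts = 10, tol = 1e-8, max_iter = 500) {
  stopifnot(K >= 1, restarts >= 1)
  X <- as.matrix(X[, c(LCA_CONTINUOUS, LCA_BINARY)])
  keep <- stats::complete.cases(X)
  X <- X[keep, , drop = FALSE]
  n <- nrow(X)
  if (n <= 8 * K) stop("under-identified: need more than 8K rows, have ", n)

  var_floor <- 1e-4 * apply(X[, LCA_CONTINUOUS, drop = FALSE], 2, stats::var)
  var_floor <- pmax(var_floor, 1e-12)
  n_distinct <- nrow(unique(X))
  degenerate <- n_distinct < K

  # each restart runs a short EM burn-in; only the best burn-in likelihood
  # is polished to full convergence (the standard emEM economy)
  burn <- min(50L, max_iter)
  best <- NULL
  for (r in seq_len(restarts)) {
    part <- lca_init_partition(X, K, derive_seed(seed, 100L + r))
    gamma0 <- matrix(0, n, K)
    gamma0[cbind(seq_len(n), part)] <- 1
    fit <- lca_em_run(X, K, gamma0, var_floor, tol,
                      if (restarts == 1) max_iter else burn)
    if (is.null(best) || fit$loglik > best$loglik + 1e-10) {
      best <- fit
      best$best_restart <- r
    }
  }
  if (restarts > 1 && !best$converged) {
    polish <- lca_em_run(X, K, best$gamma, var_floor, tol, max_iter)
    polish$ll_trace <- c(best$ll_trace, polish$ll_trace)
    polish$best_restart <- best$best_restart
    best <- polish
  }

  model <- structure(list(
    K = K, weights = best$weights, means = best$means, sds = best$sds,
    p_male = best$p_male, loglik = best$loglik,
    n_parameters = 8L * K - 1L, n_used = n,
    converged = best$converged && !degenerate,
    n_restarts = restarts, best_restart = best$best_restart,
    seed = seed, ll_trace = best$ll_trace
  ), class = "lca_model")
  if (degenerate) {
    warning("fewer distinct rows than classes; fit reported as non-converged")
  }
  model
}

lca_init_partition <- function(X, K, seed) {
  if (K == 1) return(rep(1L, nrow(X)))
  set.seed(seed)
  Z <- scale(X[, LCA_CONTINUOUS, drop = FALSE])
  Z[, apply(Z, 2, function(z) any(!is.finite(z)))] <- 0
  km <- tryCatch(stats::kmeans(Z, centers = K, nstart = 1, iter.max = 50),
                 error = function(e) NULL)
  if (is.null(km)) sample.int(K, nrow(X), replace = TRUE) else km$cluster
}

lca_em_run <- function(X, K, gamma0, var_floor, tol, max_iter) {
  n <- nrow(X)
  Xc <- X[, LCA_CONTINUOUS, drop = FALSE]
  Xc2 <- Xc^2
  s <- X[, LCA_BINARY]
  gamma <- gamma0

  m_step <- function(gamma) {
    nk <- pmax(colSums(gamma), 1e-10)
    means <- crossprod(gamma, Xc) / nk
    v <- crossprod(gamma, Xc2) / nk - means^2
    sds <- sqrt(pmax(sweep(v, 2, var_floor, pmax), 1e-12))
    p_male <- as.numeric(crossprod(gamma, s)) / nk
    list(weights = nk / n, means = means, sds = sds,
         p_male = pmin(pmax(p_male, 1e-10), 1 - 1e-10))
  }

  # class-wise log joint density + log weight, via two matrix products:
  # sum_j [-x^2/(2s^2) + x*m/s^2 - m^2/(2s^2) - log s] + Bernoulli term
  log_joint <- function(par) {
    inv_v <- 1 / par$sds^2                            # K x 3
    C1 <- t(-0.5 * inv_v)                             # 3 x K
    C2 <- t(par$means * inv_v)                        # 3 x K
    logit_p <- log(par$p_male) - log1p(-par$p_male)
    const <- -0.5 * rowSums(par$means^2 * inv_v) - rowSums(log(par$sds)) -
      1.5 * log(2 * pi) + log1p(-par$p_male) + log(par$weights)
    Xc2 %*% C1 + Xc %*% C2 + outer(s, logit_p) + rep(const, each = n)
  }

  par <- m_step(gamma)
  ll_prev <- -Inf
  ll_trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    a <- log_joint(par)
    lse <- row_log_sum_exp(a)
    ll <- sum(lse)
    ll_trace[it] <- ll
    if (ll < ll_prev - 1e-8) {
      warning("log-likelihood decreased by ", format(ll_prev - ll),
              " at iteration ", it)
    }
    if (is.finite(ll_prev) && abs(ll - ll_prev) / abs(ll_prev) < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
    ll_prev <- ll
    gamma <- exp(a - lse)
    par <- m_step(gamma)
  }
  c(par, list(loglik = ll, converged = converged,
              ll_trace = ll_trace[seq_len(it)], gamma = gamma))
}

#' Posterior class membership probabilities
#'
#' Computed in log space for numerical safety.  By default rows with any
#' missing indicator are unassignable and return `NA`; with
#' `partial = TRUE` the posterior uses only each row's observed indicators
#' (the post-hoc assignment route for patients excluded from fitting).
#'
#' @param model fitted `lca_model`.
#' @param X indicator matrix with the model's columns.
#' @param partial use available indicators for incomplete rows.
#' @return n x K matrix of posteriors; each complete row sums to 1.  The
#'   logical attribute `"partial_row"` marks rows assigned from a subset of
#'   indicators.
#' @export
lca_responsibilities <- function(model, X, partial = FALSE) {
  X <- as.matrix(X[, c(LCA_CONTINUOUS, LCA_BINARY), drop = FALSE])
  n <- nrow(X)
  gamma <- matrix(NA_real_, n, model$K)
  complete <- stats::complete.cases(X)
  groups <- if (partial) {
    pat <- apply(!is.na(X), 1, paste, collapse = "")
    split(seq_len(n), pat)
  } else {
    list(which(complete))
  }
  for (rows in groups) {
    if (!length(rows)) next
    cols <- colnames(X)[!is.na(X[rows[1], ])]
    if (!length(cols)) next
    a <- lca_log_density(model, X[rows, , drop = FALSE], cols) +
      rep(log(model$weights), each = length(rows))
    gamma[rows, ] <- exp(a - row_log_sum_exp(a))
  }
  attr(gamma, "partial_row") <- !complete & rowSums(!is.na(gamma)) > 0
  gamma
}

#' Bayesian Information Criterion of a fitted latent-class model
#'
#' `-2 * loglik + n_parameters * log(n_used)` with `n_parameters = 8K - 1`
#' ((K - 1) weights plus, per class, 3 means, 3 SDs and one Bernoulli
#' probability); lower is better.
#'
#' @param model fitted `lca_model`.
#' @return the BIC value.
#' @export
lca_bic <- function(model) {
  if (model$n_used < 2) stop("BIC undefined for fewer than 2 rows")
  -2 * model$loglik + model$n_parameters * log(model$n_used)
}

#' Fit and select the number of latent classes
#'
#' Fits every K in `K_range`, computes per-fit diagnostics, and selects the
#' lowest-BIC model among those passing both classification-quality rules:
#' every class's mean maximum posterior among its assigned members above
#' 0.70, and every class weight above 1% of the fitted patients.  If no
#' model passes, the lowest-BIC model is returned flagged as failing.  The
#' strict per-member minimum posterior is also reported, since the
#' published 70% rule admits both readings.
#'
#' @param X indicator matrix.
#' @param K_range integer vector of class counts to compare.
#' @param seed,restarts,tol,max_iter passed to [fit_lca()].
#' @param posterior_rule,share_rule thresholds for the two selection rules.
#' @return list with `model` (selected), `diagnostics` (one row per K) and
#'   `models` (all fits, named by K).
#' @export
select_lca <- function(X, K_range = 2:5, seed = 1, restarts = 10,
                       tol = 1e-8, max_iter = 500,
                       posterior_rule = 0.70, share_rule = 0.01) {
  if (!length(K_range)) stop("K_range is empty")
  models <- list()
  rows <- list()
  for (K in K_range) {
    m <- fit_lca(X, K, seed = seed, restarts = restarts, tol = tol,
                 max_iter = max_iter)
    gamma <- lca_responsibilities(m, X)
    ok <- stats::complete.cases(gamma)
    g <- gamma[ok, , drop = FALSE]
    cl <- max.col(g, ties.method = "first")
    mp <- g[cbind(seq_len(nrow(g)), cl)]
    mean_max_post <- vapply(seq_len(K), function(k) {
      if (any(cl == k)) mean(mp[cl == k]) else NA_real_
    }, numeric(1))
    models[[as.character(K)]] <- m
    rows[[as.character(K)]] <- data.frame(
      K = K, loglik = m$loglik, n_parameters = m$n_parameters,
      bic = lca_bic(m),
      min_mean_max_posterior = min(mean_max_post, na.rm = TRUE),
      min_member_posterior = min(mp),
      min_class_share = min(m$weights),
      passes_posterior_rule = all(!is.na(mean_max_post) & mean_max_post > posterior_rule),
      passes_share_rule = min(m$weights) > share_rule,
      converged = m$converged
    )
  }
  diagnostics <- do.call(rbind, rows)
  rownames(diagnostics) <- NULL
  passing <- diagnostics$passes_posterior_rule & diagnostics$passes_share_rule
  if (any(passing)) {
    sel <- diagnostics$K[passing][which.min(diagnostics$bic[passing])]
  } else {
    warning("no model passes the posterior and share rules; returning lowest-BIC fit")
    sel <- diagnostics$K[which.min(diagnostics$bic)]
  }
  list(model = models[[as.character(sel)]], diagnostics = diagnostics,
       models = models, selected_K = sel, selection_passed = any(passing))
}

#' Assign patients to classes and label classes MARD / MOD / SHD
#'
#' Assignment is the maximum-posterior class (ties to the lowest class
#' index).  With K >= 3 classes, class means are standardised across classes
#' per indicator; the class with the highest standardised HbA1c mean is
#' labelled SHD (severe hyperglycaemic diabetes), the highest standardised
#' BMI mean among the remainder is MOD (mild obesity-related), and the
#' remaining class with the largest weight is MARD (mild age-related); any
#' further classes become `other_k`.  With K < 3 generic `class_k` labels
#' are used.  Rows with incomplete indicators are post-hoc assigned from
#' their observed indicators and flagged.
#'
#' @param model fitted `lca_model`.
#' @param X indicator matrix.
#' @param manual_map optional named character vector (class index ->
#'   label) overriding the automatic labelling.
#' @return list with `mapping` (class -> label), `class` (assigned index per
#'   row), `label` (per row), `posterior` (n x K), `partial` (logical, row
#'   assigned from partial indicators).
#' @export
assign_and_label <- function(model, X, manual_map = NULL) {
  gamma <- lca_responsibilities(model, X, partial = TRUE)
  assignable <- stats::complete.cases(gamma)
  cl <- rep(NA_integer_, nrow(gamma))
  cl[assignable] <- max.col(gamma[assignable, , drop = FALSE], ties.method = "first")

  mapping <- if (!is.null(manual_map)) {
    stats::setNames(as.character(manual_map), names(manual_map) %||% seq_len(model$K))
  } else if (model$K < 3) {
    stats::setNames(paste0("class_", seq_len(model$K)), seq_len(model$K))
  } else {
    z <- scale(model$means)
    shd <- which.max(z[, "hba1c"])
    if (which.max(z[, "bmi"]) == shd) {
      stop("SHD and MOD resolve to the same class; supply manual_map")
    }
    rest <- setdiff(seq_len(model$K), shd)
    mod <- rest[which.max(z[rest, "bmi"])]
    rest <- setdiff(rest, mod)
    mard <- rest[which.max(model$weights[rest])]
    lab <- character(model$K)
    lab[shd] <- "SHD"; lab[mod] <- "MOD"; lab[mard] <- "MARD"
    extras <- setdiff(seq_len(model$K), c(shd, mod, mard))
    lab[extras] <- paste0("other_", seq_along(extras))
    stats::setNames(lab, seq_len(model$K))
  }

  list(mapping = mapping,
       class = cl,
       label = unname(mapping[as.character(cl)]),
       posterior = gamma,
       partial = attr(gamma, "partial_row"))
}

#' Ethnicity-stratified latent-class fits
#'
#' Runs [select_lca()] and [assign_and_label()] on the whole cohort and
#' separately within each requested ethnic stratum (white, South Asian and
#' black by default, mirroring the published analysis; mixed/other and
#' unknown strata are skipped).  Strata with fewer than `50 * max(K_range)`
#' usable rows are skipped with a warning.
#'
#' @param baseline baseline table with clustering indicators and `ethnicity`.
#' @param K_range,seed,restarts passed to [select_lca()].
#' @param strata ethnic strata to fit in addition to `"overall"`.
#' @return named list of per-stratum results, each holding `selection`
#'   (from [select_lca()]) and `assignments` (data.frame id, class, label,
#'   posterior columns).
#' @export
stratified_lca <- function(baseline, K_range = 2:5, seed = 1, restarts = 10,
                           strata = c("white", "south_asian", "black")) {
  out <- list()
  for (st in c("overall", strata)) {
    rows <- if (st == "overall") rep(TRUE, nrow(baseline)) else baseline$ethnicity == st
    sub <- baseline[rows, , drop = FALSE]
    X <- indicator_matrix(sub)
    n_usable <- sum(stats::complete.cases(X))
    if (n_usable < 50 * max(K_range)) {
      warning("stratum '", st, "' has only ", n_usable,
              " usable rows; skipped")
      next
    }
    sel <- select_lca(X, K_range = K_range, seed = seed, restarts = restarts)
    asg <- assign_and_label(sel$model, X)
    assignments <- data.frame(id = sub$id, stratum = st, class = asg$class,
                              label = asg$label, partial = asg$partial,
                              stringsAsFactors = FALSE)
    post <- asg$posterior
    colnames(post) <- paste0("posterior_", seq_len(ncol(post)))
    out[[st]] <- list(selection = sel, assignments = cbind(assignments, post),
                      mapping = asg$mapping)
  }
  out
}

#' Class-profile summary for radar-style display
#'
#' Per class and indicator (age, BMI, HbA1c, proportion male): the raw class
#' mean among assigned patients, and the min-max normalised value
#' `(v - min) / (max - min)` across classes, so the class at the maximum
#' maps to the polygon edge (1) and the minimum to the centre (0).  An
#' indicator constant across classes normalises to 0.5 with a warning.
#'
#' @param baseline baseline table (or any table with `age`, `hba1c_pct`,
#'   `bmi`, `sex_male`).
#' @param label per-row class label aligned with `baseline`.
#' @return long data.frame: `label`, `variable`, `mean`, `normalised`.
#' @export
radar_summary <- function(baseline, label) {
  keep <- !is.na(label)
  baseline <- baseline[keep, , drop = FALSE]
  label <- label[keep]
  labs <- sort(unique(label))
  if (length(labs) < 2) stop("radar summary needs at least 2 classes")
  hba <- baseline[["hba1c_pct"]] %||% baseline[["hba1c"]]
  vars <- list(age = baseline$age, bmi = baseline$bmi, hba1c = hba,
               prop_male = baseline$sex_male)
  rows <- list()
  for (v in names(vars)) {
    mu <- vapply(labs, function(l) mean(vars[[v]][label == l], na.rm = TRUE),
                 numeric(1))
    rng <- range(mu)
    if (diff(rng) == 0) {
      warning("indicator '", v, "' constant across classes; normalised to 0.5")
      norm <- rep(0.5, length(mu))
    } else {
      norm <- (mu - rng[1]) / diff(rng)
    }
    rows[[v]] <- data.frame(label = labs, variable = v, mean = mu,
                            normalised = norm, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
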