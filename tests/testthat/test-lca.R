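fake_model <- function(weights, means, sds, p_male) {
  colnames(means) <- c("age", "hba1c", "bmi")
  colnames(sds) <- c("age", "hba1c", "bmi")
  structure(list(K = length(weights), weights = weights, means = means,
                 sds = sds, p_male = p_male, n_used = 100L,
                 n_parameters = 8L * length(weights) - 1L),
            class = "lca_model")
}

test_that("a one-class fit returns the sample moments", {
  toy <- toy_indicators(n = 300, seed = 7)
  m <- fit_lca(toy$X, K = 1, restarts = 1)
  expect_equal(m$weights, 1)
  expect_equal(as.numeric(m$means), unname(colMeans(toy$X[, 1:3])),
               tolerance = 1e-8)
  n <- nrow(toy$X)
  expect_equal(as.numeric(m$sds),
               unname(apply(toy$X[, 1:3], 2,
                            function(x) sqrt(mean((x - mean(x))^2)))),
               tolerance = 1e-6)
  expect_equal(m$p_male, mean(toy$X[, "sex_male"]), tolerance = 1e-8)
  # log-likelihood equals the direct independent-likelihood evaluation
  expect_equal(m$loglik,
               as.numeric(direct_loglik(toy$X, 1, m$means, m$sds, m$p_male)),
               tolerance = 1e-6)
  expect_equal(m$n_parameters, 7L)
})

test_that("well-separated two-class structure is recovered almost exactly", {
  toy <- toy_indicators(n = 2000, seed = 21, sep = 6)
  m <- fit_lca(toy$X, K = 2, seed = 1, restarts = 5)
  ord <- order(m$means[, "age"])
  expect_lt(abs(m$means[ord[1], "age"] - 50), 0.1 * 10)
  expect_lt(abs(m$means[ord[2], "age"] - 110), 0.1 * 10)
  gamma <- lca_responsibilities(m, toy$X)
  assigned <- max.col(gamma)
  acc <- mean((assigned == ord[2]) == (toy$truth == 2))
  expect_gt(acc, 0.99)
})

test_that("the accepted likelihood trace never decreases", {
  for (s in 1:5) {
    toy <- toy_indicators(n = 150, seed = s, sep = 2)
    m <- fit_lca(toy$X, K = 2, seed = s, restarts = 2)
    expect_true(all(diff(m$ll_trace) >= -1e-8))
  }
})

test_that("same data, seed and restarts give a bit-identical model", {
  toy <- toy_indicators(n = 400, seed = 3)
  a <- fit_lca(toy$X, K = 2, seed = 5, restarts = 4)
  b <- fit_lca(toy$X, K = 2, seed = 5, restarts = 4)
  expect_identical(a, b)
})

test_that("under-identified fits are rejected", {
  toy <- toy_indicators(n = 16, seed = 1)
  expect_error(fit_lca(toy$X, K = 2), "under-identified")
})

test_that("posteriors normalise, and match direct density evaluation", {
  toy <- toy_indicators(n = 50, seed = 9)
  m1 <- fit_lca(toy$X, K = 1, restarts = 1)
  g1 <- lca_responsibilities(m1, toy$X)
  expect_true(all(g1 == 1))

  # symmetric two-class model, observation equidistant from both centres
  m2 <- fake_model(weights = c(0.5, 0.5),
                   means = rbind(c(40, 7, 28), c(60, 7, 28)),
                   sds = rbind(c(5, 1, 3), c(5, 1, 3)),
                   p_male = c(0.5, 0.5))
  x_mid <- cbind(age = 50, hba1c = 7, bmi = 28, sex_male = 1)
  expect_equal(as.numeric(lca_responsibilities(m2, x_mid)), c(0.5, 0.5))

  # 3-row toy set against brute-force density ratios
  m3 <- fake_model(weights = c(0.3, 0.7),
                   means = rbind(c(45, 7.1, 30), c(65, 8.2, 26)),
                   sds = rbind(c(6, 0.8, 4), c(9, 1.4, 3)),
                   p_male = c(0.2, 0.8))
  X3 <- cbind(age = c(44, 66, 55), hba1c = c(7, 8.5, 7.7),
              bmi = c(31, 25, 28), sex_male = c(0, 1, 1))
  g3 <- lca_responsibilities(m3, X3)
  for (i in 1:3) {
    f <- sapply(1:2, function(k) {
      m3$weights[k] *
        dnorm(X3[i, 1], m3$means[k, 1], m3$sds[k, 1]) *
        dnorm(X3[i, 2], m3$means[k, 2], m3$sds[k, 2]) *
        dnorm(X3[i, 3], m3$means[k, 3], m3$sds[k, 3]) *
        dbinom(X3[i, 4], 1, m3$p_male[k])
    })
    expect_equal(as.numeric(g3[i, ]), as.numeric(f / sum(f)), tolerance = 1e-12)
  }
  expect_equal(rowSums(g3), rep(1, 3), tolerance = 1e-9)
})

test_that("rows with missing indicators are unassignable unless partial", {
  toy <- toy_indicators(n = 100, seed = 2)
  m <- fit_lca(toy$X, K = 2, restarts = 2)
  Xm <- toy$X
  Xm[1, "hba1c"] <- NA
  g <- lca_responsibilities(m, Xm)
  expect_true(all(is.na(g[1, ])))
  gp <- lca_responsibilities(m, Xm, partial = TRUE)
  expect_equal(sum(gp[1, ]), 1, tolerance = 1e-9)
  expect_true(attr(gp, "partial_row")[1])
  # partial posterior equals the density ratio on observed indicators only
  f <- sapply(1:2, function(k) {
    m$weights[k] *
      dnorm(Xm[1, "age"], m$means[k, "age"], m$sds[k, "age"]) *
      dnorm(Xm[1, "bmi"], m$means[k, "bmi"], m$sds[k, "bmi"]) *
      dbinom(Xm[1, "sex_male"], 1, m$p_male[k])
  })
  expect_equal(as.numeric(gp[1, ]), as.numeric(f / sum(f)), tolerance = 1e-9)
})

test_that("BIC follows the 8K - 1 parameter penalty", {
  toy <- toy_indicators(n = 100, seed = 4)
  m1 <- fit_lca(toy$X, K = 1, restarts = 1)
  expect_equal(lca_bic(m1), -2 * m1$loglik + 7 * log(100))
  m3 <- fit_lca(toy$X, K = 3, restarts = 2)
  expect_equal(m3$n_parameters, 23L)
  expect_equal(lca_bic(m3), -2 * m3$loglik + 23 * log(100))
})

test_that("class labelling follows the published subgroup semantics", {
  # published overall class-mean rows: labels must come out MARD, MOD, SHD
  m <- fake_model(weights = c(0.823, 0.096, 0.081),
                  means = rbind(c(53.9, 7.2, 28.9),
                                c(50.6, 7.3, 41.3),
                                c(47.7, 12.1, 30.2)),
                  sds = rbind(c(13.9, 0.9, 4.2),
                              c(12.8, 1.1, 3.4),
                              c(12.1, 1.6, 5.6)),
                  p_male = c(0.563, 0.228, 0.690))
  X <- cbind(age = c(54, 50, 48), hba1c = c(7.2, 7.3, 12.1),
             bmi = c(29, 41, 30), sex_male = c(1, 0, 1))
  asg <- assign_and_label(m, X)
  expect_equal(unname(asg$mapping), c("MARD", "MOD", "SHD"))
  expect_equal(asg$label, c("MARD", "MOD", "SHD"))

  # permuting class indices leaves the final labels unchanged
  perm <- c(3, 1, 2)
  mp <- fake_model(m$weights[perm], m$means[perm, ], m$sds[perm, ],
                   m$p_male[perm])
  asg_p <- assign_and_label(mp, X)
  expect_equal(asg_p$label, asg$label)

  # K = 2 falls back to generic labels
  m2 <- fake_model(c(0.6, 0.4), m$means[1:2, ], m$sds[1:2, ], m$p_male[1:2])
  expect_equal(unname(assign_and_label(m2, X)$mapping), c("class_1", "class_2"))
})

test_that("a structureless cluster fails the selection rules", {
  set.seed(31)
  n <- 400
  X <- cbind(age = rnorm(n, 50, 1), hba1c = rnorm(n, 7, 0.1),
             bmi = rnorm(n, 30, 0.5), sex_male = rbinom(n, 1, 0.5))
  sel <- suppressWarnings(select_lca(X, K_range = 2:3, restarts = 3))
  expect_false(sel$selection_passed)
})

test_that("radar normalisation maps extremes to edge and centre", {
  base <- data.frame(age = c(53.9, 50.6, 47.7), hba1c_pct = c(7.2, 7.3, 12.1),
                     bmi = c(28.9, 41.3, 30.2), sex_male = c(0.563, 0.228, 0.690))
  lab <- c("MARD", "MOD", "SHD")
  rad <- radar_summary(base, lab)
  pick <- function(v, l) rad$normalised[rad$variable == v & rad$label == l]
  expect_equal(pick("bmi", "MOD"), 1)
  expect_equal(pick("hba1c", "SHD"), 1)
  expect_equal(pick("age", "MARD"), 1)
  expect_equal(pick("age", "SHD"), 0)
  expect_error(radar_summary(base[1, ], lab[1]), "2 classes")
  base$bmi <- 30
  expect_warning(rad2 <- radar_summary(base, lab), "constant")
  expect_true(all(rad2$normalised[rad2$variable == "bmi"] == 0.5))
})

test_that("doubling restarts leaves selected BICs essentially unchanged", {
  toy <- toy_indicators(n = 1200, seed = 8, sep = 3)
  s1 <- suppressWarnings(select_lca(toy$X, K_range = 2:3, seed = 2, restarts = 3))
  s2 <- suppressWarnings(select_lca(toy$X, K_range = 2:3, seed = 2, restarts = 6))
  expect_lt(max(abs(s1$diagnostics$bic - s2$diagnostics$bic) /
                  abs(s1$diagnostics$bic)), 0.001)
})

test_that("tiny strata are skipped with a warning", {
  toy <- toy_indicators(n = 300, seed = 12, sep = 3)
  base <- data.frame(id = as.character(seq_len(300)),
                     ethnicity = c(rep("white", 290), rep("black", 10)),
                     age = toy$X[, "age"], hba1c_pct = toy$X[, "hba1c"],
                     bmi = toy$X[, "bmi"], sex_male = toy$X[, "sex_male"])
  expect_warning(
    fits <- stratified_lca(base, K_range = 2:2, restarts = 2,
                           strata = c("white", "black")),
    "skipped")
  expect_null(fits$black)
  expect_false(is.null(fits$white))
})

test_that("within each ethnic stratum three classes are selected and calibrated", {
  cfg <- default_generator_config(n_patients = 30000, seed = 1)
  drawn <- sample_patients(cfg, seed = 1)
  ind <- drawn$indicators
  for (st in c("white", "black")) {
    rows <- drawn$patients$ethnicity == st
    X <- cbind(age = ind$age,
               hba1c = ifelse(ind$hba1c_observed, ind$hba1c, NA),
               bmi = ifelse(ind$bmi_observed, ind$bmi, NA),
               sex_male = ind$sex_male)[rows, ]
    sel <- suppressWarnings(select_lca(X, 2:5, seed = 1, restarts = 5))
    expect_equal(sel$selected_K, 3, label = st)
    m <- sel$model
    map <- assign_and_label(m, X[complete.cases(X), ])$mapping
    conf <- cfg$profiles[cfg$profiles$ethnicity == st, ]
    for (sg in c("MARD", "MOD", "SHD")) {
      k <- as.integer(names(which(map == sg)))
      expect_lt(abs(m$weights[k] - conf$share[conf$subgroup == sg]), 0.015,
                label = paste(st, sg, "share"))
      tr_rows <- rows & drawn$truth$subgroup == sg
      expect_lt(abs(m$means[k, "hba1c"] - mean(ind$hba1c[tr_rows])) /
                  mean(ind$hba1c[tr_rows]), 0.02,
                label = paste(st, sg, "hba1c mean"))
    }
  }
})
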