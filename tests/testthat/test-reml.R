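# dense-matrix restricted log-likelihood, used as an independent oracle
dense_reml_ll <- function(theta, y, X, G) {
  n <- length(y); p <- ncol(X)
  V <- theta[1L] * G + theta[2L] * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(-0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
                       drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi)))
}

test_that("design builder encodes factors, centers Het and maps records", {
  df <- data.frame(clone = c("c1", "c1", "c2", "c3"),
                   year = c(2013, 2014, 2013, 2014),
                   crop = "plant", region = "N", trial = "t1",
                   TCH = c(80, 82, 75, 90))
  ph <- pheno_table(df)
  expect_warning(des <- build_design(ph, "TCH"), "single level")
  expect_equal(colnames(des$X), c("(Intercept)", "year2014"))
  expect_equal(des$clone, df$clone)
  het <- c(c1 = 0.2, c2 = -0.1, c3 = 0.4)
  expect_warning(desh <- build_design(ph, "TCH", het = het), "single level")
  expect_equal(mean(desh$X[, "het_c"]), 0)
  # one clone with several records maps multiple rows to one genetic effect
  expect_equal(sum(desh$clone == "c1"), 2L)
})

test_that("single-kernel REML optimum matches a dense grid-search oracle", {
  set.seed(20)
  n <- 6L
  ids <- paste0("c", 1:n)
  H <- matrix(rnorm(n * 8), n)
  G <- build_grm(H)
  dimnames(G) <- list(ids, ids)
  y <- as.numeric(chol(unclass(G) + 0.5 * diag(n)) %*% rnorm(n)) + 3
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  fit <- reml_fit(y, X, ids, list(G_A = G), tol = 1e-10)

  grid1 <- seq(0.01, 5, length.out = 60)
  lls <- outer(grid1, grid1, Vectorize(function(a, b)
    dense_reml_ll(c(a, b), y, X, unclass(G))))
  best <- arrayInd(which.max(lls), dim(lls))
  # refine around the coarse optimum
  ga <- seq(max(0.001, grid1[best[1L]] - 0.1), grid1[best[1L]] + 0.1,
            length.out = 80)
  gb <- seq(max(0.001, grid1[best[2L]] - 0.1), grid1[best[2L]] + 0.1,
            length.out = 80)
  lls2 <- outer(ga, gb, Vectorize(function(a, b)
    dense_reml_ll(c(a, b), y, X, unclass(G))))
  expect_equal(fit$loglik, max(lls2), tolerance = 1e-4)
  expect_gte(fit$loglik + 1e-6, max(lls2))
  # and the reported optimum evaluates to its own likelihood under the oracle
  th <- fit$var_components$estimate
  expect_equal(dense_reml_ll(th, y, X, unclass(G)), fit$loglik,
               tolerance = 1e-6)
})

test_that("pure-noise responses drive the genetic variance to the boundary", {
  # under a true zero variance the REML estimate follows a half-normal-like
  # mixture: draws whose unconstrained optimum is negative pin at the lower
  # bound and are flagged "~0" without a standard error
  sim <- small_sim(seed = 77, n = 150L, p = 300L)
  ids <- sim$g$clone_ids
  X <- matrix(1, length(ids), 1)
  set.seed(2)
  y <- rnorm(length(ids))
  fit <- reml_fit(y, X, ids, list(G_A = sim$kset$G_A))
  vc <- fit$var_components
  expect_true(vc$boundary[vc$component == "G_A"])
  expect_true(is.na(vc$se[vc$component == "G_A"]))
  expect_equal(vc$estimate[vc$component == "residual"], var(y),
               tolerance = 0.1)
  # non-pinned null draws stay small relative to the residual variance
  set.seed(1)
  y2 <- rnorm(length(ids))
  fit2 <- reml_fit(y2, X, ids, list(G_A = sim$kset$G_A))
  vc2 <- fit2$var_components
  expect_lt(vc2$estimate[1L], 0.25 * sum(vc2$estimate))
})

test_that("AD variance components recover simulated truth within 2 SE", {
  sim <- small_sim(seed = 42, n = 200L, p = 500L)
  suppressWarnings(fit <- fit_gblup(sim$ph, sim$kset, "trait", model = "AD"))
  vc <- fit$var_components
  truth <- sim$truth$realized_var
  for (comp in c("G_A", "G_D")) {
    est <- vc$estimate[vc$component == comp]
    se <- vc$se[vc$component == comp]
    tv <- if (comp == "G_A") truth["a"] else truth["d"]
    expect_lt(abs(est - tv), 2.5 * se)
  }
  expect_true(fit$converged)
  h <- heritabilities(fit)
  expect_equal(unname(h["h2"]),
               vc$estimate[1L] / sum(vc$estimate), tolerance = 1e-10)
  expect_lte(h["h2"], h["H2"])
  expect_lte(h["H2"], 1 + 1e-9)
})

test_that("GPCP equals the sum of genetic BLUPs and permutation-invariance
           holds", {
  sim <- small_sim(seed = 42, n = 200L, p = 500L)
  suppressWarnings(fit <- fit_gblup(sim$ph, sim$kset, "trait", model = "AD"))
  expect_equal(fit$gpcp, rowSums(fit$blups), tolerance = 1e-12)

  # permuting clone order in the kernels permutes BLUPs identically
  perm <- sample(length(sim$g$clone_ids))
  ksetp <- lapply(sim$kset[c("G_A", "G_D")], function(K)
    kernel_matrix(unclass(K)[perm, perm], attr(K, "name"), psd_check = FALSE))
  des <- suppressWarnings(build_design(sim$ph, "trait"))
  fitp <- reml_fit(des$y, des$X, des$clone, ksetp)
  expect_equal(unname(fitp$gebv[sim$g$clone_ids]),
               unname(fit$gebv[sim$g$clone_ids]), tolerance = 1e-6)
  expect_equal(fitp$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("reference coding of fixed factors does not change the likelihood", {
  sim <- small_sim(seed = 42, n = 200L, p = 500L)
  df <- as.data.frame(sim$ph)
  suppressWarnings(f1 <- fit_gblup(sim$ph, sim$kset, "trait", model = "A"))
  # recode region with the last level as reference
  df$region <- factor(df$region, levels = rev(sort(unique(df$region))))
  suppressWarnings(f2 <- fit_gblup(pheno_table(df), sim$kset, "trait",
                                   model = "A"))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
})

test_that("adding a random term never decreases the REML log-likelihood", {
  sim <- small_sim(seed = 13, n = 150L, p = 400L, var_aa = 30)
  fits <- lapply(c("A", "AD", "ADE"), function(m)
    suppressWarnings(fit_gblup(sim$ph, sim$kset, "trait", model = m)))
  lls <- vapply(fits, `[[`, 0, "loglik")
  expect_true(all(diff(lls) > -1e-6))
  # and the H variant extends the fixed part, leaving nesting intact
  out <- lrt(fits[[2L]], fits[[1L]])
  expect_gte(out$stat, -1e-6)
  expect_equal(out$df, 1L)
})

test_that("likelihood-ratio test matches the chi-squared(1) reference", {
  ex <- lrt_stat(-45403.70, -45439.59)
  expect_equal(ex$stat, 71.78, tolerance = 1e-9)
  expect_true(ex$significant)
  expect_equal(lrt_stat(-10, -10)$stat, 0)
  expect_false(lrt_stat(-10, -10)$significant)
  at4 <- lrt_stat(0, -2)
  expect_equal(at4$stat, 4)
  expect_equal(at4$p_value, 0.0455, tolerance = 1e-3)
  expect_true(at4$significant)
  # non-nested models are rejected
  sim <- small_sim(seed = 42, n = 200L, p = 500L)
  suppressWarnings({
    fa <- fit_gblup(sim$ph, sim$kset, "trait", model = "A")
    fd <- fit_gblup(sim$ph, sim$kset, "trait", model = "AD")
  })
  expect_error(lrt(fa, fd), "not nested")
})

test_that("identical identity-pattern kernels are flagged as
           non-identifiable rather than split arbitrarily", {
  set.seed(30)
  n <- 80L
  ids <- paste0("c", 1:n)
  I1 <- kernel_matrix(diag(n) + 0, "I1", psd_check = FALSE)
  dimnames(I1) <- list(ids, ids)
  I2 <- kernel_matrix(diag(n) + 0, "I2", psd_check = FALSE)
  dimnames(I2) <- list(ids, ids)
  y <- rnorm(n, sd = 2)
  X <- matrix(1, n, 1)
  fit <- suppressWarnings(reml_fit(y, X, ids, list(I1 = I1, I2 = I2)))
  vc <- fit$var_components
  # either the AI system is detected as singular or the split is symmetric
  expect_true(fit$ai_singular ||
                abs(vc$estimate[1L] - vc$estimate[2L]) <
                  1e-6 * sum(vc$estimate))
})

test_that("H models estimate the heterozygosity regression and use it in
           prediction", {
  sim <- small_sim(seed = 42, n = 200L, p = 500L)
  suppressWarnings(fit <- fit_gblup(sim$ph, sim$kset, "trait", model = "ADH"))
  fe <- fit$fixed_effects
  expect_true("het_c" %in% fe$term)
  pr_with <- predict(fit, "gpcp", include_het = TRUE)
  pr_without <- predict(fit, "gpcp", include_het = FALSE)
  delta <- pr_with - pr_without
  expect_equal(unname(delta),
               unname(fit$het_coefficient * fit$het_centered[names(delta)]),
               tolerance = 1e-10)
})
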