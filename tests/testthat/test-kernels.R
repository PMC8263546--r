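test_that("NOIA additive coefficients follow the genotype-frequency formula", {
  expect_equal(unname(noia_additive_coeffs(c(0.25, 0.5, 0.25))[1L, ]),
               c(1, 0, -1))
  expect_equal(unname(noia_additive_coeffs(c(1, 0, 0))[1L, ]),
               c(0, -1, -2))
  # frequency-weighted mean is zero for any triple
  set.seed(1)
  for (i in 1:25) {
    fr <- as.numeric(stats::rgamma(3, 1)); fr <- fr / sum(fr)
    h <- noia_additive_coeffs(fr)
    expect_lt(abs(sum(fr * h)), 1e-10)
  }
})

test_that("NOIA dominance coefficients match direct evaluation and center", {
  expect_equal(unname(noia_dominance_coeffs(c(0.25, 0.5, 0.25))[1L, ]),
               c(-0.5, 0.5, -0.5))
  h <- noia_dominance_coeffs(c(0.5, 0.25, 0.25))
  expect_equal(unname(h[1L, ]), c(-0.18182, 0.72727, -0.36364),
               tolerance = 1e-4)
  expect_lt(abs(sum(c(0.5, 0.25, 0.25) * h[1L, ])), 1e-10)
  # no homozygotes: D = 0, zero column, flagged
  h0 <- noia_dominance_coeffs(c(0, 1, 0))
  expect_equal(unname(h0[1L, ]), c(0, 0, 0))
  expect_true(attr(h0, "degenerate"))
})

test_that("additive and dominance contrasts are orthogonal under HWE", {
  set.seed(2)
  for (p in c(runif(20, 0.02, 0.98), 0.5)) {
    fr <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
    ha <- noia_additive_coeffs(fr)
    hd <- noia_dominance_coeffs(fr)
    expect_lt(abs(sum(fr * ha * hd)), 1e-10)
  }
})

test_that("incidence columns have zero frequency-weighted means", {
  g <- random_geno(60, 30, seed = 3)
  for (kind in c("additive", "dominance")) {
    H <- noia_incidence(g, kind)
    fr <- g$freqs
    cf <- if (kind == "additive") noia_additive_coeffs(fr)
          else noia_dominance_coeffs(fr)
    wmean <- rowSums(fr * cf)
    expect_true(all(abs(wmean) < 1e-10))
    # realized column means also vanish (frequencies come from these data)
    expect_true(all(abs(colMeans(H)) < 1e-10))
  }
})

test_that("trace-normalized GRM matches the hand case and brute force", {
  H <- rbind(c(1, 1), c(0, 0), c(-1, -1))
  G <- build_grm(H)
  expect_equal(unname(diag(G)), c(1.5, 0, 1.5))
  expect_equal(mean(diag(G)), 1)
  expect_equal(unname(unclass(G)[1L, 3L]), -1.5)

  # brute-force pairwise oracle on random instances, n <= 10
  set.seed(4)
  for (rep in 1:5) {
    n <- sample(3:10, 1L)
    Hr <- matrix(rnorm(n * 7), n)
    Gr <- build_grm(Hr)
    tr <- sum(vapply(seq_len(n), function(i) sum(Hr[i, ]^2), 0))
    oracle <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n))
      oracle[i, j] <- sum(Hr[i, ] * Hr[j, ]) / (tr / n)
    expect_equal(unclass(Gr), oracle, ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_error(build_grm(matrix(0, 3, 2)), "degenerate")
})

test_that("duplicate genotype rows give identical GRM rows", {
  g <- random_geno(10, 40, seed = 6)
  codes <- g$codes
  codes[2L, ] <- codes[1L, ]
  g <- geno_matrix(codes)
  G <- build_grm(noia_incidence(g, "additive"))
  expect_equal(unclass(G)[1L, ], unclass(G)[2L, ], ignore_attr = TRUE)
  expect_equal(unclass(G)[1L, 2L], unclass(G)[1L, 1L])
})

test_that("Hadamard kernels rescale to unit mean diagonal", {
  n <- 4L
  ids <- paste0("c", 1:n)
  base <- matrix(0.5, n, n, dimnames = list(ids, ids)); diag(base) <- 1
  G <- kernel_matrix(base, "G", psd_check = FALSE)
  GG <- hadamard_kernel(G, G)
  expect_equal(unname(diag(unclass(GG))), rep(1, n))
  expect_equal(unclass(GG)[1L, 2L], 0.25)
  ident <- kernel_matrix(diag(n) + 0, "I", psd_check = FALSE)
  dimnames(ident) <- list(ids, ids)
  GI <- hadamard_kernel(G, ident)
  expect_true(all(unclass(GI)[upper.tri(GI)] == 0))
  # mean diagonal 1 for arbitrary inputs
  g <- random_geno(15, 50, seed = 7)
  GA <- build_grm(noia_incidence(g, "additive"))
  GD <- build_grm(noia_incidence(g, "dominance"))
  for (K in list(hadamard_kernel(GA, GA), hadamard_kernel(GA, GD),
                 hadamard_kernel(GD, GD)))
    expect_equal(mean(diag(K)), 1, tolerance = 1e-10)
  expect_error(hadamard_kernel(GA, GG), "clone order")
})

test_that("all trace-normalized kernels are symmetric and PSD", {
  g <- random_geno(40, 80, seed = 8)
  ks <- build_kernel_set(g, which = c("G_A", "G_D", "G_AA", "G_AD", "G_DD"))
  for (nm in setdiff(names(ks), "het")) {
    K <- unclass(ks[[nm]])
    expect_lt(max(abs(K - t(K))), 1e-10)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    expect_equal(mean(diag(K)), 1, tolerance = 1e-10)
  }
})

test_that("heterozygosity is +1 for fully heterozygous and -1 for fully
           homozygous clones under HWE", {
  # one fully heterozygous clone, loci at HWE with varying p
  set.seed(9)
  p <- runif(30, 0.2, 0.8)
  freqs <- cbind(p_AA = p^2, p_Aa = 2 * p * (1 - p), p_aa = (1 - p)^2)
  codes <- rbind(rep(1L, 30), rep(0L, 30), rep(2L, 30))
  g <- make_geno(codes)
  het <- heterozygosity(g, freqs = freqs)
  expect_equal(unname(het[1L]), 1, tolerance = 1e-12)

  # fully homozygous clones at p = 0.5: Het = -1
  freqs5 <- cbind(p_AA = rep(0.25, 30), p_Aa = 0.5, p_aa = 0.25)
  het5 <- heterozygosity(g, freqs = freqs5)
  expect_equal(unname(het5[2L]), -1, tolerance = 1e-12)
  expect_equal(unname(het5[3L]), -1, tolerance = 1e-12)

  # frequency-weighted mean of dominance rows is zero => centering holds
  gg <- random_geno(80, 60, seed = 10)
  hh <- heterozygosity(gg)
  expect_lt(abs(mean(hh)), 1e-10)
  expect_gt(attr(hh, "normalizer"), 0)
})

test_that("Gaussian kernel follows the squared-distance formula", {
  g <- make_geno(rbind(a = c(0L, 0L, 0L), b = c(0L, 0L, 0L),
                       c = c(2L, 2L, 2L)))
  K1 <- gaussian_kernel(g, 1)
  expect_equal(unclass(K1)["a", "b"], 1)        # identical rows
  expect_equal(unclass(K1)["a", "c"], exp(-4))  # distance 4p/p, h = 1
  expect_equal(unname(diag(unclass(K1))), rep(1, 3))
  K0 <- gaussian_kernel(g, 0)
  expect_true(all(unclass(K0) == 1))
  # monotone decreasing in h for any off-diagonal pair
  gg <- random_geno(10, 30, seed = 11)
  hs <- c(0.1, 0.5, 1, 2.5, 5, 10)
  vals <- vapply(hs, function(h) unclass(gaussian_kernel(gg, h))[1L, 2L], 0)
  expect_true(all(diff(vals) < 0))
  expect_true(all(unclass(gaussian_kernel(gg, 2)) > 0))
})

test_that("kernel text persistence round-trips values and clone ids", {
  g <- random_geno(12, 25, seed = 12)
  G <- build_grm(noia_incidence(g, "additive"))
  path <- tempfile(fileext = ".tsv")
  write_kernel(G, path)
  G2 <- read_kernel(path, name = "G_A")
  expect_equal(unclass(G2), unclass(G), ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(rownames(G2), rownames(G))
})
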