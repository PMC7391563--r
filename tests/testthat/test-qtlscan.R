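test_that("genotype probabilities are exact in degenerate cases", {
  cr <- toy_cross(1, 40, 3, n = 25)
  gp0 <- calc_genoprob(cr$geno, cr$map_df, step = 1, error_prob = 0)
  g1 <- gp0$groups[[1]]
  # at typed markers with zero error, probabilities are degenerate
  for (t in which(!is.na(g1$marker))) {
    obs <- cr$geno[, g1$marker[t]]
    for (i in seq_along(obs)) {
      pvec <- g1$prob[i, , t]
      expect_equal(unname(pvec[obs[i]]), 1, tolerance = 1e-12)
    }
  }
  # rows always sum to one
  expect_lt(max(abs(apply(g1$prob, c(1, 3), sum) - 1)), 1e-9)

  # single typed marker, error 0.05: one-step Bayes posterior
  geno1 <- matrix("AA", 1, 1, dimnames = list("i1", "m1"))
  map1 <- data.frame(group = 1, marker = "m1", pos_cM = 0)
  gp1 <- calc_genoprob(geno1, map1, step = 1, error_prob = 0.05)
  post <- gp1$groups[[1]]$prob[1, , 1]
  expected <- c(0.25 * 0.95, 0.5 * 0.025, 0.25 * 0.025)
  expect_equal(unname(post), expected / sum(expected), tolerance = 1e-12)
})

test_that("forward-backward equals exhaustive path enumeration", {
  set.seed(41)
  for (m in 2:4) {
    map <- data.frame(group = 1, marker = sprintf("m%d", 1:m),
                      pos_cM = cumsum(c(0, round(runif(m - 1, 5, 30), 2))))
    geno <- matrix(sample(c("AA", "AB", "BB", NA), 6 * m, TRUE,
                          c(0.3, 0.35, 0.25, 0.1)),
                   6, m, dimnames = list(sprintf("i%d", 1:6), map$marker))
    gp <- calc_genoprob(geno, map, step = 1000, error_prob = 0.05)
    g <- gp$groups[[1]]
    expect_equal(length(g$pos), m)  # no pseudomarkers at this step
    for (i in 1:6) {
      oracle <- enumerate_genoprob(geno[i, ], map$pos_cM, 0.05, "kosambi")
      expect_lt(max(abs(t(g$prob[i, , ]) - oracle)), 1e-10)
    }
  }
})

test_that("pseudomarker grid includes markers and honours the step", {
  cr <- toy_cross(1, 10, 2, n = 10)
  gp <- calc_genoprob(cr$geno, cr$map_df, step = 1)
  g <- gp$groups[[1]]
  expect_true(all(cr$map_df$pos_cM %in% g$pos))
  expect_equal(g$pos, 0:10)
})

test_that("EM scan reduces to the genotype-means regression at a marker", {
  cr <- toy_cross(1, 40, 3, n = 120)
  set.seed(42)
  x <- c(AA = 1, AB = 0, BB = -1)[cr$geno[, 2]]
  y <- 0.8 * x + rnorm(120)
  gp <- calc_genoprob(cr$geno, cr$map_df, step = 1000, error_prob = 1e-12)
  cv <- scan_em(gp, y)
  # oracle: (n/2) log10(RSS0/RSS1) from the one-way genotype-means model
  fit <- lm(y ~ factor(cr$geno[, 2]))
  rss1 <- sum(resid(fit)^2)
  rss0 <- sum((y - mean(y))^2)
  lod_oracle <- (120 / 2) * log10(rss0 / rss1)
  expect_equal(cv$lod[2], lod_oracle, tolerance = 1e-6)

  # LOD is invariant under affine transforms of the phenotype
  cv2 <- scan_em(gp, 3.7 * y - 11)
  expect_equal(cv2$lod, cv$lod, tolerance = 1e-5)
})

test_that("EM scan reduction holds with additive and interactive sex", {
  cr <- toy_cross(1, 30, 2, n = 150)
  set.seed(43)
  sex <- rep(c("M", "F"), 75)
  x <- c(AA = 1, AB = 0, BB = -1)[cr$geno[, 1]]
  y <- x + 0.5 * (sex == "M") + rnorm(150)
  gp <- calc_genoprob(cr$geno, cr$map_df, step = 1000, error_prob = 1e-12)
  g <- factor(cr$geno[, 1])
  for (ct in c("additive", "interactive")) {
    cv <- scan_em(gp, y, covar = sex, covar_type = ct)
    f1 <- if (ct == "additive") lm(y ~ g + sex) else lm(y ~ g * sex - sex)
    # null always keeps only the covariate main effect
    f0 <- lm(y ~ sex)
    if (ct == "interactive") f1 <- lm(y ~ g + g:sex)
    lod_oracle <- (150 / 2) * log10(sum(resid(f0)^2) / sum(resid(f1)^2))
    expect_equal(cv$lod[1], lod_oracle, tolerance = 1e-5,
                 label = sprintf("covar_type %s", ct))
  }
})

test_that("nonparametric scan reduces to Kruskal-Wallis at typed markers", {
  cr <- toy_cross(1, 40, 3, n = 90)
  set.seed(44)
  y <- rnorm(90) + c(AA = 1, AB = 0, BB = -1)[cr$geno[, 1]]
  gp <- calc_genoprob(cr$geno, cr$map_df, step = 1000, error_prob = 0)
  cv <- scan_np(gp, y)
  kw <- kruskal.test(y ~ factor(cr$geno[, 1]))$statistic
  expect_equal(cv$lod[1], unname(kw) / (2 * log(10)), tolerance = 1e-10)
  expect_gt(cv$lod[1], 0)  # monotone genotype effect gives positive LOD

  # constant phenotype: zero everywhere
  cv0 <- scan_np(gp, rep(2, 90))
  expect_true(all(cv0$lod == 0))
})

test_that("permutation thresholds behave like empirical quantiles", {
  cr <- toy_cross(2, 60, 4, n = 60)
  set.seed(45)
  y <- rnorm(60)
  gp <- calc_genoprob(cr$geno, cr$map_df, step = 10)
  pt <- perm_threshold(gp, y, n_perm = 60, alphas = c(0.05, 0.10, 0.63),
                       seed = 46)
  expect_true(all(diff(pt$thresholds) <= 0))  # larger alpha, lower threshold
  expect_equal(pt$gw_p(max(pt$maxima) + 1), 1 / 61)
  expect_equal(pt$gw_p(-1), 1)
  expect_length(pt$maxima, 60)
})

test_that("Bayes credible intervals follow the 10^LOD posterior", {
  mk_curve <- function(pos, lod, marker) {
    structure(data.frame(group = "1", pos = pos, marker = marker,
                         lod = lod),
              class = c("lod_curve", "data.frame"), n = 50,
              model = "normal_em", covar_type = "none")
  }
  # two positions with posterior mass 0.96 / 0.04: interval is the first
  lods <- log10(c(0.96, 0.04))
  cv <- mk_curve(c(10, 20), lods, c("a", "b"))
  ci <- bayes_interval(cv, prob = 0.95)
  expect_equal(ci$lo_core, 10)
  expect_equal(ci$hi_core, 10)
  # delta-like peak: single position before widening
  cv2 <- mk_curve(c(0, 5, 10), c(0, 20, 0), c("a", NA, "b"))
  ci2 <- bayes_interval(cv2)
  expect_equal(ci2$lo_core, 5)
  expect_equal(ci2$hi_core, 5)
  expect_equal(ci2$lo, 0)   # widened to flanking markers
  expect_equal(ci2$hi, 10)
  # flat curve spans the group
  cv3 <- mk_curve(c(0, 5, 10), c(1, 1, 1), c("a", NA, "b"))
  ci3 <- bayes_interval(cv3)
  expect_equal(c(ci3$lo_core, ci3$hi_core), c(0, 10))
  # interval contains the peak
  expect_true(ci2$lo <= ci2$peak_pos && ci2$peak_pos <= ci2$hi)
})

test_that("PVE follows the likelihood-ratio formula", {
  expect_equal(pve(0, 100), 0)
  expect_equal(round(pve(4.23, 107), 2), 16.64)
  expect_equal(round(pve(7.79, 103), 2), 29.41)
  expect_equal(round(pve(2.60, 19), 2), 46.75)
  expect_equal(round(pve(5.02, 103), 2), 20.10)
  expect_equal(round(pve(3.67, 107), 2), 14.61)
  # strictly increasing in LOD, decreasing in n, bounded in [0, 100)
  lods <- seq(0, 30, by = 0.5)
  expect_true(all(diff(pve(lods, 100)) > 0))
  expect_true(all(diff(pve(5, seq(20, 200, 10))) < 0))
  expect_true(all(pve(lods, 10) >= 0 & pve(lods, 10) < 100))
})

test_that("a simulated QTL is mapped near its true location", {
  map <- simulate_map(3, 100, 11, seed = 50)
  geno <- simulate_f2(map, 200, seed = 51)
  arch <- qtl_architecture(qtl = data.frame(chr = 2, pos_cM = 50, a = 1,
                                            d = 0),
                           sigma_e = 1, label = "null")
  ph <- simulate_phenotypes(geno, arch, seed = 52)
  y <- ph$phenotype[ph$class == "F2"]
  md <- attr(geno, "map_df")
  gp <- calc_genoprob(geno, data.frame(group = md$chr, marker = md$marker,
                                       pos_cM = md$pos_cM), step = 2)
  cv <- scan_em(gp, y)
  pk <- cv[which.max(cv$lod), ]
  expect_equal(as.integer(as.character(pk$group)), 2)
  expect_lt(abs(pk$pos - 50), 10)
  ci <- bayes_interval(cv)
  expect_true(ci$lo <= pk$pos && pk$pos <= ci$hi)
  sm <- summarize_qtl(cv, trait = "sim")
  expect_equal(sm$pve, pve(pk$lod, 200))
})
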