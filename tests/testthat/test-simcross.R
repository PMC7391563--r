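test_that("simulate_map places markers as requested and is deterministic", {
  m1 <- simulate_map(1, 100, 2)
  expect_equal(unname(m1$positions[[1]]), c(0, 100))
  m22 <- simulate_map(22, 100, 43, seed = 1)
  expect_equal(sum(lengths(m22$positions)), 946)
  u1 <- simulate_map(3, 80, 10, seed = 9, placement = "uniform")
  u2 <- simulate_map(3, 80, 10, seed = 9, placement = "uniform")
  expect_identical(u1, u2)
  expect_true(all(vapply(u1$positions, function(p) !is.unsorted(p),
                         logical(1))))
  expect_error(simulate_map(2, -5, 10), "positive")
  # per-chromosome marker counts
  mv <- simulate_map(3, 100, c(5, 10, 2), seed = 1)
  expect_equal(lengths(mv$positions), c(5, 10, 2), ignore_attr = TRUE)
})

test_that("F2 genotypes follow Mendelian segregation and linkage", {
  map1 <- simulate_map(1, 0.001, 2, seed = 1)  # two markers ~0 cM apart
  g <- simulate_f2(map1, 2000, seed = 3)
  expect_true(all(g[, 1] == g[, 2]))  # complete linkage (r ~ 0)

  mapA <- simulate_map(1, 100, 2, seed = 1)
  gA <- simulate_f2(mapA, 10000, seed = 4)
  tab <- table(factor(gA[, 1], c("AA", "AB", "BB")))
  p <- chisq.test(tab, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 1e-4)
  # determinism
  expect_identical(simulate_f2(mapA, 50, seed = 7),
                   simulate_f2(mapA, 50, seed = 7))
})

test_that("recombination fraction matches the Kosambi map function", {
  # two markers 27.47 cM apart: r = 0.5 * tanh(2 * 0.2747) = 0.25
  r_true <- 0.5 * tanh(2 * 27.47 / 100)
  expect_equal(r_true, 0.25, tolerance = 1e-3)
  map <- simulate_map(1, 27.47, 2, seed = 1)
  g <- simulate_f2(map, 10000, map_function = "kosambi", seed = 5)
  est <- estimate_rf(g[, 1], g[, 2])
  mc_sd <- sqrt(r_true * (1 - r_true) / (2 * 10000))
  expect_lt(abs(est$rhat - r_true), 3 * mc_sd + 0.005)
})

test_that("phenotype simulation reflects the QTL architecture", {
  map <- simulate_map(2, 100, 11, seed = 1)
  geno <- simulate_f2(map, 400, seed = 2)
  # null architecture: noise only, SD ~ 1 everywhere
  ph0 <- simulate_phenotypes(geno, qtl_architecture(sigma_e = 1), seed = 3)
  sds <- tapply(ph0$phenotype, ph0$class, sd)
  expect_true(all(abs(sds[c("F2")] - 1) < 0.15))
  expect_equal(mean(ph0$phenotype[ph0$class == "CAL"]), 0, tolerance = 1.5)

  # complementary: equal parental means, F2 variance exceeds parental
  # analytic F2 genetic variance per additive locus: a^2/2
  arch <- qtl_architecture(
    qtl = data.frame(chr = c(1, 2), pos_cM = c(50, 50), a = c(1, -1),
                     d = c(0, 0)),
    sigma_e = 0.5, label = "complementary")
  ph <- simulate_phenotypes(geno, arch, n_parentA = 200, n_parentB = 200,
                            seed = 4)
  mA <- mean(ph$phenotype[ph$class == "CAL"])
  mB <- mean(ph$phenotype[ph$class == "TAE"])
  expect_equal(mA, mB, tolerance = 0.2)  # both fixed-line means are 0
  vf2 <- var(ph$phenotype[ph$class == "F2"])
  vpar <- var(ph$phenotype[ph$class %in% c("CAL", "TAE")])
  expect_equal(vpar, 0.25, tolerance = 0.08)
  expect_equal(vf2, 2 * 0.5 + 0.25, tolerance = 0.3)
  expect_gt(vf2, vpar)

  # overdominant QTL: heterozygote mean exceeds both homozygotes by d
  archo <- qtl_architecture(qtl = data.frame(chr = 1, pos_cM = 50, a = 0,
                                             d = 2),
                            sigma_e = 0, label = "overdominant")
  pho <- simulate_phenotypes(geno, archo, seed = 5)
  f2 <- pho[pho$class == "F2", ]
  mk <- attr(geno, "map_df")
  mid <- mk$marker[mk$chr == 1][which.min(abs(mk$pos_cM[mk$chr == 1] - 50))]
  means <- tapply(f2$phenotype, geno[, mid], mean)
  expect_equal(unname(means["AB"] - means["AA"]), 2)
  expect_equal(unname(means["AB"] - means["BB"]), 2)

  expect_error(simulate_phenotypes(
    geno, qtl_architecture(qtl = data.frame(chr = 1, pos_cM = 500, a = 1,
                                            d = 0))),
    "outside")
})

test_that("landmark simulation honours its noise and nuisance settings", {
  base <- default_fish_landmarks()
  lms0 <- simulate_landmarks(c(F2 = 5), class_means = list(F2 = base),
                             noise_sd = 0, nuisance = FALSE, seed = 1)
  for (cf in lms0) expect_equal(unname(cf$points), unname(base))
  # nuisance transforms are removed exactly by superimposition
  lms1 <- simulate_landmarks(c(F2 = 5), class_means = list(F2 = base),
                             noise_sd = 0, nuisance = TRUE, seed = 2)
  for (cf in lms1)
    expect_lt(procrustes_distance(cf$points, base), 1e-8)
})

test_that("allometric landmark variation is recoverable after GPA", {
  base <- default_fish_landmarks()
  v <- matrix(0, 13, 2); v[8, 1] <- -1; v[1, 2] <- 1  # snout/depth change
  v <- v / sqrt(sum(v^2)) * 0.5
  lms <- simulate_landmarks(c(F2 = 60), class_means = list(F2 = base),
                            allometry = v, logSL_sd = 0.15,
                            noise_sd = 0.002, seed = 3)
  sp <- gpa(lms, slide = FALSE)
  lsl <- log10(sp$info$SL)
  Y <- t(apply(sp$aligned, 3, as.vector))
  xc <- lsl - mean(lsl)
  beta <- as.vector(crossprod(xc, sweep(Y, 2, colMeans(Y)))) / sum(xc^2)
  # reference: the injected vector projected into shape space (the
  # translation, scaling and rotation components are removed by GPA)
  b <- sandsift:::.center_scale(base)$m
  bhat <- as.vector(b) / sqrt(sum(b^2))
  rot <- cbind(-b[, 2], b[, 1])
  rhat <- as.vector(rot) / sqrt(sum(rot^2))
  vc <- sweep(v, 2, colMeans(v))
  vv <- as.vector(vc)
  vv <- vv - sum(vv * bhat) * bhat - sum(vv * rhat) * rhat
  ref <- vv / sqrt(sum(vv^2))
  # the GPA frame carries an arbitrary global rotation; undo it via the
  # rotation that maps the consensus onto the base configuration
  s <- svd(crossprod(sp$consensus, b))
  R <- s$u %*% diag(c(1, det(s$u %*% t(s$v)))) %*% t(s$v)
  est <- as.vector(matrix(beta, 13, 2) %*% R)
  est <- est / sqrt(sum(est^2))
  cosim <- abs(sum(est * ref))
  expect_gt(cosim, 0.95)
})

test_that("sand image simulation returns its realized fraction exactly", {
  s0 <- sim_image_spec(target_fraction = 0, seed = 1)
  r0 <- simulate_sand_images(s0)
  expect_identical(r0$before, r0$after)
  expect_equal(r0$true_fraction, 0)

  s1 <- sim_image_spec(target_fraction = 1, seed = 2)
  r1 <- simulate_sand_images(s1)
  expect_equal(r1$true_fraction, 1)

  s3 <- sim_image_spec(target_fraction = 0.30, seed = 3)
  r3 <- simulate_sand_images(s3)
  expect_equal(r3$true_fraction, sum(r3$mask) / length(r3$mask))
  expect_lt(abs(r3$true_fraction - 0.30), 0.02)
  expect_error(sim_image_spec(target_fraction = 1.2), "\\[0, 1\\]")
})

test_that("synthetic VCF round-trips through the genotype filters", {
  map <- simulate_map(2, 50, 6, seed = 1)
  geno <- simulate_f2(map, 30, seed = 2)
  path <- tempfile(fileext = ".vcf")
  simulate_vcf(map, geno, seed = 3, path = path)
  rec <- read_vcf_records(path)
  fv <- filter_variants(rec)
  expect_equal(unname(fv$counts["retained"]), 12L)  # all informative sites
  fixed <- find_reciprocally_fixed(fv$records,
                                   grep("^CAL", rec$samples, value = TRUE),
                                   grep("^TAE", rec$samples, value = TRUE))
  expect_equal(nrow(fixed), 12L)
  cross <- recode_f2(fv$records, fixed, rownames(geno))
  # recoded genotypes match the simulator truth exactly
  expect_equal(unname(cross$geno[, cross$markers$marker == "c1_m1"]),
               unname(geno[, "c1_m1"]))
  mismatch <- sum(cross$geno[, match(colnames(geno), cross$markers$marker)]
                  != geno)
  expect_equal(mismatch, 0)
  unlink(path)
})

test_that("injected violations are filtered as constructed", {
  map <- simulate_map(1, 50, 4, seed = 1)
  geno <- simulate_f2(map, 20, seed = 2)
  path <- tempfile(fileext = ".vcf")
  simulate_vcf(map, geno, violations = list(indel = 1, cluster = 2),
               seed = 3, path = path)
  rec <- read_vcf_records(path)
  fv <- filter_variants(rec)
  expect_equal(unname(fv$counts["indel"]), 1L)
  # each 3-record cluster keeps exactly one survivor
  kept_w <- sum(fv$records$meta$chrom == "chrW")
  expect_equal(kept_w, 2L)
  expect_equal(unname(fv$counts["proximity_thin"]), 4L)
  unlink(path)
})
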