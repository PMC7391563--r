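fixture_config <- function(jitter = 0, seed = NULL, id = "fix") {
  pts <- default_fish_landmarks()
  if (jitter > 0) {
    if (!is.null(seed)) set.seed(seed)
    pts <- pts + matrix(rnorm(26, 0, jitter), 13, 2)
  }
  landmark_config(pts, id = id, SL = 85, class = "F2", sex = "M")
}

test_that("TPS files round-trip and honour SCALE", {
  cfs <- list(fixture_config(0.05, 1, "a"), fixture_config(0.05, 2, "b"))
  path <- tempfile(fileext = ".tps")
  write_tps(cfs, path)
  back <- read_tps(path)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]$points, cfs[[1]]$points, tolerance = 1e-9)
  expect_equal(back[[2]]$id, "b")

  # SCALE multiplies coordinates on read
  lines <- c("LM=13", sprintf("%.12g %.12g", cfs[[1]]$points[, 1],
                              cfs[[1]]$points[, 2]),
             "ID=sc", "SCALE=0.5")
  p2 <- tempfile(fileext = ".tps")
  writeLines(lines, p2)
  sc <- read_tps(p2)
  expect_equal(sc[[1]]$points, cfs[[1]]$points * 0.5, tolerance = 1e-9)

  # malformed count names the record
  writeLines(c("LM=13", "0 0", "1 1"), p2)
  expect_error(read_tps(p2), "record 1")

  # flip_y negates the vertical axis
  fl <- read_tps(path, flip_y = TRUE)
  expect_equal(fl[[1]]$points[, 2], -cfs[[1]]$points[, 2],
               tolerance = 1e-9)
})

test_that("linear distances and mouth angle match hand arithmetic", {
  pts <- default_fish_landmarks()
  pts["1", ] <- c(0, 0); pts["15", ] <- c(3, 4)
  cf <- landmark_config(pts, SL = 80)
  d <- linear_distances(cf)
  expect_equal(unname(d["EpD"]), 5)
  expect_equal(unname(d["LJL"]),
               sqrt(sum((pts["3", ] - pts["4", ])^2)), tolerance = 1e-12)
  expect_equal(unname(d["ML"]),
               sqrt(sum((pts["3", ] - pts["10", ])^2)), tolerance = 1e-12)
  expect_equal(unname(d["EyL"]),
               sqrt(sum((pts["5", ] - pts["6", ])^2)), tolerance = 1e-12)
  # coincident points
  pts2 <- pts; pts2["15", ] <- pts2["1", ]
  expect_equal(unname(linear_distances(landmark_config(pts2))["EpD"]), 0)

  # eye axis along +x, jaw vector (1, -1): angle difference +45 degrees
  pts3 <- pts
  pts3["5", ] <- c(0, 1); pts3["6", ] <- c(1, 1)
  pts3["10", ] <- c(0, 0); pts3["3", ] <- c(1, -1)
  expect_equal(mouth_angle(landmark_config(pts3)), 45)
  # aligned vectors: zero
  pts3["3", ] <- c(1, 0)
  expect_equal(mouth_angle(landmark_config(pts3)), 0)
  # common rotation leaves the angle difference unchanged
  th <- 0.6; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts4 <- pts %*% R
  dimnames(pts4) <- dimnames(pts)
  a1 <- mouth_angle(landmark_config(pts))
  a2 <- mouth_angle(landmark_config(pts4))
  expect_lt(abs(((a2 - a1 + 180) %% 360) - 180), 1e-9)
})

test_that("jaw standardization equalizes the jaw angle, preserving length", {
  rot4 <- function(cf, deg) {
    d <- deg * pi / 180
    R <- matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2, 2)
    v <- cf$points["4", ] - cf$points["3", ]
    cf$points["4", ] <- cf$points["3", ] + as.vector(R %*% v)
    cf
  }
  base <- fixture_config()
  cfs <- list(rot4(base, -10), rot4(base, 10))  # angles 20 apart
  ang <- function(cf) {
    p <- cf$points
    v1 <- p["10", ] - p["3", ]; v2 <- p["4", ] - p["3", ]
    atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2)) * 180 / pi
  }
  a_before <- vapply(cfs, ang, numeric(1))
  std <- standardize_jaw(cfs)
  a_after <- vapply(std, ang, numeric(1))
  expect_equal(a_after[1], a_after[2], tolerance = 1e-10)
  expect_equal(a_after[1], mean(a_before), tolerance = 1e-10)
  # jaw length preserved
  ljl <- function(cf) sqrt(sum((cf$points["4", ] - cf$points["3", ])^2))
  expect_equal(vapply(std, ljl, numeric(1)),
               vapply(cfs, ljl, numeric(1)), tolerance = 1e-12)
  # already-uniform specimens are untouched
  same <- list(fixture_config(), fixture_config())
  std2 <- standardize_jaw(same)
  expect_equal(std2[[1]]$points, same[[1]]$points, tolerance = 1e-12)
})

test_that("GPA is invariant to nuisance transforms of its inputs", {
  set.seed(31)
  cfs <- lapply(1:8, function(i) fixture_config(0.05, i, sprintf("s%d", i)))
  sp1 <- gpa(cfs, slide = FALSE)
  # transform one input arbitrarily: aligned output unchanged
  cfs2 <- cfs
  th <- runif(1, -pi, pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  cfs2[[3]]$points <- 2.7 * cfs2[[3]]$points %*% R +
    matrix(c(11, -4), 13, 2, byrow = TRUE)
  sp2 <- gpa(cfs2, slide = FALSE)
  expect_lt(max(abs(sp1$aligned - sp2$aligned)), 1e-7)

  # two identical shapes: zero Procrustes distance
  expect_lt(procrustes_distance(cfs[[1]]$points, cfs[[1]]$points), 1e-12)
  m <- cfs[[1]]$points
  m2 <- 3.3 * m %*% R + matrix(c(5, -2), 13, 2, byrow = TRUE)
  expect_lt(procrustes_distance(m, m2), 1e-8)
  expect_error(gpa(cfs[1]), "at least two")
  degen <- cfs[[1]]; degen$points[] <- 1
  expect_error(gpa(list(degen, cfs[[2]])), "degenerate")
})

test_that("converged GPA minimizes summed squared distance to consensus", {
  set.seed(32)
  cfs <- lapply(1:6, function(i) fixture_config(0.08, 100 + i))
  sp <- gpa(cfs, slide = FALSE)
  ss <- sum((sweep(sp$aligned, c(1, 2), sp$consensus))^2)
  # no further rotation update reduces the criterion
  for (i in 1:6) {
    rot <- sandsift:::.opt_rotate(sp$aligned[, , i], sp$consensus)
    ss_i <- sum((rot - sp$consensus)^2)
    expect_gte(sum((sp$aligned[, , i] - sp$consensus)^2) + 1e-12, ss_i)
    expect_lt(abs(ss_i - sum((sp$aligned[, , i] - sp$consensus)^2)), 1e-10)
  }
  expect_true(ss >= 0)
})

test_that("semilandmark sliding reduces bending energy monotonically", {
  set.seed(33)
  cfs <- lapply(1:10, function(i) {
    cf <- fixture_config(0.02, 200 + i)
    # jitter the semilandmarks along the profile to give sliding work
    cf$points[as.character(11:14), ] <-
      cf$points[as.character(11:14), ] + matrix(rnorm(8, 0, 0.06), 4, 2)
    cf
  })
  sp <- gpa(cfs, slide = TRUE)
  expect_false(is.null(sp$be_trace))
  expect_true(all(sp$be_trace[, "after"] <= sp$be_trace[, "before"] + 1e-12))
  # sliding achieves no more bending energy than not sliding
  sp0 <- gpa(cfs, slide = FALSE)
  be0 <- bending_energy(sweep(sp0$aligned, c(1, 2), sp0$consensus),
                        bending_energy_matrix(sp0$consensus))
  be1 <- bending_energy(sweep(sp$aligned, c(1, 2), sp$consensus),
                        bending_energy_matrix(sp$consensus))
  expect_lte(be1, be0 + 1e-9)
})

test_that("allometry-free shapes are uncorrelated with size", {
  base <- default_fish_landmarks()
  v <- matrix(0, 13, 2); v[1, 2] <- 0.8; v[8, 1] <- -0.6
  lms <- simulate_landmarks(c(F2 = 80), class_means = list(F2 = base),
                            allometry = v, logSL_sd = 0.12,
                            noise_sd = 0.004, seed = 34)
  sp <- gpa(lms, slide = FALSE)
  af <- allometry_free(sp, seed = 1)
  expect_lt(af$report$p, 0.01)  # strong allometry detected
  lsl <- log10(sp$info$SL)
  Y <- t(apply(af$shapes, 3, as.vector))
  cors <- suppressWarnings(abs(cor(Y, lsl)))
  expect_lt(max(cors, na.rm = TRUE), 0.05)

  # no allometry: shapes unchanged up to noise, F small
  lms0 <- simulate_landmarks(c(F2 = 40), class_means = list(F2 = base),
                             noise_sd = 0.01, seed = 35)
  sp0 <- gpa(lms0, slide = FALSE)
  af0 <- allometry_free(sp0, seed = 1)
  expect_gt(af0$report$p, 0.05)
  expect_lt(max(abs(af0$shapes - sp0$aligned)), 0.05)
})

test_that("group-wise allometry correction fits independent regressions", {
  base <- default_fish_landmarks()
  v <- matrix(0, 13, 2); v[1, 2] <- 1
  lmsA <- simulate_landmarks(c(F2 = 30), class_means = list(F2 = base),
                             allometry = v, logSL_sd = 0.1,
                             noise_sd = 0.003, seed = 36)
  lmsB <- simulate_landmarks(c(MUS = 30), class_means = list(MUS = base),
                             allometry = -2 * v, logSL_sd = 0.1,
                             noise_sd = 0.003, seed = 37)
  sp <- gpa(c(lmsA, lmsB), slide = FALSE)
  grp <- sp$info$class
  hom <- allometry_homogeneity(sp, class = grp, n_perm = 199, seed = 2)
  expect_lt(hom$p, 0.05)  # slopes genuinely differ
  af <- allometry_free(sp, groups = grp, seed = 3)
  lsl <- log10(sp$info$SL)
  Y <- t(apply(af$shapes, 3, as.vector))
  for (g in unique(grp)) {
    cors <- suppressWarnings(abs(cor(Y[grp == g, ], lsl[grp == g])))
    expect_lt(max(cors, na.rm = TRUE), 0.1)
  }
  expect_length(af$coefficients, 2)
})

test_that("shape PCA recovers injected variation and scores decorrelate", {
  set.seed(38)
  base <- sandsift:::.center_scale(default_fish_landmarks())$m
  v <- matrix(rnorm(26), 13, 2)
  v <- v - matrix(colMeans(v), 13, 2, byrow = TRUE)
  v <- v - sum(v * base) * base  # orthogonal to scaling direction
  v <- v / sqrt(sum(v^2))
  shapes <- array(NA_real_, c(13, 2, 50))
  for (i in 1:50)
    shapes[, , i] <- base + rnorm(1, 0, 0.05) * v +
      matrix(rnorm(26, 0, 1e-4), 13, 2)
  dimnames(shapes) <- list(rownames(default_fish_landmarks()),
                           c("x", "y"), sprintf("s%d", 1:50))
  p <- shape_pca(shapes)
  cosim <- abs(sum(p$axes[, 1] * as.vector(v)))
  expect_gt(cosim, 0.99)
  expect_gt(p$var_frac[1], 0.95)
  cv <- cov(p$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8 * max(diag(cv)))
  expect_equal(sum(p$var_frac), 1)
})

test_that("projection reproduces in-space scores and classifies held-outs", {
  set.seed(39)
  cfs <- lapply(1:12, function(i) fixture_config(0.05, 300 + i,
                                                 sprintf("s%d", i)))
  sp <- gpa(cfs, slide = FALSE)
  p <- shape_pca(sp)
  # in-space specimen reproduces its own scores
  sc <- project_shapes(sp$aligned[, , 5], p)
  expect_lt(max(abs(sc - p$scores[5, ])), 1e-8)
  # the consensus lands at the origin
  expect_lt(max(abs(project_shapes(p$consensus, p))), 1e-8)
  # raw (untransformed) configuration also reproduces its aligned scores
  sc_raw <- project_shapes(cfs[[5]], p)
  expect_lt(max(abs(sc_raw - p$scores[5, ])), 1e-6)

  # held-out specimens from two separated classes cluster correctly
  baseA <- default_fish_landmarks()
  baseB <- baseA; baseB["4", 1] <- baseB["4", 1] - 0.5
  mkset <- function(base, n, cls, s0) lapply(1:n, function(i) {
    set.seed(s0 + i)
    landmark_config(base + matrix(rnorm(26, 0, 0.02), 13, 2,
                                  dimnames = dimnames(baseA)),
                    id = sprintf("%s%d", cls, i), class = cls)
  })
  train <- c(mkset(baseA, 10, "A", 400), mkset(baseB, 10, "B", 500))
  sp2 <- gpa(train, slide = FALSE)
  p2 <- shape_pca(sp2)
  heldA <- mkset(baseA, 5, "HA", 600)
  scores_h <- project_shapes(heldA, p2)
  centA <- colMeans(p2$scores[sp2$info$class == "A", 1, drop = FALSE])
  centB <- colMeans(p2$scores[sp2$info$class == "B", 1, drop = FALSE])
  expect_true(all(abs(scores_h[, 1] - centA) < abs(scores_h[, 1] - centB)))
})
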