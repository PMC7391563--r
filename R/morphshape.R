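#' Landmark configuration for one specimen
#'
#' Thirteen labelled 2D points using ids `1..7, 10..15`; points `11..14` are
#' semilandmarks equally spaced on the dorsal head profile between landmarks
#' 10 (snout tip) and 15 (dorsal head margin). The y axis increases upward
#' (mathematical convention); TPS files digitized in image-down coordinates
#' can be flipped on read.
#'
#' @param points 13 x 2 numeric matrix with rownames
#'   `c("1".."7","10".."15")` (any order; stored in canonical order).
#' @param id Specimen identifier.
#' @param SL,HW Directly measured standard length and head width (mm), or
#'   `NA`.
#' @param class,sex Optional labels.
#' @return Object of class `landmark_config`.
#' @export
landmark_config <- function(points, id = "specimen", SL = NA_real_,
                            HW = NA_real_, class = NA_character_,
                            sex = NA_character_) {
  ids <- as.character(c(1:7, 10:15))
  .check(is.matrix(points) && ncol(points) == 2 && nrow(points) == 13,
         "points must be a 13 x 2 matrix")
  .check(setequal(rownames(points), ids), "landmark ids must be 1..7, 10..15")
  pts <- points[ids, , drop = FALSE]
  .check(all(is.finite(pts)), "all landmarks must be finite")
  if (!is.na(SL)) .check(SL > 0, "SL must be positive")
  colnames(pts) <- c("x", "y")
  structure(list(points = pts, id = id, SL = SL, HW = HW, class = class,
                 sex = sex, semilandmarks = as.character(11:14)),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat(sprintf("landmark_config '%s' (class %s, SL %.4g mm)\n", x$id, x$class,
              x$SL))
  invisible(x)
}

#' Read a TPS landmark file
#'
#' Supports `LM=`, `IMAGE=`, `ID=` and `SCALE=` records; coordinates are
#' multiplied by the scale factor when present. With `flip_y = TRUE`, y
#' coordinates are negated to convert image-down digitizations to the
#' package's y-up convention.
#'
#' @param path File path.
#' @param flip_y Negate y coordinates on read?
#' @return List of [landmark_config()] objects.
#' @export
read_tps <- function(path, flip_y = FALSE) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  out <- list(); i <- 1; rec <- 0
  while (i <= length(lines)) {
    if (!grepl("^LM=", lines[i]))
      stop(sprintf("TPS parse error at line %d: expected LM= record", i))
    rec <- rec + 1
    k <- as.integer(sub("^LM=", "", lines[i]))
    if (is.na(k) || i + k > length(lines))
      stop(sprintf("TPS parse error in record %d: bad landmark count", rec))
    coords <- lines[(i + 1):(i + k)]
    mat <- try(matrix(as.numeric(unlist(strsplit(coords, "[ \t]+"))),
                      ncol = 2, byrow = TRUE), silent = TRUE)
    if (inherits(mat, "try-error") || nrow(mat) != k || anyNA(mat))
      stop(sprintf("TPS parse error in record %d: malformed coordinates", rec))
    i <- i + k + 1
    id <- sprintf("spec_%d", rec); scale <- 1
    while (i <= length(lines) && !grepl("^LM=", lines[i])) {
      if (grepl("^ID=", lines[i])) id <- sub("^ID=", "", lines[i])
      if (grepl("^IMAGE=", lines[i]) && id == sprintf("spec_%d", rec))
        id <- sub("^IMAGE=", "", lines[i])
      if (grepl("^SCALE=", lines[i]))
        scale <- as.numeric(sub("^SCALE=", "", lines[i]))
      i <- i + 1
    }
    mat <- mat * scale
    if (flip_y) mat[, 2] <- -mat[, 2]
    if (k == 13) {
      rownames(mat) <- as.character(c(1:7, 10:15))
      out[[rec]] <- landmark_config(mat, id = id)
    } else {
      rownames(mat) <- as.character(seq_len(k))
      out[[rec]] <- structure(list(points = mat, id = id), class = "raw_tps")
    }
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' @param configs List of `landmark_config` objects.
#' @param path File path.
#' @export
write_tps <- function(configs, path) {
  lines <- unlist(lapply(configs, function(cf) {
    c(sprintf("LM=%d", nrow(cf$points)),
      sprintf("%.10g %.10g", cf$points[, 1], cf$points[, 2]),
      sprintf("ID=%s", cf$id))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Linear head distances from a landmark configuration
#'
#' Epaxial depth EpD = d(1,15), lower jaw length LJL = d(3,4), maxilla
#' length ML = d(3,10), eye length EyL = d(5,6), in the configuration's
#' units.
#'
#' @param config A `landmark_config`.
#' @return Named numeric vector `EpD`, `LJL`, `ML`, `EyL`.
#' @export
linear_distances <- function(config) {
  p <- config$points
  d <- function(a, b) sqrt(sum((p[a, ] - p[b, ])^2))
  c(EpD = d("1", "15"), LJL = d("3", "4"), ML = d("3", "10"),
    EyL = d("5", "6"))
}

#' Mouth angle in degrees
#'
#' The angle of the eye axis (landmark 5 to 6) minus the angle of the jaw
#' axis (snout tip 10 to jaw hinge 3):
#' `atan2(y6-y5, x6-x5)*180/pi - atan2(y3-y10, x3-x10)*180/pi`.
#' An upturned mouth gives a larger angle.
#'
#' @param config A `landmark_config`.
#' @return Angle in degrees.
#' @export
mouth_angle <- function(config) {
  p <- config$points
  (atan2(p["6", 2] - p["5", 2], p["6", 1] - p["5", 1]) -
     atan2(p["3", 2] - p["10", 2], p["3", 1] - p["10", 1])) * 180 / pi
}

#' Standardize jaw opening across specimens
#'
#' Preserved specimens differ in how far the lower jaw hangs open. Landmark
#' 4 (jaw tip) is rotated about landmark 3 (jaw hinge) so that the angle
#' between the jaw axis (3 to 4) and the maxilla axis (3 to 10) equals the
#' cross-specimen mean angle; jaw length is preserved exactly.
#'
#' @param configs List of `landmark_config` objects.
#' @return The list with landmark 4 rotated in each configuration.
#' @export
standardize_jaw <- function(configs) {
  .check(length(configs) >= 1, "need at least one configuration")
  ang <- vapply(configs, function(cf) {
    p <- cf$points
    v1 <- p["10", ] - p["3", ]; v2 <- p["4", ] - p["3", ]
    atan2(v1[1] * v2[2] - v1[2] * v2[1], sum(v1 * v2))
  }, numeric(1))
  target <- mean(ang)
  lapply(seq_along(configs), function(i) {
    cf <- configs[[i]]
    d <- target - ang[i]
    R <- matrix(c(cos(d), sin(d), -sin(d), cos(d)), 2, 2)
    v <- cf$points["4", ] - cf$points["3", ]
    cf$points["4", ] <- cf$points["3", ] + as.vector(R %*% v)
    cf
  })
}

# ---- Procrustes machinery ------------------------------------------------

# center a k x 2 matrix and scale to unit centroid size
.center_scale <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  cs <- sqrt(sum(m^2))
  if (cs < 1e-12) stop("degenerate configuration: all points coincident")
  list(m = m / cs, csize = cs)
}

# optimal rotation of m onto target (both centered); no reflection
.opt_rotate <- function(m, target) {
  s <- svd(crossprod(m, target))
  R <- s$u %*% diag(c(1, det(s$u %*% t(s$v)))) %*% t(s$v)
  m %*% R
}

#' Thin-plate-spline bending energy matrix of a reference configuration
#'
#' @param ref k x 2 reference (consensus) configuration.
#' @return k x k bending energy matrix (positive semidefinite, annihilating
#'   affine transforms of the reference).
#' @export
bending_energy_matrix <- function(ref) {
  k <- nrow(ref)
  d2 <- as.matrix(stats::dist(ref))^2
  K <- ifelse(d2 == 0, 0, d2 * log(d2))
  Q <- cbind(1, ref)
  L <- rbind(cbind(K, Q), cbind(t(Q), matrix(0, 3, 3)))
  Li <- solve(L)
  Be <- Li[1:k, 1:k]
  (Be + t(Be)) / 2
}

#' Total bending energy of target configurations relative to a reference
#'
#' @param Y k x 2 matrix or k x 2 x n array of targets.
#' @param Be Bending energy matrix of the reference.
#' @return Scalar total bending energy.
#' @export
bending_energy <- function(Y, Be) {
  if (length(dim(Y)) == 2) Y <- array(Y, c(dim(Y), 1))
  sum(apply(Y, 3, function(m) sum(diag(t(m) %*% Be %*% m))))
}

# one Gauss-Seidel sliding pass for a single specimen (k x 2 matrix),
# semilandmarks slid along their local curve tangent to reduce TPS bending
# energy against the consensus. chain: 10-11-12-13-14-15.
.slide_pass <- function(m, consensus, Be, sliders = as.character(11:14)) {
  ids <- rownames(m)
  for (s in sliders) {
    j <- match(s, ids)
    nb <- as.character(as.integer(s) + c(-1, 1))
    tvec <- m[nb[2], ] - m[nb[1], ]
    tn <- sqrt(sum(tvec^2))
    if (tn < 1e-12) next
    tvec <- tvec / tn
    G <- Be %*% (m - consensus)      # gradient/2 of energy wrt coordinates
    alpha <- -sum(tvec * G[j, ]) / Be[j, j]
    m[j, ] <- m[j, ] + alpha * tvec
  }
  m
}

#' Generalized Procrustes analysis with optional sliding semilandmarks
#'
#' Iterative superimposition: each configuration is centred, scaled to unit
#' centroid size and optimally rotated to the consensus; the consensus is
#' the re-normalized mean, iterated to convergence. With `slide = TRUE`,
#' after each converged superimposition the semilandmarks are displaced
#' along their local curve tangents (one Gauss-Seidel pass per specimen) to
#' reduce thin-plate-spline bending energy against the consensus, and the
#' superimposition is repeated (up to `max_slide_iter` outer iterations).
#'
#' @param configs List of `landmark_config` objects.
#' @param slide Slide semilandmarks?
#' @param tol Convergence tolerance on the consensus change.
#' @param max_slide_iter Maximum sliding (outer) iterations.
#' @return Object of class `shape_space`: `aligned` (k x 2 x n array),
#'   `consensus`, `csize`, `ids`, `info` data.frame (id, class, sex, SL,
#'   HW), `be_trace` (bending energy before/after each sliding pass), and
#'   `semilandmarks`.
#' @export
gpa <- function(configs, slide = TRUE, tol = 1e-10, max_slide_iter = 5) {
  .check(length(configs) >= 2, "GPA needs at least two configurations")
  ids <- vapply(configs, function(cf) cf$id, character(1))
  k <- nrow(configs[[1]]$points)
  X <- array(NA_real_, c(k, 2, length(configs)),
             dimnames = list(rownames(configs[[1]]$points), c("x", "y"), ids))
  csize <- numeric(length(configs))
  for (i in seq_along(configs)) {
    cs <- .center_scale(configs[[i]]$points)
    X[, , i] <- cs$m; csize[i] <- cs$csize
  }
  superimpose <- function(X) {
    consensus <- X[, , 1]
    for (iter in seq_len(200)) {
      for (i in seq_len(dim(X)[3]))
        X[, , i] <- .opt_rotate(X[, , i], consensus)
      newc <- apply(X, c(1, 2), mean)
      newc <- .center_scale(newc)$m
      done <- sum((newc - consensus)^2) < tol
      consensus <- newc
      if (done) break
    }
    # final rotation pass against the converged consensus
    for (i in seq_len(dim(X)[3])) X[, , i] <- .opt_rotate(X[, , i], consensus)
    list(X = X, consensus = consensus)
  }
  sup <- superimpose(X)
  be_trace <- NULL
  if (slide) {
    for (it in seq_len(max_slide_iter)) {
      Be <- bending_energy_matrix(sup$consensus)
      e_before <- bending_energy(sweep(sup$X, c(1, 2), sup$consensus), Be)
      for (i in seq_len(dim(sup$X)[3]))
        sup$X[, , i] <- .slide_pass(sup$X[, , i], sup$consensus, Be)
      e_after <- bending_energy(sweep(sup$X, c(1, 2), sup$consensus), Be)
      be_trace <- rbind(be_trace, c(before = e_before, after = e_after))
      # re-superimpose (sliding changes centroid position/size slightly)
      for (i in seq_len(dim(sup$X)[3]))
        sup$X[, , i] <- .center_scale(sup$X[, , i])$m
      sup <- superimpose(sup$X)
      if (e_before - e_after < tol) break
    }
  }
  info <- data.frame(
    id = ids,
    class = vapply(configs, function(cf)
      as.character(cf$class %||% NA), character(1)),
    sex = vapply(configs, function(cf)
      as.character(cf$sex %||% NA), character(1)),
    SL = vapply(configs, function(cf) as.numeric(cf$SL %||% NA), numeric(1)),
    HW = vapply(configs, function(cf) as.numeric(cf$HW %||% NA), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(aligned = sup$X, consensus = sup$consensus, csize = csize,
                 ids = ids, info = info, be_trace = be_trace,
                 semilandmarks = configs[[1]]$semilandmarks %||%
                   as.character(11:14)),
            class = "shape_space")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.shape_space <- function(x, ...) {
  cat(sprintf("shape_space: %d specimens, %d landmarks\n", dim(x$aligned)[3],
              dim(x$aligned)[1]))
  invisible(x)
}

#' Procrustes distance between two configurations
#'
#' Both configurations are centred and scaled to unit centroid size, the
#' second optimally rotated onto the first; the distance is the square root
#' of the summed squared coordinate differences.
#'
#' @param a,b k x 2 matrices or `landmark_config` objects.
#' @return Nonnegative scalar.
#' @export
procrustes_distance <- function(a, b) {
  if (inherits(a, "landmark_config")) a <- a$points
  if (inherits(b, "landmark_config")) b <- b$points
  a <- .center_scale(a)$m
  b <- .center_scale(b)$m
  b <- .opt_rotate(b, a)
  sqrt(sum((a - b)^2))
}

#' Remove allometric shape variation
#'
#' Regresses each aligned coordinate on log10 standard length (pooled, or
#' within groups when `groups` is given, as for museum specimens with a
#' different allometric slope) and returns residuals plus the consensus.
#' The shape-on-size association is summarized by a Goodall-style F
#' statistic with a permutation p value (residual randomization).
#'
#' @param space A `shape_space`.
#' @param logSL Numeric vector of log10 SL, one per specimen (defaults to
#'   `log10(space$info$SL)`).
#' @param groups Optional factor: fit the allometric regression separately
#'   within each group.
#' @param n_perm Permutations for the shape~size test.
#' @param seed Integer seed for the permutation test.
#' @return List: `shapes` (k x 2 x n array of allometry-free shapes),
#'   `report` (F, df1, df2, p), `coefficients` (allometry vector(s), per
#'   coordinate).
#' @export
allometry_free <- function(space, logSL = NULL, groups = NULL, n_perm = 999,
                           seed = 1) {
  .check(inherits(space, "shape_space"), "space must be a shape_space")
  n <- dim(space$aligned)[3]; k <- dim(space$aligned)[1]
  if (is.null(logSL)) logSL <- log10(space$info$SL)
  .check(length(logSL) == n && all(is.finite(logSL)),
         "logSL must be available for every specimen")
  Y <- t(apply(space$aligned, 3, as.vector))   # n x 2k
  fit_resid <- function(Y, x) {
    xc <- x - mean(x)
    Yc <- sweep(Y, 2, colMeans(Y))
    beta <- as.vector(crossprod(xc, Yc)) / sum(xc^2)
    list(resid = Yc - outer(xc, beta), beta = beta)
  }
  if (is.null(groups)) {
    fr <- fit_resid(Y, logSL)
    resid <- fr$resid; beta <- fr$beta
  } else {
    groups <- as.factor(groups)
    resid <- Y * NA; beta <- list()
    for (g in levels(groups)) {
      sel <- groups == g
      fr <- fit_resid(Y[sel, , drop = FALSE], logSL[sel])
      resid[sel, ] <- fr$resid; beta[[g]] <- fr$beta
    }
  }
  # Goodall-style F for the pooled shape ~ size regression
  xc <- logSL - mean(logSL)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(Yc^2)
  ss_mod <- sum((crossprod(xc, Yc))^2) / sum(xc^2)
  ss_res <- ss_tot - ss_mod
  Fobs <- (ss_mod / 1) / (ss_res / (n - 2))
  set.seed(child_seed(seed, "allometry"))
  fstar <- replicate(n_perm, {
    xp <- sample(xc)
    sm <- sum((crossprod(xp, Yc))^2) / sum(xp^2)
    (sm / 1) / ((ss_tot - sm) / (n - 2))
  })
  pval <- (1 + sum(fstar >= Fobs)) / (n_perm + 1)
  shapes <- array(t(resid), c(k, 2, n),
                  dimnames = dimnames(space$aligned)) +
    array(space$consensus, c(k, 2, n))
  list(shapes = shapes,
       report = data.frame(F = Fobs, df1 = 1, df2 = n - 2, p = pval),
       coefficients = beta)
}

#' Test homogeneity of allometric slopes between classes
#'
#' Compares a common-slope model against class-specific slopes for the
#' shape ~ log10(SL) regression; F is the summed-SS ratio and p comes from
#' residual randomization.
#'
#' @inheritParams allometry_free
#' @param class Factor of class labels.
#' @return data.frame `F`, `df1`, `df2`, `p`.
#' @export
allometry_homogeneity <- function(space, logSL = NULL, class, n_perm = 999,
                                  seed = 1) {
  n <- dim(space$aligned)[3]
  if (is.null(logSL)) logSL <- log10(space$info$SL)
  class <- as.factor(class)
  Y <- t(apply(space$aligned, 3, as.vector))
  rss <- function(Y, X) {
    Q <- qr(X)
    sum((Y - X %*% qr.coef(Q, Y))^2)
  }
  X0 <- stats::model.matrix(~ class + logSL)
  X1 <- stats::model.matrix(~ class * logSL)
  df1 <- ncol(X1) - ncol(X0)
  df2 <- n - ncol(X1)
  r0 <- rss(Y, X0); r1 <- rss(Y, X1)
  Fobs <- ((r0 - r1) / df1) / (r1 / df2)
  # residual randomization under the reduced (common-slope) model
  fit0 <- X0 %*% qr.coef(qr(X0), Y)
  res0 <- Y - fit0
  set.seed(child_seed(seed, "homogeneity"))
  fstar <- replicate(n_perm, {
    Yp <- fit0 + res0[sample(n), , drop = FALSE]
    r0p <- rss(Yp, X0); r1p <- rss(Yp, X1)
    ((r0p - r1p) / df1) / (r1p / df2)
  })
  data.frame(F = Fobs, df1 = df1, df2 = df2,
             p = (1 + sum(fstar >= Fobs)) / (n_perm + 1))
}

#' Principal component analysis of shape
#'
#' Eigen-decomposition of the covariance of the aligned (or allometry-free)
#' coordinates. Axis signs follow a deterministic convention: the loading
#' with the largest magnitude on each axis is positive.
#'
#' @param space A `shape_space`, or a k x 2 x n array of shapes.
#' @return Object of class `shape_pca`: `axes` (2k x npc), `scores`
#'   (n x npc), `var_frac`, `center` (2k), `consensus`, `dim` = c(k, 2).
#' @export
shape_pca <- function(space) {
  shapes <- if (inherits(space, "shape_space")) space$aligned else space
  k <- dim(shapes)[1]; n <- dim(shapes)[3]
  Y <- t(apply(shapes, 3, as.vector))
  # axes come from the column-centred data; scores are taken about the
  # unit-size consensus so that projecting the consensus scores exactly zero
  consensus <- if (inherits(space, "shape_space")) space$consensus
  else .center_scale(apply(shapes, c(1, 2), mean))$m
  ctr <- as.vector(consensus)
  Yc <- sweep(Y, 2, colMeans(Y))
  sv <- svd(Yc)
  keep <- which(sv$d > max(sv$d) * 1e-10)
  axes <- sv$v[, keep, drop = FALSE]
  flip <- apply(axes, 2, function(v) sign(v[which.max(abs(v))]))
  axes <- sweep(axes, 2, flip, `*`)
  scores <- sweep(Y, 2, ctr) %*% axes
  var_frac <- sv$d[keep]^2 / sum(sv$d[keep]^2)
  colnames(axes) <- colnames(scores) <- sprintf("PC%d", seq_along(keep))
  rownames(scores) <- dimnames(shapes)[[3]]
  structure(list(axes = axes, scores = scores, var_frac = var_frac,
                 center = ctr, consensus = consensus, dim = c(k, 2)),
            class = "shape_pca")
}

#' Project external specimens into an existing shape space
#'
#' Each new configuration is superimposed onto the consensus by ordinary
#' Procrustes (centering, unit centroid size, optimal rotation; the
#' consensus is not updated and no sliding is performed), then scored on
#' the existing principal axes.
#'
#' @param configs List of `landmark_config` objects, a single k x 2 matrix,
#'   or a k x 2 x n array of already-aligned shapes.
#' @param pca A `shape_pca`.
#' @param consensus Optional k x 2 consensus to align against (defaults to
#'   the pca's consensus).
#' @return Matrix of predicted scores (n x npc).
#' @export
project_shapes <- function(configs, pca, consensus = NULL) {
  .check(inherits(pca, "shape_pca"), "pca must be a shape_pca")
  if (is.null(consensus)) consensus <- pca$consensus
  if (inherits(configs, "landmark_config")) configs <- list(configs)
  if (is.matrix(configs)) configs <- array(configs, c(dim(configs), 1))
  get_mat <- function(i) {
    if (is.array(configs)) configs[, , i] else configs[[i]]$points
  }
  n <- if (is.array(configs)) dim(configs)[3] else length(configs)
  scores <- matrix(NA_real_, n, ncol(pca$axes))
  for (i in seq_len(n)) {
    m <- .center_scale(get_mat(i))$m
    m <- .opt_rotate(m, consensus)
    scores[i, ] <- (as.vector(m) - pca$center) %*% pca$axes
  }
  colnames(scores) <- colnames(pca$axes)
  scores
}
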