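#' Kosambi mapping function
#'
#' Converts a recombination fraction to map distance,
#' `d = 25 * ln((1 + 2r) / (1 - 2r))` cM, allowing partial crossover
#' interference.
#'
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Map distance in centiMorgans.
#' @export
kosambi <- function(r) {
  .check(all(r >= 0 & r < 0.5), "r must be in [0, 0.5)")
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' Inverse Kosambi mapping function
#'
#' `r = 0.5 * tanh(2d)` with d in Morgans (input in cM).
#'
#' @param d_cM Map distance in centiMorgans (>= 0).
#' @return Recombination fraction.
#' @export
kosambi_inverse <- function(d_cM) {
  .check(all(d_cM >= 0), "d must be >= 0")
  0.5 * tanh(2 * d_cM / 100)
}

#' Haldane mapping function and inverse
#'
#' `d = -50 * ln(1 - 2r)` cM; inverse `r = 0.5 * (1 - exp(-2d))` with d in
#' Morgans (no interference).
#'
#' @param r Recombination fraction in `[0, 0.5)`.
#' @return Map distance in centiMorgans.
#' @export
haldane <- function(r) {
  .check(all(r >= 0 & r < 0.5), "r must be in [0, 0.5)")
  -50 * log(1 - 2 * r)
}

#' @rdname haldane
#' @param d_cM Map distance in centiMorgans (>= 0).
#' @export
haldane_inverse <- function(d_cM) {
  .check(all(d_cM >= 0), "d must be >= 0")
  0.5 * (1 - exp(-2 * d_cM / 100))
}

# genotype codes as integer A-allele counts; NA preserved
.code_geno <- function(geno) {
  g <- matrix(NA_integer_, nrow(geno), ncol(geno), dimnames = dimnames(geno))
  g[geno == "BB"] <- 0L; g[geno == "AB"] <- 1L; g[geno == "AA"] <- 2L
  g
}

#' Pre-mapping marker and individual QC
#'
#' Markers are tested for segregation distortion against the Mendelian
#' 1:2:1 F2 expectation (chi-square goodness of fit on non-missing counts)
#' and dropped at `p < distortion_alpha` or when missingness exceeds
#' `max_marker_missing`; all-missing markers are dropped with a dedicated
#' reason. Individuals with more than `max_individual_missing` missing
#' genotypes are then dropped.
#'
#' @param geno Character genotype matrix (individuals x markers,
#'   `AA`/`AB`/`BB`/`NA`) or an `f2_geno` object.
#' @param distortion_alpha,max_marker_missing,max_individual_missing
#'   Thresholds (study values 0.01, 0.2, 0.3).
#' @return List: `geno` (retained matrix), `markers` (data.frame `marker`,
#'   `chisq`, `p`, `missing`, `reason` — `""` if retained), `individuals`
#'   (data.frame `id`, `missing`, `retained`).
#' @export
qc_markers <- function(geno, distortion_alpha = 0.01,
                       max_marker_missing = 0.2,
                       max_individual_missing = 0.3) {
  if (inherits(geno, "f2_geno")) geno <- geno$geno
  .check(is.matrix(geno) && ncol(geno) >= 1, "geno must be a nonempty matrix")
  g <- .code_geno(geno)
  stat <- t(vapply(seq_len(ncol(g)), function(j) {
    obs <- tabulate(g[, j] + 1L, 3L)  # BB, AB, AA
    n <- sum(obs)
    if (n == 0) return(c(NA_real_, NA_real_))
    e <- n * c(0.25, 0.5, 0.25)
    x2 <- sum((obs - e)^2 / e)
    c(x2, stats::pchisq(x2, df = 2, lower.tail = FALSE))
  }, numeric(2)))
  miss <- colMeans(is.na(g))
  reason <- rep("", ncol(g))
  reason[miss > max_marker_missing] <- "missingness"
  reason[!is.na(stat[, 2]) & stat[, 2] < distortion_alpha & reason == ""] <-
    "distortion"
  reason[is.na(stat[, 2])] <- "all_missing"
  keep_m <- reason == ""
  g2 <- geno[, keep_m, drop = FALSE]
  ind_miss <- rowMeans(is.na(g2))
  keep_i <- ind_miss <= max_individual_missing
  list(geno = g2[keep_i, , drop = FALSE],
       markers = data.frame(marker = colnames(geno), chisq = stat[, 1],
                            p = stat[, 2], missing = miss, reason = reason,
                            stringsAsFactors = FALSE),
       individuals = data.frame(id = rownames(g2), missing = ind_miss,
                                retained = keep_i, stringsAsFactors = FALSE))
}

#' Pairwise independence LOD between markers
#'
#' For every marker pair, the likelihood-ratio (G) statistic of
#' independence on the observed 3 x 3 genotype table over individuals
#' non-missing at both markers, scaled to a LOD as `G / (2 ln 10)`. Pairs
#' with no overlapping individuals get LOD 0.
#'
#' @param geno Genotype matrix or `f2_geno`.
#' @return Symmetric marker x marker LOD matrix (diagonal `NA`).
#' @export
pairwise_independence_lod <- function(geno) {
  if (inherits(geno, "f2_geno")) geno <- geno$geno
  .check(ncol(geno) >= 2, "need at least two markers")
  g <- .code_geno(geno)
  m <- ncol(g)
  # indicator matrices per genotype class (missing -> all-zero row)
  ind <- lapply(0:2, function(v) {
    x <- (g == v); x[is.na(x)] <- FALSE; storage.mode(x) <- "double"; x
  })
  N <- vector("list", 9)
  for (a in 1:3) for (b in 1:3)
    N[[(a - 1) * 3 + b]] <- crossprod(ind[[a]], ind[[b]])
  ntot <- Reduce(`+`, N)
  G <- matrix(0, m, m)
  for (a in 1:3) {
    row_a <- Reduce(`+`, N[(a - 1) * 3 + 1:3])
    for (b in 1:3) {
      col_b <- Reduce(`+`, N[seq(b, 9, by = 3)])
      O <- N[[(a - 1) * 3 + b]]
      E <- row_a * col_b / ntot
      term <- O * log(O / E)
      term[O == 0 | !is.finite(term)] <- 0
      G <- G + term
    }
  }
  lod <- 2 * G / (2 * log(10))
  lod[ntot == 0] <- 0
  diag(lod) <- NA
  dimnames(lod) <- list(colnames(geno), colnames(geno))
  lod
}

# minimal union-find for single-linkage grouping
.union_find <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  if (nrow(edges) > 0)
    for (e in seq_len(nrow(edges))) {
      a <- find(edges[e, 1]); b <- find(edges[e, 2])
      if (a != b) parent[b] <- a
    }
  vapply(seq_len(n), find, integer(1))
}

#' Group markers into linkage groups
#'
#' Single-linkage transitive closure: two markers belong to the same group
#' iff they are connected by a chain of pairs with LOD at or above the
#' threshold (study value 7.0).
#'
#' @param lod LOD matrix from [pairwise_independence_lod()].
#' @param threshold Grouping LOD threshold.
#' @return Integer vector of group labels (1, 2, ... in order of first
#'   appearance), named by marker.
#' @export
group_markers <- function(lod, threshold = 7) {
  m <- nrow(lod)
  adj <- which(!is.na(lod) & lod >= threshold & upper.tri(lod), arr.ind = TRUE)
  root <- .union_find(m, adj)
  labels <- match(root, unique(root))
  stats::setNames(labels, rownames(lod))
}

# two-locus F2 genotype class probabilities given r (3x3, indices = A-count+1)
.f2_joint <- function(r) {
  hap <- c(AB = (1 - r) / 2, ab = (1 - r) / 2, Ab = r / 2, aB = r / 2)
  hx <- c(AB = 1, ab = 0, Ab = 1, aB = 0)  # A-allele at locus 1
  hy <- c(AB = 1, ab = 0, Ab = 0, aB = 1)  # A-allele at locus 2
  P <- matrix(0, 3, 3)
  for (u in 1:4) for (v in 1:4) {
    i <- hx[u] + hx[v] + 1; j <- hy[u] + hy[v] + 1
    P[i, j] <- P[i, j] + hap[u] * hap[v]
  }
  P
}

#' Estimate the recombination fraction between two markers
#'
#' Maximum-likelihood estimate for an F2 intercross with codominant
#' markers, via EM over the two-locus genotype classes (the double
#' heterozygote class mixes parental and recombinant gamete pairs).
#' The estimate is clamped to `[0, 0.4999]` to keep Kosambi distances
#' finite.
#'
#' @param g1,g2 Genotype vectors (`AA`/`AB`/`BB`/`NA`).
#' @param tol,maxit EM convergence controls.
#' @return List `rhat`, `lod` (likelihood-ratio LOD against r = 0.5), `n`
#'   (informative pairs).
#' @export
estimate_rf <- function(g1, g2, tol = 1e-10, maxit = 1000) {
  x <- .code_geno(matrix(g1, ncol = 1))[, 1]
  y <- .code_geno(matrix(g2, ncol = 1))[, 1]
  ok <- !is.na(x) & !is.na(y)
  .check(sum(ok) >= 2, "need at least two overlapping individuals")
  N <- matrix(0, 3, 3)
  for (i in which(ok)) N[x[i] + 1, y[i] + 1] <- N[x[i] + 1, y[i] + 1] + 1
  n <- sum(N)
  # expected recombinant gametes per class; double het handled in E-step
  Rfix <- matrix(c(0, 1, 2,
                   1, NA, 1,
                   2, 1, 0), 3, 3, byrow = TRUE)
  r <- 0.3
  for (it in seq_len(maxit)) {
    dh <- 2 * r^2 / ((1 - r)^2 + r^2)  # E[rec gametes | double het]
    R <- Rfix; R[2, 2] <- dh
    rnew <- sum(N * R) / (2 * n)
    rnew <- min(max(rnew, 1e-9), 0.4999)
    if (abs(rnew - r) < tol) { r <- rnew; break }
    r <- rnew
  }
  ll <- function(rr) sum(N * log(.f2_joint(rr)))
  list(rhat = r, lod = (ll(r) - ll(0.5)) / log(10), n = n)
}

# greedy nearest-neighbour seriation on a recombination-fraction matrix
.greedy_order <- function(rf) {
  m <- nrow(rf)
  if (m <= 2) return(seq_len(m))
  diag(rf) <- NA
  # start from the marker with the largest distance to its farthest peer
  start <- which.max(apply(rf, 1, max, na.rm = TRUE))
  ord <- start; left <- setdiff(seq_len(m), start)
  while (length(left) > 0) {
    last <- ord[length(ord)]
    nxt <- left[which.min(rf[last, left])]
    ord <- c(ord, nxt); left <- setdiff(left, nxt)
  }
  ord
}

#' Build a linkage map from grouped markers
#'
#' Orders the markers of each group (the given input order, assumed true in
#' simulations, or a greedy nearest-neighbour seriation on pairwise
#' recombination fractions), estimates adjacent-pair recombination
#' fractions by EM, and accumulates Kosambi distances into cM positions.
#' Multipoint regression ordering (as in commercial mapping software) is
#' deliberately not reimplemented; the ordering mode is recorded in the
#' output.
#'
#' @param groups Named group labels from [group_markers()].
#' @param geno Genotype matrix or `f2_geno` (columns must include all
#'   grouped markers).
#' @param order `"given"` or `"greedy"`.
#' @return Object of class `linkage_map`: `map` data.frame (`group`,
#'   `marker`, `pos_cM`, `rhat_prev`), `summary` list (`n_markers`,
#'   `n_groups`, `markers_per_group`, `mean`, `sd`, `min`, `max`,
#'   `length_cM`), `ordering`.
#' @export
build_map <- function(groups, geno, order = c("given", "greedy")) {
  order <- match.arg(order)
  if (inherits(geno, "f2_geno")) geno <- geno$geno
  .check(all(names(groups) %in% colnames(geno)),
         "all grouped markers must be genotyped")
  res <- list()
  for (gid in sort(unique(groups))) {
    mks <- names(groups)[groups == gid]
    sub <- geno[, mks, drop = FALSE]
    if (length(mks) > 2 && order == "greedy") {
      rf <- matrix(0.5, length(mks), length(mks))
      for (i in seq_along(mks)) for (j in seq_along(mks)) if (i < j) {
        est <- estimate_rf(sub[, i], sub[, j])
        rf[i, j] <- rf[j, i] <- est$rhat
      }
      ord <- .greedy_order(rf)
    } else ord <- seq_along(mks)
    mks <- mks[ord]
    rhat <- c(NA, vapply(seq_len(length(mks) - 1), function(i)
      estimate_rf(geno[, mks[i]], geno[, mks[i + 1]])$rhat, numeric(1)))
    pos <- cumsum(c(0, kosambi(pmin(rhat[-1], 0.4999))))
    res[[length(res) + 1]] <- data.frame(group = gid, marker = mks,
                                         pos_cM = pos, rhat_prev = rhat,
                                         stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, res)
  mpg <- table(map$group)
  summ <- list(n_markers = nrow(map), n_groups = length(mpg),
               markers_per_group = as.integer(mpg),
               mean = mean(as.integer(mpg)), sd = stats::sd(as.integer(mpg)),
               min = min(as.integer(mpg)), max = max(as.integer(mpg)),
               length_cM = sum(tapply(map$pos_cM, map$group, max)))
  structure(list(map = map, summary = summ, ordering = order),
            class = "linkage_map")
}

#' @export
print.linkage_map <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("linkage_map: %d markers in %d groups ",
                     "(mean %.2f, SD %.2f, min %d, max %d per group); ",
                     "total length %.1f cM; ordering: %s\n"),
              s$n_markers, s$n_groups, s$mean, s$sd, s$min, s$max,
              s$length_cM, x$ordering))
  invisible(x)
}
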