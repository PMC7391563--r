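#' Conditional genotype probabilities on a cM grid
#'
#' Hidden Markov forward-backward computation of
#' `P(true genotype | all marker observations)` for each individual along
#' each linkage group, on a grid of the marker positions plus pseudomarkers
#' every `step` cM (anchored at the group's first marker). Transition
#' probabilities between adjacent grid positions come from the mapping
#' function's recombination fraction for the interval, with the F2
#' transition matrix formed from two independent meioses. Emissions allow
#' a genotyping error probability: `1 - error_prob` for the observed
#' genotype and `error_prob / 2` for each other genotype; missing
#' observations emit uniformly.
#'
#' @param geno Genotype matrix (individuals x markers, `AA`/`AB`/`BB`/NA)
#'   or `f2_geno`.
#' @param map A `linkage_map` or data.frame with `group`, `marker`,
#'   `pos_cM` (positions nondecreasing within group).
#' @param step Pseudomarker step in cM.
#' @param error_prob Genotyping error probability (study value 0.05).
#' @param map_function `"kosambi"` or `"haldane"`.
#' @return Object of class `genoprob`: list `groups` (per linkage group:
#'   `pos`, `marker` (NA at pseudomarkers), `prob` array n x 3 x npos with
#'   states AA/AB/BB), `ids`, `step`, `error_prob`.
#' @export
calc_genoprob <- function(geno, map, step = 1, error_prob = 0.05,
                          map_function = c("kosambi", "haldane")) {
  map_function <- match.arg(map_function)
  if (inherits(geno, "f2_geno")) geno <- geno$geno
  if (inherits(map, "linkage_map")) map <- map$map
  .check(all(c("group", "marker", "pos_cM") %in% names(map)),
         "map must have group, marker, pos_cM")
  rfun <- .inv_map_fun(map_function)
  prior <- c(0.25, 0.5, 0.25)
  states <- c("AA", "AB", "BB")
  n <- nrow(geno)
  out <- list()
  for (gid in unique(map$group)) {
    sub <- map[map$group == gid, , drop = FALSE]
    .check(!is.unsorted(sub$pos_cM), "marker positions must be sorted")
    mpos <- sub$pos_cM
    gpos <- sort(unique(round(c(mpos, seq(min(mpos), max(mpos), by = step)),
                              8)))
    mk <- rep(NA_character_, length(gpos))
    mk[match(round(mpos, 8), gpos)] <- sub$marker
    P <- length(gpos)
    # emissions, n x 3 per position
    E <- vector("list", P)
    for (t in seq_len(P)) {
      if (is.na(mk[t])) { E[[t]] <- matrix(1, n, 3); next }
      obs <- geno[, mk[t]]
      e <- matrix(1, n, 3)
      for (s in 1:3) {
        e[, s] <- ifelse(is.na(obs), 1,
                         ifelse(obs == states[s], 1 - error_prob,
                                error_prob / 2))
      }
      E[[t]] <- e
    }
    trans <- function(r) {
      matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
               r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
               r^2, 2 * r * (1 - r), (1 - r)^2),
             3, 3, byrow = TRUE)
    }
    Tm <- lapply(rfun(diff(gpos)), trans)
    # forward
    a <- vector("list", P)
    a[[1]] <- sweep(E[[1]], 2, prior, `*`)
    a[[1]] <- a[[1]] / rowSums(a[[1]])
    if (P >= 2) for (t in 2:P) {
      tmp <- (a[[t - 1]] %*% Tm[[t - 1]]) * E[[t]]
      a[[t]] <- tmp / rowSums(tmp)
    }
    # backward
    b <- matrix(1, n, 3)
    prob <- array(NA_real_, c(n, 3, P),
                  dimnames = list(rownames(geno), states, NULL))
    po <- a[[P]] * b
    prob[, , P] <- po / rowSums(po)
    if (P >= 2) for (t in (P - 1):1) {
      b <- (b * E[[t + 1]]) %*% t(Tm[[t]])
      b <- b / rowSums(b)
      po <- a[[t]] * b
      prob[, , t] <- po / rowSums(po)
    }
    out[[as.character(gid)]] <- list(pos = gpos, marker = mk, prob = prob)
  }
  structure(list(groups = out, ids = rownames(geno), step = step,
                 error_prob = error_prob, map_function = map_function),
            class = "genoprob")
}

# flatten a genoprob into one cube (n x 3 x total positions) + position table
.assemble_grid <- function(gp, keep = NULL) {
  pos_df <- do.call(rbind, lapply(names(gp$groups), function(g)
    data.frame(group = g, pos = gp$groups[[g]]$pos,
               marker = gp$groups[[g]]$marker, stringsAsFactors = FALSE)))
  cubes <- lapply(gp$groups, function(gr)
    if (is.null(keep)) gr$prob else gr$prob[keep, , , drop = FALSE])
  n <- dim(cubes[[1]])[1]
  total <- sum(vapply(cubes, function(x) dim(x)[3], integer(1)))
  cube <- array(NA_real_, c(n, 3, total))
  off <- 0
  for (x in cubes) {
    cube[, , off + seq_len(dim(x)[3])] <- x
    off <- off + dim(x)[3]
  }
  list(cube = cube, pos_df = pos_df)
}

# build a covariate matrix from a vector/factor/matrix/data.frame
.covar_matrix <- function(covar, n) {
  if (is.null(covar)) return(matrix(0, n, 0))
  if (is.matrix(covar)) return(covar)
  if (is.data.frame(covar))
    return(stats::model.matrix(~ ., covar)[, -1, drop = FALSE])
  if (is.factor(covar) || is.character(covar))
    return(stats::model.matrix(~ f, data.frame(f = factor(covar)))[, -1,
                                                                   drop = FALSE])
  matrix(as.numeric(covar), ncol = 1)
}

#' Single-QTL genome scan by EM interval mapping
#'
#' At every grid position, fits the 3-component normal mixture with mixing
#' weights given by the genotype probabilities, by EM; reports
#' `LOD = log10(L_alt / L_null)` where the null retains intercept and
#' covariates but no genotype terms. `covar_type = "additive"` shifts all
#' genotype means by a common covariate effect; `"interactive"` gives each
#' genotype class its own covariate effect (the null keeps only the
#' covariate main effect). Individuals with a missing phenotype (or
#' covariate) are dropped.
#'
#' @param gp A [calc_genoprob()] object.
#' @param phenotype Numeric vector aligned with `gp$ids` (NAs dropped).
#' @param covar Optional covariate (vector, factor, or matrix), e.g. sex.
#' @param covar_type `"none"`, `"additive"`, or `"interactive"`.
#' @param tol,maxit EM convergence controls.
#' @return Object of class `lod_curve`: data.frame `group`, `pos`,
#'   `marker`, `lod`; attributes `n`, `model`, `covar_type`.
#' @export
scan_em <- function(gp, phenotype, covar = NULL,
                    covar_type = c("none", "additive", "interactive"),
                    tol = 1e-8, maxit = 1000) {
  covar_type <- match.arg(covar_type)
  .check(inherits(gp, "genoprob"), "gp must come from calc_genoprob()")
  n_all <- length(gp$ids)
  .check(length(phenotype) == n_all, "phenotype must align with gp$ids")
  Z <- .covar_matrix(if (covar_type == "none") NULL else covar, n_all)
  keep <- stats::complete.cases(cbind(phenotype, Z))
  grid <- .assemble_grid(gp, keep = which(keep))
  res <- scan_em_cpp(grid$cube, phenotype[keep],
                     Z[keep, , drop = FALSE],
                     covar_type == "interactive", tol, maxit)
  out <- grid$pos_df
  out$lod <- as.numeric(res$lod)
  structure(out, class = c("lod_curve", "data.frame"),
            n = sum(keep), model = "normal_em", covar_type = covar_type)
}

#' Nonparametric genome scan
#'
#' An extension of the Kruskal-Wallis rank test to probabilistic genotype
#' assignments: phenotypes are ranked, and at each position the statistic
#' is computed from genotype-probability-weighted rank sums (with the
#' standard tie correction). At a fully typed marker it reduces to the
#' classical Kruskal-Wallis statistic. `LOD = statistic / (2 ln 10)`.
#' Covariates are not supported by this model.
#'
#' @inheritParams scan_em
#' @return A `lod_curve` (model `"nonparametric"`).
#' @export
scan_np <- function(gp, phenotype) {
  .check(inherits(gp, "genoprob"), "gp must come from calc_genoprob()")
  keep <- which(!is.na(phenotype))
  grid <- .assemble_grid(gp, keep = keep)
  y <- phenotype[keep]
  N <- length(y)
  R <- rank(y)
  tie <- table(y)
  corr <- 1 - sum(tie^3 - tie) / (N^3 - N)
  npos <- dim(grid$cube)[3]
  lod <- numeric(npos)
  if (corr > 0 && stats::sd(y) > 0) {
    for (t in seq_len(npos)) {
      W <- grid$cube[, , t]
      sw <- colSums(W)
      swr <- colSums(W * R)
      ok <- sw > 1e-12
      H <- 12 / (N * (N + 1)) * sum(swr[ok]^2 / sw[ok]) - 3 * (N + 1)
      lod[t] <- max(0, H / corr) / (2 * log(10))
    }
  }
  out <- grid$pos_df
  out$lod <- lod
  structure(out, class = c("lod_curve", "data.frame"),
            n = N, model = "nonparametric", covar_type = "none")
}

#' @export
print.lod_curve <- function(x, ...) {
  pk <- x[which.max(x$lod), ]
  cat(sprintf("lod_curve (%s, covar %s, n = %d): %d positions, peak LOD %.2f at %s:%.1f cM\n",
              attr(x, "model"), attr(x, "covar_type"), attr(x, "n"),
              nrow(x), pk$lod, pk$group, pk$pos))
  invisible(x)
}

#' Genome-wide permutation thresholds for a scan
#'
#' Permutes the phenotype (rows of the covariates travel with it) against
#' the genotype grid, records the genome-wide maximum LOD of each
#' permutation scan, and returns empirical `1 - alpha` quantiles as
#' significance thresholds. The genome-wide p value of an observed peak is
#' `(1 + #\{max* >= peak\}) / (B + 1)`.
#'
#' @inheritParams scan_em
#' @param n_perm Number of permutations B (study value 1,000).
#' @param alphas Significance levels.
#' @param seed Integer seed.
#' @param model `"em"` or `"np"`.
#' @return List: `thresholds` (named by alpha), `maxima` (length B),
#'   `gw_p(peak)` function.
#' @export
perm_threshold <- function(gp, phenotype, covar = NULL,
                           covar_type = c("none", "additive",
                                          "interactive"),
                           n_perm = 1000, alphas = c(0.05, 0.10), seed = 1,
                           model = c("em", "np"), tol = 1e-8,
                           maxit = 1000) {
  covar_type <- match.arg(covar_type); model <- match.arg(model)
  n_all <- length(gp$ids)
  Z <- .covar_matrix(if (covar_type == "none") NULL else covar, n_all)
  keep <- which(stats::complete.cases(cbind(phenotype, Z)))
  grid <- .assemble_grid(gp, keep = keep)
  y <- phenotype[keep]; Zk <- Z[keep, , drop = FALSE]
  n <- length(y)
  one_max <- function(yy, ZZ) {
    if (model == "em") {
      max(scan_em_cpp(grid$cube, yy, ZZ, covar_type == "interactive",
                      tol, maxit)$lod)
    } else {
      R <- rank(yy)
      tie <- table(yy)
      corr <- 1 - sum(tie^3 - tie) / (n^3 - n)
      if (corr <= 0) return(0)
      m <- 0
      for (t in seq_len(dim(grid$cube)[3])) {
        W <- grid$cube[, , t]
        sw <- colSums(W); swr <- colSums(W * R)
        ok <- sw > 1e-12
        H <- 12 / (n * (n + 1)) * sum(swr[ok]^2 / sw[ok]) - 3 * (n + 1)
        m <- max(m, max(0, H / corr) / (2 * log(10)))
      }
      m
    }
  }
  set.seed(child_seed(seed, "permthr"))
  maxima <- vapply(seq_len(n_perm), function(b) {
    ix <- sample(n)
    one_max(y[ix], Zk[ix, , drop = FALSE])
  }, numeric(1))
  thresholds <- stats::quantile(maxima, 1 - alphas, names = FALSE)
  names(thresholds) <- sprintf("alpha_%g", alphas)
  list(thresholds = thresholds, maxima = maxima,
       gw_p = function(peak) (1 + sum(maxima >= peak)) / (n_perm + 1))
}

#' Bayesian credible interval for a QTL peak
#'
#' Treats `10^LOD`, normalized over the peak's linkage group, as a
#' posterior over position; returns the smallest contiguous set of grid
#' positions containing the peak with at least `prob` posterior mass, with
#' endpoints widened to the nearest flanking true markers.
#'
#' @param curve A `lod_curve`.
#' @param group Linkage group (defaults to the group of the global peak).
#' @param prob Credible mass (0.95).
#' @return List: `lo`, `hi` (cM, widened to markers), `lo_core`, `hi_core`
#'   (cM before widening), `lo_marker`, `hi_marker`, `peak_pos`, `group`.
#' @export
bayes_interval <- function(curve, group = NULL, prob = 0.95) {
  if (is.null(group)) group <- curve$group[which.max(curve$lod)]
  sub <- curve[curve$group == group, , drop = FALSE]
  w <- 10^(sub$lod - max(sub$lod))
  w <- w / sum(w)
  ord <- order(w, decreasing = TRUE)
  ncum <- which(cumsum(w[ord]) >= prob)[1]
  sel <- sort(ord[seq_len(ncum)])
  sel <- seq(min(sel), max(sel))  # contiguous closure
  lo_core <- sub$pos[min(sel)]; hi_core <- sub$pos[max(sel)]
  mk <- !is.na(sub$marker)
  lo_c <- which(mk & sub$pos <= lo_core + 1e-9)
  hi_c <- which(mk & sub$pos >= hi_core - 1e-9)
  lo_i <- if (length(lo_c)) max(lo_c) else which(mk)[1]
  hi_i <- if (length(hi_c)) min(hi_c) else utils::tail(which(mk), 1)
  list(lo = sub$pos[lo_i], hi = sub$pos[hi_i],
       lo_core = lo_core, hi_core = hi_core,
       lo_marker = sub$marker[lo_i], hi_marker = sub$marker[hi_i],
       peak_pos = sub$pos[which.max(sub$lod)], group = group)
}

#' Percent variance explained by a QTL
#'
#' `PVE = 100 * (1 - 10^(-2 * LOD / n))`, the variance fraction implied by
#' the likelihood ratio at the peak for a sample of `n` individuals.
#'
#' @param lod LOD score (>= 0).
#' @param n Number of phenotyped individuals (>= 1).
#' @return PVE in percent, in `[0, 100)`.
#' @export
pve <- function(lod, n) {
  .check(all(lod >= 0), "lod must be >= 0")
  .check(all(n >= 1), "n must be >= 1")
  100 * (1 - 10^(-2 * lod / n))
}

#' Summarize a scan peak as one QTL-table row
#'
#' @param curve A `lod_curve`.
#' @param perms Result of [perm_threshold()] for the same scan.
#' @param trait Trait label.
#' @param prob Credible mass for the interval.
#' @return One-row data.frame: trait, nearest marker, group, position,
#'   credible interval, LOD, genome-wide p, PVE.
#' @export
summarize_qtl <- function(curve, perms = NULL, trait = "trait",
                          prob = 0.95) {
  pk <- which.max(curve$lod)
  grp <- curve$group[pk]
  sub <- curve[curve$group == grp, ]
  mk_rows <- which(!is.na(sub$marker))
  nearest <- sub$marker[mk_rows[which.min(abs(sub$pos[mk_rows] -
                                                curve$pos[pk]))]]
  ci <- bayes_interval(curve, group = grp, prob = prob)
  data.frame(trait = trait, marker = nearest, group = grp,
             pos_cM = curve$pos[pk],
             ci = sprintf("%.1f-%.1f (%s-%s)", ci$lo, ci$hi, ci$lo_marker,
                          ci$hi_marker),
             lod = curve$lod[pk],
             p_genomewide = if (is.null(perms)) NA_real_
             else perms$gw_p(curve$lod[pk]),
             pve = pve(curve$lod[pk], attr(curve, "n")),
             stringsAsFactors = FALSE)
}
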