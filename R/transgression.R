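#' Transgression thresholds from two parental samples
#'
#' Upper threshold: the higher parental mean plus two standard deviations
#' of that parent; lower threshold: the lower parental mean minus two SDs
#' of that parent (sample SD, n-1 denominator). The classical range is the
#' min/max over the pooled parents. The parent-specific SD makes small
#' parental samples appropriately conservative.
#'
#' @param parentA,parentB Numeric vectors (>= 2 values each).
#' @return Object of class `transgression_thresholds`: list `upper`,
#'   `lower`, `classical` (length-2 range), `means`, `sds`.
#' @export
transgression_thresholds <- function(parentA, parentB) {
  parentA <- parentA[!is.na(parentA)]; parentB <- parentB[!is.na(parentB)]
  .check(length(parentA) >= 2 && length(parentB) >= 2,
         "each parent needs at least two values")
  mA <- mean(parentA); mB <- mean(parentB)
  sA <- stats::sd(parentA); sB <- stats::sd(parentB)
  hi <- if (mA >= mB) mA + 2 * sA else mB + 2 * sB
  lo <- if (mA <= mB) mA - 2 * sA else mB - 2 * sB
  structure(list(upper = hi, lower = lo,
                 classical = range(c(parentA, parentB)),
                 means = c(A = mA, B = mB), sds = c(A = sA, B = sB)),
            class = "transgression_thresholds")
}

#' Classify values against transgression thresholds
#'
#' A value is transgressive only when it strictly exceeds the upper or
#' strictly undercuts the lower threshold; ties at a threshold are not
#' transgressive. Values strictly outside the pooled parental min/max are
#' flagged `outside_classical_range`.
#'
#' @param values Numeric vector.
#' @param thresholds A [transgression_thresholds()] object.
#' @param ids Optional identifiers.
#' @return List: `calls` data.frame (`id`, `value`, `above_upper`,
#'   `below_lower`, `outside_classical_range`, `direction`), `counts`
#'   (named: `above`, `below`, `outside_range`).
#' @export
classify_transgression <- function(values, thresholds, ids = NULL) {
  .check(inherits(thresholds, "transgression_thresholds"),
         "thresholds must come from transgression_thresholds()")
  if (is.null(ids)) ids <- seq_along(values)
  up <- values > thresholds$upper
  dn <- values < thresholds$lower
  out <- values > thresholds$classical[2] | values < thresholds$classical[1]
  calls <- data.frame(id = ids, value = values, above_upper = up,
                      below_lower = dn, outside_classical_range = out,
                      direction = ifelse(up, "positive",
                                         ifelse(dn, "negative", "none")),
                      stringsAsFactors = FALSE)
  list(calls = calls,
       counts = c(above = sum(up, na.rm = TRUE),
                  below = sum(dn, na.rm = TRUE),
                  outside_range = sum(out, na.rm = TRUE)))
}

#' Two-sample permutation test for a difference in means
#'
#' The statistic is `mean(x) - mean(y)`. With `mode = "exact_enumeration"`
#' (or automatically when the number of relabelings C(n1+n2, n1) is at most
#' `exact_limit`) all relabelings are enumerated and the two-sided p value
#' is the exact fraction with `|T*| >= |T|`. Otherwise Monte-Carlo
#' resampling is used with the add-one estimator
#' `p = (1 + #{|T*| >= |T|}) / (B + 1)`.
#'
#' @param x,y Numeric samples.
#' @param n_perm Monte-Carlo resamples B.
#' @param seed Integer seed (Monte-Carlo mode).
#' @param mode `"auto"`, `"exact_enumeration"`, or `"monte_carlo"`.
#' @param exact_limit Enumeration feasibility cap.
#' @return List `p`, `statistic`, `mode`, `n_perm` (resamples or
#'   enumerated relabelings).
#' @export
perm_test <- function(x, y, n_perm = 10000, seed = 1,
                      mode = c("auto", "exact_enumeration", "monte_carlo"),
                      exact_limit = 1e6) {
  mode <- match.arg(mode)
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  .check(length(x) >= 1 && length(y) >= 1, "both samples must be nonempty")
  n1 <- length(x); n <- n1 + length(y)
  pool <- c(x, y)
  tobs <- mean(x) - mean(y)
  eps <- 1e-12 * (1 + abs(tobs))
  if (mode == "auto")
    mode <- if (choose(n, n1) <= exact_limit) "exact_enumeration"
            else "monte_carlo"
  if (mode == "exact_enumeration") {
    .check(choose(n, n1) <= exact_limit,
           "exact enumeration infeasible at this sample size")
    combs <- utils::combn(n, n1)
    tot <- sum(pool); m2 <- n - n1
    tstar <- apply(combs, 2, function(ix)
      sum(pool[ix]) / n1 - (tot - sum(pool[ix])) / m2)
    p <- mean(abs(tstar) >= abs(tobs) - eps)
    return(list(p = p, statistic = tobs, mode = mode, n_perm = ncol(combs)))
  }
  set.seed(child_seed(seed, "permtest"))
  tstar <- replicate(n_perm, {
    ix <- sample(n, n1)
    mean(pool[ix]) - mean(pool[-ix])
  })
  p <- (1 + sum(abs(tstar) >= abs(tobs) - eps)) / (n_perm + 1)
  list(p = p, statistic = tobs, mode = mode, n_perm = n_perm)
}

#' Allometric size correction of traits
#'
#' Regresses log10 trait on log10 standard length and returns residuals.
#' With `pool = "auto"`, the class-by-slope interaction is tested per trait
#' (F test, Benjamini-Hochberg adjusted across traits); traits with
#' homogeneous slopes are corrected by the pooled regression, the others
#' within class. `pool = "all"` or `"per_class"` force one behaviour
#' (behavioural efficiency is corrected within class by design; morphology
#' pools when slopes are homogeneous).
#'
#' @param traits Numeric vector, matrix, or data.frame of positive trait
#'   values (columns = traits).
#' @param SL Positive standard lengths.
#' @param class Class labels (factor or character).
#' @param pool `"auto"`, `"all"`, or `"per_class"`.
#' @param alpha Significance level applied to the FDR-adjusted interaction
#'   p values in `"auto"` mode.
#' @return List: `residuals` (same shape as `traits`), `report` data.frame
#'   (`trait`, `F`, `df1`, `df2`, `p`, `p_adj`, `pooled`).
#' @export
size_correct <- function(traits, SL, class, pool = c("auto", "all",
                                                     "per_class"),
                         alpha = 0.05) {
  pool <- match.arg(pool)
  tr <- as.matrix(traits)
  if (is.null(colnames(tr)))
    colnames(tr) <- sprintf("trait%d", seq_len(ncol(tr)))
  .check(all(tr > 0) && all(SL > 0),
         "traits and SL must be positive (log domain)")
  class <- as.factor(class)
  lsl <- log10(SL)
  rep_rows <- lapply(seq_len(ncol(tr)), function(j) {
    lt <- log10(tr[, j])
    if (nlevels(class) >= 2) {
      f0 <- stats::lm(lt ~ lsl + class)
      f1 <- stats::lm(lt ~ lsl * class)
      a <- stats::anova(f0, f1)
      data.frame(trait = colnames(tr)[j], F = a$F[2], df1 = a$Df[2],
                 df2 = a$Res.Df[2], p = a$`Pr(>F)`[2])
    } else data.frame(trait = colnames(tr)[j], F = NA, df1 = NA, df2 = NA,
                      p = NA)
  })
  report <- do.call(rbind, rep_rows)
  report$p_adj <- stats::p.adjust(report$p, method = "BH")
  resid <- tr * NA
  report$pooled <- NA
  for (j in seq_len(ncol(tr))) {
    lt <- log10(tr[, j])
    pooled_j <- switch(pool,
                       all = TRUE,
                       per_class = FALSE,
                       auto = is.na(report$p_adj[j]) ||
                         report$p_adj[j] >= alpha)
    if (pooled_j) {
      resid[, j] <- stats::resid(stats::lm(lt ~ lsl))
    } else {
      for (cl in levels(class)) {
        sel <- class == cl
        resid[sel, j] <- stats::resid(stats::lm(lt[sel] ~ lsl[sel]))
      }
    }
    report$pooled[j] <- pooled_j
  }
  if (is.vector(traits)) resid <- resid[, 1]
  list(residuals = resid, report = report)
}
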