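#' Simulate a marker map
#'
#' Generates a set of linkage groups ("chromosomes") with marker positions in
#' centiMorgans. With `placement = "even"` markers are equally spaced from 0
#' to the chromosome length (endpoints included); with `"uniform"` they are
#' drawn uniformly and sorted.
#'
#' @param n_chr Number of chromosomes (default 22, the karyotype of the
#'   haplochromine cichlids modelled here).
#' @param length_cM Chromosome length in centiMorgans (recycled across
#'   chromosomes).
#' @param markers_per_chr Markers per chromosome (>= 2).
#' @param seed Integer seed (used only for `placement = "uniform"`).
#' @param placement `"even"` or `"uniform"`.
#' @return An object of class `sim_map`: list with `chromosomes`
#'   (data.frame `chr`, `length`) and `positions` (list of ascending cM
#'   vectors, one per chromosome, named by marker).
#' @export
simulate_map <- function(n_chr = 22, length_cM = 100, markers_per_chr = 43,
                         seed = 1, placement = c("even", "uniform")) {
  placement <- match.arg(placement)
  .check(n_chr >= 1, "n_chr must be >= 1")
  .check(all(length_cM > 0), "length_cM must be positive")
  .check(all(markers_per_chr >= 2), "markers_per_chr must be >= 2")
  lens <- rep_len(length_cM, n_chr)
  nmk <- rep_len(markers_per_chr, n_chr)
  set.seed(child_seed(seed, "map"))
  positions <- lapply(seq_len(n_chr), function(i) {
    p <- if (placement == "even") {
      seq(0, lens[i], length.out = nmk[i])
    } else {
      sort(stats::runif(nmk[i], 0, lens[i]))
    }
    names(p) <- sprintf("c%d_m%d", i, seq_len(nmk[i]))
    p
  })
  structure(list(chromosomes = data.frame(chr = seq_len(n_chr), length = lens),
                 positions = positions),
            class = "sim_map")
}

#' @export
print.sim_map <- function(x, ...) {
  cat(sprintf("sim_map: %d chromosomes, %d markers, total length %.1f cM\n",
              nrow(x$chromosomes), sum(lengths(x$positions)),
              sum(x$chromosomes$length)))
  invisible(x)
}

# map-function inverses: cM gap -> recombination fraction
.inv_map_fun <- function(map_function) {
  switch(map_function,
         kosambi = function(d) 0.5 * tanh(2 * d / 100),
         haldane = function(d) 0.5 * (1 - exp(-2 * d / 100)),
         stop("unknown map function"))
}

#' Simulate F2 intercross genotypes
#'
#' Each F2 individual is the union of two independent gametes. A gamete is a
#' Markov chain along each chromosome: the allele at the first marker is
#' Bernoulli(1/2) and switches between adjacent markers with probability
#' `r(d)` given by the inverse of the chosen mapping function applied to the
#' marker gap. This reproduces the map function's marker-to-marker
#' recombination fractions without modelling crossover interference.
#'
#' @param map A `sim_map`.
#' @param n Number of F2 individuals.
#' @param map_function `"kosambi"` or `"haldane"`.
#' @param seed Integer seed.
#' @return Character matrix `n x n_markers` with entries `"AA"`, `"AB"`,
#'   `"BB"`; marker names as column names. Attribute `map_df` carries the
#'   true marker map (`chr`, `marker`, `pos_cM`).
#' @export
simulate_f2 <- function(map, n, map_function = c("kosambi", "haldane"),
                        seed = 1) {
  map_function <- match.arg(map_function)
  .check(inherits(map, "sim_map"), "map must be a sim_map")
  .check(n >= 1, "n must be >= 1")
  rfun <- .inv_map_fun(map_function)
  set.seed(child_seed(seed, "f2"))
  gamete <- function(pos) {
    m <- length(pos)
    r <- rfun(diff(pos))
    g <- matrix(0L, n, m)
    g[, 1] <- stats::rbinom(n, 1, 0.5)
    for (j in seq_len(m - 1)) {
      flip <- stats::rbinom(n, 1, r[j])
      g[, j + 1] <- ifelse(flip == 1L, 1L - g[, j], g[, j])
    }
    g
  }
  per_chr <- lapply(map$positions, function(pos) gamete(pos) + gamete(pos))
  counts <- do.call(cbind, per_chr)  # number of A alleles, 0..2
  geno <- matrix(c("BB", "AB", "AA")[counts + 1], nrow = n)
  colnames(geno) <- unlist(lapply(map$positions, names))
  rownames(geno) <- sprintf("F2_%03d", seq_len(n))
  attr(geno, "map_df") <- data.frame(
    chr = rep(map$chromosomes$chr, lengths(map$positions)),
    marker = colnames(geno),
    pos_cM = unlist(map$positions, use.names = FALSE))
  geno
}

#' Define a QTL architecture
#'
#' @param qtl data.frame with columns `chr`, `pos_cM`, `a` (additive effect,
#'   half the difference between the two homozygote means) and `d`
#'   (dominance deviation of the heterozygote).
#' @param epistasis Optional data.frame with columns `i`, `j` (QTL row
#'   indices) and `coef`; contributes `coef * x_i * x_j` with x the additive
#'   genotype score in \{-1, 0, 1\}.
#' @param sigma_e Environmental standard deviation (>= 0).
#' @param label One of `"complementary"`, `"overdominant"`, `"epistatic"`,
#'   `"null"`. A complementary architecture must mix signs in `a` (that is
#'   the mechanism producing transgressive F2 segregation).
#' @return Object of class `qtl_architecture`.
#' @export
qtl_architecture <- function(qtl = NULL, epistasis = NULL, sigma_e = 1,
                             label = c("null", "complementary",
                                       "overdominant", "epistatic")) {
  label <- match.arg(label)
  .check(sigma_e >= 0, "sigma_e must be >= 0")
  if (is.null(qtl)) qtl <- data.frame(chr = integer(), pos_cM = numeric(),
                                      a = numeric(), d = numeric())
  if (label == "complementary" && nrow(qtl) > 0)
    .check(any(qtl$a > 0) && any(qtl$a < 0),
           "complementary architecture requires mixed-sign additive effects")
  structure(list(qtl = qtl, epistasis = epistasis, sigma_e = sigma_e,
                 label = label),
            class = "qtl_architecture")
}

#' Simulate phenotypes for the F2 and both parental panels
#'
#' The genetic value of an F2 individual is the sum over QTL of
#' `a * x + d * (1 - |x|)` with x the additive score (AA = +1, AB = 0,
#' BB = -1), plus any epistatic terms, plus Normal(0, sigma_e) noise. QTL are
#' resolved to the nearest marker of the simulated map. Parental panels are
#' fully inbred: parent A is AA at every QTL, parent B is BB.
#'
#' @param genotypes F2 genotype matrix from [simulate_f2()] (with its
#'   `map_df` attribute).
#' @param arch A [qtl_architecture()].
#' @param n_parentA,n_parentB Parental panel sizes (study-scale defaults 6
#'   and 5).
#' @param seed Integer seed.
#' @return data.frame with `id`, `class` (`"F2"`, `"CAL"` = parent A,
#'   `"TAE"` = parent B), `sex` (balanced M/F) and `phenotype`.
#' @export
simulate_phenotypes <- function(genotypes, arch, n_parentA = 6,
                                n_parentB = 5, seed = 1) {
  .check(inherits(arch, "qtl_architecture"), "arch must be a qtl_architecture")
  map_df <- attr(genotypes, "map_df")
  .check(!is.null(map_df), "genotypes must carry a map_df attribute")
  n <- nrow(genotypes)
  xs <- matrix(0, n, max(1, nrow(arch$qtl)))
  if (nrow(arch$qtl) > 0) {
    for (k in seq_len(nrow(arch$qtl))) {
      on_chr <- map_df$chr == arch$qtl$chr[k]
      .check(any(on_chr), "QTL chromosome not on map")
      pos <- map_df$pos_cM[on_chr]
      .check(arch$qtl$pos_cM[k] >= min(pos) - 1e-9 &&
               arch$qtl$pos_cM[k] <= max(pos) + 1e-9,
             "QTL position outside the chromosome's marker span")
      mk <- map_df$marker[on_chr][which.min(abs(pos - arch$qtl$pos_cM[k]))]
      xs[, k] <- c(AA = 1, AB = 0, BB = -1)[genotypes[, mk]]
    }
  }
  gval <- function(x) {  # x: matrix of additive scores, one row per ind
    v <- rep(0, nrow(x))
    if (nrow(arch$qtl) > 0)
      for (k in seq_len(nrow(arch$qtl)))
        v <- v + arch$qtl$a[k] * x[, k] + arch$qtl$d[k] * (1 - abs(x[, k]))
    if (!is.null(arch$epistasis) && nrow(arch$epistasis) > 0)
      for (t in seq_len(nrow(arch$epistasis)))
        v <- v + arch$epistasis$coef[t] *
          x[, arch$epistasis$i[t]] * x[, arch$epistasis$j[t]]
    v
  }
  set.seed(child_seed(seed, "pheno"))
  nq <- max(1, nrow(arch$qtl))
  pa <- matrix(1, n_parentA, nq)   # parent A: AA everywhere
  pb <- matrix(-1, n_parentB, nq)  # parent B: BB everywhere
  ph <- c(gval(xs) + stats::rnorm(n, 0, arch$sigma_e),
          gval(pa) + stats::rnorm(n_parentA, 0, arch$sigma_e),
          gval(pb) + stats::rnorm(n_parentB, 0, arch$sigma_e))
  cls <- rep(c("F2", "CAL", "TAE"), c(n, n_parentA, n_parentB))
  ids <- c(rownames(genotypes), sprintf("CAL_%02d", seq_len(n_parentA)),
           sprintf("TAE_%02d", seq_len(n_parentB)))
  sex <- unlist(lapply(c(n, n_parentA, n_parentB), function(k)
    rep_len(c("M", "F"), k)))
  data.frame(id = ids, class = cls, sex = sex, phenotype = ph,
             stringsAsFactors = FALSE)
}

#' Default 13-point fish head landmark scheme
#'
#' A stylised lateral-head configuration using the landmark ids of the study
#' scheme: 1 preoperculum/scale-area intersection, 2 preoperculum bend,
#' 3 lower-jaw hinge, 4 lower-jaw tip, 5/6 anterior/posterior eye, 7 ventral
#' eye, 10 snout tip, 15 dorsal head margin above 1, and semilandmarks 11-14
#' equally spaced on the 10-15 dorsal profile. Units are arbitrary image
#' units; y increases upward.
#'
#' @return 13 x 2 matrix with rownames `1..7, 10..15`.
#' @export
default_fish_landmarks <- function() {
  pts <- rbind(
    `1`  = c(3.0, 1.2),
    `2`  = c(2.4, -1.0),
    `3`  = c(1.0, -0.9),
    `4`  = c(0.0, -0.5),
    `5`  = c(1.4, 0.6),
    `6`  = c(2.2, 0.6),
    `7`  = c(1.8, 0.1),
    `10` = c(0.1, 0.1),
    `15` = c(3.0, 2.2))
  prof <- sapply(1:4, function(i) pts["10", ] + i / 5 * (pts["15", ] - pts["10", ]))
  prof <- t(prof) + cbind(rep(0, 4), c(0.25, 0.45, 0.5, 0.35))  # arched profile
  rownames(prof) <- as.character(11:14)
  out <- rbind(pts[as.character(c(1:7, 10)), , drop = FALSE], prof,
               pts["15", , drop = FALSE])
  colnames(out) <- c("x", "y")
  out[as.character(c(1:7, 10:15)), ]
}

#' Simulate landmark configurations
#'
#' Each specimen is its class mean plus `(logSL - mean logSL) * allometry`
#' plus isotropic Gaussian landmark noise, then (optionally) randomly
#' rotated, translated, and scaled — the nuisance transforms that
#' generalized Procrustes analysis must remove.
#'
#' @param n_per_class Named integer vector of specimens per class.
#' @param class_means Named list of 13 x 2 mean configurations (defaults to
#'   perturbations of [default_fish_landmarks()]).
#' @param allometry 13 x 2 matrix: shape change per unit log10 SL.
#' @param logSL_mean,logSL_sd Distribution of log10 standard length (mm).
#' @param noise_sd Isotropic landmark noise SD (shape units).
#' @param nuisance Apply random rotation/translation/scaling?
#' @param seed Integer seed.
#' @return List of `landmark_config` objects.
#' @export
simulate_landmarks <- function(n_per_class = c(F2 = 20, CAL = 10, TAE = 10),
                               class_means = NULL, allometry = NULL,
                               logSL_mean = 1.9, logSL_sd = 0.08,
                               noise_sd = 0.02, nuisance = TRUE, seed = 1) {
  base <- default_fish_landmarks()
  set.seed(child_seed(seed, "landmarks"))
  if (is.null(class_means)) {
    class_means <- lapply(seq_along(n_per_class), function(i) {
      m <- base
      m["4", 1] <- m["4", 1] - 0.08 * (i - 1)   # class-specific jaw
      m["15", 2] <- m["15", 2] + 0.10 * (i - 1) # and head depth
      m
    })
    names(class_means) <- names(n_per_class)
  }
  for (m in class_means)
    .check(all(dim(m) == c(13, 2)), "class means must be 13 x 2")
  if (is.null(allometry)) allometry <- matrix(0, 13, 2)
  out <- list()
  idx <- 0
  for (cl in names(n_per_class)) {
    for (i in seq_len(n_per_class[[cl]])) {
      idx <- idx + 1
      lsl <- stats::rnorm(1, logSL_mean, logSL_sd)
      pts <- class_means[[cl]] + (lsl - logSL_mean) * allometry +
        matrix(stats::rnorm(26, 0, noise_sd), 13, 2)
      if (nuisance) {
        th <- stats::runif(1, -pi, pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
        s <- exp(stats::rnorm(1, 0, 0.2))
        pts <- s * pts %*% R +
          matrix(stats::rnorm(2, 0, 2), 13, 2, byrow = TRUE)
      }
      dimnames(pts) <- list(as.character(c(1:7, 10:15)), c("x", "y"))
      out[[idx]] <- landmark_config(pts, id = sprintf("%s_%03d", cl, i),
                                    SL = 10^lsl, HW = 0.25 * 10^lsl,
                                    class = cl,
                                    sex = rep_len(c("M", "F"), i)[i])
    }
  }
  out
}

#' Specification of a synthetic two-layer sand image pair
#'
#' The behavioural assay covers a black sand layer with beige sand; where a
#' fish sifts, black sand is brought to the surface. The simulator emulates
#' this as a single-channel brightness image: a bright "beige" background
#' with dark disk-shaped disturbance patches repainted from the "black"
#' distribution.
#'
#' @param width,height Image size in pixels.
#' @param grain Grain size in pixels (brightness is constant within a
#'   grain).
#' @param beige_mean,beige_sd,black_mean,black_sd Brightness distributions
#'   on the 0-255 scale; the beige mean must exceed, and the black mean lie
#'   below, the analysis threshold.
#' @param target_fraction Target turned-over area fraction in `[0, 1]`.
#' @param patch_radius_mean,patch_radius_sd Disturbance patch radius (px).
#' @param seed Integer seed.
#' @return Object of class `sim_image_spec`.
#' @export
sim_image_spec <- function(width = 120, height = 80, grain = 2,
                           beige_mean = 190, beige_sd = 18,
                           black_mean = 35, black_sd = 12,
                           target_fraction = 0.3,
                           patch_radius_mean = 4, patch_radius_sd = 1,
                           seed = 1) {
  .check(target_fraction >= 0 && target_fraction <= 1,
         "target_fraction must be in [0, 1]")
  .check(beige_mean > 80 && black_mean < 80,
         "brightness means must straddle the threshold (beige > 80 > black)")
  structure(as.list(environment()), class = "sim_image_spec")
}

# internal: draw a granular brightness field
.granular_field <- function(h, w, grain, mean, sd) {
  gh <- ceiling(h / grain); gw <- ceiling(w / grain)
  g <- matrix(stats::rnorm(gh * gw, mean, sd), gh, gw)
  big <- g[rep(seq_len(gh), each = grain)[1:h],
           rep(seq_len(gw), each = grain)[1:w], drop = FALSE]
  pmin(pmax(big, 0), 255)
}

#' Simulate a before/after sand image pair
#'
#' The before image is drawn from the beige distribution; the after image
#' equals the before image with dark disturbance patches added until the
#' repainted area is as close to the target fraction as patch packing
#' allows. The realized fraction (repainted pixels / total pixels) is
#' returned exactly.
#'
#' @param spec A [sim_image_spec()].
#' @return List with `before`, `after` (height x width brightness matrices,
#'   0-255), `true_fraction`, and the logical `mask` of repainted pixels.
#' @export
simulate_sand_images <- function(spec) {
  .check(inherits(spec, "sim_image_spec"), "spec must be a sim_image_spec")
  set.seed(child_seed(spec$seed, "sand"))
  h <- spec$height; w <- spec$width
  before <- .granular_field(h, w, spec$grain, spec$beige_mean, spec$beige_sd)
  mask <- matrix(FALSE, h, w)
  f <- spec$target_fraction
  if (f >= 1) {
    mask[] <- TRUE
  } else if (f > 0) {
    npix <- h * w
    rr <- matrix(rep(seq_len(h), w), h, w)
    cc <- matrix(rep(seq_len(w), each = h), h, w)
    for (it in seq_len(10000)) {
      cur <- sum(mask) / npix
      r <- max(1, stats::rnorm(1, spec$patch_radius_mean,
                               spec$patch_radius_sd))
      cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
      cand <- mask | ((rr - cy)^2 + (cc - cx)^2 <= r^2)
      new <- sum(cand) / npix
      if (abs(new - f) <= abs(cur - f)) mask <- cand else break
    }
  }
  after <- before
  if (any(mask)) {
    dark <- .granular_field(h, w, spec$grain, spec$black_mean, spec$black_sd)
    after[mask] <- dark[mask]
  }
  list(before = before, after = after, true_fraction = sum(mask) / (h * w),
       mask = mask)
}

#' Write a synthetic VCF for the cross
#'
#' Emits biallelic SNP records (VCF v4.2, 1-based positions, format
#' `GT:GQ:DP`) for the two parental panels and the F2 individuals. Parental
#' panels are fixed for opposite alleles at every marker (fully inbred
#' lines); which allele is the parent-A allele is randomized per site and
#' recorded in the returned truth table. Optional rule-violating records
#' (indels, low-quality sites, 200-bp clusters, multiallelic sites) can be
#' injected to exercise the variant filters.
#'
#' @param map A `sim_map`; marker cM positions are laid out on a physical
#'   scale of 10^5 bp per cM.
#' @param f2_geno Genotype matrix from [simulate_f2()].
#' @param n_panelA,n_panelB Panel sizes (defaults 6 and 5).
#' @param missing_rate Per-genotype missing probability.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param violations List with any of `indel`, `lowqual`, `cluster`,
#'   `multiallelic` counts of records to inject.
#' @param seed Integer seed.
#' @param path Optional file to write.
#' @return Character vector of VCF lines (invisibly if `path` given), with
#'   attributes `truth` (data.frame `chrom`, `pos`, `marker`, `A_allele`)
#'   and `samples`.
#' @export
simulate_vcf <- function(map, f2_geno, n_panelA = 6, n_panelB = 5,
                         missing_rate = 0, depth_mean = 30,
                         violations = list(), seed = 1, path = NULL) {
  .check(n_panelA >= 1 && n_panelB >= 1, "panels must have >= 1 individual")
  set.seed(child_seed(seed, "vcf"))
  map_df <- attr(f2_geno, "map_df")
  nA <- n_panelA; nB <- n_panelB; nF <- nrow(f2_geno)
  samples <- c(sprintf("CAL_%02d", 1:nA), sprintf("TAE_%02d", 1:nB),
               rownames(f2_geno))
  bases <- c("A", "C", "G", "T")
  recs <- list(); truth <- list()
  fmt_geno <- function(gt, gq, dp) sprintf("%s:%d:%d", gt, gq, dp)
  mk_field <- function(gt_codes) {
    dp <- stats::rpois(length(gt_codes), depth_mean) + 10L
    gq <- pmin(99L, stats::rpois(length(gt_codes), 60L) + 30L)
    gt <- gt_codes
    if (missing_rate > 0) {
      miss <- stats::runif(length(gt)) < missing_rate
      gt[miss] <- "./."
    }
    fmt_geno(gt, gq, dp)
  }
  for (i in seq_len(nrow(map_df))) {
    chrom <- sprintf("chr%d", map_df$chr[i])
    pos <- round(map_df$pos_cM[i] * 1e5) + 1000L
    ra <- sample(bases, 2)
    a_is_ref <- stats::runif(1) < 0.5
    gA <- if (a_is_ref) "0/0" else "1/1"
    gB <- if (a_is_ref) "1/1" else "0/0"
    code <- c(AA = gA, AB = "0/1", BB = gB)
    f2gt <- code[f2_geno[, map_df$marker[i]]]
    fields <- mk_field(c(rep(gA, nA), rep(gB, nB), f2gt))
    recs[[length(recs) + 1]] <- paste(
      c(chrom, pos, map_df$marker[i], ra[1], ra[2], "500", "PASS", ".",
        "GT:GQ:DP", fields), collapse = "\t")
    truth[[length(truth) + 1]] <- data.frame(
      chrom = chrom, pos = pos, marker = map_df$marker[i],
      A_allele = if (a_is_ref) "ref" else "alt")
  }
  # injected rule violations live on a dedicated extra chromosome
  vio <- function(n) if (is.null(n)) 0L else as.integer(n)
  vpos <- 10000L
  add_rec <- function(chrom, pos, id, ref, alt, qual) {
    fields <- mk_field(rep("0/1", nA + nB + nF))
    recs[[length(recs) + 1]] <<- paste(
      c(chrom, pos, id, ref, alt, qual, "PASS", ".", "GT:GQ:DP", fields),
      collapse = "\t")
  }
  for (k in seq_len(vio(violations$indel))) {
    add_rec("chrV", vpos, sprintf("indel%d", k), "A", "ATTG", "500")
    vpos <- vpos + 5000L
  }
  for (k in seq_len(vio(violations$lowqual))) {
    add_rec("chrV", vpos, sprintf("lowq%d", k), "A", "G", "10")
    vpos <- vpos + 5000L
  }
  for (k in seq_len(vio(violations$multiallelic))) {
    add_rec("chrV", vpos, sprintf("multi%d", k), "A", "C,G", "500")
    vpos <- vpos + 5000L
  }
  for (k in seq_len(vio(violations$cluster))) {
    # a cluster of 3 SNPs within 200 bp; thinning must keep exactly one
    for (j in 0:2) add_rec("chrW", vpos + j * 90L, sprintf("clu%d_%d", k, j),
                           "C", "T", "500")
    vpos <- vpos + 5000L
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sandsift-simulator",
           sprintf("##contig=<ID=chr%d>", unique(map_df$chr)),
           "##contig=<ID=chrV>", "##contig=<ID=chrW>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  out <- c(hdr, unlist(recs))
  attr(out, "truth") <- do.call(rbind, truth)
  attr(out, "samples") <- samples
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
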