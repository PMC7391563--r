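#' Default pipeline configuration
#'
#' Desk-scale defaults: an F2 of 113 individuals (the study's mapping
#' panel size) on a 6-chromosome genome with 15 markers per chromosome,
#' parental panels of 6 and 5, a complementary two-QTL architecture, three
#' behavioural trials per male, and 200 scan permutations.
#'
#' @param seed Master seed; every stage derives its own child seed.
#' @return Named list of stage parameters.
#' @export
pipeline_config <- function(seed = 1) {
  list(seed = seed,
       n_chr = 6, chr_length = 100, markers_per_chr = 15,
       n_f2 = 113, n_parentA = 6, n_parentB = 5,
       arch = qtl_architecture(
         qtl = data.frame(chr = c(1, 2), pos_cM = c(30, 60),
                          a = c(1, -1), d = c(0, 0)),
         sigma_e = 1, label = "complementary"),
       n_trials = 3, image = list(width = 80, height = 60),
       threshold = 80, scrape_mode = "complement",
       step = 2, error_prob = 0.05, n_perm = 200,
       grouping_lod = 7)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes the three analysis arms end to end on simulated data:
#' behaviour scoring and transgression, geometric morphometrics and shape
#' transgression, and genotype filtering, linkage mapping, and the QTL
#' scan, writing delimited result tables and a run manifest.
#'
#' @param config List from [pipeline_config()] (or a modified copy).
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @return Invisibly, a list with all stage results (`trials`,
#'   `behavior_transgression`, `perm_tests`, `shape_pca`,
#'   `shape_transgression`, `filter_counts`, `map`, `qtl_table`, ...).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  seed <- config$seed
  res <- list(config = config)

  ## --- simulate the cross ------------------------------------------------
  map <- simulate_map(config$n_chr, config$chr_length,
                      config$markers_per_chr, seed = seed)
  geno <- simulate_f2(map, config$n_f2, map_function = "kosambi",
                      seed = seed)
  pheno <- simulate_phenotypes(geno, config$arch, config$n_parentA,
                               config$n_parentB, seed = seed)

  ## --- behavioural trials ------------------------------------------------
  set.seed(child_seed(seed, "trials"))
  males <- pheno[pheno$sex == "M", ]
  trials <- do.call(rbind, lapply(seq_len(nrow(males)), function(i) {
    lam <- exp(1.5 + 0.25 * males$phenotype[i])
    data.frame(individual = males$id[i], class = males$class[i],
               trial = seq_len(config$n_trials),
               strikes = stats::rpois(config$n_trials, lam),
               hiding = sample(1:4, config$n_trials, TRUE),
               interaction = sample(1:4, config$n_trials, TRUE),
               scrape_effect = sample(c(0, 0, 0, 0.1, 0.25),
                                      config$n_trials, TRUE),
               SL = stats::rlnorm(1, log(80), 0.1),
               stringsAsFactors = FALSE)
  }))
  # a few zero-strike, always-hiding trials that must be excluded
  idle <- trials$strikes == 0
  trials$hiding[idle][seq_len(min(3, sum(idle)))] <- 5
  # sand images: turned fraction scales with strikes
  areas <- vapply(seq_len(nrow(trials)), function(i) {
    f <- min(0.9, 0.003 * trials$strikes[i])
    spec <- sim_image_spec(width = config$image$width,
                           height = config$image$height,
                           target_fraction = f,
                           seed = child_seed(seed, paste0("img", i)))
    pair <- simulate_sand_images(spec)
    c(before = quantify_sand_area(pair$before, config$threshold),
      after = quantify_sand_area(pair$after, config$threshold))
  }, numeric(2))
  trials$area_before_pct <- areas["before", ]
  trials$area_after_pct <- areas["after", ]
  trials$net_area <- net_turned_area(trials$area_before_pct,
                                     trials$area_after_pct,
                                     trials$scrape_effect,
                                     config$scrape_mode)
  trials$efficiency <- efficiency(trials$net_area, trials$strikes)$raw
  ex <- exclude_trials(trials)
  agg <- aggregate_individual(ex$valid, "max")
  agg$class <- trials$class[match(agg$individual, trials$individual)]
  res$trials <- trials
  res$excluded_trials <- ex$excluded

  ## --- behavioural transgression and permutation tests -------------------
  th_str <- transgression_thresholds(agg$strikes[agg$class == "CAL"],
                                     agg$strikes[agg$class == "TAE"])
  cls_str <- classify_transgression(agg$strikes[agg$class == "F2"], th_str,
                                    ids = agg$individual[agg$class == "F2"])
  pt <- list(
    F2_vs_CAL = perm_test(agg$strikes[agg$class == "F2"],
                          agg$strikes[agg$class == "CAL"],
                          seed = child_seed(seed, "pt1"))$p,
    F2_vs_TAE = perm_test(agg$strikes[agg$class == "F2"],
                          agg$strikes[agg$class == "TAE"],
                          seed = child_seed(seed, "pt2"))$p,
    TAE_vs_CAL = perm_test(agg$strikes[agg$class == "TAE"],
                           agg$strikes[agg$class == "CAL"],
                           seed = child_seed(seed, "pt3"))$p)
  res$behavior_transgression <- list(thresholds = th_str, calls = cls_str)
  res$perm_tests <- data.frame(comparison = names(pt),
                               p = unlist(pt), row.names = NULL)

  ## --- morphometrics ------------------------------------------------------
  lms <- simulate_landmarks(
    n_per_class = c(F2 = config$n_f2, CAL = config$n_parentA,
                    TAE = config$n_parentB),
    allometry = 0.05 * default_fish_landmarks(), noise_sd = 0.02,
    seed = seed)
  lms <- standardize_jaw(lms)
  space <- gpa(lms, slide = TRUE)
  af <- allometry_free(space, seed = seed)
  pca <- shape_pca(af$shapes)
  cls <- space$info$class
  th_pc <- transgression_thresholds(pca$scores[cls == "CAL", 1],
                                    pca$scores[cls == "TAE", 1])
  res$shape_pca <- data.frame(axis = colnames(pca$scores),
                              var_frac = pca$var_frac)
  res$shape_allometry <- af$report
  res$shape_transgression <-
    classify_transgression(pca$scores[cls == "F2", 1], th_pc)
  res$pca <- pca

  ## --- genotypes: VCF, filters, recoding ----------------------------------
  vcf_path <- tempfile(fileext = ".vcf")
  simulate_vcf(map, geno, config$n_parentA, config$n_parentB,
               violations = list(indel = 1, cluster = 1),
               seed = seed, path = vcf_path)
  rec <- read_vcf_records(vcf_path)
  fv <- filter_variants(rec)
  fi <- filter_individuals(fv$records)
  panelA <- grep("^CAL", fi$records$samples, value = TRUE)
  panelB <- grep("^TAE", fi$records$samples, value = TRUE)
  f2_ids <- grep("^F2", fi$records$samples, value = TRUE)
  fixed <- find_reciprocally_fixed(fi$records, panelA, panelB)
  cross <- recode_f2(fi$records, fixed, f2_ids)
  res$filter_counts <- fv$counts
  unlink(vcf_path)

  ## --- linkage map ---------------------------------------------------------
  qc <- qc_markers(cross)
  lodm <- pairwise_independence_lod(qc$geno)
  grp <- group_markers(lodm, threshold = config$grouping_lod)
  lmap <- build_map(grp, qc$geno, order = "given")
  res$map <- lmap

  ## --- QTL scan ------------------------------------------------------------
  gp <- calc_genoprob(qc$geno, lmap, step = config$step,
                      error_prob = config$error_prob)
  y <- pheno$phenotype[match(rownames(qc$geno), pheno$id)]
  sexc <- pheno$sex[match(rownames(qc$geno), pheno$id)]
  curve <- scan_em(gp, y)
  perms <- perm_threshold(gp, y, n_perm = config$n_perm,
                          seed = child_seed(seed, "qtlperm"))
  res$lod_curve <- curve
  res$qtl_table <- summarize_qtl(curve, perms, trait = "phenotype")
  res$thresholds <- perms$thresholds

  ## --- write tables --------------------------------------------------------
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(x, f) utils::write.csv(x, file.path(out_dir, f),
                                          row.names = FALSE)
    wr(trials, "trials.csv")
    wr(res$perm_tests, "perm_tests.csv")
    wr(res$shape_pca, "shape_pca_variance.csv")
    wr(res$qtl_table, "qtl_table.csv")
    wr(data.frame(rule = names(res$filter_counts),
                  count = as.integer(res$filter_counts)),
       "filter_report.tsv")
    wr(lmap$map, "linkage_map.csv")
    manifest <- c(sprintf("package: sandsift %s",
                          as.character(utils::packageVersion("sandsift"))),
                  sprintf("master_seed: %d", seed),
                  sprintf("n_f2: %d", config$n_f2),
                  sprintf("n_chr: %d", config$n_chr),
                  sprintf("markers_per_chr: %d", config$markers_per_chr),
                  sprintf("n_perm: %d", config$n_perm),
                  sprintf("scrape_mode: %s", config$scrape_mode),
                  sprintf("step_cM: %g", config$step),
                  sprintf("error_prob: %g", config$error_prob))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  invisible(res)
}
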