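#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the field data the downstream stages expect: an F2 intercross of
# 113 individuals genotyped on 22 linkage groups with parental panels of 6
# (CAL) and 5 (TAE), behavioural sand-sifting trials with before/after
# two-layer sand images, and 13-point landmark configurations with
# allometry. Writes a VCF, a TPS file, and delimited tables under
# results/sim/ — the same formats a real study would enter the pipeline
# with.

suppressPackageStartupMessages(library(sandsift))
seed <- 20260923
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## genome and cross: 22 chromosomes, ~1,000 markers, complementary QTL pair
map <- simulate_map(n_chr = 22, length_cM = 80, markers_per_chr = 10,
                    seed = seed)
geno <- simulate_f2(map, n = 113, map_function = "kosambi", seed = seed)
arch <- qtl_architecture(
  qtl = data.frame(chr = c(3, 11), pos_cM = c(40, 40), a = c(1, -1),
                   d = c(0, 0)),
  sigma_e = 1, label = "complementary")
pheno <- simulate_phenotypes(geno, arch, n_parentA = 6, n_parentB = 5,
                             seed = seed)
write.csv(pheno, file.path(out, "phenotypes.csv"), row.names = FALSE)
simulate_vcf(map, geno, n_panelA = 6, n_panelB = 5,
             violations = list(indel = 2, cluster = 2, lowqual = 2),
             seed = seed, path = file.path(out, "cross.vcf"))
truth <- attr(geno, "map_df")
write.csv(truth, file.path(out, "true_map.csv"), row.names = FALSE)

## behavioural trials for the males (3 trials each, as in the assay)
set.seed(child_seed(seed, "trials"))
males <- pheno[pheno$sex == "M", ]
trials <- do.call(rbind, lapply(seq_len(nrow(males)), function(i) {
  lam <- exp(1.4 + 0.3 * males$phenotype[i])
  data.frame(individual = males$id[i], class = males$class[i],
             trial = 1:3, strikes = rpois(3, lam),
             latency = round(runif(3, 1, 90), 1),
             scraping = rpois(3, 0.5),
             scrape_effect = sample(c(0, 0, 0, 0.1, 0.25), 3, TRUE),
             hiding = sample(1:4, 3, TRUE),
             interaction = sample(1:4, 3, TRUE),
             SL = round(rlnorm(1, log(82), 0.1), 1))
}))
idle <- which(trials$strikes == 0)
trials$hiding[idle[seq_len(min(4, length(idle)))]] <- 5
areas <- vapply(seq_len(nrow(trials)), function(i) {
  f <- min(0.9, 0.0035 * trials$strikes[i])
  pair <- simulate_sand_images(sim_image_spec(
    target_fraction = f, seed = child_seed(seed, paste0("img", i))))
  c(before = quantify_sand_area(pair$before, 80),
    after = quantify_sand_area(pair$after, 80),
    truth = 100 * pair$true_fraction)
}, numeric(3))
trials$area_before_pct <- round(areas["before", ], 4)
trials$area_after_pct <- round(areas["after", ], 4)
trials$true_turned_pct <- round(areas["truth", ], 4)
write.csv(trials, file.path(out, "trials.csv"), row.names = FALSE)

## landmarks: class-specific means plus allometry, with nuisance transforms
allo <- matrix(0, 13, 2); allo[1, 2] <- 0.6; allo[8, 1] <- -0.4
lms <- simulate_landmarks(
  n_per_class = c(F2 = 113, CAL = 6, TAE = 5),
  allometry = allo, logSL_mean = log10(82), logSL_sd = 0.1,
  noise_sd = 0.02, seed = seed)
write_tps(lms, file.path(out, "landmarks.tps"))
spec_info <- data.frame(
  id = vapply(lms, `[[`, "", "id"),
  class = vapply(lms, `[[`, "", "class"),
  sex = vapply(lms, `[[`, "", "sex"),
  SL = vapply(lms, `[[`, 0, "SL"))
write.csv(spec_info, file.path(out, "specimens.csv"), row.names = FALSE)

cat(sprintf("simulated %d markers x %d F2, %d trials, %d specimens -> %s\n",
            ncol(geno), nrow(geno), nrow(trials), length(lms), out))
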