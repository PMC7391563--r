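#!/usr/bin/env Rscript
# Stage 2: score the sand-sifting trials.
#
# Net turned-over area (before-picture subtracted, scrape-corrected),
# efficiency per strike, trial exclusions, per-individual aggregation,
# transgression thresholds and classification, and permutation tests for
# class mean differences — with and without size correction of efficiency.

suppressPackageStartupMessages(library(sandsift))
seed <- 20260923
trials <- read.csv("results/sim/trials.csv")
out <- "results/behavior"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

trials$net_area <- net_turned_area(trials$area_before_pct,
                                   trials$area_after_pct,
                                   trials$scrape_effect, "complement")
trials$efficiency <- efficiency(trials$net_area, trials$strikes)$raw
ex <- exclude_trials(trials)
cat(sprintf("excluded %d of %d trials (no strike + hiding/interaction 5)\n",
            nrow(ex$excluded), nrow(trials)))

agg <- aggregate_individual(ex$valid, "max")
agg$class <- trials$class[match(agg$individual, trials$individual)]
agg$SL <- trials$SL[match(agg$individual, trials$individual)]
write.csv(agg, file.path(out, "per_individual.csv"), row.names = FALSE)

report <- NULL
for (trait in c("strikes", "efficiency")) {
  v <- agg[[trait]]
  ok <- !is.na(v)
  th <- transgression_thresholds(v[ok & agg$class == "CAL"],
                                 v[ok & agg$class == "TAE"])
  cl <- classify_transgression(v[ok & agg$class == "F2"], th,
                               agg$individual[ok & agg$class == "F2"])
  report <- rbind(report, data.frame(
    trait = trait, upper = th$upper, lower = th$lower,
    range_lo = th$classical[1], range_hi = th$classical[2],
    n_above = cl$counts["above"], n_below = cl$counts["below"],
    n_outside_range = cl$counts["outside_range"]))
}
write.csv(report, file.path(out, "transgression.csv"), row.names = FALSE)

## permutation tests on strikes, raw and size-corrected log efficiency
pt_row <- function(trait, v) {
  combos <- list(c("F2", "CAL"), c("F2", "TAE"), c("TAE", "CAL"))
  do.call(rbind, lapply(combos, function(cc) {
    p <- perm_test(v[agg$class == cc[1]], v[agg$class == cc[2]],
                   n_perm = 10000, seed = child_seed(seed, paste(trait, cc[1],
                                                                 cc[2])))$p
    data.frame(trait = trait, comparison = paste(cc, collapse = " vs "),
               p = p)
  }))
}
tests <- pt_row("max strikes", agg$strikes)
ok <- !is.na(agg$efficiency)
tests <- rbind(tests, pt_row("log10 max efficiency",
                             ifelse(ok, log10(agg$efficiency), NA)))
sc <- size_correct(agg$efficiency[ok], agg$SL[ok], agg$class[ok],
                   pool = "per_class")
vv <- rep(NA_real_, nrow(agg)); vv[ok] <- sc$residuals
tests <- rbind(tests, pt_row("size-corrected efficiency", vv))
write.csv(tests, file.path(out, "perm_tests.csv"), row.names = FALSE)

cat("behaviour tables ->", out, "\n")
print(report)
print(tests)
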