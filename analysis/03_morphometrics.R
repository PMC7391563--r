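#!/usr/bin/env Rscript
# Stage 3: linear and geometric morphometrics.
#
# Reads the TPS landmark file, computes the four linear head distances and
# the mouth angle, size-corrects them with the homogeneity-of-slopes gate,
# standardizes jaw opening, runs GPA with sliding semilandmarks, removes
# allometry, and summarizes shape variation by PCA with per-axis
# transgression and projection of the parental specimens into the
# F2-only morphospace.

suppressPackageStartupMessages(library(sandsift))
seed <- 20260923
out <- "results/morph"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

configs <- read_tps("results/sim/landmarks.tps")
info <- read.csv("results/sim/specimens.csv")
for (i in seq_along(configs)) {
  j <- match(configs[[i]]$id, info$id)
  configs[[i]]$SL <- info$SL[j]
  configs[[i]]$class <- info$class[j]
  configs[[i]]$sex <- info$sex[j]
}

## linear traits + mouth angle, size-corrected
lin <- t(vapply(configs, linear_distances, numeric(4)))
ma <- vapply(configs, mouth_angle, numeric(1))
cls <- info$class[match(vapply(configs, `[[`, "", "id"), info$id)]
sc <- size_correct(lin, info$SL, cls, pool = "auto")
write.csv(cbind(info, sc$residuals, MA = ma),
          file.path(out, "linear_traits.csv"), row.names = FALSE)
write.csv(sc$report, file.path(out, "slope_homogeneity.csv"),
          row.names = FALSE)

lin_trans <- do.call(rbind, lapply(colnames(lin), function(tr) {
  v <- sc$residuals[, tr]
  th <- transgression_thresholds(v[cls == "CAL"], v[cls == "TAE"])
  cl <- classify_transgression(v[cls == "F2"], th)
  data.frame(trait = tr, n_above = cl$counts["above"],
             n_below = cl$counts["below"])
}))
write.csv(lin_trans, file.path(out, "linear_transgression.csv"),
          row.names = FALSE)

## shape: jaw standardization, GPA + sliding, allometry, PCA
configs <- standardize_jaw(configs)
space <- gpa(configs, slide = TRUE)
hom <- allometry_homogeneity(space, class = cls, n_perm = 499,
                             seed = child_seed(seed, "hom"))
af <- allometry_free(space, n_perm = 999, seed = child_seed(seed, "allo"))
cat(sprintf("shape ~ size: F = %.2f, p = %.3f; slope homogeneity p = %.3f\n",
            af$report$F, af$report$p, hom$p))

pca <- shape_pca(af$shapes)
var_tab <- data.frame(axis = colnames(pca$scores),
                      var_frac = round(pca$var_frac, 4))
write.csv(var_tab, file.path(out, "shape_pca_variance.csv"),
          row.names = FALSE)
scores <- data.frame(id = rownames(pca$scores), class = cls,
                     pca$scores[, 1:6])
write.csv(scores, file.path(out, "shape_scores.csv"), row.names = FALSE)

shape_trans <- do.call(rbind, lapply(1:6, function(k) {
  v <- pca$scores[, k]
  th <- transgression_thresholds(v[cls == "CAL"], v[cls == "TAE"])
  cl <- classify_transgression(v[cls == "F2"], th)
  data.frame(axis = colnames(pca$scores)[k],
             n_above = cl$counts["above"], n_below = cl$counts["below"])
}))
write.csv(shape_trans, file.path(out, "shape_transgression.csv"),
          row.names = FALSE)

## F2-only morphospace; parents projected in (scores reused for mapping)
f2_idx <- which(cls == "F2")
pca_f2 <- shape_pca(af$shapes[, , f2_idx])
proj_par <- project_shapes(af$shapes[, , cls != "F2"], pca_f2)
write.csv(data.frame(id = rownames(pca_f2$scores), pca_f2$scores[, 1:6]),
          file.path(out, "f2_shape_scores.csv"), row.names = FALSE)
write.csv(data.frame(id = space$ids[cls != "F2"], proj_par[, 1:6]),
          file.path(out, "parent_projected_scores.csv"), row.names = FALSE)

cat("morphometric tables ->", out, "\n")
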