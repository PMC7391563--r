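#!/usr/bin/env Rscript
# Stage 4: variant filtering and linkage-map construction.
#
# Hard-filters the VCF (site quality, genotype masking, indels and their
# neighbourhoods, multiallelic/monomorphic sites, missingness, depth cap,
# singletons/doubletons, 200-bp thinning), applies individual QC, selects
# reciprocally fixed parental markers, recodes the F2, runs pre-mapping
# marker QC, groups markers at independence LOD 7, and builds the Kosambi
# map.

suppressPackageStartupMessages(library(sandsift))
out <- "results/map"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

rec <- read_vcf_records("results/sim/cross.vcf")
cat(sprintf("read %d sites x %d samples\n", nrow(rec$meta),
            length(rec$samples)))
fv <- filter_variants(rec)
write.table(data.frame(rule = names(fv$counts),
                       count = as.integer(fv$counts)),
            file.path(out, "filter_report.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
fi <- filter_individuals(fv$records)
write.csv(fi$stats, file.path(out, "individual_qc.csv"), row.names = FALSE)

panelA <- grep("^CAL", fi$records$samples, value = TRUE)
panelB <- grep("^TAE", fi$records$samples, value = TRUE)
f2_ids <- grep("^F2", fi$records$samples, value = TRUE)
fixed <- find_reciprocally_fixed(fi$records, panelA, panelB)
cat(sprintf("%d reciprocally fixed markers over %d F2\n", nrow(fixed),
            length(f2_ids)))
cross <- recode_f2(fi$records, fixed, f2_ids)

qc <- qc_markers(cross)
write.csv(qc$markers, file.path(out, "marker_qc.csv"), row.names = FALSE)
cat(sprintf("marker QC dropped %d distorted, %d high-missing markers\n",
            sum(qc$markers$reason == "distortion"),
            sum(qc$markers$reason == "missingness")))

lodm <- pairwise_independence_lod(qc$geno)
groups <- group_markers(lodm, threshold = 7)
lmap <- build_map(groups, qc$geno, order = "given")
print(lmap)
write.csv(lmap$map, file.path(out, "linkage_map.csv"), row.names = FALSE)
write.csv(data.frame(
  n_markers = lmap$summary$n_markers, n_groups = lmap$summary$n_groups,
  mean_per_group = round(lmap$summary$mean, 2),
  sd = round(lmap$summary$sd, 2), min = lmap$summary$min,
  max = lmap$summary$max,
  length_cM = round(lmap$summary$length_cM, 1)),
  file.path(out, "map_summary.csv"), row.names = FALSE)

genof <- data.frame(id = rownames(qc$geno), qc$geno, check.names = FALSE)
write.csv(genof, file.path(out, "f2_genotypes.csv"), row.names = FALSE)
cat("map tables ->", out, "\n")
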