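#' Read a VCF into a variant-record set
#'
#' Parses a VCF (v4.2) via \pkg{vcfR} into the flat structure the filtering
#' operations work on: per-site metadata plus genotype (allele-count), GQ
#' and DP matrices. Genotypes are stored as the number of ALT alleles
#' (0, 1, 2) with `NA` for missing; phased and unphased calls are treated
#' alike.
#'
#' @param path VCF file path.
#' @return Object of class `variant_records`: list with `meta` (data.frame
#'   `chrom`, `pos`, `id`, `ref`, `alt`, `qual`), `gt`, `gq`, `dp`
#'   (site x sample matrices) and `samples`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  to_count <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_integer_, length(g))
    out[g == "0/0"] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g == "1/1"] <- 2L
    out
  }
  gt <- matrix(to_count(gt_chr), nrow = nrow(gt_chr),
               dimnames = dimnames(gt_chr))
  meta <- data.frame(chrom = fix[, "CHROM"],
                     pos = as.integer(fix[, "POS"]),
                     id = fix[, "ID"], ref = fix[, "REF"], alt = fix[, "ALT"],
                     qual = suppressWarnings(as.numeric(fix[, "QUAL"])),
                     stringsAsFactors = FALSE)
  structure(list(meta = meta, gt = gt, gq = gq, dp = dp,
                 samples = colnames(gt_chr)),
            class = "variant_records")
}

#' @export
print.variant_records <- function(x, ...) {
  cat(sprintf("variant_records: %d sites x %d samples\n", nrow(x$meta),
              length(x$samples)))
  invisible(x)
}

# positions nondecreasing within each chromosome block
.check_sorted <- function(meta) {
  by_chr <- split(meta$pos, factor(meta$chrom, levels = unique(meta$chrom)))
  if (any(vapply(by_chr, is.unsorted, logical(1))))
    stop("records must be sorted by position within chromosome")
}

#' Hard-filter variant records
#'
#' Applies, in order: (1) site quality >= `min_site_qual`; (2)
#' genotype-level masking — genotypes with GQ < `min_gq` or DP < `min_dp`
#' are set missing; (3) drop indels; (4) drop sites within
#' `indel_window` bp of an indel start (inclusive both sides); (5) drop
#' multiallelic sites; (6) drop monomorphic sites (after masking); (7) drop
#' sites with more than `max_missing` missing genotypes; (8) drop sites
#' with mean genotype depth above `max_mean_depth` (paralog enrichment);
#' (9) drop sites whose minor allele occurs at most `min_mac` times
#' (singletons and doubletons are uninformative for mapping); (10) thin to
#' one site per `thin_bp` window, keeping the lowest-position site of each
#' cluster (one SNP per RAD locus). A site failing several rules is counted
#' under the first failing rule, so the exclusion counts plus the retained
#' count always sum to the input count.
#'
#' @param rec A `variant_records` object.
#' @param min_site_qual,min_gq,min_dp,indel_window,max_missing,
#'   max_mean_depth,min_mac,thin_bp Thresholds; defaults are the study
#'   values (30, 30, 10, 10 bp, 0.5, 88, 2, 200 bp).
#' @return List: `records` (filtered, genotype-masked `variant_records`),
#'   `counts` (named exclusion counts per rule plus `retained`).
#' @export
filter_variants <- function(rec, min_site_qual = 30, min_gq = 30,
                            min_dp = 10, indel_window = 10,
                            max_missing = 0.5, max_mean_depth = 88,
                            min_mac = 2, thin_bp = 200) {
  .check(inherits(rec, "variant_records"), "rec must be variant_records")
  ns <- nrow(rec$meta)
  rules <- c("site_quality", "indel", "near_indel", "multiallelic",
             "monomorphic", "missingness", "mean_depth", "low_mac",
             "proximity_thin")
  counts <- stats::setNames(integer(length(rules)), rules)
  if (ns == 0) return(list(records = rec, counts = c(counts, retained = 0L)))
  .check_sorted(rec$meta)

  # genotype-level masking (GQ/DP) applies to all downstream rules
  mask <- (!is.na(rec$gq) & rec$gq < min_gq) |
    (!is.na(rec$dp) & rec$dp < min_dp)
  gt <- rec$gt; gt[mask] <- NA_integer_

  is_indel <- nchar(rec$meta$ref) > 1 |
    vapply(strsplit(rec$meta$alt, ","),
           function(a) any(nchar(a) > 1), logical(1))
  is_multi <- grepl(",", rec$meta$alt)

  fail <- matrix(FALSE, ns, length(rules), dimnames = list(NULL, rules))
  fail[, "site_quality"] <- is.na(rec$meta$qual) | rec$meta$qual < min_site_qual
  fail[, "indel"] <- is_indel
  near <- rep(FALSE, ns)
  for (i in which(is_indel)) {
    near <- near | (rec$meta$chrom == rec$meta$chrom[i] &
                      abs(rec$meta$pos - rec$meta$pos[i]) <= indel_window)
  }
  near[is_indel] <- FALSE
  fail[, "near_indel"] <- near
  fail[, "multiallelic"] <- is_multi

  n_nonmiss <- rowSums(!is.na(gt))
  alt_count <- rowSums(gt, na.rm = TRUE)
  ref_count <- 2 * n_nonmiss - alt_count
  mac <- pmin(alt_count, ref_count)
  fail[, "monomorphic"] <- n_nonmiss == 0 | mac == 0
  fail[, "missingness"] <- rowMeans(is.na(gt)) > max_missing
  mean_dp <- vapply(seq_len(ns), function(i) {
    d <- rec$dp[i, !is.na(gt[i, ])]
    if (length(d) == 0) 0 else mean(d, na.rm = TRUE)
  }, numeric(1))
  fail[, "mean_depth"] <- mean_dp > max_mean_depth
  fail[, "low_mac"] <- mac > 0 & mac <= min_mac

  pre <- !apply(fail[, 1:8, drop = FALSE], 1, any)
  # proximity thinning on the survivors, greedy lowest-position-first
  thin_fail <- rep(FALSE, ns)
  for (ch in unique(rec$meta$chrom)) {
    idx <- which(pre & rec$meta$chrom == ch)
    last <- -Inf
    for (i in idx) {
      if (rec$meta$pos[i] - last <= thin_bp) thin_fail[i] <- TRUE
      else last <- rec$meta$pos[i]
    }
  }
  fail[, "proximity_thin"] <- thin_fail
  first_fail <- apply(fail, 1, function(z) if (any(z)) which(z)[1] else 0L)
  for (j in seq_along(rules)) counts[j] <- sum(first_fail == j)
  keep <- first_fail == 0L
  out <- rec
  out$meta <- rec$meta[keep, , drop = FALSE]
  out$gt <- gt[keep, , drop = FALSE]
  out$gq <- rec$gq[keep, , drop = FALSE]
  out$dp <- rec$dp[keep, , drop = FALSE]
  list(records = out, counts = c(counts, retained = sum(keep)))
}

#' Filter individuals on depth and missingness
#'
#' Drops samples with mean genotype depth below `min_mean_depth` or with
#' more than `max_missing` missing genotypes, mirroring the study's
#' individual-level QC.
#'
#' @param rec `variant_records` (after [filter_variants()]).
#' @param min_mean_depth,max_missing Bounds (defaults 20 and 0.5).
#' @return List: `records` with failing samples removed, `stats` data.frame
#'   (`sample`, `mean_depth`, `missing`, `retained`).
#' @export
filter_individuals <- function(rec, min_mean_depth = 20, max_missing = 0.5) {
  .check(inherits(rec, "variant_records"), "rec must be variant_records")
  miss <- colMeans(is.na(rec$gt))
  mdp <- vapply(seq_along(rec$samples), function(j) {
    d <- rec$dp[!is.na(rec$gt[, j]), j]
    if (length(d) == 0) 0 else mean(d, na.rm = TRUE)
  }, numeric(1))
  keep <- mdp >= min_mean_depth & miss <= max_missing
  stats_df <- data.frame(sample = rec$samples, mean_depth = mdp,
                         missing = miss, retained = keep)
  out <- rec
  out$gt <- rec$gt[, keep, drop = FALSE]
  out$gq <- rec$gq[, keep, drop = FALSE]
  out$dp <- rec$dp[, keep, drop = FALSE]
  out$samples <- rec$samples[keep]
  list(records = out, stats = stats_df)
}

#' Find reciprocally fixed parental markers
#'
#' Keeps sites where every non-missing panel-A genotype is homozygous for
#' one allele, every non-missing panel-B genotype homozygous for the other,
#' and per-panel missing counts stay within bounds (the study allowed three
#' of six CAL and two of five TAE to be missing). The surviving sites stand
#' in for the unavailable grandparents of the cross.
#'
#' @param rec `variant_records`.
#' @param panelA,panelB Disjoint character vectors of sample names.
#' @param max_missing_A,max_missing_B Allowed missing counts (3, 2).
#' @return data.frame `chrom`, `pos`, `id`, `A_allele` (`"ref"` or
#'   `"alt"`).
#' @export
find_reciprocally_fixed <- function(rec, panelA, panelB, max_missing_A = 3,
                                    max_missing_B = 2) {
  .check(length(intersect(panelA, panelB)) == 0, "panels must be disjoint")
  .check(all(c(panelA, panelB) %in% rec$samples),
         "panel samples missing from records")
  ga <- rec$gt[, panelA, drop = FALSE]
  gb <- rec$gt[, panelB, drop = FALSE]
  missA <- rowSums(is.na(ga)); missB <- rowSums(is.na(gb))
  allA0 <- rowSums(ga != 0, na.rm = TRUE) == 0 & missA < length(panelA)
  allA2 <- rowSums(ga != 2, na.rm = TRUE) == 0 & missA < length(panelA)
  allB0 <- rowSums(gb != 0, na.rm = TRUE) == 0 & missB < length(panelB)
  allB2 <- rowSums(gb != 2, na.rm = TRUE) == 0 & missB < length(panelB)
  ok <- missA <= max_missing_A & missB <= max_missing_B &
    ((allA0 & allB2) | (allA2 & allB0))
  data.frame(chrom = rec$meta$chrom[ok], pos = rec$meta$pos[ok],
             id = rec$meta$id[ok],
             A_allele = ifelse(allA0[ok], "ref", "alt"),
             stringsAsFactors = FALSE)
}

#' Recode F2 genotypes against the parental allele assignment
#'
#' Maps each F2 genotype at a reciprocally fixed marker to `AA` / `AB` /
#' `BB` by counting parent-A alleles (`AA` = homozygous parent-A,
#' `BB` = homozygous parent-B); missing is preserved.
#'
#' @param rec `variant_records`.
#' @param markers data.frame from [find_reciprocally_fixed()].
#' @param f2_samples Character vector of F2 sample names.
#' @return Object of class `f2_geno`: list with `geno` (individuals x
#'   markers character matrix `AA`/`AB`/`BB`/`NA`) and `markers`
#'   (data.frame `marker`, `chrom`, `pos`).
#' @export
recode_f2 <- function(rec, markers, f2_samples) {
  key <- paste(rec$meta$chrom, rec$meta$pos)
  sel <- match(paste(markers$chrom, markers$pos), key)
  .check(!anyNA(sel), "marker set contains sites absent from records")
  gt <- rec$gt[sel, f2_samples, drop = FALSE]
  nA <- ifelse(rep(markers$A_allele == "ref", ncol(gt)), 2L - gt, gt)
  geno <- matrix(c("BB", "AB", "AA")[nA + 1L], nrow = nrow(gt))
  mk <- ifelse(is.na(markers$id) | markers$id == ".",
               paste0(markers$chrom, "_", markers$pos), markers$id)
  geno <- t(geno)  # individuals x markers
  dimnames(geno) <- list(f2_samples, mk)
  structure(list(geno = geno,
                 markers = data.frame(marker = mk, chrom = markers$chrom,
                                      pos = markers$pos,
                                      stringsAsFactors = FALSE)),
            class = "f2_geno")
}
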