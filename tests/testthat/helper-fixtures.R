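# Shared fixtures, all built in code at test time.

# Write a VCF from a list of record lists; each record:
#   list(chrom, pos, id, ref, alt, qual, gt = chr vector, gq, dp)
# gq/dp may be scalars (recycled).
write_toy_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", unique(vapply(records, `[[`,
                                                     "", "chrom"))),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"GQ\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    gq <- rep_len(r$gq %||% 60L, length(samples))
    dp <- rep_len(r$dp %||% 30L, length(samples))
    gt <- rep_len(r$gt, length(samples))
    paste(c(r$chrom, r$pos, r$id %||% ".", r$ref %||% "A", r$alt %||% "G",
            r$qual %||% 500, "PASS", ".", "GT:GQ:DP",
            sprintf("%s:%d:%d", gt, gq, dp)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A small simulated cross shared by linkage/QTL tests.
toy_cross <- function(n_chr = 2, len = 100, mk = 11, n = 150, seed = 42) {
  map <- simulate_map(n_chr, len, mk, seed = seed)
  geno <- simulate_f2(map, n, map_function = "kosambi", seed = seed + 1)
  md <- attr(geno, "map_df")
  list(map = map, geno = geno,
       map_df = data.frame(group = md$chr, marker = md$marker,
                           pos_cM = md$pos_cM))
}

# Brute-force hidden-path enumeration oracle for the genotype-probability
# HMM on a single chain of typed markers (no pseudomarkers). Returns the
# n x 3 x n_markers posterior array.
enumerate_genoprob <- function(geno_row, pos, error_prob, map_function) {
  rfun <- switch(map_function,
                 kosambi = function(d) 0.5 * tanh(2 * d / 100),
                 haldane = function(d) 0.5 * (1 - exp(-2 * d / 100)))
  states <- c("AA", "AB", "BB")
  m <- length(pos)
  prior <- c(0.25, 0.5, 0.25)
  trans <- function(r) matrix(c((1 - r)^2, 2 * r * (1 - r), r^2,
                                r * (1 - r), (1 - r)^2 + r^2, r * (1 - r),
                                r^2, 2 * r * (1 - r), (1 - r)^2),
                              3, 3, byrow = TRUE)
  Tm <- lapply(rfun(diff(pos)), trans)
  emis <- function(obs, s) {
    if (is.na(obs)) 1 else if (obs == states[s]) 1 - error_prob
    else error_prob / 2
  }
  paths <- as.matrix(expand.grid(rep(list(1:3), m)))
  pp <- apply(paths, 1, function(pth) {
    p <- prior[pth[1]] * emis(geno_row[1], pth[1])
    if (m >= 2) for (t in 2:m)
      p <- p * Tm[[t - 1]][pth[t - 1], pth[t]] * emis(geno_row[t], pth[t])
    p
  })
  post <- matrix(0, m, 3)
  for (t in 1:m) for (s in 1:3)
    post[t, s] <- sum(pp[paths[, t] == s])
  post / rowSums(post)
}
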