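# Fixture builders and independent oracles shared across the suite.

# one-hot (degenerate) genotype likelihoods from hard calls; missing
# genotypes get the uninformative triple
onehot_gl <- function(gt) {
  n <- length(gt$individuals)
  m <- length(gt$sites)
  gl <- array(1 / 3, dim = c(n, m, 3))
  for (g in 0:2) {
    hit <- !is.na(gt$geno) & gt$geno == g
    slice <- gl[, , g + 1]
    slice[hit] <- 1
    gl[, , g + 1] <- slice
  }
  hit_any <- !is.na(gt$geno)
  for (g in 0:2) {
    slice <- gl[, , g + 1]
    slice[hit_any & !(gt$geno == g)] <- 0
    gl[, , g + 1] <- slice
  }
  genotype_likelihoods(gt$individuals, gt$sites, gl)
}

# Hudson FST estimator (ratio of averages over sites)
hudson_fst <- function(geno, pop) {
  pops <- unique(pop)
  stopifnot(length(pops) == 2)
  a <- geno[pop == pops[1], , drop = FALSE]
  b <- geno[pop == pops[2], , drop = FALSE]
  num <- den <- 0
  for (j in seq_len(ncol(geno))) {
    x <- a[, j][!is.na(a[, j])]
    y <- b[, j][!is.na(b[, j])]
    n1 <- 2 * length(x)
    n2 <- 2 * length(y)
    if (n1 < 4 || n2 < 4) next
    p1 <- sum(x) / n1
    p2 <- sum(y) / n2
    num <- num + (p1 - p2)^2 -
      p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- den + p1 * (1 - p2) + p2 * (1 - p1)
  }
  num / den
}

# adjusted Rand index between two partitions
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  (sum_ij - expected) / ((sum_i + sum_j) / 2 - expected)
}

# hard-call standardized genotype covariance (the one-step oracle)
hardcall_covariance <- function(geno) {
  f <- colMeans(geno) / 2
  poly <- f > 0 & f < 1
  g <- geno[, poly, drop = FALSE]
  f <- f[poly]
  r <- sweep(sweep(g, 2, 2 * f, "-"), 2, sqrt(2 * f * (1 - f)), "/")
  tcrossprod(r) / ncol(g)
}

# small two-sample VCF: 3 biallelic records + 1 multiallelic, GT:DP
write_toy_vcf <- function(path, phased_het = FALSE, ad_only = FALSE) {
  fmt <- if (ad_only) "GT:AD" else "GT:DP"
  het1 <- if (phased_het) "0|1" else "0/1"
  het2 <- if (phased_het) "1|0" else "1/0"
  val <- function(gt, dp, ad) {
    if (ad_only) paste0(gt, ":", ad) else paste0(gt, ":", dp)
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", "s1", "s2"
    ), collapse = "\t"),
    paste(c("chr1", "100", ".", "A", "G", ".", "PASS", ".", fmt,
      val("0/0", 10, "10,0"), val(het1, 8, "3,4")), collapse = "\t"),
    paste(c("chr1", "200", ".", "C", "T", ".", "PASS", ".", fmt,
      val("1/1", 12, "0,12"), val("./.", 0, ".")), collapse = "\t"),
    paste(c("chr1", "300", ".", "G", "T,C", ".", "PASS", ".", fmt,
      val("1/1", 9, "0,9"), val("0/0", 7, "7,0")), collapse = "\t"),
    paste(c("chr1", "400", ".", "T", "A", ".", "PASS", ".", fmt,
      val(het2, 6, "3,3"), val("1/1", 11, "0,11")), collapse = "\t")
  )
  writeLines(lines, path)
  path
}
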