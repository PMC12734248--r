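## Synthetic two-population data generator. The defaults are the study
## conditions used throughout the test suite: two continental populations
## (Africa-like / Asia-like) at moderate nuclear differentiation, mean
## sequencing depth ~10x (the downsampling target used for real libraries),
## and region-structured COI haplotype pools.

#' Configuration for the two-population nuclear genotype simulator
#'
#' Neutral loci follow a Balding-Nichols model: a shared ancestral allele
#' frequency is drawn per locus, and each population's frequency is drawn
#' from a beta distribution around it whose concentration is set by the
#' target differentiation `divergence` (approximately the expected FST).
#' `planted_sites` additional loci are fully specified by the allele
#' frequency pair `planted_freqs = (p_a, p_b)` and emulate diagnostic,
#' near-fixed differences between the populations.
#'
#' @param n_pop_a,n_pop_b Individuals per population (labels `"Africa"` and
#'   `"Asia"`).
#' @param n_sites Number of neutral loci.
#' @param planted_sites Number of planted diagnostic loci.
#' @param planted_freqs Length-2 numeric, alternate-allele frequency of the
#'   planted loci in population A and B.
#' @param divergence Target allele-frequency differentiation (FST-like) of
#'   the neutral loci; `0` collapses both populations onto the ancestral
#'   frequency.
#' @param missing_rate Per-genotype missingness probability (on top of
#'   depth-0 masking).
#' @param depth_mean,depth_size Mean and size (inverse overdispersion) of
#'   the negative-binomial per-genotype depth model.
#' @param seed Integer seed; the same seed yields bitwise-identical output.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_pop_a = 60, n_pop_b = 60, n_sites = 500,
                       planted_sites = 0, planted_freqs = c(0.02, 0.98),
                       divergence = 0.1, missing_rate = 0.005,
                       depth_mean = 10, depth_size = 5, seed = 1L) {
  stopifnot(
    n_pop_a >= 1, n_pop_b >= 1, n_sites >= 1, planted_sites >= 0,
    length(planted_freqs) == 2, all(planted_freqs >= 0), all(planted_freqs <= 1),
    divergence >= 0, divergence < 1,
    missing_rate >= 0, missing_rate <= 1,
    depth_mean > 0, depth_size > 0
  )
  structure(
    list(
      n_pop_a = as.integer(n_pop_a), n_pop_b = as.integer(n_pop_b),
      n_sites = as.integer(n_sites), planted_sites = as.integer(planted_sites),
      planted_freqs = as.numeric(planted_freqs),
      divergence = divergence, missing_rate = missing_rate,
      depth_mean = depth_mean, depth_size = depth_size,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Simulate a two-population diploid genotype table
#'
#' @param cfg A [sim_config()].
#' @return A list with elements:
#'   * `gt`: a [genotype_table()] whose `class_label` carries the true
#'     population of each individual;
#'   * `truth`: data.frame of individual ids, true populations, and a
#'     logical `planted` flag per site in `site_info`;
#'   * `site_info`: data.frame of site ids, per-population allele
#'     frequencies and the planted flag.
#' @details Genotypes are alternate-allele counts drawn binomial(2, p_pop);
#'   depths are negative-binomial; genotypes are masked missing at
#'   `missing_rate` (their depth is then zeroed) and wherever the drawn
#'   depth is 0.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n_a <- cfg$n_pop_a
  n_b <- cfg$n_pop_b
  n <- n_a + n_b
  m <- cfg$n_sites + cfg$planted_sites
  pop <- c(rep("Africa", n_a), rep("Asia", n_b))
  ids <- c(sprintf("A%03d", seq_len(n_a)), sprintf("B%03d", seq_len(n_b)))

  p_anc <- runif(cfg$n_sites, 0.05, 0.95)
  if (cfg$divergence > 0) {
    conc <- (1 - cfg$divergence) / cfg$divergence
    p_a <- rbeta(cfg$n_sites, p_anc * conc, (1 - p_anc) * conc)
    p_b <- rbeta(cfg$n_sites, p_anc * conc, (1 - p_anc) * conc)
  } else {
    p_a <- p_anc
    p_b <- p_anc
  }
  planted <- rep(FALSE, m)
  if (cfg$planted_sites > 0) {
    p_a <- c(p_a, rep(cfg$planted_freqs[1], cfg$planted_sites))
    p_b <- c(p_b, rep(cfg$planted_freqs[2], cfg$planted_sites))
    planted[cfg$n_sites + seq_len(cfg$planted_sites)] <- TRUE
  }

  geno <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    geno[, j] <- c(rbinom(n_a, 2, p_a[j]), rbinom(n_b, 2, p_b[j]))
  }
  depth <- matrix(
    rnbinom(n * m, mu = cfg$depth_mean, size = cfg$depth_size),
    nrow = n, ncol = m
  )
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(n * m) < cfg$missing_rate, nrow = n)
    depth[drop] <- 0L
  }
  geno[depth == 0] <- NA_integer_

  sites <- sprintf("chr1:%d", seq_len(m) * 1000L)
  gt <- genotype_table(
    individuals = ids, sites = sites, geno = geno, depth = depth,
    class_label = pop,
    ref = setNames(rep("A", m), sites), alt = setNames(rep("G", m), sites)
  )
  list(
    gt = gt,
    truth = data.frame(id = ids, population = pop, stringsAsFactors = FALSE),
    site_info = data.frame(
      site = sites, freq_a = p_a, freq_b = p_b, planted = planted,
      stringsAsFactors = FALSE
    )
  )
}

#' Configuration for the region-structured COI haplotype simulator
#'
#' Each region carries a pool of haplotypes with given frequencies over a
#' shared haplotype set; individuals draw a haplotype from their region's
#' pool and then accumulate independent per-site substitutions at
#' `mutation_rate`. A fraction `discordance_rate` of individuals draw their
#' mitochondrial haplotype from a *different* region's pool while keeping
#' their nuclear region label, planting mitonuclear discordance.
#'
#' @param regions Named integer vector of per-region sample counts; names
#'   must be in [REGION_VOCABULARY] (not `"Unknown"`).
#' @param haplotype_pools Named list (same names as `regions`) of frequency
#'   vectors over the shared haplotype set; each must sum to 1. Default:
#'   two private haplotypes per region at frequencies (0.7, 0.3).
#' @param n_haplotypes Size of the shared haplotype set when
#'   `haplotype_pools` is `NULL`.
#' @param haplotype_divergence Per-site substitution probability separating
#'   each founding haplotype from the random ancestral barcode sequence.
#' @param mutation_rate Per-site, per-copy substitution probability applied
#'   when an individual's sequence is emitted.
#' @param barcode_length Alignment width in positions.
#' @param discordance_rate Fraction of individuals whose mitochondrial
#'   haplotype is drawn from another region's pool.
#' @param seed Integer seed.
#' @return A validated `haplotype_sim_config` list.
#' @export
haplotype_sim_config <- function(regions = c(
                                   "Africa" = 60, "East Asia" = 60,
                                   "South Asia" = 60, "Southeast Asia" = 60,
                                   "Mascarenes" = 30, "Pacific" = 30
                                 ),
                                 haplotype_pools = NULL,
                                 n_haplotypes = NULL,
                                 haplotype_divergence = 0.02,
                                 mutation_rate = 0.002,
                                 barcode_length = 658,
                                 discordance_rate = 0,
                                 seed = 1L) {
  stopifnot(
    length(regions) >= 1, all(regions >= 1),
    !is.null(names(regions)),
    all(names(regions) %in% setdiff(REGION_VOCABULARY, "Unknown")),
    mutation_rate >= 0, mutation_rate <= 1,
    haplotype_divergence >= 0, haplotype_divergence <= 1,
    barcode_length >= 3,
    discordance_rate >= 0, discordance_rate <= 1
  )
  if (is.null(haplotype_pools)) {
    # default: two private haplotypes per region, frequencies 0.7/0.3
    k <- 2L * length(regions)
    haplotype_pools <- lapply(seq_along(regions), function(i) {
      p <- rep(0, k)
      p[c(2 * i - 1, 2 * i)] <- c(0.7, 0.3)
      p
    })
    names(haplotype_pools) <- names(regions)
  }
  stopifnot(identical(sort(names(haplotype_pools)), sort(names(regions))))
  pool_len <- unique(vapply(haplotype_pools, length, integer(1)))
  if (length(pool_len) != 1) {
    stop("all haplotype pools must cover the same shared haplotype set")
  }
  for (r in names(haplotype_pools)) {
    s <- sum(haplotype_pools[[r]])
    if (abs(s - 1) > 1e-9) {
      stop(sprintf("haplotype pool for %s sums to %g, not 1", r, s))
    }
  }
  if (is.null(n_haplotypes)) n_haplotypes <- pool_len
  if (n_haplotypes != pool_len) {
    stop("haplotype pool length does not match n_haplotypes")
  }
  structure(
    list(
      regions = regions, haplotype_pools = haplotype_pools,
      n_haplotypes = as.integer(n_haplotypes),
      haplotype_divergence = haplotype_divergence,
      mutation_rate = mutation_rate,
      barcode_length = as.integer(barcode_length),
      discordance_rate = discordance_rate,
      seed = as.integer(seed)
    ),
    class = "haplotype_sim_config"
  )
}

#' Simulate a region-structured COI barcode alignment
#'
#' @param cfg A [haplotype_sim_config()].
#' @return A list with elements:
#'   * `aln`: a gapless [barcode_alignment()] whose `region` is each
#'     individual's *mitochondrial* region (i.e. after any discordance
#'     swap);
#'   * `truth`: data.frame of id, haplotype index, nuclear region,
#'     mitochondrial region, and a `discordant` flag;
#'   * `haplotypes`: character vector of the founding haplotype sequences.
#' @export
simulate_barcodes <- function(cfg) {
  stopifnot(inherits(cfg, "haplotype_sim_config"))
  set.seed(cfg$seed)
  bases <- c("A", "C", "G", "T")
  L <- cfg$barcode_length
  ancestral <- sample(bases, L, replace = TRUE)
  haps <- vapply(seq_len(cfg$n_haplotypes), function(h) {
    s <- ancestral
    mut <- runif(L) < cfg$haplotype_divergence
    if (any(mut)) {
      s[mut] <- vapply(
        s[mut],
        function(b) sample(setdiff(bases, b), 1),
        character(1)
      )
    }
    paste(s, collapse = "")
  }, character(1))

  region_names <- names(cfg$regions)
  nuclear_region <- rep(region_names, times = cfg$regions)
  n <- length(nuclear_region)
  ids <- sprintf("S%04d", seq_len(n))
  discordant <- runif(n) < cfg$discordance_rate
  mito_region <- nuclear_region
  if (any(discordant) && length(region_names) > 1) {
    for (i in which(discordant)) {
      mito_region[i] <- sample(setdiff(region_names, nuclear_region[i]), 1)
    }
  } else {
    discordant[] <- FALSE
  }

  hap_idx <- integer(n)
  seqs <- character(n)
  for (i in seq_len(n)) {
    pool <- cfg$haplotype_pools[[mito_region[i]]]
    hap_idx[i] <- sample.int(length(pool), 1, prob = pool)
    s <- strsplit(haps[hap_idx[i]], "")[[1]]
    mut <- runif(L) < cfg$mutation_rate
    if (any(mut)) {
      s[mut] <- vapply(
        s[mut],
        function(b) sample(setdiff(bases, b), 1),
        character(1)
      )
    }
    seqs[i] <- paste(s, collapse = "")
  }

  list(
    aln = barcode_alignment(ids = ids, seqs = seqs, region = mito_region),
    truth = data.frame(
      id = ids, haplotype = hap_idx,
      nuclear_region = nuclear_region, mito_region = mito_region,
      discordant = discordant, stringsAsFactors = FALSE
    ),
    haplotypes = haps
  )
}

#' Derive genotype likelihoods from a genotype table
#'
#' Bridges hard synthetic genotypes to the likelihood-based structure
#' analyses. For each genotype with depth `d`, the number of reads
#' supporting the reference allele is drawn binomial(`d`, `q`), where `q` is
#' `1 - error_rate`, `0.5`, or `error_rate` for alternate-allele counts 0, 1
#' and 2; the likelihood of each candidate genotype is the binomial
#' probability of that read configuration, normalized over the triple.
#' Missing genotypes (or depth 0) receive the uninformative triple
#' (1/3, 1/3, 1/3). As depth grows the true genotype's likelihood tends
#' to 1; at `error_rate = 0` (the noiseless limit) observed genotypes get
#' degenerate one-hot triples.
#'
#' @param gt A [genotype_table()].
#' @param error_rate Symmetric per-read base error probability.
#' @param seed Optional integer seed for the read draws.
#' @return A [genotype_likelihoods()].
#' @export
emit_beagle_from_genotypes <- function(gt, error_rate = 0.01, seed = NULL) {
  stopifnot(inherits(gt, "genotype_table"))
  stopifnot(error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  n <- length(gt$individuals)
  m <- length(gt$sites)
  q_ref <- c(1 - error_rate, 0.5, error_rate) # P(read shows REF | genotype)
  gl <- array(1 / 3, dim = c(n, m, 3))
  d <- gt$depth
  g <- gt$geno
  obs <- !is.na(g) & d > 0
  if (any(obs)) {
    idx <- which(obs, arr.ind = TRUE)
    if (error_rate == 0) {
      # noiseless limit: reads identify the genotype, one-hot triples
      for (cand in 0:2) {
        gl[cbind(idx, cand + 1L)] <- as.numeric(g[obs] == cand)
      }
    } else {
      dd <- d[obs]
      a <- rbinom(length(dd), dd, q_ref[g[obs] + 1L]) # reads supporting REF
      for (cand in 0:2) {
        lik <- dbinom(a, dd, q_ref[cand + 1L])
        gl[cbind(idx, cand + 1L)] <- lik
      }
    }
  }
  genotype_likelihoods(individuals = gt$individuals, sites = gt$sites, gl = gl)
}

#' Write a genotype table as a minimal VCF
#'
#' Emits synthetic genotype tables (GT:DP per sample) so the VCF reader and
#' shell pipelines can be exercised; not a general-purpose VCF writer.
#'
#' @param gt A [genotype_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sim_vcf <- function(gt, path) {
  stopifnot(inherits(gt, "genotype_table"))
  chrom_pos <- strsplit(gt$sites, ":", fixed = TRUE)
  chrom <- vapply(chrom_pos, `[`, character(1), 1)
  pos <- vapply(chrom_pos, `[`, character(1), 2)
  ref <- if (!is.null(gt$ref)) gt$ref else rep("A", length(gt$sites))
  alt <- if (!is.null(gt$alt)) gt$alt else rep("G", length(gt$sites))
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", gt$individuals
    ), collapse = "\t")
  )
  body <- vapply(seq_along(gt$sites), function(j) {
    calls <- vapply(seq_along(gt$individuals), function(i) {
      g <- gt$geno[i, j]
      d <- gt$depth[i, j]
      sprintf("%s:%d", if (is.na(g)) "./." else gt_str[g + 1L], d)
    }, character(1))
    paste(c(
      chrom[j], pos[j], ".", ref[j], alt[j], ".", "PASS", ".",
      "GT:DP", calls
    ), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
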