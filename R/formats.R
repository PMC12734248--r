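#' @importFrom stats cov dbinom kmeans prcomp rbeta rbinom rnbinom runif
#'   sd var hclust cutree dist predict setNames
#' @importFrom utils read.table write.table
NULL

#' Controlled vocabulary of sampling regions
#'
#' The six geographic areas used when profiling COI haplotype clusters, plus
#' `"Unknown"` for specimens without a recorded sampling location.
#'
#' @format Character vector of length 7.
#' @export
REGION_VOCABULARY <- c(
  "Africa", "East Asia", "South Asia", "Southeast Asia",
  "Mascarenes", "Pacific", "Unknown"
)

#' Default region-to-origin mapping
#'
#' Maps each sampling region onto a broad origin used for consensus calling.
#' The Mascarene islands are mapped to Asia: although geographically close to
#' Africa, their *B. dorsalis* populations carry a genetic signature aligned
#' with Asian populations, so their reference barcodes are treated as
#' representative of Asian profiles.
#'
#' @format Named character vector (region -> origin).
#' @export
DEFAULT_ORIGIN_MAP <- c(
  "Africa" = "Africa",
  "East Asia" = "Asia",
  "South Asia" = "Asia",
  "Southeast Asia" = "Asia",
  "Mascarenes" = "Asia",
  "Pacific" = "Pacific"
)

## ---------------------------------------------------------------------------
## Domain types
## ---------------------------------------------------------------------------

#' Construct a barcode alignment
#'
#' An aligned set of haploid mitochondrial (COI) sequences with per-specimen
#' region labels. All sequences must have equal length; identifiers must be
#' unique; region labels must come from [REGION_VOCABULARY].
#'
#' @param ids Character vector of unique specimen identifiers.
#' @param seqs Character vector of equal-length sequences over IUPAC
#'   nucleotide codes plus `-` (gap) and `N`. Stored uppercased.
#' @param region Optional character vector of region labels (recycled
#'   `"Unknown"` when `NULL`).
#' @return An object of class `barcode_alignment` with fields `ids`, `seqs`,
#'   `region` and `columns` (alignment width, 1-based column indexing).
#' @export
barcode_alignment <- function(ids, seqs, region = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) {
    stop("ids and seqs must have the same length")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  }
  widths <- nchar(seqs)
  if (length(seqs) > 0 && length(unique(widths)) > 1) {
    off <- which(widths != widths[1])[1]
    stop(sprintf(
      "ragged alignment: record %d ('%s') has length %d, expected %d",
      off, ids[off], widths[off], widths[1]
    ))
  }
  if (is.null(region)) {
    region <- rep("Unknown", length(ids))
  }
  region <- as.character(region)
  bad <- setdiff(unique(region), REGION_VOCABULARY)
  if (length(bad) > 0) {
    stop("region label(s) outside vocabulary: ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      ids = ids, seqs = seqs, region = region,
      columns = if (length(seqs) > 0) widths[1] else 0L
    ),
    class = "barcode_alignment"
  )
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf(
    "barcode_alignment: %d sequences x %d columns\n",
    length(x$ids), x$columns
  ))
  tab <- table(x$region)
  cat("regions:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a diploid genotype table
#'
#' Holds diploid genotype calls coded as the count of the alternate allele
#' (`0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing) together with per-genotype read depth over
#' named sites. A genotype is forced missing wherever depth is 0, so
#' zero-depth cells can never leak into allele-frequency sums.
#'
#' @param individuals Character vector of unique individual ids.
#' @param sites Character vector of unique site ids, conventionally
#'   `"<chrom>:<pos>"` with a 1-based position.
#' @param geno Integer matrix `[n_ind x n_sites]` with entries in
#'   `{0, 1, 2, NA}`.
#' @param depth Non-negative integer matrix of the same shape.
#' @param class_label Optional per-individual label (e.g. `"Africa"`,
#'   `"Asia"`).
#' @param ref,alt Optional per-site reference/alternate bases, stored so that
#'   allele polarity can be checked against other call sets.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, sites, geno, depth,
                           class_label = NULL, ref = NULL, alt = NULL) {
  individuals <- as.character(individuals)
  sites <- as.character(sites)
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  if (anyDuplicated(sites)) stop("duplicate site ids")
  geno <- as.matrix(geno)
  depth <- as.matrix(depth)
  if (!identical(dim(geno), dim(depth))) {
    stop("geno and depth must share shape")
  }
  if (nrow(geno) != length(individuals) || ncol(geno) != length(sites)) {
    stop("geno must be [n_individuals x n_sites]")
  }
  if (any(depth < 0, na.rm = TRUE)) stop("depths must be non-negative")
  ok <- is.na(geno) | geno %in% c(0, 1, 2)
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  geno[depth == 0] <- NA
  dimnames(geno) <- dimnames(depth) <- list(individuals, sites)
  if (!is.null(class_label)) {
    class_label <- as.character(class_label)
    stopifnot(length(class_label) == length(individuals))
    names(class_label) <- individuals
  }
  structure(
    list(
      individuals = individuals, sites = sites,
      geno = geno, depth = depth, class_label = class_label,
      ref = ref, alt = alt
    ),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf(
    "genotype_table: %d individuals x %d sites (%.2f%% missing)\n",
    length(x$individuals), length(x$sites), 100 * mean(is.na(x$geno))
  ))
  invisible(x)
}

#' Construct a genotype-likelihood set
#'
#' Per-individual, per-site likelihood triples over the three diploid
#' genotypes, ordered (hom-ref, het, hom-alt). Triples are renormalized to
#' sum to one on construction, since exported likelihood files are often
#' scaled.
#'
#' @param individuals Character vector of unique individual ids.
#' @param sites Character vector of unique site ids.
#' @param gl Numeric array `[n_ind x n_sites x 3]` of non-negative
#'   likelihoods.
#' @return An object of class `genotype_likelihoods` with normalized triples.
#' @export
genotype_likelihoods <- function(individuals, sites, gl) {
  individuals <- as.character(individuals)
  sites <- as.character(sites)
  if (anyDuplicated(individuals)) stop("duplicate individual ids")
  if (anyDuplicated(sites)) stop("duplicate site ids")
  gl <- as.array(gl)
  if (length(dim(gl)) != 3 || dim(gl)[3] != 3) {
    stop("gl must be an [n_ind x n_sites x 3] array")
  }
  if (dim(gl)[1] != length(individuals) || dim(gl)[2] != length(sites)) {
    stop("gl dimensions must match individuals and sites")
  }
  if (any(!is.finite(gl)) || any(gl < 0)) {
    stop("likelihoods must be finite and non-negative")
  }
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  if (any(tot <= 0)) stop("every likelihood triple must have positive sum")
  for (g in 1:3) gl[, , g] <- gl[, , g] / tot
  dimnames(gl) <- list(individuals, sites, c("hom_ref", "het", "hom_alt"))
  structure(
    list(individuals = individuals, sites = sites, gl = gl),
    class = "genotype_likelihoods"
  )
}

#' @export
print.genotype_likelihoods <- function(x, ...) {
  cat(sprintf(
    "genotype_likelihoods: %d individuals x %d sites\n",
    length(x$individuals), length(x$sites)
  ))
  invisible(x)
}

## ---------------------------------------------------------------------------
## FASTA
## ---------------------------------------------------------------------------

#' Read an aligned FASTA file into a barcode alignment
#'
#' @param path Path to an aligned FASTA file.
#' @param metadata Optional path to a tab-separated metadata table with at
#'   least columns `id` and `region`; ids not present in the table get region
#'   `"Unknown"`.
#' @return A [barcode_alignment()].
#' @details Sequences are uppercased on read. Records of unequal length and
#'   duplicated identifiers are hard errors that name the offending record.
#' @export
read_fasta_alignment <- function(path, metadata = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  region <- NULL
  if (!is.null(metadata)) {
    meta <- read_region_metadata(metadata)
    region <- meta$region[match(ids, meta$id)]
    region[is.na(region)] <- "Unknown"
  }
  barcode_alignment(ids = ids, seqs = seqs, region = region)
}

#' Write a barcode alignment to FASTA
#'
#' @param aln A [barcode_alignment()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "barcode_alignment"))
  ss <- Biostrings::BStringSet(setNames(aln$seqs, aln$ids))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a specimen region-metadata table
#'
#' Tab-separated table with columns `id` and `region` (extra columns such as
#' `country` or `known_origin` are kept but unused).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with at least `id` and `region` columns.
#' @export
read_region_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    quote = "", comment.char = ""
  )
  if (!all(c("id", "region") %in% names(meta))) {
    stop("metadata table must have 'id' and 'region' columns")
  }
  meta$id <- as.character(meta$id)
  meta$region <- as.character(meta$region)
  meta
}

#' Write a region-metadata table
#'
#' @param meta Data.frame with `id` and `region` columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_region_metadata <- function(meta, path) {
  write.table(meta, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

## ---------------------------------------------------------------------------
## VCF
## ---------------------------------------------------------------------------

#' Read diploid genotypes and depths from a VCF file
#'
#' Retains biallelic SNP records only (multiallelic records are dropped with
#' a logged count). Genotypes are coded as alternate-allele counts:
#' `0/0 -> 0`, `0/1` or `1/0` (phased or unphased) `-> 1`, `1/1 -> 2`,
#' `./.` -> missing. Depth is taken from the per-sample `DP` field; where
#' `DP` is absent the sum of the `AD` allele depths is used instead
#' (precedence `DP` over `AD`, logged).
#'
#' @param path Path to a VCF 4.x file (plain text or bgzipped).
#' @return A [genotype_table()] with 1-based `"<chrom>:<pos>"` site ids and
#'   REF/ALT bases stored.
#' @export
read_vcf_genotypes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("unreadable VCF file: ", conditionMessage(e))
  )
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fmt_keys <- unique(unlist(strsplit(v@gt[, "FORMAT"], ":")))
  if (!"GT" %in% fmt_keys) stop("VCF is missing the GT format field")
  alt <- fix[, "ALT"]
  biallelic <- !is.na(alt) & !grepl(",", alt)
  n_drop <- sum(!biallelic)
  if (n_drop > 0) {
    message(sprintf("read_vcf_genotypes: dropped %d multiallelic record(s)", n_drop))
  }
  if (!any(biallelic)) stop("no biallelic records in VCF")
  gt_raw <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  geno <- matrix(NA_integer_, nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  clean <- gsub("\\|", "/", gt_raw)
  geno[clean %in% c("0/0")] <- 0L
  geno[clean %in% c("0/1", "1/0")] <- 1L
  geno[clean %in% c("1/1")] <- 2L
  depth <- NULL
  if ("DP" %in% fmt_keys) {
    dp <- vcfR::extract.gt(v, element = "DP", as.numeric = TRUE)
    depth <- dp[biallelic, , drop = FALSE]
  }
  if (is.null(depth) || all(is.na(depth))) {
    if (!"AD" %in% fmt_keys) {
      stop("VCF has neither per-sample DP nor AD fields")
    }
    message("read_vcf_genotypes: DP absent, using summed AD as depth")
    ad <- vcfR::extract.gt(v, element = "AD")[biallelic, , drop = FALSE]
    depth <- apply(ad, c(1, 2), function(x) {
      if (is.na(x)) return(NA_real_)
      sum(as.numeric(strsplit(x, ",")[[1]]))
    })
  }
  depth[is.na(depth)] <- 0
  sites <- paste0(fix[biallelic, "CHROM"], ":", fix[biallelic, "POS"])
  genotype_table(
    individuals = colnames(gt_raw),
    sites = sites,
    geno = t(geno),
    depth = t(depth),
    ref = setNames(fix[biallelic, "REF"], sites),
    alt = setNames(fix[biallelic, "ALT"], sites)
  )
}

## ---------------------------------------------------------------------------
## Beagle genotype likelihoods
## ---------------------------------------------------------------------------

#' Read a Beagle-format genotype-likelihood file
#'
#' Whitespace-delimited text with a header row; the first three columns are
#' marker name and the two allele codes, followed by three likelihood
#' columns per individual (hom-ref, het, hom-alt). Triples are renormalized
#' to sum to one.
#'
#' @param path Path to the Beagle GL text file (optionally gzipped).
#' @return A [genotype_likelihoods()] whose site ids are the marker names.
#' @export
read_beagle_gl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.table(path, header = TRUE, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 6) stop("Beagle file must have at least 6 columns")
  n_gl_cols <- ncol(tab) - 3
  if (n_gl_cols %% 3 != 0) {
    stop(sprintf(
      "Beagle file has %d likelihood columns, not a multiple of 3", n_gl_cols
    ))
  }
  n_ind <- n_gl_cols / 3
  inds <- colnames(tab)[3 + seq(1, n_gl_cols, by = 3)]
  inds <- make.unique(sub("(\\.[0-9]+)?$", "", inds))
  sites <- as.character(tab[[1]])
  m <- as.matrix(tab[, -(1:3), drop = FALSE])
  storage.mode(m) <- "double"
  gl <- array(NA_real_, dim = c(n_ind, length(sites), 3))
  for (g in 1:3) {
    gl[, , g] <- t(m[, seq(g, n_gl_cols, by = 3), drop = FALSE])
  }
  genotype_likelihoods(individuals = inds, sites = sites, gl = gl)
}

#' Write a genotype-likelihood set in Beagle format
#'
#' @param gl A [genotype_likelihoods()].
#' @param path Output path.
#' @param ref,alt Allele codes written to the `allele1`/`allele2` columns
#'   (defaults `0` and `1`).
#' @return Invisibly, `path`.
#' @export
write_beagle_gl <- function(gl, path, ref = NULL, alt = NULL) {
  stopifnot(inherits(gl, "genotype_likelihoods"))
  n_site <- length(gl$sites)
  if (is.null(ref)) ref <- rep(0L, n_site)
  if (is.null(alt)) alt <- rep(1L, n_site)
  out <- data.frame(marker = gl$sites, allele1 = ref, allele2 = alt)
  for (i in seq_along(gl$individuals)) {
    block <- cbind(gl$gl[i, , 1], gl$gl[i, , 2], gl$gl[i, , 3])
    colnames(block) <- rep(gl$individuals[i], 3)
    out <- cbind(out, block)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Newick
## ---------------------------------------------------------------------------

#' Serialize a phylogenetic tree to newick text
#'
#' @param tree An `ape::phylo` tree with branch lengths and unique leaf
#'   labels.
#' @param path Optional output path; when `NULL` the newick string is
#'   returned.
#' @return The newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    stop(
      "duplicate leaf name(s): ",
      paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", ")
    )
  }
  txt <- ape::write.tree(tree)
  if (is.null(path)) {
    return(txt)
  }
  writeLines(txt, path)
  invisible(txt)
}

#' Read a newick tree
#'
#' @param path Path to a newick file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ape::read.tree(path)
}

## ---------------------------------------------------------------------------
## Model JSON serialization
## ---------------------------------------------------------------------------

FLYTRACE_MODEL_VERSION <- "flytrace-model-1"

#' Save a fitted DAPC model (with optional region profile) as JSON
#'
#' @param model A `dapc_model` from [fit_dapc()].
#' @param path Output path.
#' @param profile Optional `cluster_region_profile` from [region_profile()]
#'   bundled alongside the model so queries can be mapped to origins.
#' @return Invisibly, `path`.
#' @export
save_dapc_model <- function(model, path, profile = NULL) {
  stopifnot(inherits(model, "dapc_model"))
  prof_payload <- NULL
  if (!is.null(profile)) {
    prof_payload <- list(
      clusters = rownames(profile$counts),
      regions = colnames(profile$counts),
      counts = unname(profile$counts),
      normalized = unname(profile$normalized),
      n_known = unname(profile$n_known),
      region_totals = unname(profile$region_totals),
      origin_map = as.list(profile$origin_map),
      dominance_threshold = profile$dominance_threshold,
      minor_floor = profile$minor_floor
    )
  }
  payload <- list(
    version = FLYTRACE_MODEL_VERSION,
    kind = "dapc_model",
    model = unclass(model),
    profile = prof_payload
  )
  jsonlite::write_json(payload, path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  invisible(path)
}

#' Load a DAPC model saved with [save_dapc_model()]
#'
#' @param path Path to the model JSON.
#' @return A list with elements `model` (class `dapc_model`) and `profile`
#'   (class `cluster_region_profile`, or `NULL`).
#' @export
read_dapc_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$version, FLYTRACE_MODEL_VERSION)) {
    stop("unsupported model version: ", payload$version)
  }
  m <- payload$model
  m$center <- as.numeric(m$center)
  m$column_means <- setNames(as.numeric(m$column_means), m$columns)
  m$pc_loadings <- matrix(as.numeric(as.matrix(m$pc_loadings)),
    nrow = length(m$columns)
  )
  m$da_axes <- matrix(as.numeric(as.matrix(m$da_axes)), nrow = m$n_pcs)
  m$centroids <- matrix(as.numeric(as.matrix(m$centroids)), nrow = m$k)
  rownames(m$centroids) <- m$cluster_levels
  names(m$center) <- m$columns
  class(m) <- "dapc_model"
  pp <- payload$profile
  prof <- NULL
  if (!is.null(pp)) {
    dn <- list(pp$clusters, pp$regions)
    prof <- structure(
      list(
        counts = matrix(as.matrix(pp$counts), nrow = length(dn[[1]]),
          dimnames = dn),
        normalized = matrix(as.matrix(pp$normalized),
          nrow = length(dn[[1]]), dimnames = dn),
        n_known = setNames(as.numeric(pp$n_known), dn[[1]]),
        region_totals = setNames(as.numeric(pp$region_totals), dn[[2]]),
        origin_map = unlist(pp$origin_map),
        dominance_threshold = pp$dominance_threshold,
        minor_floor = pp$minor_floor
      ),
      class = "cluster_region_profile"
    )
  }
  list(model = m, profile = prof)
}
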