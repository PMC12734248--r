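## Consensus origin calling: combine the three evidence streams
## (nuclear PCA/NJ tree, diagnostic SNP tree, COI DAPC) per specimen.

#' Combine per-specimen origin calls into a consensus record
#'
#' `NA` calls are ignored; an ambiguous call (`"ambiguous:..."`) forces
#' `consensus = "no"`, even when its candidate set contains the other
#' methods' origin; agreement of all remaining calls yields
#' `consensus = "yes"` with that origin as `final_origin`; disagreement
#' yields `"no"` with `final_origin = "discordant"`; all-`NA` yields
#' `"no"` with `final_origin = NA`.
#'
#' @param pca,snp,coi Origin call of each method for one specimen: an
#'   origin label, an `"ambiguous:<o1>,<o2>"` string, or `NA`.
#' @param specimen Specimen identifier carried into the record.
#' @return A one-row data.frame: `specimen`, `call_pca`, `call_snp`,
#'   `call_coi`, `consensus` (`"yes"`/`"no"`), `final_origin`.
#' @export
combine_calls <- function(pca, snp, coi, specimen = NA_character_) {
  calls <- c(pca, snp, coi)
  present <- calls[!is.na(calls)]
  ambiguous <- grepl("^ambiguous:", present)
  if (length(present) == 0) {
    consensus <- "no"
    final <- NA_character_
  } else if (any(ambiguous)) {
    consensus <- "no"
    final <- NA_character_
  } else if (length(unique(present)) == 1) {
    consensus <- "yes"
    final <- present[1]
  } else {
    consensus <- "no"
    final <- "discordant"
  }
  data.frame(
    specimen = specimen, call_pca = pca, call_snp = snp, call_coi = coi,
    consensus = consensus, final_origin = final,
    stringsAsFactors = FALSE
  )
}

#' Combine a table of per-method origin calls
#'
#' @param calls Data.frame with columns `specimen`, `origin_pca`,
#'   `origin_snp`, `origin_coi`.
#' @return A data.frame of [combine_calls()] records, one per row.
#' @export
combine_call_table <- function(calls) {
  stopifnot(all(c("specimen", "origin_pca", "origin_snp", "origin_coi")
  %in% names(calls)))
  do.call(rbind, lapply(seq_len(nrow(calls)), function(i) {
    combine_calls(
      calls$origin_pca[i], calls$origin_snp[i], calls$origin_coi[i],
      specimen = calls$specimen[i]
    )
  }))
}

#' Count origin-call records matching filter predicates
#'
#' Deterministic, permutation-invariant counting over a long-format call
#' table. Every supplied filter must match; `origin = NA` (or the string
#' `"NA"`) matches records whose origin is missing.
#'
#' @param calls Data.frame with columns `id`, `method`, `origin` and
#'   optionally `cluster`.
#' @param method Filter on the method column.
#' @param origin Filter on the origin column (`NA` matches missing).
#' @param prefix Filter on a specimen-id prefix (e.g. `"Bd_"`).
#' @param cluster Filter on the COI cluster column.
#' @return Integer count.
#' @export
tally <- function(calls, method = NULL, origin = NULL, prefix = NULL,
                  cluster = NULL) {
  keep <- rep(TRUE, nrow(calls))
  if (!is.null(method)) keep <- keep & calls$method == method
  if (!is.null(origin)) {
    if (is.na(origin) || identical(origin, "NA")) {
      keep <- keep & is.na(calls$origin)
    } else {
      keep <- keep & !is.na(calls$origin) & calls$origin == origin
    }
  }
  if (!is.null(prefix)) keep <- keep & startsWith(calls$id, prefix)
  if (!is.null(cluster)) {
    keep <- keep & !is.na(calls$cluster) & calls$cluster == as.character(cluster)
  }
  sum(keep)
}

#' Load the shipped Belgian interception call table
#'
#' The transcribed per-method origin calls for the 22 *B. dorsalis*
#' specimens trapped in Belgian surveillance traps or intercepted in
#' imported fruit during 2023-2024: nuclear PCA/NJ-tree origin, two-SNP
#' decision-tree origin with its probability, COI DAPC haplotype cluster
#' with posterior and derived origin, and the printed consensus.
#'
#' @param path Path to the TSV (defaults to the copy shipped with the
#'   package).
#' @return A data.frame with columns `specimen`, `pca_origin`,
#'   `snp_origin`, `snp_prob`, `coi_cluster`, `coi_posterior`,
#'   `coi_origin`, `consensus`.
#' @export
read_interception_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "belgium_interceptions.tsv",
      package = "flytrace"
    )
  }
  tab <- read.table(path,
    header = TRUE, sep = "\t", stringsAsFactors = FALSE,
    na.strings = "NA", quote = "", comment.char = ""
  )
  tab$coi_cluster <- as.character(tab$coi_cluster)
  tab
}

# "Africa or South Asia" -> "ambiguous:Africa,Asia" (regions mapped to
# origins, order preserved, duplicates removed)
parse_printed_origin <- function(x, origin_map = DEFAULT_ORIGIN_MAP) {
  vapply(x, function(s) {
    if (is.na(s)) {
      return(NA_character_)
    }
    parts <- strsplit(s, " or ", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      return(s)
    }
    mapped <- ifelse(parts %in% names(origin_map), origin_map[parts], parts)
    paste0("ambiguous:", paste(unique(mapped), collapse = ","))
  }, character(1), USE.NAMES = FALSE)
}

#' Long-format per-method calls from an interception table
#'
#' Expands the wide table from [read_interception_table()] into one record
#' per specimen and method, parsing printed multi-region origins (e.g.
#' `"Africa or South Asia"`) into `"ambiguous:..."` calls.
#'
#' @param tab A data.frame as returned by [read_interception_table()].
#' @return A data.frame with columns `id`, `method`, `origin`, `cluster`,
#'   `posterior`.
#' @export
interception_calls <- function(tab) {
  rbind(
    data.frame(
      id = tab$specimen, method = "PCA/NJT", origin = tab$pca_origin,
      cluster = NA_character_, posterior = NA_real_,
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = tab$specimen, method = "SNPs", origin = tab$snp_origin,
      cluster = NA_character_, posterior = tab$snp_prob,
      stringsAsFactors = FALSE
    ),
    data.frame(
      id = tab$specimen, method = "COI-DAPC",
      origin = parse_printed_origin(tab$coi_origin),
      cluster = tab$coi_cluster, posterior = tab$coi_posterior,
      stringsAsFactors = FALSE
    )
  )
}
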