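#' Read-ratio genotype-calling thresholds
#'
#' The caller scores a genotype only when the total read count reaches
#' `min_total_depth` (8 reads). The log10 ratio of allele-A to allele-B
#' reads then separates the classes: heterozygote if the ratio lies in
#' `[-het_band, het_band]` (`0.61`, one SD around the mean of the
#' empirical het-ratio distribution, treated here as a fixed constant),
#' AA homozygote if the ratio exceeds `hom_cut` (`0.9`), BB if below
#' `-hom_cut`. Ratios in the gap `(het_band, hom_cut]` (either sign) are
#' removed — recorded as missing with reason `ambiguous_ratio`.
#'
#' @param min_total_depth minimum total reads to call.
#' @param het_band half-width of the symmetric heterozygote band.
#' @param hom_cut homozygote cutoff (must exceed `het_band`).
#' @return list of class `genotype_thresholds`.
#' @export
genotype_thresholds <- function(min_total_depth = 8L, het_band = 0.61,
                                hom_cut = 0.9) {
  stopifnot(min_total_depth >= 1, het_band > 0, hom_cut > het_band)
  structure(list(min_total_depth = as.integer(min_total_depth),
                 het_band = het_band, hom_cut = hom_cut),
            class = "genotype_thresholds")
}

#' Call genotypes from per-allele read counts
#'
#' Vectorised over paired counts. `count_b = 0` maps the ratio to +Inf
#' (AA) and `count_a = 0` to -Inf (BB) — no pseudocount, so e.g. (8, 0)
#' is a confident AA.
#'
#' @param count_a,count_b non-negative read counts supporting alleles A
#'   and B.
#' @param thresholds a [genotype_thresholds()].
#' @return data.frame with `state` in `AA/AB/BB` or `NA`, and `reason`
#'   in `called/low_depth/ambiguous_ratio`.
#' @export
call_genotype <- function(count_a, count_b,
                          thresholds = genotype_thresholds()) {
  if (any(count_a < 0 | count_b < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  total <- count_a + count_b
  r <- log10(count_a / count_b)  # 0/0 -> NaN, x/0 -> Inf, 0/x -> -Inf
  state <- rep(NA_character_, length(total))
  reason <- rep("ambiguous_ratio", length(total))
  low <- total < thresholds$min_total_depth
  reason[low] <- "low_depth"
  ok <- !low
  ab <- ok & !is.nan(r) & r >= -thresholds$het_band & r <= thresholds$het_band
  aa <- ok & !is.nan(r) & r > thresholds$hom_cut
  bb <- ok & !is.nan(r) & r < -thresholds$hom_cut
  state[ab] <- "AB"; state[aa] <- "AA"; state[bb] <- "BB"
  reason[ab | aa | bb] <- "called"
  data.frame(state = state, reason = reason, stringsAsFactors = FALSE)
}

#' Call a whole read-count matrix and attach sample metadata
#'
#' @param counts a `read_counts` object (see [simulate_read_counts()])
#'   or a list with `count_a`, `count_b` matrices and `meta`.
#' @param thresholds a [genotype_thresholds()].
#' @param meta individual metadata (individual, population, phenotype,
#'   doubled_haploid); defaults to `counts$meta`. Every column of the
#'   count matrices must appear in it.
#' @return object of class `genotype_matrix`: list with `calls`
#'   (character matrix loci x individuals, `NA` = missing), `reason`
#'   (matrix of call reasons), `meta`, and `truth` when available.
#' @export
call_matrix <- function(counts, thresholds = genotype_thresholds(),
                        meta = counts$meta) {
  ca <- counts$count_a; cb <- counts$count_b
  stopifnot(identical(dim(ca), dim(cb)))
  if (is.null(meta)) stop("individual metadata required")
  missing_meta <- setdiff(colnames(ca), meta$individual)
  if (length(missing_meta))
    stop("individuals absent from metadata: ",
         paste(missing_meta, collapse = ", "))
  gc <- call_genotype(as.vector(ca), as.vector(cb), thresholds)
  calls <- matrix(gc$state, nrow(ca), ncol(ca), dimnames = dimnames(ca))
  reason <- matrix(gc$reason, nrow(ca), ncol(ca), dimnames = dimnames(ca))
  structure(list(calls = calls, reason = reason,
                 meta = meta[match(colnames(ca), meta$individual), ,
                             drop = FALSE],
                 truth = counts$truth),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d loci x %d individuals (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

# subset a genotype_matrix by locus ids (or logical/integer index)
subset_loci <- function(gm, loci) {
  if (is.character(loci)) loci <- match(loci, rownames(gm$calls))
  gm$calls <- gm$calls[loci, , drop = FALSE]
  gm$reason <- gm$reason[loci, , drop = FALSE]
  if (!is.null(gm$truth))
    gm$truth <- gm$truth[match(rownames(gm$calls), gm$truth$locus), ,
                         drop = FALSE]
  gm
}

# integer allele-A dosage matrix (0/1/2, NA for missing)
dosage <- function(gm) {
  d <- matrix(NA_integer_, nrow(gm$calls), ncol(gm$calls),
              dimnames = dimnames(gm$calls))
  d[gm$calls == "AA"] <- 2L
  d[gm$calls == "AB"] <- 1L
  d[gm$calls == "BB"] <- 0L
  d
}
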