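#' Write/read a genotype matrix as TSV with a metadata sidecar
#'
#' The genotype table has a header row (`locus` then individual ids) and
#' cells in `{AA, AB, BB, NA}`; the sidecar carries `individual`,
#' `population`, `phenotype`, `doubled_haploid`. A written matrix reads
#' back identically.
#'
#' @param gm a `genotype_matrix`.
#' @param path genotype TSV path.
#' @param meta_path metadata TSV path (default `<path>.meta.tsv`).
#' @export
write_genotype_table <- function(gm, path,
                                 meta_path = paste0(path, ".meta.tsv")) {
  df <- data.frame(locus = rownames(gm$calls), gm$calls,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(gm$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotype_table
#' @return `read_genotype_table` returns a `genotype_matrix` (call
#'   reasons are reconstructed as `called`/`low_depth`-agnostic
#'   `missing`).
#' @export
read_genotype_table <- function(path, meta_path = paste0(path, ".meta.tsv")) {
  if (!file.size(path) > 0) stop("empty_input: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = "NA")
  if (!nrow(df)) stop("empty_input: no loci in ", path)
  if (names(df)[1] != "locus") stop("first column must be 'locus'")
  if (anyDuplicated(df$locus)) {
    dup <- df$locus[duplicated(df$locus)][1]
    stop(sprintf("duplicate locus id '%s' (line %d)", dup,
                 which(df$locus == dup)[2] + 1))
  }
  calls <- as.matrix(df[, -1, drop = FALSE])
  rownames(calls) <- df$locus
  bad <- !is.na(calls) & !(calls %in% c("AA", "AB", "BB"))
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("unknown genotype symbol '%s' at line %d, column '%s'",
                 calls[w[1], w[2]], w[1] + 1, colnames(calls)[w[2]]))
  }
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  missing_meta <- setdiff(colnames(calls), meta$individual)
  if (length(missing_meta))
    stop("metadata mismatch: no rows for ",
         paste(missing_meta, collapse = ", "))
  reason <- matrix(ifelse(is.na(calls), "missing", "called"),
                   nrow(calls), ncol(calls), dimnames = dimnames(calls))
  structure(list(calls = calls, reason = reason,
                 meta = meta[match(colnames(calls), meta$individual), ,
                             drop = FALSE]),
            class = "genotype_matrix")
}

#' Write a minimal VCF (GT only) from a genotype matrix
#'
#' Mapped loci get `CHROM`/`POS` from the linkage map, with POS the cM
#' position times 1e4 rounded to an integer (documented convention;
#' genetic maps have no base-pair coordinate); unmapped loci get
#' `CHROM = "unplaced"` and POS from their rank. AA is written `0/0`,
#' AB `0/1`, BB `1/1`, missing `./.`.
#'
#' @param gm a `genotype_matrix`.
#' @param path output path.
#' @param map optional linkage map (`locus`, `chromosome`,
#'   `position_cm`).
#' @export
write_vcf <- function(gm, path, map = NULL) {
  loci <- rownames(gm$calls)
  chrom <- rep("unplaced", length(loci))
  pos <- seq_along(loci)
  if (!is.null(map)) {
    m <- match(loci, map$locus)
    hit <- !is.na(m)
    chrom[hit] <- map$chromosome[m[hit]]
    pos[hit] <- as.integer(round(map$position_cm[m[hit]] * 1e4))
  }
  gt <- gm$calls
  gt[is.na(gt)] <- "./."
  gt[gt == "AA"] <- "0/0"; gt[gt == "AB"] <- "0/1"; gt[gt == "BB"] <- "1/1"
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radpopgen",
    "##INFO=<ID=.,Number=0,Type=Flag,Description=\"none\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(gm$calls)), collapse = "\t"))
  body <- paste(chrom, pos, loci, "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Generic TSV writers for pipeline tables
#'
#' @param df a data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Read a YAML run configuration
#'
#' Sections `sim`, `filter`, `outlier`, `window`, `smooth` override the
#' corresponding config defaults; absent keys keep their defaults.
#'
#' @param path YAML file.
#' @return list with fully-populated config objects plus `seed`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  build <- function(fun, section) do.call(fun, as.list(section %||% list()))
  list(sim = build(sim_config, y$sim),
       filter = build(filter_config, y$filter),
       outlier = build(outlier_config, y$outlier),
       window = build(window_config, y$window),
       smooth = build(smooth_config, y$smooth),
       seed = y$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
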