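#' Stack identical 89-bp reads and apply depth bounds
#'
#' De novo RAD locus construction starts from "stacks": groups of
#' byte-identical reads. Stacks with fewer than `min_depth` reads or more
#' than `max_depth` reads are discarded (repetitive sequence / sequencing
#' error guard); the bounds are inclusive on retention, so depths in
#' `[min_depth, max_depth]` survive.
#'
#' @param reads data.frame with columns `individual`, `sequence`
#'   (fixed-length reads; default 89 bp).
#' @param min_depth,max_depth retention bounds on stack depth.
#' @param tag_length required read length; a read of any other length is
#'   an input error naming the offending record.
#' @return data.frame: `sequence`, `depth`, `individuals` (list column of
#'   the distinct member individuals).
#' @export
stack_reads <- function(reads, min_depth = 5L, max_depth = 200L,
                        tag_length = 89L) {
  stopifnot(is.data.frame(reads), all(c("individual", "sequence") %in%
                                        names(reads)))
  len <- nchar(reads$sequence)
  if (any(len != tag_length)) {
    bad <- which(len != tag_length)[1]
    stop(sprintf("read %d has length %d, expected %d", bad, len[bad],
                 tag_length))
  }
  depth <- table(reads$sequence)
  keep <- depth >= min_depth & depth <= max_depth
  seqs <- names(depth)[keep]
  members <- split(reads$individual, reads$sequence)[seqs]
  data.frame(
    sequence = seqs,
    depth = as.integer(depth[keep]),
    individuals = I(lapply(members, unique)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) sum(utf8ToInt(a) != utf8ToInt(b))

# positions (1-based) at which two equal-length strings differ
mismatch_positions <- function(a, b) which(utf8ToInt(a) != utf8ToInt(b))

# candidate near-duplicate pairs among sequences, Hamming distance in
# [1, max_mismatch]. Pigeonhole bucketing: split each tag into
# max_mismatch + 1 chunks; any pair within distance max_mismatch shares
# at least one chunk exactly.
near_pairs <- function(seqs, max_mismatch = 3L) {
  n <- length(seqs)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  L <- nchar(seqs[1])
  k <- max_mismatch + 1L
  cuts <- floor(seq(0, L, length.out = k + 1))
  cand <- vector("list", k)
  for (ci in seq_len(k)) {
    key <- substr(seqs, cuts[ci] + 1, cuts[ci + 1])
    grp <- split(seq_len(n), key)
    grp <- grp[lengths(grp) > 1]
    cand[[ci]] <- do.call(rbind, lapply(grp, function(ix)
      t(utils::combn(ix, 2))))
  }
  pairs <- unique(do.call(rbind, cand))
  if (is.null(pairs) || nrow(pairs) == 0)
    return(matrix(integer(0), ncol = 2))
  d <- mapply(function(i, j) hamming(seqs[i], seqs[j]),
              pairs[, 1], pairs[, 2])
  pairs[d >= 1 & d <= max_mismatch, , drop = FALSE]
}

# minimal union-find for connected components
uf_components <- function(n, pairs) {
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (nrow(pairs)) for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Pair allele stacks into candidate biallelic SNP loci
#'
#' Stacks differing at 1-3 positions (exact Hamming matching, no indels)
#' are candidate allele pairs of one locus. Connected groups of stacks
#' whose variable positions show more than two distinct bases are
#' discarded (biallelic-only rule). Within a group, pairing is greedy by
#' depth: each unpaired stack takes its highest-depth pairable partner,
#' ties broken toward the lexicographically smaller sequence. Both
#' alleles of an emitted locus must have depth >= `min_allele_depth`.
#'
#' @param stacks output of [stack_reads()].
#' @param max_mismatch maximum SNPs per tag (default 3).
#' @param min_allele_depth minimum per-allele stack depth (default 5).
#' @return data.frame: `allele_a`, `allele_b` (allele_a lexicographically
#'   smaller), `offsets` (comma-separated 1-based SNP positions),
#'   `n_snps`, `depth_a`, `depth_b`.
#' @export
pair_alleles <- function(stacks, max_mismatch = 3L, min_allele_depth = 5L) {
  n <- nrow(stacks)
  empty <- data.frame(allele_a = character(0), allele_b = character(0),
                      offsets = character(0), n_snps = integer(0),
                      depth_a = integer(0), depth_b = integer(0),
                      stringsAsFactors = FALSE)
  if (n < 2) return(empty)
  pairs <- near_pairs(stacks$sequence, max_mismatch)
  if (nrow(pairs) == 0) return(empty)
  comp <- uf_components(n, pairs)
  out <- list()
  for (cid in unique(comp[pairs[, 1]])) {
    ix <- which(comp == cid)
    if (length(ix) < 2) next
    seqs <- stacks$sequence[ix]
    # biallelic check: any variable position with >2 distinct bases kills
    # the whole group
    mat <- do.call(rbind, lapply(seqs, function(s) utf8ToInt(s)))
    nall <- apply(mat, 2, function(col) length(unique(col)))
    if (any(nall > 2)) next
    # greedy pairing by depth within the group
    sub_pairs <- pairs[comp[pairs[, 1]] == cid, , drop = FALSE]
    depth <- stacks$depth[ix]
    local <- match(seq_len(n), ix)  # global index -> local
    adj <- lapply(seq_along(ix), function(li) {
      hits <- c(local[sub_pairs[sub_pairs[, 1] == ix[li], 2]],
                local[sub_pairs[sub_pairs[, 2] == ix[li], 1]])
      hits[!is.na(hits)]
    })
    ord <- order(-depth, seqs)
    paired <- rep(FALSE, length(ix))
    for (li in ord) {
      if (paired[li]) next
      partners <- adj[[li]]
      partners <- partners[!paired[partners]]
      if (!length(partners)) next
      po <- partners[order(-depth[partners], seqs[partners])]
      pj <- po[1]
      paired[c(li, pj)] <- TRUE
      da <- depth[li]; db <- depth[pj]
      sa <- seqs[li]; sb <- seqs[pj]
      if (da < min_allele_depth || db < min_allele_depth) next
      if (sa > sb) { tmp <- sa; sa <- sb; sb <- tmp; tmp <- da; da <- db; db <- tmp }
      pos <- mismatch_positions(sa, sb)
      out[[length(out) + 1]] <- data.frame(
        allele_a = sa, allele_b = sb,
        offsets = paste(pos, collapse = ","),
        n_snps = length(pos), depth_a = da, depth_b = db,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

#' Build a merged SNP database from several individual subsets
#'
#' Discovery is run separately on each subset of individuals (by default
#' three comparisons: everyone, population 1 only, population 2 only) so
#' that loci variable only within one population are still found; the
#' per-subset candidate lists are unioned with redundant loci (identical
#' allele-sequence pairs) removed. Locus ids are stable: assigned in
#' lexicographic order of the sorted allele pair, independent of subset
#' processing order.
#'
#' @param reads data.frame of reads (`individual`, `sequence`).
#' @param subsets named list of individual-id vectors; each must be
#'   non-empty.
#' @param max_mismatch,min_allele_depth passed to [pair_alleles()].
#' @param min_depth,max_depth passed to [stack_reads()].
#' @return data.frame: `locus`, `allele_a`, `allele_b`, `offsets`,
#'   `n_snps`, `depth_a`, `depth_b`, `found_in` (comma-separated subset
#'   names).
#' @export
build_snp_database <- function(reads, subsets, max_mismatch = 3L,
                               min_allele_depth = 5L, min_depth = 5L,
                               max_depth = 200L) {
  stopifnot(is.list(subsets), length(subsets) >= 1)
  if (any(lengths(subsets) == 0)) stop("empty individual subset")
  if (is.null(names(subsets)))
    names(subsets) <- paste0("subset", seq_along(subsets))
  found <- list()
  for (nm in names(subsets)) {
    sub <- reads[reads$individual %in% subsets[[nm]], , drop = FALSE]
    st <- stack_reads(sub, min_depth = min_depth, max_depth = max_depth)
    cand <- pair_alleles(st, max_mismatch = max_mismatch,
                         min_allele_depth = min_allele_depth)
    if (nrow(cand)) {
      cand$found_in <- nm
      found[[nm]] <- cand
    }
  }
  if (!length(found)) {
    return(data.frame(locus = character(0), allele_a = character(0),
                      allele_b = character(0), offsets = character(0),
                      n_snps = integer(0), depth_a = integer(0),
                      depth_b = integer(0), found_in = character(0),
                      stringsAsFactors = FALSE))
  }
  all <- do.call(rbind, found)
  key <- paste(all$allele_a, all$allele_b)
  first <- !duplicated(key)
  db <- all[first, , drop = FALSE]
  db$found_in <- vapply(key[first], function(k)
    paste(unique(all$found_in[key == k]), collapse = ","), character(1))
  db <- db[order(db$allele_a, db$allele_b), , drop = FALSE]
  db <- cbind(locus = sprintf("TAG%05d", seq_len(nrow(db))), db)
  rownames(db) <- NULL
  db
}

#' Count reads supporting each allele of each database locus
#'
#' Exact-match genotyping of reads against a SNP database: each read
#' identical to a locus's allele-A (allele-B) sequence increments that
#' individual's A (B) count.
#'
#' @param reads data.frame of reads (`individual`, `sequence`).
#' @param db a [build_snp_database()] result.
#' @param individuals column order of the output; defaults to the
#'   individuals present in `reads`.
#' @return list(count_a, count_b): integer matrices, loci x individuals.
#' @export
count_alleles <- function(reads, db, individuals = NULL) {
  if (is.null(individuals)) individuals <- sort(unique(reads$individual))
  nl <- nrow(db)
  count_a <- matrix(0L, nl, length(individuals),
                    dimnames = list(db$locus, individuals))
  count_b <- count_a
  ia <- match(reads$sequence, db$allele_a)
  ib <- match(reads$sequence, db$allele_b)
  ci <- match(reads$individual, individuals)
  ta <- table(factor(ia[!is.na(ia)], levels = seq_len(nl)),
              factor(ci[!is.na(ia)], levels = seq_along(individuals)))
  tb <- table(factor(ib[!is.na(ib)], levels = seq_len(nl)),
              factor(ci[!is.na(ib)], levels = seq_along(individuals)))
  count_a[] <- as.integer(ta)
  count_b[] <- as.integer(tb)
  list(count_a = count_a, count_b = count_b)
}

#' Tag-multiplicity summary of a SNP database
#'
#' Tabulates how many tags carry 1, 2, 3... SNPs and the implied total
#' SNP count (each tag contributes its SNP multiplicity).
#'
#' @param db a [build_snp_database()] result.
#' @return list: `tags_by_snps` (named integer vector), `n_tags`,
#'   `n_snps`.
#' @export
summarize_database <- function(db) {
  tab <- table(db$n_snps)
  list(tags_by_snps = stats::setNames(as.integer(tab), names(tab)),
       n_tags = nrow(db),
       n_snps = snp_count_from_multiplicities(
         stats::setNames(as.integer(tab), names(tab))))
}

#' Total SNP count implied by a tag-multiplicity table
#'
#' @param tags_by_snps named vector: names are SNPs-per-tag, values are
#'   tag counts (e.g. `c("1" = 22590, "2" = 2796, "3" = 820)`).
#' @return the implied total number of SNPs.
#' @export
snp_count_from_multiplicities <- function(tags_by_snps) {
  k <- as.integer(names(tags_by_snps))
  if (any(is.na(k))) stop("names must be SNPs-per-tag integers")
  sum(k * as.numeric(tags_by_snps))
}
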