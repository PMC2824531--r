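#' Reciprocal best hits between two genomes
#'
#' A pair `(a, b)` is kept iff `a`'s best hit over genome B is `b` and
#' `b`'s best hit over genome A is `a`, under the deterministic best-hit
#' tie rule. Queries are resolved in lexicographic id order; because the
#' best hit is single-valued the result is one-to-one.
#'
#' @param hits_ab,hits_ba directed hit tables for (A -> B) and (B -> A)
#'   under one cutoff.
#' @param ids_a,ids_b optional full cds-id universes of the two genomes;
#'   when given, hit tables referencing other ids are an error.
#' @return data.frame with columns `cds_a`, `cds_b`.
#' @export
reciprocal_best_hits <- function(hits_ab, hits_ba, ids_a = NULL,
                                 ids_b = NULL) {
  if (!is.null(ids_a)) {
    bad <- setdiff(unique(c(hits_ab$qseqid, hits_ba$sseqid)), ids_a)
    if (length(bad)) stop("hit table references unknown genome-A id(s): ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(ids_b)) {
    bad <- setdiff(unique(c(hits_ab$sseqid, hits_ba$qseqid)), ids_b)
    if (length(bad)) stop("hit table references unknown genome-B id(s): ",
                          paste(utils::head(bad, 5), collapse = ", "))
  }
  fwd <- best_hits_per_query(hits_ab)
  bwd <- best_hits_per_query(hits_ba)
  qa <- sort(names(fwd))
  used_b <- character(0)
  keep_a <- character(0); keep_b <- character(0)
  for (a in qa) {
    b <- fwd[[a]]
    if (b %in% used_b) next
    back <- if (b %in% names(bwd)) bwd[[b]] else NA_character_
    if (identical(back, a)) {
      keep_a <- c(keep_a, a); keep_b <- c(keep_b, b)
      used_b <- c(used_b, b)
    }
  }
  data.frame(cds_a = keep_a, cds_b = keep_b, stringsAsFactors = FALSE)
}

#' One-way presence/absence of query CDS in a target genome
#'
#' A CDS of genome A is present in genome B iff it has at least one hit
#' with `E <= cutoff` (one-way, not reciprocal); a CDS with no qualifying
#' hit is considered absent in the target genome.
#'
#' @param hits_ab directed hit table A -> B.
#' @param query_ids cds ids of genome A.
#' @param cutoff E-value cutoff (default `1e-20`).
#' @return named logical vector over `query_ids`.
#' @export
presence_absence <- function(hits_ab, query_ids, cutoff = 1e-20) {
  present <- unique(hits_ab$qseqid[hits_ab$evalue <= cutoff])
  setNames(query_ids %in% present, query_ids)
}

hit_key <- function(a, b) paste0(a, "->", b)

#' Conservation count matrix
#'
#' Cell (target genome T, query genome Q) counts the CDS of Q present in T
#' by the one-way presence rule; percentages are relative to Q's total CDS,
#' one decimal. The diagonal is each genome's total CDS (100%).
#'
#' @param collection a [genome_collection()].
#' @param hits named list of directed hit tables, keyed `"Q->T"`.
#' @param queries,targets genome ids (default: all genomes with hits both
#'   ways available).
#' @param cutoff E-value cutoff.
#' @return list with integer matrix `counts`, numeric matrix `percent`
#'   (rows = targets, cols = queries) and a formatted character matrix
#'   `pretty` (`"3589 (83.9)"` style).
#' @export
conservation_table <- function(collection, hits, queries, targets,
                               cutoff = 1e-20) {
  counts <- matrix(NA_integer_, length(targets), length(queries),
                   dimnames = list(targets, queries))
  pct <- matrix(NA_real_, length(targets), length(queries),
                dimnames = list(targets, queries))
  for (q in queries) {
    qids <- collection$cds$cds_id[collection$cds$genome_id == q]
    for (t in targets) {
      if (t == q) {
        counts[t, q] <- length(qids); pct[t, q] <- 100
        next
      }
      key <- hit_key(q, t)
      if (is.null(hits[[key]]))
        stop("missing hit table ", key)
      pa <- presence_absence(hits[[key]], qids, cutoff)
      counts[t, q] <- sum(pa)
      pct[t, q] <- round(100 * sum(pa) / length(qids), 1)
    }
  }
  pretty <- matrix(sprintf("%d (%.1f)", counts, pct), nrow(counts),
                   dimnames = dimnames(counts))
  list(counts = counts, percent = pct, pretty = pretty)
}

#' Conservation percentage at printed precision
#' @param count CDS conserved in the target.
#' @param total total CDS of the query genome.
#' @export
conservation_percent <- function(count, total) round(100 * count / total, 1)

#' Core CDS set of the focal genome
#'
#' CDS of the focal genome having a reciprocal-best-hit partner in every
#' other genome of the outermost hierarchy level.
#'
#' @param collection a [genome_collection()].
#' @param rbh named list of RBH pair frames (names = other genome ids,
#'   `cds_a` = focal side).
#' @export
core_set <- function(collection, rbh) {
  others <- setdiff(collection$hierarchy[[1]], collection$focal)
  miss <- setdiff(others, names(rbh))
  if (length(miss))
    stop("missing RBH table(s) for: ", paste(miss, collapse = ", "))
  Reduce(intersect, lapply(rbh[others], function(p) p$cds_a))
}

default_level_names <- function(hierarchy) {
  nm <- names(hierarchy)
  auto <- c("CDS_c",
            if (length(hierarchy) > 1)
              paste0("CDS_", lengths(hierarchy)[-1]))
  if (is.null(nm)) return(auto)
  ifelse(nzchar(nm), nm, auto)
}

#' Nested CDS partition of the focal genome
#'
#' Sequential-deduction labelling over the collection's nested hierarchy:
#' the outermost level (the core, `CDS_c`) takes every focal CDS with an
#' RBH partner in all other genomes of that level; each inner level takes
#' the CDS with partners in all of its genomes minus everything already
#' labelled; the leftover is the strain-specific `CDS_1`.
#'
#' @param collection a [genome_collection()].
#' @param rbh named list of RBH pair frames keyed by partner genome id.
#' @return object of class `partition_table`: named per-CDS `labels`,
#'   per-label `counts`, level names, focal genome id and total CDS.
#' @export
nested_partition <- function(collection, rbh) {
  focal <- collection$focal
  ids <- collection$cds$cds_id[collection$cds$genome_id == focal]
  lev_names <- default_level_names(collection$hierarchy)
  labels <- setNames(rep(NA_character_, length(ids)), ids)
  for (k in seq_along(collection$hierarchy)) {
    others <- setdiff(collection$hierarchy[[k]], focal)
    miss <- setdiff(others, names(rbh))
    if (length(miss))
      stop("missing RBH table(s) for: ", paste(miss, collapse = ", "))
    shared <- Reduce(intersect, lapply(rbh[others], function(p) p$cds_a))
    take <- intersect(shared, ids[is.na(labels)])
    labels[take] <- lev_names[k]
  }
  labels[is.na(labels)] <- "CDS_1"
  all_levels <- c(lev_names, "CDS_1")
  counts <- table(factor(labels, levels = all_levels))
  structure(list(labels = labels,
                 counts = setNames(as.integer(counts), all_levels),
                 levels = all_levels, focal = focal,
                 total_cds = length(ids)),
            class = "partition_table")
}

#' @export
print.partition_table <- function(x, ...) {
  cat("CDS partition of", x$focal, "(", x$total_cds, "CDS )\n")
  for (l in x$levels) cat(sprintf("  %-8s %d\n", l, x$counts[[l]]))
  invisible(x)
}

#' Partition summary frame
#'
#' Mirrors the conventional per-genome accounting: total CDS, core size,
#' total non-core, and the per-level sizes.
#'
#' @param partition a `partition_table`.
#' @export
partition_summary <- function(partition) {
  core <- partition$counts[[partition$levels[1]]]
  data.frame(
    row = c("total_CDS", partition$levels[1], "total_CDS_nc",
            partition$levels[-1]),
    count = c(partition$total_cds, core, partition$total_cds - core,
              unname(partition$counts[partition$levels[-1]])),
    stringsAsFactors = FALSE)
}

#' Nested-set arithmetic from shared-ortholog counts
#'
#' Applies the sequential-deduction identities to pre-computed counts: given
#' a genome's total CDS and the cumulative common-first-hit counts at each
#' hierarchy level (outermost first, e.g. shared among all strains, shared
#' among the clade, shared with the closest partner), returns the core size,
#' the non-core total, the per-level deducted sizes and the strain-specific
#' remainder.
#'
#' @param total_cds total CDS of the genome.
#' @param shared_counts numeric vector of cumulative shared counts,
#'   outermost level first; must be non-decreasing and `<= total_cds`.
#' @export
partition_arithmetic <- function(total_cds, shared_counts) {
  if (any(diff(shared_counts) < 0))
    stop("cumulative shared counts must be non-decreasing inward")
  if (any(shared_counts > total_cds))
    stop("shared counts exceed total CDS")
  core <- shared_counts[[1]]
  levels <- diff(shared_counts)
  list(core = core,
       nc = total_cds - core,
       level_sizes = unname(levels),
       remainder = total_cds - shared_counts[[length(shared_counts)]])
}

#' Write a per-CDS partition file
#' @param partition a `partition_table`.
#' @param path output path.
#' @export
write_partition <- function(partition, path) {
  utils::write.table(
    data.frame(cds_id = names(partition$labels),
               label = unname(partition$labels)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
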