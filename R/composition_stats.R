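#' Average amino-acid composition (ACAA)
#'
#' Pooled residue counts over all proteins (percent of total counted
#' residues), not a mean of per-protein percentages. `X` and any other
#' non-canonical symbol (`B`, `Z`, `U`, stop) are excluded from both
#' numerator and denominator.
#'
#' @param proteins character vector of amino-acid sequences.
#' @return named numeric vector over the 20 canonical residues summing to
#'   100, with attribute `counted` (total residues counted).
#' @export
aa_composition <- function(proteins) {
  res <- strsplit(paste(proteins, collapse = ""), "")[[1]]
  counts <- table(factor(res, levels = AA_ALPHABET))
  total <- sum(counts)
  if (total == 0L) stop("no canonical amino-acid residues to count")
  out <- setNames(100 * as.numeric(counts) / total, AA_ALPHABET)
  attr(out, "counted") <- as.integer(total)
  out
}

#' Pooled nucleotide content of a CDS set
#'
#' G+C and A+G percent over the concatenated sequences; `N` excluded from
#' numerator and denominator.
#'
#' @param nt_seqs character vector of DNA sequences.
#' @return list with `gc_percent`, `ag_percent`, `bases` (counted total).
#' @export
nt_content <- function(nt_seqs) {
  res <- strsplit(paste(nt_seqs, collapse = ""), "")[[1]]
  counts <- table(factor(res, levels = c("A", "C", "G", "T")))
  total <- sum(counts)
  if (total == 0L) stop("no counted bases (A/C/G/T)")
  list(gc_percent = 100 * (counts[["G"]] + counts[["C"]]) / total,
       ag_percent = 100 * (counts[["A"]] + counts[["G"]]) / total,
       bases = as.integer(total))
}

#' Per-genome composition feature matrix
#'
#' Rows are genomes, columns the 20 amino-acid percentages plus `GC` and
#' `AG` (from the CDS nucleotide sequences). With `scope = "set"`, only the
#' CDS carrying `set_label` in `partition` are pooled (the partition must
#' be of the corresponding genome; other genomes fall back to all CDS with
#' a warning-free restriction only where labels exist).
#'
#' @param collection a [genome_collection()].
#' @param genomes genome ids (default all in the outermost hierarchy level
#'   if set, else all genomes).
#' @param cds_filter optional character vector of cds ids to restrict to
#'   (e.g. a core set union across genomes); applied before pooling.
#' @return numeric matrix genomes x 22.
#' @export
composition_matrix <- function(collection, genomes = NULL,
                               cds_filter = NULL) {
  if (is.null(genomes))
    genomes <- if (length(collection$hierarchy))
      collection$hierarchy[[1]] else collection$meta$genome_id
  feat <- c(AA_ALPHABET, "GC", "AG")
  out <- matrix(NA_real_, length(genomes), length(feat),
                dimnames = list(genomes, feat))
  cds <- collection$cds
  if (!is.null(cds_filter)) cds <- cds[cds$cds_id %in% cds_filter, ]
  for (g in genomes) {
    sel <- cds$genome_id == g
    if (!any(sel)) stop("no CDS for genome ", g, " under the given filter")
    out[g, AA_ALPHABET] <- aa_composition(cds$aa_seq[sel])
    nc <- nt_content(cds$nt_seq[sel])
    out[g, "GC"] <- nc$gc_percent
    out[g, "AG"] <- nc$ag_percent
  }
  out
}

#' Deviation profile
#'
#' Per-entity deviation from the unweighted across-entity mean, feature by
#' feature (rows = entities); each feature's deviations sum to zero.
#'
#' @param mat numeric matrix, entities x features.
#' @export
deviation_profile <- function(mat) {
  if (nrow(mat) < 2L) stop("need at least 2 entities")
  sweep(mat, 2L, colMeans(mat))
}

#' Welch two-sample t-test
#'
#' Two-sided unequal-variance t-test (Welch-Satterthwaite df) as in the
#' standard R default. Degenerate case: when both groups have zero
#' variance, `t = 0, p = 1` if the means agree, else `t = +/-Inf, p = 0`.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list `(delta, t, p)` with `delta = mean(x) - mean(y)`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  delta <- mean(x) - mean(y)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (isTRUE(all.equal(delta, 0)) || delta == 0)
      return(list(delta = 0, t = 0, p = 1))
    return(list(delta = delta, t = sign(delta) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(delta = delta, t = unname(tt$statistic), p = tt$p.value)
}

#' Cold-vs-warm group contrast of composition features
#'
#' Per-feature (20 amino acids + GC + AG) Welch t-test between the cold-
#' and warm-labelled genomes, with the genome as the sampling unit and
#' groups weighted equally per genome. `scope = "common"` pools only the
#' core-labelled CDS of each genome (requires `partition`; the core label
#' is the outermost partition level and non-focal genomes contribute the
#' RBH partners of the focal core when `core_ids` is supplied).
#'
#' @param collection a [genome_collection()].
#' @param scope `"total"` or `"common"`.
#' @param core_ids for `scope = "common"`: character vector of cds ids to
#'   restrict to (focal core members plus their orthologs).
#' @param adjust apply Benjamini-Hochberg correction to the p-values
#'   (off by default; raw per-feature p-values are reported).
#' @return data.frame: `feature`, `mean_cold`, `mean_warm`, `delta`
#'   (cold - warm), `t`, `p` (and `p_adj` when `adjust`).
#' @export
group_compare <- function(collection, scope = c("total", "common"),
                          core_ids = NULL, adjust = FALSE) {
  scope <- match.arg(scope)
  genomes <- if (length(collection$hierarchy))
    collection$hierarchy[[1]] else collection$meta$genome_id
  hab <- collection$meta$habitat[match(genomes, collection$meta$genome_id)]
  if (any(hab == "unlabeled"))
    stop("habitat label missing for: ",
         paste(genomes[hab == "unlabeled"], collapse = ", "))
  cold <- genomes[hab == "cold"]; warm <- genomes[hab == "warm"]
  if (length(cold) < 2L || length(warm) < 2L)
    stop("need at least 2 genomes per habitat group (cold = ",
         length(cold), ", warm = ", length(warm), ")")
  filt <- if (scope == "common") {
    if (is.null(core_ids)) stop("scope = 'common' requires core_ids")
    core_ids
  } else NULL
  mat <- composition_matrix(collection, genomes, cds_filter = filt)
  contrast_table(mat, setNames(hab, genomes), adjust = adjust)
}

#' Group contrast from a precomputed feature matrix
#'
#' @param mat numeric matrix, genomes x features.
#' @param labels named habitat labels (`cold`/`warm`) over the rows.
#' @param adjust apply Benjamini-Hochberg correction.
#' @export
contrast_table <- function(mat, labels, adjust = FALSE) {
  labels <- labels[rownames(mat)]
  res <- lapply(colnames(mat), function(f) {
    w <- welch_t(mat[labels == "cold", f], mat[labels == "warm", f])
    data.frame(feature = f,
               mean_cold = mean(mat[labels == "cold", f]),
               mean_warm = mean(mat[labels == "warm", f]),
               delta = w$delta, t = w$t, p = w$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust) out$p_adj <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Null calibration by label shuffling
#'
#' Shuffles the habitat labels `n_shuffles` times and reports the fraction
#' of per-feature Welch tests with `p < alpha`; on data without a planted
#' group difference this estimates the per-feature false-positive rate.
#'
#' @param mat numeric matrix, genomes x features.
#' @param labels habitat labels over the rows.
#' @param n_shuffles number of random relabellings.
#' @param alpha nominal level.
#' @param seed RNG seed.
#' @return list `(fpr, n_tests)`.
#' @export
shuffle_null_fpr <- function(mat, labels, n_shuffles = 1000, alpha = 0.05,
                             seed = 1) {
  set.seed(seed)
  labels <- as.character(labels)
  hits <- 0L; total <- 0L
  for (b in seq_len(n_shuffles)) {
    lb <- sample(labels)
    ic <- lb == "cold"; iw <- lb == "warm"
    for (f in seq_len(ncol(mat))) {
      p <- welch_t(mat[ic, f], mat[iw, f])$p
      hits <- hits + (p < alpha); total <- total + 1L
    }
  }
  list(fpr = hits / total, n_tests = total)
}

#' GC / amino-acid correlation across genomes
#'
#' Pearson correlation and least-squares slope of each amino acid's
#' composition against genome GC percent, plus the genome ordering by GC
#' for cumulative-composition display.
#'
#' @param collection a [genome_collection()] (or a matrix from
#'   [composition_matrix()] via `mat`).
#' @param mat optional precomputed composition matrix (genomes x features
#'   including a `GC` column); overrides `collection`.
#' @return list with data.frame `by_aa` (`aa`, `r`, `slope`), the `gc`
#'   vector, and `order_by_gc` (genome ids, ascending GC).
#' @export
gc_aa_correlation <- function(collection = NULL, mat = NULL) {
  if (is.null(mat)) mat <- composition_matrix(collection)
  if (nrow(mat) < 2L) stop("need at least 2 genomes")
  gc <- mat[, "GC"]
  if (isTRUE(all.equal(stats::sd(gc), 0)) || stats::sd(gc) == 0)
    stop("zero variance in genome GC content")
  by_aa <- do.call(rbind, lapply(AA_ALPHABET, function(a) {
    fit <- stats::lm.fit(cbind(1, gc), mat[, a])
    data.frame(aa = a, aa3 = AA_THREE[[a]],
               r = stats::cor(gc, mat[, a]),
               slope = fit$coefficients[[2]],
               stringsAsFactors = FALSE)
  }))
  rownames(by_aa) <- NULL
  list(by_aa = by_aa, gc = gc,
       order_by_gc = rownames(mat)[order(gc)])
}

#' Write a contrast table in the conventional report layout
#'
#' Feature (three-letter amino-acid names plus `G+C`, `A+G`), group means
#' to one decimal, p to two decimals.
#'
#' @param contrast frame from [group_compare()].
#' @param path output path.
#' @export
write_contrast_table <- function(contrast, path) {
  lab <- ifelse(contrast$feature %in% names(AA_THREE),
                AA_THREE[contrast$feature],
                ifelse(contrast$feature == "GC", "G+C",
                       ifelse(contrast$feature == "AG", "A+G",
                              contrast$feature)))
  out <- data.frame(feature = lab,
                    cold = sprintf("%.1f", contrast$mean_cold),
                    warm = sprintf("%.1f", contrast$mean_warm),
                    delta = sprintf("%+.1f", contrast$delta),
                    p = sprintf("%.2f", contrast$p))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
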