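#' Aligner / E-value parameters
#'
#' Parameters of the built-in affine-gap local aligner and its
#' Karlin-Altschul E-value model. The defaults (BLOSUM62, gap open 11 /
#' extend 1, K = 0.041, lambda = 0.267) mirror the conventional protein
#' search setup; the ungapped-style constants are applied to gapped scores,
#' a documented approximation adequate for thresholding at a fixed cutoff.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix_name name of the substitution matrix shipped by Biostrings.
#' @param gap_open,gap_extend positive integer gap penalties.
#' @param K,lambda positive Karlin-Altschul constants (lambda in nats per
#'   raw-score unit).
#' @return an object of class `align_params`.
#' @export
align_params <- function(matrix_name = "BLOSUM62", gap_open = 11L,
                         gap_extend = 1L, K = 0.041, lambda = 0.267) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  if (gap_open <= 0 || gap_extend <= 0)
    stop("gap penalties must be positive")
  smat <- if (matrix_name == "BLOSUM62") blosum62() else {
    e <- new.env()
    utils::data(list = matrix_name, package = "Biostrings", envir = e)
    as.matrix(get(matrix_name, envir = e))
  }
  storage.mode(smat) <- "integer"
  structure(list(matrix_name = matrix_name, smat = smat,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 K = K, lambda = lambda),
            class = "align_params")
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman with affine gaps over the configured substitution matrix.
#' Residues absent from the matrix score as the worst-case substitution.
#' Traceback is deterministic: end-cell ties resolve to the smallest query
#' then subject coordinate, path ties prefer diagonal moves.
#'
#' @param a,b non-empty protein sequences.
#' @param params an [align_params()] object.
#' @return list with `raw_score`, `bitscore`, `pident`, `aln_len`,
#'   `matches`, `mismatch`, `gapopen` and the 1-based inclusive spans
#'   `qstart`,`qend`,`sstart`,`send` (all 0 / spans empty when the optimal
#'   local score is 0).
#' @export
local_align <- function(a, b, params = align_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  r <- .sw_align_one(a, b, params$smat, params$gap_open, params$gap_extend)
  pid <- if (r$length > 0) 100 * r$matches / r$length else 0
  list(raw_score = r$score, bitscore = bitscore(r$score, params),
       pident = pid, aln_len = r$length, matches = r$matches,
       mismatch = r$mismatch, gapopen = r$gapopen,
       qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send)
}

#' Karlin-Altschul E-value
#'
#' `E = K * m * n * exp(-lambda * S)` for raw score `S`, query length `m`
#' and total subject residues `n`.
#'
#' @param score raw alignment score (scalar or vector).
#' @param m query length (>= 1).
#' @param n total residues in the subject database (>= 1).
#' @param params an [align_params()] object.
#' @export
evalue <- function(score, m, n, params = align_params()) {
  if (any(m < 1) || any(n < 1)) stop("m and n must be >= 1")
  params$K * m * n * exp(-params$lambda * score)
}

bitscore <- function(score, params = align_params()) {
  (params$lambda * score - log(params$K)) / log(2)
}

#' All-vs-all protein similarity search
#'
#' Aligns every query against every subject, converts raw scores to
#' E-values against the full subject set (`n` = total subject residues) and
#' keeps pairs with `E <= cutoff`. Self pairs (identical ids) are excluded.
#' Hits are grouped by query in input order and sorted within query by
#' ascending E-value, then descending bitscore, then subject id.
#'
#' @param queries,subjects named character vectors of protein sequences.
#' @param params an [align_params()] object.
#' @param cutoff E-value cutoff (default `1e-20`).
#' @return data.frame in the 12-column tabular hit layout.
#' @export
all_vs_all <- function(queries, subjects, params = align_params(),
                       cutoff = 1e-20) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(queries) == 0L || length(subjects) == 0L) return(empty_hits())
  check_proteome(queries); check_proteome(subjects)
  scores <- .sw_score_block(unname(queries), unname(subjects), params$smat,
                            params$gap_open, params$gap_extend)
  n_total <- sum(nchar(subjects))
  hits_from_scores(scores, queries, subjects, n_total, params, cutoff)
}

check_proteome <- function(x) {
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("proteome sequences must be named by cds id")
  if (anyDuplicated(names(x))) stop("duplicate cds ids in proteome")
  if (any(!nzchar(x))) stop("empty sequence in proteome")
  invisible(x)
}

# score matrix -> thresholded, sorted hit frame
hits_from_scores <- function(scores, queries, subjects, n_total, params,
                             cutoff, pair_cache = NULL) {
  E <- params$K * outer(nchar(queries), rep(n_total, length(subjects))) *
    exp(-params$lambda * scores)
  keep <- which(E <= cutoff, arr.ind = TRUE)
  if (nrow(keep)) {
    self <- names(queries)[keep[, 1]] == names(subjects)[keep[, 2]]
    keep <- keep[!self, , drop = FALSE]
  }
  if (nrow(keep) == 0L) return(empty_hits())
  rows <- vector("list", nrow(keep))
  for (r in seq_len(nrow(keep))) {
    i <- keep[r, 1]; j <- keep[r, 2]
    al <- if (!is.null(pair_cache)) pair_cache(i, j) else
      .sw_align_one(queries[[i]], subjects[[j]], params$smat,
                    params$gap_open, params$gap_extend)
    rows[[r]] <- data.frame(
      qseqid = names(queries)[i], sseqid = names(subjects)[j],
      pident = if (al$length > 0) 100 * al$matches / al$length else 0,
      length = al$length, mismatch = al$mismatch, gapopen = al$gapopen,
      qstart = al$qstart, qend = al$qend, sstart = al$sstart, send = al$send,
      evalue = E[i, j], bitscore = bitscore(scores[i, j], params),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  qlev <- factor(out$qseqid, levels = unique(names(queries)))
  out <- out[order(qlev, out$evalue, -out$bitscore, out$sseqid), ]
  rownames(out) <- NULL
  out
}

#' All-vs-all search for a genome pair, both directions
#'
#' Computes the symmetric score matrix once and derives both directed hit
#' tables (E-values differ by direction because the subject-database size
#' differs), reusing tracebacks across directions.
#'
#' @param prot_a,prot_b named protein vectors for genomes A and B.
#' @inheritParams all_vs_all
#' @return list with elements `ab` and `ba`, each a hit data.frame.
#' @export
all_vs_all_pair <- function(prot_a, prot_b, params = align_params(),
                            cutoff = 1e-20) {
  if (length(prot_a) == 0L || length(prot_b) == 0L)
    return(list(ab = empty_hits(), ba = empty_hits()))
  check_proteome(prot_a); check_proteome(prot_b)
  scores <- .sw_score_block(unname(prot_a), unname(prot_b), params$smat,
                            params$gap_open, params$gap_extend)
  cache <- new.env(parent = emptyenv())
  get_al <- function(i, j) {
    key <- paste0(i, "_", j)
    if (is.null(cache[[key]]))
      cache[[key]] <- .sw_align_one(prot_a[[i]], prot_b[[j]], params$smat,
                                    params$gap_open, params$gap_extend)
    cache[[key]]
  }
  ab <- hits_from_scores(scores, prot_a, prot_b, sum(nchar(prot_b)),
                         params, cutoff, pair_cache = get_al)
  mirror <- function(i, j) {  # i indexes prot_b, j indexes prot_a
    al <- get_al(j, i)
    list(score = al$score, length = al$length, matches = al$matches,
         mismatch = al$mismatch, gapopen = al$gapopen,
         qstart = al$sstart, qend = al$send,
         sstart = al$qstart, send = al$qend)
  }
  ba <- hits_from_scores(t(scores), prot_b, prot_a, sum(nchar(prot_a)),
                         params, cutoff, pair_cache = mirror)
  list(ab = ab, ba = ba)
}

#' Best hit of a single query
#'
#' The subject with minimal E-value; ties broken by higher bitscore, then
#' lexicographically smallest subject id. `NA` if the hit list is empty.
#'
#' @param hits hit data.frame rows sharing one query.
#' @export
best_hit <- function(hits) {
  if (nrow(hits) == 0L) return(NA_character_)
  if (length(unique(hits$qseqid)) > 1L)
    stop("hits must all share one query")
  o <- order(hits$evalue, -hits$bitscore, hits$sseqid)
  hits$sseqid[o[1]]
}

# vectorized best hit per query over a hit frame; named character vector
best_hits_per_query <- function(hits) {
  if (nrow(hits) == 0L) return(setNames(character(0), character(0)))
  o <- order(hits$qseqid, hits$evalue, -hits$bitscore, hits$sseqid)
  h <- hits[o, ]
  first <- !duplicated(h$qseqid)
  setNames(h$sseqid[first], h$qseqid[first])
}
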