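#' Exclusion case for lateral-transfer calling
#'
#' One strain-exclusion rule: drop hits whose subject genome is in
#' `exclude` (genome ids or lineage tags), take the top surviving match,
#' and call the query foreign if that match's genome carries none of the
#' `scope` lineage tags.
#'
#' @param exclude character vector of genome ids and/or lineage tags to
#'   remove before taking the top match.
#' @param scope character vector of lineage tags; a top match inside the
#'   scope is lineage-native for this case.
#' @param name optional case label.
#' @export
exclusion_case <- function(exclude, scope, name = NULL) {
  structure(list(exclude = as.character(exclude),
                 scope = as.character(scope),
                 name = if (is.null(name)) paste(scope, collapse = "|")
                        else name),
            class = "exclusion_case")
}

# resolve an exclusion spec to genome ids against the panel metadata
resolve_excluded <- function(exclude, meta) {
  tags <- split_tags(meta$lineage_tags)
  by_tag <- meta$genome_id[vapply(tags, function(tg) any(tg %in% exclude),
                                  logical(1))]
  by_id <- intersect(exclude, meta$genome_id)
  unresolved <- setdiff(exclude,
                        c(meta$genome_id, unique(unlist(tags))))
  if (length(unresolved))
    stop("exclusion entries not resolvable in panel metadata: ",
         paste(unresolved, collapse = ", "))
  union(by_id, by_tag)
}

in_scope <- function(genome_id, scope, meta) {
  tg <- split_tags(meta$lineage_tags[match(genome_id, meta$genome_id)])[[1]]
  any(tg %in% scope)
}

#' Top match of a CDS after strain exclusion
#'
#' Applies the deterministic best-hit rule after removing hits whose
#' subject genome is excluded.
#'
#' @param hits hit rows for one query against the panel.
#' @param meta panel metadata (maps subject genomes to taxa and tags).
#' @param cds2genome named vector mapping cds id to genome id.
#' @param exclude genome ids / lineage tags to exclude.
#' @return list `(genome_id, taxon_label, cds_id)` or `NULL` if nothing
#'   survives.
#' @export
top_match <- function(hits, meta, cds2genome, exclude = character(0)) {
  if (nrow(hits) == 0L) return(NULL)
  excl_g <- resolve_excluded(exclude, meta)
  sg <- unname(cds2genome[hits$sseqid])
  if (anyNA(sg)) stop("panel hits reference cds ids with unknown genome")
  hits <- hits[!(sg %in% excl_g), , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  b <- best_hit(hits)
  g <- unname(cds2genome[[b]])
  list(genome_id = g,
       taxon_label = meta$taxon_label[match(g, meta$genome_id)],
       cds_id = b)
}

#' Classify CDS as lineage-native or laterally transferred
#'
#' Evaluates the ordered exclusion cases for each query CDS: a query is
#' `lateral` if for ANY case the top match surviving that case's exclusions
#' falls outside the case's lineage scope (the first triggering case and
#' its donor are recorded); `native` if hits exist but no case triggers;
#' `no_hit` if the CDS has no panel hit at the cutoff at all (reported
#' separately, never counted as lateral).
#'
#' @param cds_ids queries to classify.
#' @param panel_hits hit table of the queries against the reference panel.
#' @param meta panel metadata frame.
#' @param cds2genome named vector mapping panel cds ids to genome ids.
#' @param cases list of [exclusion_case()] objects, evaluated in order.
#' @param cutoff E-value cutoff (default `1e-20`).
#' @return data.frame of origin calls: `cds_id`, `label`, `case` (index of
#'   the triggering case or `NA`), `donor_genome`, `donor_taxon`.
#' @export
classify_lateral <- function(cds_ids, panel_hits, meta, cds2genome, cases,
                             cutoff = 1e-20) {
  stopifnot(length(cases) >= 1)
  for (cs in cases) {
    if (!inherits(cs, "exclusion_case")) stop("cases must be exclusion_case")
    resolve_excluded(cs$exclude, meta)  # validate up front
  }
  ph <- panel_hits[panel_hits$evalue <= cutoff, , drop = FALSE]
  by_q <- split(seq_len(nrow(ph)), ph$qseqid)
  out <- data.frame(cds_id = cds_ids, label = "no_hit",
                    case = NA_integer_, donor_genome = NA_character_,
                    donor_taxon = NA_character_, stringsAsFactors = FALSE)
  for (r in seq_along(cds_ids)) {
    idx <- by_q[[cds_ids[[r]]]]
    if (is.null(idx)) next
    h <- ph[idx, , drop = FALSE]
    out$label[r] <- "native"
    for (k in seq_along(cases)) {
      tm <- top_match(h, meta, cds2genome, cases[[k]]$exclude)
      if (is.null(tm)) next
      if (!in_scope(tm$genome_id, cases[[k]]$scope, meta)) {
        out$label[r] <- "lateral"
        out$case[r] <- k
        out$donor_genome[r] <- tm$genome_id
        out$donor_taxon[r] <- tm$taxon_label
        break
      }
    }
  }
  out
}

#' Default exclusion cases for a collection
#'
#' Encodes the two-case rule: case 1 (three sub-cases) asks whether the
#' top match is still within the genus after excluding the closest
#' relative, the three closest relatives, or the four closest relatives;
#' case 2 asks whether, after excluding the whole genus, the top match is
#' still a marine gamma-proteobacterium or a gamma-proteobacterium.
#' Relatives are ordered from the collection hierarchy (innermost partners
#' first).
#'
#' @param collection a [genome_collection()].
#' @param genus_tag lineage tag naming the genus scope.
#' @param outer_scope lineage tags for the case-2 scope.
#' @return list of [exclusion_case()] objects.
#' @export
default_exclusion_cases <- function(collection, genus_tag = "Shewanella",
                                    outer_scope = c("marine-gamma",
                                                    "gamma")) {
  focal <- collection$focal
  rel <- character(0)
  for (k in rev(seq_along(collection$hierarchy)))
    rel <- union(rel, setdiff(collection$hierarchy[[k]], focal))
  sizes <- unique(pmin(c(1L, 3L, 4L), length(rel)))
  cases <- lapply(sizes, function(s)
    exclusion_case(rel[seq_len(s)], genus_tag,
                   name = paste0("case1-excl", s)))
  c(cases, list(exclusion_case(genus_tag, outer_scope, name = "case2")))
}

#' Donor taxon summary of lateral calls
#'
#' Per-donor-taxon counts of lateral calls plus cold/warm marginal totals
#' from the panel habitat labels.
#'
#' @param calls origin-call frame from [classify_lateral()].
#' @param meta panel metadata frame.
#' @return list with data.frame `by_taxon` (taxon, habitat, n) and named
#'   vector `habitat_totals`.
#' @export
donor_summary <- function(calls, meta) {
  lat <- calls[calls$label == "lateral", , drop = FALSE]
  if (nrow(lat) == 0L)
    return(list(by_taxon = data.frame(taxon = character(0),
                                      habitat = character(0),
                                      n = integer(0)),
                habitat_totals = c(cold = 0L, warm = 0L, unlabeled = 0L)))
  hab <- meta$habitat[match(lat$donor_genome, meta$genome_id)]
  tab <- as.data.frame(table(taxon = lat$donor_taxon, habitat = hab),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "n"
  rownames(tab) <- NULL
  totals <- c(cold = sum(hab == "cold"), warm = sum(hab == "warm"),
              unlabeled = sum(hab == "unlabeled"))
  list(by_taxon = tab, habitat_totals = totals)
}

#' Write origin calls
#' @param calls origin-call frame.
#' @param path output path.
#' @export
write_origin_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
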