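#' Read a FASTA file
#'
#' Minimal strict FASTA reader for per-genome protein or CDS files. Record
#' ids are the first whitespace-delimited token of each header line and must
#' be unique within the file; sequences are uppercased. The residue alphabet
#' is validated against the declared kind: `"dna"` allows `A C G T N`,
#' `"protein"` the 20 canonical letters plus `X`, and `"aligned_dna"`
#' additionally allows the gap character `-` (for pre-aligned input to the
#' distance functions).
#'
#' @param path path to a FASTA file.
#' @param kind one of `"dna"`, `"protein"`, `"aligned_dna"`.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, kind = c("dna", "protein", "aligned_dna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  ids <- character(0)
  seqs <- character(0)
  buf <- character(0)
  flush <- function() {
    if (length(ids) > length(seqs))
      seqs[[length(seqs) + 1L]] <<- paste(buf, collapse = "")
    buf <<- character(0)
  }
  for (k in seq_along(lines)) {
    ln <- lines[[k]]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      id <- strsplit(trimws(sub("^>", "", ln)), "\\s+")[[1]][1]
      if (is.na(id) || !nzchar(id))
        stop("empty FASTA header at line ", k, " of ", path)
      ids <- c(ids, id)
    } else {
      if (length(ids) == 0L)
        stop("sequence data before first header at line ", k, " of ", path)
      buf <- c(buf, gsub("\\s+", "", ln))
    }
  }
  flush()
  seqs <- toupper(unlist(seqs, use.names = FALSE))
  if (length(seqs) == 0L) return(setNames(character(0), character(0)))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  allowed <- switch(kind,
                    dna = "ACGTN",
                    aligned_dna = "ACGTN-",
                    protein = paste0(paste(AA_ALPHABET, collapse = ""), "X"))
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 strsplit(allowed, "")[[1]])
  if (length(bad))
    stop("illegal ", kind, " residue(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Translate a CDS nucleotide sequence
#'
#' Plain codon translation under the standard genetic code (no special
#' initiator handling). A trailing stop codon is stripped; an internal stop
#' is an error naming the codon index; any codon containing `N` translates
#' to `X`.
#'
#' @param nt_seq DNA string over `A C G T N`, length divisible by 3.
#' @return amino-acid string.
#' @export
translate_cds <- function(nt_seq) {
  nt_seq <- toupper(nt_seq)
  n <- nchar(nt_seq)
  if (n %% 3L != 0L)
    stop("CDS length ", n, " is not divisible by 3")
  bad <- setdiff(unique(strsplit(nt_seq, "")[[1]]), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("illegal DNA residue(s): ", paste(bad, collapse = ", "))
  if (n == 0L) return("")
  codons <- substring(nt_seq, seq(1L, n - 2L, 3L), seq(3L, n, 3L))
  gc <- genetic_code()
  aa <- ifelse(grepl("N", codons, fixed = TRUE), "X", unname(gc[codons]))
  aa[is.na(aa)] <- "X"
  k <- length(aa)
  if (aa[k] == "*") aa <- aa[-k]
  if (any(aa == "*"))
    stop("internal stop codon at codon index ", which(aa == "*")[1])
  paste(aa, collapse = "")
}

HIT_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")

#' Read a 12-column tabular hit file
#'
#' The de-facto standard tabular alignment format (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore),
#' tab-separated, `#` comment lines allowed. Lines with any other column
#' count are rejected with the offending line number.
#'
#' @param path path to the hit table.
#' @return data.frame with one row per hit, columns as above.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) == 0L) return(empty_hits())
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    b <- which(nf != 12L)[1]
    stop("expected 12 tab-separated columns but found ", nf[b],
         " at line ", keep[b], " of ", path)
  }
  m <- do.call(rbind, parts)
  num <- function(col, ln) {
    v <- suppressWarnings(as.numeric(col))
    if (anyNA(v))
      stop("unparseable numeric value '", col[which(is.na(v))[1]],
           "' at line ", ln[which(is.na(v))[1]], " of ", path)
    v
  }
  int_cols <- c(4L, 5L, 6L, 7L, 8L, 9L, 10L)
  out <- data.frame(qseqid = m[, 1], sseqid = m[, 2],
                    pident = num(m[, 3], keep),
                    length = 0L, mismatch = 0L, gapopen = 0L,
                    qstart = 0L, qend = 0L, sstart = 0L, send = 0L,
                    evalue = num(m[, 11], keep),
                    bitscore = num(m[, 12], keep),
                    stringsAsFactors = FALSE)
  for (j in int_cols) out[[HIT_COLUMNS[j]]] <- as.integer(num(m[, j], keep))
  validate_hits(out)
  out
}

empty_hits <- function() {
  out <- data.frame(qseqid = character(0), sseqid = character(0),
                    pident = numeric(0), length = integer(0),
                    mismatch = integer(0), gapopen = integer(0),
                    qstart = integer(0), qend = integer(0),
                    sstart = integer(0), send = integer(0),
                    evalue = numeric(0), bitscore = numeric(0),
                    stringsAsFactors = FALSE)
  out
}

validate_hits <- function(hits) {
  stopifnot(identical(names(hits), HIT_COLUMNS))
  if (any(hits$evalue < 0)) stop("negative E-value in hit table")
  if (any(hits$qstart > hits$qend) || any(hits$sstart > hits$send))
    stop("inverted alignment span in hit table")
  invisible(hits)
}

#' Write a 12-column tabular hit file
#' @param hits data.frame as returned by [all_vs_all()] or [read_hit_table()].
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  validate_hits(hits)
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(hits)) {
    lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                     hits$qseqid, hits$sseqid, hits$pident, hits$length,
                     hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                     hits$sstart, hits$send,
                     format_evalue(hits$evalue), hits$bitscore)
    writeLines(lines, con)
  }
  invisible(path)
}

format_evalue <- function(e) {
  ifelse(e == 0, "0.0", sprintf("%.2e", e))
}

#' Write a report table
#'
#' Tab-separated with a header row. Numeric columns whose names contain
#' `percent`/`pct` are printed with one decimal; columns named like E-values
#' in scientific notation; everything else with full precision so the file
#' round-trips through [read_report_table()].
#'
#' @param table data.frame with named columns.
#' @param path output path.
#' @export
write_report_table <- function(table, path) {
  if (is.null(names(table)) || any(!nzchar(names(table))))
    stop("table must have named columns")
  out <- table
  for (j in seq_along(out)) {
    nm <- tolower(names(out)[j])
    if (is.numeric(out[[j]]) && !is.integer(out[[j]])) {
      if (grepl("percent|pct", nm)) out[[j]] <- sprintf("%.1f", out[[j]])
      else if (grepl("evalue", nm)) out[[j]] <- format_evalue(out[[j]])
      else out[[j]] <- sprintf("%.10g", out[[j]])
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a report table written by [write_report_table()]
#' @param path path to the table.
#' @export
read_report_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

split_tags <- function(x) {
  lapply(strsplit(as.character(x), ","), function(v) trimws(v[nzchar(trimws(v))]))
}

join_tags <- function(x) vapply(x, paste, "", collapse = ",")

#' Genome metadata table
#'
#' Construct / validate the per-genome metadata frame: `genome_id`,
#' `taxon_label`, `habitat` (`cold`, `warm` or `unlabeled`), `lineage_tags`
#' and `groups` (comma-joined strings).
#'
#' @param genome_id,taxon_label character vectors.
#' @param habitat character vector over `cold`/`warm`/`unlabeled`.
#' @param lineage_tags,groups comma-joined tag strings (or list of vectors).
#' @export
genome_meta <- function(genome_id, taxon_label, habitat = "unlabeled",
                        lineage_tags = "", groups = "") {
  if (anyDuplicated(genome_id)) stop("duplicate genome ids")
  habitat <- rep_len(habitat, length(genome_id))
  if (!all(habitat %in% c("cold", "warm", "unlabeled")))
    stop("habitat must be cold, warm or unlabeled")
  if (is.list(lineage_tags)) lineage_tags <- join_tags(lineage_tags)
  if (is.list(groups)) groups <- join_tags(groups)
  data.frame(genome_id = as.character(genome_id),
             taxon_label = as.character(taxon_label),
             habitat = habitat,
             lineage_tags = rep_len(as.character(lineage_tags),
                                    length(genome_id)),
             groups = rep_len(as.character(groups), length(genome_id)),
             stringsAsFactors = FALSE)
}

#' Read / write the genome metadata table
#' @param path path to a tab-separated metadata table.
#' @rdname genome_meta
#' @export
read_genome_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "taxon_label", "habitat", "lineage_tags", "groups")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata table missing column(s): ",
                         paste(miss, collapse = ", "))
  genome_meta(df$genome_id, df$taxon_label, df$habitat,
              as.character(df$lineage_tags), as.character(df$groups))
}

#' @param meta metadata frame.
#' @rdname genome_meta
#' @export
write_genome_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Assemble a genome collection
#'
#' The universal pipeline input: per-genome metadata, the CDS table (one row
#' per protein-coding gene with nucleotide and amino-acid sequence), a
#' strictly nested hierarchy of genome-id sets (outermost first; every set
#' must contain the focal genome), and the focal genome id.
#'
#' @param meta metadata frame from [genome_meta()].
#' @param cds data.frame with columns `cds_id`, `genome_id`, `nt_seq`,
#'   `aa_seq` (`nt_seq` may be `NA` when only proteomes are available).
#' @param hierarchy list of character vectors of genome ids, outermost first.
#' @param focal focal genome id.
#' @export
genome_collection <- function(meta, cds, hierarchy, focal) {
  stopifnot(is.data.frame(meta), is.data.frame(cds))
  need <- c("cds_id", "genome_id", "nt_seq", "aa_seq")
  miss <- setdiff(need, names(cds))
  if (length(miss)) stop("cds table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(cds$cds_id))
    stop("duplicate cds ids: ",
         paste(utils::head(unique(cds$cds_id[duplicated(cds$cds_id)]), 5),
               collapse = ", "))
  unknown <- setdiff(unique(cds$genome_id), meta$genome_id)
  if (length(unknown))
    stop("cds reference unknown genome(s): ", paste(unknown, collapse = ", "))
  if (any(!nzchar(cds$aa_seq)))
    stop("empty protein sequence in cds table")
  if (!is.list(hierarchy) || length(hierarchy) < 1L)
    stop("hierarchy must be a non-empty list of genome-id sets")
  hierarchy <- lapply(hierarchy, as.character)
  for (k in seq_along(hierarchy)) {
    unknown <- setdiff(hierarchy[[k]], meta$genome_id)
    if (length(unknown))
      stop("hierarchy level ", k, " references unknown genome(s): ",
           paste(unknown, collapse = ", "))
    if (!focal %in% hierarchy[[k]])
      stop("hierarchy level ", k, " does not contain the focal genome ", focal)
    if (k > 1L && !all(hierarchy[[k]] %in% hierarchy[[k - 1L]]))
      stop("hierarchy not nested: level ", k,
           " is not a subset of level ", k - 1L)
    if (k > 1L && length(hierarchy[[k]]) >= length(hierarchy[[k - 1L]]))
      stop("hierarchy not strictly nested at level ", k)
  }
  structure(list(meta = meta, cds = cds, hierarchy = hierarchy,
                 focal = focal),
            class = "genome_collection")
}

#' @export
print.genome_collection <- function(x, ...) {
  cat("genome_collection:", nrow(x$meta), "genomes,", nrow(x$cds),
      "CDS; focal =", x$focal, "\n")
  cat("hierarchy levels:", paste(lengths(x$hierarchy), collapse = " / "),
      "genomes\n")
  invisible(x)
}

#' Extract one genome's proteome
#' @param collection a [genome_collection()].
#' @param genome_id genome id.
#' @return named character vector of protein sequences.
#' @export
proteome <- function(collection, genome_id) {
  sel <- collection$cds$genome_id == genome_id
  if (!any(sel)) stop("no CDS for genome ", genome_id)
  setNames(collection$cds$aa_seq[sel], collection$cds$cds_id[sel])
}

#' Extract one genome's CDS nucleotide sequences
#' @rdname proteome
#' @export
cds_seqs <- function(collection, genome_id) {
  sel <- collection$cds$genome_id == genome_id
  if (!any(sel)) stop("no CDS for genome ", genome_id)
  setNames(collection$cds$nt_seq[sel], collection$cds$cds_id[sel])
}

cds_genome_map <- function(collection) {
  setNames(collection$cds$genome_id, collection$cds$cds_id)
}

#' Write / read a genome collection as FASTA + metadata
#'
#' One protein FASTA (`<genome>.faa`) and one CDS FASTA (`<genome>.fna`) per
#' genome plus `metadata.tsv` and `hierarchy.tsv` under `dir`.
#'
#' @param collection a [genome_collection()].
#' @param dir output directory (created if absent).
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_meta(collection$meta, file.path(dir, "metadata.tsv"))
  hf <- data.frame(level = rep(seq_along(collection$hierarchy),
                               lengths(collection$hierarchy)),
                   genome_id = unlist(collection$hierarchy))
  utils::write.table(hf, file.path(dir, "hierarchy.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(collection$focal, file.path(dir, "focal.txt"))
  for (g in collection$meta$genome_id) {
    sel <- collection$cds$genome_id == g
    if (!any(sel)) next
    write_fasta(setNames(collection$cds$aa_seq[sel],
                         collection$cds$cds_id[sel]),
                file.path(dir, paste0(g, ".faa")))
    if (!anyNA(collection$cds$nt_seq[sel]))
      write_fasta(setNames(collection$cds$nt_seq[sel],
                           collection$cds$cds_id[sel]),
                  file.path(dir, paste0(g, ".fna")))
  }
  invisible(dir)
}

#' @rdname write_collection
#' @export
read_collection <- function(dir) {
  meta <- read_genome_meta(file.path(dir, "metadata.tsv"))
  hf <- utils::read.delim(file.path(dir, "hierarchy.tsv"),
                          stringsAsFactors = FALSE)
  hierarchy <- split(as.character(hf$genome_id), hf$level)
  names(hierarchy) <- NULL
  focal <- readLines(file.path(dir, "focal.txt"))[1]
  cds <- NULL
  for (g in meta$genome_id) {
    fa <- file.path(dir, paste0(g, ".faa"))
    if (!file.exists(fa)) next
    aa <- read_fasta(fa, "protein")
    fn <- file.path(dir, paste0(g, ".fna"))
    nt <- if (file.exists(fn)) read_fasta(fn, "dna") else
      setNames(rep(NA_character_, length(aa)), names(aa))
    cds <- rbind(cds, data.frame(cds_id = names(aa), genome_id = g,
                                 nt_seq = unname(nt[names(aa)]),
                                 aa_seq = unname(aa),
                                 stringsAsFactors = FALSE))
  }
  genome_collection(meta, cds, hierarchy, focal)
}
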