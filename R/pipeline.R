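#' Pipeline configuration
#'
#' One structured configuration for the end-to-end run: either a
#' simulation config or an input directory (FASTA + metadata as written by
#' [write_collection()]), the aligner parameters or an external hit-table
#' directory, the E-value cutoff, the lateral-transfer exclusion cases and
#' output locations. Exactly one of `aligner` / `hits_dir` is active.
#'
#' @param sim a [sim_config()] to simulate the inputs, or `NULL`.
#' @param input_dir directory with a written collection (used when `sim`
#'   is `NULL`).
#' @param outdir output directory for report tables.
#' @param aligner an [align_params()] object for the built-in aligner.
#' @param hits_dir directory of precomputed 12-column hit tables named
#'   `<A>__<B>.tsv` (bypasses the aligner entirely).
#' @param cutoff E-value cutoff (default `1e-20`).
#' @param cases list of [exclusion_case()] or `NULL` for the collection
#'   default.
#' @param compare run the cold-vs-warm composition contrast.
#' @param seed seed for any stage randomness.
#' @export
pipeline_config <- function(sim = NULL, input_dir = NULL,
                            outdir = tempfile("psychrocomp_run_"),
                            aligner = align_params(), hits_dir = NULL,
                            cutoff = 1e-20, cases = NULL, compare = FALSE,
                            seed = 1L) {
  if (is.null(sim) && is.null(input_dir))
    stop("provide either a simulation config or an input directory")
  if (!is.null(hits_dir) && !dir.exists(hits_dir))
    stop("hits_dir does not exist: ", hits_dir)
  if (cutoff <= 0) stop("cutoff must be positive")
  structure(list(sim = sim, input_dir = input_dir, outdir = outdir,
                 aligner = aligner, hits_dir = hits_dir, cutoff = cutoff,
                 cases = cases, compare = compare, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Compute (or load) the directed hit tables a partition run needs
#'
#' All unordered pairs of the focal genome with every other genome of the
#' outermost hierarchy level, plus the focal genome against every panel
#' genome outside the hierarchy (the donor panel). Scores are computed once
#' per unordered pair and mirrored. With `hits_dir` set, tables are read
#' instead (never mixed with the aligner for one pair).
#'
#' @param collection a [genome_collection()].
#' @param config a [pipeline_config()].
#' @return named list of directed hit frames keyed `"A->B"`.
#' @export
compute_focal_hits <- function(collection, config) {
  focal <- collection$focal
  natives <- collection$hierarchy[[1]]
  panel <- setdiff(collection$meta$genome_id, natives)
  partners <- c(setdiff(natives, focal), panel)
  hits <- list()
  pf <- proteome(collection, focal)
  for (g in partners) {
    if (!is.null(config$hits_dir)) {
      hits[[hit_key(focal, g)]] <-
        read_hit_table(file.path(config$hits_dir,
                                 paste0(focal, "__", g, ".tsv")))
      hits[[hit_key(g, focal)]] <-
        read_hit_table(file.path(config$hits_dir,
                                 paste0(g, "__", focal, ".tsv")))
    } else {
      pr <- all_vs_all_pair(pf, proteome(collection, g),
                            config$aligner, config$cutoff)
      hits[[hit_key(focal, g)]] <- pr$ab
      hits[[hit_key(g, focal)]] <- pr$ba
    }
  }
  hits
}

#' Run the comparative pipeline end to end
#'
#' Stages: simulate (or load) -> all-vs-all hits -> reciprocal best hits ->
#' nested partition -> lateral-transfer calls and donor summary ->
#' composition tables (-> cold/warm contrast when requested). Reports are
#' written under `config$outdir`; the returned bundle carries every
#' intermediate object (and the simulation truth when simulating). A rerun
#' with the same config is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return invisible list: `collection`, `truth`, `hits`, `rbh`,
#'   `partition`, `conservation`, `calls`, `donors`, `contrast`, `log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(paste0("psychrocomp ",
                        as.character(utils::packageVersion("psychrocomp")),
                        " seed=", config$seed, " cutoff=", config$cutoff))
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    res
  }

  truth <- NULL
  collection <- stage("input", {
    if (!is.null(config$sim)) {
      s <- simulate_collection(config$sim)
      truth <- s$truth
      s$collection
    } else read_collection(config$input_dir)
  })
  if (config$compare) {
    hab <- collection$meta$habitat[
      match(collection$hierarchy[[1]], collection$meta$genome_id)]
    if (any(hab == "unlabeled"))
      stop("stage 'validate' failed: compare requested but habitat ",
           "labels missing", call. = FALSE)
  }
  focal <- collection$focal
  log_lines <- c(log_lines,
                 paste0("input: ", nrow(collection$meta), " genomes, ",
                        nrow(collection$cds), " CDS, focal=", focal))

  hits <- stage("hits", compute_focal_hits(collection, config))
  log_lines <- c(log_lines,
                 paste0("hits: ", sum(vapply(hits, nrow, 0L)),
                        " across ", length(hits), " directed tables"))

  natives <- collection$hierarchy[[1]]
  others <- setdiff(natives, focal)
  rbh <- stage("rbh", {
    out <- lapply(others, function(g)
      reciprocal_best_hits(hits[[hit_key(focal, g)]],
                           hits[[hit_key(g, focal)]]))
    setNames(out, others)
  })
  log_lines <- c(log_lines,
                 paste0("rbh: ", sum(vapply(rbh, nrow, 0L)), " pairs"))

  partition <- stage("partition", nested_partition(collection, rbh))
  write_partition(partition, file.path(config$outdir, "partition.tsv"))
  write_report_table(partition_summary(partition),
                     file.path(config$outdir, "partition_summary.tsv"))
  log_lines <- c(log_lines, paste0(
    "partition: ",
    paste(sprintf("%s=%d", names(partition$counts), partition$counts),
          collapse = " ")))

  cons <- stage("conservation",
                conservation_table(collection, hits, queries = focal,
                                   targets = natives,
                                   cutoff = config$cutoff))
  utils::write.table(
    data.frame(target = rownames(cons$pretty),
               conserved = cons$pretty[, focal]),
    file.path(config$outdir, "conservation.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  panel <- setdiff(collection$meta$genome_id, natives)
  calls <- donors <- NULL
  if (length(panel) || length(others)) {
    cases <- config$cases %||% default_exclusion_cases(collection)
    panel_hits <- stage("hgt", {
      ph <- do.call(rbind, unname(
        hits[vapply(c(others, panel), function(g) hit_key(focal, g), "")]))
      if (is.null(ph)) empty_hits() else ph
    })
    fids <- collection$cds$cds_id[collection$cds$genome_id == focal]
    calls <- stage("hgt", classify_lateral(
      fids, panel_hits, collection$meta, cds_genome_map(collection),
      cases, config$cutoff))
    write_origin_calls(calls, file.path(config$outdir, "origin_calls.tsv"))
    donors <- donor_summary(calls, collection$meta)
    if (nrow(donors$by_taxon))
      utils::write.table(donors$by_taxon,
                         file.path(config$outdir, "donor_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    log_lines <- c(log_lines, paste0(
      "hgt: ", sum(calls$label == "lateral"), " lateral, ",
      sum(calls$label == "native"), " native, ",
      sum(calls$label == "no_hit"), " no_hit"))
  }

  compo <- stage("compo", composition_matrix(collection, natives))
  utils::write.table(data.frame(genome_id = rownames(compo),
                                round(compo, 4)),
                     file.path(config$outdir, "composition.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  contrast <- NULL
  if (config$compare) {
    contrast <- stage("compare", group_compare(collection, "total"))
    write_contrast_table(contrast,
                         file.path(config$outdir, "contrast_total.tsv"))
    log_lines <- c(log_lines, paste0(
      "compare: ", sum(contrast$p < 0.05), " of ", nrow(contrast),
      " features at p<0.05"))
  }

  writeLines(log_lines, file.path(config$outdir, "run_log.txt"))
  invisible(list(collection = collection, truth = truth, hits = hits,
                 rbh = rbh, partition = partition, conservation = cons,
                 calls = calls, donors = donors, composition = compo,
                 contrast = contrast, log = log_lines,
                 outdir = config$outdir))
}
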