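#' Amino-acid frequencies expected under a base-composition bias
#'
#' The sense-codon expectation of the standard genetic code when every
#' codon position draws bases independently with `P(G) = P(C) = theta/2`
#' and `P(A) = P(T) = (1-theta)/2` (stop codons excluded, renormalized).
#' `theta = 0.5` gives the uniform-usage expectation of the codon table,
#' the generator's baseline; varying theta reproduces the mechanical
#' GC-to-amino-acid coupling (Ala/Pro/Arg/Gly rise with GC, Ile/Lys/Asn/Tyr
#' fall).
#'
#' @param theta GC bias in (0, 1).
#' @return named frequency vector over the 20 residues, summing to 1.
#' @export
aa_freq_from_theta <- function(theta) {
  if (theta <= 0 || theta >= 1) stop("theta must be in (0, 1)")
  gc <- genetic_code()
  codons <- names(gc)[gc != "*"]
  pbase <- c(A = (1 - theta) / 2, C = theta / 2, G = theta / 2,
             T = (1 - theta) / 2)
  m <- do.call(rbind, strsplit(codons, ""))
  p <- pbase[m[, 1]] * pbase[m[, 2]] * pbase[m[, 3]]
  p <- p / sum(p)
  freq <- tapply(p, gc[codons], sum)
  out <- setNames(as.numeric(freq[AA_ALPHABET]), AA_ALPHABET)
  out / sum(out)
}

# codon bookkeeping for reverse translation, cached per session
codon_info <- function() {
  if (is.null(.pkg_cache$codon_info)) {
    gc <- genetic_code()
    codons <- names(gc)[gc != "*"]
    by_aa <- split(codons, gc[codons])
    third <- function(x) substr(x, 3, 3)
    info <- lapply(by_aa, function(cs) {
      s <- cs[third(cs) %in% c("G", "C")]
      w <- cs[third(cs) %in% c("A", "T")]
      list(s = s, w = w)
    })
    .pkg_cache$codon_info <- info[AA_ALPHABET]
  }
  .pkg_cache$codon_info
}

#' Reverse translation under a GC3 target
#'
#' For each residue a synonymous codon is drawn: residues with both
#' strong- (G/C third base) and weak-ending codons take a strong-ending
#' codon with a probability chosen so that the realized third-position GC
#' fraction equals `gc3_target` in expectation (accounting for Met and Trp,
#' whose single codons are G-ending); within the chosen class codons are
#' uniform. A `TAA` stop codon is appended, so [translate_cds()] inverts
#' the construction exactly.
#'
#' @param aa_seq protein sequence over the 20 canonical residues.
#' @param gc3_target target third-position GC fraction in (0, 1).
#' @return a CDS nucleotide string of length `3 * (nchar(aa_seq) + 1)`.
#' @export
reverse_translate <- function(aa_seq, gc3_target) {
  if (gc3_target < 0 || gc3_target > 1) stop("gc3_target must be in [0, 1]")
  res <- strsplit(aa_seq, "")[[1]]
  bad <- setdiff(unique(res), AA_ALPHABET)
  if (length(bad)) stop("non-canonical residue(s): ",
                        paste(bad, collapse = ", "))
  info <- codon_info()
  forced_s <- vapply(info, function(x) length(x$w) == 0L, logical(1))
  forced_w <- vapply(info, function(x) length(x$s) == 0L, logical(1))
  fS <- mean(forced_s[res]); fW <- mean(forced_w[res])
  free <- 1 - fS - fW
  pS <- if (free > 0) min(max((gc3_target - fS) / free, 0), 1) else 0.5
  n <- length(res)
  use_s <- stats::runif(n) < pS
  use_s[forced_s[res]] <- TRUE
  use_s[forced_w[res]] <- FALSE
  codons <- character(n)
  grp <- paste0(res, ifelse(use_s, "S", "W"))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    aa <- substr(g, 1, 1)
    pool <- if (substr(g, 2, 2) == "S") info[[aa]]$s else info[[aa]]$w
    codons[idx] <- pool[sample.int(length(pool), length(idx),
                                   replace = TRUE)]
  }
  paste0(paste(codons, collapse = ""), "TAA")
}

# substitution kernel: P(replacement b | original a), a != b, rows sum to 1,
# weighted by exp(BLOSUM62 / 2)
base_kernel <- function() {
  if (is.null(.pkg_cache$kern0)) {
    s <- blosum62()[AA_ALPHABET, AA_ALPHABET]
    k <- exp(s / 2)
    diag(k) <- 0
    .pkg_cache$kern0 <- k / rowSums(k)
  }
  .pkg_cache$kern0
}

replacement_marginal <- function(kernel, pi0) {
  setNames(as.numeric(pi0 %*% kernel), colnames(kernel))
}

# tilt the kernel (iterative proportional fitting on the columns) so that
# its replacement marginal under source composition pi0 equals `target`
tilt_kernel <- function(kernel, pi0, target, iters = 60) {
  t_col <- rep(1, ncol(kernel))
  k <- kernel
  for (it in seq_len(iters)) {
    marg <- replacement_marginal(k, pi0)
    t_col <- t_col * target / pmax(marg, 1e-12)
    k <- sweep(kernel, 2, t_col, `*`)
    k <- k / rowSums(k)
  }
  k
}

#' Mutate a family member away from its ancestor
#'
#' Each site is substituted independently with probability `divergence`;
#' the replacement residue is drawn from the row of `kernel` for the
#' original residue (the kernel never returns the original residue, so the
#' expected observed difference fraction equals `divergence`).
#'
#' @param ancestor protein sequence.
#' @param divergence substitution probability per site, in `[0, 1)`.
#' @param kernel 20 x 20 replacement kernel (default BLOSUM-weighted).
#' @export
mutate_family <- function(ancestor, divergence, kernel = base_kernel()) {
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  if (divergence == 0) return(ancestor)
  res <- strsplit(ancestor, "")[[1]]
  hit <- which(stats::runif(length(res)) < divergence)
  if (length(hit)) {
    for (a in unique(res[hit])) {
      idx <- hit[res[hit] == a]
      res[idx] <- AA_ALPHABET[sample.int(20L, length(idx), replace = TRUE,
                                         prob = kernel[a, ])]
    }
  }
  paste(res, collapse = "")
}

#' Default foreign donor panel specification
#'
#' Six reference genomes outside the focal genus: four marine
#' gamma-proteobacteria (two cold-, two warm-adapted) and two
#' alpha-proteobacteria, each carrying its own private gene families.
#'
#' @param n_families families per donor genome.
#' @export
default_donor_panel <- function(n_families = 30L) {
  data.frame(
    genome_id = sprintf("D%02d", 1:6),
    taxon_label = c("Colwellia_like", "Psychromonas_like",
                    "Vibrio_like", "Aeromonas_like",
                    "Rhodospirillum_like", "Parvibaculum_like"),
    habitat = c("cold", "cold", "warm", "warm", "warm", "cold"),
    lineage_tags = c("marine-gamma,gamma", "marine-gamma,gamma",
                     "marine-gamma,gamma", "marine-gamma,gamma",
                     "alpha", "alpha"),
    n_families = as.integer(n_families),
    stringsAsFactors = FALSE)
}

#' Simulation configuration
#'
#' Defines the synthetic genome collection: a nested hierarchy of genomes
#' sharing gene families at each level, a per-genome GC3 gradient,
#' habitat-linked amino-acid shifts applied to cold genomes during
#' substitution, and foreign genes planted from a labelled donor panel.
#'
#' @param n_genomes genomes in the native panel.
#' @param clade_size,pair_size sizes of the inner hierarchy levels (the
#'   first `clade_size` / `pair_size` genomes; `NULL` drops the level).
#' @param n_core,n_clade,n_pair,n_private gene families shared by all
#'   genomes / the clade / the pair / private to each single genome.
#' @param mean_len,min_len protein length distribution (Poisson shifted to
#'   a minimum).
#' @param divergence expected substitutions per site between a genome copy
#'   and the family ancestor.
#' @param gc3 per-genome GC3 targets (recycled / interpolated to
#'   `n_genomes`).
#' @param habitat per-genome habitat labels (`cold`/`warm`).
#' @param shift named vector of cold-genome composition shifts in
#'   percentage points (names are one-letter residues); compensated
#'   internally to sum to zero and realized as the expected cold - warm
#'   proteome delta.
#' @param n_hgt foreign genes planted into the focal genome.
#' @param donors donor panel frame (see [default_donor_panel()]); `NULL`
#'   for none.
#' @param donor_divergence substitutions per site between donor-family
#'   copies (donor genome and planted gene are two draws from the donor
#'   ancestor).
#' @param aa_from_gc draw each genome's private-family ancestors from the
#'   codon-model expectation of its own GC3 (couples amino-acid usage to
#'   genome GC); shared-family ancestors always use the theta = 0.5
#'   baseline.
#' @param genus_tag,extra_tags lineage tags given to native genomes.
#' @param seed RNG seed.
#' @export
sim_config <- function(n_genomes = 17L, clade_size = 4L, pair_size = 2L,
                       n_core = 200L, n_clade = 100L, n_pair = 80L,
                       n_private = 50L, mean_len = 120L, min_len = 30L,
                       divergence = 0.15,
                       gc3 = seq(0.3, 0.7, length.out = n_genomes),
                       habitat = NULL,
                       shift = c(A = -0.8, P = -0.3, R = -0.5,
                                 I = 0.6, K = 0.4, N = 0.4),
                       n_hgt = 10L, donors = default_donor_panel(),
                       donor_divergence = 0.05, aa_from_gc = FALSE,
                       genus_tag = "Shewanella",
                       extra_tags = c("marine-gamma", "gamma"),
                       seed = 1L) {
  if (is.null(habitat)) {
    n_cold <- min(max(clade_size %||% 0L + 1L, 2L), n_genomes - 2L)
    habitat <- c(rep("cold", n_cold), rep("warm", n_genomes - n_cold))
  }
  habitat <- rep_len(habitat, n_genomes)
  gc3 <- rep_len(gc3, n_genomes)
  if (!is.null(shift) && length(shift)) {
    bad <- setdiff(names(shift), AA_ALPHABET)
    if (length(bad)) stop("unknown residue(s) in shift: ",
                          paste(bad, collapse = ", "))
  }
  if (!is.null(clade_size) && clade_size >= n_genomes)
    stop("clade_size must be smaller than n_genomes")
  if (!is.null(pair_size) && !is.null(clade_size) &&
      pair_size >= clade_size)
    stop("pair_size must be smaller than clade_size")
  if (n_hgt > 0 && (is.null(donors) || sum(donors$n_families) < n_hgt))
    stop("donor panel too small for n_hgt")
  structure(list(n_genomes = as.integer(n_genomes),
                 clade_size = clade_size, pair_size = pair_size,
                 n_core = n_core, n_clade = n_clade, n_pair = n_pair,
                 n_private = n_private, mean_len = mean_len,
                 min_len = min_len, divergence = divergence, gc3 = gc3,
                 habitat = habitat, shift = shift, n_hgt = as.integer(n_hgt),
                 donors = donors, donor_divergence = donor_divergence,
                 aa_from_gc = aa_from_gc, genus_tag = genus_tag,
                 extra_tags = extra_tags, seed = as.integer(seed)),
            class = "sim_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Preset: habitat contrast panel
#'
#' Cold and warm genome groups with the default planted shift, a single
#' hierarchy level and no foreign genes — the configuration for composition
#' group contrasts. Cold genomes get slightly lower GC3 (0.40-0.44 vs
#' 0.46-0.50), mirroring the lower GC of cold-adapted genomes.
#'
#' @param n_cold,n_warm group sizes.
#' @param shift cold-genome shift vector (percentage points); `NULL` or
#'   all-zero gives a null panel.
#' @param ... passed on to [sim_config()].
#' @export
sim_config_habitat_panel <- function(n_cold = 10L, n_warm = 10L,
                                     shift = c(A = -0.8, P = -0.3,
                                               R = -0.5, I = 0.6,
                                               K = 0.4, N = 0.4), ...) {
  n <- n_cold + n_warm
  sim_config(n_genomes = n, clade_size = NULL, pair_size = NULL,
             n_core = 150L, n_clade = 0L, n_pair = 0L, n_private = 30L,
             gc3 = c(seq(0.40, 0.44, length.out = n_cold),
                     seq(0.46, 0.50, length.out = n_warm)),
             habitat = c(rep("cold", n_cold), rep("warm", n_warm)),
             shift = shift, n_hgt = 0L, donors = NULL, ...)
}

#' Preset: GC-gradient panel (codon model)
#'
#' Unrelated genomes spanning a GC3 gradient whose amino-acid usage is
#' drawn from the codon-model expectation of each genome's GC — the
#' configuration for GC / amino-acid correlation checks.
#'
#' @param n_genomes number of genomes.
#' @param gc_range GC3 endpoints of the gradient.
#' @param n_proteins private families per genome.
#' @param ... passed on to [sim_config()].
#' @export
sim_config_gc_panel <- function(n_genomes = 16L, gc_range = c(0.3, 0.7),
                                n_proteins = 150L, ...) {
  sim_config(n_genomes = n_genomes, clade_size = NULL, pair_size = NULL,
             n_core = 0L, n_clade = 0L, n_pair = 0L,
             n_private = n_proteins,
             gc3 = seq(gc_range[1], gc_range[2], length.out = n_genomes),
             habitat = rep("unlabeled", n_genomes), shift = NULL,
             divergence = 0, n_hgt = 0L, donors = NULL,
             aa_from_gc = TRUE, ...)
}

#' Simulate a genome collection with planted ground truth
#'
#' Draws ancestral proteins per gene family from the baseline codon-table
#' amino-acid frequencies, mutates per-genome copies to the configured
#' divergence with a BLOSUM-weighted replacement kernel (tilted for cold
#' genomes so the expected cold - warm composition delta equals the
#' configured shift vector), reverse-translates every protein under its
#' genome's GC3 target, and plants foreign genes copied from the donor
#' panel into the focal genome. Deterministic for a fixed seed.
#'
#' @param config a [sim_config()].
#' @return list with the [genome_collection()] (`collection`) and
#'   `truth`: per-focal-CDS `partition` labels, per-focal-CDS `origin`
#'   frame (`vertical`/`hgt` + donor genome), and per-genome frame
#'   (`gc3`, `habitat`).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genomes
  gids <- sprintf("G%02d", seq_len(n))
  focal <- gids[1]
  hierarchy <- list(gids)
  if (!is.null(config$clade_size))
    hierarchy <- c(hierarchy, list(gids[seq_len(config$clade_size)]))
  if (!is.null(config$pair_size))
    hierarchy <- c(hierarchy, list(gids[seq_len(config$pair_size)]))
  lev_names <- default_level_names(hierarchy)

  meta <- genome_meta(
    gids, paste0(config$genus_tag, "_sp_", gids), config$habitat,
    lineage_tags = paste(c(config$genus_tag, config$extra_tags),
                         collapse = ","),
    groups = "strains")
  if (!is.null(config$donors)) {
    meta <- rbind(meta, genome_meta(
      config$donors$genome_id, config$donors$taxon_label,
      config$donors$habitat, config$donors$lineage_tags,
      groups = "donor-panel"))
  }

  pi0 <- aa_freq_from_theta(0.5)
  kern0 <- base_kernel()
  marg0 <- replacement_marginal(kern0, pi0)
  kern_cold <- kern0
  if (!is.null(config$shift) && length(config$shift) &&
      any(config$shift != 0) && config$divergence > 0) {
    shift <- setNames(rep(0, 20), AA_ALPHABET)
    shift[names(config$shift)] <- config$shift
    shift <- shift - mean(shift)          # keep the simplex balanced
    target <- marg0 + (shift / 100) / config$divergence
    if (any(target <= 0))
      stop("shift vector drives a replacement frequency negative; ",
           "reduce shifts or raise divergence")
    kern_cold <- tilt_kernel(kern0, pi0, target)
  }

  draw_len <- function(k) config$min_len + stats::rpois(k, max(
    config$mean_len - config$min_len, 1))
  draw_protein <- function(len, freq)
    paste(AA_ALPHABET[sample.int(20L, len, replace = TRUE, prob = freq)],
          collapse = "")

  fam <- list()
  add_fams <- function(k, type, members, prefix, freq_by_member = NULL) {
    if (k <= 0) return(invisible(NULL))
    lens <- draw_len(k)
    for (f in seq_len(k)) {
      freq <- if (is.null(freq_by_member)) pi0 else freq_by_member
      fam[[length(fam) + 1L]] <<- list(
        name = sprintf("%s%04d", prefix, f), type = type,
        members = members, ancestor = draw_protein(lens[f], freq))
    }
  }
  add_fams(config$n_core, "core", gids, "core")
  if (!is.null(config$clade_size))
    add_fams(config$n_clade, "clade", gids[seq_len(config$clade_size)],
             "clade")
  if (!is.null(config$pair_size))
    add_fams(config$n_pair, "pair", gids[seq_len(config$pair_size)],
             "pair")
  for (g in gids) {
    freq <- if (config$aa_from_gc)
      aa_freq_from_theta(config$gc3[match(g, gids)]) else NULL
    add_fams(config$n_private, "private", g, paste0("prv", g),
             freq_by_member = freq)
  }
  donor_fams <- list()
  if (!is.null(config$donors)) {
    for (r in seq_len(nrow(config$donors))) {
      d <- config$donors$genome_id[r]
      kf <- config$donors$n_families[r]
      lens <- draw_len(kf)
      for (f in seq_len(kf))
        donor_fams[[length(donor_fams) + 1L]] <- list(
          name = sprintf("dnr%s_%03d", d, f), donor = d,
          ancestor = draw_protein(lens[f], pi0))
    }
  }

  cds <- list()
  truth_partition <- character(0)
  type_label <- c(core = lev_names[1],
                  clade = if (length(lev_names) > 1) lev_names[2] else NA,
                  pair = if (length(lev_names) > 2) lev_names[3] else NA,
                  private = "CDS_1")
  for (g in gids) {
    kern <- if (config$habitat[match(g, gids)] == "cold") kern_cold
            else kern0
    gc3 <- config$gc3[match(g, gids)]
    for (fm in fam) {
      if (!g %in% fm$members) next
      aa <- mutate_family(fm$ancestor, config$divergence, kern)
      id <- paste0(g, "_", fm$name)
      cds[[length(cds) + 1L]] <- list(cds_id = id, genome_id = g,
                                      aa = aa, gc3 = gc3)
      if (g == focal)
        truth_partition[id] <- type_label[[fm$type]]
    }
  }
  for (df in donor_fams) {
    aa <- mutate_family(df$ancestor, config$donor_divergence, kern0)
    cds[[length(cds) + 1L]] <- list(
      cds_id = paste0(df$donor, "_", df$name), genome_id = df$donor,
      aa = aa, gc3 = 0.5)
  }
  origin <- data.frame(cds_id = names(truth_partition),
                       origin = "vertical",
                       donor_genome = NA_character_,
                       stringsAsFactors = FALSE)
  if (config$n_hgt > 0) {
    pick <- sample.int(length(donor_fams), config$n_hgt)
    for (k in seq_along(pick)) {
      df <- donor_fams[[pick[k]]]
      aa <- mutate_family(df$ancestor, config$donor_divergence, kern0)
      id <- sprintf("%s_hgt%03d_%s", focal, k, df$name)
      cds[[length(cds) + 1L]] <- list(cds_id = id, genome_id = focal,
                                      aa = aa,
                                      gc3 = config$gc3[1])
      truth_partition[id] <- "CDS_1"
      origin <- rbind(origin, data.frame(cds_id = id, origin = "hgt",
                                         donor_genome = df$donor,
                                         stringsAsFactors = FALSE))
    }
  }

  cds_df <- data.frame(
    cds_id = vapply(cds, `[[`, "", "cds_id"),
    genome_id = vapply(cds, `[[`, "", "genome_id"),
    nt_seq = NA_character_,
    aa_seq = vapply(cds, `[[`, "", "aa"),
    stringsAsFactors = FALSE)
  cds_df$nt_seq <- vapply(seq_len(nrow(cds_df)), function(i)
    reverse_translate(cds_df$aa_seq[i], cds[[i]]$gc3), "")

  collection <- genome_collection(meta, cds_df, hierarchy, focal)
  truth <- list(
    partition = truth_partition,
    origin = origin,
    genome = data.frame(genome_id = gids,
                        gc3 = config$gc3,
                        habitat = config$habitat,
                        stringsAsFactors = FALSE))
  list(collection = collection, truth = truth)
}
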