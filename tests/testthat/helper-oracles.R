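# fixture builders and independent oracles used across test files

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_aa_seq <- function(n) paste(sample(AA20, n, replace = TRUE),
                                 collapse = "")

rand_dna_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")

# substitute a fraction of DNA sites to a different random base
mutate_dna <- function(s, frac) {
  v <- strsplit(s, "")[[1]]
  idx <- which(runif(length(v)) < frac)
  v[idx] <- vapply(v[idx], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  paste(v, collapse = "")
}

# random 12-column hit table between two id sets
rand_hits <- function(qids, sids, density = 0.3) {
  grid <- expand.grid(q = qids, s = sids, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < density, , drop = FALSE]
  n <- nrow(grid)
  if (n == 0L) return(psychrocomp::read_hit_table(tempfile_empty()))
  data.frame(qseqid = grid$q, sseqid = grid$s,
             pident = runif(n, 30, 100), length = sample(50:200, n, TRUE),
             mismatch = sample(0:50, n, TRUE),
             gapopen = sample(0:5, n, TRUE),
             qstart = 1L, qend = 50L, sstart = 1L, send = 50L,
             evalue = 10^-runif(n, 21, 60), bitscore = runif(n, 80, 400),
             stringsAsFactors = FALSE)
}

tempfile_empty <- function() {
  f <- tempfile()
  writeLines(character(0), f)
  f
}

# independent best-hit: minimal E, then max bitscore, then smallest id
oracle_best <- function(hits, q) {
  h <- hits[hits$qseqid == q, , drop = FALSE]
  if (nrow(h) == 0L) return(NA_character_)
  h <- h[h$evalue == min(h$evalue), , drop = FALSE]
  h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
  sort(h$sseqid)[1]
}

# exhaustive two-direction RBH check over every candidate pair
oracle_rbh <- function(hits_ab, hits_ba) {
  pairs <- unique(rbind(hits_ab[, c("qseqid", "sseqid")],
                        setNames(hits_ba[, c("sseqid", "qseqid")],
                                 c("qseqid", "sseqid"))))
  keep <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs$qseqid[r]; b <- pairs$sseqid[r]
    identical(oracle_best(hits_ab, a), b) &&
      identical(oracle_best(hits_ba, b), a)
  }, logical(1))
  out <- pairs[keep, , drop = FALSE]
  out[order(out$qseqid), , drop = FALSE]
}

# independent sequential-deduction partition from raw directed hit tables
oracle_partition <- function(focal_ids, hierarchy, focal, hits) {
  lab <- setNames(rep(NA_character_, length(focal_ids)), focal_ids)
  lev <- psychrocomp:::default_level_names(hierarchy)
  for (k in seq_along(hierarchy)) {
    others <- setdiff(hierarchy[[k]], focal)
    for (id in focal_ids[is.na(lab)]) {
      ok <- all(vapply(others, function(g) {
        ab <- hits[[paste0(focal, "->", g)]]
        ba <- hits[[paste0(g, "->", focal)]]
        b <- oracle_best(ab, id)
        !is.na(b) && identical(oracle_best(ba, b), id)
      }, logical(1)))
      if (ok) lab[id] <- lev[k]
    }
  }
  lab[is.na(lab)] <- "CDS_1"
  lab
}

# permutation p-value for the two-sided Welch statistic
perm_t_p <- function(x, y, B = 4000) {
  t_obs <- abs(psychrocomp::welch_t(x, y)$t)
  pool <- c(x, y)
  n <- length(x)
  hits <- 0L
  for (b in seq_len(B)) {
    idx <- sample(length(pool), n)
    tb <- abs(psychrocomp::welch_t(pool[idx], pool[-idx])$t)
    if (tb >= t_obs) hits <- hits + 1L
  }
  (hits + 1) / (B + 1)
}

# four-point-condition quartet pairing: 1 = (ij|kl), 2 = (ik|jl), 3 = (il|jk)
quartet_pairing <- function(D, q) {
  s <- c(D[q[1], q[2]] + D[q[3], q[4]],
         D[q[1], q[3]] + D[q[2], q[4]],
         D[q[1], q[4]] + D[q[2], q[3]])
  which.min(s)
}

# every quartet of the tree agrees with the four-point condition on D
quartets_agree <- function(tree, D) {
  TD <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  quads <- utils::combn(rownames(D), 4)
  all(vapply(seq_len(ncol(quads)), function(i) {
    q <- quads[, i]
    quartet_pairing(D, q) == quartet_pairing(TD, q)
  }, logical(1)))
}

# small simulated collection plus its directed focal hit tables
small_sim_run <- function(seed, n_genomes = 4, n_core = 6, n_private = 2,
                          mean_len = 60) {
  cfg <- psychrocomp::sim_config(
    n_genomes = n_genomes, clade_size = NULL, pair_size = NULL,
    n_core = n_core, n_clade = 0, n_pair = 0, n_private = n_private,
    mean_len = mean_len, n_hgt = 0, donors = NULL, seed = seed)
  psychrocomp::simulate_collection(cfg)
}
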