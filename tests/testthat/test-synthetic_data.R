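test_that("codon-model amino-acid frequencies shift with GC bias", {
  f5 <- aa_freq_from_theta(0.5)
  expect_equal(sum(f5), 1)
  # theta = 0.5 is the uniform-usage expectation: Leu (6 codons) = 6/61
  expect_equal(unname(f5["L"]), 6 / 61)
  expect_equal(unname(f5["M"]), 1 / 61)
  hi <- aa_freq_from_theta(0.7); lo <- aa_freq_from_theta(0.3)
  expect_true(all(hi[c("A", "P", "R", "G")] > lo[c("A", "P", "R", "G")]))
  expect_true(all(hi[c("I", "K", "N", "Y")] < lo[c("I", "K", "N", "Y")]))
  expect_error(aa_freq_from_theta(1), "in \\(0, 1\\)")
})

test_that("reverse translation inverts exactly and meets its GC3 target", {
  set.seed(71)
  for (i in 1:10) {
    aa <- rand_aa_seq(sample(10:80, 1))
    nt <- reverse_translate(aa, runif(1))
    expect_identical(nchar(nt), 3L * (nchar(aa) + 1L))
    expect_identical(translate_cds(nt), aa)
  }
  # gc3 = 1: every third base strong
  nt1 <- reverse_translate(rand_aa_seq(200), 1.0)
  third <- substring(nt1, seq(3, nchar(nt1) - 3, 3), seq(3, nchar(nt1) - 3, 3))
  expect_true(all(third %in% c("G", "C")))
  # law of large numbers: realized GC3 within 1% of target over 1e5 codons
  big <- paste(sample(AA20, 1e5, TRUE,
                      prob = psychrocomp::aa_freq_from_theta(0.5)),
               collapse = "")
  ntb <- reverse_translate(big, 0.55)
  t3 <- substring(ntb, seq(3, nchar(ntb) - 3, 3), seq(3, nchar(ntb) - 3, 3))
  expect_lt(abs(mean(t3 %in% c("G", "C")) - 0.55), 0.01)
  expect_error(reverse_translate("AXB", 0.5), "non-canonical")
})

test_that("family mutation hits its divergence and honours tilts", {
  set.seed(72)
  anc <- rand_aa_seq(1000)
  expect_identical(mutate_family(anc, 0), anc)
  fracs <- replicate(30, {
    m <- mutate_family(anc, 0.1)
    mean(strsplit(m, "")[[1]] != strsplit(anc, "")[[1]])
  })
  expect_lt(abs(mean(fracs) - 0.1), 0.02)
  expect_error(mutate_family(anc, 1), "in \\[0, 1\\)")

  # a kernel tilted toward Ile raises Ile content of the mutated set
  pi0 <- psychrocomp::aa_freq_from_theta(0.5)
  k0 <- psychrocomp:::base_kernel()
  m0 <- psychrocomp:::replacement_marginal(k0, pi0)
  target <- m0; target["I"] <- target["I"] + 0.10
  target <- target / sum(target)
  kI <- psychrocomp:::tilt_kernel(k0, pi0, target)
  mut <- vapply(1:40, function(i) mutate_family(anc, 0.3, kI), "")
  ile_anc <- aa_composition(anc)["I"]
  ile_mut <- aa_composition(mut)["I"]
  expect_gt(ile_mut, ile_anc)
})

test_that("simulation is deterministic and honours degenerate limits", {
  cfg <- sim_config(n_genomes = 4, clade_size = 2, pair_size = NULL,
                    n_core = 8, n_clade = 4, n_pair = 0, n_private = 3,
                    mean_len = 70, n_hgt = 2,
                    donors = default_donor_panel(5), seed = 77)
  s1 <- simulate_collection(cfg)
  s2 <- simulate_collection(cfg)
  expect_identical(s1$collection$cds, s2$collection$cds)
  expect_identical(s1$truth, s2$truth)

  # zero divergence, no foreign genes, flat GC3: identical shared proteomes
  cfg0 <- sim_config(n_genomes = 3, clade_size = NULL, pair_size = NULL,
                     n_core = 6, n_clade = 0, n_pair = 0, n_private = 0,
                     divergence = 0, gc3 = 0.5, n_hgt = 0, donors = NULL,
                     mean_len = 60, seed = 78)
  s0 <- simulate_collection(cfg0)
  by_fam <- split(s0$collection$cds$aa_seq,
                  sub("^G\\d+_", "", s0$collection$cds$cds_id))
  expect_true(all(vapply(by_fam, function(v)
    length(unique(v)) == 1L, logical(1))))
  # and the recovered partition equals the planted one
  res <- run_pipeline(pipeline_config(sim = cfg0, outdir = tempfile()))
  expect_identical(res$partition$labels[names(res$truth$partition)],
                   res$truth$partition)
})

test_that("GC3 targets drive pooled GC in the configured direction", {
  cfg <- sim_config(n_genomes = 2, clade_size = NULL, pair_size = NULL,
                    n_core = 20, n_clade = 0, n_pair = 0, n_private = 0,
                    divergence = 0, gc3 = c(0.3, 0.7), n_hgt = 0,
                    donors = NULL, mean_len = 80, seed = 79)
  s <- simulate_collection(cfg)
  gc <- vapply(c("G01", "G02"), function(g)
    nt_content(cds_seqs(s$collection, g))$gc_percent, 0)
  expect_lt(gc["G01"], gc["G02"])
})

test_that("impossible shift vectors are rejected at generation time", {
  cfg <- sim_config(n_genomes = 4, clade_size = NULL, pair_size = NULL,
                    n_core = 5, n_clade = 0, n_pair = 0, n_private = 0,
                    habitat = c("cold", "cold", "warm", "warm"),
                    shift = c(A = -30), divergence = 0.15, n_hgt = 0,
                    donors = NULL, seed = 80)
  expect_error(simulate_collection(cfg), "negative")
})

test_that("realized cold-warm deltas track the configured shift vector", {
  s <- simulate_collection(sim_config_habitat_panel(seed = 81))
  mat <- composition_matrix(s$collection)
  hab <- s$truth$genome$habitat
  delta <- colMeans(mat[hab == "cold", AA20]) -
    colMeans(mat[hab == "warm", AA20])
  shift <- setNames(rep(0, 20), AA20)
  shift[c("A", "P", "R", "I", "K", "N")] <-
    c(-0.8, -0.3, -0.5, 0.6, 0.4, 0.4)
  shift <- shift - mean(shift)
  expect_true(all(abs(delta - shift) <= 0.15))
})
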