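test_that("pooled amino-acid composition and the X-exclusion rule", {
  c1 <- aa_composition("AAAA")
  expect_equal(unname(c1["A"]), 100)
  expect_equal(sum(c1), 100)

  c2 <- aa_composition("ACDEFGHIKLMNPQRSTVWY")
  expect_true(all(abs(c2 - 5) < 1e-12))

  c3 <- aa_composition(c("AAX", "A"))
  expect_equal(unname(c3["A"]), 100)
  expect_identical(attr(c3, "counted"), 3L)
  expect_error(aa_composition("XXX"), "no canonical")
})

test_that("pooled composition equals the count-weighted mean of parts", {
  set.seed(51)
  prots <- vapply(1:12, function(i) rand_aa_seq(sample(30:120, 1)), "")
  whole <- aa_composition(prots)
  part1 <- aa_composition(prots[1:5]); part2 <- aa_composition(prots[6:12])
  w1 <- attr(part1, "counted"); w2 <- attr(part2, "counted")
  blended <- (w1 * unclass(part1) + w2 * unclass(part2)) / (w1 + w2)
  attr(blended, "counted") <- NULL
  cmp <- unclass(whole); attr(cmp, "counted") <- NULL
  expect_equal(cmp, blended, tolerance = 1e-12)
})

test_that("nucleotide content pools bases and excludes N", {
  nc <- nt_content("ATGC")
  expect_equal(nc$gc_percent, 50)
  expect_equal(nc$ag_percent, 50)
  expect_equal(nt_content("GGCC")$gc_percent, 100)
  nc2 <- nt_content("AANT")
  expect_equal(nc2$gc_percent, 0)
  expect_identical(nc2$bases, 3L)
  expect_error(nt_content("NNN"), "no counted")
})

test_that("deviation profiles are centred", {
  m <- rbind(g1 = c(A = 9, I = 4), g2 = c(A = 8, I = 6))
  d <- deviation_profile(m)
  expect_equal(unname(d[, "A"]), c(0.5, -0.5))
  expect_true(all(abs(colSums(d)) < 1e-9))
  expect_equal(unname(deviation_profile(rbind(m[1, ], m[1, ]))[1, ]),
               c(0, 0))
  expect_error(deviation_profile(m[1, , drop = FALSE]), "at least 2")
})

test_that("Welch t handles identity, antisymmetry and degeneracy", {
  x <- c(1, 2, 3, 4)
  w <- welch_t(x, x)
  # identical groups with spread: delta 0, t 0, p 1
  expect_equal(c(w$delta, w$t, w$p), c(0, 0, 1))
  y <- c(5, 7, 6, 9)
  wxy <- welch_t(x, y); wyx <- welch_t(y, x)
  expect_equal(wxy$t, -wyx$t)
  expect_equal(wxy$p, wyx$p)
  expect_equal(wxy$delta, -wyx$delta)
  # zero-variance degenerate cases
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_identical(welch_t(c(3, 3), c(2, 2))$t, Inf)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Welch p agrees with a permutation oracle on shifted groups", {
  set.seed(52)
  x <- rnorm(12); y <- rnorm(12) + 1
  w <- welch_t(x, y)
  expect_equal(w$delta, mean(x) - mean(y))
  expect_lt(w$delta, 0)
  p_perm <- perm_t_p(x, y, B = 4000)
  expect_lt(abs(w$p - p_perm), 0.03)
})

test_that("group contrasts need labels and two genomes per group", {
  s <- small_sim_run(seed = 53, n_genomes = 4, n_core = 20, n_private = 0)
  coll <- s$collection
  coll$meta$habitat <- c("cold", "cold", "warm", "warm")
  ct <- group_compare(coll, "total")
  expect_identical(nrow(ct), 22L)
  expect_true(all(c("GC", "AG") %in% ct$feature))
  expect_equal(ct$delta, ct$mean_cold - ct$mean_warm)
  expect_true(all(ct$p > 0 & ct$p <= 1))

  coll$meta$habitat <- rep("cold", 4)
  expect_error(group_compare(coll, "total"), "2 genomes per habitat")
  coll$meta$habitat <- rep("unlabeled", 4)
  expect_error(group_compare(coll, "total"), "habitat")
})

test_that("duplicating one group as the other zeroes every delta", {
  s <- small_sim_run(seed = 54, n_genomes = 2, n_core = 25, n_private = 0)
  coll <- s$collection
  cds2 <- coll$cds
  cds2$cds_id <- paste0("dup_", cds2$cds_id)
  cds2$genome_id <- sub("G01", "G03", sub("G02", "G04", cds2$genome_id))
  meta <- genome_meta(c("G01", "G02", "G03", "G04"), paste0("sp", 1:4),
                      c("cold", "cold", "warm", "warm"))
  coll2 <- genome_collection(meta, rbind(coll$cds, cds2),
                             list(meta$genome_id), "G01")
  ct <- contrast_table(composition_matrix(coll2, meta$genome_id),
                       setNames(meta$habitat, meta$genome_id))
  expect_true(all(abs(ct$delta) < 1e-12))
  expect_true(all(ct$p == 1))
})

test_that("scope = common restricts pooling to the supplied core ids", {
  s <- small_sim_run(seed = 55, n_genomes = 4, n_core = 20, n_private = 10)
  coll <- s$collection
  coll$meta$habitat <- c("cold", "cold", "warm", "warm")
  core_ids <- coll$cds$cds_id[grepl("_core", coll$cds$cds_id)]
  ct <- group_compare(coll, "common", core_ids = core_ids)
  expect_identical(nrow(ct), 22L)
  expect_error(group_compare(coll, "common"), "core_ids")
})

test_that("GC correlation needs GC spread; degenerate two-genome case", {
  s <- small_sim_run(seed = 56, n_genomes = 3, n_core = 15, n_private = 0)
  coll <- s$collection
  mat <- composition_matrix(coll)
  mat[, "GC"] <- 50
  expect_error(gc_aa_correlation(mat = mat), "zero variance")

  g <- simulate_collection(sim_config_gc_panel(n_genomes = 2,
                                               n_proteins = 60, seed = 57))
  co <- gc_aa_correlation(g$collection)
  expect_true(all(abs(abs(co$by_aa$r) - 1) < 1e-9))
  m2 <- composition_matrix(g$collection)
  dir <- sign(m2[co$order_by_gc[2], co$by_aa$aa] -
              m2[co$order_by_gc[1], co$by_aa$aa])
  expect_identical(sign(co$by_aa$slope), unname(dir))
})
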