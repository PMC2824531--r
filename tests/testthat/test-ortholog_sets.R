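test_that("reciprocal best hits keep mutual pairs and drop asymmetry", {
  row <- function(q, s, e) data.frame(
    qseqid = q, sseqid = s, pident = 90, length = 10L, mismatch = 0L,
    gapopen = 0L, qstart = 1L, qend = 10L, sstart = 1L, send = 10L,
    evalue = e, bitscore = 100)
  ab <- rbind(row("a1", "b1", 1e-40), row("a2", "b1", 1e-30))
  ba <- rbind(row("b1", "a1", 1e-40))
  r <- reciprocal_best_hits(ab, ba)
  expect_identical(r$cds_a, "a1")
  expect_identical(r$cds_b, "b1")

  # a1's best is b1 but b1 points back to a2: a1 stays unpaired
  ba2 <- rbind(row("b1", "a2", 1e-50))
  r2 <- reciprocal_best_hits(ab, ba2)
  expect_false("a1" %in% r2$cds_a)
  expect_identical(r2$cds_a, "a2")   # a2 and b1 are mutual best

  expect_error(reciprocal_best_hits(ab, ba, ids_a = "a1"), "unknown")
})

test_that("RBH matches the exhaustive two-direction oracle", {
  set.seed(21)
  for (rep in 1:30) {
    qa <- paste0("a", 1:sample(3:20, 1))
    qb <- paste0("b", 1:sample(3:20, 1))
    ab <- rand_hits(qa, qb, density = 0.4)
    ba <- rand_hits(qb, qa, density = 0.4)
    got <- reciprocal_best_hits(ab, ba)
    want <- oracle_rbh(ab, ba)
    expect_identical(got$cds_a, want$qseqid)
    expect_identical(got$cds_b, want$sseqid)
    # one-to-one
    expect_false(any(duplicated(got$cds_a)))
    expect_false(any(duplicated(got$cds_b)))
  }
})

test_that("presence is one-way any-hit at the cutoff", {
  h <- data.frame(qseqid = c("x1", "x2"), sseqid = "y", pident = 80,
                  length = 10L, mismatch = 0L, gapopen = 0L, qstart = 1L,
                  qend = 10L, sstart = 1L, send = 10L,
                  evalue = c(1e-30, 1e-5), bitscore = 100)
  pa <- presence_absence(h, c("x1", "x2", "x3"))
  expect_identical(unname(pa), c(TRUE, FALSE, FALSE))
  # more permissive cutoff never shrinks presence
  pa2 <- presence_absence(h, c("x1", "x2", "x3"), cutoff = 1e-4)
  expect_true(all(pa2 >= pa))
})

test_that("conservation matrix counts and formats per query genome", {
  s <- small_sim_run(seed = 22, n_genomes = 3, n_core = 5, n_private = 2,
                     mean_len = 80)
  coll <- s$collection
  hits <- compute_focal_hits(coll, pipeline_config(
    sim = sim_config(seed = 1), outdir = tempfile()))
  ct <- conservation_table(coll, hits, queries = coll$focal,
                           targets = coll$hierarchy[[1]])
  expect_identical(ct$counts["G01", "G01"], 7L)   # diagonal = total CDS
  expect_equal(ct$percent["G01", "G01"], 100)
  expect_identical(ct$counts["G02", "G01"], 5L)   # core only
  expect_match(ct$pretty["G02", "G01"], "^5 \\(71.4\\)$")
})

test_that("nested partition agrees with brute force on random collections", {
  set.seed(23)
  for (rep in 1:25) {
    n_genomes <- sample(3:5, 1)
    gids <- paste0("g", seq_len(n_genomes))
    n_cds <- sample(10:50, 1)
    ids <- setNames(lapply(gids, function(g)
      paste0(g, "_c", seq_len(n_cds))), gids)
    hierarchy <- list(gids, gids[1:2])
    meta <- genome_meta(gids, gids)
    cds <- data.frame(cds_id = unlist(ids),
                      genome_id = rep(gids, each = n_cds),
                      nt_seq = NA_character_, aa_seq = "M")
    coll <- genome_collection(meta, cds, hierarchy, "g1")
    hits <- list()
    for (g in gids[-1]) {
      hits[[paste0("g1->", g)]] <- rand_hits(ids$g1, ids[[g]], 0.15)
      hits[[paste0(g, "->g1")]] <- rand_hits(ids[[g]], ids$g1, 0.15)
    }
    rbh <- setNames(lapply(gids[-1], function(g)
      reciprocal_best_hits(hits[[paste0("g1->", g)]],
                           hits[[paste0(g, "->g1")]])), gids[-1])
    part <- nested_partition(coll, rbh)
    # disjoint + exhaustive + sizes sum to total
    expect_setequal(names(part$labels), ids$g1)
    expect_false(anyNA(part$labels))
    expect_identical(sum(part$counts), part$total_cds)
    # exact agreement with the raw-hit oracle
    want <- oracle_partition(ids$g1, hierarchy, "g1", hits)
    expect_identical(part$labels[names(want)], want)
  }
})

test_that("core set requires a partner in every other genome", {
  rbh <- list(
    g2 = data.frame(cds_a = c("g1_a", "g1_b"), cds_b = c("g2_a", "g2_b")),
    g3 = data.frame(cds_a = "g1_a", cds_b = "g3_a"))
  meta <- genome_meta(c("g1", "g2", "g3"), c("g1", "g2", "g3"))
  cds <- data.frame(cds_id = c("g1_a", "g1_b"), genome_id = "g1",
                    nt_seq = NA_character_, aa_seq = "M")
  coll <- genome_collection(meta, cds, list(c("g1", "g2", "g3")), "g1")
  expect_identical(core_set(coll, rbh), "g1_a")
  expect_error(core_set(coll, rbh["g2"]), "g3")
})

test_that("nested-set arithmetic applies the sequential deductions", {
  # cumulative shared counts: core, clade, closest partner
  res <- partition_arithmetic(4278, c(1814, 2665, 3588))
  expect_identical(res$core, 1814)
  expect_identical(res$nc, 2464)
  expect_identical(res$level_sizes, c(851, 923))
  expect_identical(res$remainder, 690)
  expect_error(partition_arithmetic(100, c(50, 40)), "non-decreasing")
  expect_error(partition_arithmetic(100, c(50, 120)), "exceed")
})
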