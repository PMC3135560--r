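test_that("config validation catches infeasible worlds", {
  expect_error(sim_config(gc_target = 0.9), "feasible")
  expect_error(sim_config(gc_target = 0.1), "feasible")
  expect_error(sim_config(spacer_len_range = c(2, 10)))
  expect_error(sim_config(fragment_len = 100, fragment_overlap = 200))
  expect_error(sim_config(n_families = 5, family_rates = c(1, 2)))
})

test_that("identical seeds give byte-identical datasets; seeds matter", {
  cfg <- sim_config(n_genomes = 3, n_families = 4, seed = 5)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(lapply(a$genomes, `[[`, "residues"),
                   lapply(b$genomes, `[[`, "residues"))
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$truth$orthology, b$truth$orthology)
  expect_identical(ape::write.tree(a$truth$tree),
                   ape::write.tree(b$truth$tree))
  c3 <- simulate_dataset(sim_config(n_genomes = 3, n_families = 4,
                                    seed = 6))
  expect_false(identical(a$genomes[[1]]$residues,
                         c3$genomes[[1]]$residues))
})

test_that("zero branch lengths give identical protein sets and
           one cluster per family", {
  tree <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  # length ratios are kept below ~3: under the shorter-sequence
  # denominator a very short random gene can spuriously exceed 40%
  # similarity against a long one, so the one-cluster-per-family claim
  # needs comparable lengths (see the methods vignette)
  cfg <- sim_config(n_genomes = 4, n_families = 5, tree = tree, seed = 9,
                    family_lengths = c(450L, 350L, 180L, 160L, 150L))
  sim <- simulate_dataset(cfg)
  byfam <- split(sim$proteins$aa_seq, sim$proteins$gene_id)
  for (fam in byfam) expect_length(unique(fam), 1L)
  cl <- greedy_cluster(sim$proteins, 0.40)
  expect_length(cl$clusters, 5L)
})

test_that("realized identity matches the closed-form expectation", {
  # two leaves at path distance 0.8: E[id] = exp(-0.8) + (1-exp(-0.8))/20
  tree <- ape::read.tree(text = "(a:0.4,b:0.4);")
  ids <- c()
  for (sd in 1:3) {
    cfg <- sim_config(n_genomes = 2, n_families = 2, tree = tree,
                      family_lengths = c(500L, 500L), seed = sd)
    sim <- simulate_dataset(cfg)
    for (fam in split(sim$proteins$aa_seq, sim$proteins$gene_id)) {
      v1 <- strsplit(fam[1], "")[[1]]; v2 <- strsplit(fam[2], "")[[1]]
      ids <- c(ids, mean(v1 == v2))
    }
  }
  expect_lt(abs(mean(ids) - expected_identity(0.8)), 0.03)
})

test_that("realized GC tracks the target within 2 points over 20 seeds", {
  gcs <- vapply(1:20, function(sd) {
    sim <- simulate_dataset(sim_config(n_genomes = 2, n_families = 6,
                                       seed = 100 + sd))
    mean(vapply(sim$genomes, function(g) composition(g)$gc_fraction,
                numeric(1)))
  }, numeric(1))
  expect_true(all(abs(gcs - 0.40) <= 0.02))
})

test_that("genome sizes land in the small-phage range and genes tile them", {
  sim <- simulate_dataset(sim_config(n_genomes = 3, seed = 42))
  lens <- vapply(sim$genomes, function(g) g$length, numeric(1))
  expect_true(all(lens > 3000 & lens < 9000))
  co <- sim$truth$coordinates
  for (gid in names(sim$genomes)) {
    g <- sim$genomes[[gid]]
    rows <- co[co$genome_id == gid, ]
    for (r in seq_len(nrow(rows))) {
      nt <- substr(g$residues, rows$start[r], rows$end[r])
      aa <- sim$proteins$aa_seq[sim$proteins$genome_id == gid &
                                  sim$proteins$gene_id == rows$gene_id[r]]
      expect_equal(phagecg:::translate_nt(substr(nt, 1, nchar(nt) - 3)),
                   aa)
    }
  }
})

test_that("orf_caller recovers at least 95% of truth coordinates", {
  hits <- 0; tot <- 0
  for (sd in 1:3) {
    sim <- simulate_dataset(sim_config(n_genomes = 2, seed = 200 + sd))
    for (gid in names(sim$genomes)) {
      o <- find_orfs(sim$genomes[[gid]])$records
      co <- sim$truth$coordinates
      co <- co[co$genome_id == gid, ]
      tot <- tot + nrow(co)
      hits <- hits + sum(mapply(function(s, e)
        any(o$start == s & o$end == e & o$strand == "+"),
        co$start, co$end))
    }
  }
  expect_gte(hits / tot, 0.95)
})

test_that("shred tiles the circle with the stated overlap structure", {
  set.seed(45)
  g <- circ_seq("g", random_dna(5514))
  sh <- shred(g, fragment_len = 1000, step = 750, seed = 2)
  expect_length(sh$fragments, 8L)
  expect_true(all(nchar(sh$fragments) == 1000))
  # neighbours overlap by 250 nt exactly (oriented back to "+")
  dbl <- paste0(g$residues, g$residues)
  plus <- vapply(seq_along(sh$fragments), function(i) {
    fr <- sh$fragments[[i]]
    if (sh$layout$strand[i] == "-") revcomp(fr) else fr
  }, "")
  for (i in 1:7)
    expect_equal(substr(plus[i], 751, 1000), substr(plus[i + 1], 1, 250))
  # conservation: unioned fragment span covers the genome exactly once
  expect_equal(sh$layout$offset, seq(1, 5514, by = 750))

  expect_equal(nchar(shred(g, 5514, 5000, seed = 1)$fragments[[1]]),
               5514L)
  expect_error(shred(g, 6000, 700), "exceeds")
  expect_error(shred(g, 500, 600), "step")
})

test_that("tetra R2 nearest matches the true nearest leaf in the
           well-separated world (10 seeds, >= 80%)", {
  tot <- 0; ok <- 0
  for (sd in 1:10) {
    sim <- simulate_dataset(clade_world(sd))
    sm <- pairwise_r2(unname(lapply(sim$genomes, tetra_zscores)))
    pd <- ape::cophenetic.phylo(sim$truth$tree)
    for (g in names(sim$genomes)) {
      others <- setdiff(colnames(pd), g)
      near <- setdiff(names(which(pd[g, ] == min(pd[g, others]))), g)
      tot <- tot + 1
      ok <- ok + (sm$nearest[g] %in% near)
    }
  }
  expect_gte(ok / tot, 0.80)
})
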