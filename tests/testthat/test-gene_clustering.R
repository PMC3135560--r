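prot_df <- function(genome, genes, seqs) {
  data.frame(genome_id = genome, gene_id = genes, aa_seq = seqs)
}

# derive a protein at a given point identity from a template (no indels)
mutate_protein <- function(aa, identity) {
  v <- strsplit(aa, "")[[1]]
  n <- length(v)
  k <- round((1 - identity) * n)
  idx <- sample(n, k)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  v[idx] <- vapply(v[idx], function(x) sample(setdiff(alpha, x), 1), "")
  paste(v, collapse = "")
}

test_that("identical sequences form one cluster; basic errors raised", {
  set.seed(61)
  a <- random_protein(60)
  cl <- greedy_cluster(prot_df(c("g1", "g2", "g3"), c("x", "x", "x"), a))
  expect_length(cl$clusters, 1L)
  expect_length(cl$clusters[[1]]$members, 3L)
  expect_error(greedy_cluster(prot_df("g", c("a", "a"),
                                      c(a, a))), "duplicate")
  expect_error(greedy_cluster(prot_df("g", "a", a), threshold = 0),
               "threshold")
  expect_error(greedy_cluster(prot_df(character(), character(),
                                      character())), "empty")
})

test_that("the threshold is strict: boundary similarity founds a cluster", {
  # B matches A at exactly 4 of 10 positions and cannot realign better:
  # similarity 0.40 is not > 0.40
  a <- "MAAAAAAAAA"
  b <- "MWWWWWWAAA"
  r <- global_align(a, b)
  expect_equal(r$n_identical, 4L)
  cl <- greedy_cluster(prot_df("g", c("a", "b"), c(a, b)),
                       threshold = 0.40)
  expect_length(cl$clusters, 2L)
  # just above the boundary they merge
  cl2 <- greedy_cluster(prot_df("g", c("a", "b"), c(a, b)),
                        threshold = 0.39)
  expect_length(cl2$clusters, 1L)
})

test_that("clustering recovers generator families and matches the
           exhaustive-matrix oracle", {
  set.seed(62)
  fams <- lapply(1:4, function(i) random_protein(sample(80:120, 1)))
  rows <- list()
  for (g in 1:5) for (f in 1:4)
    rows[[length(rows) + 1L]] <- prot_df(
      sprintf("g%d", g), sprintf("f%d", f),
      mutate_protein(fams[[f]], identity = 0.72))
  prot <- do.call(rbind, rows)
  cl <- greedy_cluster(prot, 0.40)
  truth <- rep(1:4, times = 5)
  expect_equal(ari(cl$assignments$cluster,
                   truth[match(cl$assignments$key,
                               protein_keys(prot))]), 1.0)

  # oracle: same greedy rule driven by an explicit similarity matrix
  keys <- protein_keys(prot)
  n <- nrow(prot)
  sim <- matrix(0, n, n, dimnames = list(keys, keys))
  for (i in 1:n) for (j in 1:n) {
    if (i == j) { sim[i, j] <- 1; next }
    r <- global_align(prot$aa_seq[i], prot$aa_seq[j])
    sim[i, j] <- r$n_identical / min(nchar(prot$aa_seq[i]),
                                     nchar(prot$aa_seq[j]))
  }
  want <- oracle_greedy_from_matrix(keys, nchar(prot$aa_seq), sim, 0.40)
  got <- setNames(cl$assignments$cluster, cl$assignments$key)[keys]
  expect_equal(ari(got, want), 1.0)
})

test_that("partition property and threshold monotonicity hold", {
  set.seed(63)
  fams <- lapply(1:3, function(i) random_protein(100))
  rows <- list()
  for (g in 1:4) for (f in 1:3)
    rows[[length(rows) + 1L]] <- prot_df(
      sprintf("g%d", g), sprintf("f%d", f),
      mutate_protein(fams[[f]], identity = runif(1, 0.45, 0.9)))
  prot <- do.call(rbind, rows)
  sizes <- integer(0)
  for (th in c(0.3, 0.4, 0.5, 0.6)) {
    cl <- greedy_cluster(prot, th)
    members <- unlist(lapply(cl$clusters, `[[`, "members"))
    expect_setequal(members, protein_keys(prot))      # cover
    expect_equal(anyDuplicated(members), 0L)          # disjoint
    # representatives are the longest member of their cluster
    for (c0 in cl$clusters) {
      lens <- nchar(prot$aa_seq[match(c0$members, protein_keys(prot))])
      expect_equal(nchar(prot$aa_seq[match(c0$representative,
                                           protein_keys(prot))]),
                   max(lens))
    }
    sizes <- c(sizes, length(cl$clusters))
  }
  expect_true(all(diff(sizes) >= 0))
})

test_that("membership matrix counts, permutes and binarizes correctly", {
  set.seed(64)
  prot <- rbind(prot_df("g1", c("a", "b", "c"),
                        vapply(1:3, function(i) random_protein(50), "")),
                prot_df("g2", "a", random_protein(50)))
  cl <- greedy_cluster(prot, 0.4)
  m <- membership_matrix(cl, c("g1", "g2"))
  expect_equal(rowSums(m), c(g1 = 3, g2 = 1))
  expect_equal(sum(m), nrow(prot))
  sizes <- vapply(cl$clusters, function(x) length(x$members), integer(1))
  expect_equal(unname(colSums(m)), sizes)
  # permuting genome order permutes rows identically
  m2 <- membership_matrix(cl, c("g2", "g1"))
  expect_equal(m2, m[c("g2", "g1"), ])
  mb <- membership_matrix(cl, c("g1", "g2"), binarize = TRUE)
  expect_true(all(mb %in% 0:1))
  expect_equal(mb > 0, m > 0)
  expect_error(membership_matrix(cl, "g1"), "not in")
})

test_that("clstr-style output lists every member once", {
  set.seed(65)
  prot <- prot_df("g1", letters[1:4],
                  vapply(1:4, function(i) random_protein(40), ""))
  cl <- greedy_cluster(prot, 0.4)
  f <- withr::local_tempfile()
  write_clstr(cl, f)
  ln <- readLines(f)
  expect_equal(sum(startsWith(ln, ">Cluster")), length(cl$clusters))
  expect_equal(sum(!startsWith(ln, ">Cluster")), nrow(prot))
})
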