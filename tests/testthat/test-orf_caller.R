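# padding for constructed cases: CCA repeats contain no start or stop
# codon in any frame, and their reverse complement (TGG repeats) contains
# no ATG and no stop either
pad <- function(n) substr(strrep("CCA", ceiling(n / 3) + 1L), 1L, n)

test_that("a constructed single-ORF circle yields exactly that ORF", {
  s <- circ_seq("x", paste0("ATGAAATAA", pad(91)))
  o <- find_orfs(s, min_nt = 9)
  expect_equal(nrow(o$records), 1L)
  expect_equal(o$records$aa_seq, "MK")
  expect_equal(o$records$aa_length, 2L)
  expect_equal(o$records$nt_length, 9L)
  expect_equal(o$records$start, 1L)
  expect_equal(o$records$end, 9L)
  expect_equal(o$records$strand, "+")
})

test_that("wraparound ORFs are found with modular coordinates", {
  # place the ORF so it spans the origin: last 6 nt then first 3 nt
  core <- "ATGAAATAA"
  s <- circ_seq("w", paste0(substr(core, 7, 9), pad(91),
                            substr(core, 1, 6)))
  o <- find_orfs(s, min_nt = 9)
  expect_equal(nrow(o$records), 1L)
  expect_equal(o$records$aa_seq, "MK")
  expect_equal(o$records$start, 95L)
  expect_equal(o$records$end, 3L)  # end < start marks the wrap
  # linear topology must not find it
  s_lin <- circ_seq("w", s$residues, "linear")
  expect_equal(nrow(find_orfs(s_lin, min_nt = 9)$records), 0L)
})

test_that("ORF calls equal the exhaustive modular-arithmetic oracle", {
  for (sd in 1:6) {
    set.seed(300 + sd)
    s <- random_dna(600)
    got <- find_orfs(circ_seq("g", s), min_nt = 60)$records
    want <- oracle_find_orfs(s, circular = TRUE, min_nt = 60)
    expect_equal(got[c("start", "end", "strand", "nt_length")],
                 want, ignore_attr = TRUE)
    # linear mode agrees too
    got_l <- find_orfs(circ_seq("g", s, "linear"), min_nt = 60)$records
    want_l <- oracle_find_orfs(s, circular = FALSE, min_nt = 60)
    if (is.null(want_l)) {
      expect_equal(nrow(got_l), 0L)
    } else {
      expect_equal(got_l[c("start", "end", "strand", "nt_length")],
                   want_l, ignore_attr = TRUE)
    }
  }
})

test_that("ORF calling is rotation-invariant and strand-symmetric", {
  set.seed(333)
  s <- random_dna(600)
  base <- find_orfs(circ_seq("g", s), min_nt = 60)$records
  key <- function(df) {
    k <- paste(df$start, df$end, df$strand)
    sort(k)
  }
  L <- 600L
  for (k in c(1, 57, 299, 600)) {
    rot <- canonicalize(circ_seq("g", s), k)
    got <- find_orfs(rot, min_nt = 60)$records
    # map rotated coordinates back: position p' in rotation is
    # p = ((p' - 1 + k - 1) mod L) + 1
    back <- got
    back$start <- ((got$start - 1L + k - 1L) %% L) + 1L
    back$end <- ((got$end - 1L + k - 1L) %% L) + 1L
    expect_equal(key(back), key(base))
  }
  rc <- find_orfs(circ_seq("g", revcomp(s)), min_nt = 60)$records
  mirrored <- data.frame(start = (L - rc$end) %% L + 1L,
                         end = (L - rc$start) %% L + 1L,
                         strand = ifelse(rc$strand == "+", "-", "+"))
  expect_equal(sort(paste(mirrored$start, mirrored$end, mirrored$strand)),
               key(base))
})

test_that("reported translations reproduce themselves from genome slices", {
  set.seed(71)
  s <- random_dna(900)
  seqobj <- circ_seq("g", s)
  o <- find_orfs(seqobj, min_nt = 90)
  d <- paste0(s, s)
  rcd <- paste0(revcomp(s), revcomp(s))
  for (r in seq_len(nrow(o$records))) {
    rec <- o$records[r, ]
    if (rec$strand == "+") {
      nt <- substr(d, rec$start, rec$start + rec$nt_length - 1L)
    } else {
      p <- 900L - rec$end + 1L
      nt <- substr(rcd, p, p + rec$nt_length - 1L)
    }
    aa <- phagecg:::translate_nt(substr(nt, 1, rec$nt_length - 3L))
    expect_equal(aa, rec$aa_seq)
    expect_equal(rec$nt_length, 3L * (rec$aa_length + 1L))
    expect_false(grepl("*", rec$aa_seq, fixed = TRUE))
  }
})

test_that("coding capacity: union equals a position bitmap and is bounded", {
  set.seed(77)
  s <- random_dna(600)
  o <- find_orfs(circ_seq("g", s), min_nt = 60)
  cc_union <- coding_capacity(o, 600, mode = "union")
  # independent bitmap oracle
  hit <- logical(600)
  for (r in seq_len(nrow(o$records))) {
    rec <- o$records[r, ]
    pos <- if (rec$start <= rec$end) rec$start:rec$end else
      c(rec$start:600, 1:rec$end)
    hit[pos] <- TRUE
  }
  expect_equal(cc_union, 100 * mean(hit))
  expect_lte(cc_union, 100)
  # union capacity is monotone as ORFs are added
  caps <- vapply(seq_len(nrow(o$records)), function(k) {
    sub <- structure(list(genome_id = "g",
                          records = o$records[seq_len(k), ]),
                     class = "orf_set")
    coding_capacity(sub, 600, mode = "union")
  }, numeric(1))
  expect_true(all(diff(caps) >= 0))
  empty <- structure(list(genome_id = "g",
                          records = o$records[0, ]), class = "orf_set")
  expect_equal(coding_capacity(empty, 600), 0)
})

test_that("GFF3 round trip preserves ORF records, including wraps", {
  s <- circ_seq("w", paste0(substr("ATGAAATAA", 7, 9), pad(121),
                            "ATGCATAAATCCTAA", pad(40),
                            substr("ATGAAATAA", 1, 6)))
  o <- find_orfs(s, min_nt = 9)
  expect_gte(nrow(o$records), 2L)
  f <- withr::local_tempfile()
  write_orfs_gff3(o, s$length, f)
  back <- read_orfs_gff3(f)
  expect_equal(back$genome_id, o$genome_id)
  expect_equal(back$records, o$records)
})
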