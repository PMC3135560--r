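# Independent oracles used across the suite. These deliberately share no
# code with the package: explicit-loop dynamic programming, modular
# arithmetic ORF enumeration, literal-formula tetramer statistics. They are
# slow and only run on tiny inputs.

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

# --- affine-gap DP oracles (three-matrix recurrences, explicit loops) ----

# global, end gaps penalized; gap of length L costs open + L * ext
oracle_nw_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (a residue over gap)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[av[i], bv[j]]
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# local (Smith-Waterman): clamp states at 0, best over all cells
oracle_sw_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); M[1, ] <- 0; M[, 1] <- 0
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- mat[av[i], bv[j]]
    M[i + 1, j + 1] <- max(0, s + max(M[i, j], X[i, j], Y[i, j]))
    X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext, X[i, j + 1] - ext,
                           Y[i, j + 1] - open - ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext, Y[i + 1, j] - ext,
                           X[i + 1, j] - open - ext)
    best <- max(best, M[i + 1, j + 1])
  }
  best
}

# --- tetranucleotide oracle: literal window loops, modular indexing ------

oracle_kmer_counts <- function(s, k, circular) {
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  lim <- if (circular) L else L - k + 1L
  counts <- new.env()
  for (i in seq_len(max(lim, 0L))) {
    w <- paste(v[((i - 1L + 0:(k - 1L)) %% L) + 1L], collapse = "")
    if (grepl("N", w, fixed = TRUE)) next
    counts[[w]] <- (if (is.null(counts[[w]])) 0L else counts[[w]]) + 1L
  }
  out <- setNames(numeric(length(mget(ls(counts), counts))),
                  ls(counts))
  for (w in ls(counts)) out[w] <- counts[[w]]
  out
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

oracle_tetra_z <- function(s, circular = TRUE) {
  get0n <- function(tab, w) if (w %in% names(tab)) tab[[w]] else 0
  both <- function(k) {
    a <- oracle_kmer_counts(s, k, circular)
    b <- oracle_kmer_counts(oracle_revcomp(s), k, circular)
    keys <- union(names(a), names(b))
    setNames(vapply(keys, function(w) get0n(a, w) + get0n(b, w),
                    numeric(1)), keys)
  }
  n2 <- both(2L); n3 <- both(3L); n4 <- both(4L)
  bases <- c("A", "C", "G", "T")
  tets <- apply(expand.grid(bases, bases, bases, bases), 1L,
                function(r) paste(rev(r), collapse = ""))
  tets <- sort(tets)
  z <- setNames(numeric(256), tets)
  for (w in tets) {
    l3 <- substr(w, 1, 3); r3 <- substr(w, 2, 4); m2 <- substr(w, 2, 3)
    Nm <- get0n(n2, m2)
    if (Nm == 0) next
    Nl <- get0n(n3, l3); Nr <- get0n(n3, r3)
    E <- Nl * Nr / Nm
    v <- E * (1 - Nl / Nm) * (1 - Nr / Nm)
    if (E > 0 && v > 0) z[w] <- (get0n(n4, w) - E) / sqrt(v)
  }
  z
}

# --- ORF oracle: enumerate (position, frame via start, strand) by -------
# explicit modular arithmetic on the original string

oracle_find_orfs <- function(residues, circular, min_nt,
                             start_codons = "ATG") {
  gc11 <- Biostrings::getGeneticCode("11")
  stops <- names(gc11)[gc11 == "*"]
  L <- nchar(residues)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") residues else oracle_revcomp(residues)
    v <- strsplit(s, "")[[1]]
    codon_at <- function(p) paste(v[((p - 1L + 0:2) %% L) + 1L],
                                  collapse = "")
    for (p in seq_len(L)) {
      if (!circular && p + 2L > L) next
      if (!(codon_at(p) %in% start_codons)) next
      nt <- NA
      q <- p
      for (step in seq_len(ceiling(L / 3))) {
        if (!circular && q + 2L > L) break
        if (codon_at(q) %in% stops) { nt <- q + 3L - p; break }
        q <- q + 3L
      }
      if (is.na(nt) || nt < min_nt || nt > L) next
      stop_key <- ((p + nt - 3L - 1L) %% L)
      res[[length(res) + 1L]] <- list(p = p, nt = nt, strand = strand,
                                      stop_key = paste(strand, stop_key))
    }
  }
  if (!length(res)) return(NULL)
  # longest ORF per stop
  keys <- vapply(res, `[[`, character(1), "stop_key")
  keep <- unlist(lapply(split(seq_along(res), keys), function(ix)
    ix[which.max(vapply(res[ix], `[[`, numeric(1), "nt"))]))
  rows <- lapply(res[sort(keep)], function(r) {
    if (r$strand == "+") {
      g1 <- r$p; g2 <- (r$p + r$nt - 2L) %% L + 1L
    } else {
      g1 <- (L - ((r$p + r$nt - 2L) %% L + 1L)) %% L + 1L
      g2 <- L - r$p + 1L
    }
    data.frame(start = g1, end = g2, strand = r$strand, nt_length = r$nt)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# --- misc ---------------------------------------------------------------

# adjusted Rand index between two label vectors
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c2 <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * c2 / choose(n, 2)
  (a - e) / ((b + c2) / 2 - e)
}

# greedy clustering replayed from an explicit similarity matrix (the same
# rule as the package, but driven by a precomputed matrix in plain loops)
oracle_greedy_from_matrix <- function(keys, lens, sim, threshold) {
  ord <- order(-lens, keys)
  reps <- integer(0)
  assign <- setNames(integer(length(keys)), keys)
  for (i in ord) {
    best <- 0L; best_s <- -Inf
    for (ci in seq_along(reps)) {
      s <- sim[keys[i], keys[reps[ci]]]
      if (s > best_s) { best_s <- s; best <- ci }
    }
    if (best > 0L && best_s > threshold) {
      assign[keys[i]] <- best
    } else {
      reps <- c(reps, i)
      assign[keys[i]] <- length(reps)
    }
  }
  assign
}

# well-separated-clade world shared by the parameter-recovery tests:
# 5 clades of 3 tips; cherries join at height 0.15, the third tip at 0.7,
# clades join along a ladder at heights 2.0, 2.9, 4.2, 6.0. Family rate
# tiers are chosen so every between-merge distance is resolved by some
# family at the 0.40 clustering horizon with a wide identity margin.
clade_world <- function(seed) {
  clade <- function(i) {
    t <- sprintf("t%02d", (i - 1) * 3 + 1:3)
    sprintf("((%s:0.15,%s:0.15):0.55,%s:0.7)", t[1], t[2], t[3])
  }
  nwk <- sprintf("((((%s:1.3,%s:1.3):0.9,%s:2.2):1.3,%s:3.5):1.8,%s:5.3);",
                 clade(1), clade(2), clade(3), clade(4), clade(5))
  tree <- ape::read.tree(text = nwk)
  sim_config(n_genomes = 15L, n_families = 9L, tree = tree,
             family_rates = c(1.67, 1.67, 0.42, 0.42, 0.42,
                              0.204, 0.143, 0.143, 0.1),
             family_lengths = c(300L, 280L, 320L, 260L, 300L,
                                340L, 300L, 320L, 280L),
             seed = seed)
}
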