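# Tetranucleotide usage signatures. Observed 4-mer counts are normalized
# against a maximal-order Markov expectation built from 3-mer and 2-mer
# counts; the z-scores form a 256-element genome fingerprint compared
# between genomes by the squared Pearson correlation (regression R^2) of
# the two z-vectors. Counting follows the TETRA convention: the sequence
# and its reverse complement are counted independently (no chimeric words
# at a junction), which makes the profile strand-invariant by construction
# -- appropriate for ssDNA genomes compared via their replicative form.

all_kmers <- function(k) {
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE)[k:1])
}

# k-mer counts of one oriented string; circular counting appends the first
# k-1 bases so wraparound windows are included. Windows containing N are
# simply never counted (they form no ACGT word).
count_kmers_oriented <- function(s, k, circular) {
  if (circular) s <- paste0(s, substr(s, 1L, k - 1L))
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(s),
                                              width = k)
  cnt[sort(names(cnt))]
}

count_kmers_bothstrands <- function(seq, k, circular) {
  count_kmers_oriented(seq$residues, k, circular) +
    count_kmers_oriented(revcomp(seq$residues), k, circular)
}

#' Tetranucleotide z-score profile of a genome
#'
#' For each tetramer `n1 n2 n3 n4`, the expected count under the
#' maximal-order Markov model is
#' `E = N(n1 n2 n3) * N(n2 n3 n4) / N(n2 n3)` with variance
#' `var = E * (1 - N(n1 n2 n3)/N(n2 n3)) * (1 - N(n2 n3 n4)/N(n2 n3))`,
#' and `z = (N - E) / sqrt(var)`; degenerate divisors (`E = 0` or
#' `var <= 0`) give `z = 0`.
#'
#' @param seq a [circ_seq] of length >= 7.
#' @param mode `"zscore"` (default) or `"rawfreq"` (plain 4-mer
#'   frequencies summing to 1, for sensitivity analysis).
#' @return object of class `tetra_profile`: `genome_id`, `z` (named
#'   numeric, 256 tetramers in lexicographic order), `counts` (raw
#'   both-strand tetramer counts).
#' @export
tetra_zscores <- function(seq, mode = c("zscore", "rawfreq")) {
  mode <- match.arg(mode)
  stopifnot(is(seq, "circ_seq"))
  if (seq$length < 7L) stop("sequence shorter than 7 nt")
  circular <- seq$topology == "circular"
  n2 <- count_kmers_bothstrands(seq, 2L, circular)
  n3 <- count_kmers_bothstrands(seq, 3L, circular)
  n4 <- count_kmers_bothstrands(seq, 4L, circular)
  w <- names(n4)
  if (mode == "rawfreq") {
    z <- if (sum(n4) > 0) n4 / sum(n4) else n4 * 0
  } else {
    left <- substr(w, 1L, 3L)
    right <- substr(w, 2L, 4L)
    mid <- substr(w, 2L, 3L)
    Nl <- n3[left]; Nr <- n3[right]; Nm <- n2[mid]
    E <- ifelse(Nm > 0, Nl * Nr / Nm, 0)
    v <- ifelse(Nm > 0, E * (1 - Nl / Nm) * (1 - Nr / Nm), 0)
    z <- ifelse(E > 0 & v > 0, (n4 - E) / sqrt(v), 0)
  }
  names(z) <- w
  structure(list(genome_id = seq$id, z = z, counts = n4),
            class = "tetra_profile")
}

#' Pairwise R-squared matrix of tetranucleotide profiles
#'
#' @param profiles list of `tetra_profile` objects with matching key sets.
#' @return object of class `similarity_matrix`: `genome_ids`, `r2`
#'   (symmetric matrix of squared Pearson correlations, unit diagonal),
#'   `nearest` (named character: per genome, the highest-R^2 partner).
#' @export
pairwise_r2 <- function(profiles) {
  stopifnot(length(profiles) >= 2L)
  ids <- vapply(profiles, function(p) p$genome_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate genome ids")
  keys <- names(profiles[[1]]$z)
  Z <- t(vapply(profiles, function(p) {
    stopifnot(identical(sort(names(p$z)), sort(keys)))
    unname(p$z[keys])
  }, numeric(length(keys))))
  sds <- apply(Z, 1L, stats::sd)
  if (any(sds == 0))
    stop("constant z-vector for genome(s): ",
         paste(ids[sds == 0], collapse = ", "))
  r2 <- stats::cor(t(Z))^2
  diag(r2) <- 1
  dimnames(r2) <- list(ids, ids)
  nearest <- vapply(seq_along(ids), function(i) {
    ids[-i][which.max(r2[i, -i])]
  }, character(1))
  names(nearest) <- ids
  structure(list(genome_ids = ids, r2 = r2, nearest = nearest),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d genomes; nearest matches:\n",
              length(x$genome_ids)))
  for (g in x$genome_ids)
    cat(sprintf("  %s -> %s (R2 = %.2f)\n", g, x$nearest[g],
                x$r2[g, x$nearest[g]]))
  invisible(x)
}
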