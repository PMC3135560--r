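# Greedy incremental protein clustering at a similarity threshold, the
# CD-HIT strategy: sequences are processed longest first; each is compared
# against all existing cluster representatives by optimal global alignment
# and joins the best-matching representative whose similarity strictly
# exceeds the threshold, otherwise it founds a new cluster. No short-word
# prefilter is used -- input sets here are tiny (~150 proteins) so
# exactness wins over speed.

#' Canonical `genome:gene` keys of a protein table
#' @param proteins data.frame with columns genome_id and gene_id.
#' @return character vector of `genome_id:gene_id` keys.
#' @export
protein_keys <- function(proteins) {
  paste(proteins$genome_id, proteins$gene_id, sep = ":")
}

check_protein_df <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("genome_id", "gene_id", "aa_seq") %in% names(proteins)))
  if (!nrow(proteins)) stop("empty protein set")
  k <- protein_keys(proteins)
  if (anyDuplicated(k))
    stop("duplicate (genome_id, gene_id) keys: ",
         paste(unique(k[duplicated(k)]), collapse = ", "))
  invisible(k)
}

# similarity of one sequence against a set of representatives, vectorized
# through pairwiseAlignment; identical inputs score 1 by construction
rep_similarities <- function(aa, reps_aa, similarity_def) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(reps_aa), Biostrings::AAStringSet(aa)[[1]],
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5)
  nid <- Biostrings::nmatch(pa)
  if (similarity_def == "shorter") {
    nid / pmin(nchar(reps_aa), nchar(aa))
  } else {
    nid / nchar(Biostrings::alignedPattern(pa))
  }
}

#' Greedy incremental clustering of protein sequences
#'
#' @param proteins data.frame with columns genome_id, gene_id, aa_seq.
#' @param threshold similarity threshold in (0, 1] (default 0.40). The
#'   cutoff is strict: a member's similarity to its representative must
#'   exceed `threshold`; boundary equality founds a new cluster.
#' @param similarity_def `"shorter"` (identities in the optimal global
#'   alignment divided by the shorter sequence length, the CD-HIT
#'   convention; default) or `"columns"` (divided by alignment columns).
#' @return object of class `clustering`: `clusters` (list of
#'   `list(representative, members)`, members include the representative),
#'   `threshold`, and `assignments` (data.frame key, genome_id, gene_id,
#'   cluster, similarity_to_rep).
#' @export
greedy_cluster <- function(proteins, threshold = 0.40,
                           similarity_def = c("shorter", "columns")) {
  similarity_def <- match.arg(similarity_def)
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  keys <- check_protein_df(proteins)
  ord <- order(-nchar(proteins$aa_seq), keys)
  proteins <- proteins[ord, , drop = FALSE]
  keys <- keys[ord]

  rep_aa <- character(0)     # representative sequences, by cluster
  rep_key <- character(0)
  cluster_of <- integer(nrow(proteins))
  sim_of <- numeric(nrow(proteins))
  for (i in seq_len(nrow(proteins))) {
    aa <- proteins$aa_seq[i]
    assigned <- 0L
    if (length(rep_aa)) {
      sims <- rep_similarities(aa, rep_aa, similarity_def)
      best <- which.max(sims)
      if (sims[best] > threshold) {
        assigned <- best
        sim_of[i] <- sims[best]
      }
    }
    if (assigned == 0L) {
      rep_aa <- c(rep_aa, aa)
      rep_key <- c(rep_key, keys[i])
      assigned <- length(rep_aa)
      sim_of[i] <- 1
    }
    cluster_of[i] <- assigned
  }

  clusters <- lapply(seq_along(rep_key), function(ci)
    list(representative = rep_key[ci], members = keys[cluster_of == ci]))
  assignments <- data.frame(key = keys, genome_id = proteins$genome_id,
                            gene_id = proteins$gene_id,
                            cluster = cluster_of,
                            similarity_to_rep = sim_of)
  rownames(assignments) <- NULL
  structure(list(clusters = clusters, threshold = threshold,
                 similarity_def = similarity_def,
                 assignments = assignments),
            class = "clustering")
}

#' @export
print.clustering <- function(x, ...) {
  sizes <- vapply(x$clusters, function(cl) length(cl$members), integer(1))
  cat(sprintf("<clustering> %d sequence(s) in %d cluster(s) at >%.0f%% similarity\n",
              nrow(x$assignments), length(x$clusters), 100 * x$threshold))
  cat("  cluster sizes:", paste(sort(sizes, decreasing = TRUE),
                                collapse = " "), "\n")
  invisible(x)
}

#' Genome-by-cluster membership matrix
#'
#' @param clustering a `clustering` from [greedy_cluster()].
#' @param genomes ordered character vector of genome ids (must cover every
#'   genome present in the clustering).
#' @param binarize return presence/absence (0/1) instead of gene counts.
#' @return integer matrix, rows = genomes, columns = clusters
#'   (`c1`, `c2`, ...).
#' @export
membership_matrix <- function(clustering, genomes, binarize = FALSE) {
  stopifnot(is(clustering, "clustering"))
  a <- clustering$assignments
  unknown <- setdiff(a$genome_id, genomes)
  if (length(unknown))
    stop("genome id(s) in clustering but not in 'genomes': ",
         paste(unknown, collapse = ", "))
  ncl <- length(clustering$clusters)
  m <- matrix(0L, nrow = length(genomes), ncol = ncl,
              dimnames = list(genomes, paste0("c", seq_len(ncl))))
  for (r in seq_len(nrow(a)))
    m[a$genome_id[r], a$cluster[r]] <- m[a$genome_id[r], a$cluster[r]] + 1L
  if (binarize) m <- (m > 0L) + 0L
  m
}

#' Write a clustering in a CD-HIT-like `.clstr` text layout
#' @param clustering a `clustering`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clstr <- function(clustering, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ci in seq_along(clustering$clusters)) {
    cl <- clustering$clusters[[ci]]
    writeLines(sprintf(">Cluster %d", ci - 1L), con)
    for (mi in seq_along(cl$members)) {
      tag <- if (cl$members[mi] == cl$representative) "*" else ""
      writeLines(sprintf("%d\t%s %s", mi - 1L, cl$members[mi], tag), con)
    }
  }
  invisible(path)
}
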