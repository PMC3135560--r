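# Pangenome shared/unique gene analysis. The pangenome is the plain union
# of all predicted genes across the reference genomes (no deduplication
# unless asked). A query gene is "shared" by the cluster route if a joint
# greedy clustering at the similarity threshold puts it in a cluster with
# at least one pangenome gene, and by the local route if its best local
# alignment against the pooled pangenome reaches the E-value cutoff with a
# database-style search space (n = total pangenome residues). The two
# routes are reported independently: global-identity clustering at 40% is
# stricter than E <= 0.01, so neither set is assumed to contain the other.

#' Build a pangenome as the union of per-genome protein sets
#'
#' @param genome_protein_sets named list; each element a data.frame with
#'   columns genome_id, gene_id, aa_seq (one genome each).
#' @param dedup collapse byte-identical sequences first (default FALSE:
#'   the pangenome is a plain union).
#' @return object of class `pangenome`: `proteins` (pooled data.frame),
#'   `source_manifest` (named integer, genome id -> gene count).
#' @export
build_pangenome <- function(genome_protein_sets, dedup = FALSE) {
  stopifnot(is.list(genome_protein_sets), length(genome_protein_sets) >= 1L)
  for (i in seq_along(genome_protein_sets)) {
    gs <- genome_protein_sets[[i]]
    if (!is.data.frame(gs) || !nrow(gs))
      stop("genome protein set ", i, " is empty or not a data.frame")
  }
  pool <- do.call(rbind, genome_protein_sets)
  rownames(pool) <- NULL
  check_protein_df(pool)
  if (dedup) pool <- pool[!duplicated(pool$aa_seq), , drop = FALSE]
  manifest <- table(factor(pool$genome_id, levels = unique(pool$genome_id)))
  structure(list(proteins = pool,
                 source_manifest = setNames(as.integer(manifest),
                                            names(manifest))),
            class = "pangenome")
}

#' @export
print.pangenome <- function(x, ...) {
  cat(sprintf("<pangenome> %d proteins from %d genome(s)\n",
              nrow(x$proteins), length(x$source_manifest)))
  invisible(x)
}

#' Shared and unique genes of a query genome against a pangenome
#'
#' @param query data.frame of query proteins (genome_id, gene_id, aa_seq).
#' @param pan a `pangenome` from [build_pangenome()].
#' @param cluster_threshold similarity threshold for the cluster route
#'   (default 0.40, strict `>`).
#' @param evalue_cutoff E-value cutoff for the local route (default 0.01).
#' @param similarity_def passed to [greedy_cluster()].
#' @param K,lambda Karlin-Altschul parameters for the local route.
#' @return object of class `shared_unique_report`: `query_id`,
#'   `n_query_genes`, `shared_by_cluster`, `shared_by_local`, `unique`
#'   (character vectors of gene keys; `unique` = genes in neither shared
#'   set), and `best_hits` (per-gene best pangenome hit with identity,
#'   score and E-value).
#' @export
shared_unique <- function(query, pan, cluster_threshold = 0.40,
                          evalue_cutoff = 0.01,
                          similarity_def = c("shorter", "columns"),
                          K = 0.041, lambda = 0.267) {
  similarity_def <- match.arg(similarity_def)
  stopifnot(is(pan, "pangenome"))
  qkeys <- check_protein_df(query)
  if (!nrow(pan$proteins)) stop("empty pangenome")
  pkeys <- protein_keys(pan$proteins)
  if (length(intersect(qkeys, pkeys)))
    stop("query and pangenome share gene keys")

  # cluster route: joint clustering, shared iff cluster holds a pan gene
  joint <- rbind(query, pan$proteins)
  cl <- greedy_cluster(joint, threshold = cluster_threshold,
                       similarity_def = similarity_def)
  a <- cl$assignments
  pan_clusters <- unique(a$cluster[a$key %in% pkeys])
  shared_by_cluster <- a$key[a$key %in% qkeys & a$cluster %in% pan_clusters]

  # local route: best Smith-Waterman hit vs the pooled pangenome
  db_len <- sum(nchar(pan$proteins$aa_seq))
  pan_set <- Biostrings::AAStringSet(setNames(pan$proteins$aa_seq, pkeys))
  shared_by_local <- character(0)
  hits <- list()
  for (i in seq_len(nrow(query))) {
    pa <- Biostrings::pairwiseAlignment(
      pan_set, Biostrings::AAStringSet(query$aa_seq[i])[[1]],
      type = "local", substitutionMatrix = blosum62(),
      gapOpening = 11, gapExtension = 1)
    scores <- pmax(Biostrings::score(pa), 0)
    best <- which.max(scores)
    ev <- evalue(scores[best], nchar(query$aa_seq[i]), db_len, K, lambda)
    id_pct <- if (scores[best] > 0)
      100 * Biostrings::nmatch(pa[best]) /
        nchar(as.character(Biostrings::alignedPattern(pa[best]))) else 0
    if (ev <= evalue_cutoff)
      shared_by_local <- c(shared_by_local, qkeys[i])
    hits[[i]] <- data.frame(
      gene = qkeys[i], best_hit = pkeys[best], identity_pct = id_pct,
      score = scores[best], evalue = ev,
      shared_by_cluster = qkeys[i] %in% shared_by_cluster,
      shared_by_local = ev <= evalue_cutoff)
  }
  best_hits <- do.call(rbind, hits)
  rownames(best_hits) <- NULL
  structure(list(
    query_id = query$genome_id[1], n_query_genes = nrow(query),
    shared_by_cluster = shared_by_cluster,
    shared_by_local = shared_by_local,
    unique = setdiff(qkeys, union(shared_by_cluster, shared_by_local)),
    best_hits = best_hits),
    class = "shared_unique_report")
}

#' @export
print.shared_unique_report <- function(x, ...) {
  cat(sprintf(
    "<shared_unique_report> %s: %d genes | shared by cluster %d, by local %d, unique %d\n",
    x$query_id, x$n_query_genes, length(x$shared_by_cluster),
    length(x$shared_by_local), length(x$unique)))
  invisible(x)
}
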