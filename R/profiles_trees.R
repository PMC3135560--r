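# Profile tables (cluster memberships or functional-category counts) to
# distance matrices and UPGMA dendrograms. The agglomeration is written out
# explicitly rather than delegated to hclust so the tie-break is fully
# specified: at each step the minimum-distance pair is merged, ties resolved
# in favor of the lexicographically smallest (label, label) pair, where a
# cluster is labeled by its smallest member id. Heights are ultrametric
# (half the merge distance). Trees are returned as ape "phylo" objects and
# serialized as Newick via ape.

#' Distance matrix from a profile table
#'
#' @param table numeric matrix (rows = genomes, columns = clusters or
#'   functional categories) with non-negative entries and unique row and
#'   column names.
#' @param metric `"jaccard"` (on presence/absence; two all-zero rows have
#'   distance 0) or `"braycurtis"` (on counts; an all-zero row is an
#'   error).
#' @param binarize convert counts to presence/absence first. Default: TRUE
#'   for jaccard, FALSE for braycurtis.
#' @return symmetric distance matrix in `[0, 1]` with zero diagonal.
#' @export
profile_distance <- function(table, metric = c("jaccard", "braycurtis"),
                             binarize = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(table), nrow(table) >= 2L,
            !is.null(rownames(table)), !anyDuplicated(rownames(table)),
            all(table >= 0))
  if (is.null(binarize)) binarize <- metric == "jaccard"
  x <- if (binarize) (table > 0) + 0 else table
  n <- nrow(x)
  if (metric == "braycurtis") {
    zero <- rowSums(x) == 0
    if (any(zero))
      stop("all-zero profile row(s) for Bray-Curtis: ",
           paste(rownames(x)[zero], collapse = ", "))
  }
  d <- matrix(0, n, n, dimnames = list(rownames(x), rownames(x)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- x[i, ]; b <- x[j, ]
    dij <- if (metric == "jaccard") {
      un <- sum(a > 0 | b > 0)
      if (un == 0) 0 else 1 - sum(a > 0 & b > 0) / un
    } else {
      sum(abs(a - b)) / sum(a + b)
    }
    d[i, j] <- d[j, i] <- dij
  }
  d
}

#' UPGMA (average linkage) dendrogram from a distance matrix
#'
#' @param d symmetric non-negative distance matrix with zero diagonal and
#'   unique row names (leaf labels).
#' @return a rooted ultrametric [ape::phylo] tree; node heights equal half
#'   the merge distance. The per-leaf root-to-tip path length equals half
#'   the final merge distance.
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 2L, !is.null(rownames(d)))
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(d < 0)) stop("negative distances")
  ids <- rownames(d)
  n <- length(ids)
  # active clusters: members (ids), size, height, newick fragment, label
  act <- lapply(ids, function(id)
    list(members = id, size = 1L, height = 0, nwk = id, label = id))
  dm <- d
  dimnames(dm) <- NULL
  while (length(act) > 1L) {
    m <- length(act)
    best <- NULL
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      lab <- sort(c(act[[i]]$label, act[[j]]$label))
      if (is.null(best) || dm[i, j] < best$d - 1e-15 ||
          (abs(dm[i, j] - best$d) <= 1e-15 &&
             (lab[1] < best$lab[1] ||
                (lab[1] == best$lab[1] && lab[2] < best$lab[2]))))
        best <- list(i = i, j = j, d = dm[i, j], lab = lab)
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    a <- act[[i]]; b <- act[[j]]
    merged <- list(
      members = c(a$members, b$members), size = a$size + b$size,
      height = h,
      nwk = sprintf("(%s:%.10g,%s:%.10g)", a$nwk, h - a$height,
                    b$nwk, h - b$height),
      label = min(a$label, b$label))
    # average-linkage update
    keep <- setdiff(seq_len(m), c(i, j))
    newrow <- vapply(keep, function(k)
      (a$size * dm[i, k] + b$size * dm[j, k]) / (a$size + b$size),
      numeric(1))
    dm <- dm[keep, keep, drop = FALSE]
    dm <- rbind(cbind(dm, newrow), c(newrow, 0))
    act <- c(act[keep], list(merged))
  }
  tr <- ape::read.tree(text = paste0(act[[1]]$nwk, ";"))
  tr
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric difference of the non-trivial bipartitions induced by the
#' internal edges of each (unrooted) tree.
#'
#' @param t1,t2 [ape::phylo] trees over the same leaf set.
#' @return non-negative integer count.
#' @export
rf_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees have different leaf sets")
  b1 <- bipartitions(t1)
  b2 <- bipartitions(t2)
  length(setdiff(b1, b2)) + length(setdiff(b2, b1))
}

# canonical string keys of the non-trivial bipartitions of a phylo tree
bipartitions <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  keys <- vapply(pp, function(s) {
    side <- sort(labs[s])
    if (length(side) <= 1L || length(side) >= n - 1L) return(NA_character_)
    if (!(tips[1] %in% side)) side <- sort(setdiff(tips, side))
    paste(side, collapse = "|")
  }, character(1))
  unique(keys[!is.na(keys)])
}

#' Read a profile table from TSV (genome rows, category columns)
#' @param path TSV path with a header line and row ids in the first column.
#' @return numeric matrix with row and column names.
#' @export
read_profile_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   row.names = 1, comment.char = "")
  as.matrix(df)
}

#' Write a numeric matrix as TSV with row ids in the first column
#' @param m matrix with dimnames.
#' @param path output path.
#' @param id_col name for the first (row id) column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
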