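# Exact-overlap greedy assembler. Fragments are merged only on 100%-identity
# suffix/prefix overlaps (either orientation), the criterion used when the
# genome was closed by primer walking; there is no mismatch tolerance, which
# keeps the round-trip oracle exact.

# longest k in [min_k, max_k] with suffix(a, k) == prefix(b, k), else 0
longest_overlap <- function(a, b, min_k, max_k = min(nchar(a), nchar(b))) {
  if (max_k < min_k) return(0L)
  for (k in seq(max_k, min_k)) {
    if (substr(a, nchar(a) - k + 1L, nchar(a)) == substr(b, 1L, k))
      return(as.integer(k))
  }
  0L
}

#' Assemble a circular genome from fragments by exact overlap merging
#'
#' Greedy overlap-layout: repeatedly merge the pair of contigs with the
#' longest exact suffix/prefix overlap of at least `min_overlap` nucleotides,
#' considering both orientations, until no merge is possible. A contig whose
#' own ends share an exact overlap of at least `min_overlap` is circularized
#' by trimming one copy of the overlap. Deterministic: ties are broken by the
#' lexicographically smallest (contig, contig) pair of representative
#' fragment ids, and an unflipped merge is preferred over a flipped one.
#'
#' @param fragments named character vector (names are fragment ids) or a
#'   list of objects with `id`/`residues` fields. Alphabet `{A,C,G,T}`.
#' @param min_overlap minimum exact overlap in nt (default 250, the overlap
#'   the subclone walk was designed to leave; must be >= 20).
#' @return object of class `assembly_result`: `contigs` (list of
#'   [circ_seq]), `layout` (data.frame fragment, contig, offset, strand),
#'   `circularized` (logical per contig), `coverage_fold` (total fragment
#'   length / total contig length).
#' @examples
#' g <- paste(rep("ACGTT", 100), collapse = "")  # 500 nt "genome"
#' fr <- c(f1 = substr(g, 1, 300), f2 = substr(g, 251, 500))
#' a <- assemble_exact(fr, min_overlap = 50)
#' a$contigs[[1]]$length  # 500
#' @export
assemble_exact <- function(fragments, min_overlap = 250L) {
  fragments <- as_named_seqs(fragments)
  if (min_overlap < 20L) stop("min_overlap must be >= 20")
  if (any(grepl("[^ACGT]", fragments)))
    stop("fragments must be over {A,C,G,T}")
  if (max(nchar(fragments)) < min_overlap)
    stop("min_overlap (", min_overlap, ") exceeds every fragment length")

  # each contig: seq, layout rows (fragment, offset, strand), rep id
  contigs <- lapply(names(fragments), function(id)
    list(seq = fragments[[id]],
         layout = data.frame(fragment = id, offset = 1L, strand = "+"),
         rep = id))

  flip_contig <- function(ct) {
    L <- nchar(ct$seq)
    lay <- ct$layout
    flen <- nchar(fragments[lay$fragment])
    lay$offset <- L - (lay$offset + flen - 1L) + 1L
    lay$strand <- ifelse(lay$strand == "+", "-", "+")
    list(seq = revcomp(ct$seq), layout = lay, rep = ct$rep)
  }

  repeat {
    n <- length(contigs)
    if (n < 2L) break
    # enumerate all mergeable (ordered pair, orientation) candidates, then
    # pick longest overlap; ties by lexicographic (repA, repB), unflipped
    # before flipped
    cands <- list()
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      a <- contigs[[i]]; b <- contigs[[j]]
      for (flip in c(FALSE, TRUE)) {
        bseq <- if (flip) revcomp(b$seq) else b$seq
        k <- longest_overlap(a$seq, bseq, min_overlap)
        if (k > 0L)
          cands[[length(cands) + 1L]] <- list(i = i, j = j, k = k,
                                              flip = flip, key = c(a$rep, b$rep))
      }
    }
    best <- NULL
    for (cand in cands) {
      if (is.null(best) || cand$k > best$k ||
          (cand$k == best$k &&
             (cand$key[1] < best$key[1] ||
                (cand$key[1] == best$key[1] && cand$key[2] < best$key[2]) ||
                (all(cand$key == best$key) && !cand$flip && best$flip))))
        best <- cand
    }
    if (is.null(best)) break
    a <- contigs[[best$i]]
    b <- contigs[[best$j]]
    if (best$flip) b <- flip_contig(b)
    shift <- nchar(a$seq) - best$k
    b$layout$offset <- b$layout$offset + shift
    merged <- list(seq = paste0(a$seq, substr(b$seq, best$k + 1L, nchar(b$seq))),
                   layout = rbind(a$layout, b$layout),
                   rep = min(a$rep, b$rep))
    contigs <- c(contigs[-c(best$i, best$j)], list(merged))
  }

  circularized <- logical(length(contigs))
  out <- vector("list", length(contigs))
  for (ci in seq_along(contigs)) {
    ct <- contigs[[ci]]
    k <- longest_overlap(ct$seq, ct$seq, min_overlap,
                         max_k = nchar(ct$seq) - 1L)
    circ <- k > 0L
    if (circ) ct$seq <- substr(ct$seq, 1L, nchar(ct$seq) - k)
    circularized[ci] <- circ
    out[[ci]] <- list(
      contig = circ_seq(sprintf("contig%03d", ci), ct$seq,
                        if (circ) "circular" else "linear"),
      layout = cbind(ct$layout, contig = sprintf("contig%03d", ci)))
  }
  layout <- do.call(rbind, lapply(out, `[[`, "layout"))
  layout <- layout[, c("fragment", "contig", "offset", "strand")]
  rownames(layout) <- NULL
  ctgs <- lapply(out, `[[`, "contig")
  structure(list(contigs = ctgs, layout = layout,
                 circularized = circularized,
                 coverage_fold = sum(nchar(fragments)) /
                   sum(vapply(ctgs, function(x) x$length, numeric(1)))),
            class = "assembly_result")
}

#' @export
print.assembly_result <- function(x, ...) {
  cat(sprintf("<assembly_result> %d contig(s), %.1f-fold coverage\n",
              length(x$contigs), x$coverage_fold))
  for (i in seq_along(x$contigs))
    cat(sprintf("  %s: %d nt, %s\n", x$contigs[[i]]$id,
                x$contigs[[i]]$length,
                if (x$circularized[i]) "circular" else "linear"))
  invisible(x)
}
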