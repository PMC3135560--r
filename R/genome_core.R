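# Sequence containers, FASTA I/O, circular coordinate arithmetic and
# composition statistics. Coordinates are 1-based inclusive throughout
# (GenBank convention); for circular topology index arithmetic is modulo
# the genome length.

#' Construct a (possibly circular) nucleotide sequence
#'
#' The basic container used across the package: an identifier, an
#' upper-case residue string over `{A,C,G,T,N}`, and a topology flag.
#'
#' @param id character scalar, sequence label.
#' @param residues character scalar, nucleotide string. Lower case is
#'   normalized to upper case and `U` is mapped to `T`. Non-`ACGTN` IUPAC
#'   ambiguity codes are mapped to `N` with a warning; anything else is an
#'   error.
#' @param topology `"circular"` or `"linear"`.
#' @return An object of class `circ_seq` with fields `id`, `residues`,
#'   `topology` and `length`.
#' @examples
#' s <- circ_seq("g1", "acgu")
#' s$residues  # "ACGT"
#' @export
circ_seq <- function(id, residues, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  r <- toupper(residues)
  r <- chartr("U", "T", r)
  if (grepl("[^ACGTN]", r)) {
    iupac <- "RYSWKMBDHV"
    bad <- gsub(sprintf("[ACGTN%s]", iupac), "", r)
    if (nzchar(bad))
      stop("illegal characters in sequence '", id, "': ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ""))
    warning("sequence '", id, "': IUPAC ambiguity codes mapped to N")
    r <- gsub(sprintf("[%s]", iupac), "N", r)
  }
  if (nchar(r) == 0L) stop("zero-length sequence for record '", id, "'")
  structure(list(id = id, residues = r, topology = topology,
                 length = nchar(r)),
            class = "circ_seq")
}

#' @export
print.circ_seq <- function(x, ...) {
  cat(sprintf("<circ_seq> %s: %d nt, %s\n", x$id, x$length, x$topology))
  invisible(x)
}

#' Read a FASTA file of nucleotide sequences
#'
#' @param path path to a FASTA file (wrapped or unwrapped lines).
#' @param topology topology assigned to every record.
#' @return list of [circ_seq] objects; the header token before the first
#'   whitespace becomes the id.
#' @export
read_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  lapply(seq_along(set), function(i)
    circ_seq(ids[i], as.character(set[[i]]), topology))
}

#' Write sequences to a FASTA file (60-column wrapping)
#'
#' @param seqs a [circ_seq], a list of them, or a named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  v <- as_named_seqs(seqs)
  set <- Biostrings::BStringSet(v)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

# Coerce the accepted sequence-collection shapes to a named character vector.
as_named_seqs <- function(seqs) {
  if (is(seqs, "circ_seq")) seqs <- list(seqs)
  if (is.list(seqs)) {
    v <- vapply(seqs, function(s) {
      if (is(s, "circ_seq")) s$residues else as.character(s)
    }, character(1))
    nm <- vapply(seqs, function(s) {
      if (is(s, "circ_seq")) s$id else NA_character_
    }, character(1))
    if (anyNA(nm)) nm <- names(seqs)
    names(v) <- nm
    seqs <- v
  }
  stopifnot(is.character(seqs), !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  seqs
}

#' Nucleotide composition of a sequence
#'
#' Fractions are computed over non-`N` residues; `N`s are excluded from the
#' denominator and reported separately.
#'
#' @param seq a [circ_seq].
#' @return object of class `composition_stats`: `frac_A`, `frac_C`,
#'   `frac_G`, `frac_T`, `gc_fraction`, `n_count`, `length`.
#' @examples
#' composition(circ_seq("x", "ACGT"))$gc_fraction  # 0.5
#' @export
composition <- function(seq) {
  stopifnot(is(seq, "circ_seq"))
  tab <- table(strsplit(seq$residues, "", fixed = TRUE)[[1]])
  cnt <- setNames(rep(0, 5), c("A", "C", "G", "T", "N"))
  cnt[names(tab)] <- as.numeric(tab)
  eff <- seq$length - cnt[["N"]]
  if (eff == 0L) stop("all-N sequence: composition undefined for '",
                      seq$id, "'")
  structure(list(
    frac_A = cnt[["A"]] / eff, frac_C = cnt[["C"]] / eff,
    frac_G = cnt[["G"]] / eff, frac_T = cnt[["T"]] / eff,
    gc_fraction = (cnt[["C"]] + cnt[["G"]]) / eff,
    n_count = as.integer(cnt[["N"]]), length = seq$length),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf("length %d nt | A %.1f%%  C %.1f%%  G %.1f%%  T %.1f%% | GC %.1f%%\n",
              x$length, 100 * x$frac_A, 100 * x$frac_C, 100 * x$frac_G,
              100 * x$frac_T, 100 * x$gc_fraction))
  invisible(x)
}

#' Rotate a circular sequence so a chosen position becomes position 1
#'
#' @param seq a circular [circ_seq].
#' @param anchor_start 1-based position mapped to position 1 of the result.
#' @return the rotated [circ_seq]; the original rotation offset is kept in
#'   attribute `"rotation"` (0 for `anchor_start = 1`).
#' @examples
#' canonicalize(circ_seq("x", "ACGT"), 3)$residues  # "GTAC"
#' @export
canonicalize <- function(seq, anchor_start) {
  stopifnot(is(seq, "circ_seq"))
  if (seq$topology != "circular")
    stop("rotation is undefined for linear sequences ('", seq$id, "')")
  stopifnot(anchor_start >= 1, anchor_start <= seq$length)
  anchor_start <- as.integer(anchor_start)
  r <- if (anchor_start == 1L) seq$residues else
    paste0(substr(seq$residues, anchor_start, seq$length),
           substr(seq$residues, 1L, anchor_start - 1L))
  out <- circ_seq(seq$id, r, "circular")
  attr(out, "rotation") <- anchor_start - 1L
  out
}

#' Reverse complement of a nucleotide string
#' @param x character scalar over `ACGTN`.
#' @return reverse-complemented character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Per-sequence composition table for a FASTA file
#'
#' Convenience wrapper behind the `stats` CLI subcommand.
#'
#' @param seqs list of [circ_seq] (e.g. from [read_fasta()]).
#' @return data.frame with columns id, length, A_pct, C_pct, G_pct, T_pct,
#'   GC_pct (percentages rounded to one decimal, the display convention).
#' @export
composition_table <- function(seqs) {
  rows <- lapply(seqs, function(s) {
    cs <- composition(s)
    data.frame(id = s$id, length = cs$length,
               A_pct = round(100 * cs$frac_A, 1),
               C_pct = round(100 * cs$frac_C, 1),
               G_pct = round(100 * cs$frac_G, 1),
               T_pct = round(100 * cs$frac_T, 1),
               GC_pct = round(100 * cs$gc_fraction, 1))
  })
  do.call(rbind, rows)
}
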