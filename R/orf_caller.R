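# Circular-aware ORF prediction. The rule is deliberately simple and
# deterministic: on each strand and frame every stop-to-stop interval
# contributes at most one ORF, the one beginning at the first in-frame start
# codon, kept if its start-through-stop span meets the length threshold.
# Wraparound across the origin is handled by scanning the doubled sequence
# and deduplicating by modular coordinates; an ORF may not wrap onto itself
# (span <= genome length).

codon_split <- function(s) {
  n <- nchar(s) %/% 3L
  substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translate_nt <- function(nt, table = "11") {
  gc <- Biostrings::getGeneticCode(table)
  paste(gc[codon_split(nt)], collapse = "")
}

# all ORFs on one oriented string; returns start (1-based, in that string's
# own coordinates), nt_length; circular: scan doubled string, dedup later
scan_orfs_oriented <- function(s, L, circular, min_nt, start_codons, table) {
  gc <- Biostrings::getGeneticCode(table)
  stops <- names(gc)[gc == "*"]
  d <- if (circular) paste0(s, s) else s
  nd <- nchar(d)
  hits <- list()
  # candidate start positions restricted to the original copy
  for (p in seq_len(L)) {
    if (!circular && p > nchar(s) - 2L) break
    if (!(substr(d, p, p + 2L) %in% start_codons)) next
    q <- p
    found <- FALSE
    while (q + 2L <= nd) {
      cod <- substr(d, q, q + 2L)
      if (cod %in% stops) { found <- TRUE; break }
      q <- q + 3L
    }
    if (!found) next
    nt_len <- q + 3L - p
    if (nt_len < min_nt || nt_len > L) next
    hits[[length(hits) + 1L]] <- c(start = p, nt = nt_len)
  }
  if (!length(hits)) return(NULL)
  m <- do.call(rbind, hits)
  # one ORF per stop: keep the earliest start (longest ORF) for each
  # modular stop-codon position
  stop_pos <- (m[, "start"] + m[, "nt"] - 3L - 1L) %% L
  best <- tapply(seq_len(nrow(m)), stop_pos, function(ix)
    ix[which.max(m[ix, "nt"])])
  m[sort(unlist(best)), , drop = FALSE]
}

#' Predict open reading frames on a (circular) genome
#'
#' Both strands are scanned by default (set `forward_only = TRUE` for
#' genomes known to encode on one strand). Coordinates are 1-based
#' inclusive on the forward strand with `start <= end`, except for ORFs
#' wrapping the origin of a circular genome, where `end < start`.
#'
#' @param seq a [circ_seq].
#' @param min_nt minimum ORF span in nt, start codon through stop codon
#'   inclusive (default 100, i.e. "longer than 99 nt"; must be >= 3).
#' @param start_codons character vector of permitted start codons
#'   (default `"ATG"`; add `"GTG"`, `"TTG"` for alternative starts).
#' @param table genetic code id as understood by
#'   [Biostrings::getGeneticCode()] (default `"11"`, bacterial/phage).
#' @param forward_only scan only the forward strand.
#' @return object of class `orf_set`: `genome_id` plus a data.frame
#'   `records` (start, end, strand, nt_length, aa_length, aa_seq) sorted by
#'   start. `nt_length` includes the stop codon; `aa_length` excludes it.
#' @examples
#' s <- circ_seq("x", paste0("ATGAAATAA", strrep("C", 91)))
#' find_orfs(s, min_nt = 9)$records$aa_seq  # "MK"
#' @export
find_orfs <- function(seq, min_nt = 100L, start_codons = "ATG",
                      table = "11", forward_only = FALSE) {
  stopifnot(is(seq, "circ_seq"))
  if (min_nt < 3L) stop("min_nt must be >= 3")
  L <- seq$length
  if (L < min_nt) stop("sequence shorter than min_nt")
  circular <- seq$topology == "circular"
  strands <- if (forward_only) "+" else c("+", "-")
  rows <- list()
  for (strand in strands) {
    s <- if (strand == "+") seq$residues else revcomp(seq$residues)
    m <- scan_orfs_oriented(s, L, circular, min_nt, start_codons, table)
    if (is.null(m)) next
    d <- if (circular) paste0(s, s) else s
    for (r in seq_len(nrow(m))) {
      p <- m[r, "start"]; nt <- m[r, "nt"]
      nt_seq <- substr(d, p, p + nt - 1L)
      aa <- translate_nt(substr(nt_seq, 1L, nt - 3L), table)
      # map the oriented span [p, p+nt-1] back to forward coordinates
      if (strand == "+") {
        g1 <- p; g2 <- (p + nt - 2L) %% L + 1L
      } else {
        g1 <- (L - ((p + nt - 2L) %% L + 1L)) %% L + 1L
        g2 <- L - p + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        start = g1, end = g2, strand = strand,
        nt_length = nt, aa_length = nchar(aa), aa_seq = aa)
    }
  }
  rec <- if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(), end = integer(), strand = character(),
               nt_length = integer(), aa_length = integer(),
               aa_seq = character())
  rec <- rec[!duplicated(rec[c("start", "end", "strand")]), , drop = FALSE]
  rec <- rec[order(rec$start, rec$end, rec$strand), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(genome_id = seq$id, records = rec), class = "orf_set")
}

#' @export
print.orf_set <- function(x, ...) {
  cat(sprintf("<orf_set> %s: %d ORF(s)\n", x$genome_id, nrow(x$records)))
  if (nrow(x$records)) print(x$records[, setdiff(names(x$records), "aa_seq")])
  invisible(x)
}

#' Coding capacity of a genome
#'
#' @param orfs an `orf_set` from [find_orfs()].
#' @param genome_length genome length in nt.
#' @param mode `"union"`: percent of genome positions covered by at least
#'   one ORF (cannot exceed 100). `"sum"`: 100 x (sum of ORF nt lengths) /
#'   genome length, which can exceed 100 with heavily overlapping ORFs.
#' @return percentage (numeric; round to integer for display).
#' @export
coding_capacity <- function(orfs, genome_length,
                            mode = c("union", "sum")) {
  mode <- match.arg(mode)
  stopifnot(is(orfs, "orf_set"), genome_length > 0)
  rec <- orfs$records
  if (!nrow(rec)) return(0)
  if (any(rec$nt_length > genome_length))
    stop("ORF longer than the genome")
  if (mode == "sum") return(100 * sum(rec$nt_length) / genome_length)
  covered <- logical(genome_length)
  for (r in seq_len(nrow(rec))) {
    pos <- if (rec$start[r] <= rec$end[r]) rec$start[r]:rec$end[r] else
      c(rec$start[r]:genome_length, 1:rec$end[r])
    covered[pos] <- TRUE
  }
  100 * sum(covered) / genome_length
}

#' Write an ORF set as GFF3
#'
#' Wraparound ORFs are emitted as two CDS parts sharing one `ID` and
#' carrying a `wrap=true` attribute.
#'
#' @param orfs an `orf_set`.
#' @param genome_length genome length (needed to split wrapped features).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_orfs_gff3 <- function(orfs, genome_length, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  rec <- orfs$records
  for (r in seq_len(nrow(rec))) {
    id <- sprintf("%s_orf%02d", orfs$genome_id, r)
    attr0 <- sprintf("ID=%s;aa_length=%d;aa_seq=%s", id, rec$aa_length[r],
                     rec$aa_seq[r])
    if (rec$start[r] <= rec$end[r]) {
      writeLines(paste(orfs$genome_id, "orf_caller", "CDS", rec$start[r],
                       rec$end[r], ".", rec$strand[r], "0", attr0,
                       sep = "\t"), con)
    } else {
      attr1 <- paste0(attr0, ";wrap=true")
      writeLines(paste(orfs$genome_id, "orf_caller", "CDS", rec$start[r],
                       genome_length, ".", rec$strand[r], "0", attr1,
                       sep = "\t"), con)
      writeLines(paste(orfs$genome_id, "orf_caller", "CDS", 1L,
                       rec$end[r], ".", rec$strand[r], "0", attr1,
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a GFF3 file written by [write_orfs_gff3()] back into an `orf_set`
#' @param path GFF3 path.
#' @return an `orf_set`.
#' @export
read_orfs_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln))
    return(structure(list(genome_id = NA_character_,
                          records = data.frame()), class = "orf_set"))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  att <- f[, 9]
  id <- sub("^ID=([^;]+).*", "\\1", att)
  aa <- sub(".*;aa_seq=([^;]*).*", "\\1", att)
  rows <- lapply(split(seq_along(id), factor(id, levels = unique(id))),
                 function(ix) {
    starts <- as.integer(f[ix, 4]); ends <- as.integer(f[ix, 5])
    if (length(ix) == 1L) {
      data.frame(start = starts, end = ends, strand = f[ix, 7],
                 aa_seq = aa[ix])
    } else {  # wrapped: part starting past 1 holds the true start
      data.frame(start = max(starts), end = ends[starts == 1L],
                 strand = f[ix[1], 7], aa_seq = aa[ix[1]])
    }
  })
  rec <- do.call(rbind, rows)
  rec$aa_length <- nchar(rec$aa_seq)
  rec$nt_length <- 3L * (rec$aa_length + 1L)
  rec <- rec[order(rec$start, rec$end, rec$strand),
             c("start", "end", "strand", "nt_length", "aa_length", "aa_seq")]
  rownames(rec) <- NULL
  structure(list(genome_id = f[1, 1], records = rec), class = "orf_set")
}

#' Extract ORF translations as a protein set
#' @param orfs an `orf_set`.
#' @return data.frame with columns genome_id, gene_id (`orf01`...), aa_seq,
#'   ordered by decreasing length (the numbering convention for small phage
#'   genomes annotates the longest ORF as 01).
#' @export
orf_proteins <- function(orfs) {
  rec <- orfs$records
  if (!nrow(rec))
    return(data.frame(genome_id = character(), gene_id = character(),
                      aa_seq = character()))
  rec <- rec[order(-rec$aa_length, rec$start), , drop = FALSE]
  data.frame(genome_id = orfs$genome_id,
             gene_id = sprintf("orf%02d", seq_len(nrow(rec))),
             aa_seq = rec$aa_seq)
}
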