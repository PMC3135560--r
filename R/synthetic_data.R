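# Seeded synthetic datasets with the statistical structure the analyses
# assume: orthologous protein families evolved along a known tree by a
# uniform amino-acid replacement model, back-translated with a GC-biased
# codon choice, concatenated with spacers into modular circular genomes,
# and optionally shredded into overlapping fragments. Every stage records
# its ground truth so recovery can be tested exactly.
#
# Replacement model: along a branch of length b (expected substitutions per
# site), each site experiences a replacement event with probability
# 1 - exp(-b); an event draws the new residue uniformly from the 20 amino
# acids (possibly the same one). This gives the closed-form expected
# identity between two leaves at path distance d:
#   E[identity] = exp(-d) + (1 - exp(-d)) / 20
# which is what makes the generator testable against an oracle.

# Nucleotide-level realism: the ancestral gene is back-translated once and
# codons then evolve down the tree -- a replacement event re-draws the
# codon for the new residue, and synonymous churn re-draws the codon for
# the same residue at the neutral rate (one expected event per site per
# unit branch length, not scaled by the family rate). Intergenic spacers
# likewise mutate per site at the neutral rate. This preserves
# phylogenetic signal in tetranucleotide space, which leaf-wise
# independent back-translation would destroy.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# deterministic per-stage seed derivation from one master seed (< 2^31)
derive_seed <- function(seed, stage) {
  ((seed %% 1000003) * 1009 + 97 * stage) %% 2147483647
}

#' Expected pairwise identity under the uniform replacement model
#' @param d path distance between two leaves (expected substitutions/site).
#' @return expected fraction of identical sites.
#' @export
expected_identity <- function(d) exp(-d) + (1 - exp(-d)) / 20

#' Simulation configuration
#'
#' Defaults describe a Microviridae-like world: 15 small circular genomes
#' (one "query" plus 14 references), about ten genes each in a modular
#' arrangement (one capsid-sized gene of 480-600 aa, one rep-sized gene of
#' 300-400 aa, the rest 40-150 aa), target GC 40%, short intergenic
#' spacers, and 1 kb fragments leaving 250 nt exact overlaps.
#'
#' @param n_genomes number of genomes (tree leaves).
#' @param n_families number of orthologous gene families (>= 2).
#' @param tree_height root-to-tip height in expected substitutions/site.
#' @param gc_target genome GC fraction; feasible range about 0.25-0.75.
#' @param spacer_len_range integer range (min, max) of intergenic spacer
#'   lengths in nt; min must be >= 3 (each spacer ends with an in-frame
#'   TAA so predicted gene starts match the truth exactly).
#' @param fragment_len,fragment_overlap shredding defaults in nt.
#' @param seed master integer seed; all stage randomness derives from it.
#' @param tree optional [ape::phylo] with `n_genomes` tips to use instead
#'   of a random tree (tip labels become genome ids).
#' @param family_rates optional numeric vector of per-family rate
#'   multipliers applied to every branch length (default all 1). Real
#'   phage genes evolve at very different rates (capsid slow,
#'   hypotheticals fast); spreading rates also lets a fixed clustering
#'   threshold resolve several depths of the tree.
#' @param family_lengths optional integer vector of exact family lengths
#'   in aa, overriding the modular size scheme.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genomes = 15L, n_families = 10L,
                       tree_height = 1.0, gc_target = 0.40,
                       spacer_len_range = c(12L, 60L),
                       fragment_len = 1000L, fragment_overlap = 250L,
                       seed = 1L, tree = NULL, family_rates = NULL,
                       family_lengths = NULL) {
  stopifnot(n_genomes >= 2L, n_families >= 2L, tree_height > 0,
            spacer_len_range[1] >= 3L,
            spacer_len_range[2] >= spacer_len_range[1],
            fragment_overlap < fragment_len, seed == as.integer(seed))
  if (gc_target < 0.25 || gc_target > 0.75)
    stop("gc_target outside the feasible range (~0.25-0.75) of the ",
         "codon-bias scheme")
  if (is.null(family_rates)) family_rates <- rep(1, n_families)
  stopifnot(length(family_rates) == n_families, all(family_rates > 0))
  if (!is.null(family_lengths))
    stopifnot(length(family_lengths) == n_families,
              all(family_lengths >= 10L))
  structure(list(n_genomes = as.integer(n_genomes),
                 n_families = as.integer(n_families),
                 tree_height = tree_height, gc_target = gc_target,
                 spacer_len_range = as.integer(spacer_len_range),
                 fragment_len = as.integer(fragment_len),
                 fragment_overlap = as.integer(fragment_overlap),
                 seed = as.integer(seed), tree = tree,
                 family_rates = family_rates,
                 family_lengths = if (is.null(family_lengths)) NULL else
                   as.integer(family_lengths)),
            class = "sim_config")
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# synonymous codon sets of the bacterial/phage code, split into the
# maximum-GC and minimum-GC choices used by the two-point bias scheme
codon_bias_tables <- function() {
  if (is.null(.pkg_cache$codon_bias)) {
    gc11 <- Biostrings::getGeneticCode("11")
    cods <- names(gc11)[gc11 != "*"]
    gcfrac <- vapply(cods, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")) / 3, numeric(1))
    by_aa <- split(seq_along(cods), gc11[cods])
    hi <- lapply(by_aa, function(ix) cods[ix][gcfrac[ix] == max(gcfrac[ix])])
    lo <- lapply(by_aa, function(ix) cods[ix][gcfrac[ix] == min(gcfrac[ix])])
    gc_of <- function(set) mean(vapply(set, function(cd)
      sum(strsplit(cd, "")[[1]] %in% c("G", "C")) / 3, numeric(1)))
    .pkg_cache$codon_bias <- list(
      hi = hi, lo = lo,
      hi_gc = vapply(hi, gc_of, numeric(1)),
      lo_gc = vapply(lo, gc_of, numeric(1)))
  }
  .pkg_cache$codon_bias
}

# mixing weight of the two-point scheme: each codon is the max-GC
# synonymous choice with probability pi, else the min-GC choice; pi is
# solved for the target GC under a uniform amino-acid composition (which
# is how ancestral proteins are drawn)
gc_pi <- function(gc_target) {
  tb <- codon_bias_tables()
  g_hi <- mean(tb$hi_gc[AA20])
  g_lo <- mean(tb$lo_gc[AA20])
  min(1, max(0, (gc_target - g_lo) / (g_hi - g_lo)))
}

# one codon for each residue of v under the two-point bias scheme
draw_codons <- function(v, pi) {
  tb <- codon_bias_tables()
  use_hi <- stats::runif(length(v)) < pi
  vapply(seq_along(v), function(i) {
    set <- if (use_hi[i]) tb$hi[[v[i]]] else tb$lo[[v[i]]]
    if (length(set) == 1L) set else sample(set, 1L)
  }, character(1))
}

# evolve one gene (aa residue vector + codon vector) along one branch;
# aa_b: branch length scaled by the family rate, neut_b: unscaled
mutate_gene <- function(gene, aa_b, neut_b, pi) {
  v <- gene$aa; cod <- gene$cod
  n <- length(v)
  hit <- which(stats::runif(n) < 1 - exp(-aa_b))
  hit <- hit[hit > 1L]  # hold site 1 (M) fixed to keep ATG starts
  if (length(hit)) {
    v[hit] <- sample(AA20, length(hit), replace = TRUE)
    cod[hit] <- draw_codons(v[hit], pi)
  }
  syn <- setdiff(which(stats::runif(n) < 1 - exp(-neut_b)), hit)
  syn <- syn[syn > 1L]
  if (length(syn)) cod[syn] <- draw_codons(v[syn], pi)
  list(aa = v, cod = cod)
}

# per-site neutral substitution of a spacer, trailing in-frame TAA fixed
mutate_spacer <- function(sp, neut_b) {
  n <- length(sp)
  hit <- which(stats::runif(n) < 1 - exp(-neut_b))
  hit <- hit[hit <= n - 3L]
  if (length(hit)) sp[hit] <- sample(c("A", "C", "G", "T"), length(hit),
                                     replace = TRUE)
  sp
}

random_spacer <- function(len, gc_target) {
  p <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
         (1 - gc_target) / 2)
  c(sample(c("A", "C", "G", "T"), len - 3L, replace = TRUE, prob = p),
    "T", "A", "A")  # in-frame stop right before the next gene start
}

#' Generate a complete synthetic comparative-genomics dataset
#'
#' Samples a rooted bifurcating tree, draws ancestral protein families
#' (first residue fixed to M), evolves them down the tree under the
#' uniform replacement model, back-translates with GC-biased codon choice,
#' and concatenates genes with spacers into circular genomes. Fully
#' reproducible per seed.
#'
#' @param config a [sim_config()].
#' @return list with `genomes` (list of [circ_seq]), `proteins`
#'   (data.frame genome_id, gene_id, aa_seq), `truth` (list: `tree`
#'   \[ape::phylo\], `orthology` data.frame (key, family),
#'   `coordinates` data.frame (genome_id, gene_id, family, start, end,
#'   strand)), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(is(config, "sim_config"))
  ng <- config$n_genomes; nf <- config$n_families

  # stage 1: tree
  set.seed(derive_seed(config$seed, 1L))
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rtree(ng, rooted = TRUE)
    tree$tip.label <- sprintf("sim%02d", seq_len(ng))
    depth <- max(ape::node.depth.edgelength(tree)[seq_len(ng)])
    tree$edge.length <- tree$edge.length * config$tree_height / depth
  }
  stopifnot(length(tree$tip.label) == ng)
  genome_ids <- tree$tip.label

  # stage 2: ancestral state (modular size scheme, codons, spacers)
  set.seed(derive_seed(config$seed, 2L))
  pi <- gc_pi(config$gc_target)
  fam_len <- if (!is.null(config$family_lengths)) config$family_lengths else {
    fl <- c(sample(480:600, 1L), sample(300:400, 1L),
            if (nf > 2L) sample(40:150, nf - 2L, replace = TRUE))
    fl[seq_len(nf)]
  }
  root_state <- list(
    genes = lapply(fam_len, function(L) {
      v <- c("M", strsplit(random_aa(L - 1L), "")[[1]])
      list(aa = v, cod = draw_codons(v, pi))
    }),
    spacers = lapply(seq_len(nf), function(f)
      random_spacer(sample(config$spacer_len_range[1]:
                             config$spacer_len_range[2], 1L),
                    config$gc_target)))

  # stage 3: evolve genes and spacers down the tree (preorder over edges)
  set.seed(derive_seed(config$seed, 3L))
  tree_pre <- stats::reorder(tree, "cladewise")  # parents before children
  nnode <- max(tree_pre$edge)
  states <- vector("list", nnode)
  root <- setdiff(tree_pre$edge[, 1], tree_pre$edge[, 2])[1]
  states[[root]] <- root_state
  for (ei in seq_len(nrow(tree_pre$edge))) {
    parent <- tree_pre$edge[ei, 1]; child <- tree_pre$edge[ei, 2]
    bl <- tree_pre$edge.length[ei]
    ps <- states[[parent]]
    states[[child]] <- list(
      genes = lapply(seq_len(nf), function(f)
        mutate_gene(ps$genes[[f]], bl * config$family_rates[f], bl, pi)),
      spacers = lapply(ps$spacers, mutate_spacer, neut_b = bl))
  }

  # stage 4: assemble circular genomes from leaf states
  genomes <- vector("list", ng)
  prot_rows <- list(); coord_rows <- list()
  for (g in seq_len(ng)) {
    gid <- genome_ids[g]
    st <- states[[which(tree$tip.label == gid)]]
    parts <- character(0)
    pos <- 1L
    for (f in seq_len(nf)) {
      nt <- paste0(paste(st$genes[[f]]$cod, collapse = ""), "TAA")
      gene_id <- sprintf("g%02d", f)
      coord_rows[[length(coord_rows) + 1L]] <- data.frame(
        genome_id = gid, gene_id = gene_id,
        family = sprintf("fam%02d", f),
        start = pos, end = pos + nchar(nt) - 1L, strand = "+")
      prot_rows[[length(prot_rows) + 1L]] <- data.frame(
        genome_id = gid, gene_id = gene_id,
        aa_seq = paste(st$genes[[f]]$aa, collapse = ""))
      sp <- paste(st$spacers[[f]], collapse = "")
      parts <- c(parts, nt, sp)
      pos <- pos + nchar(nt) + nchar(sp)
    }
    genomes[[g]] <- circ_seq(gid, paste(parts, collapse = ""), "circular")
  }
  proteins <- do.call(rbind, prot_rows)
  coordinates <- do.call(rbind, coord_rows)
  orthology <- data.frame(key = protein_keys(proteins),
                          family = coordinates$family)
  list(genomes = setNames(genomes, genome_ids), proteins = proteins,
       truth = list(tree = tree, orthology = orthology,
                    coordinates = coordinates),
       config = config)
}

#' Shred a circular genome into overlapping oriented fragments
#'
#' Fragments of `fragment_len` nt start every `step` nt around the circle
#' (wraparound allowed), each reverse-complemented with probability 1/2,
#' emulating unoriented ~1 kb subclones leaving exact overlaps.
#'
#' @param genome a circular [circ_seq].
#' @param fragment_len fragment length in nt (<= genome length).
#' @param step distance between successive fragment starts; the overlap
#'   between neighbors is `fragment_len - step` (must be positive).
#' @param seed integer seed for the orientation draws.
#' @return list: `fragments` (named character vector) and `layout`
#'   (data.frame fragment, genome, offset, strand) recording the truth.
#' @export
shred <- function(genome, fragment_len = 1000L, step = 750L, seed = 1L) {
  stopifnot(is(genome, "circ_seq"), genome$topology == "circular")
  L <- genome$length
  if (fragment_len > L) stop("fragment_len exceeds genome length")
  if (step >= fragment_len) stop("step must be < fragment_len")
  set.seed(derive_seed(seed, 7L))
  starts <- seq(1L, L, by = step)
  d <- paste0(genome$residues, genome$residues)
  frs <- character(length(starts)); strands <- character(length(starts))
  for (i in seq_along(starts)) {
    fr <- substr(d, starts[i], starts[i] + fragment_len - 1L)
    flip <- stats::runif(1) < 0.5
    frs[i] <- if (flip) revcomp(fr) else fr
    strands[i] <- if (flip) "-" else "+"
  }
  names(frs) <- sprintf("frag%03d", seq_along(starts))
  list(fragments = frs,
       layout = data.frame(fragment = names(frs), genome = genome$id,
                           offset = starts, strand = strands))
}
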