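# Seeded simulator of multi-species, multi-individual, multi-locus aligned
# barcode datasets with known truth. The generator emulates the structure of
# a typical plant-barcoding study: a Yule species tree, one to a few
# individuals per species (singletons allowed), several loci with strongly
# unequal substitution rates (the nuclear locus fastest), indel-bearing
# loci, and optional chloroplast capture that makes all plastid loci
# discordant with the nuclear locus for one sister-species pair.
#
# Trees are held internally as nested lists of node heights (tips at height
# 0), so ultrametricity is preserved by construction; branch lengths are in
# expected substitutions/site at rate multiplier 1.

# ---- internal height-tree representation ------------------------------

.leaf <- function(label) list(height = 0, label = label)
.node <- function(height, children) list(height = height, children = children)

.is_leaf <- function(x) !is.null(x$label)

.tree_newick <- function(x) paste0(.nwk(x, NULL), ";")

.nwk <- function(x, parent_h) {
  s <- if (.is_leaf(x)) x$label
  else paste0("(", paste(vapply(x$children, .nwk, "", parent_h = x$height),
                         collapse = ","), ")")
  if (is.null(parent_h)) s
  else paste0(s, ":", sprintf("%.10f", parent_h - x$height))
}

.tree_phylo <- function(x) ape::read.tree(text = .tree_newick(x))

# scale all node heights by a factor
.tree_scale <- function(x, f) {
  x$height <- x$height * f
  if (!.is_leaf(x)) x$children <- lapply(x$children, .tree_scale, f = f)
  x
}

# lengthen every terminal branch by e (adds e to every internal height)
.tree_stretch_tips <- function(x, e) {
  if (.is_leaf(x)) return(x)
  x$height <- x$height + e
  x$children <- lapply(x$children, .tree_stretch_tips, e = e)
  x
}

.tree_leaves <- function(x) {
  if (.is_leaf(x)) return(x$label)
  unlist(lapply(x$children, .tree_leaves), use.names = FALSE)
}

# derive reproducible per-stage seeds from one master seed
.substream <- function(seed, k) {
  s <- (as.numeric(seed) + 104729 * k) %% 2147483647
  as.integer(s) + 1L
}

# ---- configuration ----------------------------------------------------

#' Locus configuration for the simulator
#'
#' @param name locus name.
#' @param length alignment length in columns.
#' @param rate substitution-rate multiplier relative to the species tree
#'   scale (the nuclear locus of a barcode study is typically the fastest).
#' @param kappa transition/transversion rate ratio of the K2P process.
#' @param indel_mean expected number of indel events on the alignment.
#' @param indel_len integer length range `c(min, max)` of an indel event,
#'   in columns.
#' @param inheritance `"nuclear"` or `"plastid"`; all plastid loci share one
#'   haplotype genealogy per individual, the nuclear locus has its own.
#' @return list of class `locus_config`.
#' @export
locus_config <- function(name, length, rate = 1, kappa = 2,
                         indel_mean = 0, indel_len = c(1L, 1L),
                         inheritance = c("plastid", "nuclear")) {
  inheritance <- match.arg(inheritance)
  stopifnot(length > 0, rate > 0, kappa > 0, indel_mean >= 0,
            all(indel_len >= 1L), indel_len[1L] <= indel_len[2L])
  structure(list(name = name, length = as.integer(length), rate = rate,
                 kappa = kappa, indel_mean = indel_mean,
                 indel_len = as.integer(indel_len),
                 inheritance = inheritance),
            class = "locus_config")
}

#' Simulation configuration
#'
#' Full parameterization of the synthetic barcode dataset generator.
#'
#' @param n_individuals integer vector: individuals sampled per species
#'   (values of 1 create singleton species); its length is the number of
#'   species.
#' @param loci list of [locus_config()] objects.
#' @param birth_rate Yule (pure-birth) speciation rate of the species tree.
#' @param mean_divergence if non-`NULL`, the species tree is rescaled so the
#'   mean tip-to-tip path length equals this value (substitutions/site at
#'   rate 1).
#' @param min_divergence if non-`NULL`, terminal branches are lengthened
#'   equally until the smallest tip-to-tip path length is at least this
#'   value (keeps the tree ultrametric).
#' @param intra_depth expected within-species coalescent depth; the expected
#'   intraspecific distance at rate 1 is twice this. 0 gives identical
#'   conspecific sequences.
#' @param introgression_prob probability that a sister-species pair
#'   undergoes chloroplast capture (plastid loci only).
#' @param introgression_pairs optional list of `c(recipient, donor)` species
#'   name pairs for which capture is forced regardless of probability.
#' @param missing named list: locus name -> sample ids to drop from that
#'   locus (emulates amplification failure for some samples).
#' @param seed integer master seed; mandatory. All stages draw from named
#'   substreams derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, loci, birth_rate = 1,
                       mean_divergence = NULL, min_divergence = NULL,
                       intra_depth = 0.002, introgression_prob = 0,
                       introgression_pairs = NULL, missing = list(),
                       seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  n_individuals <- as.integer(n_individuals)
  if (length(n_individuals) < 2L) stop("need at least 2 species")
  if (any(n_individuals < 1L)) stop("each species needs >= 1 individual")
  if (!length(loci)) stop("need at least one locus")
  if (!all(vapply(loci, inherits, TRUE, "locus_config")))
    stop("'loci' must be a list of locus_config objects")
  names(loci) <- vapply(loci, `[[`, "", "name")
  stopifnot(birth_rate > 0, intra_depth >= 0,
            introgression_prob >= 0, introgression_prob <= 1)
  structure(list(n_species = length(n_individuals),
                 n_individuals = n_individuals, loci = loci,
                 birth_rate = birth_rate,
                 mean_divergence = mean_divergence,
                 min_divergence = min_divergence,
                 intra_depth = intra_depth,
                 introgression_prob = introgression_prob,
                 introgression_pairs = introgression_pairs,
                 missing = missing, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: ", x$n_species, " species (",
      sum(x$n_individuals == 1L), " singletons), ",
      sum(x$n_individuals), " samples, ", length(x$loci),
      " loci, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# ---- species tree -----------------------------------------------------

#' Simulate a Yule species tree
#'
#' Backward construction: starting from `n` contemporaneous lineages, pairs
#' are merged at exponentially distributed waiting times (rate `k * birth`
#' while `k` lineages remain), giving an ultrametric pure-birth tree whose
#' expected root height is `(1/birth) * sum_{k=2}^{n} 1/k`.
#'
#' @param n number of species (>= 2).
#' @param birth_rate speciation rate.
#' @param labels optional tip labels (default `Taxon01`...).
#' @param seed optional integer seed.
#' @return an ultrametric `phylo` tree.
#' @export
simulate_species_tree <- function(n, birth_rate = 1, labels = NULL,
                                  seed = NULL) {
  .tree_phylo(.sim_yule(n, birth_rate, labels, seed))
}

.sim_yule <- function(n, birth_rate = 1, labels = NULL, seed = NULL) {
  if (n < 2L) stop("need at least 2 species")
  if (is.null(labels)) labels <- sprintf("Taxon%02d", seq_len(n))
  if (!is.null(seed)) set.seed(seed)
  lineages <- lapply(labels, .leaf)
  h <- 0
  for (k in seq(n, 2L)) {
    h <- h + rexp(1L, rate = k * birth_rate)
    pair <- sample.int(length(lineages), 2L)
    merged <- .node(h, lineages[pair])
    lineages <- c(lineages[-pair], list(merged))
  }
  lineages[[1L]]
}

# ---- individual genealogies -------------------------------------------

# replace each species leaf by a star of its individuals joining at depth
# delta (truncated below the species' terminal branch); `capture` maps
# recipient species -> donor species for plastid chloroplast capture
.attach_individuals <- function(x, parent_h, samples_of, delta_of, capture) {
  if (.is_leaf(x)) {
    sp <- x$label
    donors <- names(capture)[capture == sp]
    groups <- c(sp, donors[!is.na(donors)])
    if (sp %in% names(capture)) return(NULL)   # captured: samples move away
    ids <- unlist(samples_of[groups], use.names = FALSE)
    if (length(ids) == 1L) return(.leaf(ids))
    delta <- min(max(vapply(groups, function(g) delta_of[[g]], 0)),
                 0.9 * parent_h)
    return(.node(delta, lapply(ids, .leaf)))
  }
  kids <- lapply(x$children, .attach_individuals, parent_h = x$height,
                 samples_of = samples_of, delta_of = delta_of,
                 capture = capture)
  kids <- kids[!vapply(kids, is.null, TRUE)]
  if (length(kids) == 0L) return(NULL)
  if (length(kids) == 1L) return(kids[[1L]])   # suppress degree-2 node
  .node(x$height, kids)
}

#' Simulate per-locus genealogies over the sampled individuals
#'
#' Individuals of each species attach to their species lineage as a clade
#' joining at a within-species depth drawn from an exponential distribution
#' with mean `intra_depth` (truncated below the terminal branch). All
#' plastid loci share one genealogy per individual; the nuclear locus gets
#' an independent one. With probability `introgression_prob` per
#' sister-species pair (cherry of the species tree) — or always for pairs
#' listed in `introgression_pairs` — the recipient's plastid samples are
#' moved wholesale into the donor's within-species cluster (chloroplast
#' capture), and the event is recorded.
#'
#' @param sp_tree internal height-tree of species (from `.sim_yule`); users
#'   normally call [generate_dataset()] instead.
#' @param config a `sim_config`.
#' @param samples_of named list: species -> sample ids.
#' @param seed integer seed for this stage.
#' @return list with `nuclear` and `plastid` (height-trees over samples)
#'   and `introgression` (data frame `recipient`, `donor`).
#' @keywords internal
.simulate_genealogies <- function(sp_tree, config, samples_of, seed) {
  set.seed(seed)
  species <- names(samples_of)
  draw_delta <- function() {
    d <- if (config$intra_depth > 0)
      rexp(length(species), rate = 1 / config$intra_depth)
    else rep(0, length(species))
    setNames(d, species)
  }
  delta_nuc <- draw_delta()
  delta_pla <- draw_delta()
  # cherries of the species tree are the candidate capture pairs
  cherries <- .find_cherries(sp_tree)
  capture <- character(0)
  forced <- config$introgression_pairs
  if (!is.null(forced))
    for (p in forced) capture[p[[1L]]] <- p[[2L]]
  if (config$introgression_prob > 0 && length(cherries))
    for (ch in cherries) {
      if (ch[1L] %in% names(capture) || ch[2L] %in% names(capture)) next
      if (runif(1L) < config$introgression_prob) capture[ch[1L]] <- ch[2L]
    }
  root_h <- sp_tree$height
  nuclear <- .attach_individuals(sp_tree, parent_h = root_h * 1.111,
                                 samples_of, delta_nuc, capture = character(0))
  plastid <- .attach_individuals(sp_tree, parent_h = root_h * 1.111,
                                 samples_of, delta_pla, capture = capture)
  intro <- if (length(capture))
    data.frame(recipient = names(capture), donor = unname(capture),
               row.names = NULL)
  else data.frame(recipient = character(0), donor = character(0))
  list(nuclear = nuclear, plastid = plastid, introgression = intro)
}

.find_cherries <- function(x) {
  out <- list()
  walk <- function(node) {
    if (.is_leaf(node)) return(invisible())
    if (length(node$children) == 2L &&
        all(vapply(node$children, .is_leaf, TRUE)))
      out[[length(out) + 1L]] <<- sort(vapply(node$children, `[[`, "",
                                              "label"))
    lapply(node$children, walk)
    invisible()
  }
  walk(x)
  out
}

# ---- sequence evolution -----------------------------------------------

# K80 per-branch category probabilities for branch length t (subs/site)
.k80_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e4 <- exp(-4 * beta * t)
  e2 <- exp(-2 * (alpha + beta) * t)
  c(same = 0.25 + 0.25 * e4 + 0.5 * e2,
    ti = 0.25 + 0.25 * e4 - 0.5 * e2,
    tv = 0.5 - 0.5 * e4)   # total over the two transversion targets
}

# evolve integer-coded sequence (1..4) along one branch
.k80_step <- function(seq_int, t, kappa) {
  p <- .k80_probs(t, kappa)
  L <- length(seq_int)
  u <- runif(L)
  out <- seq_int
  ti <- u >= p[1L] & u < p[1L] + p[2L]
  tv <- u >= p[1L] + p[2L]
  out[ti] <- (seq_int[ti] + 1L) %% 4L + 1L          # A<->G, C<->T
  if (any(tv)) {
    odd <- seq_int %% 2L == 1L                      # purines A, G
    pick <- runif(sum(tv)) < 0.5
    tv1 <- ifelse(odd[tv], 2L, 1L)
    tv2 <- ifelse(odd[tv], 4L, 3L)
    out[tv] <- ifelse(pick, tv1, tv2)
  }
  out
}

#' Evolve sequences along a genealogy under the K2P model
#'
#' The root sequence is uniform over A/C/G/T; a Kimura two-parameter
#' substitution process with transition/transversion ratio `kappa` acts
#' along every branch (branch lengths in expected substitutions/site after
#' multiplication by the locus rate). Optional indel events are placed on
#' branches chosen proportionally to branch length and gap-code all
#' descendant sequences over a contiguous column run, so the alignment
#' stays rectangular.
#'
#' @param tree a `phylo` genealogy over sample ids, branch lengths at
#'   rate 1.
#' @param locus a [locus_config()].
#' @param species named character: species of each sample (for labels).
#' @param seed integer seed for this stage.
#' @return a [locus_alignment()].
#' @export
evolve_sequences <- function(tree, locus, species, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  L <- locus$length
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  seqs <- vector("list", n_tip + n_node)
  root <- n_tip + 1L
  seqs[[root]] <- sample.int(4L, L, replace = TRUE)
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
    t_e <- ord$edge.length[e] * locus$rate
    seqs[[to]] <- if (t_e > 0) .k80_step(seqs[[from]], t_e, locus$kappa)
    else seqs[[from]]
  }
  m <- do.call(rbind, seqs[seq_len(n_tip)])
  rownames(m) <- tree$tip.label
  chars <- matrix(.BC_BASES[m], nrow = n_tip, dimnames = dimnames(m))
  # indels: one event = one branch, one contiguous column run, gapping all
  # tips below the bearing branch
  n_ev <- if (locus$indel_mean > 0) rpois(1L, locus$indel_mean) else 0L
  if (n_ev > 0L) {
    below <- .tips_below(tree)
    w <- ord$edge.length
    if (sum(w) <= 0) w <- rep(1, length(w))
    for (i in seq_len(n_ev)) {
      e <- sample.int(nrow(ord$edge), 1L, prob = w)
      len <- if (locus$indel_len[1L] == locus$indel_len[2L])
        locus$indel_len[1L]
      else sample(seq(locus$indel_len[1L], locus$indel_len[2L]), 1L)
      len <- min(len, L)
      start <- sample.int(L - len + 1L, 1L)
      tips <- below[[ord$edge[e, 2L]]]
      chars[tips, start:(start + len - 1L)] <- "-"
    }
  }
  ids <- tree$tip.label
  locus_alignment(apply(chars, 1L, paste, collapse = ""),
                  species = unname(species[ids]), sample_id = ids,
                  locus = locus$name)
}

# tip indices below each node (index = node id)
.tips_below <- function(tree) {
  n_tip <- length(tree$tip.label)
  out <- vector("list", n_tip + tree$Nnode)
  for (i in seq_len(n_tip)) out[[i]] <- i
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    from <- ord$edge[e, 1L]; to <- ord$edge[e, 2L]
    out[[from]] <- c(out[[from]], out[[to]])
  }
  out
}

# ---- dataset orchestration --------------------------------------------

#' Generate a complete synthetic barcode dataset
#'
#' Runs the full generation path — species tree, per-individual nuclear and
#' plastid genealogies (with optional chloroplast capture), per-locus
#' sequence evolution, indels, and per-locus sample dropping — from one
#' master seed with named substreams per stage, so the output is fully
#' deterministic.
#'
#' @param config a [sim_config()].
#' @return object of class `barcode_sim`: list with `loci` (named list of
#'   [locus_alignment()]), `truth` (sample table with species, subclade and
#'   introgression donor; generating trees in Newick), and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  species <- sprintf("Taxon%02d", seq_len(config$n_species))
  samples_of <- setNames(lapply(seq_along(species), function(i)
    sprintf("%s_i%d", sub("Taxon", "t", species[i]),
            seq_len(config$n_individuals[i]))), species)
  sp_tree <- .sim_yule(config$n_species, config$birth_rate, species,
                       seed = .substream(config$seed, 1L))
  sp_phylo <- .tree_phylo(sp_tree)
  coph <- ape::cophenetic.phylo(sp_phylo)
  off <- coph[upper.tri(coph)]
  if (!is.null(config$mean_divergence)) {
    sp_tree <- .tree_scale(sp_tree, config$mean_divergence / mean(off))
    sp_phylo <- .tree_phylo(sp_tree)
    coph <- ape::cophenetic.phylo(sp_phylo)
    off <- coph[upper.tri(coph)]
  }
  if (!is.null(config$min_divergence) && min(off) < config$min_divergence)
    sp_tree <- .tree_stretch_tips(sp_tree,
                                  (config$min_divergence - min(off)) / 2)
  gen <- .simulate_genealogies(sp_tree, config, samples_of,
                               seed = .substream(config$seed, 2L))
  sample_species <- species_of(structure(list(samples = samples_of),
                                         class = "species_map"))
  trees <- list(nuclear = .tree_phylo(gen$nuclear),
                plastid = .tree_phylo(gen$plastid))
  loci <- vector("list", length(config$loci))
  names(loci) <- names(config$loci)
  for (i in seq_along(config$loci)) {
    lc <- config$loci[[i]]
    gtree <- trees[[lc$inheritance]]
    aln <- evolve_sequences(gtree, lc, sample_species,
                            seed = .substream(config$seed, 2L + i))
    drop <- config$missing[[lc$name]]
    if (!is.null(drop))
      aln <- subset_alignment(aln, setdiff(aln$sample_id, drop))
    loci[[i]] <- aln
  }
  subclade <- .root_side(sp_tree)
  truth_tab <- data.frame(
    sample_id = names(sample_species),
    species = unname(sample_species),
    subclade = unname(subclade[sample_species]),
    introgression_donor = NA_character_, row.names = NULL)
  if (nrow(gen$introgression))
    truth_tab$introgression_donor <-
      gen$introgression$donor[match(truth_tab$species,
                                    gen$introgression$recipient)]
  structure(list(
    loci = loci,
    truth = list(table = truth_tab,
                 species_tree = .tree_newick(sp_tree),
                 gene_trees = lapply(trees, ape::write.tree),
                 introgression = gen$introgression),
    config = config), class = "barcode_sim")
}

# which side of the root each species sits on ("A"/"B"/...)
.root_side <- function(sp_tree) {
  sides <- lapply(sp_tree$children, .tree_leaves)
  out <- character(0)
  for (i in seq_along(sides))
    out[sides[[i]]] <- LETTERS[i]
  out
}

#' @export
print.barcode_sim <- function(x, ...) {
  cat("barcode_sim: ", x$config$n_species, " species, ",
      sum(x$config$n_individuals), " samples, loci: ",
      paste(names(x$loci), collapse = ", "), "\n", sep = "")
  if (nrow(x$truth$introgression))
    cat("  chloroplast capture: ",
        paste(x$truth$introgression$recipient, "<-",
              x$truth$introgression$donor, collapse = "; "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits one aligned FASTA per locus (headers `Species|sample`), the truth
#' table as TSV, and the generating trees as Newick.
#'
#' @param sim a `barcode_sim` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (aln in sim$loci)
    write_locus_fasta(aln, file.path(dir, paste0(aln$locus, ".fasta")))
  utils::write.table(sim$truth$table, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$species_tree, file.path(dir, "species_tree.nwk"))
  for (nm in names(sim$truth$gene_trees))
    writeLines(sim$truth$gene_trees[[nm]],
               file.path(dir, paste0("gene_tree_", nm, ".nwk")))
  invisible(dir)
}

#' Preset emulating a Pulsatilla-style barcoding study design
#'
#' 19 species in the sampling structure of a typical congeneric study
#' (1-5 individuals per species, 9 singletons, 52 samples), four loci with
#' strongly unequal substitution rates ordered nuclear ITS-like >
#' trnH-psbA-like ~ matK-like > rbcL-like, indels on the two indel-prone
#' loci, and two samples of one species missing the two slow plastid loci
#' (so those loci hold 50 individuals). Defaults give mean interspecific
#' divergence on the fastest locus near 0.03 substitutions/site and mean
#' intraspecific divergence near 0.003, the magnitudes a congeneric plant
#' barcode study reports.
#'
#' @param seed integer master seed (mandatory).
#' @param intra_depth expected within-species coalescent depth (rate-1
#'   scale); default 0.0016.
#' @param mean_divergence target mean species-tree tip-to-tip distance;
#'   default 0.032.
#' @param min_divergence optional floor on species-tree tip-to-tip
#'   distances (useful for known-truth runs); default `NULL`.
#' @param introgression_prob chloroplast-capture probability per sister
#'   pair; default 0.
#' @param introgression_pairs forced capture pairs, as in [sim_config()].
#' @return a [sim_config()].
#' @export
pulsatilla_profile <- function(seed, intra_depth = 0.0016,
                               mean_divergence = 0.032,
                               min_divergence = NULL,
                               introgression_prob = 0,
                               introgression_pairs = NULL) {
  counts <- c(5L, 4L, 5L, 4L, 5L, 4L, 4L, 4L, 4L, 4L, rep(1L, 9L))
  loci <- list(
    locus_config("rbcL", 1207L, rate = 0.11, kappa = 2,
                 inheritance = "plastid"),
    locus_config("matK", 835L, rate = 0.20, kappa = 2,
                 inheritance = "plastid"),
    locus_config("trnH-psbA", 379L, rate = 0.19, kappa = 2,
                 indel_mean = 11, indel_len = c(1L, 25L),
                 inheritance = "plastid"),
    locus_config("ITS", 589L, rate = 1, kappa = 2,
                 indel_mean = 5, indel_len = c(1L, 2L),
                 inheritance = "nuclear"))
  # species 8 (4 individuals) lacks the two slow plastid loci for two
  # samples, as when amplification fails for part of a series
  missing <- list(rbcL = c("t08_i2", "t08_i3"), matK = c("t08_i2", "t08_i3"))
  sim_config(n_individuals = counts, loci = loci, birth_rate = 1,
             mean_divergence = mean_divergence,
             min_divergence = min_divergence,
             intra_depth = intra_depth,
             introgression_prob = introgression_prob,
             introgression_pairs = introgression_pairs,
             missing = missing, seed = seed)
}
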