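#' Construct a per-site selection profile from partition blocks
#'
#' Builds the ground-truth per-site (alpha, beta) vectors for the simulator:
#' piecewise-constant omega over non-overlapping blocks tiling 1..n_sites,
#' with alpha fixed at 1 (so beta_s = omega_s), emulating coding sequences
#' with strongly purified core blocks, relaxed flanking blocks, and optional
#' sites under positive selection. Site 1 may be flagged as an invariant
#' initiator methionine: both rates 0 and the state pinned to ATG.
#'
#' @param blocks Either a named numeric vector like
#'   `c("1-40" = 0.8, "41-120" = 0.1)` or a data frame with columns `start`,
#'   `end`, `omega` and optionally `name`.
#' @param n_sites Total number of codon sites; the blocks must tile
#'   `1..n_sites` without overlap.
#' @param invariant_start_met Flag site 1 as an invariant ATG (default
#'   `FALSE`).
#' @return Data frame of class `site_profile`: `site`, `alpha`, `beta`,
#'   `omega`, `partition`, `invariant_start_met`, `planted_positive`.
#' @export
make_site_profile <- function(blocks, n_sites, invariant_start_met = FALSE) {
  if (is.numeric(blocks) && !is.null(names(blocks))) {
    rng <- lapply(names(blocks), function(s)
      as.integer(strsplit(s, "-")[[1]]))
    blocks <- data.frame(start = vapply(rng, `[`, 1L, 1),
                         end = vapply(rng, function(r) r[length(r)], 1L),
                         omega = unname(blocks),
                         name = names(blocks), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("start", "end", "omega") %in% names(blocks)))
  if (is.null(blocks$name))
    blocks$name <- paste0("block", seq_len(nrow(blocks)))
  if (any(blocks$omega < 0)) stop("block omega values must be >= 0")
  covered <- integer(0)
  for (i in seq_len(nrow(blocks))) {
    sites <- seq.int(blocks$start[i], blocks$end[i])
    if (length(intersect(covered, sites)))
      stop("overlapping blocks at sites ",
           paste(utils::head(intersect(covered, sites), 5), collapse = ","))
    covered <- c(covered, sites)
  }
  if (!setequal(covered, seq_len(n_sites)))
    stop("blocks must tile 1..", n_sites, " exactly")
  prof <- data.frame(site = seq_len(n_sites), alpha = 1, beta = NA_real_,
                     omega = NA_real_, partition = NA_character_,
                     invariant_start_met = FALSE, planted_positive = FALSE,
                     stringsAsFactors = FALSE)
  for (i in seq_len(nrow(blocks))) {
    sites <- seq.int(blocks$start[i], blocks$end[i])
    prof$omega[sites] <- blocks$omega[i]
    prof$beta[sites] <- blocks$omega[i]
    prof$partition[sites] <- blocks$name[i]
  }
  prof$planted_positive <- prof$omega > 1
  if (invariant_start_met) {
    prof$alpha[1] <- prof$beta[1] <- 0
    prof$omega[1] <- NA_real_
    prof$invariant_start_met[1] <- TRUE
    prof$planted_positive[1] <- FALSE
  }
  class(prof) <- c("site_profile", class(prof))
  prof
}

#' Simulate a codon alignment under MG94xREV with site-specific selection
#'
#' Forward simulation along a tree: root codons are drawn from the model's
#' equilibrium frequencies, and each branch transition samples the end state
#' directly from the per-site transition matrix built from (alpha_s, beta_s)
#' scaling the synonymous and nonsynonymous generator components. The
#' generator is normalized so that one unit of branch length equals one
#' expected substitution per codon site at omega = 1, hence a neutral
#' profile accrues substitutions at rate 1 per unit length. The same
#' (arguments, seed) pair always yields byte-identical output.
#'
#' @param profile A `site_profile` from [make_site_profile()].
#' @param n_taxa Number of taxa (>= 3; default 64, a desk-scale stand-in for
#'   the large vertebrate ortholog sets that give site-level methods their
#'   power).
#' @param seed Mandatory RNG seed.
#' @param tree Tree shape: `"yule"` (random topology), `"balanced"`
#'   (requires `n_taxa` a power of 2), or a `phylo` object with branch
#'   lengths (used as is; `n_taxa` ignored).
#' @param tree_length Total tree length in expected substitutions per codon
#'   site at omega = 1 (default 6); random and balanced trees are rescaled
#'   to this total.
#' @param rev_rates Nucleotide exchangeabilities for the generating model
#'   (default transition-biased: AG = CT = 4, others 1).
#' @param nuc_freqs 4 x 3 position-specific nucleotide frequencies (default
#'   uniform).
#' @return List of class `codon_simulation`: `alignment` (a
#'   `CodonAlignment`, reference = first taxon), `tree` (`phylo`), `truth`
#'   (the profile with per-site partition labels), `config` (echo of the
#'   generating settings).
#' @export
simulate_codon_alignment <- function(profile, n_taxa = 64, seed,
                                     tree = "yule", tree_length = 6,
                                     rev_rates = c(AC = 1, AG = 4, AT = 1,
                                                   CG = 1, CT = 4, GT = 1),
                                     nuc_freqs = NULL) {
  stopifnot(inherits(profile, "site_profile"))
  if (missing(seed)) stop("seed is mandatory for simulation")
  set.seed(seed)
  n_sites <- nrow(profile)

  if (inherits(tree, "phylo")) {
    phy <- tree
    if (is.null(phy$edge.length)) stop("user tree must have branch lengths")
    tree_shape <- "user"
  } else {
    tree_shape <- match.arg(tree, c("yule", "balanced"))
    if (n_taxa < 3L) stop("need at least 3 taxa")
    if (tree_shape == "balanced") {
      if (bitwAnd(n_taxa, n_taxa - 1L) != 0L)
        stop("balanced tree shape requires n_taxa to be a power of 2")
      phy <- ape::stree(n_taxa, "balanced")
      phy$edge.length <- rep(1, nrow(phy$edge))
    } else {
      phy <- ape::rtree(n_taxa)
    }
    phy$edge.length <- phy$edge.length * tree_length / sum(phy$edge.length)
  }
  phy$tip.label <- sprintf("taxon_%03d", seq_along(phy$tip.label))

  pars <- mg94_params(rev_rates, omega = 1, nuc_freqs = nuc_freqs)
  Qm <- mg94_rate_matrix(pars)  # S, N normalized at omega = 1
  pi <- Qm$freqs
  code <- .code()
  atg <- code$codon_index[["ATG"]]

  # distinct (alpha, beta) classes share decompositions and P matrices
  cls_key <- paste(profile$alpha, profile$beta)
  cls <- split(seq_len(n_sites), cls_key)
  decs <- lapply(cls, function(sites) {
    a <- profile$alpha[sites[1]]
    b <- profile$beta[sites[1]]
    if (a == 0 && b == 0) return(NULL)
    if (a > 0) list(dec = .codon_decomp(Qm$S + (b / a) * Qm$N, pi), scale = a)
    else list(dec = .codon_decomp(Qm$N, pi), scale = b)
  })

  tr <- ape::reorder.phylo(phy, "postorder")
  ntot <- length(tr$tip.label) + tr$Nnode
  root <- length(tr$tip.label) + 1L
  node_states <- matrix(NA_integer_, ntot, n_sites)
  node_states[root, ] <- sample.int(61L, n_sites, replace = TRUE, prob = pi)
  if (any(profile$invariant_start_met))
    node_states[root, profile$invariant_start_met] <- atg

  for (e in rev(seq_len(nrow(tr$edge)))) {  # preorder: root edges first
    p <- tr$edge[e, 1]
    ch <- tr$edge[e, 2]
    t <- tr$edge.length[e]
    node_states[ch, ] <- node_states[p, ]
    for (k in seq_along(cls)) {
      d <- decs[[k]]
      if (is.null(d)) next  # zero-rate sites stay put
      P <- d$dec$L %*% (exp(d$dec$values * t * d$scale) * d$dec$R)
      P[P < 0] <- 0
      for (s in cls[[k]]) {
        node_states[ch, s] <- sample.int(61L, 1L, prob = P[node_states[p, s], ])
      }
    }
  }

  tip_states <- node_states[seq_along(tr$tip.label), , drop = FALSE]
  seqs <- apply(tip_states, 1, function(st)
    paste(code$codons[st], collapse = ""))
  names(seqs) <- tr$tip.label
  seqs <- seqs[sort(names(seqs))]
  aln <- codon_alignment(seqs, reference = names(seqs)[1])

  structure(list(alignment = aln, tree = phy, truth = profile,
                 config = list(n_taxa = length(phy$tip.label), seed = seed,
                               tree = tree_shape, tree_length = tree_length,
                               rev_rates = rev_rates)),
            class = "codon_simulation")
}

#' Build a curation fixture with planted identity/similarity
#'
#' Generates a synthetic reference protein and a set of mutants engineered to
#' hit requested percent-identity and percent-similarity targets (within +/- 2
#' points, verified by [global_align()]): conservative substitutions (positive
#' BLOSUM62 score) raise similarity above identity, radical substitutions
#' (negative score) lower both. Matching coding sequences are emitted so the
#' fixture exercises the full curation path, and each record carries its
#' expected include/exclude truth at the 50/60 thresholds. Cysteine, glycine
#' and proline are excluded from the reference because they have no
#' positive-scoring substitute under BLOSUM62, which would make exact
#' similarity targets unreachable.
#'
#' @param targets Data frame with columns `identity` and `similarity`
#'   (percent, 0..100, similarity >= identity).
#' @param ref_length Reference protein length in residues (default 120).
#' @param seed Mandatory RNG seed.
#' @return List with `reference` (`ProteinRecord`), `records` (list of
#'   mutant `ProteinRecord`s with CDS), and `truth` (data frame: taxon,
#'   targets, achieved values, `expected_included`).
#' @export
make_curation_fixture <- function(targets, ref_length = 120, seed) {
  if (missing(seed)) stop("seed is mandatory for fixture generation")
  stopifnot(is.data.frame(targets),
            all(c("identity", "similarity") %in% names(targets)))
  if (any(targets$identity < 0 | targets$identity > 100 |
          targets$similarity < 0 | targets$similarity > 100))
    stop("identity/similarity targets must be within [0, 100]")
  if (any(targets$similarity < targets$identity))
    stop("similarity target cannot be below identity target")
  set.seed(seed)
  aa_pool <- setdiff(.aa20(), c("C", "G", "P"))
  ref_seq <- paste0("M", paste(sample(aa_pool, ref_length - 1L,
                                      replace = TRUE), collapse = ""))
  reference <- protein_record("reference", ref_seq,
                              .reverse_translate(ref_seq))
  mat <- .substitution_matrix("BLOSUM62")
  conservative <- lapply(stats::setNames(nm = .aa20()), function(a) {
    cand <- setdiff(.aa20(), a)
    cand[mat[a, cand] > 0]
  })
  radical <- lapply(stats::setNames(nm = .aa20()), function(a) {
    cand <- setdiff(.aa20(), a)
    cand[mat[a, cand] < 0]
  })

  rows <- list()
  records <- list()
  for (i in seq_len(nrow(targets))) {
    ti <- targets$identity[i]
    ts <- targets$similarity[i]
    n_diff <- round(ref_length * (1 - ti / 100))
    n_cons <- max(0L, round(ref_length * ts / 100) - (ref_length - n_diff))
    n_cons <- min(n_cons, n_diff)
    pos <- sample(2:ref_length, n_diff)  # never touch the initiator Met
    resid <- strsplit(ref_seq, "")[[1]]
    for (j in seq_len(n_diff)) {
      a <- resid[pos[j]]
      pool <- if (j <= n_cons) conservative[[a]] else radical[[a]]
      if (!length(pool)) stop("no usable substitute for residue ", a)
      resid[pos[j]] <- pool[sample.int(length(pool), 1L)]
    }
    mutant_seq <- paste(resid, collapse = "")
    taxon <- sprintf("mutant_%02d", i)
    rec <- protein_record(taxon, mutant_seq, .reverse_translate(mutant_seq))
    aln <- global_align(rec, reference)
    if (abs(aln$percent_identity - ti) > 2 ||
        abs(aln$percent_similarity - ts) > 2)
      stop("fixture generation missed targets for ", taxon,
           " (achieved ", round(aln$percent_identity, 1), "/",
           round(aln$percent_similarity, 1), ")")
    records[[taxon]] <- rec
    rows[[i]] <- data.frame(taxon = taxon,
                            target_identity = ti, target_similarity = ts,
                            achieved_identity = aln$percent_identity,
                            achieved_similarity = aln$percent_similarity,
                            expected_included = ti >= 50 && ts >= 60,
                            stringsAsFactors = FALSE)
  }
  list(reference = reference, records = records, truth = do.call(rbind, rows))
}

# deterministic reverse translation: alphabetically first codon per amino
# acid, TAA stop appended
.reverse_translate <- function(protein) {
  code <- .code()
  first_codon <- vapply(split(code$codons, code$aa), `[`, "", 1)
  resid <- strsplit(protein, "")[[1]]
  paste0(paste(first_codon[resid], collapse = ""), "TAA")
}
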