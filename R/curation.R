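#' Protein record
#'
#' A candidate ortholog: taxon label, amino-acid sequence (standard 20 letters
#' plus `X` for unknown residues), and optionally its source coding sequence,
#' whose in-frame translation must equal the protein (final stop codon may be
#' present or already stripped).
#'
#' @param taxon Taxon label.
#' @param sequence Amino-acid string.
#' @param source_cds Optional nucleotide CDS string.
#' @return Object of class `ProteinRecord`.
#' @export
protein_record <- function(taxon, sequence, source_cds = NULL) {
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("empty protein sequence for '", taxon, "'")
  bad <- setdiff(strsplit(sequence, "")[[1]], c(.aa20(), "X"))
  if (length(bad))
    stop("unknown residue character '", bad[1], "' in sequence for '", taxon, "'")
  if (!is.null(source_cds)) {
    source_cds <- toupper(gsub("U", "T", source_cds, fixed = TRUE))
    nres <- nchar(sequence)
    if (!nchar(source_cds) %in% c(3L * nres, 3L * nres + 3L))
      stop("source_cds length does not match protein length for '", taxon, "'")
    starts <- 3L * (seq_len(nres) - 1L) + 1L
    aa <- .translate_codons(substring(source_cds, starts, starts + 2L))
    aa[is.na(aa)] <- "X"
    prot <- strsplit(sequence, "")[[1]]
    if (any(aa != prot & aa != "X" & prot != "X"))
      stop("source_cds translation disagrees with protein for '", taxon, "'")
  }
  structure(list(taxon = taxon, sequence = sequence, source_cds = source_cds),
            class = "ProteinRecord")
}

.aa20 <- function() strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

.as_protein <- function(x, taxon = "query") {
  if (inherits(x, "ProteinRecord")) x else protein_record(taxon, x)
}

#' Scoring configuration for pairwise global protein alignment
#'
#' Defaults follow the conventions of the classical global aligner used for
#' ortholog screening: BLOSUM62 with affine gap penalties, end gaps penalized.
#' A gap of length L costs `gap_open + gap_extend * L`. The unknown residue
#' `X` scores 0 against everything and never counts as identical.
#'
#' @param matrix_name Substitution matrix name (`"BLOSUM62"` or `"BLOSUM50"`).
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty per residue (positive).
#' @return List of class `align_scoring` with the resolved substitution matrix.
#' @export
align_scoring <- function(matrix_name = "BLOSUM62", gap_open = 10,
                          gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be non-negative")
  mat <- .substitution_matrix(matrix_name)
  structure(list(matrix_name = matrix_name, matrix = mat,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

.substitution_matrix <- function(name) {
  key <- paste0("submat_", name)
  if (!is.null(.felscan_cache[[key]])) return(.felscan_cache[[key]])
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  m <- e[[name]]
  keep <- c(.aa20(), "X")
  m <- m[keep, keep]
  m["X", ] <- 0
  m[, "X"] <- 0
  storage.mode(m) <- "double"
  .felscan_cache[[key]] <- m
  m
}

#' Optimal global alignment of two protein sequences
#'
#' Needleman-Wunsch global alignment with affine gap penalties (end gaps
#' penalized). Percent identity is the fraction of alignment columns with
#' identical residues (`X` never counts); percent similarity is the fraction
#' of columns whose substitution score is positive. Both denominators include
#' gap columns, matching the reporting convention of the classical global
#' aligner used for ortholog inclusion screening.
#'
#' @param query,reference `ProteinRecord`s or plain amino-acid strings.
#' @param scoring An [align_scoring()] configuration.
#' @return List of class `PairwiseAlignmentResult`: `percent_identity`,
#'   `percent_similarity`, `aligned_query`, `aligned_reference`, `score`.
#' @export
global_align <- function(query, reference, scoring = align_scoring()) {
  q <- .as_protein(query, "query")
  r <- .as_protein(reference, "reference")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q$sequence), Biostrings::AAString(r$sequence),
    substitutionMatrix = scoring$matrix,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend,
    type = "global")
  aq <- as.character(Biostrings::alignedPattern(aln))
  ar <- as.character(Biostrings::alignedSubject(aln))
  stats <- .alignment_stats(aq, ar, scoring$matrix)
  structure(list(percent_identity = stats$identity,
                 percent_similarity = stats$similarity,
                 aligned_query = aq, aligned_reference = ar,
                 score = Biostrings::score(aln)),
            class = "PairwiseAlignmentResult")
}

.alignment_stats <- function(aq, ar, mat) {
  a <- strsplit(aq, "")[[1]]
  b <- strsplit(ar, "")[[1]]
  n <- length(a)
  resid <- a != "-" & b != "-"
  ident <- resid & a == b & a != "X"
  sim <- rep(FALSE, n)
  if (any(resid)) sim[resid] <- mat[cbind(a[resid], b[resid])] > 0
  list(identity = 100 * sum(ident) / n, similarity = 100 * sum(sim) / n)
}

#' Apply the ortholog inclusion thresholds
#'
#' Inclusion rule: a candidate is retained iff its percent identity and
#' percent similarity to the reference, over the global alignment, meet the
#' thresholds (boundary inclusive). Identity is checked first, so a record
#' failing both is reported as `below_identity`.
#'
#' @param records Data frame with at least `taxon`, `identity`, `similarity`
#'   columns (draft curation records).
#' @param identity_min Minimum percent identity (default 50).
#' @param similarity_min Minimum percent similarity (default 60).
#' @return The data frame with `included` (logical) and `exclusion_reason`
#'   (`"none"`, `"below_identity"`, `"below_similarity"`) set.
#' @export
apply_inclusion_filter <- function(records, identity_min = 50,
                                   similarity_min = 60) {
  if (identity_min < 0 || similarity_min < 0)
    stop("inclusion thresholds must be non-negative")
  stopifnot(all(c("identity", "similarity") %in% names(records)))
  reason <- rep("none", nrow(records))
  reason[records$similarity < similarity_min] <- "below_similarity"
  reason[records$identity < identity_min] <- "below_identity"  # checked first
  records$included <- reason == "none"
  records$exclusion_reason <- reason
  records
}

#' Trim a spurious N-terminal extension to the canonical start
#'
#' Residues of the query that align upstream of the reference's first residue
#' in the global alignment are removed; these correspond to in-silico
#' predicted N-terminal extensions with no experimental support, replaced by
#' the canonical initiation codon implied by the reference alignment. If the
#' first retained residue is not methionine a warning is issued but the
#' sequence is kept. Any source CDS is trimmed by 3 nucleotides per removed
#' residue.
#'
#' @param query,reference `ProteinRecord`s or strings.
#' @param scoring An [align_scoring()] configuration.
#' @return List with `record` (trimmed `ProteinRecord`) and `trimmed_offset`.
#' @export
trim_to_canonical_start <- function(query, reference,
                                    scoring = align_scoring()) {
  q <- .as_protein(query, "query")
  aln <- global_align(q, reference, scoring)
  a <- strsplit(aln$aligned_query, "")[[1]]
  b <- strsplit(aln$aligned_reference, "")[[1]]
  first_ref <- which(b != "-")[1]
  offset <- if (first_ref > 1) sum(a[seq_len(first_ref - 1L)] != "-") else 0L
  offset <- as.integer(offset)
  if (offset >= nchar(q$sequence))
    stop("trimming to the canonical start would empty sequence '", q$taxon, "'")
  if (offset == 0L)
    return(list(record = q, trimmed_offset = 0L))
  seq2 <- substring(q$sequence, offset + 1L)
  cds2 <- if (!is.null(q$source_cds)) substring(q$source_cds, 3L * offset + 1L)
  if (substring(seq2, 1L, 1L) != "M")
    warning("first retained residue of '", q$taxon,
            "' after canonical-start trimming is not Met")
  list(record = protein_record(q$taxon, seq2, cds2), trimmed_offset = offset)
}

#' Assign a candidate to an ortholog group by tree clustering
#'
#' Builds a neighbor-joining tree from pairwise global-alignment distances
#' (1 - identity/100) over the reference paralog panel plus the query, and
#' inspects the query's position: the adjacent subtree containing the tip
#' closest to the query (by patristic distance) is taken as its sister group.
#' If that subtree carries exactly one family label, the query is assigned to
#' it; if the nearest subtrees tie across different families, or the sister
#' clade mixes families, the candidate is unresolvable and `NA` is returned
#' (to be excluded as a non-ortholog).
#'
#' @param query `ProteinRecord` or string.
#' @param panel List of `ProteinRecord`s with a `family` attribute each, or a
#'   named character vector with names `"family|taxon"`.
#' @param scoring An [align_scoring()] configuration.
#' @return Family label (character) or `NA_character_`.
#' @export
assign_ortholog_group <- function(query, panel, scoring = align_scoring()) {
  q <- .as_protein(query, "query")
  panel <- .as_panel(panel)
  fams <- vapply(panel, function(p) attr(p, "family"), "")
  if (length(unique(fams)) < 2L)
    stop("reference panel must contain at least 2 distinct family labels")
  recs <- c(panel, list(q))
  n <- length(recs)
  if (n < 3L) stop("need at least 3 sequences to build a clustering tree")
  labs <- make.unique(vapply(recs, function(p) p$taxon, ""))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <-
      1 - global_align(recs[[i]], recs[[j]], scoring)$percent_identity / 100
  }
  tree <- nj_tree(d, labs)
  qtip <- which(tree$tip.label == labs[n])
  fam_of <- stats::setNames(c(fams, NA_character_), labs)

  # adjacent subtrees at the query's attachment node
  parent <- tree$edge[tree$edge[, 2] == qtip, 1]
  nbr_edges <- which(tree$edge[, 1] == parent & tree$edge[, 2] != qtip |
                     tree$edge[, 2] == parent)
  ntip <- length(tree$tip.label)
  groups <- lapply(nbr_edges, function(e) {
    if (tree$edge[e, 2] == parent) {
      # the "up" side: everything not below parent
      below <- .tips_below(tree, parent)
      setdiff(seq_len(ntip), c(below, qtip))
    } else {
      .tips_below(tree, tree$edge[e, 2])
    }
  })
  groups <- Filter(length, groups)
  if (!length(groups)) return(NA_character_)
  cd <- stats::cophenetic(tree)[tree$tip.label[qtip], ]
  mins <- vapply(groups, function(g) min(cd[tree$tip.label[g]]), 0)
  best <- which(mins <= min(mins) + 1e-9)
  fam_sets <- lapply(groups[best], function(g)
    unique(fam_of[tree$tip.label[g]]))
  if (length(best) > 1L) {
    u <- unique(unlist(fam_sets))
    if (length(u) != 1L || anyNA(u)) return(NA_character_)
    return(u)
  }
  fs <- fam_sets[[1]]
  if (length(fs) == 1L && !is.na(fs)) fs else NA_character_
}

.tips_below <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, .tips_below, tree = tree))
}

.as_panel <- function(panel) {
  if (is.character(panel)) {
    nm <- names(panel)
    if (is.null(nm) || any(!grepl("|", nm, fixed = TRUE)))
      stop("character panel must be named 'family|taxon'")
    panel <- lapply(seq_along(panel), function(i) {
      parts <- strsplit(nm[i], "|", fixed = TRUE)[[1]]
      r <- protein_record(parts[2], panel[[i]])
      attr(r, "family") <- parts[1]
      r
    })
  }
  ok <- vapply(panel, function(p)
    inherits(p, "ProteinRecord") && !is.null(attr(p, "family")), TRUE)
  if (!all(ok)) stop("panel members must be ProteinRecords with a family attribute")
  panel
}

#' Read a protein FASTA, optionally parsing "family|taxon" headers
#'
#' @param path FASTA file path.
#' @param panel If `TRUE`, headers are parsed as `family|taxon` and the family
#'   is attached as an attribute to each record.
#' @return List of `ProteinRecord`s.
#' @export
read_protein_fasta <- function(path, panel = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  lapply(seq_along(ss), function(i) {
    if (panel) {
      parts <- strsplit(nm[i], "|", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("panel FASTA headers must be 'family|taxon': ", nm[i])
      r <- protein_record(parts[2], as.character(ss[[i]]))
      attr(r, "family") <- parts[1]
      r
    } else {
      protein_record(nm[i], as.character(ss[[i]]))
    }
  })
}

#' Run the full curation stage on a set of candidate sequences
#'
#' For each candidate: global alignment against the reference, inclusion
#' filtering at the identity/similarity thresholds, canonical-start trimming,
#' and (if a paralog panel is supplied) ortholog-group assignment, where an
#' ambiguous placement excludes the candidate as `non_ortholog`.
#'
#' @param queries List of `ProteinRecord`s.
#' @param reference Reference `ProteinRecord` (or string).
#' @param panel Optional reference paralog panel (see [assign_ortholog_group()]).
#' @param identity_min,similarity_min Inclusion thresholds (percent).
#' @param trim Trim N-terminal extensions to the canonical start first.
#' @param scoring An [align_scoring()] configuration.
#' @return List with `report` (data frame: taxon, identity, similarity,
#'   included, exclusion_reason, assigned_family, trimmed_offset) and
#'   `records` (the trimmed `ProteinRecord`s of included candidates).
#' @export
curate_sequences <- function(queries, reference, panel = NULL,
                             identity_min = 50, similarity_min = 60,
                             trim = TRUE, scoring = align_scoring()) {
  reference <- .as_protein(reference, "reference")
  rows <- list()
  kept <- list()
  for (q in queries) {
    offset <- 0L
    if (trim) {
      tr <- trim_to_canonical_start(q, reference, scoring)
      q <- tr$record
      offset <- tr$trimmed_offset
    }
    aln <- global_align(q, reference, scoring)
    row <- data.frame(taxon = q$taxon,
                      identity = aln$percent_identity,
                      similarity = aln$percent_similarity,
                      assigned_family = NA_character_,
                      trimmed_offset = offset,
                      stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- row
    kept[[q$taxon]] <- q
  }
  report <- do.call(rbind, rows)
  report <- apply_inclusion_filter(report, identity_min, similarity_min)
  if (!is.null(panel)) {
    for (i in seq_len(nrow(report))) {
      if (!report$included[i]) next
      fam <- assign_ortholog_group(kept[[report$taxon[i]]], panel, scoring)
      report$assigned_family[i] <- fam
      if (is.na(fam)) {
        report$included[i] <- FALSE
        report$exclusion_reason[i] <- "non_ortholog"
      }
    }
  }
  report <- report[, c("taxon", "identity", "similarity", "included",
                       "exclusion_reason", "assigned_family", "trimmed_offset")]
  list(report = report, records = kept[report$taxon[report$included]])
}

#' Write a curation report TSV
#'
#' @param report The `report` data frame from [curate_sequences()].
#' @param path Output TSV path.
#' @export
write_curation_report <- function(report, path) {
  .write_tsv(.format_num_cols(report, c("identity", "similarity")), path)
}
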