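#' In-frame codon alignment with a designated reference row
#'
#' Container for a gapped, in-frame coding alignment. Sequences must share a
#' common length divisible by 3. One row is designated the reference (e.g. the
#' human ortholog); all site-level results are reported in reference codon
#' coordinates, and columns where the reference row is gapped are omitted from
#' site reports, mirroring the convention of reporting only codons with
#' homologous sites in the reference sequence.
#'
#' Codons containing gap characters or ambiguity codes are treated as missing
#' data. Codons that translate to stop are an error unless `mask_stops = TRUE`,
#' in which case they too become missing.
#'
#' @param sequences Named character vector of aligned nucleotide sequences
#'   (gaps as `-`), equal lengths divisible by 3.
#' @param reference Name of the reference taxon (must be in `names(sequences)`).
#' @param mask_stops Treat in-frame stop codons as missing instead of erroring.
#' @return An object of class `CodonAlignment`: list with `sequences`,
#'   `reference`, `n_col` (codon columns), `codon_chars` (taxa x columns
#'   character matrix), `states` (taxa x columns integer matrix of sense-codon
#'   indices, `NA` = missing).
#' @export
codon_alignment <- function(sequences, reference, mask_stops = FALSE) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("sequences must be a named character vector")
  if (anyDuplicated(names(sequences)))
    stop("duplicate taxon names in alignment")
  len <- unique(nchar(sequences))
  if (length(len) != 1L) stop("aligned sequences must have equal length")
  if (len %% 3L != 0L) stop("alignment length must be divisible by 3")
  if (!reference %in% names(sequences))
    stop("reference taxon '", reference, "' not found in alignment")
  n_col <- len %/% 3L
  code <- .code()
  seqs <- toupper(gsub("U", "T", sequences, fixed = TRUE))
  chars <- matrix("", length(seqs), n_col, dimnames = list(names(seqs), NULL))
  states <- matrix(NA_integer_, length(seqs), n_col,
                   dimnames = list(names(seqs), NULL))
  starts <- 3L * (seq_len(n_col) - 1L) + 1L
  for (i in seq_along(seqs)) {
    cods <- substring(seqs[i], starts, starts + 2L)
    chars[i, ] <- cods
    idx <- code$codon_index[cods]
    is_stop <- cods %in% code$stop_codons
    if (any(is_stop) && !mask_stops)
      stop("in-frame stop codon in '", names(seqs)[i], "' at codon column ",
           which(is_stop)[1], " (use mask_stops = TRUE to treat as missing)")
    states[i, ] <- unname(idx)
  }
  structure(list(sequences = seqs, reference = reference, n_col = n_col,
                 codon_chars = chars, states = states),
            class = "CodonAlignment")
}

#' @export
print.CodonAlignment <- function(x, ...) {
  cat("CodonAlignment:", nrow(x$states), "taxa x", x$n_col, "codon columns;",
      "reference:", x$reference, "\n")
  invisible(x)
}

#' Read a codon alignment from a FASTA file
#'
#' @param path FASTA file of aligned in-frame coding sequences.
#' @param reference Reference taxon name; defaults to the first record.
#' @param mask_stops Passed to [codon_alignment()].
#' @return A `CodonAlignment`.
#' @export
read_codon_alignment <- function(path, reference = NULL, mask_stops = FALSE) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  if (is.null(reference)) reference <- names(seqs)[1]
  codon_alignment(seqs, reference, mask_stops = mask_stops)
}

#' Write a codon alignment to FASTA
#'
#' @param alignment A `CodonAlignment`.
#' @param path Output file path.
#' @export
write_codon_alignment <- function(alignment, path) {
  con <- file(path, "wb")  # binary mode: byte-stable line endings
  on.exit(close(con))
  for (nm in names(alignment$sequences)) {
    writeLines(c(paste0(">", nm), alignment$sequences[[nm]]), con, sep = "\n")
  }
  invisible(path)
}

#' Map alignment columns to reference codon coordinates
#'
#' Columns where the reference row is gapped (or otherwise missing) map to
#' nothing and are excluded from all site-level reporting; the remaining
#' columns are numbered 1..reference_length in order.
#'
#' @param alignment A `CodonAlignment`.
#' @param reference_taxon Optional override of the alignment's reference row.
#' @return List of class `ReferenceColumnMap` with `column_to_ref`
#'   (integer per alignment column, `NA` where the reference is gapped),
#'   `ref_to_column` (integer per reference codon), and `reference_length`.
#' @export
map_alignment_to_reference <- function(alignment, reference_taxon = NULL) {
  stopifnot(inherits(alignment, "CodonAlignment"))
  ref <- if (is.null(reference_taxon)) alignment$reference else reference_taxon
  if (!ref %in% rownames(alignment$codon_chars))
    stop("reference taxon '", ref, "' not present in alignment")
  ref_codons <- alignment$codon_chars[ref, ]
  is_gap <- grepl("-", ref_codons, fixed = TRUE)
  if (all(is_gap)) stop("reference row is all gaps")
  column_to_ref <- rep(NA_integer_, alignment$n_col)
  column_to_ref[!is_gap] <- seq_len(sum(!is_gap))
  structure(list(column_to_ref = column_to_ref,
                 ref_to_column = which(!is_gap),
                 reference_length = sum(!is_gap)),
            class = "ReferenceColumnMap")
}

# columns whose observed states are all identical (ignoring missing); such
# columns yield the undefined 0/0 omega status in FEL and are excluded from
# aggregate fits
.invariant_columns <- function(alignment) {
  apply(alignment$states, 2, function(s) {
    s <- s[!is.na(s)]
    length(unique(s)) <= 1L
  })
}
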