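#' The universal genetic code as used by the codon model
#'
#' Builds a stable, alphabetically ordered view of the standard genetic code:
#' the 61 sense codons (the state space of the MG94xREV model), their amino
#' acids, and the 3 stop codons. The ordering is fixed (codons sorted
#' alphabetically over A < C < G < T) so that state indices are reproducible
#' across runs and platforms.
#'
#' @return A list of class `genetic_code` with elements
#'   \describe{
#'     \item{codons}{character(61), the sense codons in fixed order}
#'     \item{aa}{character(61), one-letter amino acid per sense codon}
#'     \item{stop_codons}{character(3)}
#'     \item{codon_index}{named integer, codon string -> state index (sense only)}
#'   }
#' @export
universal_genetic_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  codons <- sort(names(gc))
  aa <- unname(gc[codons])
  sense <- codons[aa != "*"]
  list2 <- list(
    codons = sense,
    aa = unname(gc[sense]),
    stop_codons = codons[aa == "*"],
    codon_index = stats::setNames(seq_along(sense), sense)
  )
  stopifnot(length(list2$codons) == 61L, length(list2$stop_codons) == 3L)
  class(list2) <- "genetic_code"
  list2
}

# cache: the code and the one-step-change table are fixed objects
.felscan_cache <- new.env(parent = emptyenv())

.code <- function() {
  if (is.null(.felscan_cache$code)) .felscan_cache$code <- universal_genetic_code()
  .felscan_cache$code
}

# Table of all single-nucleotide codon changes among sense codons.
# Columns: i, j (state indices), pos (1:3), from, to (nucleotide indices 1:4
# over ACGT), pair (1:6 over AC,AG,AT,CG,CT,GT), syn (logical).
.one_step_table <- function() {
  if (!is.null(.felscan_cache$steps)) return(.felscan_cache$steps)
  code <- .code()
  nt <- c("A", "C", "G", "T")
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  n <- nrow(cmat)
  rows <- vector("list", 3L * n)
  k <- 0L
  pair_id <- function(a, b) {
    p <- sort(c(a, b))
    match(paste(nt[p[1]], nt[p[2]]), c("A C", "A G", "A T", "C G", "C T", "G T"))
  }
  for (pos in 1:3) {
    for (i in seq_len(n)) {
      for (to in 1:4) {
        if (nt[to] == cmat[i, pos]) next
        cod <- cmat[i, ]
        cod[pos] <- nt[to]
        j <- code$codon_index[paste(cod, collapse = "")]
        if (is.na(j)) next  # change into a stop codon
        k <- k + 1L
        from <- match(cmat[i, pos], nt)
        rows[[k]] <- c(i, j, pos, from, to, pair_id(from, to),
                       as.integer(code$aa[i] == code$aa[j]))
      }
    }
  }
  steps <- do.call(rbind, rows[seq_len(k)])
  colnames(steps) <- c("i", "j", "pos", "from", "to", "pair", "syn")
  .felscan_cache$steps <- steps
  steps
}

.translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codons])
}
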