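#' MG94xREV model parameters
#'
#' Parameters of the MG94xREV codon substitution model: six symmetric
#' nucleotide exchangeabilities (AC, AG, AT, CG, CT, GT; GT is fixed to 1 for
#' identifiability), position-specific nucleotide frequencies (the F3x4
#' components from which the 61 sense-codon equilibrium frequencies are
#' formed), and the nonsynonymous/synonymous rate ratio omega.
#'
#' @param rev_rates Named numeric of length 6 (`AC, AG, AT, CG, CT, GT`).
#' @param omega dN/dS ratio, >= 0.
#' @param nuc_freqs 4 x 3 matrix of nucleotide frequencies (rows A,C,G,T;
#'   columns codon positions), each column summing to 1. Default uniform.
#' @return Object of class `MG94Params` with derived `codon_freqs` (61,
#'   summing to 1).
#' @export
mg94_params <- function(rev_rates = c(AC = 1, AG = 1, AT = 1, CG = 1,
                                      CT = 1, GT = 1),
                        omega = 1, nuc_freqs = NULL) {
  need <- c("AC", "AG", "AT", "CG", "CT", "GT")
  if (is.null(names(rev_rates))) names(rev_rates) <- need
  if (!setequal(names(rev_rates), need)) stop("rev_rates must be named ", paste(need, collapse = ","))
  rev_rates <- rev_rates[need]
  if (any(rev_rates < 0)) stop("exchangeabilities must be >= 0")
  if (omega < 0) stop("omega must be >= 0")
  if (is.null(nuc_freqs)) nuc_freqs <- matrix(0.25, 4, 3,
                                              dimnames = list(c("A", "C", "G", "T"), NULL))
  stopifnot(nrow(nuc_freqs) == 4, ncol(nuc_freqs) == 3)
  nuc_freqs <- sweep(nuc_freqs, 2, colSums(nuc_freqs), "/")
  structure(list(rev_rates = rev_rates, omega = omega,
                 nuc_freqs = nuc_freqs,
                 codon_freqs = .codon_freqs_f3x4(nuc_freqs)),
            class = "MG94Params")
}

# F3x4: product of position-specific nucleotide frequencies over the 61 sense
# codons, renormalized
.codon_freqs_f3x4 <- function(nuc_freqs) {
  code <- .code()
  cmat <- do.call(rbind, strsplit(code$codons, ""))
  cidx <- matrix(match(cmat, c("A", "C", "G", "T")), nrow = 61L)
  pr <- vapply(seq_len(61L), function(i)
    prod(nuc_freqs[cbind(cidx[i, ], 1:3)]), 0)
  stats::setNames(pr / sum(pr), code$codons)
}

#' Empirical F3x4 codon frequencies from an alignment
#'
#' Position-specific nucleotide frequencies counted over all non-missing
#' codons of all taxa, floored at a small value to keep every sense codon
#' reachable, then combined into codon frequencies by the F3x4 product rule.
#'
#' @param alignment A `CodonAlignment`.
#' @param floor Minimum per-position nucleotide frequency (default 1e-4).
#' @return 4 x 3 nucleotide frequency matrix (rows A,C,G,T).
#' @export
f3x4_frequencies <- function(alignment, floor = 1e-4) {
  stopifnot(inherits(alignment, "CodonAlignment"))
  obs <- alignment$codon_chars[!is.na(alignment$states)]
  nt <- c("A", "C", "G", "T")
  m <- vapply(1:3, function(pos) {
    tab <- table(factor(substring(obs, pos, pos), levels = nt))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(m) <- nt
  m <- pmax(m, floor)
  sweep(m, 2, colSums(m), "/")
}

# Unnormalized synonymous (S) and nonsynonymous (N) rate components: entry
# (i,j) for a one-step change via nucleotides x->y at position k is
# rev_rate(x,y) * nuc_freq(y, k). Diagonals make each component's rows sum to
# zero, so alpha*S + beta*N is a proper generator for any alpha, beta >= 0.
.mg94_components <- function(rev_rates, nuc_freqs) {
  steps <- .one_step_table()
  S <- matrix(0, 61, 61)
  N <- matrix(0, 61, 61)
  rate <- unname(rev_rates[steps[, "pair"]]) *
    nuc_freqs[cbind(steps[, "to"], steps[, "pos"])]
  syn <- steps[, "syn"] == 1L
  S[steps[syn, c("i", "j"), drop = FALSE]] <- rate[syn]
  N[steps[!syn, c("i", "j"), drop = FALSE]] <- rate[!syn]
  diag(S) <- -rowSums(S)
  diag(N) <- -rowSums(N)
  list(S = S, N = N)
}

#' Build the normalized MG94xREV rate matrix
#'
#' Off-diagonal rates are nonzero only between sense codons differing at one
#' nucleotide position; a change via nucleotides x->y at codon position k has
#' rate `rev_rate(x,y) * freq(y,k)`, multiplied by omega when the amino acid
#' changes. The generator is normalized so the expected number of
#' substitutions per codon site per unit branch length is 1 at the supplied
#' parameters.
#'
#' @param params An `MG94Params` object.
#' @return List of class `RateMatrix`: `Q` (61 x 61 generator), `scaling`
#'   (the normalization constant divided out), `freqs` (equilibrium codon
#'   frequencies), `S`, `N` (the normalized synonymous and nonsynonymous
#'   components, `Q = S + omega * N`).
#' @export
mg94_rate_matrix <- function(params) {
  stopifnot(inherits(params, "MG94Params"))
  comp <- .mg94_components(params$rev_rates, params$nuc_freqs)
  pi <- unname(params$codon_freqs)
  Q <- comp$S + params$omega * comp$N
  scaling <- -sum(pi * diag(Q))
  if (scaling <= 0) stop("degenerate rate matrix: zero total rate")
  structure(list(Q = Q / scaling, scaling = scaling, freqs = pi,
                 S = comp$S / scaling, N = comp$N / scaling),
            class = "RateMatrix")
}

# Symmetric eigendecomposition of a reversible generator M (detailed balance
# with respect to pi): P(t) = L diag(exp(lambda t)) R with L = D^{-1/2} U,
# R = U' D^{1/2}. Exact for reversible M and cheap to reuse across branch
# lengths and rate scalings.
.codon_decomp <- function(M, pi) {
  d <- sqrt(pi)
  Sym <- M * (d %o% (1 / d))
  Sym <- (Sym + t(Sym)) / 2
  e <- eigen(Sym, symmetric = TRUE)
  list(values = e$values, L = e$vectors / d,
       R = t(e$vectors) * rep(d, each = length(d)), pi = pi)
}

#' Transition probability matrix of the codon model
#'
#' `P(t) = exp(Q t)`, computed through the symmetric eigendecomposition of the
#' reversible generator. Tiny negative entries from round-off are clipped to 0.
#'
#' @param Q A `RateMatrix` from [mg94_rate_matrix()].
#' @param t Branch length (expected substitutions per codon site), >= 0.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(inherits(Q, "RateMatrix"))
  if (t < 0) stop("branch length must be >= 0")
  dec <- .codon_decomp(Q$Q, Q$freqs)
  P <- dec$L %*% (exp(dec$values * t) * dec$R)
  P[P < 0] <- 0
  P
}
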