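#' Fit the global MG94xREV model to an alignment
#'
#' Maximizes the alignment-wide log-likelihood over the five free nucleotide
#' exchangeabilities (GT fixed at 1), a single alignment-wide omega, and the
#' branch lengths, with codon equilibrium frequencies set empirically by the
#' F3x4 estimator (not optimized). This fit supplies the nuisance parameters
#' (branch lengths, exchangeabilities, frequencies) that the per-site FEL
#' fits and the partition-level aggregate fits hold fixed.
#'
#' Branch lengths are always refit under the codon model, so input trees in
#' other units (e.g. nucleotide substitutions) are re-estimated, not rescaled;
#' after the fit they are in expected substitutions per codon site.
#'
#' @param alignment A `CodonAlignment` with >= 3 taxa and >= 1 variable column.
#' @param tree A `phylo` tree over the alignment taxa (branch lengths used as
#'   starting values; missing lengths start at 0.1).
#' @param omega_init Starting omega (default 0.5).
#' @param freq_method `"F3x4"` (empirical, default) or `"uniform"`.
#' @param refit_branches Refit branch lengths (default `TRUE`).
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_outer Maximum alternations between the rate/omega step and the
#'   branch-length step.
#' @return Object of class `mg94_fit`: `params` (`MG94Params` at the optimum),
#'   `tree` (refit branch lengths, postorder), `logL`, `logL_trace` (monotone
#'   non-decreasing stage log), `converged`, and the normalized synonymous /
#'   nonsynonymous generator components `A`, `B` (so the fitted generator is
#'   `A + omega * B`, the per-site FEL generator `alpha * A + beta * B`).
#' @export
fit_global_model <- function(alignment, tree, omega_init = 0.5,
                             freq_method = c("F3x4", "uniform"),
                             refit_branches = TRUE, tol = 1e-6,
                             max_outer = 25L) {
  stopifnot(inherits(alignment, "CodonAlignment"))
  freq_method <- match.arg(freq_method)
  if (nrow(alignment$states) < 3L) stop("need at least 3 taxa")
  if (all(.invariant_columns(alignment)))
    stop("alignment has no variable columns")
  nf <- if (freq_method == "F3x4") f3x4_frequencies(alignment) else NULL
  pp <- .prep_tree(tree, alignment)
  elen <- pmin(pmax(pp$elen, 1e-8), 25)

  lik_at <- function(rev5, omega, elen) {
    pars <- mg94_params(c(rev5, GT = 1), omega, nf)
    Qm <- mg94_rate_matrix(pars)
    dec <- .codon_decomp(Qm$Q, Qm$freqs)
    ll <- sum(cpp_lik_all(dec$values, dec$L, dec$R, Qm$freqs, pp$edge, elen,
                          pp$ntip, pp$nnode, pp$states, 1.0))
    list(ll = ll, Qm = Qm, dec = dec)
  }

  rev5 <- c(AC = 1, AG = 1, AT = 1, CG = 1, CT = 1)
  omega <- omega_init
  cur <- lik_at(rev5, omega, elen)
  trace <- c(init = cur$ll)

  for (outer in seq_len(max_outer)) {
    ll_before <- cur$ll

    # (a) exchangeabilities + omega, branches fixed
    obj <- function(par) {
      r <- exp(par[1:5]); names(r) <- names(rev5)
      ll <- tryCatch(lik_at(r, exp(par[6]), elen)$ll, error = function(e) -Inf)
      if (!is.finite(ll)) -1e10 else ll
    }
    opt <- stats::optim(c(log(rev5), log(omega)), obj, method = "L-BFGS-B",
                        lower = log(1e-6), upper = log(100),
                        control = list(fnscale = -1, maxit = 200))
    if (opt$value > cur$ll) {
      rev5 <- stats::setNames(exp(opt$par[1:5]), c("AC", "AG", "AT", "CG", "CT"))
      omega <- exp(opt$par[6])
      cur <- lik_at(rev5, omega, elen)
    }
    trace <- c(trace, rates = cur$ll)

    # (b) branch lengths, model fixed: edge-wise Brent on cached partials
    if (refit_branches) {
      dec <- cur$dec
      parts <- cpp_edge_partials(dec$values, dec$L, dec$R, cur$Qm$freqs,
                                 pp$edge, elen, pp$ntip, pp$nnode,
                                 pp$states, 1.0)
      new_elen <- elen
      for (e in seq_along(elen)) {
        f <- function(t) cpp_edge_loglik(dec$values, dec$L, dec$R,
                                         parts$A[[e]], parts$A_scale[[e]],
                                         parts$D[[e]], parts$D_scale[[e]], t)
        o <- stats::optimize(f, c(0, 25), maximum = TRUE, tol = 1e-7)
        new_elen[e] <- if (f(0) >= o$objective) 0 else o$maximum
      }
      ll_new <- lik_at(rev5, omega, new_elen)$ll
      if (ll_new > cur$ll) {
        elen <- new_elen
        cur <- lik_at(rev5, omega, elen)
      } else {
        # simultaneous update overshot: fall back to sequential refits
        for (e in seq_along(elen)) {
          f <- function(t) {
            el <- elen; el[e] <- t
            lik_at(rev5, omega, el)$ll
          }
          o <- stats::optimize(f, c(0, 25), maximum = TRUE, tol = 1e-6)
          if (o$objective > cur$ll) {
            elen[e] <- o$maximum
            cur <- lik_at(rev5, omega, elen)
          }
        }
      }
      trace <- c(trace, branches = cur$ll)
    }
    if (cur$ll - ll_before < tol) break
  }
  converged <- outer < max_outer || cur$ll - ll_before < tol
  if (!converged)
    warning("global MG94xREV fit did not reach |dlogL| < ", tol,
            " within ", max_outer, " alternations; returning best found")

  tr <- pp$tree
  tr$edge.length <- elen
  pars <- mg94_params(c(rev5, GT = 1), omega, nf)
  Qm <- mg94_rate_matrix(pars)
  structure(list(params = pars, tree = tr, logL = cur$ll,
                 logL_trace = trace, converged = converged,
                 A = Qm$S, B = Qm$N, rate_matrix = Qm),
            class = "mg94_fit")
}

#' @export
print.mg94_fit <- function(x, ...) {
  cat("MG94xREV global fit: logL =", format(x$logL, digits = 10),
      " omega =", signif(x$params$omega, 6), "\n")
  cat("exchangeabilities:",
      paste(names(x$params$rev_rates),
            signif(x$params$rev_rates, 4), sep = "=", collapse = " "), "\n")
  invisible(x)
}
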