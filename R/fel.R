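# Fixed effects likelihood machinery. The per-site generator is
# alpha * A + beta * B, where A and B are the synonymous and nonsynonymous
# components of the global fit's normalized generator and branch lengths,
# exchangeabilities and frequencies are held fixed (two-stage FEL). Writing
# beta = omega * alpha, the generator is alpha * (A + omega * B): for a fixed
# omega a single eigendecomposition serves every alpha, which is the workhorse
# of both the per-site fits and the shared-omega aggregate fits.

.RATE_FLOOR <- 1e-8

.fel_context <- function(fit, alignment) {
  stopifnot(inherits(fit, "mg94_fit"), inherits(alignment, "CodonAlignment"))
  pp <- .prep_tree(fit$tree, alignment)
  ctx <- new.env(parent = emptyenv())
  ctx$A <- fit$A
  ctx$B <- fit$B
  ctx$pi <- fit$rate_matrix$freqs
  ctx$pp <- pp
  ctx$alignment <- alignment
  ctx$cache <- new.env(parent = emptyenv())
  ctx
}

# decomposition of A + omega * B (omega = 0, Inf handled as the pure
# synonymous / nonsynonymous components); the three reusable points
# (0, 1, Inf) are cached
.ctx_decomp <- function(ctx, omega) {
  key <- if (omega == 0) "w0" else if (is.infinite(omega)) "wInf"
         else if (omega == 1) "w1" else NA
  if (!is.na(key) && !is.null(ctx$cache[[key]])) return(ctx$cache[[key]])
  M <- if (omega == 0) ctx$A else if (is.infinite(omega)) ctx$B
       else ctx$A + omega * ctx$B
  dec <- .codon_decomp(M, ctx$pi)
  if (!is.na(key)) ctx$cache[[key]] <- dec
  dec
}

.site_lik <- function(ctx, dec, col, scale) {
  cpp_lik_site(dec$values, dec$L, dec$R, ctx$pi, ctx$pp$edge, ctx$pp$elen,
               ctx$pp$ntip, ctx$pp$nnode, col, scale)
}

# likelihood at zero rates: the column evolves nowhere, so the probability is
# the equilibrium frequency of the (single) observed state, or 1 if nothing
# is observed, or 0 if the column varies
.lik_zero <- function(ctx, col) {
  s <- unique(col[col > 0L])
  if (length(s) == 0L) return(0)
  if (length(s) > 1L) return(-Inf)
  log(ctx$pi[s])
}

# profile over the overall rate scale (alpha, with beta = omega * alpha baked
# into dec) for one column; the zero-rate boundary competes with the interior
.profile_alpha <- function(ctx, dec, col, bounds = c(1e-7, 1e3)) {
  # a boundary generator (omega = 0 or Inf) can be unable to produce the
  # column at all; floor the impossible case so the optimizer stays finite
  f <- function(la) {
    v <- .site_lik(ctx, dec, col, exp(la))
    if (is.finite(v)) v else -1e12
  }
  opt <- stats::optimize(f, log(bounds), maximum = TRUE, tol = 1e-6)
  l0 <- .lik_zero(ctx, col)
  # prefer the boundary within numerical noise so invariant columns land
  # exactly on the zero-rate solution
  if (l0 >= opt$objective - 1e-9) list(alpha = 0, loglik = l0)
  else list(alpha = exp(opt$maximum), loglik = opt$objective)
}

# summed profile log-likelihood at a shared omega over a list of parts, each
# part = list(ctx, cols = alignment column indices); per-site alphas profiled
.shared_profile <- function(parts, omega) {
  total <- 0
  alphas <- vector("list", length(parts))
  for (k in seq_along(parts)) {
    ctx <- parts[[k]]$ctx
    dec <- .ctx_decomp(ctx, omega)
    cols <- parts[[k]]$cols
    a <- numeric(length(cols))
    for (m in seq_along(cols)) {
      pr <- .profile_alpha(ctx, dec, ctx$pp$states[, cols[m]])
      a[m] <- pr$alpha
      total <- total + pr$loglik
    }
    alphas[[k]] <- a
  }
  list(loglik = total, alphas = alphas)
}

# Shared-omega maximum likelihood over one or more site sets, with
# profile-likelihood confidence bounds. This single engine backs the FEL
# alternative fit (one site), the partition-level aggregate fits, and the
# joint (null) fit of a two-partition comparison.
.fit_shared_omega <- function(parts, ci_level = 0.95, ci = TRUE,
                              omega_bounds = c(1e-4, 1e4), ci_cap = 1e4) {
  g <- function(w) .shared_profile(parts, w)$loglik
  opt <- stats::optimize(function(lw) g(exp(lw)), log(omega_bounds),
                         maximum = TRUE, tol = 1e-6)
  cand <- list(list(omega = exp(opt$maximum), loglik = opt$objective),
               list(omega = 0, loglik = g(0)),
               list(omega = Inf, loglik = g(Inf)))
  best <- cand[[which.max(vapply(cand, `[[`, 0, "loglik"))]]
  omega_hat <- best$omega
  prof <- .shared_profile(parts, omega_hat)
  logL <- prof$loglik

  ci_lower <- ci_upper <- NA_real_
  if (ci) {
    if (ci_level <= 0 || ci_level >= 1) stop("ci_level must be in (0, 1)")
    cutoff <- logL - stats::qchisq(ci_level, df = 1) / 2
    h <- function(lw) g(exp(lw)) - cutoff
    lo_edge <- log(1e-6)
    hi_edge <- log(ci_cap)
    anchor <- log(min(max(if (is.finite(omega_hat) && omega_hat > 0)
      omega_hat else 1e-6, 1e-6), ci_cap))
    safe_root <- function(lo, hi, fallback) {
      r <- tryCatch(stats::uniroot(h, c(lo, hi), tol = 1e-4),
                    error = function(e) NULL)
      if (is.null(r)) fallback else exp(r$root)
    }
    # lower bound
    if (g(0) >= cutoff - 1e-9 || h(lo_edge) >= 0) {
      ci_lower <- 0
    } else {
      ci_lower <- safe_root(lo_edge, anchor, exp(anchor))
    }
    # upper bound
    if (is.infinite(omega_hat) || h(hi_edge) >= 0) {
      ci_upper <- Inf
    } else {
      ci_upper <- safe_root(anchor, hi_edge, exp(anchor))
    }
  }
  list(omega = omega_hat, logL = logL, alphas = prof$alphas,
       ci_lower = ci_lower, ci_upper = ci_upper)
}

#' Fit the FEL model at a single codon site
#'
#' Maximizes the site likelihood over the synonymous rate alpha and
#' nonsynonymous rate beta (scaling the synonymous and nonsynonymous
#' components of the global generator on all branches, with all global
#' nuisance parameters fixed). The null model constrains alpha = beta; the
#' likelihood-ratio statistic is referred to the asymptotic chi-square
#' distribution with 1 degree of freedom. A 95 percent profile-likelihood
#' interval for omega = beta/alpha is reported, the lower bound floored at 0
#' and the upper flagged infinite beyond the search cap.
#'
#' Rates below 1e-8 are reported as 0 when determining the omega status:
#' an invariant column gives alpha = beta = 0 (omega undefined, 0/0, as for
#' strictly conserved initiator methionines); a column with nonsynonymous but
#' no synonymous variation gives the infinite status (beta/0).
#'
#' @param alignment A `CodonAlignment`.
#' @param fit The global `mg94_fit`.
#' @param site Reference codon index (1-based, in reference coordinates).
#' @param p_threshold LRT p-value threshold for the selection class
#'   (default 0.1).
#' @param ci_level Profile-likelihood confidence level (default 0.95).
#' @return One-row data frame (a `SiteResult`): `site`, `alpha`, `beta`,
#'   `omega`, `omega_status`, `ci_lower`, `ci_upper`, `lrt`, `p_value`,
#'   `class`.
#' @export
fel_fit_site <- function(alignment, fit, site, p_threshold = 0.1,
                         ci_level = 0.95) {
  map <- map_alignment_to_reference(alignment)
  if (!is.numeric(site) || site < 1 || site > map$reference_length)
    stop("site index ", site, " is not a mapped reference codon (1..",
         map$reference_length, ")")
  ctx <- .fel_context(fit, alignment)
  .fel_fit_site_ctx(ctx, map$ref_to_column[site], site, p_threshold, ci_level)
}

.fel_fit_site_ctx <- function(ctx, column, site, p_threshold, ci_level) {
  col <- ctx$pp$states[, column]
  alt <- .fit_shared_omega(list(list(ctx = ctx, cols = column)),
                           ci_level = ci_level, ci = TRUE)
  scale_hat <- alt$alphas[[1]][1]
  if (alt$omega == 0) {
    alpha <- scale_hat; beta <- 0
  } else if (is.infinite(alt$omega)) {
    alpha <- 0; beta <- scale_hat
  } else {
    alpha <- scale_hat; beta <- alt$omega * scale_hat
  }
  if (alpha < .RATE_FLOOR) alpha <- 0
  if (beta < .RATE_FLOOR) beta <- 0

  if (alpha == 0 && beta == 0) {
    status <- "undefined_0_over_0"; omega <- NA_real_
  } else if (alpha == 0) {
    status <- "infinite_beta_over_0"; omega <- Inf
  } else {
    status <- "defined"; omega <- beta / alpha
  }

  dec_null <- .ctx_decomp(ctx, 1)
  null <- .profile_alpha(ctx, dec_null, col)
  lrt <- max(0, 2 * (alt$logL - null$loglik))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)

  res <- data.frame(site = site, alpha = alpha, beta = beta, omega = omega,
                    omega_status = status,
                    ci_lower = if (status == "undefined_0_over_0") NA_real_ else alt$ci_lower,
                    ci_upper = if (status == "undefined_0_over_0") NA_real_ else alt$ci_upper,
                    lrt = lrt, p_value = p, class = NA_character_,
                    stringsAsFactors = FALSE)
  res$class <- classify_site(res, p_threshold)
  res
}

#' Selection class of a site result
#'
#' `purifying` if omega < 1 with p at or below the threshold, `diversifying`
#' if omega > 1 with p at or below the threshold, `neutral` otherwise, and
#' `undefined` for sites with the 0/0 omega status (e.g. strictly conserved
#' Met/Trp codons).
#'
#' @param result A `SiteResult` row (or data frame of them).
#' @param p_threshold LRT p-value threshold (default 0.1).
#' @return Character vector of classes.
#' @export
classify_site <- function(result, p_threshold = 0.1) {
  mapply(function(status, omega, p) {
    if (status == "undefined_0_over_0") return("undefined")
    if (is.na(p) || p > p_threshold) return("neutral")
    if (is.infinite(omega) || omega > 1) return("diversifying")
    if (omega < 1) return("purifying")
    "neutral"
  }, result$omega_status, result$omega, result$p_value, USE.NAMES = FALSE)
}

#' Site-by-site FEL scan over all mapped reference codons
#'
#' Runs [fel_fit_site()] for every codon with a homologous site in the
#' reference sequence, in reference order, and attaches per-class summary
#' counts.
#'
#' @inheritParams fel_fit_site
#' @return Data frame of `SiteResult` rows (class `fel_scan`), one per mapped
#'   reference codon, with the class summary from [summarize_classes()] as
#'   attribute `"summary"`.
#' @export
fel_scan <- function(alignment, fit, p_threshold = 0.1, ci_level = 0.95) {
  map <- map_alignment_to_reference(alignment)
  ctx <- .fel_context(fit, alignment)
  rows <- lapply(seq_len(map$reference_length), function(s)
    .fel_fit_site_ctx(ctx, map$ref_to_column[s], s, p_threshold, ci_level))
  out <- do.call(rbind, rows)
  attr(out, "summary") <- summarize_classes(out)
  class(out) <- c("fel_scan", class(out))
  out
}

#' @export
print.fel_scan <- function(x, ...) {
  cat("FEL scan over", nrow(x), "reference codons\n")
  print(attr(x, "summary"))
  invisible(x)
}
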