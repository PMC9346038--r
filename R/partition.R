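#' Define a partition of reference codon sites
#'
#' A named set of reference codon positions analyzed as a unit: a structural
#' region (e.g. the N-terminal region, central region, alpha-crystallin
#' domain, C-terminal extension), an exon, or the full-length sequence.
#'
#' @param name Partition name (e.g. `"NTR"`, `"exon2"`, `"FL"`).
#' @param sites Integer vector of 1-based reference codon indices.
#' @param category One of `"region"`, `"exon"`, `"full_length"`.
#' @return Object of class `Partition`.
#' @export
partition <- function(name, sites, category = c("region", "exon",
                                                "full_length")) {
  category <- match.arg(category)
  sites <- sort(unique(as.integer(sites)))
  if (!length(sites) || any(sites < 1L)) stop("partition sites must be >= 1")
  structure(list(name = name, sites = sites, category = category),
            class = "Partition")
}

#' Read partition definitions from a TSV config
#'
#' Expected columns: `name`, `category`, `ranges`, where `ranges` is a
#' comma-separated list of 1-based inclusive codon ranges in reference
#' coordinates (e.g. `"1-85"` or `"1-40,90-110"`).
#'
#' @param path TSV file path.
#' @return Named list of `Partition` objects.
#' @export
read_partitions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "category", "ranges") %in% names(df)))
  if (anyDuplicated(df$name)) stop("duplicate partition names in config")
  out <- lapply(seq_len(nrow(df)), function(i)
    partition(df$name[i], .parse_ranges(df$ranges[i]), df$category[i]))
  stats::setNames(out, df$name)
}

.parse_ranges <- function(spec) {
  parts <- strsplit(gsub("\\s", "", spec), ",")[[1]]
  unlist(lapply(parts, function(p) {
    ab <- as.integer(strsplit(p, "-")[[1]])
    if (anyNA(ab)) stop("bad codon range: ", p)
    if (length(ab) == 1L) ab else seq.int(ab[1], ab[2])
  }))
}

#' Aggregate omega estimate for a partition
#'
#' Fits a single aggregate omega over the partition's usable sites, with the
#' global nuisance parameters fixed and each site's synonymous rate profiled
#' out, plus a profile-likelihood confidence interval by the same chi-square
#' rule as the site-level intervals. Sites with the undefined 0/0 omega
#' status (invariant columns, e.g. strictly conserved Met/Trp codons) are
#' excluded before fitting.
#'
#' @param alignment A `CodonAlignment`.
#' @param fit The global `mg94_fit` for this alignment.
#' @param part A `Partition` (sites in reference coordinates).
#' @param ci_level Confidence level (default 0.95).
#' @return Object of class `PartitionResult`: `name`, `category`,
#'   `omega_bar`, `ci_lower`, `ci_upper`, `logL`, `n_sites_used`.
#' @export
fit_aggregate_omega <- function(alignment, fit, part, ci_level = 0.95) {
  stopifnot(inherits(part, "Partition"))
  map <- map_alignment_to_reference(alignment)
  bad <- setdiff(part$sites, seq_len(map$reference_length))
  if (length(bad))
    stop("partition '", part$name, "' has sites outside reference coordinates: ",
         paste(utils::head(bad, 5), collapse = ","))
  ctx <- .fel_context(fit, alignment)
  cols <- map$ref_to_column[part$sites]
  usable <- !.invariant_columns(alignment)[cols]
  if (!any(usable))
    stop("partition '", part$name,
         "' has no usable sites after excluding undefined (invariant) codons")
  cols <- cols[usable]
  res <- .fit_shared_omega(list(list(ctx = ctx, cols = cols)),
                           ci_level = ci_level, ci = TRUE)
  structure(list(name = part$name, category = part$category,
                 omega_bar = res$omega, ci_lower = res$ci_lower,
                 ci_upper = res$ci_upper, logL = res$logL,
                 n_sites_used = length(cols),
                 sites = part$sites[usable],
                 ctx = ctx, cols = cols),
            class = "PartitionResult")
}

#' @export
print.PartitionResult <- function(x, ...) {
  cat(sprintf("Partition %s (%s): omega_bar = %.4g [%.4g, %s], %d sites\n",
              x$name, x$category, x$omega_bar, x$ci_lower,
              if (is.infinite(x$ci_upper)) "inf" else sprintf("%.4g", x$ci_upper),
              x$n_sites_used))
  invisible(x)
}

#' Likelihood-ratio comparison of two aggregate omega fits
#'
#' One-degree-of-freedom likelihood ratio test: the null model enforces a
#' single shared aggregate omega over both partitions (or genes), the
#' alternative estimates them separately. Partitions from the same alignment
#' must be disjoint; partitions from different alignments (cross-gene
#' comparisons) share only the aggregate omega under the null, each gene
#' keeping its own fixed nuisance parameters.
#'
#' @param fitA,fitB `PartitionResult`s from [fit_aggregate_omega()].
#' @return Object of class `ComparisonResult`: `a`, `b`, `omega_a`,
#'   `omega_b`, `lrt`, `p_value`, `higher` (name of the member with the
#'   greater aggregate omega).
#' @export
compare_aggregate <- function(fitA, fitB) {
  stopifnot(inherits(fitA, "PartitionResult"), inherits(fitB, "PartitionResult"))
  same_aln <- identical(fitA$ctx$alignment, fitB$ctx$alignment)
  if (same_aln && setequal(fitA$sites, fitB$sites)) {
    # identical site sets: the separate fit is the joint fit, degenerate test
    higher <- if (fitB$omega_bar > fitA$omega_bar) fitB$name else fitA$name
    return(structure(list(a = fitA$name, b = fitB$name,
                          omega_a = fitA$omega_bar, omega_b = fitB$omega_bar,
                          omega_shared = fitA$omega_bar,
                          lrt = 0, p_value = 1, higher = higher),
                     class = "ComparisonResult"))
  }
  if (same_aln) {
    shared <- intersect(fitA$sites, fitB$sites)
    if (length(shared))
      stop("partitions '", fitA$name, "' and '", fitB$name,
           "' overlap at sites: ", paste(utils::head(shared, 10), collapse = ","))
  }
  # canonical part order makes the test exactly symmetric in (A, B)
  parts <- list(list(ctx = fitA$ctx, cols = fitA$cols, name = fitA$name),
                list(ctx = fitB$ctx, cols = fitB$cols, name = fitB$name))
  parts <- parts[order(vapply(parts, `[[`, "", "name"))]
  null <- .fit_shared_omega(parts, ci = FALSE)
  lrt <- max(0, 2 * ((fitA$logL + fitB$logL) - null$logL))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  higher <- if (fitB$omega_bar > fitA$omega_bar) fitB$name else fitA$name
  structure(list(a = fitA$name, b = fitB$name,
                 omega_a = fitA$omega_bar, omega_b = fitB$omega_bar,
                 omega_shared = null$omega,
                 lrt = lrt, p_value = p, higher = higher),
            class = "ComparisonResult")
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("%s (%.4g) vs %s (%.4g): LRT = %.4g, p = %.3g, higher = %s\n",
              x$a, x$omega_a, x$b, x$omega_b, x$lrt, x$p_value, x$higher))
  invisible(x)
}
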