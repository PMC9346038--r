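# Orchestration: curate -> (tree) -> global fit -> FEL scan -> partition fits
# -> comparisons -> Hasse, with fixed-format TSV outputs so runs with the
# same inputs are byte-identical.

.write_tsv <- function(df, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}

# fixed serialization: rates 6 significant digits, p-values scientific with
# 3 digits, infinity as "inf", undefined as "NA"
.fmt_rate <- function(x) {
  ifelse(is.na(x), "NA",
         ifelse(is.infinite(x), "inf", formatC(x, digits = 6, format = "g")))
}

.fmt_p <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 3, format = "e"))
}

.format_num_cols <- function(df, rate_cols = character(), p_cols = character()) {
  for (cc in intersect(rate_cols, names(df))) df[[cc]] <- .fmt_rate(df[[cc]])
  for (cc in intersect(p_cols, names(df))) df[[cc]] <- .fmt_p(df[[cc]])
  df
}

#' Format a FEL site table for serialization
#'
#' @param site_results A `fel_scan` data frame.
#' @return Data frame of strings in the fixed output format.
#' @keywords internal
.format_site_results <- function(site_results) {
  .format_num_cols(as.data.frame(site_results),
                   rate_cols = c("alpha", "beta", "omega", "ci_lower",
                                 "ci_upper", "lrt"),
                   p_cols = "p_value")
}

#' Per-class counts and fractions of a FEL scan
#'
#' Counts sites per selection class and formats fractions in the
#' `"n/N; x.x%"` style used for reporting the share of, e.g., neutrally
#' evolving codons; a zero denominator is reported as `"0/0; -"`.
#'
#' @param site_results A `fel_scan` data frame (needs a `class` column).
#' @return Data frame: `class`, `count`, `fraction`, `label`.
#' @export
summarize_classes <- function(site_results) {
  classes <- c("purifying", "neutral", "diversifying", "undefined")
  n_total <- nrow(site_results)
  counts <- vapply(classes, function(k) sum(site_results$class == k), 0L)
  label <- if (n_total == 0) rep("0/0; -", length(classes)) else
    sprintf("%d/%d; %.1f%%", counts, n_total, 100 * counts / n_total)
  data.frame(class = classes, count = unname(counts),
             fraction = if (n_total == 0) rep(NA_real_, length(classes))
                        else unname(counts) / n_total,
             label = label, stringsAsFactors = FALSE)
}

#' Annotate sites of interest with their selection estimates
#'
#' Joins a list of 1-based reference codon positions (e.g. disease-associated
#' missense mutation sites) with the FEL scan results, and flags sites with
#' omega below 0.05, the benchmark used for sites under highly stringent
#' purifying selection.
#'
#' @param site_results A `fel_scan` data frame.
#' @param sites Data frame with columns `site`, `label` and optionally
#'   `phenotype`, or a TSV path with those columns.
#' @return Data frame joining the annotations with `omega`, `ci_lower`,
#'   `ci_upper`, `class`, plus logical `below_0.05`.
#' @export
report_sites_of_interest <- function(site_results, sites) {
  if (is.character(sites)) sites <- utils::read.delim(sites,
                                                      stringsAsFactors = FALSE)
  if (nrow(sites) == 0)
    return(data.frame(site = integer(), label = character(),
                      phenotype = character(), omega = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      class = character(), below_0.05 = logical(),
                      stringsAsFactors = FALSE))
  stopifnot(all(c("site", "label") %in% names(sites)))
  if (is.null(sites$phenotype)) sites$phenotype <- NA_character_
  bad <- setdiff(sites$site, site_results$site)
  if (length(bad))
    stop("sites of interest outside reference coordinates: ",
         paste(bad, collapse = ","))
  idx <- match(sites$site, site_results$site)
  out <- data.frame(site = sites$site, label = sites$label,
                    phenotype = sites$phenotype,
                    omega = site_results$omega[idx],
                    ci_lower = site_results$ci_lower[idx],
                    ci_upper = site_results$ci_upper[idx],
                    class = site_results$class[idx],
                    stringsAsFactors = FALSE)
  out$below_0.05 <- !is.na(out$omega) & out$omega < 0.05
  out
}

#' Run the full selection-analysis pipeline
#'
#' Orchestrates the complete analysis on one gene: optional curation of
#' candidate sequences, tree acquisition (user Newick or the neighbor-joining
#' fallback), the global MG94xREV fit, the site-level FEL scan, partition
#' aggregate fits, pairwise likelihood-ratio comparisons of all disjoint
#' partition pairs, and per-category Hasse diagrams. All outputs are TSV/DOT
#' text with fixed number formats, so identical inputs yield identical bytes.
#'
#' @param config Named list (or YAML file path, requires the `yaml` package)
#'   with entries:
#'   \describe{
#'     \item{alignment}{FASTA path or `CodonAlignment` (required)}
#'     \item{tree}{Newick path, `phylo`, or `"nj"` for the fallback
#'       (default `"nj"`)}
#'     \item{partitions}{partition TSV path or list of `Partition`s (optional)}
#'     \item{sites_of_interest}{TSV path or data frame (optional)}
#'     \item{curation}{list with `queries`, `reference`, optional `panel`
#'       FASTA paths (optional)}
#'     \item{out_dir}{output directory (required)}
#'     \item{p_site, alpha_hasse, ci_level, identity_min, similarity_min}{
#'       thresholds; defaults 0.1, 0.05, 0.95, 50, 60}
#'   }
#' @return Invisibly, a list with the in-memory results (`fit`, `sites`,
#'   `partitions`, `comparisons`, `hasse`, `report_paths`).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(tree = "nj", p_site = 0.1, alpha_hasse = 0.05,
                                ci_level = 0.95, identity_min = 50,
                                similarity_min = 60), config)
  if (is.null(cfg$alignment)) stop("config must name an alignment")
  if (is.null(cfg$out_dir)) stop("config must name an out_dir")
  for (fld in c("alignment", "tree", "partitions", "sites_of_interest")) {
    v <- cfg[[fld]]
    if (is.character(v) && length(v) == 1L && !identical(v, "nj") &&
        !file.exists(v))
      stop("config input does not exist: ", fld, " = ", v)
  }
  .chk <- function(x) if (x <= 0 || x >= 1) stop("threshold out of range")
  .chk(cfg$p_site); .chk(cfg$alpha_hasse); .chk(cfg$ci_level)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  logl <- c(sprintf("felscan %s", as.character(utils::packageVersion("felscan"))),
            sprintf("p_site=%g alpha_hasse=%g ci_level=%g identity_min=%g similarity_min=%g",
                    cfg$p_site, cfg$alpha_hasse, cfg$ci_level,
                    cfg$identity_min, cfg$similarity_min),
            if (!is.null(cfg$seed)) sprintf("seed=%d", cfg$seed))

  # curation (optional)
  if (!is.null(cfg$curation)) {
    cu <- cfg$curation
    queries <- if (is.character(cu$queries)) read_protein_fasta(cu$queries) else cu$queries
    ref <- if (is.character(cu$reference)) read_protein_fasta(cu$reference)[[1]] else cu$reference
    panel <- if (is.character(cu$panel)) read_protein_fasta(cu$panel, panel = TRUE) else cu$panel
    cur <- curate_sequences(queries, ref, panel, cfg$identity_min,
                            cfg$similarity_min)
    paths$curation <- file.path(cfg$out_dir, "curation_report.tsv")
    write_curation_report(cur$report, paths$curation)
    logl <- c(logl, sprintf("curation: %d candidates, %d included",
                            nrow(cur$report), sum(cur$report$included)))
  }

  aln <- if (is.character(cfg$alignment)) read_codon_alignment(cfg$alignment)
         else cfg$alignment
  tree <- if (inherits(cfg$tree, "phylo")) cfg$tree
  else if (identical(cfg$tree, "nj")) nj_tree(.alignment_p_distances(aln))
  else ape::read.tree(cfg$tree)

  fit <- fit_global_model(aln, tree)
  logl <- c(logl, sprintf("global fit: logL=%.6f omega=%.6g", fit$logL,
                          fit$params$omega))

  sites <- fel_scan(aln, fit, p_threshold = cfg$p_site,
                    ci_level = cfg$ci_level)
  paths$sites <- file.path(cfg$out_dir, "site_results.tsv")
  .write_tsv(.format_site_results(sites), paths$sites)
  summ <- summarize_classes(sites)
  paths$summary <- file.path(cfg$out_dir, "class_summary.tsv")
  .write_tsv(summ, paths$summary)

  if (!is.null(cfg$sites_of_interest)) {
    soi <- report_sites_of_interest(sites, cfg$sites_of_interest)
    paths$sites_of_interest <- file.path(cfg$out_dir, "sites_of_interest.tsv")
    .write_tsv(.format_num_cols(soi, c("omega", "ci_lower", "ci_upper")),
               paths$sites_of_interest)
  }

  part_fits <- list()
  comparisons <- list()
  hasse <- list()
  if (!is.null(cfg$partitions)) {
    parts <- if (is.character(cfg$partitions)) read_partitions(cfg$partitions)
             else cfg$partitions
    nm <- vapply(parts, `[[`, "", "name")
    if (anyDuplicated(nm)) stop("duplicate partition names")
    part_fits <- lapply(parts, function(p)
      fit_aggregate_omega(aln, fit, p, ci_level = cfg$ci_level))
    names(part_fits) <- nm
    pr <- data.frame(name = nm,
                     category = vapply(part_fits, `[[`, "", "category"),
                     omega_bar = vapply(part_fits, `[[`, 0, "omega_bar"),
                     ci_lower = vapply(part_fits, `[[`, 0, "ci_lower"),
                     ci_upper = vapply(part_fits, `[[`, 0, "ci_upper"),
                     n_sites_used = vapply(part_fits, `[[`, 0L, "n_sites_used"),
                     stringsAsFactors = FALSE)
    paths$partitions <- file.path(cfg$out_dir, "partition_report.tsv")
    .write_tsv(.format_num_cols(pr, c("omega_bar", "ci_lower", "ci_upper")),
               paths$partitions)

    if (length(part_fits) > 1) {
      pairs <- utils::combn(nm, 2)
      for (k in seq_len(ncol(pairs))) {
        a <- part_fits[[pairs[1, k]]]
        b <- part_fits[[pairs[2, k]]]
        if (length(intersect(a$sites, b$sites))) {
          logl <- c(logl, sprintf("comparison skipped (overlap): %s vs %s",
                                  a$name, b$name))
          next
        }
        comparisons[[length(comparisons) + 1L]] <- compare_aggregate(a, b)
      }
      if (length(comparisons)) {
        cdf <- data.frame(a = vapply(comparisons, `[[`, "", "a"),
                          b = vapply(comparisons, `[[`, "", "b"),
                          omega_a = vapply(comparisons, `[[`, 0, "omega_a"),
                          omega_b = vapply(comparisons, `[[`, 0, "omega_b"),
                          lrt = vapply(comparisons, `[[`, 0, "lrt"),
                          p_value = vapply(comparisons, `[[`, 0, "p_value"),
                          higher = vapply(comparisons, `[[`, "", "higher"),
                          stringsAsFactors = FALSE)
        paths$comparisons <- file.path(cfg$out_dir, "comparisons.tsv")
        .write_tsv(.format_num_cols(cdf, c("omega_a", "omega_b", "lrt"),
                                    "p_value"), paths$comparisons)
        # Hasse per category, where every within-category pair was compared
        for (cat in unique(pr$category)) {
          sub <- pr$name[pr$category == cat]
          if (length(sub) < 2) next
          sc <- cdf[cdf$a %in% sub & cdf$b %in% sub, , drop = FALSE]
          if (nrow(sc) < choose(length(sub), 2)) {
            logl <- c(logl, sprintf("hasse skipped (incomplete pairs): %s", cat))
            next
          }
          h <- build_hasse(pr[pr$category == cat, ], sc,
                           alpha = cfg$alpha_hasse)
          hasse[[cat]] <- h
          pth <- file.path(cfg$out_dir, sprintf("hasse_%s.dot", cat))
          write_hasse_dot(h, pth)
          paths[[paste0("hasse_", cat)]] <- pth
        }
      }
    }
  }

  paths$log <- file.path(cfg$out_dir, "run_log.txt")
  con <- file(paths$log, "wb")
  writeLines(logl, con, sep = "\n")
  close(con)

  invisible(list(fit = fit, sites = sites, partitions = part_fits,
                 comparisons = comparisons, hasse = hasse,
                 report_paths = paths))
}
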