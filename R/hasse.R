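#' Hasse diagram of significant aggregate-omega orderings
#'
#' Builds the transitively reduced directed graph of the significant partial
#' order among partitions or genes: for every pair whose aggregate omegas
#' differ significantly at level `alpha`, a directed edge points from the
#' member with the lower aggregate omega toward the member with the greater
#' one (i.e. toward less stringent purifying selection); edges implied by
#' transitivity are then removed. Because every edge points from a lower to
#' a higher omega, the diagram is acyclic by construction.
#'
#' @param results List of `PartitionResult`s (or a data frame with `name`
#'   and `omega_bar`).
#' @param comparisons List of `ComparisonResult`s (or a data frame with
#'   `a`, `b`, `p_value`, `higher`) covering every unordered pair of names.
#' @param alpha Significance level for drawing an edge (default 0.05).
#' @return Object of class `HasseDiagram`: `nodes` (data frame name,
#'   omega_bar, ordered by omega_bar), `edges` (data frame from, to, p_value),
#'   `alpha`.
#' @export
build_hasse <- function(results, comparisons, alpha = 0.05) {
  nodes <- if (is.data.frame(results)) results[, c("name", "omega_bar")]
  else data.frame(name = vapply(results, `[[`, "", "name"),
                  omega_bar = vapply(results, `[[`, 0, "omega_bar"),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(nodes$name)) stop("duplicate node names")
  cmp <- if (is.data.frame(comparisons)) comparisons
  else data.frame(a = vapply(comparisons, `[[`, "", "a"),
                  b = vapply(comparisons, `[[`, "", "b"),
                  p_value = vapply(comparisons, `[[`, 0, "p_value"),
                  higher = vapply(comparisons, `[[`, "", "higher"),
                  stringsAsFactors = FALSE)
  want <- utils::combn(sort(nodes$name), 2)
  have <- unique(apply(cmp[, c("a", "b")], 1, function(x)
    paste(sort(x), collapse = "\r")))
  missing <- apply(want, 2, paste, collapse = "\r")
  missing <- setdiff(missing, have)
  if (length(missing))
    stop("missing pairwise comparisons: ",
         paste(gsub("\r", " vs ", missing), collapse = "; "))

  nodes <- nodes[order(nodes$omega_bar, nodes$name), , drop = FALSE]
  rownames(nodes) <- NULL
  sig <- cmp[cmp$p_value <= alpha, , drop = FALSE]
  edges <- data.frame(from = character(), to = character(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (nrow(sig)) {
    to <- sig$higher
    from <- ifelse(sig$higher == sig$a, sig$b, sig$a)
    edges <- data.frame(from = from, to = to, p_value = sig$p_value,
                        stringsAsFactors = FALSE)
    edges <- edges[order(match(edges$from, nodes$name),
                         match(edges$to, nodes$name)), , drop = FALSE]
    rownames(edges) <- NULL
    edges <- .transitive_reduction(edges)
  }
  structure(list(nodes = nodes, edges = edges, alpha = alpha),
            class = "HasseDiagram")
}

# drop every edge (u, v) for which a directed path u -> v exists through the
# remaining edges; graphs here are tiny, so plain DFS reachability suffices
.transitive_reduction <- function(edges) {
  keep <- rep(TRUE, nrow(edges))
  reach <- function(u, v, skip) {
    stack <- u
    seen <- character()
    while (length(stack)) {
      x <- stack[[1]]
      stack <- stack[-1]
      if (x %in% seen) next
      seen <- c(seen, x)
      nxt <- edges$to[keep & edges$from == x &
                      !(seq_len(nrow(edges)) == skip)]
      if (v %in% nxt) return(TRUE)
      stack <- c(stack, nxt)
    }
    FALSE
  }
  for (i in seq_len(nrow(edges))) {
    if (reach(edges$from[i], edges$to[i], skip = i)) keep[i] <- FALSE
  }
  out <- edges[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.HasseDiagram <- function(x, ...) {
  cat("Hasse diagram at alpha =", x$alpha, ":", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges\n")
  if (nrow(x$edges))
    cat(paste0("  ", x$edges$from, " -> ", x$edges$to, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a Hasse diagram as DOT text
#'
#' @param hasse A `HasseDiagram`.
#' @param path Output `.dot` file path.
#' @export
write_hasse_dot <- function(hasse, path) {
  stopifnot(inherits(hasse, "HasseDiagram"))
  lines <- c("digraph hasse {",
             "  rankdir=BT;",
             sprintf("  \"%s\" [label=\"%s\\nomega=%.3g\"];",
                     hasse$nodes$name, hasse$nodes$name, hasse$nodes$omega_bar))
  if (nrow(hasse$edges))
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                              hasse$edges$from, hasse$edges$to))
  lines <- c(lines, "}")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
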