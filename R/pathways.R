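#' Hypergeometric over-representation p-value for one pathway
#'
#' Exact upper tail `P(X >= x)` for
#' `X ~ Hypergeometric(N = |universe|, K = |members in universe|, n = |hits|)`
#' where `x` is the observed overlap between the hit list and the pathway
#' members. Pathway members are intersected with the universe before testing.
#'
#' @param hits Character set of selected compound ids (must lie in the
#'   universe).
#' @param pathway A `pathway_def` (see [load_pathway_library()]).
#' @param universe Character set of all detected/annotated compound ids.
#' @return Scalar p-value.
#' @export
ora_hypergeometric <- function(hits, pathway, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe))
    stop("hit(s) outside the universe: ",
         paste(setdiff(hits, universe), collapse = ", "))
  K <- length(intersect(pathway$members, universe))
  n <- length(hits)
  x <- length(intersect(hits, pathway$members))
  # exact tail sum of the hypergeometric mass function
  stats::phyper(x - 1, K, length(universe) - K, n, lower.tail = FALSE)
}

# pathway graph as igraph, isolated members included
pathway_graph <- function(pathway) {
  igraph::graph_from_data_frame(
    d = as.data.frame(pathway$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = pathway$members, stringsAsFactors = FALSE))
}

#' Topology-based pathway impact
#'
#' Relative-betweenness impact: node betweenness centrality is computed on the
#' undirected pathway graph, normalized so all centralities sum to one, and
#' the impact is the sum over hit nodes. Degenerate graphs whose centralities
#' are all zero (no node lies between any pair) get impact 0 with a warning.
#'
#' @inheritParams ora_hypergeometric
#' @return Impact in \[0, 1\].
#' @export
pathway_impact <- function(hits, pathway) {
  if (nrow(pathway$edges) == 0) return(0)
  g <- pathway_graph(pathway)
  bc <- igraph::betweenness(g, directed = FALSE)
  total <- sum(bc)
  if (total == 0) {
    warning("pathway ", pathway$pathway_id,
            ": all betweenness centralities are zero; impact set to 0")
    return(0)
  }
  sum(bc[names(bc) %in% hits]) / total
}

#' Pathway over-representation and impact analysis
#'
#' Per pathway: exact hypergeometric enrichment p-value of the selected
#' metabolites, Benjamini-Hochberg q across pathways, and relative-betweenness
#' impact. A pathway is flagged `potential` when `q <= q_max` or
#' `impact >= impact_min`.
#'
#' @param selected Character vector of selected compound ids.
#' @param library Pathway library (see [load_pathway_library()] /
#'   [triomix_library()]).
#' @param universe All detected/annotated compound ids.
#' @param q_max,impact_min Flagging thresholds (defaults 0.05 and 0.1).
#' @return `data.frame` with one row per pathway, sorted by p ascending then
#'   impact descending then id: `pathway_id`, `name`, `n_members`, `n_hits`,
#'   `expected_hits`, `p_ora`, `q`, `impact`, `potential`.
#' @export
analyze_pathways <- function(selected, library, universe,
                             q_max = 0.05, impact_min = 0.1) {
  universe <- unique(universe)
  selected <- unique(intersect(selected, universe))
  rows <- lapply(library, function(pw) {
    members_u <- intersect(pw$members, universe)
    hits <- intersect(selected, members_u)
    data.frame(pathway_id = pw$pathway_id, name = pw$name,
               n_members = length(members_u), n_hits = length(hits),
               expected_hits = length(selected) * length(members_u) /
                 max(length(universe), 1),
               p_ora = ora_hypergeometric(selected, pw, universe),
               impact = pathway_impact(hits, pw),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_ora)
  out$potential <- out$q <= q_max | out$impact >= impact_min
  out <- out[order(out$p_ora, -out$impact, out$pathway_id),
             c("pathway_id", "name", "n_members", "n_hits", "expected_hits",
               "p_ora", "q", "impact", "potential")]
  rownames(out) <- NULL
  out
}
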