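#' Read a metabolite-to-pathway map
#'
#' Two-column TSV (`pathway_id`, `metabolite_id`), optionally a third
#' `pathway_name` column. The background universe defaults to all annotated
#' metabolites in the map.
#'
#' @param path TSV path.
#' @return an object of class `pathway_map`: `pathways` (named list of member
#'   metabolite vectors), `names` (pathway display names), `background`.
#' @export
read_pathway_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway_id", "metabolite_id") %in% names(df)))
  pathways <- split(df$metabolite_id, df$pathway_id)
  pathways <- lapply(pathways, unique)
  if (any(lengths(pathways) == 0L)) stop("empty pathway in map")
  nm <- if ("pathway_name" %in% names(df)) {
    tapply(df$pathway_name, df$pathway_id, `[`, 1L)
  } else {
    stats::setNames(names(pathways), names(pathways))
  }
  structure(list(pathways = pathways, names = nm,
                 background = sort(unique(df$metabolite_id))),
            class = "pathway_map")
}

#' Pathway over-representation analysis
#'
#' One-sided hypergeometric test per pathway: with `N` background
#' metabolites, `K` of them in the pathway and `n` panel metabolites in the
#' background of which `k` hit the pathway, the p-value is the upper tail
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`. Benjamini-Hochberg
#' q-values are reported across the tested pathways; the `significant` flag
#' follows the raw p-value at `alpha` (q-values alongside for the
#' multiplicity-aware reading). Panel metabolites without annotation are
#' dropped (count reported).
#'
#' @param panel a `panel` object or character vector of metabolite ids.
#' @param map a [read_pathway_map()] result.
#' @param alpha significance level on the raw p-value (default 0.05).
#' @param universe optional reference metabolome (the metabolites actually
#'   measured). When supplied it becomes the background universe `N` — the
#'   usual convention when the assay's coverage is known — and pathway
#'   memberships are restricted to it; when `NULL` the background is the
#'   map's annotated set and panel metabolites outside it are dropped.
#' @return data.frame of class `enrichment_result`: pathway_id, pathway_name,
#'   k, K, n, N, p_value, q_value, significant; plus attribute
#'   `n_unannotated` (panel metabolites carrying no pathway annotation).
#' @export
enrich <- function(panel, map, alpha = 0.05, universe = NULL) {
  ids <- if (inherits(panel, "panel")) panel_features(panel) else as.character(panel)
  background <- if (is.null(universe)) map$background else unique(universe)
  eff <- intersect(ids, background)
  n_unannotated <- length(ids) - length(intersect(ids, map$background))
  if (!length(eff)) stop("no panel metabolite is in the annotated background")
  N <- length(background)
  n <- length(eff)
  rows <- lapply(names(map$pathways), function(pid) {
    members <- intersect(map$pathways[[pid]], background)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(eff, members))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway_id = pid, pathway_name = unname(map$names[pid]),
               k = k, K = K, n = n, N = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q_value <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_value < alpha
  res <- res[order(res$p_value, res$pathway_id), ]
  rownames(res) <- NULL
  attr(res, "n_unannotated") <- n_unannotated
  class(res) <- c("enrichment_result", class(res))
  res
}
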