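#' Hypergeometric overrepresentation analysis
#'
#' For each gene set, tests whether the query is enriched for set members
#' using the one-sided hypergeometric upper tail `P[X >= hits]`. Sets are
#' intersected with the universe before testing; the query must be a subset
#' of the universe. BH q-values are computed across the tested sets. Rows are
#' sorted by p then set name. Following common practice for proteomics
#' enrichment, the recommended universe is the detected (post-filter)
#' proteome, not the whole genome.
#'
#' @param query character vector of feature ids.
#' @param gene_sets named list of member id vectors (see [read_gmt()]).
#' @param universe character vector of all detectable feature ids.
#' @param alpha significance threshold on the unadjusted p (default 0.01).
#' @param min_size sets with fewer members in the universe are skipped.
#' @return `data.frame`: `set`, `hits`, `set_size`, `query_size`,
#'   `universe_size`, `fold_enrichment`, `p`, `q`, `significant`.
#' @export
ora <- function(query, gene_sets, universe, alpha = 0.01, min_size = 1) {
  universe <- unique(universe)
  query <- unique(query)
  offenders <- setdiff(query, universe)
  if (length(offenders))
    stop("query ids not in universe: ",
         paste(utils::head(offenders, 5), collapse = ", "),
         if (length(offenders) > 5) sprintf(" (+%d more)",
                                            length(offenders) - 5) else "")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    members <- intersect(unique(gene_sets[[nm]]), universe)
    K <- length(members)
    if (K < min_size) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    data.frame(set = nm, hits = k, set_size = K, query_size = n,
               universe_size = N, fold_enrichment = fold, p = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows))
    return(data.frame(set = character(0), hits = integer(0),
                      set_size = integer(0), query_size = integer(0),
                      universe_size = integer(0),
                      fold_enrichment = numeric(0), p = numeric(0),
                      q = numeric(0), significant = logical(0)))
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out$significant <- out$p < alpha
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
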