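#' Fisher's exact pathway over-representation
#'
#' For each pathway, the one-sided (greater) Fisher exact test on the
#' 2x2 table
#' `[[hits, query - hits], [pathway - hits, universe - query - pathway + hits]]`,
#' i.e., whether the pathway holds more of the query's genes than expected
#' by chance in the background universe. Rows are sorted by ascending p
#' and flagged at the raw (uncorrected) `alpha` — matching the convention
#' of reporting uncorrected p < 0.05 per pathway.
#'
#' @param query A [gene_set] of query genes. Members outside the universe
#'   are dropped with a warning.
#' @param pathways A [pathway_collection].
#' @param universe Optional [gene_set] overriding the collection's
#'   universe.
#' @param alpha Significance cutoff on the raw p (default 0.05).
#' @return A tibble of class `enrichment_result` with columns `pathway`,
#'   `n_hits`, `n_set`, `n_pathway`, `n_universe`, `p_value`,
#'   `significant`.
#' @examples
#' pc <- pathway_collection(list(P1 = c("A", "B", "C"), P2 = c("D", "E")))
#' fisher_enrichment(gene_set(c("A", "B")), pc)
#' @export
fisher_enrichment <- function(query, pathways, universe = NULL, alpha = 0.05) {
  stopifnot(inherits(pathways, "pathway_collection"))
  uni <- unique(toupper(universe %||% pathways$universe))
  q <- unique(toupper(as.character(query)))
  mapped <- intersect(q, uni)
  if (length(mapped) < length(q)) {
    warn(sprintf("fisher_enrichment: %d query gene(s) outside the universe dropped",
                 length(q) - length(mapped)))
  }
  if (length(mapped) == 0) abort("fisher_enrichment: empty query after mapping")
  n_universe <- length(uni)
  n_set <- length(mapped)
  rows <- purrr::map(names(pathways$sets), function(nm) {
    pw <- intersect(pathways$sets[[nm]], uni)
    if (length(pw) > n_universe) abort("fisher_enrichment: pathway larger than universe")
    hits <- length(intersect(mapped, pw))
    tab <- matrix(c(hits, n_set - hits,
                    length(pw) - hits,
                    n_universe - n_set - length(pw) + hits), nrow = 2)
    p <- fisher.test(tab, alternative = "greater")$p.value
    tibble(pathway = nm, n_hits = hits, n_set = n_set,
           n_pathway = length(pw), n_universe = n_universe, p_value = p)
  })
  res <- bind_rows(rows) |>
    mutate(significant = .data$p_value < alpha) |>
    arrange(.data$p_value, .data$pathway)
  structure(res, class = c("enrichment_result", class(res)), alpha = alpha)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %d pathway(s), %d significant at alpha %.3g\n",
              nrow(x), sum(x$significant), attr(x, "alpha")))
  NextMethod()
}

#' @export
glance.enrichment_result <- function(x, ...) {
  tibble(
    n_pathways = nrow(x),
    n_significant = sum(x$significant),
    min_p = if (nrow(x) > 0) min(x$p_value) else NA_real_,
    alpha = attr(x, "alpha")
  )
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- as_tibble(object) |>
    mutate(pathway = stats::reorder(.data$pathway, -.data$p_value))
  ggplot2::ggplot(df, ggplot2::aes(-log10(.data$p_value), .data$pathway,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = -log10(attr(object, "alpha")),
                        linetype = 2) +
    ggplot2::labs(x = "-log10 p", y = NULL, fill = "significant") +
    ggplot2::theme_minimal()
}
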