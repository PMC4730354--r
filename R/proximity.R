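#' Shortest-path distances from a gene set
#'
#' Exact unweighted (breadth-first) shortest-path lengths from every mapped
#' member of `set_a` to every node of the network. Members absent from the
#' network are dropped with a warning; nodes unreachable from a source are
#' `Inf` in its row.
#'
#' @param set_a A [gene_set] of source genes.
#' @param network A [ppi_network].
#' @return Numeric matrix, one row per mapped source, one column per
#'   network node.
#' @export
shortest_path_lengths_from <- function(set_a, network) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network_nodes(network)
  mapped <- intersect(toupper(as.character(set_a)), nodes)
  n_unmapped <- length(unique(toupper(as.character(set_a)))) - length(mapped)
  if (length(mapped) == 0) {
    abort("no mapped source nodes")
  }
  if (n_unmapped > 0) {
    warn(sprintf("shortest_path_lengths_from: %d member(s) not in network",
                 n_unmapped))
  }
  igraph::distances(network$graph, v = mapped, weights = NA)
}

#' Inter-set average shortest-path distance
#'
#' The proximity statistic: the mean unweighted shortest-path length
#' `dis(i, j)` over all cross-set pairs, one gene `i` from `set_a` and one
#' gene `j` from `set_b`, in the background network. Genes shared by the
#' two sets contribute distance 0 as ordinary pairs (or are dropped first
#' with `drop_shared = TRUE`). Pairs in different network components have
#' no finite distance; the `exclude` policy leaves them out of the mean
#' (their count is reported) while `penalize` scores them as the network
#' diameter plus one.
#'
#' @param set_a,set_b [gene_set]s; members absent from the network are
#'   dropped with a warning.
#' @param network A [ppi_network].
#' @param unreachable_policy `"exclude"` (default) or `"penalize"`.
#' @param drop_shared Drop genes present in both sets before averaging?
#' @return A `proximity_result`: list with `dis_observed`,
#'   `pair_count_used`, `excluded_pairs`, `mapped_sizes`, and the policy.
#' @examples
#' net <- ppi_network(data.frame(from = c("A", "B", "C"), to = c("B", "C", "D")))
#' average_shortest_distance(gene_set("A"), gene_set(c("C", "D")), net)
#' @export
average_shortest_distance <- function(set_a, set_b, network,
                                      unreachable_policy = c("exclude", "penalize"),
                                      drop_shared = FALSE) {
  unreachable_policy <- match.arg(unreachable_policy)
  a <- unique(toupper(as.character(set_a)))
  b <- unique(toupper(as.character(set_b)))
  if (drop_shared) {
    shared <- intersect(a, b)
    a <- setdiff(a, shared)
    b <- setdiff(b, shared)
  }
  if (length(a) == 0 || length(b) == 0) {
    abort("average_shortest_distance: empty set after mapping")
  }
  D <- shortest_path_lengths_from(gene_set(a), network)
  b_mapped <- intersect(b, colnames(D))
  if (length(b_mapped) < length(b)) {
    warn(sprintf("average_shortest_distance: %d member(s) of %s not in network",
                 length(b) - length(b_mapped), set_name(set_b)))
  }
  if (length(b_mapped) == 0) {
    abort("average_shortest_distance: empty set after mapping")
  }
  sub <- D[, b_mapped, drop = FALSE]
  diameter <- if (unreachable_policy == "penalize") {
    network_diameter(network)
  } else NA_real_
  summarise_distance_block(sub, unreachable_policy, diameter = diameter)
}

# mean over a sources-by-targets block of BFS distances under a policy
summarise_distance_block <- function(sub, unreachable_policy, diameter) {
  finite <- is.finite(sub)
  n_pairs <- length(sub)
  n_excluded <- sum(!finite)
  if (unreachable_policy == "exclude") {
    if (n_excluded == n_pairs) abort("no finite pairs")
    dis <- mean(sub[finite])
    used <- n_pairs - n_excluded
  } else {
    vals <- sub
    vals[!finite] <- diameter + 1
    dis <- mean(vals)
    used <- n_pairs
    n_excluded <- 0L
  }
  structure(
    list(dis_observed = dis,
         pair_count_used = used,
         excluded_pairs = n_excluded,
         mapped_sizes = c(nrow(sub), ncol(sub)),
         unreachable_policy = unreachable_policy),
    class = "proximity_result"
  )
}

network_diameter <- function(network) {
  igraph::diameter(network$graph, weights = NA)
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(
    "<proximity_result> Dis = %.4f over %d pairs (%d excluded; sets %d x %d)\n",
    x$dis_observed, x$pair_count_used, x$excluded_pairs,
    x$mapped_sizes[1], x$mapped_sizes[2]))
  invisible(x)
}

#' @export
glance.proximity_result <- function(x, ...) {
  tibble(
    dis_observed = x$dis_observed,
    pair_count_used = x$pair_count_used,
    excluded_pairs = x$excluded_pairs,
    n_set_a = x$mapped_sizes[1],
    n_set_b = x$mapped_sizes[2],
    unreachable_policy = x$unreachable_policy
  )
}

#' Permutation test for network proximity
#'
#' Replaces one of the two gene sets by uniform random samples of equal
#' size (without replacement) from a sampling universe — all network nodes
#' by default, or a supplied background set — and recomputes the average
#' shortest distance each time. The Z-score standardises the observed
#' distance against the permutation null and is signed so that evidence of
#' closeness (observed distance below the null mean) is positive; the
#' empirical p-value is one-sided toward small distances with add-one
#' smoothing, `p = (r + 1) / (n + 1)`.
#'
#' A degree-binned null (each sampled node drawn from the degree bin of a
#' node in the original set) is offered as a labelled sensitivity analysis;
#' the primary null is uniform.
#'
#' @inheritParams average_shortest_distance
#' @param randomized_side `"a"` or `"b"`: which set is resampled.
#' @param n_permutations Number of resamples (>= 100).
#' @param seed Integer seed; identical seed and inputs give bit-identical
#'   results.
#' @param sampling_universe `NULL` for all network nodes, or a [gene_set]
#'   background (restricted to network nodes).
#' @param null_model `"uniform"` (default) or `"degree_binned"`.
#' @param n_degree_bins Number of quantile degree bins for the binned null.
#' @return A `permutation_result`: observed statistic, null values,
#'   `z_score`, `p_empirical`, `randomized_side`, `seed`, and bookkeeping.
#' @export
permutation_test_proximity <- function(set_a, set_b, network,
                                       randomized_side = c("a", "b"),
                                       n_permutations = 1000,
                                       seed = 1L,
                                       sampling_universe = NULL,
                                       unreachable_policy = c("exclude", "penalize"),
                                       null_model = c("uniform", "degree_binned"),
                                       n_degree_bins = 10) {
  randomized_side <- match.arg(randomized_side)
  unreachable_policy <- match.arg(unreachable_policy)
  null_model <- match.arg(null_model)
  stopifnot(n_permutations >= 100)
  nodes <- network_nodes(network)
  a <- intersect(unique(toupper(as.character(set_a))), nodes)
  b <- intersect(unique(toupper(as.character(set_b))), nodes)
  if (length(a) == 0 || length(b) == 0) abort("no mapped source nodes")
  universe <- if (is.null(sampling_universe)) {
    nodes
  } else {
    intersect(unique(toupper(as.character(sampling_universe))), nodes)
  }
  rand <- if (randomized_side == "a") a else b
  fixed <- if (randomized_side == "a") b else a
  if (length(universe) < length(rand)) {
    abort("sampling universe smaller than the randomized set")
  }
  # the diameter is only needed to price unreachable pairs
  diameter <- if (unreachable_policy == "penalize") {
    network_diameter(network)
  } else NA_real_
  # distances from the fixed side to every node: computed once, each
  # permutation is then a column subset
  D <- igraph::distances(network$graph, v = fixed, weights = NA)
  observed <- summarise_distance_block(D[, rand, drop = FALSE],
                                       unreachable_policy, diameter)
  obs <- observed$dis_observed
  null_values <- with_seed(seed, {
    if (null_model == "degree_binned") {
      deg <- igraph::degree(network$graph)[universe]
      breaks <- unique(stats::quantile(deg, probs = seq(0, 1, length.out = n_degree_bins + 1)))
      bin_of <- cut(deg, breaks = breaks, include.lowest = TRUE, labels = FALSE)
      by_bin <- split(universe, bin_of)
      rand_bins <- cut(igraph::degree(network$graph)[rand], breaks = breaks,
                       include.lowest = TRUE, labels = FALSE)
      vapply(seq_len(n_permutations), function(i) {
        samp <- unique(unlist(lapply(seq_along(rand), function(j) {
          pool <- by_bin[[as.character(rand_bins[j])]] %||% universe
          sample(pool, 1)
        })))
        while (length(samp) < length(rand)) {
          samp <- unique(c(samp, sample(universe, length(rand) - length(samp))))
        }
        null_stat(D, samp, unreachable_policy, diameter)
      }, numeric(1))
    } else {
      # integer column indices: character sampling is needlessly slow here
      universe_idx <- match(universe, colnames(D))
      vapply(seq_len(n_permutations), function(i) {
        samp <- universe_idx[sample.int(length(universe_idx), length(rand))]
        null_stat(D, samp, unreachable_policy, diameter)
      }, numeric(1))
    }
  })
  permutation_result(
    observed = obs, null_values = null_values,
    alternative = "less", randomized_side = randomized_side, seed = seed,
    statistic = "average_shortest_distance", null_model = null_model,
    extra = list(observed_detail = observed)
  )
}

null_stat <- function(D, cols, unreachable_policy, diameter) {
  sub <- D[, cols, drop = FALSE]
  finite <- is.finite(sub)
  if (unreachable_policy == "exclude") {
    if (!any(finite)) return(NA_real_)
    mean(sub[finite])
  } else {
    sub[!finite] <- diameter + 1
    mean(sub)
  }
}

#' Permutation results
#'
#' Container shared by the proximity and profile-similarity permutation
#' tests. `z_score` is the observed statistic standardised against the
#' null, signed so that evidence in the direction of the one-sided
#' alternative is positive; when the null has zero spread the Z-score is
#' `NA` (with a warning) while the empirical p-value remains valid.
#'
#' @param observed Observed statistic.
#' @param null_values Numeric vector of resampled statistic values
#'   (`NA` entries mark degenerate permutations and are dropped from the
#'   moments but kept in the record).
#' @param alternative `"less"` (small values extreme, e.g., distances) or
#'   `"greater"` (large values extreme, e.g., similarities).
#' @param randomized_side `"a"` or `"b"`.
#' @param seed Seed used.
#' @param statistic Label of the statistic.
#' @param null_model Label of the null.
#' @param extra Optional list of extra fields.
#' @return A `permutation_result`.
#' @export
permutation_result <- function(observed, null_values, alternative,
                               randomized_side, seed, statistic,
                               null_model = "uniform", extra = list()) {
  stopifnot(alternative %in% c("less", "greater"))
  finite_null <- null_values[!is.na(null_values)]
  mu <- mean(finite_null)
  sigma <- sd(finite_null)
  direction <- if (alternative == "less") -1 else 1
  if (isTRUE(sigma > 0)) {
    z <- direction * (observed - mu) / sigma
  } else {
    warn("permutation null has zero spread; z_score undefined")
    z <- NA_real_
  }
  r <- if (alternative == "less") {
    sum(finite_null <= observed)
  } else {
    sum(finite_null >= observed)
  }
  p <- (r + 1) / (length(finite_null) + 1)
  structure(
    c(list(observed = observed, null_values = null_values,
           n_permutations = length(null_values),
           n_degenerate = sum(is.na(null_values)),
           null_mean = mu, null_sd = sigma,
           z_score = z, p_empirical = p,
           alternative = alternative,
           randomized_side = randomized_side, seed = seed,
           statistic = statistic, null_model = null_model),
      extra),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s: observed = %.4f, null %.4f +/- %.4f (n = %d)\n  Z = %s, empirical p = %.4g (side %s randomized, seed %d)\n",
    x$statistic, x$observed, x$null_mean, x$null_sd, x$n_permutations,
    ifelse(is.na(x$z_score), "NA", sprintf("%.3f", x$z_score)),
    x$p_empirical, x$randomized_side, x$seed))
  invisible(x)
}

#' @export
tidy.permutation_result <- function(x, ...) {
  tibble(permutation = seq_along(x$null_values), value = x$null_values)
}

#' @export
glance.permutation_result <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    observed = x$observed,
    null_mean = x$null_mean,
    null_sd = x$null_sd,
    z_score = x$z_score,
    p_empirical = x$p_empirical,
    n_permutations = x$n_permutations,
    n_degenerate = x$n_degenerate,
    randomized_side = x$randomized_side,
    null_model = x$null_model,
    seed = x$seed
  )
}

#' @export
autoplot.permutation_result <- function(object, bins = 40, ...) {
  df <- tibble(value = object$null_values[!is.na(object$null_values)])
  ggplot2::ggplot(df, ggplot2::aes(.data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(
      x = object$statistic, y = "permutations",
      title = sprintf("observed = %.3f, Z = %.2f, p = %.3g",
                      object$observed, object$z_score, object$p_empirical)) +
    ggplot2::theme_minimal()
}
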