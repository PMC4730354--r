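#' Graph-based term similarity model
#'
#' Wang-style semantic similarity: the contribution of an ancestor `a` to
#' a term `t` (its S-value) is the maximum, over root-ward paths from `t`
#' to `a`, of the product of per-edge semantic contribution factors
#' (`is_a` 0.8, `part_of` 0.6 — the published defaults of the graph-based
#' method), with `S_t(t) = 1`. The similarity of two terms is the summed
#' S-values of their common ancestors (self included) normalised by the
#' total semantic values `SV(t) = sum of all S-values of t`.
#'
#' @param dag A [go_dag].
#' @param w_is_a,w_part_of Edge contribution factors, strictly in (0, 1).
#' @return A `term_sim_model`.
#' @export
term_sim_model <- function(dag, w_is_a = 0.8, w_part_of = 0.6) {
  stopifnot(inherits(dag, "go_dag"),
            w_is_a > 0, w_is_a < 1, w_part_of > 0, w_part_of < 1)
  structure(list(dag = dag,
                 weights = c(is_a = w_is_a, part_of = w_part_of)),
            class = "term_sim_model")
}

# S-values of a term: named vector over its ancestor closure (self included).
# Max-product dynamic programme over child->parent edges, processed so a
# parent is finalised only after all its contributing children.
s_values <- function(term, model) {
  dag <- model$dag
  w <- model$weights
  closure <- term_ancestors(dag, term, include_self = TRUE)
  sv <- setNames(rep(-Inf, length(closure)), closure)
  sv[term] <- 1
  # iterate to fixed point; closures are small so this is cheap and needs
  # no explicit topological sort over the induced subgraph
  edges <- dag$edges[dag$edges$child %in% closure &
                       dag$edges$parent %in% closure, , drop = FALSE]
  repeat {
    changed <- FALSE
    cand <- w[edges$type] * sv[edges$child]
    for (k in seq_len(nrow(edges))) {
      p <- edges$parent[k]
      if (cand[k] > sv[p]) {
        sv[p] <- cand[k]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sv[is.finite(sv)]
}

#' Semantic similarity of two ontology terms
#'
#' @param t1,t2 Term ids (same namespace, non-obsolete).
#' @param model A [term_sim_model].
#' @return Similarity in `[0, 1]`; 0 when the terms share no ancestor
#'   (different roots), 1 for identical terms.
#' @export
term_similarity <- function(t1, t2, model) {
  stopifnot(inherits(model, "term_sim_model"))
  dag <- model$dag
  for (t in c(t1, t2)) {
    if (!t %in% dag_terms(dag)) abort(paste0("unknown or obsolete term: ", t))
  }
  ns <- dag$terms$namespace[match(c(t1, t2), dag$terms$id)]
  if (!anyNA(ns) && ns[1] != ns[2]) {
    abort("term_similarity: terms from different namespaces")
  }
  s1 <- s_values(t1, model)
  s2 <- s_values(t2, model)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# all pairwise similarities between two term vectors (cached S-values)
term_similarity_matrix <- function(terms1, terms2, model) {
  all_terms <- unique(c(terms1, terms2))
  svs <- lapply(all_terms, s_values, model = model)
  names(svs) <- all_terms
  tot <- vapply(svs, sum, numeric(1))
  out <- matrix(0, length(terms1), length(terms2),
                dimnames = list(terms1, terms2))
  for (i in seq_along(terms1)) {
    s1 <- svs[[terms1[i]]]
    for (j in seq_along(terms2)) {
      s2 <- svs[[terms2[j]]]
      common <- intersect(names(s1), names(s2))
      if (length(common) > 0) {
        out[i, j] <- sum(s1[common] + s2[common]) /
          (tot[terms1[i]] + tot[terms2[j]])
      }
    }
  }
  out
}

#' Enriched GO-term profile of a gene set
#'
#' The functional profile of a gene set: all ontology terms at a fixed
#' level (depth from the namespace root) that are over-represented in the
#' set at raw hypergeometric `p < alpha`, against the universe of all
#' annotated genes. Annotations are propagated to ancestors (true-path
#' rule) before counting unless `propagate = FALSE`. No multiplicity
#' correction is applied; the profile carries raw p-values.
#'
#' @param gene_set A [gene_set].
#' @param annotations An [annotation_map] (direct annotations).
#' @param level Ontology level of candidate terms (default 4).
#' @param alpha Significance cutoff on the raw p (default 0.05).
#' @param propagate Apply the true-path rule before counting?
#' @param depth_rule,root_level Level conventions, see [term_depths()].
#' @return A `go_profile`: tibble of class `go_profile` with columns
#'   `term`, `name`, `level`, `n_hits`, `n_set`, `n_term`, `n_universe`,
#'   `p_value`.
#' @export
enrich_profile <- function(gene_set, annotations, level = 4, alpha = 0.05,
                           propagate = TRUE,
                           depth_rule = "shortest", root_level = 0L) {
  stopifnot(inherits(annotations, "annotation_map"))
  counts <- profile_count_context(annotations, level = level,
                                  propagate = propagate,
                                  depth_rule = depth_rule,
                                  root_level = root_level)
  profile_from_counts(gene_set, counts, alpha = alpha, level = level,
                      set_name = set_name(gene_set))
}

# Precomputed per-DAG context: gene-by-term membership at one level.
# Shared by enrich_profile and the profile-similarity permutation test so
# each resample costs one colSums.
profile_count_context <- function(annotations, level, propagate,
                                  depth_rule = "shortest", root_level = 0L) {
  dag <- annotations$dag
  ann <- if (propagate) propagate_annotations(annotations) else annotations
  depths <- term_depths(dag, rule = depth_rule, root_level = root_level)
  level_terms <- names(depths)[depths == level]
  if (length(level_terms) == 0) {
    abort(sprintf("enrich_profile: no terms at level %d", level))
  }
  background <- annotation_background(annotations)
  mp <- ann$mapping[ann$mapping$term %in% level_terms, , drop = FALSE]
  M <- matrix(FALSE, length(background), length(level_terms),
              dimnames = list(background, level_terms))
  M[cbind(match(mp$gene, background), match(mp$term, level_terms))] <- TRUE
  list(membership = M, background = background, level_terms = level_terms,
       dag = dag, level = level)
}

profile_from_counts <- function(genes, counts, alpha, level,
                                set_name = "gene_set") {
  q <- intersect(unique(toupper(as.character(genes))), counts$background)
  if (length(q) == 0) {
    abort("enrich_profile: gene set does not intersect the annotation background")
  }
  M <- counts$membership
  hits <- colSums(M[q, , drop = FALSE])
  n_term <- colSums(M)
  n_universe <- length(counts$background)
  n_set <- length(q)
  # one-sided over-representation tail P(X >= hits)
  p <- phyper(hits - 1, n_term, n_universe - n_term, n_set,
              lower.tail = FALSE)
  keep <- p < alpha
  dagt <- counts$dag$terms
  res <- tibble(
    term = counts$level_terms[keep],
    name = dagt$name[match(counts$level_terms[keep], dagt$id)],
    level = level,
    n_hits = as.integer(hits[keep]),
    n_set = n_set,
    n_term = as.integer(n_term[keep]),
    n_universe = n_universe,
    p_value = unname(p[keep])
  ) |> arrange(.data$p_value, .data$term)
  structure(res, class = c("go_profile", class(res)),
            gene_set_name = set_name, alpha = alpha, profile_level = level)
}

#' @export
print.go_profile <- function(x, ...) {
  cat(sprintf("<go_profile> %s: %d enriched term(s) at level %d (alpha %.3g)\n",
              attr(x, "gene_set_name") %||% "gene_set", nrow(x),
              attr(x, "profile_level"), attr(x, "alpha")))
  NextMethod()
}

#' Write a GO profile as TSV
#' @param profile A `go_profile`.
#' @param path Output path.
#' @export
write_profile <- function(profile, path) {
  readr::write_tsv(as_tibble(profile), path)
  invisible(path)
}

#' Best-match-average similarity of two GO profiles
#'
#' For each term of one profile, its best similarity against the other
#' profile; the BMA score averages these best matches over both
#' directions: `(sum over p1 of best match in p2 + sum over p2 of best
#' match in p1) / (|p1| + |p2|)`. Symmetric, in `[0, 1]`, and exactly 1
#' for identical profiles.
#'
#' @param p1,p2 `go_profile` objects (or character vectors of term ids);
#'   must be non-empty.
#' @param model A [term_sim_model].
#' @return Similarity in `[0, 1]`.
#' @export
profile_similarity <- function(p1, p2, model) {
  t1 <- profile_terms(p1)
  t2 <- profile_terms(p2)
  if (length(t1) == 0 || length(t2) == 0) {
    abort("cannot compare empty profile")
  }
  S <- term_similarity_matrix(t1, t2, model)
  bma_from_matrix(S)
}

profile_terms <- function(p) {
  if (inherits(p, "go_profile")) unique(p$term) else unique(as.character(p))
}

bma_from_matrix <- function(S) {
  (sum(apply(S, 1, max)) + sum(apply(S, 2, max))) / (nrow(S) + ncol(S))
}

#' Permutation test for GO-profile similarity
#'
#' Resamples one GENE set uniformly (equal size, without replacement) from
#' the annotation background, rebuilds its enriched profile, and recomputes
#' the best-match-average similarity against the other set's profile. The
#' empirical p-value is one-sided toward large similarity. Permutations
#' whose resampled profile is empty carry no similarity and are recorded
#' and skipped; if more than half are empty the null is degenerate and the
#' test errors.
#'
#' @inheritParams enrich_profile
#' @param set_a,set_b [gene_set]s.
#' @param randomized_side `"a"` or `"b"`.
#' @param n_permutations Number of resamples (>= 100).
#' @param seed Integer seed.
#' @param model Optional [term_sim_model]; defaults to the standard
#'   weights on the annotation DAG.
#' @return A [permutation_result] with the observed BMA similarity.
#' @export
permutation_test_profile_similarity <- function(set_a, set_b, annotations,
                                                randomized_side = c("a", "b"),
                                                n_permutations = 1000,
                                                seed = 1L,
                                                level = 4, alpha = 0.05,
                                                propagate = TRUE,
                                                model = NULL) {
  randomized_side <- match.arg(randomized_side)
  stopifnot(n_permutations >= 100)
  model <- model %||% term_sim_model(annotations$dag)
  counts <- profile_count_context(annotations, level = level,
                                  propagate = propagate)
  prof_a <- profile_from_counts(set_a, counts, alpha, level, set_name(set_a))
  prof_b <- profile_from_counts(set_b, counts, alpha, level, set_name(set_b))
  if (nrow(prof_a) == 0 || nrow(prof_b) == 0) {
    abort("cannot compare empty profile")
  }
  # similarities among all level terms, computed once; every resampled
  # profile is a subset of these terms
  S_all <- term_similarity_matrix(counts$level_terms, counts$level_terms,
                                  model)
  idx <- function(terms) match(terms, counts$level_terms)
  bma_idx <- function(i1, i2) bma_from_matrix(S_all[i1, i2, drop = FALSE])
  observed <- bma_idx(idx(prof_a$term), idx(prof_b$term))
  fixed_idx <- if (randomized_side == "a") idx(prof_b$term) else idx(prof_a$term)
  rand_set <- if (randomized_side == "a") set_a else set_b
  n_rand <- length(intersect(unique(toupper(as.character(rand_set))),
                             counts$background))
  background <- counts$background
  M <- counts$membership
  n_universe <- length(background)
  n_term <- colSums(M)
  null_values <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      samp <- sample(background, n_rand)
      hits <- colSums(M[samp, , drop = FALSE])
      p <- phyper(hits - 1, n_term, n_universe - n_term, n_rand,
                  lower.tail = FALSE)
      keep <- which(p < alpha)
      if (length(keep) == 0) return(NA_real_)
      if (randomized_side == "a") {
        bma_idx(keep, fixed_idx)
      } else {
        bma_idx(fixed_idx, keep)
      }
    }, numeric(1))
  })
  if (mean(is.na(null_values)) > 0.5) {
    abort("null degenerate: more than half of the permutations yield empty profiles")
  }
  permutation_result(
    observed = observed, null_values = null_values,
    alternative = "greater", randomized_side = randomized_side, seed = seed,
    statistic = "profile_similarity_bma",
    extra = list(profile_a = prof_a, profile_b = prof_b)
  )
}
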