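# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own algorithms: Floyd-Warshall
# for distances, exhaustive path enumeration for semantic S-values, and
# iterative relaxation for term depths.

# all-pairs shortest paths by Floyd-Warshall on the adjacency matrix
bf_all_pairs <- function(network) {
  nodes <- network_nodes(network)
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  ed <- network_edges(network)
  for (k in seq_len(nrow(ed))) {
    D[ed$from[k], ed$to[k]] <- 1
    D[ed$to[k], ed$from[k]] <- 1
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# brute-force S-values: enumerate every child->parent path from `term`,
# S(ancestor) = max over paths of the product of edge weights
bf_s_values <- function(dag, term, w = c(is_a = 0.8, part_of = 0.6)) {
  sv <- new.env(parent = emptyenv())
  assign(term, 1, envir = sv)
  recurse <- function(node, value) {
    idx <- which(dag$edges$child == node)
    for (k in idx) {
      p <- dag$edges$parent[k]
      v <- value * w[[dag$edges$type[k]]]
      cur <- if (exists(p, envir = sv)) get(p, envir = sv) else -Inf
      if (v > cur) assign(p, v, envir = sv)
      recurse(p, v)
    }
  }
  recurse(term, 1)
  vals <- mget(ls(sv), envir = sv)
  setNames(as.numeric(vals), names(vals))
}

bf_term_similarity <- function(dag, t1, t2, w = c(is_a = 0.8, part_of = 0.6)) {
  s1 <- bf_s_values(dag, t1, w)
  s2 <- bf_s_values(dag, t2, w)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# term levels by iterative relaxation from the roots (shortest rule)
bf_term_depths <- function(dag) {
  live <- dag_terms(dag)
  depth <- setNames(rep(Inf, length(live)), live)
  depth[dag$roots] <- 0
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(dag$edges))) {
      ch <- dag$edges$child[k]; pa <- dag$edges$parent[k]
      if (depth[pa] + 1 < depth[ch]) {
        depth[ch] <- depth[pa] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  depth
}

# random simple connected-ish graph over `n` nodes for oracle comparisons
random_test_network <- function(n, p = 0.08, seed = 1) {
  withr::with_seed(seed, {
    pairs <- t(combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    # a random spanning path guards against fully isolated nodes
    path <- cbind(1:(n - 1), 2:n)
    el <- rbind(pairs[keep, , drop = FALSE], path)
    lab <- sprintf("N%02d", 1:n)
    ppi_network(data.frame(from = lab[el[, 1]], to = lab[el[, 2]]))
  })
}

# random DAG over n terms: each term gets 1-2 parents among earlier terms
random_test_dag <- function(n, seed = 1, p_part_of = 0.3) {
  withr::with_seed(seed, {
    ids <- sprintf("T%02d", 1:n)
    edges <- list()
    for (i in 2:n) {
      parents <- sample(seq_len(i - 1), min(sample(1:2, 1), i - 1))
      edges[[i]] <- tibble::tibble(
        child = ids[i], parent = ids[parents],
        type = sample(c("is_a", "part_of"), length(parents),
                      replace = TRUE, prob = c(1 - p_part_of, p_part_of)))
    }
    go_dag(tibble::tibble(id = ids, name = ids,
                          namespace = "biological_process",
                          obsolete = FALSE),
           dplyr::bind_rows(edges))
  })
}

# three-term chain fixture used across the semantic-similarity tests:
# A --is_a--> C --is_a--> ROOT
chain_dag <- function() {
  go_dag(
    tibble::tibble(id = c("ROOT", "C", "A"),
                   name = c("root", "mid", "leaf"),
                   namespace = "biological_process",
                   obsolete = FALSE),
    tibble::tibble(child = c("C", "A"), parent = c("ROOT", "C"),
                   type = "is_a"))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
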