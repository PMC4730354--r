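#' Ontology DAGs
#'
#' A `go_dag` is a rooted directed acyclic graph of ontology terms with
#' typed child-to-parent edges (`is_a` or `part_of`). Obsolete terms are
#' carried in the term table but excluded from every traversal. Roots are
#' the non-obsolete terms with no parents.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`, `obsolete`.
#' @param edges Tibble with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`).
#' @return A `go_dag` object.
#' @export
go_dag <- function(terms, edges) {
  terms <- as_tibble(terms)
  edges <- as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace", "obsolete") %in% names(terms)),
            all(c("child", "parent", "type") %in% names(edges)))
  if (nrow(edges) > 0 && !all(edges$type %in% c("is_a", "part_of"))) {
    abort("go_dag: edge types restricted to is_a / part_of")
  }
  live <- terms$id[!terms$obsolete]
  edges <- edges[edges$child %in% live & edges$parent %in% live, , drop = FALSE]
  unknown <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(unknown) > 0) {
    abort(paste0("go_dag: unknown term id(s) in edges: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  cyc <- find_cycle(edges)
  if (!is.null(cyc)) {
    abort(paste0("go_dag: cycle detected: ", paste(cyc, collapse = " -> ")))
  }
  roots <- setdiff(live, unique(edges$child))
  if (length(live) > 0 && length(roots) == 0) {
    abort("go_dag: no root term found")
  }
  parents <- split(seq_len(nrow(edges)), edges$child)
  structure(
    list(terms = terms, edges = edges, roots = sort(roots),
         parent_index = parents),
    class = "go_dag"
  )
}

# DFS over child->parent edges; returns one cycle as an id path, or NULL.
find_cycle <- function(edges) {
  if (nrow(edges) == 0) return(NULL)
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character(0)
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- state[[v]] %||% 0L
    if (st == 1L) {
      found <<- c(path[which(path == v)[1]:length(path)], v)
      return()
    }
    if (st == 2L) return()
    state[[v]] <- 1L
    path <<- c(path, v)
    for (p in adj[[v]] %||% character(0)) visit(p)
    path <<- path[-length(path)]
    state[[v]] <- 2L
  }
  for (v in unique(edges$child)) {
    visit(v)
    if (!is.null(found)) return(found)
  }
  NULL
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms (%d obsolete), %d edges, %d root(s)\n",
              nrow(x$terms), sum(x$terms$obsolete), nrow(x$edges),
              length(x$roots)))
  invisible(x)
}

#' Live (non-obsolete) term ids of a DAG
#' @param dag A [go_dag].
#' @export
dag_terms <- function(dag) {
  stopifnot(inherits(dag, "go_dag"))
  dag$terms$id[!dag$terms$obsolete]
}

#' Ancestors of a term
#'
#' All terms reachable from `id` by following child-to-parent edges,
#' excluding `id` itself unless `include_self`.
#'
#' @param dag A [go_dag].
#' @param id Term id.
#' @param include_self Include the term itself?
#' @return Character vector of term ids.
#' @export
term_ancestors <- function(dag, id, include_self = FALSE) {
  stopifnot(inherits(dag, "go_dag"))
  if (!id %in% dag_terms(dag)) {
    abort(paste0("unknown or obsolete term: ", id))
  }
  seen <- character(0)
  frontier <- id
  while (length(frontier) > 0) {
    nxt <- unlist(lapply(frontier, function(v) {
      dag$edges$parent[dag$parent_index[[v]] %||% integer(0)]
    }), use.names = FALSE)
    nxt <- setdiff(unique(nxt), c(seen, id))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (include_self) c(id, seen) else seen
}

#' Term depth (level) assignment
#'
#' Assigns each live term the length of its shortest (default) or longest
#' child-to-parent path to any root, over both `is_a` and `part_of` edges.
#' The root level defaults to 0 — ontology "levels" are convention-dependent,
#' so both the path rule and the origin are configurable.
#'
#' @param dag A [go_dag].
#' @param rule `"shortest"` (default) or `"longest"` path to a root.
#' @param root_level Level assigned to roots (0 by default).
#' @return Named integer vector, term id -> level.
#' @export
term_depths <- function(dag, rule = c("shortest", "longest"), root_level = 0L) {
  rule <- match.arg(rule)
  stopifnot(inherits(dag, "go_dag"))
  live <- dag_terms(dag)
  if (length(live) == 0) return(setNames(integer(0), character(0)))
  # BFS / DP from roots over parent->child edges
  children <- split(dag$edges$child, dag$edges$parent)
  depth <- setNames(rep(NA_integer_, length(live)), live)
  depth[dag$roots] <- 0L
  if (rule == "shortest") {
    frontier <- dag$roots
    d <- 0L
    while (length(frontier) > 0) {
      d <- d + 1L
      nxt <- unique(unlist(children[frontier], use.names = FALSE))
      nxt <- nxt[is.na(depth[nxt])]
      depth[nxt] <- d
      frontier <- nxt
    }
  } else {
    # longest path: relax in topological order
    ord <- topo_order(dag)
    for (v in ord) {
      ps <- dag$edges$parent[dag$parent_index[[v]] %||% integer(0)]
      if (length(ps) > 0) {
        depth[v] <- max(depth[ps]) + 1L
      }
    }
  }
  if (anyNA(depth)) {
    bad <- names(depth)[is.na(depth)][1]
    abort(paste0("term_depths: term unreachable from any root: ", bad))
  }
  depth + as.integer(root_level)
}

# topological order of live terms, roots first
topo_order <- function(dag) {
  live <- dag_terms(dag)
  indeg <- setNames(rep(0L, length(live)), live)
  tab <- table(dag$edges$child)
  indeg[names(tab)] <- as.integer(tab)
  ord <- character(0)
  queue <- names(indeg)[indeg == 0L]
  children <- split(dag$edges$child, dag$edges$parent)
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    ord <- c(ord, v)
    for (c in children[[v]] %||% character(0)) {
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  ord
}

#' Read an ontology from an OBO 1.2 file
#'
#' Parses `[Term]` stanzas (`id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `is_obsolete`), optionally restricted to one
#' namespace. Cycles and references to unknown parents are hard errors.
#'
#' @param path Path to the OBO file.
#' @param namespace `"biological_process"` (default) to keep only that
#'   namespace, or `"all"`.
#' @return A [go_dag].
#' @export
read_obo <- function(path, namespace = c("biological_process", "all")) {
  namespace <- match.arg(namespace)
  lines <- read_clean_lines(path)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) {
    abort(paste0("read_obo: no [Term] stanzas in ", path))
  }
  bounds <- c(stanza_starts, length(lines) + 1L)
  terms <- vector("list", length(stanza_starts))
  edges <- vector("list", length(stanza_starts))
  for (k in seq_along(stanza_starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    chunk <- chunk[!startsWith(chunk, "[")]
    get1 <- function(tag) {
      hit <- chunk[startsWith(chunk, paste0(tag, ":"))]
      if (length(hit) == 0) return(NA_character_)
      trimws(sub(paste0("^", tag, ":"), "", hit[1]))
    }
    id <- get1("id")
    if (is.na(id)) next
    obsolete <- identical(tolower(get1("is_obsolete")), "true")
    isa_lines <- chunk[startsWith(chunk, "is_a:")]
    isa <- vapply(isa_lines, function(l) {
      trimws(strsplit(sub("^is_a:", "", l), "!", fixed = TRUE)[[1]][1])
    }, character(1), USE.NAMES = FALSE)
    rel_lines <- chunk[startsWith(chunk, "relationship:")]
    po <- character(0)
    for (l in rel_lines) {
      body <- trimws(strsplit(sub("^relationship:", "", l), "!",
                              fixed = TRUE)[[1]][1])
      fields <- strsplit(body, "[ \t]+")[[1]]
      if (length(fields) >= 2 && fields[1] == "part_of") {
        po <- c(po, fields[2])
      }
    }
    terms[[k]] <- tibble(
      id = id,
      name = get1("name") %||% NA_character_,
      namespace = get1("namespace") %||% NA_character_,
      obsolete = obsolete
    )
    if (!obsolete && (length(isa) + length(po)) > 0) {
      edges[[k]] <- tibble(
        child = id,
        parent = c(isa, po),
        type = c(rep("is_a", length(isa)), rep("part_of", length(po)))
      )
    }
  }
  terms <- bind_rows(terms)
  edges <- bind_rows(edges)
  missing_parents <- setdiff(edges$parent, terms$id)
  if (length(missing_parents) > 0) {
    abort(paste0("read_obo: unknown parent id(s): ",
                 paste(head(missing_parents, 5), collapse = ", ")))
  }
  if (namespace != "all") {
    terms <- terms[is.na(terms$namespace) | terms$namespace == namespace, ,
                   drop = FALSE]
    keep <- terms$id
    edges <- edges[edges$child %in% keep & edges$parent %in% keep, ,
                   drop = FALSE]
  }
  go_dag(terms, edges)
}

#' Write an ontology as a minimal OBO 1.2 file
#'
#' Emits one `[Term]` stanza per term with `is_a` / `relationship: part_of`
#' lines, sufficient to round-trip through [read_obo()].
#'
#' @param dag A [go_dag].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "go_dag"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  by_child <- split(dag$edges, dag$edges$child)
  for (i in seq_len(nrow(dag$terms))) {
    tr <- dag$terms[i, ]
    out <- c("[Term]",
             paste0("id: ", tr$id),
             paste0("name: ", tr$name),
             paste0("namespace: ", tr$namespace))
    if (tr$obsolete) out <- c(out, "is_obsolete: true")
    ed <- by_child[[tr$id]]
    if (!is.null(ed)) {
      for (j in seq_len(nrow(ed))) {
        out <- c(out, if (ed$type[j] == "is_a") {
          paste0("is_a: ", ed$parent[j])
        } else {
          paste0("relationship: part_of ", ed$parent[j])
        })
      }
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' @export
tidy.go_dag <- function(x, ...) {
  depths <- term_depths(x)
  x$terms |>
    filter(!.data$obsolete) |>
    mutate(level = unname(depths[.data$id])) |>
    select("id", "name", "namespace", "level")
}
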