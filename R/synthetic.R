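#' Synthetic study specification
#'
#' Parameters for the seeded generators that emulate every input the
#' pipeline needs: a sparse scale-free interaction network, two gene sets
#' with a tunable planted proximity, a rooted GO-like ontology with
#' annotations whose term usage overlaps between the two sets, a pathway
#' collection with one planted over-represented pathway, and a docking
#' table with a known strong/weak split. Defaults mirror the published
#' study's scale: 59 putative targets vs 89 disease proteins on a
#' 9500-node scale-free network (the size of the curated human
#' interactome the proximity statistic is used on), and a 39-row docking
#' comparison of which 21 rows (53.85%) are strong.
#'
#' @param seed Integer master seed; every generator is a pure function of
#'   the spec (seed included).
#' @param n_nodes Network size (>= 10).
#' @param pa_power,pa_m Preferential-attachment exponent and edges added
#'   per step.
#' @param network_model `"preferential_attachment"` (default) or
#'   `"erdos_renyi"`.
#' @param size_a,size_b Gene-set sizes (compound targets, disease genes).
#' @param proximity_radius,proximity_bias Planted-closeness controls: each
#'   member of set B is drawn from within `proximity_radius` of set A with
#'   probability `proximity_bias`, uniformly otherwise. `bias = 0` gives
#'   two independent uniform sets.
#' @param disjoint_sets Force the two sets to be disjoint?
#' @param ontology_depth,branching Tree depth (root = level 0) and
#'   children per term of the ontology scaffold; depth must be >= 5 so
#'   level-4 terms exist.
#' @param part_of_fraction Fraction of edges typed `part_of`.
#' @param extra_parent_fraction Fraction of terms given a second parent
#'   (makes the ontology a DAG rather than a tree).
#' @param terms_per_gene Leaf annotations per gene.
#' @param n_families Number of leaf-term families a focused gene group
#'   draws from.
#' @param annotation_overlap Fraction of term families shared between the
#'   two designated gene groups (0 = disjoint, 1 = identical).
#' @param annotation_focus Probability that a group gene annotates within
#'   its family rather than uniformly.
#' @param n_pathways,pathway_size Number of pathways and the size of each.
#' @param enrich_strength Fraction of the planted pathway drawn from the
#'   designated query set (0 = no planting).
#' @param dock_rows,strong_fraction Docking-table size and the fraction of
#'   rows constructed to satisfy the default [comparison_rule()].
#' @return A `synthetic_spec` (validated list).
#' @export
synthetic_spec <- function(seed = 1L,
                           n_nodes = 9500, pa_power = 1, pa_m = 3,
                           network_model = c("preferential_attachment",
                                             "erdos_renyi"),
                           size_a = 59, size_b = 89,
                           proximity_radius = 2, proximity_bias = 0.95,
                           disjoint_sets = TRUE,
                           ontology_depth = 6, branching = 3,
                           part_of_fraction = 0.15,
                           extra_parent_fraction = 0.1,
                           terms_per_gene = 3,
                           n_families = 8,
                           annotation_overlap = 0.9,
                           annotation_focus = 0.8,
                           n_pathways = 7, pathway_size = 40,
                           enrich_strength = 0.3,
                           dock_rows = 39, strong_fraction = 21 / 39) {
  network_model <- match.arg(network_model)
  spec <- list(seed = as.integer(seed), n_nodes = n_nodes,
               pa_power = pa_power, pa_m = pa_m,
               network_model = network_model,
               size_a = size_a, size_b = size_b,
               proximity_radius = proximity_radius,
               proximity_bias = proximity_bias,
               disjoint_sets = disjoint_sets,
               ontology_depth = ontology_depth, branching = branching,
               part_of_fraction = part_of_fraction,
               extra_parent_fraction = extra_parent_fraction,
               terms_per_gene = terms_per_gene,
               n_families = n_families,
               annotation_overlap = annotation_overlap,
               annotation_focus = annotation_focus,
               n_pathways = n_pathways, pathway_size = pathway_size,
               enrich_strength = enrich_strength,
               dock_rows = dock_rows, strong_fraction = strong_fraction)
  with(spec, {
    stopifnot(n_nodes >= 10, size_a > 0, size_b > 0,
              size_a <= n_nodes / 4, size_b <= n_nodes / 4,
              proximity_bias >= 0, proximity_bias <= 1,
              annotation_overlap >= 0, annotation_overlap <= 1,
              annotation_focus >= 0, annotation_focus <= 1,
              part_of_fraction >= 0, part_of_fraction <= 1,
              strong_fraction >= 0, strong_fraction <= 1,
              ontology_depth >= 5, branching >= 2,
              n_pathways > 0, dock_rows > 0)
  })
  structure(spec, class = "synthetic_spec")
}

# generator-local seeds derived from the master seed; kept below 2^31
sub_seed <- function(spec, offset) {
  as.integer((as.numeric(spec$seed) * 101 + offset) %% .Machine$integer.max)
}

#' Generate a synthetic interaction network
#'
#' A connected preferential-attachment (Barabasi-Albert) graph — sparse
#' with a heavy-tailed degree sequence, the two distributional facts the
#' proximity statistic relies on in real interactomes — or an
#' Erdos-Renyi alternative. Nodes are labelled `G0001 ...`.
#'
#' @param spec A [synthetic_spec].
#' @return A [ppi_network].
#' @export
gen_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  g <- with_seed(sub_seed(spec, 1), {
    if (spec$network_model == "preferential_attachment") {
      igraph::sample_pa(spec$n_nodes, power = spec$pa_power, m = spec$pa_m,
                        directed = FALSE)
    } else {
      # keep the giant component connected by adding a spanning cycle
      g0 <- igraph::sample_gnm(spec$n_nodes, spec$n_nodes * spec$pa_m)
      igraph::add_edges(g0, rbind(seq_len(spec$n_nodes),
                                  c(2:spec$n_nodes, 1L)))
    }
  })
  el <- igraph::as_edgelist(g)
  lab <- sprintf("G%04d", seq_len(spec$n_nodes))
  ppi_network(data.frame(from = lab[as.integer(el[, 1])],
                         to = lab[as.integer(el[, 2])]),
              nodes = lab)
}

#' Generate two gene sets with planted network proximity
#'
#' Set A is a uniform sample of network nodes. Each member of set B is,
#' with probability `proximity_bias`, drawn uniformly from the nodes
#' within `proximity_radius` of set A, and uniformly from all nodes
#' otherwise; with bias 0 the sets are independent uniform samples.
#'
#' @param network A [ppi_network] (typically from [gen_network()]).
#' @param spec A [synthetic_spec].
#' @return A list with elements `a` and `b`, both [gene_set]s.
#' @export
gen_proximal_sets <- function(network, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  nodes <- network_nodes(network)
  with_seed(sub_seed(spec, 2), {
    a <- sample(nodes, spec$size_a)
    pool_b_all <- if (spec$disjoint_sets) setdiff(nodes, a) else nodes
    near <- names(which(apply(
      igraph::distances(network$graph, v = a, weights = NA) <=
        spec$proximity_radius, 2, any)))
    near <- intersect(near, pool_b_all)
    if (spec$proximity_bias >= 1 && length(near) < spec$size_b) {
      abort("gen_proximal_sets: radius neighborhood smaller than set B with bias 1")
    }
    b <- character(0)
    while (length(b) < spec$size_b) {
      pick_near <- stats::runif(1) < spec$proximity_bias &&
        length(setdiff(near, b)) > 0
      pool <- if (pick_near) setdiff(near, b) else setdiff(pool_b_all, b)
      b <- c(b, sample(pool, 1))
    }
    list(a = gene_set(a, name = "set_a"), b = gene_set(b, name = "set_b"))
  })
}

#' Generate a GO-like ontology and gene annotations
#'
#' Builds a single-rooted term tree of the configured depth and branching
#' (so level-4 terms always exist), types each edge `is_a` or `part_of`,
#' optionally adds second parents to make a true DAG, and annotates each
#' gene to `terms_per_gene` leaf terms. Two designated gene groups draw
#' their annotations from leaf-term families that overlap by
#' `annotation_overlap`: with overlap 1 the groups use the same term
#' families (functionally similar), with overlap 0 disjoint ones.
#'
#' @param spec A [synthetic_spec].
#' @param genes Character vector of gene symbols to annotate.
#' @param group_a,group_b Optional gene subsets receiving family-focused
#'   annotations.
#' @return List with elements `dag` ([go_dag]) and `annotations`
#'   ([annotation_map]).
#' @export
gen_ontology_and_annotations <- function(spec, genes,
                                         group_a = NULL, group_b = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), length(genes) > 0)
  genes <- toupper(genes)
  group_a <- intersect(toupper(group_a %||% character(0)), genes)
  group_b <- intersect(toupper(group_b %||% character(0)), genes)
  with_seed(sub_seed(spec, 3), {
    # term tree: one root, `branching` children per term down to depth
    parent_of <- character(0)
    counter <- 0L
    by_level <- list(`0` = "T000000")
    for (d in seq_len(spec$ontology_depth)) {
      prev <- by_level[[as.character(d - 1)]]
      cur <- character(0)
      for (p in prev) {
        for (k in seq_len(spec$branching)) {
          counter <- counter + 1L
          id <- sprintf("T%06d", counter)
          parent_of[id] <- p
          cur <- c(cur, id)
        }
      }
      by_level[[as.character(d)]] <- cur
    }
    all_ids <- c("T000000", names(parent_of))
    edges <- tibble(
      child = names(parent_of),
      parent = unname(parent_of),
      type = ifelse(stats::runif(length(parent_of)) < spec$part_of_fraction,
                    "part_of", "is_a")
    )
    # second parents: pick another term from the primary parent's level
    lvl <- rep(seq(0, spec$ontology_depth), lengths(by_level))
    names(lvl) <- unlist(by_level, use.names = FALSE)
    extra_kids <- names(parent_of)[lvl[names(parent_of)] >= 2 &
                                     stats::runif(length(parent_of)) <
                                     spec$extra_parent_fraction]
    extra <- purrr::map(extra_kids, function(id) {
      cands <- setdiff(by_level[[as.character(lvl[id] - 1)]], parent_of[id])
      if (length(cands) == 0) return(NULL)
      tibble(child = id, parent = sample(cands, 1),
             type = sample(c("is_a", "part_of"), 1,
                           prob = c(1 - spec$part_of_fraction,
                                    spec$part_of_fraction)))
    })
    edges <- bind_rows(edges, purrr::compact(extra))
    terms <- tibble(id = all_ids,
                    name = paste("synthetic term", all_ids),
                    namespace = "biological_process",
                    obsolete = FALSE)
    dag <- go_dag(terms, edges)

    # leaf-term families: disjoint blocks of leaves under distinct
    # level-4 subtrees for groups A and B, overlapping as configured
    leaves <- by_level[[as.character(spec$ontology_depth)]]
    level4 <- by_level[["4"]]
    n_shared <- round(spec$annotation_overlap * spec$n_families)
    fam_roots <- sample(level4, min(length(level4),
                                    2 * spec$n_families - n_shared))
    fam_a <- fam_roots[seq_len(min(spec$n_families, length(fam_roots)))]
    fam_b <- c(fam_a[seq_len(n_shared)],
               setdiff(fam_roots, fam_a)[seq_len(spec$n_families - n_shared)])
    fam_b <- fam_b[!is.na(fam_b)]
    leaves_under <- function(roots) {
      anc_hit <- vapply(leaves, function(l) {
        any(term_ancestors(dag, l) %in% roots)
      }, logical(1))
      leaves[anc_hit]
    }
    pool_a <- leaves_under(fam_a)
    pool_b <- leaves_under(fam_b)
    draw_terms <- function(gene) {
      pool <- if (gene %in% group_a && stats::runif(1) < spec$annotation_focus) {
        pool_a
      } else if (gene %in% group_b && stats::runif(1) < spec$annotation_focus) {
        pool_b
      } else {
        leaves
      }
      sample(pool, min(spec$terms_per_gene, length(pool)))
    }
    ann <- purrr::map(genes, function(g) tibble(gene = g, term = draw_terms(g)))
    list(dag = dag, annotations = annotation_map(bind_rows(ann), dag))
  })
}

#' Generate a pathway collection with one planted enrichment
#'
#' Samples `n_pathways` pathways uniformly from the universe; the first
#' (`planted` in the names) additionally draws
#' `round(enrich_strength * pathway_size)` of its members from the
#' designated query set, so it is over-represented at the planted
#' strength (strength 0 reduces to a random pathway).
#'
#' @param spec A [synthetic_spec].
#' @param universe Character vector of background genes.
#' @param query Character vector (or [gene_set]) the planted pathway
#'   over-samples from.
#' @return A [pathway_collection] whose planted pathway is named
#'   `"planted_pathway"`.
#' @export
gen_pathways <- function(spec, universe, query = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"), length(universe) > 0)
  universe <- unique(toupper(universe))
  query <- intersect(unique(toupper(as.character(query %||% character(0)))),
                     universe)
  n_planted <- round(spec$enrich_strength * spec$pathway_size)
  if (n_planted > length(query) && spec$enrich_strength > 0) {
    abort("gen_pathways: planted strength incompatible with query size")
  }
  if (spec$pathway_size > length(universe)) {
    abort("gen_pathways: pathway size exceeds universe")
  }
  with_seed(sub_seed(spec, 4), {
    sets <- list()
    planted <- character(0)
    if (n_planted > 0) planted <- sample(query, n_planted)
    sets[["planted_pathway"]] <- unique(c(
      planted,
      sample(setdiff(universe, planted), spec$pathway_size - length(planted))))
    for (k in seq_len(spec$n_pathways - 1)) {
      sets[[sprintf("pathway_%02d", k)]] <- sample(universe, spec$pathway_size)
    }
    pathway_collection(sets, universe = universe)
  })
}

#' Generate a docking comparison table with a known strong/weak split
#'
#' Draws known-ligand affinities from realistic ranges (MM/GBVI in
#' [-40, -8] kcal/mol, pKi in [4, 15]) and constructs the compound's
#' affinities so that exactly `round(strong_fraction * dock_rows)` rows
#' satisfy the default [comparison_rule()] (better-or-close on at least
#' one metric) and the rest fail both metrics beyond tolerance.
#'
#' @param spec A [synthetic_spec].
#' @return A `docking_table` tibble; column `planted_strong` records the
#'   construction label.
#' @export
gen_docking_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$dock_rows
  n_strong <- round(spec$strong_fraction * n)
  rule <- comparison_rule()
  with_seed(sub_seed(spec, 5), {
    known_mmgbvi <- round(stats::runif(n, -40, -8), 2)
    known_pki <- round(stats::runif(n, 4, 15), 2)
    strong <- seq_len(n) <= n_strong
    icariin_mmgbvi <- ifelse(
      strong,
      known_mmgbvi - round(stats::runif(n, 0.5, 10), 2),       # better energy
      known_mmgbvi + rule$tol_energy + round(stats::runif(n, 1, 10), 2))
    icariin_pki <- ifelse(
      strong,
      pmax(0.5, known_pki + round(stats::runif(n, -3, 3), 2)),
      pmax(0.5, known_pki - rule$tol_pki - round(stats::runif(n, 0.5, 3), 2)))
    tb <- tibble(
      target_uniprot = sprintf("P%05d", seq_len(n)),
      gene_symbol = sprintf("SYNT%02d", seq_len(n)),
      pdb_code = sprintf("%04X", seq_len(n)),
      known_ligand_name = sprintf("ligand_%02d", seq_len(n)),
      known_mmgbvi = known_mmgbvi, known_pki = known_pki,
      icariin_mmgbvi = icariin_mmgbvi, icariin_pki = icariin_pki,
      planted_strong = strong
    )
    structure(tb, class = c("docking_table", class(tb)))
  })
}

#' Write a docking table as CSV
#' @param x A `docking_table`.
#' @param path Output path.
#' @export
write_docking_table <- function(x, path) {
  cols <- c("target_uniprot", "gene_symbol", "pdb_code", "known_ligand_name",
            "known_mmgbvi", "known_pki", "icariin_mmgbvi", "icariin_pki")
  readr::write_csv(as_tibble(x)[, cols], path, progress = FALSE)
  invisible(path)
}

#' Write a complete synthetic input bundle
#'
#' Generates every pipeline input from one spec and writes them into a
#' directory in the standard interchange formats: network edge list
#' (`network.tsv`), gene lists (`set_a.txt`, `set_b.txt`), ontology
#' (`ontology.obo`), annotations (`annotations.gaf`), pathways
#' (`pathways.gmt`), docking table (`docking.csv`) and the spec itself
#' (`spec.yaml`).
#'
#' @param spec A [synthetic_spec].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_synthetic_bundle <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  network <- gen_network(spec)
  sets <- gen_proximal_sets(network, spec)
  onto <- gen_ontology_and_annotations(spec, genes = network_nodes(network),
                                       group_a = sets$a, group_b = sets$b)
  pathways <- gen_pathways(spec, universe = network_nodes(network),
                           query = sets$a)
  docking <- gen_docking_table(spec)
  paths <- list(
    network = file.path(dir, "network.tsv"),
    set_a = file.path(dir, "set_a.txt"),
    set_b = file.path(dir, "set_b.txt"),
    obo = file.path(dir, "ontology.obo"),
    gaf = file.path(dir, "annotations.gaf"),
    gmt = file.path(dir, "pathways.gmt"),
    docking = file.path(dir, "docking.csv"),
    spec = file.path(dir, "spec.yaml")
  )
  write_ppi_edgelist(network, paths$network)
  write_gene_set(sets$a, paths$set_a)
  write_gene_set(sets$b, paths$set_b)
  write_obo(onto$dag, paths$obo)
  write_gaf(onto$annotations, paths$gaf)
  write_gmt(pathways, paths$gmt)
  write_docking_table(docking, paths$docking)
  yaml::write_yaml(unclass(spec), paths$spec)
  invisible(paths)
}
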