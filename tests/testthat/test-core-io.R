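# readers and writers for gene lists, edge lists, OBO, GAF, GMT

test_that("gene set reading uppercases, deduplicates and rejects empty files", {
  path <- write_lines_tmp(c("# a comment", "tp53", "TP53", "brca1"))
  gs <- suppressMessages(read_gene_set(path, name = "demo"))
  expect_setequal(unclass(gs), c("TP53", "BRCA1"))
  expect_length(gs, 2)

  empty <- write_lines_tmp(c("# only", "# comments"))
  expect_error(read_gene_set(empty), "empty gene set")
})

test_that("gene sets round-trip through write/read", {
  gs <- gene_set(c("ZFP1", "ABC2", "M1"), name = "rt")
  path <- withr::local_tempfile(fileext = ".txt")
  write_gene_set(gs, path)
  expect_setequal(unclass(read_gene_set(path, "rt")), unclass(gs))
})

test_that("edge-list reader drops self-loops and symmetric duplicates", {
  path <- write_lines_tmp(c("A\tB", "B\tA", "C\tC"))
  net <- suppressMessages(read_ppi_edgelist(path))
  expect_setequal(network_nodes(net), c("A", "B"))
  expect_equal(nrow(network_edges(net)), 1)
})

test_that("edge-list reader is idempotent under row reversal and duplication", {
  rows <- c("A\tB", "B\tC", "C\tD", "D\tA")
  net1 <- read_ppi_edgelist(write_lines_tmp(rows))
  net2 <- suppressMessages(
    read_ppi_edgelist(write_lines_tmp(c(rev(sub("(\\w)\t(\\w)", "\\2\t\\1", rows)), rows))))
  expect_equal(network_edges(net1), network_edges(net2))
  expect_setequal(network_nodes(net1), network_nodes(net2))
})

test_that("SIF rows fan out one edge per trailing node", {
  net <- read_ppi_edgelist(write_lines_tmp("A pp B C"), dialect = "sif")
  ed <- network_edges(net)
  expect_equal(nrow(ed), 2)
  expect_setequal(paste(ed$from, ed$to), c("A B", "A C"))
})

test_that("a path-graph file yields the expected node and edge counts", {
  net <- read_ppi_edgelist(write_lines_tmp(c("A\tB", "B\tC", "C\tD")))
  expect_length(network_nodes(net), 4)
  expect_equal(nrow(network_edges(net)), 3)
})

test_that("malformed edge rows error with the line number", {
  expect_error(read_ppi_edgelist(write_lines_tmp(c("A\tB", "C"))), "line 2")
})

test_that("readers tolerate CRLF endings and a UTF-8 BOM", {
  path <- withr::local_tempfile(fileext = ".txt")
  con <- file(path, "wb")
  writeBin(c(as.raw(c(0xEF, 0xBB, 0xBF)), charToRaw("tp53\r\nbrca1\r\n")), con)
  close(con)
  gs <- read_gene_set(path, "bom")
  expect_setequal(unclass(gs), c("TP53", "BRCA1"))
})

test_that("networks round-trip through the edge-list writer", {
  net <- random_test_network(15, seed = 3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ppi_edgelist(net, path)
  net2 <- read_ppi_edgelist(path)
  expect_equal(network_edges(net), network_edges(net2))
})

test_that("OBO chains, obsolete terms and part_of relationships parse", {
  obo <- write_lines_tmp(c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:1", "name: root", "namespace: biological_process", "",
    "[Term]", "id: GO:2", "name: mid", "namespace: biological_process",
    "is_a: GO:1 ! root", "",
    "[Term]", "id: GO:3", "name: leaf", "namespace: biological_process",
    "is_a: GO:2 ! mid", "",
    "[Term]", "id: GO:4", "name: old", "namespace: biological_process",
    "is_obsolete: true", "",
    "[Term]", "id: GO:5", "name: part", "namespace: biological_process",
    "relationship: part_of GO:1 ! root", ""), ext = ".obo")
  dag <- read_obo(obo)
  expect_setequal(dag_terms(dag), c("GO:1", "GO:2", "GO:3", "GO:5"))
  expect_equal(dag$roots, "GO:1")
  expect_equal(sum(dag$edges$type == "is_a"), 2)
  expect_equal(dag$edges$type[dag$edges$child == "GO:5"], "part_of")
  expect_false("GO:4" %in% dag_terms(dag))
})

test_that("OBO cycles and unknown parents are hard errors", {
  cyc <- write_lines_tmp(c(
    "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:2", "",
    "[Term]", "id: GO:2", "name: b", "namespace: biological_process",
    "is_a: GO:1", ""), ext = ".obo")
  expect_error(read_obo(cyc), "cycle")

  orphan <- write_lines_tmp(c(
    "[Term]", "id: GO:1", "name: a", "namespace: biological_process",
    "is_a: GO:99", ""), ext = ".obo")
  expect_error(read_obo(orphan), "unknown parent")
})

test_that("ancestor closure reaches a root and never a descendant", {
  dag <- random_test_dag(25, seed = 9)
  depths <- term_depths(dag)
  for (id in sample(dag_terms(dag), 8)) {
    anc <- term_ancestors(dag, id)
    if (!(id %in% dag$roots)) {
      expect_true(any(anc %in% dag$roots))
    }
    # no descendant of id can be its ancestor (acyclicity)
    for (a in anc) expect_false(id %in% term_ancestors(dag, a))
  }
})

test_that("GAF rows map genes to terms, honouring NOT and unknown terms", {
  dag <- chain_dag()
  gaf_row <- function(gene, term, qual = "") {
    paste(c("DB", gene, gene, qual, term, "REF", "IEA", "", "P",
            "", "", "protein", "taxon:9606", "20240101", "DB", "", ""),
          collapse = "\t")
  }
  gaf <- write_lines_tmp(c("!gaf-version: 2.2",
                           gaf_row("G1", "A"), gaf_row("G1", "C"),
                           gaf_row("G2", "A", qual = "NOT"),
                           gaf_row("G3", "UNKNOWN:1")), ext = ".gaf")
  ann <- suppressMessages(read_gaf(gaf, dag))
  expect_equal(sort(tidy(ann)$term[tidy(ann)$gene == "G1"]), c("A", "C"))
  expect_false("G2" %in% annotation_background(ann))
  expect_equal(ann$n_dropped_terms, 1)
})

test_that("malformed GAF rows are skipped; all-malformed is an error", {
  dag <- chain_dag()
  ok <- paste(c("DB", "G1", "G1", "", "A", "REF", "IEA", "", "P",
                "", "", "protein", "taxon:9606", "20240101", "DB", "", ""),
              collapse = "\t")
  gaf <- write_lines_tmp(c(ok, "too\tfew\tcolumns"), ext = ".gaf")
  expect_warning(ann <- read_gaf(gaf, dag), "malformed")
  expect_equal(nrow(tidy(ann)), 1)

  bad <- write_lines_tmp(c("too\tfew", "also\tbad"), ext = ".gaf")
  expect_error(read_gaf(bad, dag), "malformed")
})

test_that("annotation propagation adds ancestors and keeps direct terms", {
  dag <- chain_dag()
  ann <- annotation_map(data.frame(gene = "G1", term = "A"), dag)
  prop <- propagate_annotations(ann)
  expect_setequal(tidy(prop)$term, c("A", "C", "ROOT"))
})

test_that("GMT parsing, duplicate names, empty files and round-trips behave", {
  gmt <- write_lines_tmp(c("P1\tdesc\tA\tB", "P2\tdesc\tC"), ext = ".gmt")
  pc <- read_gmt(gmt)
  expect_length(pc, 2)
  expect_setequal(pc$sets$P1, c("A", "B"))

  dup <- write_lines_tmp(c("P1\td\tA", "P1\td\tB"), ext = ".gmt")
  expect_error(read_gmt(dup), "duplicate pathway name")

  empty <- withr::local_tempfile(fileext = ".gmt")
  file.create(empty)
  expect_warning(pc0 <- read_gmt(empty), "empty")
  expect_length(pc0, 0)

  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(pc, path)
  pc2 <- read_gmt(path)
  expect_equal(lapply(pc2$sets, sort), lapply(pc$sets, sort))
})

test_that("the shipped docking table parses to the published 21 records", {
  path <- system.file("extdata", "icariin_docking_table.csv",
                      package = "netprox")
  tb <- read_docking_table(path)
  expect_equal(nrow(tb), 21)
  rock1 <- tb[tb$gene_symbol == "ROCK1", ]
  expect_equal(rock1$known_mmgbvi, -21.03)
  expect_equal(rock1$known_pki, 8.10)
  expect_equal(rock1$icariin_mmgbvi, -33.03)
  expect_equal(rock1$icariin_pki, 14.34)
})

test_that("docking reader rejects non-numeric affinities and warns on empty", {
  hdr <- "target_uniprot,gene_symbol,pdb_code,known_ligand_name,known_mmgbvi,known_pki,icariin_mmgbvi,icariin_pki"
  bad <- write_lines_tmp(c(hdr, "P1,G1,1ABC,lig,abc,5,-10,6"), ext = ".csv")
  expect_error(read_docking_table(bad), "known_mmgbvi")

  empty <- write_lines_tmp(hdr, ext = ".csv")
  expect_warning(tb <- read_docking_table(empty), "no records")
  expect_equal(nrow(tb), 0)
})
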