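#' Gene-to-term annotation maps
#'
#' An `annotation_map` is a long gene/term table tied to a [go_dag]. Every
#' term is live in the DAG; the background is the set of genes with at
#' least one annotation.
#'
#' @param mapping Data frame with columns `gene`, `term` (direct
#'   annotations).
#' @param dag The [go_dag] the terms belong to. Annotations to unknown or
#'   obsolete terms are dropped, with the count recorded on the object.
#' @return An `annotation_map`.
#' @export
annotation_map <- function(mapping, dag) {
  stopifnot(inherits(dag, "go_dag"))
  mapping <- as_tibble(mapping)
  stopifnot(all(c("gene", "term") %in% names(mapping)))
  mapping$gene <- toupper(mapping$gene)
  live <- dag_terms(dag)
  ok <- mapping$term %in% live
  n_dropped <- sum(!ok)
  mapping <- distinct(mapping[ok, c("gene", "term")])
  structure(
    list(mapping = mapping, dag = dag, n_dropped_terms = n_dropped),
    class = "annotation_map"
  )
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d annotations, %d genes, %d terms\n",
              nrow(x$mapping), length(annotation_background(x)),
              length(unique(x$mapping$term))))
  invisible(x)
}

#' Annotation background
#'
#' All genes carrying at least one annotation — the universe of the
#' hypergeometric enrichment test and of profile-similarity permutations.
#'
#' @param annotations An [annotation_map].
#' @return Character vector of gene symbols.
#' @export
annotation_background <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  sort(unique(annotations$mapping$gene))
}

#' Propagate annotations to ancestors (true-path rule)
#'
#' Every gene annotated to a term is also annotated to all of that term's
#' ancestors. Direct annotations are never removed.
#'
#' @param annotations An [annotation_map].
#' @return An [annotation_map] with the propagated mapping.
#' @export
propagate_annotations <- function(annotations) {
  stopifnot(inherits(annotations, "annotation_map"))
  dag <- annotations$dag
  terms_used <- unique(annotations$mapping$term)
  anc <- lapply(terms_used, term_ancestors, dag = dag, include_self = TRUE)
  closure <- tibble(
    term = rep(terms_used, lengths(anc)),
    anc_term = unlist(anc, use.names = FALSE)
  )
  prop <- annotations$mapping |>
    inner_join(closure, by = "term", relationship = "many-to-many") |>
    mutate(term = .data$anc_term) |>
    select("gene", "term") |>
    distinct()
  annotation_map(prop, dag)
}

#' Read gene annotations from a GAF 2.x file
#'
#' Uses the DB Object Symbol (column 3), qualifier (column 4), GO id
#' (column 5) and aspect (column 9). Rows with a `NOT` qualifier are
#' dropped, as are rows whose term is unknown or obsolete in `dag`
#' (counts recorded). Malformed rows (not 17 columns) are skipped with a
#' warning; if every row is malformed the read is a hard error.
#'
#' @param path Path to the GAF file (`!` lines are comments).
#' @param dag A [go_dag] used to validate terms.
#' @param aspect Keep only this GO aspect (`"P"` biological process,
#'   default; `"all"` keeps everything).
#' @param exclude_evidence Optional character vector of evidence codes to
#'   drop (all are accepted by default).
#' @return An [annotation_map].
#' @export
read_gaf <- function(path, dag, aspect = c("P", "all"),
                     exclude_evidence = NULL) {
  aspect <- match.arg(aspect)
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  if (length(lines) == 0) abort(paste0("read_gaf: no data rows in ", path))
  # sentinel keeps trailing empty columns, which strsplit would drop
  fields <- strsplit(paste0(lines, "\x01"), "\t", fixed = TRUE)
  fields <- lapply(fields, function(f) {
    f[length(f)] <- sub("\x01$", "", f[length(f)])
    f
  })
  ok_shape <- lengths(fields) == 17L
  if (!any(ok_shape)) abort("read_gaf: all rows malformed (expected 17 columns)")
  if (any(!ok_shape)) {
    warn(sprintf("read_gaf: skipped %d malformed row(s)", sum(!ok_shape)))
  }
  m <- do.call(rbind, fields[ok_shape])
  keep <- !grepl("(^|\\|)NOT($|\\|)", m[, 4])
  if (aspect != "all") keep <- keep & m[, 9] == aspect
  if (!is.null(exclude_evidence)) keep <- keep & !(m[, 7] %in% exclude_evidence)
  mapping <- tibble(gene = m[keep, 3], term = m[keep, 5])
  res <- annotation_map(mapping, dag)
  if (res$n_dropped_terms > 0) {
    inform(sprintf("read_gaf: dropped %d annotation(s) to unknown/obsolete terms",
                   res$n_dropped_terms))
  }
  res
}

#' Write an annotation map as a minimal GAF 2.2 file
#'
#' @param annotations An [annotation_map].
#' @param path Output path.
#' @param aspect Aspect code written in column 9.
#' @return `path`, invisibly.
#' @export
write_gaf <- function(annotations, path, aspect = "P") {
  stopifnot(inherits(annotations, "annotation_map"))
  mp <- arrange(annotations$mapping, .data$gene, .data$term)
  rows <- sprintf(
    "DB\t%s\t%s\t\t%s\tREF\tIEA\t\t%s\t\t\tprotein\ttaxon:9606\t20240101\tDB\t\t",
    mp$gene, mp$gene, mp$term, aspect)
  writeLines(c("!gaf-version: 2.2", rows), path)
  invisible(path)
}

#' @export
tidy.annotation_map <- function(x, ...) as_tibble(x$mapping)
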