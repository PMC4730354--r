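#' Pathway collections
#'
#' A named collection of pathway gene sets plus the background universe
#' against which over-representation is judged. The default universe is
#' the union of all pathway members, so analyses are reproducible without
#' a genome annotation download; supply an explicit background to override.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param universe Optional character vector of background gene symbols;
#'   defaults to the union of all pathway members.
#' @return A `pathway_collection`.
#' @export
pathway_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    abort("pathway_collection: pathway names must be unique and non-empty")
  }
  sets <- lapply(sets, function(s) unique(toupper(s)))
  sets <- sets[lengths(sets) > 0]
  universe <- unique(toupper(universe %||% unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, universe = sort(universe)),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  cat(sprintf("<pathway_collection> %d pathways, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$sets)

#' Read pathway gene sets from a GMT file
#'
#' Each row is `name<TAB>description<TAB>member...`. Pathways with no
#' members are dropped; duplicate names are a hard error.
#'
#' @param path Path to the GMT file.
#' @param universe Optional explicit background gene vector.
#' @return A [pathway_collection].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- read_clean_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warn(paste0("read_gmt: empty file ", path))
    return(pathway_collection(list(), universe = universe))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(fields, `[`, character(1), 1)
  if (anyDuplicated(nm)) {
    abort(paste0("read_gmt: duplicate pathway name: ",
                 nm[duplicated(nm)][1]))
  }
  sets <- lapply(fields, function(f) if (length(f) > 2) f[-(1:2)] else character(0))
  names(sets) <- nm
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warn(sprintf("read_gmt: dropped %d pathway(s) with no members", sum(empty)))
  }
  pathway_collection(sets[!empty], universe = universe)
}

#' Write a pathway collection as GMT
#'
#' @param x A [pathway_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "pathway_collection"))
  rows <- vapply(names(x$sets), function(nm) {
    paste(c(nm, "na", sort(x$sets[[nm]])), collapse = "\t")
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' @export
tidy.pathway_collection <- function(x, ...) {
  tibble(
    pathway = rep(names(x$sets), lengths(x$sets)),
    gene = unlist(lapply(x$sets, sort), use.names = FALSE)
  )
}
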