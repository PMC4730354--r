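#' Gene sets
#'
#' A gene set is a named, unordered collection of unique gene symbols
#' (uppercased strings). It is one side of every statistic in the package:
#' the compound's putative targets, the disease proteins, a pathway, or a
#' background universe.
#'
#' @param members Character vector of gene symbols. Symbols are uppercased
#'   and deduplicated; empty strings are dropped.
#' @param name Short label for the set.
#' @return A `gene_set` object (a classed character vector with a `name`
#'   attribute).
#' @examples
#' gene_set(c("tp53", "TP53", "brca1"), name = "demo")
#' @export
gene_set <- function(members, name = "gene_set") {
  members <- toupper(trimws(as.character(members)))
  members <- unique(members[nzchar(members)])
  structure(members, name = name, class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d symbols\n", set_name(x), length(x)))
  cat(" ", paste(head(unclass(x), 10), collapse = ", "),
      if (length(x) > 10) "..." else "", "\n")
  invisible(x)
}

set_name <- function(x) attr(x, "name") %||% "gene_set"

#' Read a gene set from a plain-text file
#'
#' One symbol per line; lines starting with `#` are comments. Symbols are
#' uppercased and deduplicated (the number of duplicates dropped is
#' reported as a message).
#'
#' @param path Path to the file.
#' @param name Label for the set; defaults to the file name.
#' @return A [gene_set].
#' @export
read_gene_set <- function(path, name = NULL) {
  name <- name %||% tools::file_path_sans_ext(basename(path))
  lines <- read_clean_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  symbols <- toupper(lines)
  n_dup <- length(symbols) - length(unique(symbols))
  if (length(unique(symbols)) == 0) {
    abort(paste0("empty gene set: ", path))
  }
  if (n_dup > 0) {
    inform(sprintf("read_gene_set: dropped %d duplicate symbol(s) in %s",
                   n_dup, path))
  }
  gene_set(symbols, name = name)
}

#' Write a gene set to a plain-text file
#'
#' @param x A [gene_set].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(x, path) {
  stopifnot(inherits(x, "gene_set"))
  writeLines(sort(unclass(x)), path)
  invisible(path)
}

#' @export
tidy.gene_set <- function(x, ...) {
  tibble(set = set_name(x), gene = sort(unclass(x)))
}
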