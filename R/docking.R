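#' Docking comparison tables
#'
#' One row per putative target that was re-docked alongside its known
#' ligand in the same pocket: the known ligand's MM/GBVI binding energy
#' (kcal/mol, more negative = stronger) and pKi, and the compound's
#' MM/GBVI and pKi on the same site.
#'
#' `read_docking_table()` reads the CSV transcription of such a table;
#' the shipped fixture `system.file("extdata", "icariin_docking_table.csv",
#' package = "netprox")` holds the 21 published strong-binding rows for
#' icariin.
#'
#' @param path Path to a CSV with columns `target_uniprot`, `gene_symbol`,
#'   `pdb_code`, `known_ligand_name`, `known_mmgbvi`, `known_pki`,
#'   `icariin_mmgbvi`, `icariin_pki`.
#' @return A tibble of class `docking_table`, one row per record.
#' @export
read_docking_table <- function(path) {
  need <- c("target_uniprot", "gene_symbol", "pdb_code", "known_ligand_name",
            "known_mmgbvi", "known_pki", "icariin_mmgbvi", "icariin_pki")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    abort(paste0("read_docking_table: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  raw <- raw[, need]
  if (nrow(raw) == 0) {
    warn(paste0("read_docking_table: no records in ", path))
  }
  num_cols <- c("known_mmgbvi", "known_pki", "icariin_mmgbvi", "icariin_pki")
  for (cl in num_cols) {
    # tolerate the Unicode minus sign used in typeset tables
    vals <- suppressWarnings(as.numeric(gsub("−", "-", raw[[cl]])))
    bad <- which(is.na(vals) & !is.na(raw[[cl]]))
    if (length(bad) > 0) {
      abort(sprintf("read_docking_table: non-numeric value in column %s, row %d",
                    cl, bad[1]))
    }
    if (anyNA(vals) && nrow(raw) > 0) {
      abort(sprintf("read_docking_table: missing value in column %s", cl))
    }
    raw[[cl]] <- vals
  }
  if (nrow(raw) > 0 && any(raw$known_pki <= 0 | raw$icariin_pki <= 0)) {
    abort("read_docking_table: pKi values must be positive")
  }
  structure(as_tibble(raw), class = c("docking_table", class(as_tibble(raw))))
}

#' Better-or-close binding comparison rule
#'
#' A putative target is called a strong ("true") binder when the compound's
#' affinity is better than, or close to, the known ligand's on at least one
#' metric: MM/GBVI within `tol_energy` kcal/mol, or pKi within `tol_pki`
#' units. "Close" is a reverse-engineered convention — the published table
#' never defines it — and the defaults (4.0 kcal/mol, 1.0 pKi unit) are the
#' smallest round values under which every published strong row classifies
#' strong; both are configurable.
#'
#' @param tol_energy Tolerance on MM/GBVI (kcal/mol), >= 0.
#' @param tol_pki Tolerance on pKi units, >= 0.
#' @return A `comparison_rule`.
#' @export
comparison_rule <- function(tol_energy = 4.0, tol_pki = 1.0) {
  stopifnot(tol_energy >= 0, tol_pki >= 0)
  structure(list(tol_energy = tol_energy, tol_pki = tol_pki,
                 combine = "any_metric"),
            class = "comparison_rule")
}

#' Classify docking records as strong or weak binders
#'
#' For each record, the MM/GBVI metric passes when
#' `icariin_mmgbvi <= known_mmgbvi + tol_energy` (more negative is better)
#' and the pKi metric passes when `icariin_pki >= known_pki - tol_pki`
#' (higher is better); the record is strong when at least one metric
#' passes. `classify_table()` additionally summarises counts and the
#' percentage strong of a supplied denominator (e.g., all docked targets,
#' including weak rows not present in the table).
#'
#' @param records A `docking_table` (or data frame with its columns).
#' @param rule A [comparison_rule].
#' @return `classify_records()`: a tibble of class `dock_comparison` with,
#'   per record, `strong`, `pass_mmgbvi`, `pass_pki`, and the signed
#'   icariin-minus-known margins (`margin_mmgbvi`, `margin_pki`; negative
#'   energy margin and positive pKi margin mean icariin is better).
#' @export
classify_records <- function(records, rule = comparison_rule()) {
  stopifnot(inherits(rule, "comparison_rule"))
  records <- as_tibble(records)
  if (nrow(records) == 0) abort("classify_records: no records")
  stopifnot(all(is.finite(records$known_mmgbvi)),
            all(is.finite(records$icariin_mmgbvi)),
            all(is.finite(records$known_pki)),
            all(is.finite(records$icariin_pki)))
  res <- records |>
    mutate(
      margin_mmgbvi = .data$icariin_mmgbvi - .data$known_mmgbvi,
      margin_pki = .data$icariin_pki - .data$known_pki,
      pass_mmgbvi = .data$margin_mmgbvi <= rule$tol_energy,
      pass_pki = .data$margin_pki >= -rule$tol_pki,
      strong = .data$pass_mmgbvi | .data$pass_pki
    )
  structure(res, class = c("dock_comparison", class(res)),
            rule = rule)
}

#' @rdname classify_records
#' @param n_total Denominator for the percentage strong; defaults to the
#'   number of records, but is typically the full count of docked targets
#'   when the table only lists the strong rows.
#' @return `classify_table()`: the `dock_comparison` tibble with a
#'   `summary` attribute; see [glance.dock_comparison()].
#' @export
classify_table <- function(records, rule = comparison_rule(), n_total = NULL) {
  res <- classify_records(records, rule)
  n_total <- n_total %||% nrow(res)
  n_strong <- sum(res$strong)
  if (n_total < n_strong) {
    abort("classify_table: n_total smaller than the number of strong records")
  }
  attr(res, "summary") <- tibble(
    n_records = nrow(res),
    n_strong = n_strong,
    n_weak = nrow(res) - n_strong,
    n_total = as.integer(n_total),
    pct_strong = round(100 * n_strong / n_total, 2)
  )
  res
}

#' @export
glance.dock_comparison <- function(x, ...) {
  attr(x, "summary") %||% tibble(
    n_records = nrow(x),
    n_strong = sum(x$strong),
    n_weak = sum(!x$strong),
    n_total = nrow(x),
    pct_strong = round(100 * mean(x$strong), 2)
  )
}

#' @export
tidy.dock_comparison <- function(x, ...) {
  as_tibble(x)[, c("gene_symbol", "strong", "pass_mmgbvi", "pass_pki",
                   "margin_mmgbvi", "margin_pki")]
}

#' @export
print.dock_comparison <- function(x, ...) {
  s <- glance(x)
  cat(sprintf("<dock_comparison> strong=%d of %d (%.2f%%)\n",
              s$n_strong, s$n_total, s$pct_strong))
  NextMethod()
}

#' @export
autoplot.dock_comparison <- function(object, metric = c("mmgbvi", "pki"), ...) {
  metric <- match.arg(metric)
  known <- paste0("known_", metric)
  ica <- paste0("icariin_", metric)
  lab <- if (metric == "mmgbvi") "MM/GBVI (kcal/mol)" else "pKi"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data[[known]], .data[[ica]],
                               colour = .data$strong)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste("Known ligand", lab),
                  y = paste("Icariin", lab), colour = "strong") +
    ggplot2::theme_minimal()
}
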