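# Aggregate reporting: evaluation and annotation tables as TSV with JSON
# twins, the reads-per-contig histogram, and run-configuration capture so a
# saved run can be reproduced byte-identically.

#' Capture the run configuration
#'
#' Collects every tunable in one place with provenance (`default` vs
#' `user`). Serialized verbatim (`config.used.yaml`) into every report
#' directory by [render_reports()].
#'
#' @param ... Named overrides of the defaults (`match, mismatch, gap_open,
#'   gap_extend, evalue_max, full_length_threshold, merge_threshold,
#'   ssr_min_units, clip_min_len, adapter_max_mismatch_frac,
#'   adapter_min_match, seed`).
#' @return A named list of class `qc_config`; each element has fields
#'   `value` and `source`.
#' @export
qc_config <- function(...) {
  defaults <- list(
    match = 1, mismatch = -2, gap_open = -3, gap_extend = -1,
    evalue_max = 1e-5, full_length_threshold = 0.90, merge_threshold = 75,
    ssr_min_units = as.list(DEFAULT_MIN_UNITS),
    clip_min_len = 20, adapter_max_mismatch_frac = 0.1, adapter_min_match = 10,
    seed = NA_integer_
  )
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config option(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- purrr::imap(defaults, function(v, nm) {
    if (nm %in% names(user)) list(value = user[[nm]], source = "user")
    else list(value = v, source = "default")
  })
  structure(cfg, class = "qc_config")
}

#' @export
print.qc_config <- function(x, ...) {
  cat("<qc_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]$value
    cat(sprintf("  %-26s %s  [%s]\n", nm,
                paste(unlist(v), collapse = ","), x[[nm]]$source))
  }
  invisible(x)
}

config_value <- function(cfg, name) cfg[[name]]$value

#' Reads-per-contig histogram
#'
#' Distribution of member-read counts over contigs (singletons excluded):
#' in a well-normalized library most contigs assemble from just two reads.
#'
#' @param assembly A [assembly()] object.
#' @param membership Optional membership tibble; defaults to the assembly's
#'   own membership.
#' @return Tibble with columns `n_reads`, `n_contigs`.
#' @export
reads_per_contig_histogram <- function(assembly, membership = NULL) {
  membership <- membership %||% assembly_membership(assembly)
  unknown <- setdiff(membership$contig_id, assembly$contigs$id)
  if (length(unknown) > 0) {
    abort(sprintf("membership references unknown contig(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  if (nrow(assembly$contigs) == 0) {
    return(tibble(n_reads = integer(), n_contigs = integer()))
  }
  membership %>%
    dplyr::count(.data$contig_id, name = "n_reads") %>%
    dplyr::count(.data$n_reads, name = "n_contigs") %>%
    dplyr::arrange(.data$n_reads)
}

#' Bar chart of contigs by member-read count
#'
#' @param histogram Tibble from [reads_per_contig_histogram()].
#' @return A ggplot object.
#' @export
plot_reads_per_contig <- function(histogram) {
  ggplot2::ggplot(histogram, ggplot2::aes(x = .data$n_reads, y = .data$n_contigs)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "reads per contig", y = "contigs")
}

#' Write the evaluation/annotation/histogram reports
#'
#' Writes each supplied table as TSV together with a field-for-field JSON
#' twin, plus `config.used.yaml`. Outputs are deterministic: re-rendering
#' from the same inputs and configuration is byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param evaluations Optional [evaluate_assemblies()] table.
#' @param summaries Optional tibble of [annotation_summary()] rows.
#' @param histogram Optional [reads_per_contig_histogram()] tibble.
#' @param config A [qc_config()] object.
#' @return Character vector of files written, invisibly.
#' @export
render_reports <- function(outdir, evaluations = NULL, summaries = NULL,
                           histogram = NULL, config = qc_config()) {
  ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) abort(sprintf("cannot create output directory: %s", outdir))
  written <- character(0)
  emit <- function(tbl, stem) {
    tsv <- file.path(outdir, paste0(stem, ".tsv"))
    json <- file.path(outdir, paste0(stem, ".json"))
    readr::write_tsv(tbl, tsv)
    jsonlite::write_json(tbl, json, dataframe = "rows", digits = NA, pretty = TRUE)
    c(tsv, json)
  }
  if (!is.null(evaluations)) written <- c(written, emit(as_tibble(evaluations), "evaluation"))
  if (!is.null(summaries)) written <- c(written, emit(summaries, "annotation"))
  if (!is.null(histogram)) written <- c(written, emit(histogram, "reads_per_contig"))
  cfg_path <- file.path(outdir, "config.used.yaml")
  yaml::write_yaml(lapply(unclass(config), function(e) {
    e$value <- if (is.list(e$value)) lapply(e$value, unclass) else unclass(e$value)
    e
  }), cfg_path)
  written <- c(written, cfg_path)
  invisible(written)
}
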