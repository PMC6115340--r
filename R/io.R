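# Plain-text interchange formats: per-tissue expression matrices with a
# tissue annotation, count tables, FASTA promoters carrying a "tss=" token,
# profile trace tables, truth records and parameter-stamped result tables.

#' Read and write multi-tissue expression panels
#'
#' On disk a panel is one tab-separated matrix per tissue (first column
#' `gene_id`, one column per sample) named `<tissue>.tsv`, plus
#' `tissue_annotation.tsv` mapping `sample_id` to `tissue`.
#'
#' @param panel A long panel tibble (`tissue`, `sample_id`, `gene_id`,
#'   `value`).
#' @param dir Directory to write to / read from.
#' @return `read_expression_panel()` returns the long panel tibble;
#'   `write_expression_panel()` returns `dir` invisibly.
#' @export
write_expression_panel <- function(panel, dir) {
  .check_panel(panel)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ann <- distinct(panel, .data$sample_id, .data$tissue)
  readr::write_tsv(ann, file.path(dir, "tissue_annotation.tsv"))
  for (ts in unique(panel$tissue)) {
    wide <- panel %>%
      filter(.data$tissue == ts) %>%
      select("gene_id", "sample_id", "value") %>%
      tidyr::pivot_wider(names_from = "sample_id", values_from = "value")
    readr::write_tsv(wide, file.path(dir, paste0(ts, ".tsv")))
  }
  invisible(dir)
}

#' @rdname write_expression_panel
#' @export
read_expression_panel <- function(dir) {
  ann <- readr::read_tsv(file.path(dir, "tissue_annotation.tsv"),
                         show_col_types = FALSE)
  purrr::map(unique(ann$tissue), function(ts) {
    wide <- readr::read_tsv(file.path(dir, paste0(ts, ".tsv")),
                            show_col_types = FALSE)
    wide %>%
      tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                          values_to = "value") %>%
      mutate(tissue = ts)
  }) %>%
    bind_rows() %>%
    select("tissue", "sample_id", "gene_id", "value")
}

#' Read and write count matrices
#'
#' Tab-separated table: `gene_id` plus one integer column per library.
#'
#' @param counts Count tibble (see [simulate_count_matrix()]).
#' @param path File path.
#' @return `read_counts()` returns the count tibble.
#' @export
write_counts <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Read and write promoter FASTA with a TSS offset token
#'
#' The description line of each record carries the 1-based index of the TSS
#' base after a `tss=` token, e.g. `>prom1 tss=801`.
#'
#' @param promoters Tibble with columns `id`, `sequence`, `tss_index`.
#' @param path FASTA file path.
#' @return `read_promoters()` returns the promoter tibble.
#' @export
write_promoters <- function(promoters, path) {
  stopifnot(all(c("id", "sequence", "tss_index") %in% names(promoters)))
  seqs <- Biostrings::DNAStringSet(promoters$sequence)
  names(seqs) <- sprintf("%s tss=%d", promoters$id,
                         as.integer(promoters$tss_index))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_promoters
#' @export
read_promoters <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  headers <- names(seqs)
  tss <- stringr::str_match(headers, "tss=(\\d+)")[, 2]
  if (anyNA(tss)) abort("Every FASTA header needs a 'tss=' token.")
  tibble(
    id = stringr::str_extract(headers, "^\\S+"),
    sequence = unname(as.character(seqs)),
    tss_index = as.integer(tss)
  )
}

#' Read and write membrane profile traces
#'
#' Tab-separated table with columns `profile_id`, `position_index`,
#' `channel1`, `channel2` (in memory the position column is named
#' `position`).
#'
#' @param profiles Profile tibble (see [simulate_membrane_profiles()]).
#' @param path File path.
#' @return `read_profiles()` returns the profile tibble.
#' @export
write_profiles <- function(profiles, path) {
  profiles %>%
    rename(position_index = "position") %>%
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE) %>%
    rename(position = "position_index")
}

#' Serialize a planted-structure truth record as JSON
#'
#' @param truth A [new_sim_truth()] record.
#' @param path JSON file path.
#' @return `read_sim_truth()` returns the restored `sim_truth`.
#' @export
write_sim_truth <- function(truth, path) {
  x <- unclass(truth)
  # keep names of named vectors (e.g. per-tissue expected r) as JSON keys
  x <- purrr::map(x, function(v) {
    if (is.atomic(v) && !is.null(names(v))) as.list(v) else v
  })
  jsonlite::write_json(x, path, auto_unbox = TRUE,
                       dataframe = "columns", pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sim_truth
#' @export
read_sim_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(x$planted_motifs)) {
    x$planted_motifs <- as_tibble(x$planted_motifs)
  }
  structure(x, class = "sim_truth")
}

#' Write a result table with a self-describing parameter header
#'
#' Prepends `#`-prefixed `key=value` comment lines recording the run
#' parameters, then the tab-separated table.
#'
#' @param x A data frame.
#' @param path File path.
#' @param params Named list of parameters to stamp into the header.
#' @return `read_result_table()` returns the tibble (header comments
#'   attached as attribute `params`).
#' @export
write_result_table <- function(x, path, params = list()) {
  header <- sprintf("# %s=%s", names(params),
                    vapply(params, function(v) paste(format(v), collapse = ","),
                           character(1)))
  writeLines(header, path)
  readr::write_tsv(as_tibble(x), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  lines <- readLines(path)
  header <- grep("^#", lines, value = TRUE)
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  kv <- stringr::str_match(header, "^# ([^=]+)=(.*)$")
  params <- setNames(as.list(kv[, 3]), kv[, 2])
  attr(out, "params") <- params
  out
}
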