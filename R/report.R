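# Abundance tables stratified by sample metadata, plus Shannon diversity.
#
# The reporting convention groups samples by forest, season and depth layer
# with layers "b" and "c" merged to "b,c"; within each group, percentages of
# the classified-plus-other total close to 100.

REPORT_LABELS <- c("MnP", "VP", "LiP", "rest-AA2", "non-AA2/other")

#' Read a sample metadata table
#'
#' TSV with header columns `sample_id`, `forest`, `plot`, `depth_layer`
#' (`a`, `b`, `c` or `b,c`) and `season` (`I` winter, `II` summer).
#'
#' @param path TSV path.
#' @return Validated tibble.
#' @export
read_sample_metadata <- function(path) {
  meta <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                          col_types = readr::cols(.default = "c"))
  validate_sample_metadata(meta)
}

#' Validate sample metadata
#' @param meta Tibble with the columns of [read_sample_metadata()].
#' @return The tibble, invisibly checked (unique ids, closed enums).
#' @export
validate_sample_metadata <- function(meta) {
  required <- c("sample_id", "forest", "plot", "depth_layer", "season")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("sample metadata missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id")
  if (!all(meta$depth_layer %in% c("a", "b", "c", "b,c"))) {
    abort("depth_layer must be one of a, b, c, b,c")
  }
  if (!all(meta$season %in% c("I", "II"))) {
    abort("season must be I or II")
  }
  tibble::as_tibble(meta)
}

#' Tabulate peroxidase classes into a stratified abundance table
#'
#' Joins OTU-level classifications to reads and samples, groups by (forest,
#' season, depth layer with `b` and `c` merged to `b,c`), and reports the
#' percentage of each class within the group. The `non-AA2/other` row is the
#' remainder closing every column to 100. Empty groups are omitted with a
#' message.
#'
#' @param classifications Classification tibble from [classify_otus()]
#'   (columns `otu_id`, `label`).
#' @param membership Tibble `read_id`, `otu_id` (see [otu_membership()]).
#' @param samples Tibble `read_id`, `sample_id`; every read must map to
#'   exactly one known sample.
#' @param metadata Sample metadata tibble ([read_sample_metadata()]).
#' @param unit `"reads"` (reads per class) or `"otus"` (distinct OTUs per
#'   class; an OTU counts once in every group where it has reads).
#' @param merge_depth Merge layers `b` and `c` into `b,c` (default `TRUE`,
#'   the reporting convention; `FALSE` keeps raw layers).
#' @return An `aa2_abundance` tibble in long form: `group`, `forest`,
#'   `season`, `depth_layer`, `label`, `n`, `pct`.
#' @export
tabulate_classes <- function(classifications, membership, samples, metadata,
                             unit = c("reads", "otus"), merge_depth = TRUE) {
  unit <- match.arg(unit)
  metadata <- validate_sample_metadata(metadata)
  unknown <- setdiff(samples$sample_id, metadata$sample_id)
  if (length(unknown) > 0) {
    abort(paste0("read(s) mapped to unknown sample id(s): ",
                 paste(unknown, collapse = ", ")))
  }
  if (anyDuplicated(samples$read_id)) {
    abort("a read maps to more than one sample")
  }
  df <- membership |>
    dplyr::inner_join(samples, by = "read_id") |>
    dplyr::left_join(classifications[, c("otu_id", "label")], by = "otu_id") |>
    dplyr::left_join(metadata, by = "sample_id") |>
    dplyr::mutate(
      depth_layer = if (merge_depth) {
        ifelse(.data$depth_layer %in% c("b", "c"), "b,c", .data$depth_layer)
      } else .data$depth_layer,
      label = ifelse(is.na(.data$label) | .data$label == "non-AA2",
                     "non-AA2/other", .data$label),
      group = paste0(.data$forest, .data$season, .data$depth_layer)
    )
  counts <- if (unit == "reads") {
    dplyr::count(df, .data$group, .data$forest, .data$season,
                 .data$depth_layer, .data$label, name = "n")
  } else {
    df |>
      dplyr::distinct(.data$group, .data$forest, .data$season,
                      .data$depth_layer, .data$label, .data$otu_id) |>
      dplyr::count(.data$group, .data$forest, .data$season,
                   .data$depth_layer, .data$label, name = "n")
  }
  groups <- dplyr::distinct(counts, .data$group, .data$forest, .data$season,
                            .data$depth_layer)
  out <- tidyr::expand_grid(groups, label = REPORT_LABELS) |>
    dplyr::left_join(counts,
                     by = c("group", "forest", "season", "depth_layer",
                            "label")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(label = factor(.data$label, levels = REPORT_LABELS)) |>
    dplyr::arrange(.data$group, .data$label)
  empty <- setdiff(paste0(metadata$forest, metadata$season,
                          ifelse(merge_depth & metadata$depth_layer %in% c("b", "c"),
                                 "b,c", metadata$depth_layer)),
                   out$group)
  if (length(empty) > 0) {
    message("empty group(s) omitted: ", paste(unique(empty), collapse = ", "))
  }
  structure(out, unit = unit, class = c("aa2_abundance", class(out)))
}

#' Pivot an abundance table to the wide (one column per group) layout
#' @param table `aa2_abundance` tibble.
#' @param value `"pct"` or `"n"`.
#' @return Wide tibble, one row per class label.
#' @export
abundance_wide <- function(table, value = c("pct", "n")) {
  value <- match.arg(value)
  tidyr::pivot_wider(tibble::as_tibble(table)[, c("group", "label", value)],
                     names_from = "group", values_from = dplyr::all_of(value))
}

#' Shannon diversity index (natural log)
#'
#' H = -sum p_i log p_i over taxa with positive counts.
#'
#' @param counts Non-negative numeric vector with at least one positive
#'   entry.
#' @return The Shannon index.
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) abort("counts must be non-negative")
  if (sum(counts) == 0) abort("all counts are zero")
  unname(vegan::diversity(counts, index = "shannon"))
}

#' Write an abundance report (TSV + JSON)
#'
#' The TSV renders the wide percentage table at 2 decimals; the JSON holds
#' the long table and diversity values at full precision and reloads
#' losslessly.
#'
#' @param table `aa2_abundance` tibble.
#' @param diversity Named list or vector of diversity values (optional).
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tsv` and `<prefix>.json`.
#' @return Invisibly, the two paths.
#' @export
write_report <- function(table, diversity = NULL, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  json <- paste0(path_prefix, ".json")
  wide <- abundance_wide(table, "pct")
  wide_fmt <- dplyr::mutate(wide, dplyr::across(-"label",
                                                ~ sprintf("%.2f", .x)))
  readr::write_tsv(wide_fmt, tsv, progress = FALSE)
  payload <- list(
    table = tibble::as_tibble(table) |>
      dplyr::mutate(label = as.character(.data$label)),
    unit = attr(table, "unit"),
    diversity = diversity
  )
  jsonlite::write_json(payload, json, digits = NA, auto_unbox = TRUE)
  invisible(c(tsv = tsv, json = json))
}

#' Reload the JSON half of a written report
#' @param path JSON path from [write_report()].
#' @return List with `table` tibble, `unit`, `diversity`.
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$table <- tibble::as_tibble(x$table)
  x
}

#' @export
autoplot.aa2_abundance <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$group, y = .data$pct,
                               fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "sample group (forest, season, depth)",
                  y = paste0("% of ", attr(object, "unit")),
                  fill = "class") +
    ggplot2::theme_minimal()
}
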