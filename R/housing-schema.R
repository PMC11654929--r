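#' Material classification schema
#'
#' Loads the packaged three-category classification of dwelling construction
#' materials (natural / rudimentary / finished, per component) used by
#' household survey programs, optionally extended with user synonyms. The
#' binary recode treats finished as "improved" and groups rudimentary with
#' natural as "unimproved", consistently across floors, walls and roofs.
#'
#' Quirks inherited from the source classification and kept as printed: "tin"
#' walls are natural (although metal roofs are finished), and "no walls" /
#' "no roof" are natural.
#'
#' @param extra Optional data frame of synonym rows with columns
#'   `component`, `label`, `category` appended to the packaged schema.
#' @return A tibble with columns `component`, `label`, `category`.
#' @export
material_schema <- function(extra = NULL) {
  path <- system.file("extdata", "material_schema.csv", package = "dwellmap")
  sch <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(extra)) {
    extra <- tibble::as_tibble(extra)[, c("component", "label", "category")]
    sch <- dplyr::bind_rows(sch, extra)
  }
  sch <- dplyr::mutate(sch,
    component = normalize_label(.data$component),
    label = normalize_label(.data$label),
    category = normalize_label(.data$category))
  bad <- !sch$component %in% c("floor", "wall", "roof") |
    !sch$category %in% c("natural", "rudimentary", "finished")
  if (any(bad)) stop("invalid schema rows: ", sum(bad), call. = FALSE)
  dup <- duplicated(sch[, c("component", "label")])
  sch[!dup, ]
}

normalize_label <- function(x) {
  x <- tolower(trimws(as.character(x)))
  gsub("\\s+", " ", x)
}

#' Classify a material label
#'
#' Case- and whitespace-insensitive lookup of a raw material label into the
#' three-category schema. Unknown labels return `NA` (the missing marker, as
#' for survey "other" responses) with a warning rather than an error.
#'
#' @param component One of `"floor"`, `"wall"`, `"roof"` (recycled).
#' @param label Character vector of raw material labels.
#' @param schema A schema tibble from [material_schema()].
#' @return Character vector in `c("natural", "rudimentary", "finished", NA)`.
#' @export
classify_material <- function(component, label, schema = material_schema()) {
  component <- normalize_label(component)
  bad <- !component %in% c("floor", "wall", "roof")
  if (any(bad))
    stop("invalid component(s): ", paste(unique(component[bad]), collapse = ", "),
         "; must be floor, wall or roof", call. = FALSE)
  if (any(!nzchar(trimws(as.character(label))) & !is.na(label)))
    stop("empty material label", call. = FALSE)
  key <- paste(component, normalize_label(label), sep = "\r")
  lut <- setNames(schema$category, paste(schema$component, schema$label, sep = "\r"))
  out <- unname(lut[key])
  out[is.na(label)] <- NA_character_
  unknown <- is.na(out) & !is.na(label)
  if (any(unknown))
    warning("unknown material label(s): ",
            paste(unique(label[unknown]), collapse = ", "), call. = FALSE)
  out
}

#' Binary improved/unimproved recode
#'
#' @param category Character vector in
#'   `c("natural", "rudimentary", "finished", NA)`.
#' @return `"improved"` for finished, `"unimproved"` for natural and
#'   rudimentary, `NA` propagated.
#' @export
recode_binary <- function(category) {
  ok <- category %in% c("natural", "rudimentary", "finished") | is.na(category)
  if (!all(ok))
    stop("unknown category: ", paste(unique(category[!ok]), collapse = ", "), call. = FALSE)
  dplyr::case_when(
    is.na(category) ~ NA_character_,
    category == "finished" ~ "improved",
    TRUE ~ "unimproved"
  )
}

#' Sample one household per cluster
#'
#' Randomly retains a single household with a non-missing outcome per
#' cluster, dropping clusters whose outcome is entirely missing. Selection is
#' uniform over eligible households, seeded, and performed independently per
#' outcome component (call once per component with its own outcome column).
#'
#' @param households Data frame with a `cluster_id` column.
#' @param outcome_col Name of the binary outcome column to screen on.
#' @param seed Integer seed.
#' @return A tibble with at most one row per cluster, ordered by cluster id.
#' @export
sample_one_per_cluster <- function(households, outcome_col, seed = 1L) {
  hh <- tibble::as_tibble(households)
  if (nrow(hh) == 0) {
    warning("empty household table", call. = FALSE)
    return(hh)
  }
  stopifnot("cluster_id" %in% names(hh), outcome_col %in% names(hh))
  hh <- hh[!is.na(hh[[outcome_col]]), , drop = FALSE]
  hh <- dplyr::arrange(hh, .data$cluster_id)
  with_seed(seed, {
    hh |>
      dplyr::group_by(.data$cluster_id) |>
      dplyr::slice_sample(n = 1) |>
      dplyr::ungroup()
  })
}
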