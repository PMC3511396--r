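canonical_cols <- c(
  "publication_id", "n_rate_kg_ha", "n2o_kg_n_ha_yr", "replicate",
  "land_use", "soil_class", "gas_measured", "inhibitor", "grazing",
  "continent", "climate"
)
required_cols <- c("publication_id", "n_rate_kg_ha", "n2o_kg_n_ha_yr")

#' Read a table of field N2O emission measurements
#'
#' Reads a delimiter-separated text file with one row per
#' publication x N-dose x replicate into the canonical emission tibble.
#' Canonical columns: `publication_id`, `n_rate_kg_ha` (applied N,
#' kg N ha^-1), `n2o_kg_n_ha_yr` (emission, kg N2O-N ha^-1 yr^-1),
#' `replicate`, and the exclusion metadata `land_use`
#' (agricultural/natural), `soil_class` (mineral/organic), `gas_measured`
#' (N2O/NO/both), `inhibitor` and `grazing` (0/1), plus optional
#' `continent` and `climate`. Files using other column names are remapped
#' through `schema`.
#'
#' Rows whose dose or emission fail to parse as numbers are dropped with
#' one warning per row, never silently.
#'
#' @param path Path to a delimited text file with a header row.
#' @param schema Optional named character vector mapping canonical names to
#'   the file's column names, e.g. `c(n_rate_kg_ha = "n_rate")`.
#' @param delim Field delimiter (default comma).
#' @return A tibble with the canonical columns present in the file,
#'   `n_rate_kg_ha` and `n2o_kg_n_ha_yr` numeric, `inhibitor`/`grazing`
#'   logical when present.
#' @seealso [write_emission_table()], [apply_exclusion_filters()]
#' @export
read_emission_table <- function(path, schema = NULL, delim = ",") {
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) == 0L) stop("empty input: no data rows in ", path, call. = FALSE)
  if (!is.null(schema)) {
    missing_src <- setdiff(unname(schema), names(raw))
    if (length(missing_src)) {
      stop("schema maps to columns absent from the file: ",
           paste(missing_src, collapse = ", "), call. = FALSE)
    }
    names(raw)[match(unname(schema), names(raw))] <- names(schema)
  }
  absent <- setdiff(required_cols, names(raw))
  if (length(absent)) {
    stop("missing required column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, intersect(canonical_cols, names(raw))]

  dose <- suppressWarnings(as.numeric(out$n_rate_kg_ha))
  n2o <- suppressWarnings(as.numeric(out$n2o_kg_n_ha_yr))
  bad <- which(is.na(dose) | is.na(n2o))
  for (i in bad) {
    warning("row ", i, ": unparseable dose ('", out$n_rate_kg_ha[i],
            "') or n2o ('", out$n2o_kg_n_ha_yr[i], "'); row skipped",
            call. = FALSE)
  }
  out$n_rate_kg_ha <- dose
  out$n2o_kg_n_ha_yr <- n2o
  if (length(bad)) out <- out[-bad, ]

  if ("replicate" %in% names(out)) {
    out$replicate <- as.integer(out$replicate)
  } else {
    out$replicate <- 1L
  }
  for (col in c("inhibitor", "grazing")) {
    if (col %in% names(out)) out[[col]] <- out[[col]] %in% c("1", "TRUE", "true")
  }
  if (any(out$publication_id == "" | is.na(out$publication_id))) {
    stop("publication_id must be non-empty for every row", call. = FALSE)
  }
  if (any(out$n_rate_kg_ha < 0)) stop("negative dose in input", call. = FALSE)
  if (any(out$replicate < 1L, na.rm = TRUE)) {
    stop("replicate indices must be >= 1", call. = FALSE)
  }
  out
}

#' @rdname read_emission_table
#' @param data Emission tibble to write.
#' @export
write_emission_table <- function(data, path) {
  out <- data
  for (col in c("inhibitor", "grazing")) {
    if (col %in% names(out)) out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

# exclusion criteria in their canonical order; each returns TRUE where a
# record is to be dropped. Missing metadata columns never exclude.
exclusion_criteria <- list(
  natural_area = function(d) d$land_use == "natural",
  no_only = function(d) d$gas_measured == "NO",
  organic_soil = function(d) d$soil_class == "organic",
  inhibitor = function(d) d$inhibitor,
  grazing = function(d) d$grazing,
  dose_gt_500 = function(d) d$n_rate_kg_ha > 500
)

#' Apply the standard exclusion filters
#'
#' Restricts an emission table to the records the emission-factor analysis
#' is defined for, applying six criteria in a fixed order: (i) natural
#' (unmanaged) areas, (ii) NO-only measurements, (iii) organic soils,
#' (iv) nitrification-inhibitor experiments, (v) grazed systems, and
#' (vi) doses exceeding 500 kg N ha^-1 yr^-1 (strictly above; a dose of
#' exactly 500 is retained). A record violating several criteria is counted
#' under the first in this order, so the audit counts are deterministic.
#' Metadata columns absent from the table exclude nothing.
#'
#' Filtering is idempotent and the audit counts do not depend on row order.
#'
#' @param data Emission tibble (see [read_emission_table()]).
#' @return The retained rows, with the audit attached as attribute
#'   `"audit"`; retrieve it with [filter_audit()].
#' @examples
#' d <- tibble::tibble(
#'   publication_id = c("a", "a", "b"), n_rate_kg_ha = c(0, 510, 100),
#'   n2o_kg_n_ha_yr = c(0.5, 3, 1.2), land_use = "agricultural",
#'   soil_class = "mineral", gas_measured = "N2O",
#'   inhibitor = FALSE, grazing = FALSE
#' )
#' filtered <- apply_exclusion_filters(d)
#' filter_audit(filtered)
#' @export
apply_exclusion_filters <- function(data) {
  n <- nrow(data)
  needed <- c(natural_area = "land_use", no_only = "gas_measured",
              organic_soil = "soil_class", inhibitor = "inhibitor",
              grazing = "grazing", dose_gt_500 = "n_rate_kg_ha")
  excluded_by <- rep(NA_character_, n)
  for (crit in names(exclusion_criteria)) {
    if (!needed[[crit]] %in% names(data)) next
    hit <- exclusion_criteria[[crit]](data)
    hit[is.na(hit)] <- FALSE
    excluded_by[is.na(excluded_by) & hit] <- crit
  }
  keep <- is.na(excluded_by)
  counts <- tibble::tibble(
    criterion = names(exclusion_criteria),
    n_excluded = vapply(unname(names(exclusion_criteria)),
                        function(cr) sum(excluded_by == cr, na.rm = TRUE),
                        integer(1), USE.NAMES = FALSE)
  )
  out <- data[keep, ]
  attr(out, "audit") <- structure(
    list(counts = counts,
         n_input = n,
         n_retained = sum(keep),
         n_publications_retained = length(unique(out$publication_id))),
    class = "filter_audit"
  )
  out
}

#' @rdname apply_exclusion_filters
#' @param filtered Result of `apply_exclusion_filters()`.
#' @export
filter_audit <- function(filtered) {
  a <- attr(filtered, "audit")
  if (is.null(a)) stop("no audit attached; was this filtered?", call. = FALSE)
  a
}

#' @export
print.filter_audit <- function(x, ...) {
  cat("<filter_audit> ", x$n_input, " records in, ", x$n_retained,
      " retained (", x$n_publications_retained, " publications)\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Summary statistics of emission and dose
#'
#' Min, median, mean, max and count for the N2O emission and the applied-N
#' dose, overall or by a grouping column (e.g. `continent`) — the layout of
#' the descriptive tables customary for these global compilations.
#'
#' @param data Emission tibble.
#' @param group_by Optional name of a column to group by.
#' @return A tibble with columns `variable`, `group`, `min`, `median`,
#'   `mean`, `max`, `n`.
#' @export
summarize_emissions <- function(data, group_by = NULL) {
  if (!is.null(group_by) && !group_by %in% names(data)) {
    stop("unknown grouping column '", group_by, "'", call. = FALSE)
  }
  vars <- c(n2o = "n2o_kg_n_ha_yr", dose = "n_rate_kg_ha")
  grp <- if (is.null(group_by)) rep("all", nrow(data)) else data[[group_by]]
  purrr::map_dfr(names(vars), function(v) {
    x <- data[[vars[[v]]]]
    tibble::tibble(value = x, group = grp) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        min = min(.data$value), median = stats::median(.data$value),
        mean = mean(.data$value), max = max(.data$value),
        n = dplyr::n(), .groups = "drop"
      ) |>
      dplyr::mutate(variable = v, .before = 1)
  })
}
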