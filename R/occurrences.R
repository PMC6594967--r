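#' Occurrence-record ingestion and cleaning
#'
#' File-based replacement for the usual OBIS/GBIF extraction workflow:
#' records are read from Darwin-Core-style CSV, flagged by rule-based vetting
#' (out-of-range coordinates, implausible depths, fossils), deduplicated,
#' reconciled against a synonym table, restricted to the study box, and
#' categorised into shallow/deep x benthic/pelagic groups. Every dropping
#' step reports its count so the record accounting always balances.
#'
#' @name occurrence_io
NULL

default_dialect <- function() {
  list(
    name = "scientificName",
    latitude = "decimalLatitude",
    longitude = "decimalLongitude",
    depth = c("depth", "minimumDepthInMeters"),
    event_date = "eventDate",
    dataset_id = "datasetID",
    basis = "basisOfRecord",
    record_id = "occurrenceID"
  )
}

pick_col <- function(df, candidates) {
  hit <- candidates[candidates %in% names(df)]
  if (length(hit)) hit[[1]] else NA_character_
}

add_flag <- function(flags, where, flag) {
  ifelse(where & !is.na(where),
    ifelse(flags == "", flag, paste(flags, flag, sep = ";")),
    flags
  )
}

has_flag <- function(flags, flag) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(f) flag %in% f, logical(1))
}

#' Convert a data frame of raw rows into occurrence records
#'
#' Maps columns via a `dialect` (a named list of candidate column names),
#' coerces types, and applies rule-based vetting flags: latitude outside
#' \[-90, 90\] or longitude outside \[-180, 180\] or unparseable -> `dubious`;
#' depth negative, above 11,000 m or unparseable -> `dubious`; a fossil
#' basis-of-record -> `fossil`. In strict mode any flaggable value raises an
#' error instead.
#'
#' @param df A data frame as read from CSV.
#' @param dialect Column-name mapping; see `default_dialect` in the source
#'   for the Darwin-Core defaults.
#' @param strict Raise on unparseable values instead of flagging.
#' @return A tibble of occurrence records: `record_id`, `raw_name`,
#'   `accepted_name` (NA until reconciled), `species` (working name),
#'   `latitude`, `longitude`, `depth`, `event_date`, `dataset_id`, `flags`.
#' @export
as_occurrences <- function(df, dialect = default_dialect(), strict = FALSE) {
  df <- tibble::as_tibble(df)
  d <- utils::modifyList(default_dialect(), dialect)
  for (req in c("name", "latitude", "longitude")) {
    if (is.na(pick_col(df, d[[req]]))) {
      stop_hexrich(
        sprintf(
          "required column '%s' (%s) not found",
          req, paste(d[[req]], collapse = "/")
        ),
        "format_error"
      )
    }
  }
  get_num <- function(key) {
    col <- pick_col(df, d[[key]])
    if (is.na(col)) {
      return(rep(NA_real_, nrow(df)))
    }
    suppressWarnings(as.numeric(df[[col]]))
  }
  get_chr <- function(key, default = NA_character_) {
    col <- pick_col(df, d[[key]])
    if (is.na(col)) rep(default, nrow(df)) else as.character(df[[col]])
  }

  lat <- get_num("latitude")
  lon <- get_num("longitude")
  depth_col <- pick_col(df, d$depth)
  depth_raw <- if (is.na(depth_col)) rep(NA_character_, nrow(df)) else as.character(df[[depth_col]])
  depth <- suppressWarnings(as.numeric(depth_raw))
  date_col <- pick_col(df, d$event_date)
  if (!is.na(date_col) && inherits(df[[date_col]], "Date")) {
    # fast path: already parsed
    date_raw <- rep(NA_character_, nrow(df))
    date_num <- as.numeric(df[[date_col]])
  } else {
    date_raw <- if (is.na(date_col)) rep(NA_character_, nrow(df)) else as.character(df[[date_col]])
    date_num <- suppressWarnings(
      vapply(date_raw, function(s) {
        if (is.na(s) || s == "") {
          return(NA_real_)
        }
        out <- tryCatch(as.numeric(as.Date(s)), error = function(e) NaN)
        if (is.na(out) && !is.nan(out)) NaN else out
      }, numeric(1), USE.NAMES = FALSE)
    )
  }
  bad_date <- is.nan(date_num)
  event_date <- as.Date(
    ifelse(is.nan(date_num), NA_real_, date_num),
    origin = "1970-01-01"
  )

  lat_raw <- get_chr("latitude")
  lon_raw <- get_chr("longitude")
  bad_coord <- (is.na(lat) & !is.na(lat_raw) & lat_raw != "") |
    (is.na(lon) & !is.na(lon_raw) & lon_raw != "") |
    (!is.na(lat) & (lat < -90 | lat > 90)) |
    (!is.na(lon) & (lon < -180 | lon > 180))
  bad_depth <- (is.na(depth) & !is.na(depth_raw) & depth_raw != "") |
    (!is.na(depth) & (depth < 0 | depth > 11000))
  basis <- get_chr("basis")
  fossil <- !is.na(basis) & grepl("fossil", basis, ignore.case = TRUE)

  if (strict && any(bad_coord | bad_depth | bad_date)) {
    k <- which(bad_coord | bad_depth | bad_date)[1]
    stop_hexrich(
      sprintf("unparseable or out-of-range value in row %d", k),
      "format_error"
    )
  }

  flags <- rep("", nrow(df))
  flags <- add_flag(flags, bad_coord | bad_depth | bad_date, "dubious")
  flags <- add_flag(flags, fossil, "fossil")

  rid <- get_chr("record_id")
  if (all(is.na(rid))) rid <- sprintf("r%06d", seq_len(nrow(df)))

  tibble::tibble(
    record_id = rid,
    raw_name = get_chr("name"),
    accepted_name = NA_character_,
    species = get_chr("name"),
    latitude = lat,
    longitude = lon,
    depth = ifelse(bad_depth, NA_real_, depth),
    event_date = event_date,
    dataset_id = get_chr("dataset_id", default = "unknown"),
    flags = flags
  )
}

#' Read occurrence records from CSV
#'
#' @param path CSV file path (UTF-8, header row). An empty file (header
#'   only) yields an empty record set, not an error.
#' @inheritParams as_occurrences
#' @return A tibble of occurrence records; see [as_occurrences()].
#' @export
read_occurrences <- function(path, dialect = default_dialect(),
                             strict = FALSE) {
  if (!file.exists(path)) {
    stop_hexrich(sprintf("file not found: %s", path), "format_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  as_occurrences(df, dialect = dialect, strict = strict)
}

#' Remove exact duplicate records
#'
#' A duplicate is exact key equality on (working species name, latitude,
#' longitude, depth, event date); the first record in input order is kept.
#' The number removed is attached as the `n_removed` attribute.
#'
#' @param records Occurrence tibble.
#' @return Deduplicated tibble (stable order).
#' @export
deduplicate <- function(records) {
  records <- tibble::as_tibble(records)
  key <- paste(
    dplyr::coalesce(records$accepted_name, records$raw_name),
    records$latitude, records$longitude, records$depth, records$event_date,
    sep = "\r"
  )
  keep <- !duplicated(key)
  out <- records[keep, ]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Reconcile names against a synonym table
#'
#' Fills `accepted_name` (and the working `species` column) from a
#' two-column synonym table. The mapping is made idempotent by ensuring
#' every accepted name maps to itself. Unmatched names are dropped or kept
#' under their raw name per `unmatched_policy`; the count is attached as the
#' `n_unmatched` attribute.
#'
#' @param records Occurrence tibble.
#' @param synonyms Data frame with `raw_name`, `accepted_name` columns.
#' @param unmatched_policy `"keep_raw"` (default) or `"drop"`.
#' @return Reconciled tibble.
#' @export
reconcile_names <- function(records, synonyms,
                            unmatched_policy = c("keep_raw", "drop")) {
  unmatched_policy <- match.arg(unmatched_policy)
  records <- tibble::as_tibble(records)
  synonyms <- tibble::as_tibble(synonyms)
  stopifnot(all(c("raw_name", "accepted_name") %in% names(synonyms)))
  # Idempotence: accepted names always map to themselves.
  closure <- dplyr::bind_rows(
    synonyms[, c("raw_name", "accepted_name")],
    tibble::tibble(
      raw_name = unique(synonyms$accepted_name),
      accepted_name = unique(synonyms$accepted_name)
    )
  ) |> dplyr::distinct(.data$raw_name, .keep_all = TRUE)

  idx <- match(
    dplyr::coalesce(records$accepted_name, records$raw_name),
    closure$raw_name
  )
  matched <- !is.na(idx)
  records$accepted_name[matched] <- closure$accepted_name[idx[matched]]
  n_unmatched <- sum(!matched)
  if (unmatched_policy == "drop") {
    records <- records[matched, ]
  }
  records$species <- dplyr::coalesce(records$accepted_name, records$raw_name)
  attr(records, "n_unmatched") <- n_unmatched
  records
}

#' Restrict records to the study area
#'
#' Keeps records inside the study bounding box (closed on all edges) and
#' discards records flagged `fossil` or `dubious`. Counts of each dropped
#' class are attached as attributes (`n_out_of_area`, `n_flagged`).
#'
#' @param records Occurrence tibble.
#' @param bbox `c(lat_min, lat_max, lon_min, lon_max)`; default the study
#'   box 0-90 N, 100-180 E.
#' @return Filtered tibble.
#' @export
filter_study_area <- function(records, bbox = c(0, 90, 100, 180)) {
  if (bbox[2] <= bbox[1] || bbox[4] <= bbox[3]) {
    stop_hexrich("invalid bounding box", "parameter_error")
  }
  records <- tibble::as_tibble(records)
  flagged <- has_flag(records$flags, "fossil") | has_flag(records$flags, "dubious")
  in_box <- !is.na(records$latitude) & !is.na(records$longitude) &
    records$latitude >= bbox[1] & records$latitude <= bbox[2] &
    records$longitude >= bbox[3] & records$longitude <= bbox[4]
  out_of_area <- !in_box & !flagged
  records$flags <- add_flag(records$flags, out_of_area, "out_of_area")
  out <- records[in_box & !flagged, ]
  attr(out, "n_out_of_area") <- sum(out_of_area)
  attr(out, "n_flagged") <- sum(flagged)
  out
}

#' Categorise records into depth x habitat groups
#'
#' Assigns each depth-bearing record to shallow (depth <= threshold) or deep
#' (depth > threshold) and crosses this with the species' habitat from the
#' trait table. Species with habitat `"both"` contribute one category-record
#' to the benthic and one to the pelagic group, so category totals can
#' exceed the record count. Records without depth, or whose species lacks a
#' trait entry, are excluded and counted (`n_no_depth`, `n_unclassified`).
#'
#' @param records Occurrence tibble.
#' @param traits Data frame with `accepted_name` and `habitat`
#'   (`"benthic"`, `"pelagic"` or `"both"`).
#' @param depth_threshold Shallow/deep boundary in metres (default 500).
#' @return A long tibble: one row per record x category with a `category`
#'   column such as `"shallow-benthic"`.
#' @export
classify_records <- function(records, traits, depth_threshold = 500) {
  records <- tibble::as_tibble(records)
  traits <- tibble::as_tibble(traits)
  stopifnot(all(c("accepted_name", "habitat") %in% names(traits)))
  n_no_depth <- sum(is.na(records$depth))
  rec <- dplyr::filter(records, !is.na(.data$depth))
  hab <- traits$habitat[match(rec$species, traits$accepted_name)]
  n_unclassified <- sum(is.na(hab))
  rec <- rec[!is.na(hab), ]
  hab <- hab[!is.na(hab)]
  rec$stratum <- ifelse(rec$depth <= depth_threshold, "shallow", "deep")
  rec$habitat <- hab
  out <- rec |>
    dplyr::mutate(
      habitat = purrr::map(
        .data$habitat,
        function(h) if (h == "both") c("benthic", "pelagic") else h
      )
    ) |>
    tidyr::unnest("habitat") |>
    dplyr::mutate(category = paste(.data$stratum, .data$habitat, sep = "-"))
  attr(out, "n_no_depth") <- n_no_depth
  attr(out, "n_unclassified") <- n_unclassified
  out
}

#' Run the full cleaning pipeline with record accounting
#'
#' read (or take) records, deduplicate, reconcile, and filter to the study
#' area, collecting the conservation accounting
#' `input = kept + duplicates + unmatched + out_of_area + flagged`.
#'
#' @param records Occurrence tibble (e.g. from [read_occurrences()]).
#' @param synonyms Optional synonym table for [reconcile_names()].
#' @param unmatched_policy Passed to [reconcile_names()].
#' @param bbox Passed to [filter_study_area()].
#' @return A list with `records` (the cleaned tibble) and `accounting`
#'   (a one-row tibble of counts).
#' @export
clean_occurrences <- function(records, synonyms = NULL,
                              unmatched_policy = "keep_raw",
                              bbox = c(0, 90, 100, 180)) {
  n_input <- nrow(records)
  rec <- deduplicate(records)
  n_dup <- attr(rec, "n_removed")
  n_unmatched_dropped <- 0L
  if (!is.null(synonyms)) {
    rec <- reconcile_names(rec, synonyms, unmatched_policy)
    if (unmatched_policy == "drop") {
      n_unmatched_dropped <- attr(rec, "n_unmatched")
    }
  }
  rec2 <- filter_study_area(rec, bbox)
  accounting <- tibble::tibble(
    n_input = n_input,
    n_kept = nrow(rec2),
    n_duplicates = n_dup,
    n_unmatched_dropped = n_unmatched_dropped,
    n_out_of_area = attr(rec2, "n_out_of_area"),
    n_flagged = attr(rec2, "n_flagged")
  )
  stopifnot(
    accounting$n_input == accounting$n_kept + accounting$n_duplicates +
      accounting$n_unmatched_dropped + accounting$n_out_of_area +
      accounting$n_flagged
  )
  list(records = rec2, accounting = accounting)
}
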