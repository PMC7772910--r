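#' Read a scenario from disk
#'
#' Supported formats: `json` (the native schema, one file), `csv` (a
#' directory holding `users.csv`, `aeds.csv`, `emergencies.csv` and an
#' optional `scenario.csv` with the coordinate system), and `geojson` (a
#' FeatureCollection of Points whose `properties` carry the entity kind and
#' attributes). Unavailable users and non-functional AEDs are retained and
#' flagged; they are filtered only when paths are enumerated.
#'
#' @param path file (json/geojson) or directory (csv).
#' @param format one of `"json"`, `"csv"`, `"geojson"`; guessed from the file
#'   extension when omitted.
#' @param strict if `TRUE` (default), stop when [validate_scenario()] reports
#'   any violation; the error names the offending records.
#' @return An [rns_scenario()].
#' @export
load_scenario <- function(path, format = NULL, strict = TRUE) {
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("json", "csv", "geojson"))
  if (!file.exists(path)) stop("no such file or directory: ", path, call. = FALSE)
  scn <- switch(format,
    json = scenario_from_json(path),
    csv = scenario_from_csv(path),
    geojson = scenario_from_geojson(path))
  if (strict) {
    d <- validate_scenario(scn)
    if (nrow(d)) {
      stop("invalid scenario (", nrow(d), " issue(s)): ",
           paste(utils::head(d$message, 5L), collapse = "; "), call. = FALSE)
    }
  }
  scn
}

#' Write a scenario to disk
#'
#' Round-trips are lossless for every field in every supported format
#' (numerics are serialized at full double precision). The CSV dialect writes
#' one UTF-8 file per entity type into `path` (created if needed); the
#' precomputed distance matrix, when present, goes to
#' `distance_user_aed.csv` / `distance_aed_emergency.csv`.
#'
#' @param scenario an [rns_scenario()].
#' @param path destination file (json/geojson) or directory (csv).
#' @param format one of `"json"`, `"csv"`, `"geojson"`.
#' @return `path`, invisibly.
#' @export
save_scenario <- function(scenario, path, format = NULL) {
  stopifnot(inherits(scenario, "rns_scenario"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("json", "csv", "geojson"))
  switch(format,
    json = scenario_to_json(scenario, path),
    csv = scenario_to_csv(scenario, path),
    geojson = scenario_to_geojson(scenario, path))
  invisible(path)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") "json" else if (ext == "geojson") "geojson" else "csv"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- JSON (native schema, version 1) ------------------------------------

scenario_to_json <- function(scenario, path) {
  dm <- scenario$distance_matrix
  obj <- list(
    schema = "rns_scenario", schema_version = 1L,
    coordinate_system = scenario$coordinate_system,
    users = scenario$users, aeds = scenario$aeds,
    emergencies = scenario$emergencies)
  if (!is.null(dm)) {
    obj$distance_matrix <- list(
      user_aed = matrix_to_list(dm$user_aed),
      aed_emergency = matrix_to_list(dm$aed_emergency))
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", na = "null")
}

scenario_from_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  dm <- NULL
  if (!is.null(obj$distance_matrix)) {
    dm <- list(user_aed = list_to_matrix(obj$distance_matrix$user_aed),
               aed_emergency = list_to_matrix(obj$distance_matrix$aed_emergency))
  }
  tryCatch(
    rns_scenario(obj$users, obj$aeds, obj$emergencies,
                 coordinate_system = obj$coordinate_system %||% "planar_m",
                 distance_matrix = dm),
    error = function(e) stop("failed to parse scenario JSON '", path, "': ",
                             conditionMessage(e), call. = FALSE))
}

matrix_to_list <- function(m) {
  list(rows = rownames(m), cols = colnames(m),
       values = unname(apply(m, 1L, function(r) unname(r), simplify = FALSE)))
}

list_to_matrix <- function(l) {
  vals <- l$values
  if (is.list(vals)) vals <- do.call(rbind, vals)
  vals <- matrix(as.numeric(vals), nrow = length(l$rows), byrow = FALSE,
                 dimnames = list(l$rows, l$cols))
  vals
}

## ---- CSV (one file per entity, header row, UTF-8) -----------------------

# full-precision numeric serialization so round-trips are exact
fmt_num_df <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]])) df[[col]] <- sprintf("%.17g", df[[col]])
  }
  df
}

scenario_to_csv <- function(scenario, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  wr <- function(df, file) {
    utils::write.csv(fmt_num_df(df), file.path(path, file),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(scenario$users, "users.csv")
  wr(scenario$aeds, "aeds.csv")
  wr(scenario$emergencies, "emergencies.csv")
  utils::write.csv(
    data.frame(key = "coordinate_system", value = scenario$coordinate_system),
    file.path(path, "scenario.csv"), row.names = FALSE, fileEncoding = "UTF-8")
  dm <- scenario$distance_matrix
  if (!is.null(dm)) {
    utils::write.csv(fmt_num_df(as.data.frame(dm$user_aed)),
                     file.path(path, "distance_user_aed.csv"),
                     row.names = TRUE, fileEncoding = "UTF-8")
    utils::write.csv(fmt_num_df(as.data.frame(dm$aed_emergency)),
                     file.path(path, "distance_aed_emergency.csv"),
                     row.names = TRUE, fileEncoding = "UTF-8")
  }
}

scenario_from_csv <- function(path) {
  if (!dir.exists(path)) stop("csv format expects a directory: ", path, call. = FALSE)
  rd <- function(file) {
    f <- file.path(path, file)
    if (!file.exists(f)) stop("missing entity file '", file, "' in ", path,
                              call. = FALSE)
    utils::read.csv(f, colClasses = c(id = "character"),
                    fileEncoding = "UTF-8", stringsAsFactors = FALSE)
  }
  meta_file <- file.path(path, "scenario.csv")
  cs <- "planar_m"
  if (file.exists(meta_file)) {
    meta <- utils::read.csv(meta_file, stringsAsFactors = FALSE)
    v <- meta$value[meta$key == "coordinate_system"]
    if (length(v)) cs <- v
  }
  dm <- NULL
  f1 <- file.path(path, "distance_user_aed.csv")
  f2 <- file.path(path, "distance_aed_emergency.csv")
  if (file.exists(f1) && file.exists(f2)) {
    rd_m <- function(f) {
      d <- utils::read.csv(f, row.names = 1L, check.names = FALSE,
                           fileEncoding = "UTF-8")
      as.matrix(d)
    }
    dm <- list(user_aed = rd_m(f1), aed_emergency = rd_m(f2))
  }
  rns_scenario(rd("users.csv"), rd("aeds.csv"), rd("emergencies.csv"),
               coordinate_system = cs, distance_matrix = dm)
}

## ---- GeoJSON (FeatureCollection of Points) ------------------------------

scenario_to_geojson <- function(scenario, path) {
  feat <- function(df, kind) {
    lapply(seq_len(nrow(df)), function(i) {
      props <- as.list(df[i, setdiff(names(df), c("x", "y")), drop = FALSE])
      props$kind <- kind
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(df$x[i], df$y[i])),
           properties = props)
    })
  }
  features <- c(feat(scenario$users, "user"),
                feat(scenario$aeds, "aed"),
                feat(scenario$emergencies, "emergency"))
  obj <- list(type = "FeatureCollection",
              coordinate_system = scenario$coordinate_system,
              features = features)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
}

scenario_from_geojson <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("GeoJSON scenario must be a FeatureCollection: ", path, call. = FALSE)
  }
  rows <- lapply(obj$features, function(f) {
    p <- f$properties
    xy <- as.numeric(f$geometry$coordinates)
    c(list(x = xy[1L], y = xy[2L]), p)
  })
  kinds <- vapply(rows, function(r) as.character(r$kind), character(1))
  pick <- function(kind) {
    sub <- rows[kinds == kind]
    if (!length(sub)) return(NULL)
    do.call(rbind, lapply(sub, function(r) {
      as.data.frame(r[setdiff(names(r), "kind")], stringsAsFactors = FALSE)
    }))
  }
  rns_scenario(pick("user"), pick("aed"), pick("emergency"),
               coordinate_system = obj$coordinate_system %||% "planar_m")
}

## ---- Match sets ---------------------------------------------------------

#' Write a solver result to disk
#'
#' One record per accepted match (`user_id`, `aed_id`, `emergency_id`,
#' `travel_time`), plus -- in JSON -- a summary block with the total match
#' time and per-emergency counts. Reloading with [load_matches()] reproduces
#' the match set exactly.
#'
#' @param match_set a `match_set` as returned by the solvers.
#' @param path destination file.
#' @param format `"json"` or `"csv"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
save_matches <- function(match_set, path, format = NULL) {
  stopifnot(inherits(match_set, "match_set"))
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    obj <- list(
      schema = "rns_matches", schema_version = 1L,
      method = match_set$method %||% NA_character_,
      matches = match_set$matches,
      summary = list(
        total_match_time = match_set$total_match_time,
        per_emergency_counts = as.list(match_set$per_emergency_counts)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    utils::write.csv(fmt_num_df(match_set$matches), path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

#' Read a saved solver result
#'
#' @param path file written by [save_matches()].
#' @param format `"json"` or `"csv"`; guessed from the extension when omitted.
#' @return A `match_set`.
#' @export
load_matches <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  format <- match.arg(format, c("json", "csv"))
  if (format == "json") {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    m <- obj$matches
    if (is.null(m) || !length(m)) m <- NULL
    emergency_ids <- names(obj$summary$per_emergency_counts)
    new_match_set(m, method = obj$method, emergency_ids = emergency_ids)
  } else {
    m <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(user_id = "character",
                                        aed_id = "character",
                                        emergency_id = "character"))
    if (!nrow(m)) m <- NULL
    new_match_set(m)
  }
}
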