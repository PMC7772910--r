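#' Construct a responder-network scenario
#'
#' A scenario bundles the three entity tables a responder network system (RNS)
#' reasons about when a cardiac arrest is reported: registered volunteer
#' responders ("users"), automated external defibrillators (AEDs), and the
#' emergencies reported at the same time. Positions are planar coordinates in
#' meters by default; set `coordinate_system = "geographic"` to interpret
#' `x`/`y` as longitude/latitude in degrees (distances then use the haversine
#' formula).
#'
#' Unavailable users and non-functional AEDs are retained in the scenario so
#' that it remains auditable; they are excluded later, at path-enumeration
#' time, not at load time.
#'
#' @param users data frame with columns `id`, `x`, `y`, `walking_speed`
#'   (m/s), `battery_level` (percent points, 0--100),
#'   `battery_consumption_rate` (percent points per second) and optionally
#'   `available` (logical, default `TRUE`).
#' @param aeds data frame with columns `id`, `x`, `y` and optionally
#'   `functional` (logical, default `TRUE`).
#' @param emergencies data frame with columns `id`, `x`, `y`.
#' @param coordinate_system `"planar_m"` (default) or `"geographic"`.
#' @param distance_matrix optional precomputed travel distances: a list with
#'   matrices `user_aed` (users x AEDs) and `aed_emergency` (AEDs x
#'   emergencies), both in meters with entity ids as dimnames. This is the
#'   hook for realistic route distances (a straight line of 100 m can be a
#'   600 m walk around a building).
#' @return An object of class `rns_scenario`.
#' @seealso [validate_scenario()], [load_scenario()], [enumerate_paths()]
#' @export
rns_scenario <- function(users, aeds, emergencies,
                         coordinate_system = c("planar_m", "geographic"),
                         distance_matrix = NULL) {
  coordinate_system <- match.arg(coordinate_system)
  users <- as_entity_df(users, c("id", "x", "y", "walking_speed",
                                 "battery_level", "battery_consumption_rate"),
                        optional = c(available = TRUE), entity = "user")
  aeds <- as_entity_df(aeds, c("id", "x", "y"),
                       optional = c(functional = TRUE), entity = "aed")
  emergencies <- as_entity_df(emergencies, c("id", "x", "y"),
                              optional = NULL, entity = "emergency")
  if (!is.null(distance_matrix)) {
    distance_matrix <- check_distance_matrix(distance_matrix)
  }
  structure(
    list(users = users, aeds = aeds, emergencies = emergencies,
         coordinate_system = coordinate_system,
         distance_matrix = distance_matrix),
    class = "rns_scenario"
  )
}

# coerce and type-check one entity table; fills optional logical columns
as_entity_df <- function(df, required, optional, entity) {
  if (is.null(df) || (is.data.frame(df) && nrow(df) == 0L) ||
      (is.list(df) && length(df) == 0L && !is.data.frame(df))) {
    df <- empty_entity_df(required, optional)
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s table is missing column(s): %s", entity,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$id <- as.character(df$id)
  for (col in setdiff(required, "id")) df[[col]] <- as.numeric(df[[col]])
  for (col in names(optional)) {
    if (is.null(df[[col]])) df[[col]] <- rep(optional[[col]], nrow(df))
    df[[col]] <- as.logical(df[[col]])
  }
  rownames(df) <- NULL
  df[, c(required, names(optional)), drop = FALSE]
}

empty_entity_df <- function(required, optional) {
  out <- c(
    list(id = character(0)),
    stats::setNames(rep(list(numeric(0)), length(required) - 1L),
                    setdiff(required, "id")),
    stats::setNames(rep(list(logical(0)), length(optional)), names(optional))
  )
  as.data.frame(out, stringsAsFactors = FALSE)
}

check_distance_matrix <- function(dm) {
  if (!is.list(dm) || !all(c("user_aed", "aed_emergency") %in% names(dm))) {
    stop("distance_matrix must be a list with matrices 'user_aed' and ",
         "'aed_emergency'", call. = FALSE)
  }
  dm$user_aed <- as.matrix(dm$user_aed)
  dm$aed_emergency <- as.matrix(dm$aed_emergency)
  dm[c("user_aed", "aed_emergency")]
}

#' Validate a scenario against its invariants
#'
#' Checks every type invariant (unique ids, positive walking speeds, battery
#' level within 0--100, positive battery consumption rates, finite
#' coordinates, distance-matrix coverage and non-negativity) and returns one
#' diagnostic row per violation rather than throwing: an invalid scenario can
#' still be inspected.
#'
#' @param scenario an [rns_scenario()].
#' @return A data frame with columns `entity`, `id`, `field`, `message`;
#'   zero rows if and only if the scenario satisfies all invariants.
#' @export
validate_scenario <- function(scenario) {
  stopifnot(inherits(scenario, "rns_scenario"))
  diags <- list()
  add <- function(entity, id, field, message) {
    diags[[length(diags) + 1L]] <<- data.frame(
      entity = entity, id = id, field = field, message = message,
      stringsAsFactors = FALSE)
  }
  check_ids <- function(df, entity) {
    dup <- unique(df$id[duplicated(df$id)])
    for (d in dup) add(entity, d, "id", sprintf("duplicated %s id '%s'", entity, d))
    bad <- df$id[is.na(df$id) | df$id == ""]
    for (d in bad) add(entity, d, "id", sprintf("empty or missing %s id", entity))
  }
  check_coords <- function(df, entity) {
    bad <- !is.finite(df$x) | !is.finite(df$y)
    for (d in df$id[bad]) add(entity, d, "position", "non-finite coordinate")
    if (scenario$coordinate_system == "geographic") {
      off <- is.finite(df$x) & is.finite(df$y) &
        (abs(df$x) > 180 | abs(df$y) > 90)
      for (d in df$id[off]) {
        add(entity, d, "position", "lon/lat outside valid geographic range")
      }
    }
  }
  u <- scenario$users
  check_ids(u, "user"); check_coords(u, "user")
  for (d in u$id[!is.finite(u$walking_speed) | u$walking_speed <= 0]) {
    add("user", d, "walking_speed", "walking_speed must be > 0")
  }
  for (d in u$id[!is.finite(u$battery_level) | u$battery_level < 0 |
                 u$battery_level > 100]) {
    add("user", d, "battery_level", "battery_level must be in [0, 100]")
  }
  for (d in u$id[!is.finite(u$battery_consumption_rate) |
                 u$battery_consumption_rate <= 0]) {
    add("user", d, "battery_consumption_rate",
        "battery_consumption_rate must be > 0")
  }
  check_ids(scenario$aeds, "aed"); check_coords(scenario$aeds, "aed")
  check_ids(scenario$emergencies, "emergency")
  check_coords(scenario$emergencies, "emergency")

  dm <- scenario$distance_matrix
  if (!is.null(dm)) {
    cover <- function(mat, rows, cols, name) {
      miss_r <- setdiff(rows, rownames(mat))
      miss_c <- setdiff(cols, colnames(mat))
      for (d in miss_r) add("scenario", d, name, sprintf("missing %s row", name))
      for (d in miss_c) add("scenario", d, name, sprintf("missing %s column", name))
      if (any(!is.finite(mat)) || any(mat < 0, na.rm = TRUE)) {
        add("scenario", NA_character_, name,
            sprintf("%s entries must be finite and >= 0", name))
      }
    }
    cover(dm$user_aed, u$id, scenario$aeds$id, "distance_matrix$user_aed")
    cover(dm$aed_emergency, scenario$aeds$id, scenario$emergencies$id,
          "distance_matrix$aed_emergency")
  }
  if (length(diags)) do.call(rbind, diags) else
    data.frame(entity = character(0), id = character(0),
               field = character(0), message = character(0),
               stringsAsFactors = FALSE)
}

#' @export
print.rns_scenario <- function(x, ...) {
  cat(sprintf(
    "<rns_scenario> %d users (%d available), %d AEDs (%d functional), %d emergencies\n",
    nrow(x$users), sum(x$users$available),
    nrow(x$aeds), sum(x$aeds$functional),
    nrow(x$emergencies)))
  cat(sprintf("  coordinates: %s; distance matrix: %s\n",
              x$coordinate_system,
              if (is.null(x$distance_matrix)) "none" else "precomputed"))
  invisible(x)
}

#' @export
summary.rns_scenario <- function(object, ...) {
  d <- validate_scenario(object)
  print(object)
  if (nrow(d)) {
    cat(sprintf("  %d validation issue(s); see validate_scenario()\n", nrow(d)))
  } else {
    cat("  all invariants satisfied\n")
  }
  invisible(d)
}
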