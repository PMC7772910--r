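#' Create a travel-distance provider
#'
#' Radius-based responder selection assumes straight-line distance equals
#' travel distance, which is false in built environments (a 100 m straight
#' line can be a 600 m walk). Distances therefore go through a pluggable
#' provider:
#' \describe{
#'   \item{`euclidean`}{straight-line planar distance (haversine when the
#'     scenario is geographic); the default.}
#'   \item{`manhattan_grid`}{L1 distance on a rectilinear street grid,
#'     optionally quantized to a block spacing (planar scenarios only).}
#'   \item{`matrix`}{looks distances up in the scenario's precomputed
#'     `distance_matrix` -- the hook for real route distances from a map
#'     service. Asymmetry is permitted only in this mode.}
#' }
#'
#' @param mode `"euclidean"`, `"manhattan_grid"` or `"matrix"`.
#' @param grid_spacing optional block size in meters for `manhattan_grid`;
#'   distances are rounded up to whole blocks when given.
#' @return An object of class `distance_provider`.
#' @export
distance_provider <- function(mode = c("euclidean", "manhattan_grid", "matrix"),
                              grid_spacing = NULL) {
  mode <- match.arg(mode)
  if (!is.null(grid_spacing)) stopifnot(grid_spacing > 0)
  structure(list(mode = mode, grid_spacing = grid_spacing),
            class = "distance_provider")
}

EARTH_RADIUS_M <- 6371008.8

haversine_m <- function(lon1, lat1, lon2, lat2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(1, sqrt(a)))
}

# straight-line distance between two point sets (n x 2 each), row-wise
straight_line_m <- function(x1, y1, x2, y2, coordinate_system) {
  if (coordinate_system == "geographic") {
    haversine_m(x1, y1, x2, y2)
  } else {
    sqrt((x1 - x2)^2 + (y1 - y2)^2)
  }
}

# pairwise distance matrix between entity tables `from` and `to`
pairwise_dist <- function(provider, from, to, coordinate_system,
                          matrix_block = NULL) {
  nf <- nrow(from); nt <- nrow(to)
  if (provider$mode == "matrix") {
    if (is.null(matrix_block)) {
      stop("distance provider mode 'matrix' requires a scenario distance_matrix",
           call. = FALSE)
    }
    miss_r <- setdiff(from$id, rownames(matrix_block))
    miss_c <- setdiff(to$id, colnames(matrix_block))
    if (length(miss_r) || length(miss_c)) {
      stop("distance_matrix is missing entries for: ",
           paste(c(miss_r, miss_c), collapse = ", "), call. = FALSE)
    }
    m <- matrix_block[from$id, to$id, drop = FALSE]
    storage.mode(m) <- "double"
    return(m)
  }
  if (nf == 0L || nt == 0L) {
    return(matrix(numeric(0), nf, nt, dimnames = list(from$id, to$id)))
  }
  fi <- rep(seq_len(nf), times = nt)
  ti <- rep(seq_len(nt), each = nf)
  d <- switch(provider$mode,
    euclidean = straight_line_m(from$x[fi], from$y[fi], to$x[ti], to$y[ti],
                                coordinate_system),
    manhattan_grid = {
      if (coordinate_system == "geographic") {
        stop("manhattan_grid provider requires planar coordinates", call. = FALSE)
      }
      d0 <- abs(from$x[fi] - to$x[ti]) + abs(from$y[fi] - to$y[ti])
      if (!is.null(provider$grid_spacing)) {
        ceiling(d0 / provider$grid_spacing) * provider$grid_spacing
      } else d0
    })
  matrix(d, nf, nt, dimnames = list(from$id, to$id))
}

#' Travel time for one responder-AED-emergency path
#'
#' The time for a user to reach an emergency while picking up an AED on the
#' way: `(d(user, AED) + d(AED, emergency)) / walking_speed`.
#'
#' @param user,aed,emergency single-row data frames (or named lists) with at
#'   least `id`, `x`, `y`; the user additionally needs `walking_speed`.
#' @param provider a [distance_provider()].
#' @param scenario required when `provider` is in `"matrix"` mode (the matrix
#'   lives on the scenario); also supplies the coordinate system when given.
#' @return Travel time in seconds.
#' @export
travel_time <- function(user, aed, emergency,
                        provider = distance_provider("euclidean"),
                        scenario = NULL) {
  user <- as.data.frame(user, stringsAsFactors = FALSE)
  aed <- as.data.frame(aed, stringsAsFactors = FALSE)
  emergency <- as.data.frame(emergency, stringsAsFactors = FALSE)
  stopifnot(nrow(user) == 1L, nrow(aed) == 1L, nrow(emergency) == 1L)
  if (!is.finite(user$walking_speed) || user$walking_speed <= 0) {
    stop("walking_speed must be > 0", call. = FALSE)
  }
  cs <- if (!is.null(scenario)) scenario$coordinate_system else "planar_m"
  dm <- if (!is.null(scenario)) scenario$distance_matrix else NULL
  d1 <- pairwise_dist(provider, user, aed, cs, dm$user_aed)[1L, 1L]
  d2 <- pairwise_dist(provider, aed, emergency, cs, dm$aed_emergency)[1L, 1L]
  (d1 + d2) / user$walking_speed
}

#' How long a responder's phone stays powered
#'
#' A match is useless if the responder's device dies before arrival: the
#' responder navigates with it. Powered-on time is the battery level divided
#' by the consumption rate.
#'
#' @param user single-row data frame (or named list) with `battery_level`
#'   and `battery_consumption_rate`.
#' @return Seconds of remaining powered-on time.
#' @export
powered_time <- function(user) {
  user <- as.data.frame(user, stringsAsFactors = FALSE)
  if (any(!is.finite(user$battery_consumption_rate) |
          user$battery_consumption_rate <= 0)) {
    stop("battery_consumption_rate must be > 0", call. = FALSE)
  }
  user$battery_level / user$battery_consumption_rate
}

#' Can the device stay powered for the whole trip?
#'
#' Inclusive at the boundary: a device that dies exactly on arrival still got
#' the responder there.
#'
#' @param user single-row data frame (or named list) with battery fields.
#' @param travel_time trip duration in seconds (vectorized).
#' @return Logical.
#' @export
battery_feasible <- function(user, travel_time) {
  stopifnot(all(travel_time >= 0))
  powered_time(user) >= travel_time
}

#' Enumerate all candidate responder paths
#'
#' Builds one candidate path per (available user, functional AED, emergency)
#' triple -- the full combinatorial search space (4 users x 3 AEDs x
#' 2 emergencies = 24 paths) -- annotated with travel distance, travel time
#' and battery feasibility. Unavailable users and non-functional AEDs are
#' excluded here, not at load time.
#'
#' @param scenario an [rns_scenario()].
#' @param provider a [distance_provider()].
#' @return An object of class `path_set`: a list with `paths` (data frame
#'   ordered lexicographically by user, AED, emergency id), the sentinel
#'   `max_edge_weight` (max travel time + 1, strictly above every real
#'   path), and the counts that define the search-space size.
#' @export
enumerate_paths <- function(scenario,
                            provider = distance_provider("euclidean")) {
  stopifnot(inherits(scenario, "rns_scenario"))
  users <- scenario$users[scenario$users$available, , drop = FALSE]
  aeds <- scenario$aeds[scenario$aeds$functional, , drop = FALSE]
  emergencies <- scenario$emergencies
  users <- users[order(users$id, method = "radix"), , drop = FALSE]
  aeds <- aeds[order(aeds$id, method = "radix"), , drop = FALSE]
  emergencies <- emergencies[order(emergencies$id, method = "radix"), ,
                             drop = FALSE]
  n <- nrow(users); m <- nrow(aeds); o <- nrow(emergencies)
  if (n == 0L || m == 0L || o == 0L) {
    paths <- data.frame(user_id = character(0), aed_id = character(0),
                        emergency_id = character(0),
                        travel_distance = numeric(0), travel_time = numeric(0),
                        battery_feasible = logical(0), stringsAsFactors = FALSE)
    return(new_path_set(paths, max_edge_weight = 1,
                        n_available = n, n_functional = m, n_emergencies = o,
                        emergency_ids = emergencies$id))
  }
  dm <- scenario$distance_matrix
  d_ua <- pairwise_dist(provider, users, aeds, scenario$coordinate_system,
                        dm$user_aed)
  d_ae <- pairwise_dist(provider, aeds, emergencies,
                        scenario$coordinate_system, dm$aed_emergency)
  # lexicographic row order: user-major, then AED, then emergency
  ui <- rep(seq_len(n), each = m * o)
  ai <- rep(rep(seq_len(m), each = o), times = n)
  ei <- rep(seq_len(o), times = n * m)
  dist <- d_ua[cbind(ui, ai)] + d_ae[cbind(ai, ei)]
  tt <- dist / users$walking_speed[ui]
  powered <- users$battery_level / users$battery_consumption_rate
  feas <- powered[ui] >= tt
  paths <- data.frame(
    user_id = users$id[ui], aed_id = aeds$id[ai],
    emergency_id = emergencies$id[ei],
    travel_distance = dist, travel_time = tt, battery_feasible = feas,
    stringsAsFactors = FALSE)
  new_path_set(paths, max_edge_weight = max(tt) + 1,
               n_available = n, n_functional = m, n_emergencies = o,
               emergency_ids = emergencies$id)
}

new_path_set <- function(paths, max_edge_weight, n_available, n_functional,
                         n_emergencies, emergency_ids, sliced = FALSE) {
  structure(
    list(paths = paths, max_edge_weight = max_edge_weight,
         n_available = n_available, n_functional = n_functional,
         n_emergencies = n_emergencies, emergency_ids = emergency_ids,
         sliced = sliced),
    class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf(
    "<path_set%s> %d path(s) (%d x %d x %d), %d battery-feasible, sentinel %.2f s\n",
    if (x$sliced) " [sliced]" else "",
    nrow(x$paths), x$n_available, x$n_functional, x$n_emergencies,
    sum(x$paths$battery_feasible), x$max_edge_weight))
  invisible(x)
}

#' Legacy radius-based responder selection
#'
#' The baseline behavior of deployed responder networks: notify every user
#' within a fixed straight-line radius (500 m by default) of the emergency.
#' Provided for comparison output only -- it embodies the radius fallacy: a
#' user 100 m away in a straight line whose actual walking route is 600 m is
#' still selected.
#'
#' @param users user table (as in [rns_scenario()]).
#' @param emergency single-row data frame or named list with `x`, `y`.
#' @param radius selection radius in meters (>= 0).
#' @param coordinate_system `"planar_m"` or `"geographic"`.
#' @return The subset of `users` within the radius (inclusive boundary).
#' @export
radius_select <- function(users, emergency, radius = 500,
                          coordinate_system = "planar_m") {
  stopifnot(radius >= 0)
  emergency <- as.data.frame(emergency, stringsAsFactors = FALSE)
  if (!nrow(users)) return(users)
  d <- straight_line_m(users$x, users$y, emergency$x[1L], emergency$y[1L],
                       coordinate_system)
  users[d <= radius, , drop = FALSE]
}
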