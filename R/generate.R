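#' Specification for a synthetic scenario
#'
#' No public registry of responder positions, AED locations and cardiac
#' arrest calls exists, so scenarios are simulated. The generator emulates
#' the experimental grid used to benchmark responder matching (2--1750
#' users, 1--250 AEDs, 1--5 simultaneous emergencies) in two density
#' profiles: `urban` (2 km x 2 km, responders and AEDs clustered around
#' emergency hotspots) and `rural` (10 km x 10 km, sparse uniform
#' placement). Walking speeds default to U(1.0, 1.6) m/s (brisk adult
#' walking), battery levels to U(20, 100) percent and consumption rates to
#' U(0.002, 0.02) percent/s, chosen so a realistic minority of candidate
#' paths fail the battery filter.
#'
#' @param n_users,n_aeds,n_emergencies non-negative entity counts.
#' @param density_profile `"urban"` or `"rural"`.
#' @param area_side square area side in meters; defaults to 2000 (urban) or
#'   10000 (rural).
#' @param walking_speed_range,battery_level_range,battery_rate_range
#'   two-element min/max vectors for the uniform draws.
#' @param p_available probability a user is flagged available (default 1).
#' @param distance_mode stored hint for downstream [distance_provider()]
#'   choice; positions themselves are planar meters.
#' @param seed integer; fully determines the generated scenario.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_users, n_aeds, n_emergencies,
                           density_profile = c("urban", "rural"),
                           area_side = NULL,
                           walking_speed_range = c(1.0, 1.6),
                           battery_level_range = c(20, 100),
                           battery_rate_range = c(0.002, 0.02),
                           p_available = 1,
                           distance_mode = "euclidean",
                           seed = 1L) {
  density_profile <- match.arg(density_profile)
  n_users <- as.integer(n_users); n_aeds <- as.integer(n_aeds)
  n_emergencies <- as.integer(n_emergencies)
  if (any(c(n_users, n_aeds, n_emergencies) < 0L)) {
    stop("entity counts must be non-negative", call. = FALSE)
  }
  area_side <- area_side %||%
    if (density_profile == "urban") 2000 else 10000
  stopifnot(area_side > 0, length(walking_speed_range) == 2L,
            all(walking_speed_range > 0),
            length(battery_level_range) == 2L,
            all(battery_level_range >= 0), all(battery_level_range <= 100),
            length(battery_rate_range) == 2L, all(battery_rate_range > 0),
            p_available >= 0, p_available <= 1)
  structure(
    list(n_users = n_users, n_aeds = n_aeds, n_emergencies = n_emergencies,
         density_profile = density_profile, area_side = area_side,
         walking_speed_range = sort(walking_speed_range),
         battery_level_range = sort(battery_level_range),
         battery_rate_range = sort(battery_rate_range),
         p_available = p_available,
         distance_mode = distance_mode, seed = as.integer(seed)),
    class = "generator_spec")
}

# run fn with a private, seeded RNG stream; global RNG state is untouched
with_seed <- function(seed, fn) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  fn()
}

#' Generate a synthetic scenario
#'
#' Deterministic under the spec's seed: the same `generator_spec` always
#' yields a byte-identical scenario, on every platform (Mersenne-Twister
#' stream, fixed draw order).
#'
#' @param spec a [generator_spec()], or the first of positional counts
#'   `n_users, n_aeds, n_emergencies` forwarded to [generator_spec()].
#' @param ... forwarded to [generator_spec()] when `spec` is a count.
#' @return An [rns_scenario()] that passes [validate_scenario()].
#' @export
generate_scenario <- function(spec, ...) {
  if (!inherits(spec, "generator_spec")) spec <- generator_spec(spec, ...)
  with_seed(spec$seed, function() {
    side <- spec$area_side
    ne <- spec$n_emergencies
    eme <- data.frame(
      id = sprintf("e%d", seq_len(ne)),
      x = stats::runif(ne, 0, side), y = stats::runif(ne, 0, side),
      stringsAsFactors = FALSE)
    place <- function(n) {
      if (n == 0L || ne == 0L || spec$density_profile == "rural") {
        return(cbind(stats::runif(n, 0, side), stats::runif(n, 0, side)))
      }
      # urban: 70% of entities cluster around emergency hotspots
      clustered <- stats::runif(n) < 0.7
      hot <- sample.int(ne, n, replace = TRUE)
      x <- ifelse(clustered,
                  stats::rnorm(n, eme$x[hot], side / 10),
                  stats::runif(n, 0, side))
      y <- ifelse(clustered,
                  stats::rnorm(n, eme$y[hot], side / 10),
                  stats::runif(n, 0, side))
      cbind(pmin(pmax(x, 0), side), pmin(pmax(y, 0), side))
    }
    uxy <- place(spec$n_users)
    axy <- place(spec$n_aeds)
    users <- data.frame(
      id = sprintf("u%04d", seq_len(spec$n_users)),
      x = uxy[, 1], y = uxy[, 2],
      walking_speed = stats::runif(spec$n_users, spec$walking_speed_range[1],
                                   spec$walking_speed_range[2]),
      battery_level = stats::runif(spec$n_users, spec$battery_level_range[1],
                                   spec$battery_level_range[2]),
      battery_consumption_rate = stats::runif(spec$n_users,
                                              spec$battery_rate_range[1],
                                              spec$battery_rate_range[2]),
      available = stats::runif(spec$n_users) <= spec$p_available,
      stringsAsFactors = FALSE)
    aeds <- data.frame(
      id = sprintf("a%04d", seq_len(spec$n_aeds)),
      x = axy[, 1], y = axy[, 2], functional = TRUE,
      stringsAsFactors = FALSE)
    rns_scenario(users, aeds, eme, coordinate_system = "planar_m")
  })
}

#' The greedy-matching showcase scenario
#'
#' A hand-constructed 4-user / 4-AED / 2-emergency instance exposing the
#' weakness of time-only matching: each user stands next to their own AED,
#' 60 s from emergency `e1`; routes to `e2` take 70 s (users 1-2) or 80 s
#' (users 3-4). All 32 candidate paths are battery-feasible. The time-only
#' optimum sends all four responders to `e1` (total 240 s) and leaves `e2`
#' unattended; the fair optimum splits 2/2 (total 260 s).
#'
#' @return An [rns_scenario()].
#' @export
special_case_scenario <- function() {
  # AEDs on a 60 m circle around e1 = (0,0); e2 = (100,0). Angles chosen by
  # the law of cosines so |a - e2| is exactly 70 m (users 1-2) or 80 m
  # (users 3-4); users are collocated with their own AED.
  d_e1e2 <- 100; r <- 60
  ang <- function(d2) acos((r^2 + d_e1e2^2 - d2^2) / (2 * r * d_e1e2))
  th <- c(ang(70), -ang(70), ang(80), -ang(80))
  ax <- r * cos(th); ay <- r * sin(th)
  users <- data.frame(
    id = paste0("u", 1:4), x = ax, y = ay,
    walking_speed = 1.0, battery_level = 100,
    battery_consumption_rate = 0.01, available = TRUE,
    stringsAsFactors = FALSE)
  aeds <- data.frame(id = paste0("a", 1:4), x = ax, y = ay,
                     functional = TRUE, stringsAsFactors = FALSE)
  emergencies <- data.frame(id = c("e1", "e2"), x = c(0, d_e1e2), y = c(0, 0),
                            stringsAsFactors = FALSE)
  rns_scenario(users, aeds, emergencies)
}

#' The benchmark size grid
#'
#' The 35 generated rows of the benchmark layout: users 50..1750, AEDs
#' 2..250, emergencies 1..5 (the 36th benchmark entry is the hand-built
#' [special_case_scenario()]).
#'
#' @return Data frame with columns `n_users`, `n_aeds`, `n_emergencies`.
#' @export
default_suite_rows <- function() {
  data.frame(
    n_users = c(seq(50, 450, by = 50), 500, 550, seq(600, 1750, by = 50)),
    n_aeds = c(2:10, 10, 10, seq(20, 250, by = 10)),
    n_emergencies = rep(1:5, c(15, 5, 5, 5, 5)))
}

#' Generate the benchmark suite of scenarios
#'
#' One scenario per (users, AEDs, emergencies) row; the default grid
#' reproduces the 36-test-case benchmark layout (50/2/1 up to 1750/250/5,
#' plus the greedy-matching special case as the final entry). Row seeds are
#' derived from `base_seed` and the row index only, so appending rows never
#' perturbs earlier scenarios.
#'
#' @param rows data frame with columns `n_users`, `n_aeds`, `n_emergencies`;
#'   `NULL` for the default grid (in which case the special case is
#'   appended).
#' @param base_seed integer.
#' @param ... forwarded to [generator_spec()] (e.g. `density_profile`,
#'   battery ranges).
#' @return A list of [rns_scenario()] objects.
#' @export
generate_suite <- function(rows = NULL, base_seed = 1L, ...) {
  default_grid <- is.null(rows)
  if (default_grid) rows <- default_suite_rows()
  rows <- as.data.frame(rows)
  stopifnot(all(c("n_users", "n_aeds", "n_emergencies") %in% names(rows)))
  out <- lapply(seq_len(nrow(rows)), function(i) {
    generate_scenario(generator_spec(
      rows$n_users[i], rows$n_aeds[i], rows$n_emergencies[i],
      seed = suite_row_seed(base_seed, i), ...))
  })
  if (default_grid) out <- c(out, list(special_case_scenario()))
  out
}

# splittable per-row seed: depends only on base_seed and the row index,
# stays below 2^31 (R integers are 32-bit)
suite_row_seed <- function(base_seed, i) {
  as.integer((((base_seed %% 1048573) * 2039) + i * 101) %% 2147483647)
}
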