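#' Travel scenario for the tour-length approximation
#'
#' @param area service area in km^2.
#' @param clients number of client visits in the day part (repeat visits to
#'   the same client count separately).
#' @param workers number of care workers, i.e. routes.
#' @param depot_distance average distance from clients to the central
#'   location in km (0 when teams do not operate from a depot).
#' @param k_l tour-length constant; empirical values lie between 0.44 and
#'   0.59, default 0.5. A warning is issued outside `[0.4, 0.6]`.
#' @param k_c depot constant, close to 2.
#' @return an object of class `travel_scenario`.
#' @export
travel_scenario <- function(area, clients, workers = 1,
                            depot_distance = 0, k_l = 0.5, k_c = 2) {
  if (area <= 0) stop("area must be positive")
  if (clients < 0 || clients != round(clients)) {
    stop("clients must be a non-negative integer")
  }
  if (workers < 1) stop("workers must be at least 1")
  if (depot_distance < 0) stop("depot_distance must be non-negative")
  if (k_l < 0.4 || k_l > 0.6) {
    warning("k_l outside the empirically supported range [0.4, 0.6]")
  }
  structure(list(area = area, clients = clients, workers = workers,
                 depot_distance = depot_distance, k_l = k_l, k_c = k_c),
            class = "travel_scenario")
}

#' @export
print.travel_scenario <- function(x, ...) {
  cat(sprintf(
    "Travel scenario: %.3g km^2, %d visits, %g routes -> %.3g km per day part\n",
    x$area, x$clients, x$workers, route_length(x)))
  invisible(x)
}

#' Square-root tour-length approximation
#'
#' Total route length for serving `n` clients in an area `A` with `M`
#' routes from a central location at mean distance `r`:
#' `k_l * sqrt(A * n) + k_c * r * M` km. The first term is the classical
#' square-root law for the optimal travelling-salesman tour; the second is
#' the stem travel to and from the depot. Travel per client therefore
#' decreases as client density grows, but pooling regions brings no travel
#' gain (see [merged_route_length()]).
#'
#' @param s a [travel_scenario].
#' @return estimated route length in km per day part.
#' @export
route_length <- function(s) {
  s$k_l * sqrt(s$area * s$clients) + s$k_c * s$depot_distance * s$workers
}

#' Route length after merging R identical regions
#'
#' Merging `R` identical neighbouring regions multiplies clients, area and
#' workers by `R`; with an unchanged depot distance the total length is
#' exactly `R` times the single-region length — no economies of scale in
#' travel.
#'
#' @inheritParams route_length
#' @param R number of identical regions merged (integer >= 1).
#' @export
merged_route_length <- function(s, R) {
  if (R < 1 || R != round(R)) stop("R must be an integer >= 1")
  s$k_l * sqrt((s$area * R) * (s$clients * R)) +
    s$k_c * s$depot_distance * s$workers * R
}

#' Route length under fixed client-to-worker assignment
#'
#' When the `n` clients are pre-assigned at random to the `M` workers (for
#' continuity of care), each worker tours clients spread over the whole
#' area, giving total length `M * (k_l * sqrt(A * n / M) + k_c * r)` =
#' `sqrt(M)` times the pooled tour term plus per-worker stem travel.
#'
#' @inheritParams route_length
#' @export
individual_routes_length <- function(s) {
  s$workers * (s$k_l * sqrt(s$area * s$clients / s$workers) +
                 s$k_c * s$depot_distance)
}
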