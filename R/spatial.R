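#' Exact spherical grid-cell areas
#'
#' Area of a regular latitude-longitude cell by the spherical band
#' formula `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with
#' `R = 6371 km`. The formula telescopes: summed over a global grid it
#' recovers the sphere area `4 pi R^2` exactly.
#'
#' @param lat cell-center latitudes (degrees).
#' @param dlat,dlon grid steps (degrees).
#' @return numeric vector of areas (km^2), one per latitude band.
#' @export
cell_areas <- function(lat, dlat, dlon) {
  R <- 6371
  rad <- pi / 180
  R^2 * (dlon * rad) *
    (sin((lat + dlat / 2) * rad) - sin((lat - dlat / 2) * rad))
}

# per-cell areas (km^2) aligned with cube_cells() ordering
.cell_area_vec <- function(lat, lon, cells = NULL) {
  dlat <- if (length(lat) > 1) diff(lat)[1] else
    stop("cannot infer dlat from a single latitude")
  dlon <- if (length(lon) > 1) diff(lon)[1] else 360
  a <- cell_areas(lat, dlat, dlon)
  rep(a, length(lon))
}

# adjacency offsets for 4- or 8-connectivity
.conn_offsets <- function(connectivity) {
  if (connectivity == 4) {
    list(c(1L, 0L), c(0L, 1L))
  } else if (connectivity == 8) {
    list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  } else stop("connectivity must be 4 or 8")
}

#' Label contiguous regions of a daily binary mask
#'
#' Connected-component labeling on the latitude-longitude grid, with
#' diagonal adjacency by default ("connected in any direction") and a
#' seam-free wrap across the longitude boundary; there is no wrap across
#' the poles. Components are numbered deterministically in order of their
#' smallest member cell index.
#'
#' @param mask logical matrix `[nlat, nlon]`.
#' @param connectivity 8 (diagonals connect) or 4.
#' @param wrap_longitude connect the first and last longitude columns.
#' @return integer matrix `[nlat, nlon]`: 0 outside the mask, component
#'   label inside.
#' @export
label_contiguous <- function(mask, connectivity = 8,
                             wrap_longitude = TRUE) {
  nlat <- nrow(mask)
  nlon <- ncol(mask)
  mask[is.na(mask)] <- FALSE
  on <- which(mask)
  lab <- matrix(0L, nlat, nlon)
  if (length(on) == 0) return(lab)
  id <- matrix(0L, nlat, nlon)
  id[on] <- seq_along(on)
  edges <- NULL
  for (off in .conn_offsets(connectivity)) {
    di <- off[1]; dj <- off[2]
    i <- ((on - 1L) %% nlat) + 1L
    j <- ((on - 1L) %/% nlat) + 1L
    i2 <- i + di
    j2 <- j + dj
    if (wrap_longitude) j2 <- ((j2 - 1L) %% nlon) + 1L
    ok <- i2 >= 1L & i2 <= nlat & j2 >= 1L & j2 <= nlon
    if (!any(ok)) next
    tgt <- (j2[ok] - 1L) * nlat + i2[ok]
    hit <- mask[tgt]
    if (!any(hit)) next
    edges <- rbind(edges,
                   cbind(id[on[ok][hit]], id[tgt[hit]]))
  }
  g <- igraph::make_empty_graph(n = length(on), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # deterministic labels: order components by smallest member cell index
  first <- tapply(on, memb, min)
  relab <- rank(first)[memb]
  lab[on] <- as.integer(relab)
  lab
}

#' Per-component extent metrics for one day
#'
#' @param lab label matrix from [label_contiguous()].
#' @param area_vec per-cell areas (km^2), cube cell order.
#' @param ssta optional SSTA matrix `[nlat, nlon]` for the area-integrated
#'   anomaly.
#' @return data.frame per component: `label`, `n_cells`, `area_Mkm2`,
#'   `int_ssta` (degC Mkm^2, NA if `ssta` missing).
#' @export
component_table <- function(lab, area_vec, ssta = NULL) {
  on <- which(lab > 0)
  if (length(on) == 0)
    return(data.frame(label = integer(), n_cells = integer(),
                      area_Mkm2 = numeric(), int_ssta = numeric()))
  l <- lab[on]
  a <- area_vec[on] / 1e6
  out <- data.frame(label = sort(unique(l)))
  out$n_cells <- as.integer(tapply(rep(1L, length(l)), l, sum))
  out$area_Mkm2 <- as.numeric(tapply(a, l, sum))
  out$int_ssta <- if (is.null(ssta)) NA_real_ else
    as.numeric(tapply(ssta[on] * a, l, sum))
  out
}

#' Daily series of the largest contiguous heatwave
#'
#' For every day, cells above the severity threshold (and inside a
#' detected event, when the severity field carries the event mask) are
#' labeled into contiguous components; the component of largest area is
#' reported with its area-integrated SSTA. Components intersecting a
#' stated equatorial-Pacific box can be excluded, to show the extent
#' record with the directly ENSO-forced signal removed.
#'
#' @param sev a `severity_field` from [severity()].
#' @param min_severity severity threshold defining the mask (1 = at least
#'   moderate, 2 = at least strong).
#' @param exclude_box optional `c(lat_min, lat_max, lon_min, lon_max)`;
#'   components with any cell inside are dropped (the published variant
#'   uses the equatorial central/eastern Pacific, east of 170 E within 5
#'   degrees of the equator: `c(-5, 5, 170, 290)`).
#' @param connectivity,wrap_longitude see [label_contiguous()].
#' @return data.frame per day: `t`, `area_Mkm2`, `int_ssta`, `n_cells`,
#'   `tie` (TRUE when two components share the maximal area; the
#'   earliest-labeled one is reported). Days with no cells in heatwave
#'   state give zero-area rows.
#' @export
largest_event_series <- function(sev, min_severity = 1,
                                 exclude_box = NULL, connectivity = 8,
                                 wrap_longitude = TRUE) {
  stopifnot(inherits(sev, "severity_field"))
  nlat <- length(sev$lat)
  nlon <- length(sev$lon)
  area_vec <- .cell_area_vec(sev$lat, sev$lon)
  nt <- dim(sev$S)[1]
  in_box <- if (is.null(exclude_box)) NULL else {
    cells <- cube_cells(sev)
    cells$lat >= exclude_box[1] & cells$lat <= exclude_box[2] &
      cells$lon >= exclude_box[3] & cells$lon <= exclude_box[4]
  }
  out <- data.frame(t = seq_len(nt), area_Mkm2 = 0, int_ssta = 0,
                    n_cells = 0L, tie = FALSE)
  for (tt in seq_len(nt)) {
    m <- matrix(sev$S[tt, , ] > min_severity, nlat, nlon)
    m[is.na(m)] <- FALSE
    if (!is.null(sev$in_event)) m <- m & matrix(sev$in_event[tt, , ],
                                                nlat, nlon)
    if (!any(m)) next
    lab <- label_contiguous(m, connectivity, wrap_longitude)
    tab <- component_table(lab, area_vec, matrix(sev$ssta[tt, , ],
                                                 nlat, nlon))
    if (!is.null(in_box)) {
      bad <- unique(lab[in_box & lab > 0])
      tab <- tab[!(tab$label %in% bad), ]
      if (nrow(tab) == 0) next
    }
    top <- which(tab$area_Mkm2 == max(tab$area_Mkm2))
    k <- top[1]  # earliest label on ties
    out$area_Mkm2[tt] <- tab$area_Mkm2[k]
    out$int_ssta[tt] <- tab$int_ssta[k]
    out$n_cells[tt] <- tab$n_cells[k]
    out$tie[tt] <- length(top) > 1
  }
  out
}
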