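# Capillary morphometry on digitised muscle cross-sections: capillary-to-
# fiber ratio (C:F), capillary density (CD, per mm^2), mean fiber
# cross-sectional area (FCSA, um^2), and the Voronoi "capillary domain"
# tessellation -- the area of tissue closer to one capillary than to any
# other -- whose log-transformed area spread (logSD) indexes the
# heterogeneity of capillary supply.  Domains are computed exactly by
# clipping the section region with the perpendicular-bisector half-planes
# of every capillary pair, so the domain areas sum to the region area by
# construction.

shoelace_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

point_in_polygon <- function(px, py, ring, eps = 1e-9) {
  # ray casting with inclusive boundary
  x <- ring[, 1]; y <- ring[, 2]
  n <- length(x)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    # on-segment check
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((px - x[i]) * dx + (py - y[i]) * dy) / len2
      t <- min(max(t, 0), 1)
      qx <- x[i] + t * dx; qy <- y[i] + t * dy
      if ((px - qx)^2 + (py - qy)^2 < eps^2) return(TRUE)
    }
    if ((y[i] > py) != (y[j] > py)) {
      xint <- x[i] + (py - y[i]) / (y[j] - y[i]) * (x[j] - x[i])
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

# Clip polygon (n x 2 matrix, open ring) with the half-plane a.x <= b
# (Sutherland-Hodgman).
clip_halfplane <- function(poly, a, b) {
  if (is.null(poly) || nrow(poly) == 0) return(poly)
  n <- nrow(poly)
  out_x <- numeric(0); out_y <- numeric(0)
  sv <- poly[n, ]
  s_in <- sum(a * sv) <= b
  for (i in seq_len(n)) {
    ev <- poly[i, ]
    e_in <- sum(a * ev) <= b
    if (e_in) {
      if (!s_in) {
        t <- (b - sum(a * sv)) / sum(a * (ev - sv))
        out_x <- c(out_x, sv[1] + t * (ev[1] - sv[1]))
        out_y <- c(out_y, sv[2] + t * (ev[2] - sv[2]))
      }
      out_x <- c(out_x, ev[1]); out_y <- c(out_y, ev[2])
    } else if (s_in) {
      t <- (b - sum(a * sv)) / sum(a * (ev - sv))
      out_x <- c(out_x, sv[1] + t * (ev[1] - sv[1]))
      out_y <- c(out_y, sv[2] + t * (ev[2] - sv[2]))
    }
    sv <- ev; s_in <- e_in
  }
  if (!length(out_x)) return(NULL)
  cbind(out_x, out_y)
}

#' Capillary section
#'
#' Bundles the digitised coordinates of one muscle cross-section:
#' capillary locations, fiber boundary polygons, and the boundary of the
#' analysed region.  All coordinates in micrometres.
#'
#' @param capillary_points two-column matrix or data frame of (x, y)
#'   capillary coordinates; all points must lie inside (or on) the region
#'   boundary and be distinct.
#' @param fiber_polygons list of two-column matrices, one closed vertex
#'   ring per fiber (last vertex need not repeat the first).
#' @param region_boundary two-column matrix: the region's vertex ring.
#' @return object of class `"CapillarySection"`.
#' @export
capillary_section <- function(capillary_points, fiber_polygons = list(),
                              region_boundary) {
  pts <- as.matrix(capillary_points)
  storage.mode(pts) <- "double"
  region <- as.matrix(region_boundary)
  storage.mode(region) <- "double"
  if (ncol(pts) != 2) stop("capillary points must have two columns")
  if (nrow(region) < 3) stop("region boundary needs at least 3 vertices")
  if (shoelace_area(region) <= 0) stop("region boundary has zero area")
  dup <- duplicated(pts)
  if (any(dup)) {
    lab <- apply(pts[dup, , drop = FALSE], 1, paste, collapse = ",")
    stop("duplicate capillary points: (",
         paste(lab, collapse = "), ("), ")")
  }
  outside <- !vapply(seq_len(nrow(pts)), function(i)
    point_in_polygon(pts[i, 1], pts[i, 2], region), logical(1))
  if (any(outside))
    stop("capillary points outside the region boundary: rows ",
         paste(which(outside), collapse = ", "))
  fiber_polygons <- lapply(fiber_polygons, function(p) {
    p <- as.matrix(p); storage.mode(p) <- "double"
    if (ncol(p) != 2 || nrow(p) < 3)
      stop("each fiber polygon needs >= 3 (x, y) vertices")
    p
  })
  structure(list(capillary_points = pts,
                 fiber_polygons = fiber_polygons,
                 region_boundary = region),
            class = "CapillarySection")
}

#' @export
print.CapillarySection <- function(x, ...) {
  cat("CapillarySection:", nrow(x$capillary_points), "capillaries,",
      length(x$fiber_polygons), "fibers, region area",
      format(shoelace_area(x$region_boundary), digits = 6), "um^2\n")
  invisible(x)
}

#' Capillary-to-fiber ratio
#' @param n_capillaries,n_fibers counts.
#' @return `n_capillaries / n_fibers`.
#' @export
cf_ratio <- function(n_capillaries, n_fibers) {
  if (n_fibers <= 0) stop("fiber count must be positive")
  n_capillaries / n_fibers
}

#' Capillary density (per mm^2)
#' @param section a `"CapillarySection"` with coordinates in micrometres.
#' @return capillaries per mm^2 of region area.
#' @export
capillary_density <- function(section) {
  area_um2 <- shoelace_area(section$region_boundary)
  nrow(section$capillary_points) / (area_um2 / 1e6)
}

#' Mean fiber cross-sectional area (um^2)
#'
#' Shoelace area of each fiber polygon; degenerate (zero-area) polygons
#' are excluded with a warning.
#'
#' @param section a `"CapillarySection"`.
#' @return mean fiber area in um^2.
#' @export
fiber_csa <- function(section) {
  areas <- vapply(section$fiber_polygons, shoelace_area, numeric(1))
  if (any(areas == 0)) {
    warning(sum(areas == 0), " degenerate fiber polygon(s) excluded")
    areas <- areas[areas > 0]
  }
  if (!length(areas)) stop("no non-degenerate fiber polygons")
  mean(areas)
}

#' Voronoi capillary domains and morphometry summary
#'
#' The domain of capillary i is the set of points of the region closer to
#' i than to any other capillary: the region polygon clipped by the
#' perpendicular-bisector half-planes against every other capillary.
#' Domains are pairwise interior-disjoint and their areas sum to the
#' region area.
#'
#' @param section a `"CapillarySection"`.
#' @return object of class `"DomainSummary"`: `domains` (list of vertex
#'   rings), `areas` (um^2), `cf_ratio` (NA without fibers),
#'   `capillary_density`, `mean_fcsa` (NA without fibers), `logsd`
#'   (natural-log scale, see [domain_logsd()]), `log_base`,
#'   `region_area`.
#' @export
voronoi_domains <- function(section) {
  stopifnot(inherits(section, "CapillarySection"))
  pts <- section$capillary_points
  n <- nrow(pts)
  if (n < 1) stop("at least one capillary is required")
  region <- section$region_boundary
  domains <- vector("list", n)
  for (i in seq_len(n)) {
    cell <- region
    for (j in seq_len(n)) {
      if (j == i || is.null(cell)) next
      a <- 2 * (pts[j, ] - pts[i, ])
      b <- sum(pts[j, ]^2) - sum(pts[i, ]^2)
      cell <- clip_halfplane(cell, a, b)
    }
    domains[[i]] <- cell
  }
  areas <- vapply(domains, function(d)
    if (is.null(d) || nrow(d) < 3) 0 else shoelace_area(d), numeric(1))
  region_area <- shoelace_area(region)
  n_fib <- length(section$fiber_polygons)
  structure(list(domains = domains, areas = areas,
                 cf_ratio = if (n_fib) cf_ratio(n, n_fib) else NA_real_,
                 capillary_density = capillary_density(section),
                 mean_fcsa = if (n_fib) fiber_csa(section) else NA_real_,
                 logsd = if (n >= 2) domain_logsd(areas) else NA_real_,
                 log_base = "natural",
                 region_area = region_area),
            class = "DomainSummary")
}

#' @export
print.DomainSummary <- function(x, ...) {
  cat("Capillary domain summary\n")
  cat("  domains:", length(x$areas),
      "  region area:", format(x$region_area, digits = 6), "um^2\n")
  cat("  C:F:", format(x$cf_ratio, digits = 4),
      "  CD:", format(x$capillary_density, digits = 6), "per mm^2",
      "  FCSA:", format(x$mean_fcsa, digits = 6), "um^2\n")
  cat("  logSD (natural log):", format(x$logsd, digits = 5), "\n")
  invisible(x)
}

#' Heterogeneity of capillary supply: logSD
#'
#' Sample standard deviation (n - 1 denominator) of the natural-log
#' domain areas.  Scale-invariant: multiplying all areas by a constant
#' leaves it unchanged.
#'
#' @param areas positive domain areas, at least two.
#' @return nonnegative logSD.
#' @export
domain_logsd <- function(areas) {
  if (length(areas) < 2) stop("at least two domain areas are required")
  if (any(areas <= 0)) stop("domain areas must be positive")
  stats::sd(log(areas))
}

#' Read capillary points from tab-delimited (x, y) text
#' @param path file with header columns `x`, `y`.
#' @return two-column numeric matrix.
#' @export
read_capillary_points <- function(path) {
  df <- utils::read.delim(path)
  as.matrix(df[c("x", "y")])
}

#' Read polygons from tab-delimited text
#'
#' Columns `polygon_id`, `vertex_index`, `x`, `y`; vertices sorted by
#' index within each polygon.
#'
#' @param path file path.
#' @return named list of two-column vertex matrices.
#' @export
read_polygons <- function(path) {
  df <- utils::read.delim(path)
  need <- c("polygon_id", "vertex_index", "x", "y")
  if (!all(need %in% names(df)))
    stop("polygon file needs columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$polygon_id), function(p) {
    p <- p[order(p$vertex_index), ]
    as.matrix(p[c("x", "y")])
  })
  out
}

#' Write a domain summary as tab-delimited text
#'
#' Writes `<prefix>.summary.tsv` (one row of the scalar morphometry
#' indices, with the log base recorded) and `<prefix>.domain_areas.tsv`
#' (per-capillary areas).
#'
#' @param x a `"DomainSummary"`.
#' @param prefix output path prefix.
#' @export
write_domain_summary <- function(x, prefix) {
  utils::write.table(
    data.frame(cf_ratio = x$cf_ratio,
               capillary_density_per_mm2 = x$capillary_density,
               mean_fcsa_um2 = x$mean_fcsa,
               logsd = x$logsd, log_base = x$log_base,
               region_area_um2 = x$region_area),
    paste0(prefix, ".summary.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(capillary = seq_along(x$areas), area_um2 = x$areas),
    paste0(prefix, ".domain_areas.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write domain polygons as GeoJSON-style text
#' @param x a `"DomainSummary"`.
#' @param path output path.
#' @export
write_domains_geojson <- function(x, path) {
  features <- lapply(seq_along(x$domains), function(i) {
    d <- x$domains[[i]]
    ring <- rbind(d, d[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(capillary = i, area_um2 = x$areas[[i]]),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(
                           seq_len(nrow(ring)),
                           function(k) as.numeric(ring[k, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection",
                            features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
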