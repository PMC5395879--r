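#' Idealized trachea configuration
#'
#' Parameterizes the idealized pediatric trachea: a semicircular anterior
#' wall of alternating cartilage rings (2 mm) and fibrous gaps (1 mm), a
#' flat posterior trachealis muscle closing the chord, and a 0.2 mm mucosa
#' layer lining the whole lumen. The quoted diameter is the inner lumen
#' diameter; wall layers stack outward (mucosa, then 0.8 mm cartilage or
#' fibrous wall). The default 50 mm length tiles exactly as 17 rings + 16
#' gaps.
#'
#' @param diameter Lumen diameter, mm (6, 8 or 10 in the study conditions).
#' @param length Axial length, mm.
#' @param ring_width,gap_width Cartilage ring / fibrous gap width, mm.
#' @param wall_thickness Cartilage/fibrous (and muscle) thickness, mm.
#' @param mucosa_thickness Mucosa lining thickness, mm.
#' @param muscle_thickness Trachealis muscle thickness, mm.
#' @param n_arc Circumferential element count along the semicircle (even).
#' @param n_chord Element count along the flat posterior chord (even).
#' @param n_wall Through-thickness element count in the 0.8 mm wall layers.
#' @param n_axial_ring,n_axial_gap Axial element count per ring / gap band
#'   (`n_axial_ring` even so a node plane falls at mid-length).
#' @return A `trachea_config` list.
#' @export
trachea_config <- function(diameter = 10, length = 50, ring_width = 2,
                           gap_width = 1, wall_thickness = 0.8,
                           mucosa_thickness = 0.2, muscle_thickness = 0.8,
                           n_arc = 16, n_chord = 8, n_wall = 1,
                           n_axial_ring = 2, n_axial_gap = 1) {
  dims <- c(diameter, length, ring_width, gap_width, wall_thickness,
            mucosa_thickness, muscle_thickness)
  if (any(!is.finite(dims)) || any(dims <= 0)) stop("all dimensions must be positive")
  if (n_arc %% 2 != 0 || n_chord %% 2 != 0)
    stop("`n_arc` and `n_chord` must be even (a node line is needed at x = 0)")
  if (n_axial_ring %% 2 != 0)
    stop("`n_axial_ring` must be even (a node plane is needed at mid-length)")
  n_rings <- (length + gap_width) / (ring_width + gap_width)
  if (abs(n_rings - round(n_rings)) > 1e-9 || round(n_rings) < 1)
    stop(sprintf(
      "length %g is not decomposable into the ring/gap band pattern (%g + %g)",
      length, ring_width, gap_width))
  structure(list(
    diameter = diameter, length = length, ring_width = ring_width,
    gap_width = gap_width, wall_thickness = wall_thickness,
    mucosa_thickness = mucosa_thickness, muscle_thickness = muscle_thickness,
    n_arc = as.integer(n_arc), n_chord = as.integer(n_chord),
    n_wall = as.integer(n_wall), n_axial_ring = as.integer(n_axial_ring),
    n_axial_gap = as.integer(n_axial_gap), n_rings = as.integer(round(n_rings))
  ), class = "trachea_config")
}

#' Malacic span length from ring count
#'
#' `n` rings of width `ring_width` with `n - 1` interposed gaps:
#' 1, 3, 5, 7 rings give 2, 8, 14, 20 mm with the default 2/1 mm pattern.
#'
#' @param n_rings Ring count (non-negative).
#' @param ring_width,gap_width Band widths, mm.
#' @return Span length in mm.
#' @export
malacic_length <- function(n_rings, ring_width = 2, gap_width = 1) {
  if (any(n_rings < 0)) stop("ring count must be non-negative")
  n_rings * ring_width + pmax(n_rings - 1, 0) * gap_width
}

#' Malacia specification
#'
#' @param target `"anterior"` (cartilage ring weakening) or `"posterior"`
#'   (trachealis muscle weakening).
#' @param severity `"soft"` or `"mucosa"` for anterior; `"posterior"` is
#'   implied for posterior targets, with coefficients `a`, `b`.
#' @param rings Ring count for anterior malacia (odd, centered).
#' @param length_mm Axial extent for posterior malacia, mm (centered).
#' @param a,b Replacement trachealis Ogden coefficients (posterior only).
#' @return A `malacia_spec` list.
#' @export
malacia_spec <- function(target = c("anterior", "posterior"),
                         severity = NULL, rings = NULL, length_mm = NULL,
                         a = NULL, b = NULL) {
  target <- match.arg(target)
  if (target == "anterior") {
    if (is.null(rings) || rings %% 2 != 1)
      stop("anterior malacia needs an odd `rings` count")
    severity <- match.arg(severity, c("soft", "mucosa"))
  } else {
    if (is.null(length_mm) || length_mm < 0)
      stop("posterior malacia needs a non-negative `length_mm`")
    if (is.null(a) || is.null(b))
      stop("posterior malacia needs replacement coefficients `a`, `b`")
    severity <- "posterior"
  }
  structure(list(target = target, severity = severity, rings = rings,
                 length_mm = length_mm, a = a, b = b),
            class = "malacia_spec")
}

# axial band table: alternating cartilage/fibrous starting and ending with
# cartilage, plus the per-band axial element split
band_table <- function(config) {
  n <- config$n_rings
  types <- rep(c("cartilage", "fibrous"), length.out = 2 * n - 1)
  widths <- ifelse(types == "cartilage", config$ring_width, config$gap_width)
  z1 <- cumsum(widths)
  z0 <- z1 - widths
  ring_index <- cumsum(types == "cartilage")
  ring_index[types != "cartilage"] <- NA
  tibble::tibble(band = seq_along(types), type = types, z0 = z0, z1 = z1,
                 ring = ring_index)
}

#' Build the idealized trachea hexahedral mesh
#'
#' Cross-section: half-annulus (mucosa then cartilage/fibrous wall) over the
#' semicircular lumen, butt-jointed at y = 0 to a flat slab (mucosa lining
#' on top, trachealis muscle below) spanning the full outer width. All
#' interfaces share nodes. The luminal surface facets are oriented with
#' normals pointing into the airway cavity.
#'
#' @param config A [trachea_config()].
#' @return A `trachea_mesh`: list with `nodes` (n x 3, mm), `elems`
#'   (ne x 8, 1-based VTK hexahedron ordering), `region` (character per
#'   element), `elem_band` (axial band index per element, NA for muscle
#'   rows), `lumen_facets` (nf x 4), node sets and the ordered mid-plane
#'   lumen loop.
#' @export
build_trachea_mesh <- function(config) {
  stopifnot(inherits(config, "trachea_config"))
  R <- config$diameter / 2
  tm <- config$mucosa_thickness
  tw <- config$wall_thickness
  tmu <- config$muscle_thickness
  nw <- config$n_wall

  # axial node planes
  bands <- band_table(config)
  zs <- 0
  for (i in seq_len(nrow(bands))) {
    nsub <- if (bands$type[i] == "cartilage") config$n_axial_ring else config$n_axial_gap
    zs <- c(zs, bands$z0[i] + (bands$z1[i] - bands$z0[i]) * seq_len(nsub) / nsub)
  }
  nz <- length(zs)
  if (!any(abs(zs - config$length / 2) < 1e-9))
    stop("no node plane at mid-length; adjust axial splits")

  # cross-section template ------------------------------------------------
  radii <- c(R, R + tm, R + tm + tw * seq_len(nw) / nw)
  nr <- length(radii)
  thetas <- pi * (0:config$n_arc) / config$n_arc
  ylev <- c(-tm - tmu * rev(seq_len(nw)) / nw, -tm, 0)   # bottom to top
  ny <- length(ylev)
  xcols <- c(-rev(radii), -R + 2 * R * seq_len(config$n_chord - 1) / config$n_chord,
             radii)

  env <- new.env(hash = TRUE, parent = emptyenv())
  coords <- list()
  nid <- function(x, y) {
    key <- sprintf("%.8f_%.8f", x + 0, y + 0)
    id <- env[[key]]
    if (is.null(id)) {
      id <- length(coords) + 1L
      coords[[id]] <<- c(x, y)
      env[[key]] <<- id
    }
    id
  }

  # slab nodes first (so the theta = 0, pi annulus lines reuse them)
  slab_id <- matrix(0L, length(xcols), ny)
  for (i in seq_along(xcols)) for (j in seq_len(ny))
    slab_id[i, j] <- nid(xcols[i], ylev[j])
  ann_id <- matrix(0L, length(thetas), nr)
  for (k in seq_along(thetas)) for (j in seq_len(nr))
    ann_id[k, j] <- nid(round(radii[j] * cos(thetas[k]), 10),
                        round(radii[j] * sin(thetas[k]), 10))
  cs <- do.call(rbind, coords)
  ncs <- nrow(cs)

  # cross-section quads (CCW), with role and ring-arc flag
  quads <- list(); qrole <- character(); qarc <- integer()
  for (k in seq_len(config$n_arc)) for (j in seq_len(nr - 1)) {
    quads[[length(quads) + 1L]] <-
      c(ann_id[k, j], ann_id[k, j + 1], ann_id[k + 1, j + 1], ann_id[k + 1, j])
    qrole <- c(qrole, if (j == 1) "mucosa" else "wall")
    qarc <- c(qarc, 1L)
  }
  for (i in seq_len(length(xcols) - 1)) for (j in seq_len(ny - 1)) {
    quads[[length(quads) + 1L]] <-
      c(slab_id[i, j], slab_id[i + 1, j], slab_id[i + 1, j + 1], slab_id[i, j + 1])
    qrole <- c(qrole, if (j == ny - 1) "mucosa" else "muscle")
    qarc <- c(qarc, 0L)
  }
  quads <- do.call(rbind, quads)
  nq <- nrow(quads)

  # extrude along z
  nodes <- cbind(cs[rep(seq_len(ncs), nz), , drop = FALSE],
                 rep(zs, each = ncs))
  nel <- nq * (nz - 1)
  elems <- matrix(0L, nel, 8)
  region <- character(nel)
  elem_band <- rep(NA_integer_, nel)
  band_of <- function(zc) which(bands$z0 - 1e-9 <= zc & zc <= bands$z1 + 1e-9)[1]
  e <- 0L
  for (p in seq_len(nz - 1)) {
    off0 <- (p - 1L) * ncs
    off1 <- p * ncs
    zc <- (zs[p] + zs[p + 1]) / 2
    bnd <- band_of(zc)
    btype <- bands$type[bnd]
    for (q in seq_len(nq)) {
      e <- e + 1L
      elems[e, ] <- c(quads[q, ] + off0, quads[q, ] + off1)
      region[e] <- switch(qrole[q],
                          mucosa = "mucosa",
                          muscle = "muscle",
                          wall = btype)
      if (qrole[q] != "muscle") elem_band[e] <- bnd
    }
  }

  # luminal surface facets, oriented into the cavity -----------------------
  lum_loop_cs <- c(ann_id[, 1],                                  # theta 0..pi at r = R
                   slab_id[match(-R, xcols) + seq_len(config$n_chord - 1), ny])
  # loop order: (R,0) CCW over the arc to (-R,0), then across the chord
  facets <- list()
  seg <- cbind(head(c(lum_loop_cs, lum_loop_cs[1]), -1),
               c(lum_loop_cs[-1], lum_loop_cs[1]))
  for (p in seq_len(nz - 1)) {
    off0 <- (p - 1L) * ncs
    off1 <- p * ncs
    for (s in seq_len(nrow(seg)))
      facets[[length(facets) + 1L]] <-
        c(seg[s, 1] + off0, seg[s, 2] + off0, seg[s, 2] + off1, seg[s, 1] + off1)
  }
  facets <- do.call(rbind, facets)
  # orient normals toward an interior reference point on the facet's plane
  for (fidx in seq_len(nrow(facets))) {
    xq <- nodes[facets[fidx, ], ]
    nrm <- cross3(xq[3, ] - xq[1, ], xq[4, ] - xq[2, ])
    ref <- c(0, R / 2, mean(xq[, 3]))
    if (sum(nrm * (ref - colMeans(xq))) < 0)
      facets[fidx, ] <- facets[fidx, c(2, 1, 4, 3)]
  }

  midp <- which(abs(zs - config$length / 2) < 1e-9)[1]
  mid_loop <- lum_loop_cs + (midp - 1L) * ncs

  tolc <- 1e-8
  sets <- list(
    end_z0 = which(abs(nodes[, 3]) < tolc),
    end_zL = which(abs(nodes[, 3] - config$length) < tolc),
    sym_plane = which(abs(nodes[, 1]) < tolc),
    muscle_midline = which(abs(nodes[, 1]) < tolc & nodes[, 2] < tolc),
    lumen_nodes = sort(unique(as.vector(facets)))
  )

  structure(list(
    nodes = nodes, elems = elems, region = region, elem_band = elem_band,
    lumen_facets = facets, mid_loop = mid_loop, sets = sets,
    bands = bands, config = config
  ), class = "trachea_mesh")
}

#' @export
print.trachea_mesh <- function(x, ...) {
  cat(sprintf(
    "<trachea_mesh> D = %g mm, L = %g mm: %d nodes, %d hexes (%s)\n",
    x$config$diameter, x$config$length, nrow(x$nodes), nrow(x$elems),
    paste(sprintf("%s %d", names(table(x$region)), table(x$region)),
          collapse = ", ")))
  invisible(x)
}

#' Select the malacic element set
#'
#' Anterior malacia targets the `n` centermost cartilage rings plus the
#' fibrous gaps interposed within that span (wall elements only, not the
#' mucosa lining); posterior malacia targets muscle elements whose axial
#' centroid lies within the centered span. Both selections are symmetric
#' about mid-length.
#'
#' @param mesh A [build_trachea_mesh()] result.
#' @param spec A [malacia_spec()].
#' @return Integer vector of element ids (empty if the extent is 0).
#' @export
select_malacic_elements <- function(mesh, spec) {
  stopifnot(inherits(mesh, "trachea_mesh"), inherits(spec, "malacia_spec"))
  cfg <- mesh$config
  zc <- (mesh$nodes[mesh$elems[, 1], 3] + mesh$nodes[mesh$elems[, 5], 3]) / 2
  if (spec$target == "anterior") {
    if (spec$rings == 0) return(integer())
    if (spec$rings > cfg$n_rings) stop("malacic ring count exceeds the mesh")
    rings <- mesh$bands$ring[mesh$bands$type == "cartilage"]
    mid_ring <- stats::median(rings)
    sel_rings <- mid_ring + seq(-(spec$rings - 1) / 2, (spec$rings - 1) / 2)
    zspan <- range(mesh$bands$z0[which(mesh$bands$ring %in% sel_rings)],
                   mesh$bands$z1[which(mesh$bands$ring %in% sel_rings)])
    which(mesh$region %in% c("cartilage", "fibrous") &
            zc > zspan[1] - 1e-9 & zc < zspan[2] + 1e-9)
  } else {
    if (spec$length_mm > cfg$length) stop("malacic length exceeds the mesh")
    if (spec$length_mm == 0) return(integer())
    half <- spec$length_mm / 2
    which(mesh$region == "muscle" &
            abs(zc - cfg$length / 2) < half + 1e-9)
  }
}

#' Luminal surface area
#'
#' Sum of the luminal facet areas of the (undeformed) mesh; approaches
#' \eqn{\pi (D/2) L + D L} with circumferential refinement.
#'
#' @param mesh A `trachea_mesh`.
#' @return Area in mm^2.
#' @export
lumen_surface_area <- function(mesh) {
  f <- mesh$lumen_facets
  x <- mesh$nodes
  a <- 0
  for (i in seq_len(nrow(f))) {
    q <- x[f[i, ], ]
    a <- a + 0.5 * sqrt(sum(cross3(q[3, ] - q[1, ], q[4, ] - q[2, ])^2))
  }
  a
}

#' Deformed mid-length lumen cross-section polygon
#'
#' Ordered planar polygon of the luminal node loop at z = length/2,
#' projected to the x-y plane after applying nodal displacements.
#'
#' @param mesh A `trachea_mesh`.
#' @param displacements Length `3 * n_nodes` displacement vector (or NULL
#'   for the reference configuration).
#' @return Two-column matrix of vertex coordinates, one row per vertex, in
#'   loop order.
#' @export
mid_cross_section_loop <- function(mesh, displacements = NULL) {
  ids <- mesh$mid_loop
  xy <- mesh$nodes[ids, 1:2, drop = FALSE]
  if (!is.null(displacements)) {
    u <- matrix(displacements, ncol = 3, byrow = TRUE)
    xy <- xy + u[ids, 1:2, drop = FALSE]
  }
  xy
}
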