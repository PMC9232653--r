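# Coarse-grained bead-model builders for DNA helix-bundle geometries:
# parametric B-DNA duplexes, ring/side-by-side/stacked bundle
# arrangements, laterally squished (gas-phase compacted) variants, and
# PDB round-tripping.

# Default flatten ratio for the squished 6-helix ring; see squish().
.SQUISH_FLATTEN_DEFAULT <- 0.53

#' Parametric B-DNA coarse-grain parameters
#'
#' Three beads per nucleotide (phosphate P, sugar S, base B) are placed on
#' an ideal B-form helix: 3.38 Angstrom rise and 34.3 degrees twist per
#' base pair, with the two strands' backbones separated by a 154 degree
#' glycosidic phase (minor/major groove asymmetry). The default radial
#' bead placements (9.8/7.4/4.8 Angstrom with 2.9 Angstrom collision
#' radii) sit slightly outside the atomistic positions: a three-bead
#' chain leaves see-through gaps an all-atom surface does not have, so
#' the placements are calibrated once such that the projected area of
#' the assembled six-helix barrel reproduces published atomistic
#' projection-approximation values, and then used unchanged for every
#' other geometry.
#'
#' @param rise Axial rise per bp, Angstrom.
#' @param twist Helical twist per bp, degrees.
#' @param layout data.frame with one row per bead per nucleotide:
#'   `tag`, `radial` (Angstrom), `ang_offset` (deg), `axial_offset`
#'   (Angstrom), `radius` (Angstrom).
#' @param strand_phase Angular offset between the two strands, degrees.
#' @return Object of class `bdna_params`.
#' @export
bdna_params <- function(rise = 3.38, twist = 34.3,
                        layout = data.frame(
                          tag = c("P", "S", "B"),
                          radial = c(9.8, 7.4, 4.8),
                          ang_offset = c(0, 35, 70),
                          axial_offset = c(0, 0, 0),
                          radius = c(2.9, 2.9, 2.9),
                          stringsAsFactors = FALSE),
                        strand_phase = 154) {
  stopifnot(rise > 0, all(layout$radius > 0), all(layout$radial >= 0))
  structure(list(rise = rise, twist = twist, layout = layout,
                 strand_phase = strand_phase),
            class = "bdna_params")
}

.new_bead_model <- function(beads, label, provenance) {
  stopifnot(nrow(beads) > 0, all(is.finite(as.matrix(beads[, c("x", "y", "z")]))),
            all(beads$radius > 0))
  structure(list(beads = beads, label = label, provenance = provenance),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  ext <- apply(x$beads[, c("x", "y", "z")], 2, function(v) diff(range(v)))
  cat(sprintf("<bead_model> %s: %d beads, extent %.1f x %.1f x %.1f Angstrom\n",
              x$label, nrow(x$beads), ext[1], ext[2], ext[3]))
  invisible(x)
}

# Beads of one duplex with its axis along +z starting at the origin.
.duplex_beads <- function(n_bp, params, phase_deg = 0, helix = 1L) {
  lay <- params$layout
  i <- rep(seq_len(n_bp) - 1L, each = 2L * nrow(lay))
  strand <- rep(rep(1:2, each = nrow(lay)), times = n_bp)
  li <- rep(seq_len(nrow(lay)), times = 2L * n_bp)
  base_ang <- (i * params$twist + phase_deg +
                 ifelse(strand == 2L, params$strand_phase, 0) +
                 lay$ang_offset[li]) * pi / 180
  data.frame(
    x = lay$radial[li] * cos(base_ang),
    y = lay$radial[li] * sin(base_ang),
    z = i * params$rise + lay$axial_offset[li],
    radius = lay$radius[li],
    tag = lay$tag[li],
    helix = helix,
    stringsAsFactors = FALSE)
}

#' Build a coarse-grained B-DNA duplex
#'
#' @param n_bp Number of base pairs (>= 1).
#' @param params A [bdna_params()].
#' @param label Model label.
#' @return A `bead_model` with `n_bp * 2 * beads_per_nt` beads and axial
#'   bead-center extent `(n_bp - 1) * rise`.
#' @examples
#' m <- build_duplex(21)
#' diff(range(m$beads$z))  # 67.6
#' @export
build_duplex <- function(n_bp, params = bdna_params(), label = "duplex") {
  if (n_bp < 1) stop("n_bp must be >= 1")
  beads <- .duplex_beads(as.integer(n_bp), params)
  .new_bead_model(beads, label,
                  list(builder = "build_duplex", n_bp = n_bp, params = params))
}

#' Specify a helix-bundle geometry
#'
#' @param n_helices Number of duplexes in one barrel.
#' @param bp_per_helix Base pairs per duplex (default 21).
#' @param spacing Distance between adjacent helix axes, Angstrom
#'   (default 22: ~20 Angstrom helix diameter plus 2 Angstrom; the design
#'   spacing is not a measured quantity and is deliberately exposed).
#' @param arrangement One of `"ring"`, `"side_by_side"`, `"stacked"`,
#'   `"squished_ring"`.
#' @param copies Number of barrel copies for the multi-barrel
#'   arrangements (`side_by_side`, `stacked`); must be 1 otherwise.
#' @param include_linkers Add 4-thymidine loop bead arcs bridging
#'   adjacent helix ends of closed barrels (default TRUE).
#' @param gap Axial gap between stacked copies, Angstrom (default 0).
#' @param multi_layout For `side_by_side` with 3 copies: `"triangle"` or
#'   `"linear"` placement of the barrel axes.
#' @param flatten Flatten ratio for `squished_ring` with 6 helices; see
#'   [squish()]. `NULL` uses the package default.
#' @return Object of class `bundle_spec`.
#' @export
bundle_spec <- function(n_helices = 6, bp_per_helix = 21, spacing = 22,
                        arrangement = c("ring", "side_by_side", "stacked",
                                        "squished_ring"),
                        copies = 1, include_linkers = TRUE, gap = 0,
                        multi_layout = c("triangle", "linear"),
                        flatten = NULL) {
  arrangement <- match.arg(arrangement)
  multi_layout <- match.arg(multi_layout)
  stopifnot(n_helices >= 1, bp_per_helix >= 1, spacing > 0, copies >= 1)
  if (copies > 1 && !arrangement %in% c("side_by_side", "stacked"))
    stop("copies > 1 requires a side_by_side or stacked arrangement")
  if (arrangement %in% c("side_by_side", "stacked") && copies < 2)
    stop(arrangement, " arrangement needs copies >= 2")
  structure(list(n_helices = as.integer(n_helices),
                 bp_per_helix = as.integer(bp_per_helix),
                 spacing = spacing, arrangement = arrangement,
                 copies = as.integer(copies),
                 include_linkers = isTRUE(include_linkers),
                 gap = gap, multi_layout = multi_layout, flatten = flatten),
            class = "bundle_spec")
}

# Axis positions of an n-helix ring: circle of radius s / (2 sin(pi/n)).
.ring_axes <- function(n, s) {
  if (n == 1) return(matrix(0, 1, 2))
  R <- s / (2 * sin(pi / n))
  ang <- 2 * pi * (seq_len(n) - 1) / n
  cbind(R * cos(ang), R * sin(ang))
}

# Linker arc of n_beads beads bridging two helix-end points, bulging
# axially away from the barrel body (a coarse stand-in for a 4-thymidine
# loop).
.linker_beads <- function(p1, p2, zdir, n_beads = 4, radius = 2.9,
                          bulge = 4, helix = NA_integer_) {
  t <- seq_len(n_beads) / (n_beads + 1)
  data.frame(
    x = (1 - t) * p1[1] + t * p2[1],
    y = (1 - t) * p1[2] + t * p2[2],
    z = (1 - t) * p1[3] + t * p2[3] + zdir * bulge * sin(pi * t),
    radius = radius, tag = "L", helix = helix,
    stringsAsFactors = FALSE)
}

# Assemble one barrel given explicit axis positions (cyclic order).
# Linker arcs alternate top/bottom around the ring, as in the design
# where each strand crosses to the neighbouring helix at alternating
# ends. Bead count depends only on (n, bp, layout, include_linkers), so
# rebuilding at squished axis positions preserves it exactly.
.barrel_at <- function(axis_xy, spec, params) {
  n <- nrow(axis_xy)
  z_top <- (spec$bp_per_helix - 1) * params$rise
  beads <- do.call(rbind, lapply(seq_len(n), function(k) {
    b <- .duplex_beads(spec$bp_per_helix, params,
                       phase_deg = 360 * (k - 1) / max(n, 1), helix = k)
    b$x <- b$x + axis_xy[k, 1]
    b$y <- b$y + axis_xy[k, 2]
    b
  }))
  if (spec$include_linkers && n >= 2) {
    rad <- params$layout$radius[1]
    links <- do.call(rbind, lapply(seq_len(n), function(k) {
      k2 <- if (k == n) 1L else k + 1L
      zdir <- if (k %% 2 == 1) 1 else -1
      zend <- if (zdir > 0) z_top else 0
      .linker_beads(c(axis_xy[k, ], zend), c(axis_xy[k2, ], zend),
                    zdir, radius = rad, helix = k)
    }))
    beads <- rbind(beads, links)
  }
  beads
}

# Outer envelope radius of one barrel (axis circle + helix envelope).
.barrel_outer_radius <- function(n, spec, params) {
  R <- if (n > 1) spec$spacing / (2 * sin(pi / n)) else 0
  R + max(params$layout$radial + params$layout$radius)
}

#' Build a helix-bundle bead model
#'
#' `ring`: helix axes parallel on a circle of radius
#' `spacing / (2 sin(pi/n))`. `side_by_side`: copies of the ring barrel
#' with parallel axes and adjacent outer surfaces in contact (3 copies
#' admit `"triangle"` or `"linear"` layouts). `stacked`: copies translated
#' end-to-end along the barrel axis by the axial extent plus `gap`.
#' `squished_ring`: the ring passed through [squish()].
#'
#' @param spec A [bundle_spec()].
#' @param params A [bdna_params()].
#' @param label Model label; defaults to a description of the spec.
#' @return A `bead_model`.
#' @examples
#' b <- build_bundle(bundle_spec(n_helices = 6))
#' @export
build_bundle <- function(spec, params = bdna_params(), label = NULL) {
  stopifnot(inherits(spec, "bundle_spec"))
  n <- spec$n_helices
  if (is.null(label))
    label <- sprintf("%dHB-%s", n * spec$copies, spec$arrangement)
  if (spec$arrangement == "squished_ring") {
    ring_spec <- spec
    ring_spec$arrangement <- "ring"
    ring <- build_bundle(ring_spec, params, label = paste0(label, "-ring"))
    return(squish(ring, flatten = spec$flatten, label = label))
  }
  axis_xy <- .ring_axes(n, spec$spacing)
  one <- .barrel_at(axis_xy, spec, params)
  beads <- one
  if (spec$arrangement == "side_by_side") {
    D <- 2 * .barrel_outer_radius(n, spec, params)
    centers <- switch(spec$multi_layout,
      linear = cbind((seq_len(spec$copies) - 1) * D, 0),
      triangle = {
        if (spec$copies == 2) cbind(c(0, D), c(0, 0))
        else if (spec$copies == 3)
          rbind(c(0, 0), c(D, 0), c(D / 2, D * sqrt(3) / 2))
        else stop("triangle layout supports 2 or 3 copies")
      })
    if (spec$copies > nrow(centers)) stop("unsupported copies for layout")
    beads <- do.call(rbind, lapply(seq_len(spec$copies), function(ci) {
      b <- one
      b$x <- b$x + centers[ci, 1]
      b$y <- b$y + centers[ci, 2]
      b$helix <- b$helix + (ci - 1L) * n
      b
    }))
  } else if (spec$arrangement == "stacked") {
    extent <- (spec$bp_per_helix - 1) * params$rise
    beads <- do.call(rbind, lapply(seq_len(spec$copies), function(ci) {
      b <- one
      b$z <- b$z + (ci - 1) * (extent + spec$gap)
      b$helix <- b$helix + (ci - 1L) * n
      b
    }))
  }
  rownames(beads) <- NULL
  .new_bead_model(beads, label,
                  list(builder = "build_bundle", spec = spec, params = params,
                       axis_xy = axis_xy))
}

# Squished axis positions. For n >= 8 (even): a stadium ("cigar")
# cross-section whose two caps are arcs of the 6-helix ring (cap radius =
# spacing, i.e. the 6HB circumradius) holding 3 helices each, with the
# remaining helices evenly spaced on the two straight segments; every
# cyclically adjacent pair stays exactly `spacing` apart. For n == 6 the
# stadium construction degenerates to the unchanged ring, so the 6-helix
# case is instead flattened by an edge-preserving hinge fold: the four
# off-axis vertices of the hexagon of helix axes move to height
# +/- flatten * spacing * sin(60 deg) while the two end vertices slide
# outward to keep all adjacent spacings exact.
.squished_axes <- function(n, s, flatten) {
  if (n < 6) stop("squish requires >= 6 helices")
  if (n == 6) {
    c0 <- s * sin(pi / 3)
    cc <- flatten * c0
    a <- s / 2 + sqrt(s^2 - cc^2)
    return(rbind(c(a, 0), c(s / 2, cc), c(-s / 2, cc),
                 c(-a, 0), c(-s / 2, -cc), c(s / 2, -cc)))
  }
  if (n %% 2 != 0)
    stop("stadium squish needs an even helix count, got ", n)
  m <- (n - 6L) / 2L          # helices per straight segment
  cx <- m * s / 2             # cap center offset
  h <- s * sin(pi / 3)        # straight-segment height
  right_cap <- rbind(c(cx + s / 2, -h), c(cx + s, 0), c(cx + s / 2, h))
  top <- if (m > 0) cbind(cx + s / 2 - s * seq_len(m), h) else NULL
  left_cap <- rbind(c(-cx - s / 2, h), c(-cx - s, 0), c(-cx - s / 2, -h))
  bottom <- if (m > 0) cbind(-cx - s / 2 + s * seq_len(m), -h) else NULL
  rbind(right_cap, top, left_cap, bottom)
}

#' Laterally squish a ring bundle
#'
#' Emulates gas-phase compaction of hollow barrels by re-placing the
#' helix axes on a flattened ("cigar") cross-section while keeping every
#' pair of cyclically adjacent axes at the original spacing; bead count
#' and helix axial extents are preserved exactly. For 12 and more helices
#' the cross-section is a stadium whose rounded caps are 3-helix arcs
#' with the curvature of the 6-helix ring; the 6-helix ring itself is
#' mildly flattened by a spacing-preserving hinge fold controlled by
#' `flatten` (1 = unchanged ring, smaller = flatter; 0.5 would put the
#' six axes in two staggered close-packed rows of three; the default
#' 0.53 is calibrated to the ~4 percent projected-area reduction
#' reported for mildly compacted hexamer models).
#'
#' @param model A `bead_model` built as a ring bundle (>= 6 helices).
#' @param flatten Flatten ratio for the 6-helix case; `NULL` uses the
#'   package default of 0.53.
#' @param label Label of the squished model.
#' @return A `bead_model`.
#' @export
squish <- function(model, flatten = NULL, label = NULL) {
  stopifnot(inherits(model, "bead_model"))
  prov <- model$provenance
  if (is.null(prov$spec) || prov$spec$arrangement != "ring")
    stop("squish applies to models built as ring bundles")
  if (is.null(flatten)) flatten <- .SQUISH_FLATTEN_DEFAULT
  stopifnot(flatten > 0, flatten <= 1)
  spec <- prov$spec
  axes <- .squished_axes(spec$n_helices, spec$spacing, flatten)
  beads <- .barrel_at(axes, spec, prov$params)
  rownames(beads) <- NULL
  if (is.null(label)) label <- paste0(model$label, "-SQ")
  .new_bead_model(beads, label,
                  list(builder = "squish", spec = spec, params = prov$params,
                       axis_xy = axes, flatten = flatten))
}

#' Registry of candidate helix-bundle geometries
#'
#' Named [bundle_spec()]s for the candidate topologies of the 6-, 12- and
#' 18-mer species: single barrels (`6HB`, `12HB`, `18HB`), side-by-side
#' multi-barrels (`12HB-a`, `18HB-a` triangle, `18HB-b` linear), stacked
#' end-to-end multi-barrels (`12HB-b`, `18HB-c`) and the laterally
#' squished barrels (`6HB-SQ`, `12HB-SQ`, `18HB-SQ`).
#'
#' @return Named list of `bundle_spec` objects.
#' @export
model_registry <- function() {
  list(
    "6HB"     = bundle_spec(6),
    "6HB-SQ"  = bundle_spec(6, arrangement = "squished_ring"),
    "12HB-a"  = bundle_spec(6, arrangement = "side_by_side", copies = 2,
                            multi_layout = "linear"),
    "12HB-b"  = bundle_spec(6, arrangement = "stacked", copies = 2),
    "12HB"    = bundle_spec(12),
    "12HB-SQ" = bundle_spec(12, arrangement = "squished_ring"),
    "18HB-a"  = bundle_spec(6, arrangement = "side_by_side", copies = 3,
                            multi_layout = "triangle"),
    "18HB-b"  = bundle_spec(6, arrangement = "side_by_side", copies = 3,
                            multi_layout = "linear"),
    "18HB-c"  = bundle_spec(6, arrangement = "stacked", copies = 3),
    "18HB"    = bundle_spec(18),
    "18HB-SQ" = bundle_spec(18, arrangement = "squished_ring")
  )
}

#' @rdname model_registry
#' @param name Registry model name.
#' @param params A [bdna_params()].
#' @export
build_registry_model <- function(name, params = bdna_params()) {
  reg <- model_registry()
  if (!name %in% names(reg))
    stop("unknown model '", name, "'; registry: ",
         paste(names(reg), collapse = ", "))
  build_bundle(reg[[name]], params, label = name)
}

#' Write / read a bead model as PDB
#'
#' Beads become pseudo-atoms (tag in the atom-name field, collision
#' radius in the B-factor column); model provenance is recorded in
#' REMARK 300 records. Coordinates round-trip to PDB precision (1e-3
#' Angstrom).
#'
#' @param model A `bead_model`.
#' @param path File path.
#' @return `read_pdb()` returns the restored `bead_model`.
#' @export
write_pdb <- function(model, path) {
  stopifnot(inherits(model, "bead_model"))
  b <- model$beads
  con <- file(path, "w")
  prov <- model$provenance
  writeLines(c(
    sprintf("REMARK 300 bundleIMS bead model '%s'", model$label),
    sprintf("REMARK 300 builder=%s n_beads=%d",
            if (is.null(prov$builder)) "unknown" else prov$builder, nrow(b)),
    "REMARK 300 atom name = bead tag; B-factor = collision radius (Angstrom)"),
    con)
  close(con)
  n <- nrow(b)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(b[, c("x", "y", "z")]))),
                   type = rep("ATOM", n), eleno = seq_len(n),
                   resno = ifelse(is.na(b$helix), 0L, as.integer(b$helix)),
                   resid = rep("BED", n), elety = b$tag,
                   chain = rep("A", n),
                   o = rep(1, n), b = b$radius,
                   append = TRUE)
  invisible(path)
}

#' @rdname write_pdb
#' @export
read_pdb <- function(path) {
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path)),
                  error = function(e) stop("malformed PDB '", path, "': ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0 ||
      any(!is.finite(a$x)) || any(!is.finite(a$y)) || any(!is.finite(a$z)))
    stop("malformed PDB '", path, "': no parseable ATOM records")
  beads <- data.frame(x = a$x, y = a$y, z = a$z, radius = a$b,
                      tag = trimws(a$elety),
                      helix = ifelse(a$resno == 0, NA_integer_, a$resno),
                      stringsAsFactors = FALSE)
  .new_bead_model(beads, label = basename(path),
                  provenance = list(builder = "read_pdb", path = path))
}

#' Write / read a bundle spec as YAML
#'
#' @param spec A [bundle_spec()].
#' @param path File path.
#' @return `read_bundle_spec()` returns the restored `bundle_spec`.
#' @export
write_bundle_spec <- function(spec, path) {
  stopifnot(inherits(spec, "bundle_spec"))
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_bundle_spec
#' @export
read_bundle_spec <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(bundle_spec, x[!vapply(x, is.null, TRUE)])
}
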