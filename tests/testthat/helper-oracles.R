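# Shared fixtures and independent oracles, built in code at test time.

# Minimal bead model from coordinate/radius vectors.
make_bead_model <- function(x, y, z, radius = 2.9, tag = "P", label = "test") {
  beads <- data.frame(x = x, y = y, z = z, radius = radius, tag = tag,
                      helix = NA_integer_, stringsAsFactors = FALSE)
  structure(list(beads = beads, label = label,
                 provenance = list(builder = "helper")),
            class = "bead_model")
}

single_bead <- function(r = 2.9) make_bead_model(0, 0, 0, radius = r)

two_beads <- function(d, r = 2.9) make_bead_model(c(0, 0), c(0, 0), c(0, d),
                                                  radius = r)

# Orientation-averaged projected area of two equal spheres at center
# distance d, by high-resolution quadrature over the polar angle between
# the view axis and the dumbbell axis. Union area of two radius-r disks
# with center separation t is 2*pi*r^2 minus the lens overlap.
two_sphere_pa_oracle <- function(r, d) {
  union_area <- function(t) {
    t <- pmin(t, 2 * r)
    overlap <- 2 * r^2 * acos(t / (2 * r)) - (t / 2) * sqrt(4 * r^2 - t^2)
    2 * pi * r^2 - overlap
  }
  stats::integrate(function(th) union_area(d * sin(th)) * sin(th),
                   0, pi / 2, rel.tol = 1e-10)$value
}

# Deterministic fine-grid projection: rasterize the projected disks at
# pixel size px for each supplied orientation and average.
raster_pa_oracle <- function(model, radii, orientations, px = 0.1) {
  xyz <- as.matrix(model$beads[, c("x", "y", "z")])
  if (length(radii) == 1) radii <- rep(radii, nrow(xyz))
  areas <- vapply(seq_len(nrow(orientations)), function(o) {
    u <- orientations[o, ]
    a <- if (abs(u[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    e1 <- c(a[2] * u[3] - a[3] * u[2], a[3] * u[1] - a[1] * u[3],
            a[1] * u[2] - a[2] * u[1])
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    P <- cbind(xyz %*% e1, xyz %*% e2)
    lo <- c(min(P[, 1] - radii), min(P[, 2] - radii)) - px
    hi <- c(max(P[, 1] + radii), max(P[, 2] + radii)) + px
    gx <- seq(lo[1] + px / 2, hi[1], by = px)
    gy <- seq(lo[2] + px / 2, hi[2], by = px)
    covered <- matrix(FALSE, length(gx), length(gy))
    for (b in seq_len(nrow(P))) {
      ix <- which(abs(gx - P[b, 1]) <= radii[b])
      iy <- which(abs(gy - P[b, 2]) <= radii[b])
      if (length(ix) == 0 || length(iy) == 0) next
      d2 <- outer((gx[ix] - P[b, 1])^2, (gy[iy] - P[b, 2])^2, "+")
      covered[ix, iy] <- covered[ix, iy] | (d2 <= radii[b]^2)
    }
    sum(covered) * px^2
  }, 0)
  mean(areas)
}

# Unit vectors quasi-covering the sphere for oracle comparisons.
fixed_orientations <- function(n, seed = 99) {
  set.seed(seed)
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Brute-force enumeration of contiguous runs on a labelled cycle: test
# every ordered k-subset for cyclic contiguity, deduplicate, and
# identify rotations of the full ring.
brute_force_runs <- function(labels, k) {
  n <- length(labels)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  is_run <- function(ord) {
    start <- match(ord[1], labels)
    idx <- ((start - 1 + seq_along(ord) - 1) %% n) + 1
    identical(labels[idx], ord)
  }
  found <- character(0)
  for (subset in utils::combn(labels, k, simplify = FALSE))
    for (p in perms(subset))
      if (is_run(p)) found <- c(found, paste(p, collapse = "-"))
  found <- unique(found)
  if (k == n) {
    canon <- vapply(found, function(s) {
      v <- strsplit(s, "-")[[1]]
      rots <- vapply(seq_along(v), function(i)
        paste(c(v[i:length(v)], v[seq_len(i - 1)]), collapse = "-"), "")
      min(rots)
    }, "")
    found <- unique(canon)
  }
  sort(found)
}

# Random DNA sequence over A/C/G/T.
random_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                         replace = TRUE), collapse = "")
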