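test_that("duplex geometry follows rise, twist and bead layout", {
  m <- build_duplex(21)
  expect_equal(nrow(m$beads), 21 * 2 * 3)
  expect_equal(diff(range(m$beads$z)), 20 * 3.38, tolerance = 1e-9)
  one <- build_duplex(1)
  expect_equal(diff(range(one$beads$z)), 0)
  expect_equal(nrow(one$beads), 6)
  expect_error(build_duplex(0), "n_bp")
  # radial placement: phosphate beads sit on their layout radius
  p <- m$beads[m$beads$tag == "P", ]
  expect_equal(sqrt(p$x^2 + p$y^2), rep(bdna_params()$layout$radial[1], nrow(p)),
               tolerance = 1e-9)
})

test_that("ring bundles place helix axes on the prescribed circle", {
  b6 <- build_bundle(bundle_spec(6))
  ax <- b6$provenance$axis_xy
  expect_equal(sqrt(rowSums(ax^2)), rep(22, 6), tolerance = 1e-9)
  b12 <- build_bundle(bundle_spec(12))
  expect_equal(sqrt(rowSums(b12$provenance$axis_xy^2)),
               rep(22 / (2 * sin(pi / 12)), 12), tolerance = 1e-9)
  expect_equal(round(22 / (2 * sin(pi / 12)), 2), 42.50)
  # adjacent axis spacing is the design spacing
  d <- sqrt(rowSums((ax - ax[c(2:6, 1), ])^2))
  expect_equal(d, rep(22, 6), tolerance = 1e-9)
})

test_that("linker-free ring bundles have exact n-fold symmetry", {
  for (n in c(6, 12)) {
    b <- build_bundle(bundle_spec(n, include_linkers = FALSE))
    xyz <- as.matrix(b$beads[, c("x", "y", "z")])
    th <- 2 * pi / n
    rot <- xyz %*% t(matrix(c(cos(th), -sin(th), 0,
                              sin(th), cos(th), 0,
                              0, 0, 1), 3, 3, byrow = TRUE))
    # rotation permutes the bead set: nearest-neighbour distance is ~0
    for (k in sample(nrow(xyz), 25)) {
      d <- sqrt(colSums((t(xyz) - rot[k, ])^2))
      expect_lt(min(d), 1e-6)
    }
  }
})

test_that("stacked and side-by-side multimers compose as specified", {
  single <- build_bundle(bundle_spec(6))
  stacked <- build_bundle(bundle_spec(6, arrangement = "stacked", copies = 2))
  expect_equal(diff(range(stacked$beads$z[stacked$beads$tag != "L"])),
               2 * diff(range(single$beads$z[single$beads$tag != "L"])),
               tolerance = 1e-9)
  gap5 <- build_bundle(bundle_spec(6, arrangement = "stacked", copies = 2, gap = 5))
  expect_equal(diff(range(gap5$beads$z[gap5$beads$tag != "L"])),
               2 * diff(range(single$beads$z[single$beads$tag != "L"])) + 5,
               tolerance = 1e-9)
  sbs <- build_bundle(bundle_spec(6, arrangement = "side_by_side", copies = 2))
  expect_equal(nrow(sbs$beads), 2 * nrow(single$beads))
  # triangle 18-mer has three barrels with pairwise-equal center distances
  tri <- build_bundle(bundle_spec(6, arrangement = "side_by_side", copies = 3,
                                  multi_layout = "triangle"))
  expect_equal(nrow(tri$beads), 3 * nrow(single$beads))
  expect_error(build_bundle(bundle_spec(6, copies = 2)), "side_by_side or stacked")
  expect_error(bundle_spec(6, arrangement = "stacked", copies = 1), "copies >= 2")
})

test_that("squish preserves bead count, axial extents and neighbour spacing", {
  for (n in c(6, 12, 18)) {
    ring <- build_bundle(bundle_spec(n))
    sq <- squish(ring)
    expect_equal(nrow(sq$beads), nrow(ring$beads))
    for (k in seq_len(n)) {
      zr <- range(ring$beads$z[ring$beads$helix == k & ring$beads$tag != "L"])
      zs <- range(sq$beads$z[sq$beads$helix == k & sq$beads$tag != "L"])
      expect_equal(diff(zs), diff(zr), tolerance = 1e-12)
    }
    ax <- sq$provenance$axis_xy
    d <- sqrt(rowSums((ax - ax[c(2:n, 1), ])^2))
    expect_equal(d, rep(22, n), tolerance = 22 * 0.02)
    # cigar cross-section: wider than tall
    expect_gt(diff(range(ax[, 1])), diff(range(ax[, 2])))
  }
})

test_that("the 12-helix stadium has 3+3 cap helices and 3 per straight side", {
  sq <- squish(build_bundle(bundle_spec(12)))
  ax <- sq$provenance$axis_xy
  h <- 22 * sin(pi / 3)
  expect_equal(sum(abs(abs(ax[, 2]) - h) < 1e-9), 10)  # caps ends + straights
  expect_equal(sum(abs(ax[, 2]) < 1e-9), 2)            # two cap apices
  # straight-segment helices: three at +h and three at -h strictly
  # between the cap ends
  cx <- 3 * 22 / 2
  inner <- abs(ax[, 1]) < cx + 1e-9 & abs(abs(ax[, 2]) - h) < 1e-9
  expect_equal(sum(inner & ax[, 2] > 0), 3)
  expect_equal(sum(inner & ax[, 2] < 0), 3)
})

test_that("squish rejects unsuitable models", {
  expect_error(squish(build_duplex(5)), "ring")
  expect_error(squish(build_bundle(bundle_spec(4))), ">= 6")
  sbs <- build_bundle(bundle_spec(6, arrangement = "side_by_side", copies = 2))
  expect_error(squish(sbs), "ring")
})

test_that("every registry geometry is constructible from config alone", {
  reg <- model_registry()
  expect_setequal(names(reg),
                  c("6HB", "6HB-SQ", "12HB-a", "12HB-b", "12HB", "12HB-SQ",
                    "18HB-a", "18HB-b", "18HB-c", "18HB", "18HB-SQ"))
  counts <- vapply(names(reg), function(nm)
    nrow(build_registry_model(nm)$beads), 0)
  expect_equal(counts[["6HB"]], counts[["6HB-SQ"]])
  expect_equal(counts[["12HB"]], counts[["12HB-SQ"]])
  expect_equal(counts[["12HB-a"]], counts[["12HB-b"]])
  expect_error(build_registry_model("24HB"), "unknown model")
})

test_that("PDB output round-trips coordinates, radii and tags", {
  m <- build_duplex(21)
  f <- tempfile(fileext = ".pdb")
  write_pdb(m, f)
  lines <- readLines(f)
  expect_equal(sum(grepl("^ATOM", lines)), 126)
  expect_true(any(grepl("^REMARK 300", lines)))
  back <- read_pdb(f)
  expect_equal(as.matrix(back$beads[, c("x", "y", "z")]),
               as.matrix(m$beads[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(back$beads$tag, m$beads$tag)
  expect_equal(back$beads$radius, m$beads$radius, tolerance = 1e-2)
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a pdb", bad)
  expect_error(read_pdb(bad), "malformed|PDB")
})

test_that("bundle specs round-trip through YAML", {
  spec <- bundle_spec(12, arrangement = "squished_ring", spacing = 23.5)
  f <- tempfile(fileext = ".yaml")
  write_bundle_spec(spec, f)
  back <- read_bundle_spec(f)
  expect_equal(back$n_helices, 12L)
  expect_equal(back$arrangement, "squished_ring")
  expect_equal(back$spacing, 23.5)
})
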