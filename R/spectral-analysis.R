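# From a 2-D (m/z x drift) profile or peak list: peak picking, detection
# of charge-state series, neutral-mass deconvolution, stoichiometry
# assignment against the assembly species table, and mobility-separated
# relative abundance quantification.

#' Pick peaks from a 2-D profile or merge a raw peak list
#'
#' For an [simulate_dataset()]-style grid: local maxima (over the
#' 8-neighbourhood) above `min_snr` times a robust noise estimate
#' (median absolute deviation of the grid) are kept, maxima closer than
#' `min_separation` are merged into the higher one, and areas are
#' obtained by local integration - every grid cell above the noise floor
#' is assigned to the nearest retained peak in separation-scaled
#' coordinates. For a raw data.frame of `(mz, drift, area)` rows, peaks
#' within `min_separation` are merged (area-weighted centroid).
#'
#' @param x An `imms_dataset` or a data.frame with columns `mz`,
#'   `drift` (optional), `area`.
#' @param min_snr Signal-to-noise threshold for maxima (default 8: the
#'   expected extreme of pure Gaussian noise over a megacell grid is
#'   5-6 sigma, so 8 keeps noise maxima out while costing little
#'   sensitivity at native-MS peak heights).
#' @param min_separation Named vector `c(mz = , drift = )` giving the
#'   merge radius in each dimension.
#' @param max_peaks Cap on retained maxima (highest first).
#' @return A `peak_list` data.frame (`mz`, `drift`, `height`, `area`)
#'   sorted by m/z. All-zero input gives an empty list, not an error.
#' @export
pick_peaks <- function(x, min_snr = 8, min_separation = c(mz = 12, drift = 0.4),
                       max_peaks = 500) {
  UseMethod("pick_peaks")
}

#' @export
pick_peaks.imms_dataset <- function(x, min_snr = 8,
                                    min_separation = c(mz = 12, drift = 0.4),
                                    max_peaks = 500) {
  int <- x$intensity
  if (all(int == 0))
    return(.empty_peaklist())
  # robust noise scale for a zero-clipped Gaussian floor: the median of
  # the positive cells is 0.6745 sigma when signal occupies few cells
  noise <- median(int[int > 0]) / 0.6745
  floor_thr <- if (noise > 0) min_snr * noise else
    1e-9 * max(int)  # noiseless grid: anything structurally non-zero
  nr <- nrow(int); nc <- ncol(int)
  # 8-neighbourhood local maxima via shifted comparisons
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- int
  is_max <- int >= floor_thr
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    is_max <- is_max & (int >= pad[(2 + di):(nr + 1 + di),
                                   (2 + dj):(nc + 1 + dj)])
  }
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(.empty_peaklist())
  cand_d <- x$drift[idx[, 1]]
  cand_m <- x$mz[idx[, 2]]
  cand_h <- int[idx]
  o <- order(-cand_h)
  cand_d <- cand_d[o]; cand_m <- cand_m[o]; cand_h <- cand_h[o]
  km <- kd <- kh <- numeric(0)
  for (i in seq_along(cand_h)) {
    if (length(km) >= max_peaks) break
    if (length(km) > 0) {
      d2 <- ((km - cand_m[i]) / min_separation[["mz"]])^2 +
            ((kd - cand_d[i]) / min_separation[["drift"]])^2
      if (any(d2 < 1)) next
    }
    km <- c(km, cand_m[i]); kd <- c(kd, cand_d[i]); kh <- c(kh, cand_h[i])
  }
  kept <- data.frame(mz = km, drift = kd, height = kh)
  # local integration: assign every above-floor cell to its nearest peak
  cell <- (x$mz[2] - x$mz[1]) * (x$drift[2] - x$drift[1])
  on <- which(int > (if (noise > 0) noise else 0), arr.ind = TRUE)
  vals <- int[on]
  cd <- x$drift[on[, 1]]; cm <- x$mz[on[, 2]]
  nearest <- rep(NA_integer_, length(vals))
  best <- rep(Inf, length(vals))
  for (p in seq_len(nrow(kept))) {
    d2 <- ((cm - kept$mz[p]) / min_separation[["mz"]])^2 +
          ((cd - kept$drift[p]) / min_separation[["drift"]])^2
    upd <- d2 < best
    nearest[upd] <- p
    best[upd] <- d2[upd]
  }
  # cells further than 3 merge radii from every peak belong to none
  nearest[best > 9] <- NA_integer_
  area <- vapply(seq_len(nrow(kept)), function(p)
    sum(vals[!is.na(nearest) & nearest == p]) * cell, 0)
  out <- data.frame(mz = kept$mz, drift = kept$drift,
                    height = kept$height, area = area)
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  class(out) <- c("peak_list", "data.frame")
  out
}

#' @export
pick_peaks.data.frame <- function(x, min_snr = 8,
                                  min_separation = c(mz = 12, drift = 0.4),
                                  max_peaks = 500) {
  stopifnot(all(c("mz", "area") %in% names(x)))
  if (nrow(x) == 0) return(.empty_peaklist())
  if (!"drift" %in% names(x)) x$drift <- NA_real_
  if (!"height" %in% names(x)) x$height <- x$area
  if (any(x$mz <= 0) || any(x$area < 0))
    stop("peak rows must have mz > 0 and area >= 0")
  x <- x[order(-x$area), ]
  kept <- x[0, ]
  for (i in seq_len(nrow(x))) {
    if (nrow(kept) > 0) {
      dd <- ifelse(is.na(x$drift[i]) | is.na(kept$drift), 0,
                   (kept$drift - x$drift[i]) / min_separation[["drift"]])
      d2 <- ((kept$mz - x$mz[i]) / min_separation[["mz"]])^2 + dd^2
      if (any(d2 < 1)) {
        j <- which.min(d2)
        w <- c(kept$area[j], x$area[i])
        if (sum(w) > 0) {
          kept$mz[j] <- sum(w * c(kept$mz[j], x$mz[i])) / sum(w)
          if (!is.na(x$drift[i]) && !is.na(kept$drift[j]))
            kept$drift[j] <- sum(w * c(kept$drift[j], x$drift[i])) / sum(w)
        }
        kept$area[j] <- sum(w)
        kept$height[j] <- max(kept$height[j], x$height[i])
        next
      }
    }
    kept <- rbind(kept, x[i, c("mz", "drift", "height", "area")])
  }
  kept <- kept[order(kept$mz), ]
  rownames(kept) <- NULL
  class(kept) <- c("peak_list", "data.frame")
  kept
}

.empty_peaklist <- function() {
  out <- data.frame(mz = numeric(0), drift = numeric(0),
                    height = numeric(0), area = numeric(0))
  class(out) <- c("peak_list", "data.frame")
  out
}

#' Detect charge-state series and deconvolve neutral masses
#'
#' Greedy-then-refine search: anchors are visited in decreasing area
#' order; for each candidate charge of an anchor the companion m/z at
#' neighbouring charges is predicted through the m/z relation and matched
#' against unassigned peaks within `tol_ppm`. The longest consistent run
#' (ties broken by the smallest variance of the per-member deduced
#' neutral masses) of length >= 2 is accepted; each peak joins at most
#' one series. The deconvolved mass is the average of the per-member
#' inversions. Unassignable peaks are returned as singleton series
#' flagged `ambiguous`.
#'
#' @param peaks A `peak_list`.
#' @param z_range Candidate charge range (within 1..30).
#' @param polarity `"positive"` or `"negative"`.
#' @param tol_ppm Relative m/z matching tolerance (ppm).
#' @param tol_mz Absolute m/z tolerance floor in Th (centroids from a
#'   gridded profile are quantized to the grid pitch, so the floor
#'   should exceed it).
#' @return List of `charge_series` objects; see [series_summary()].
#' @export
detect_series <- function(peaks, z_range = c(3, 30),
                          polarity = c("positive", "negative"),
                          tol_ppm = 300, tol_mz = 2.5) {
  polarity <- match.arg(polarity)
  stopifnot(z_range[1] >= 1, z_range[2] <= 30, z_range[1] <= z_range[2])
  n <- nrow(peaks)
  series <- list()
  if (n == 0) return(series)
  used <- logical(n)
  ord <- order(-peaks$area)
  for (a in ord) {
    if (used[a]) next
    best <- NULL
    for (z in seq(z_range[1], z_range[2])) {
      M <- neutral_mass_of(peaks$mz[a], z, polarity)
      if (M <= 0) next
      members <- data.frame(idx = a, z = z)
      for (dir in c(-1, 1)) {
        zz <- z + dir
        last_drift <- peaks$drift[a]
        while (zz >= z_range[1] && zz <= z_range[2]) {
          pred <- (M + (if (polarity == "positive") 1 else -1) *
                     zz * .PROTON_MASS) / zz
          tol <- max(pred * tol_ppm * 1e-6, tol_mz)
          cand <- which(!used & abs(peaks$mz - pred) <= tol)
          cand <- setdiff(cand, members$idx)
          # one species at fixed CCS drifts faster the more charge it
          # carries, so drift must fall with z along a genuine series;
          # this rejects chimeras gluing different species (the closed
          # assemblies here are exact mass multiples of each other, so
          # m/z alone aliases their series)
          if (length(cand) > 0 && !is.na(last_drift)) {
            dr <- peaks$drift[cand]
            cand <- cand[is.na(dr) | (if (dir > 0) dr < last_drift
                                      else dr > last_drift)]
          }
          if (length(cand) == 0) break
          pick <- cand[which.max(peaks$area[cand])]
          members <- rbind(members, data.frame(idx = pick, z = zz))
          if (!is.na(peaks$drift[pick])) last_drift <- peaks$drift[pick]
          zz <- zz + dir
        }
      }
      if (nrow(members) < 2) next
      Ms <- neutral_mass_of(peaks$mz[members$idx], members$z, polarity)
      score <- c(nrow(members), -stats::var(Ms))
      if (is.null(best) || score[1] > best$score[1] ||
          (score[1] == best$score[1] && score[2] > best$score[2]))
        best <- list(members = members, score = score)
    }
    if (is.null(best)) {
      series[[length(series) + 1]] <- structure(
        list(members = data.frame(idx = a, z = NA_integer_,
                                  mz = peaks$mz[a], drift = peaks$drift[a],
                                  area = peaks$area[a]),
             neutral_mass = NA_real_, mass_sd = NA_real_,
             polarity = polarity, ambiguous = TRUE),
        class = "charge_series")
      used[a] <- TRUE
      next
    }
    mm <- best$members
    mm$mz <- peaks$mz[mm$idx]
    mm$drift <- peaks$drift[mm$idx]
    mm$area <- peaks$area[mm$idx]
    Ms <- neutral_mass_of(mm$mz, mm$z, polarity)
    series[[length(series) + 1]] <- structure(
      list(members = mm[order(mm$z), ],
           neutral_mass = mean(Ms),
           mass_sd = if (length(Ms) > 1) sd(Ms) else 0,
           polarity = polarity, ambiguous = FALSE),
      class = "charge_series")
    used[mm$idx] <- TRUE
  }
  series
}

#' @export
print.charge_series <- function(x, ...) {
  if (x$ambiguous)
    cat(sprintf("<charge_series> singleton at m/z %.1f (ambiguous)\n",
                x$members$mz[1]))
  else
    cat(sprintf("<charge_series> M = %.1f +/- %.1f Da, z = %s (%s mode)\n",
                x$neutral_mass, x$mass_sd,
                paste(range(x$members$z), collapse = "-"), x$polarity))
  invisible(x)
}

#' Summarize a series list
#'
#' @param series List returned by [detect_series()].
#' @return data.frame with one row per series: `series`, `neutral_mass`,
#'   `mass_sd`, `n_members`, `z_min`, `z_max`, `area`, `ambiguous`.
#' @export
series_summary <- function(series) {
  do.call(rbind, lapply(seq_along(series), function(i) {
    s <- series[[i]]
    data.frame(series = i, neutral_mass = s$neutral_mass,
               mass_sd = s$mass_sd, n_members = nrow(s$members),
               z_min = suppressWarnings(min(s$members$z)),
               z_max = suppressWarnings(max(s$members$z)),
               area = sum(s$members$area), ambiguous = s$ambiguous)
  }))
}

#' Assign oligomer stoichiometries to deconvolved series
#'
#' Each series' neutral mass is matched against the species table
#' allowing 0..`max_adducts` sodium adducts. Every species row within
#' `mass_tol` is reported; when several compositions of one order match
#' (inevitable for the near-degenerate open oligomers) the candidate set
#' is reported in full, and when several orders match the series becomes
#' a multi-assignment - ties are reported, never silently resolved.
#'
#' @param series List from [detect_series()].
#' @param species Species table with columns `order`, `mass` (and
#'   optionally `label`), e.g. from [species_table()] or
#'   [default_species_table()].
#' @param mass_tol Absolute tolerance in Da; default
#'   `max(1e-4 * M, 2)` per series.
#' @param max_adducts Maximum sodium adducts considered.
#' @return data.frame with one row per series: `series`, `neutral_mass`,
#'   `area`, `order` (NA when unmatched or tied across orders),
#'   `n_orders`, `orders`, `n_candidates`, `candidates`, `adducts`,
#'   `matched`.
#' @export
assign_species <- function(series, species, mass_tol = NULL, max_adducts = 10) {
  stopifnot(length(series) > 0, nrow(species) > 0,
            all(c("order", "mass") %in% names(species)))
  if (!"label" %in% names(species)) species$label <- as.character(species$order)
  dNa <- modification_delta("sodium_adduct")
  rows <- lapply(seq_along(series), function(i) {
    s <- series[[i]]
    M <- s$neutral_mass
    area <- sum(s$members$area)
    if (is.na(M))
      return(data.frame(series = i, neutral_mass = NA_real_, area = area,
                        order = NA_integer_, n_orders = 0L, orders = "",
                        n_candidates = 0L, candidates = "",
                        adducts = NA_real_, matched = FALSE))
    tol <- if (is.null(mass_tol)) max(1e-4 * M, 2) else mass_tol
    # sodium satellites are unresolved at these m/z and merge into the
    # peak, shifting the apparent mass upward continuously; match
    # against the continuum [mass, mass + max_adducts * deltaNa]
    nad <- pmin(pmax((M - species$mass) / dNa, 0), max_adducts)
    delta <- M - (species$mass + nad * dNa)
    hit <- abs(delta) <= tol
    if (!any(hit))
      return(data.frame(series = i, neutral_mass = M, area = area,
                        order = NA_integer_, n_orders = 0L, orders = "",
                        n_candidates = 0L, candidates = "",
                        adducts = NA_real_, matched = FALSE))
    cands <- species[hit, , drop = FALSE]
    orders <- sort(unique(cands$order))
    data.frame(series = i, neutral_mass = M, area = area,
               order = if (length(orders) == 1) orders else NA_integer_,
               n_orders = length(orders),
               orders = paste(orders, collapse = "|"),
               n_candidates = nrow(cands),
               candidates = paste(cands$label, collapse = "|"),
               adducts = round(mean(nad[hit])),
               matched = TRUE)
  })
  do.call(rbind, rows)
}

#' Quantify relative oligomer abundances
#'
#' Sums the (mobility-resolved) member-peak areas of every series
#' assigned to a unique oligomer order and reports percentages of the
#' total considered intensity, plus the per-charge-state contributions.
#' Because peaks keep their drift coordinate through picking and series
#' detection, series overlapping in m/z but separated in drift are
#' integrated independently. Series matched to more than one order
#' (joint, unresolvable in either dimension) are excluded from the
#' percentages and reported in `excluded`.
#'
#' @param assignments From [assign_species()].
#' @param series The matching series list.
#' @return Object of class `abundance_table`: `table` (order, area,
#'   percent), `by_charge` (order, z, area, percent_of_total),
#'   `excluded` (series ids left out).
#' @export
quantify_abundances <- function(assignments, series) {
  stopifnot(nrow(assignments) > 0)
  ok <- !is.na(assignments$order)
  if (!any(ok)) stop("no uniquely assigned series to quantify")
  total <- sum(assignments$area[ok])
  per_z <- do.call(rbind, lapply(which(ok), function(i) {
    s <- series[[assignments$series[i]]]
    data.frame(order = assignments$order[i], z = s$members$z,
               area = s$members$area)
  }))
  by_charge <- stats::aggregate(area ~ order + z, per_z, sum)
  by_charge <- by_charge[order(by_charge$order, by_charge$z), ]
  by_charge$percent_of_total <- 100 * by_charge$area / total
  tab <- stats::aggregate(area ~ order, per_z, sum)
  tab$percent <- 100 * tab$area / total
  rownames(by_charge) <- rownames(tab) <- NULL
  structure(list(table = tab, by_charge = by_charge,
                 excluded = assignments$series[!ok],
                 considered_total = total),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat("<abundance_table> percent of total considered intensity:\n")
  print(x$table[, c("order", "percent")], row.names = FALSE)
  if (length(x$excluded) > 0)
    cat("excluded (joint/unassigned) series:",
        paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' Extract per-order CCS from mobility data
#'
#' For each uniquely assigned order, takes the charge state with the
#' highest peak intensity and converts its drift time to a CCS with the
#' supplied calibration (the conventional per-group reporting choice).
#'
#' @param assignments From [assign_species()].
#' @param series The matching series list.
#' @param fit A [fit_calibration()] result.
#' @return data.frame with `order`, `z`, `mz`, `drift`, `ccs`, `ccs_se`,
#'   `extrapolated`.
#' @export
series_ccs <- function(assignments, series, fit) {
  ok <- which(!is.na(assignments$order))
  out <- lapply(ok, function(i) {
    s <- series[[assignments$series[i]]]
    j <- which.max(s$members$area)
    m <- s$members[j, ]
    cal <- apply_calibration(fit, m$drift, m$mz, m$z,
                             m_ion = s$neutral_mass + m$z * .PROTON_MASS)
    data.frame(order = assignments$order[i], z = m$z, mz = m$mz,
               drift = m$drift, ccs = cal$ccs, ccs_se = cal$ccs_se,
               extrapolated = cal$extrapolated)
  })
  res <- do.call(rbind, out)
  res[order(res$order), ]
}

#' Write a peak list CSV
#'
#' @param peaks A `peak_list`.
#' @param path Output path.
#' @export
write_peaklist <- function(peaks, path) {
  write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  df <- read.csv(path)
  stopifnot(all(c("mz", "area") %in% names(df)))
  if (!"drift" %in% names(df)) df$drift <- NA_real_
  if (!"height" %in% names(df)) df$height <- df$area
  df <- df[order(df$mz), c("mz", "drift", "height", "area")]
  class(df) <- c("peak_list", "data.frame")
  df
}
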