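# Cyclic strand connectivity of the helix-bundle design and enumeration
# of the contiguous oligomer compositions that can exist along the
# assembly pathway.

#' Cyclic strand-connectivity map
#'
#' In the six-helix-bundle design, each strand pairs with its two cyclic
#' neighbours over 21-bp duplex regions, so the six strands form a single
#' cycle. Any partial assembly is a contiguous run of strands on that
#' cycle.
#'
#' @param labels Strand labels in cycle order (adjacent labels pair).
#' @param duplex_len Base pairs per pairwise duplex region (default 21).
#' @return An object of class `connectivity_map`.
#' @examples
#' connectivity_map(c("I", "II", "III", "IV", "V", "VI"))
#' @export
connectivity_map <- function(labels = c("I", "II", "III", "IV", "V", "VI"),
                             duplex_len = 21) {
  stopifnot(is.character(labels), length(labels) >= 1,
            !anyDuplicated(labels), duplex_len >= 1)
  structure(list(n_strands = length(labels), adjacency = labels,
                 duplex_len = as.integer(duplex_len)),
            class = "connectivity_map")
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat(sprintf("<connectivity_map> %d strands on a cycle (%s), %d bp duplexes\n",
              x$n_strands, paste(x$adjacency, collapse = "-"), x$duplex_len))
  invisible(x)
}

#' An oligomer composition (contiguous run on the cycle)
#'
#' @param members Strand labels, consecutive on the cycle.
#' @param map The [connectivity_map()] the run lives on.
#' @return Object of class `oligomer_composition` with fields `members`,
#'   `order_k` and `closed` (TRUE iff the run is the full ring).
#' @export
oligomer_composition <- function(members, map) {
  stopifnot(inherits(map, "connectivity_map"))
  k <- length(members)
  if (k < 1 || k > map$n_strands)
    stop("run length must be in 1..", map$n_strands)
  if (!all(members %in% map$adjacency))
    stop("unknown strand label(s): ",
         paste(setdiff(members, map$adjacency), collapse = ", "))
  if (k < map$n_strands) {
    start <- match(members[1], map$adjacency)
    idx <- ((start - 1 + seq_len(k) - 1) %% map$n_strands) + 1
    if (!identical(map$adjacency[idx], members))
      stop("members are not consecutive on the cycle: ",
           paste(members, collapse = "-"))
  }
  structure(list(members = members, order_k = k,
                 closed = (k == map$n_strands)),
            class = "oligomer_composition")
}

#' @export
print.oligomer_composition <- function(x, ...) {
  cat(sprintf("<oligomer_composition> k=%d%s: %s\n", x$order_k,
              if (x$closed) " (closed ring)" else "",
              paste(x$members, collapse = "-")))
  invisible(x)
}

#' Enumerate all contiguous k-mers on the cycle
#'
#' For k < n there are exactly n distinct runs (one per start strand); for
#' k = n the rotations of the full ring are identified, giving a single
#' closed species. The pentamer (k = 5 on a 6-cycle) is a perfectly valid
#' enumerable species here; its experimental absence is a property of the
#' data (cooperativity), not of the model.
#'
#' @param map A [connectivity_map()].
#' @param k Oligomer order, 1..n_strands.
#' @return List of [oligomer_composition()] objects.
#' @examples
#' length(enumerate_oligomers(connectivity_map(), 3))  # 6 distinct trimers
#' @export
enumerate_oligomers <- function(map, k) {
  stopifnot(inherits(map, "connectivity_map"))
  if (k < 1 || k > map$n_strands)
    stop("k must be in 1..", map$n_strands, ", got ", k)
  n <- map$n_strands
  if (k == n)
    return(list(oligomer_composition(map$adjacency, map)))
  lapply(seq_len(n), function(start) {
    idx <- ((start - 1 + seq_len(k) - 1) %% n) + 1
    oligomer_composition(map$adjacency[idx], map)
  })
}

#' Enumerate every distinct species across all orders
#'
#' @param map A [connectivity_map()].
#' @return List of [oligomer_composition()] objects over k = 1..n; the
#'   total count is n * (n - 1) + 1 (31 for the six-strand design).
#' @export
enumerate_all_oligomers <- function(map) {
  unlist(lapply(seq_len(map$n_strands), enumerate_oligomers, map = map),
         recursive = FALSE)
}

#' Mass of a non-covalent oligomer
#'
#' Sum of member strand masses. The complexes are held together by base
#' pairing, not new covalent bonds, so no condensation correction applies.
#'
#' @param comp An [oligomer_composition()].
#' @param strand_masses Named numeric vector, label -> mass in Da.
#' @return Mass in Da.
#' @export
oligomer_mass <- function(comp, strand_masses) {
  stopifnot(inherits(comp, "oligomer_composition"))
  missing <- setdiff(comp$members, names(strand_masses))
  if (length(missing) > 0)
    stop("no mass for strand(s): ", paste(missing, collapse = ", "))
  sum(strand_masses[comp$members])
}

#' Multimer of a closed ring
#'
#' Describes species made of several copies of the complete ring, e.g. the
#' 12-mer and 18-mer with double and triple the hexamer mass.
#'
#' @param base A closed [oligomer_composition()].
#' @param copies Positive integer number of ring copies.
#' @param strand_masses Optional named masses to compute the total mass.
#' @return List with `members` (repeated), `order_k`, `copies`, `label`
#'   (e.g. `"12-mer"`), and `mass` when masses were given.
#' @export
multimer_composition <- function(base, copies, strand_masses = NULL) {
  stopifnot(inherits(base, "oligomer_composition"))
  if (!base$closed)
    stop("multimers are built from the closed ring; got an open ", base$order_k, "-mer")
  if (length(copies) != 1 || copies != as.integer(copies) || copies < 1)
    stop("copies must be a positive integer")
  copies <- as.integer(copies)
  k <- base$order_k * copies
  out <- list(members = rep(base$members, copies), order_k = k,
              copies = copies, label = paste0(k, "-mer"))
  if (!is.null(strand_masses))
    out$mass <- copies * oligomer_mass(base, strand_masses)
  out
}

#' Species table over the assembly pathway
#'
#' Builds a table of all contiguous oligomer species (orders 1..n) plus
#' ring multimers, with per-species masses. Within an order, the
#' composition variants (e.g. the six distinct trimers) are listed
#' individually; the representative `mass` used for order-level work is
#' carried per row so near-degenerate variants stay distinguishable.
#'
#' @param map A [connectivity_map()].
#' @param strand_masses Named numeric vector, label -> Da.
#' @param multimer_copies Integer vector of ring multiples to append
#'   (default `c(2, 3)`, the 12-mer and 18-mer).
#' @return data.frame with columns `label`, `order`, `members`, `mass`,
#'   `closed`.
#' @export
species_table <- function(map, strand_masses, multimer_copies = c(2, 3)) {
  sp <- enumerate_all_oligomers(map)
  df <- data.frame(
    label = vapply(sp, function(s) paste(s$members, collapse = "-"), ""),
    order = vapply(sp, function(s) s$order_k, 0L),
    members = vapply(sp, function(s) paste(s$members, collapse = "-"), ""),
    mass = vapply(sp, oligomer_mass, 0, strand_masses = strand_masses),
    closed = vapply(sp, function(s) s$closed, TRUE),
    stringsAsFactors = FALSE)
  ring <- sp[[length(sp)]]
  for (cp in multimer_copies) {
    mm <- multimer_composition(ring, cp, strand_masses)
    df <- rbind(df, data.frame(label = mm$label, order = mm$order_k,
                               members = mm$label, mass = mm$mass,
                               closed = TRUE, stringsAsFactors = FALSE))
  }
  df
}
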