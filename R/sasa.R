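#' Deterministic quasi-uniform points on the unit sphere
#'
#' Golden-section spiral; the same point set is used for every atom so SASA
#' values are bit-stable across runs.
#'
#' @param n Number of points (>= 1).
#' @return n x 3 matrix of unit vectors.
#' @keywords internal
sphere_points <- function(n) {
  i <- seq_len(n) - 1
  z <- 1 - (2 * i + 1) / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

.atoms_of <- function(x) {
  if (inherits(x, "structure_model")) x$atoms
  else if (inherits(x, "element")) x$atoms
  else if (is.data.frame(x)) x
  else stop("cannot extract atoms from object of class ", class(x)[1])
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Rolls a probe sphere (default 1.4 Angstrom, water-sized) over the atom
#' set: each atom's solvent-expanded sphere is sampled with a deterministic
#' golden-spiral point set and a point counts as accessible when it lies
#' outside every neighbouring expanded sphere.
#'
#' @param atoms A `structure_model`, `element`, or atom data frame with
#'   columns `x`, `y`, `z`, `radius`.
#' @param probe_radius Probe radius in Angstrom.
#' @param n_sphere_points Quadrature points per atom (>= 32).
#' @return A `sasa_result`: list with `total_area`, `per_atom_area` (both in
#'   square Angstrom), `probe_radius`, `n_sphere_points`.
#' @export
shrake_rupley_sasa <- function(atoms, probe_radius = 1.4,
                               n_sphere_points = 960) {
  a <- .atoms_of(atoms)
  if (nrow(a) == 0L) stop("empty atom set")
  if (n_sphere_points < 32L) stop("n_sphere_points must be >= 32")
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  r <- a$radius + probe_radius
  n <- nrow(xyz)
  pts <- sphere_points(n_sphere_points)
  d <- as.matrix(stats::dist(xyz))
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    if (length(nb) == 0L) {
      per_atom[i] <- 4 * pi * r[i]^2
      next
    }
    p <- pts * r[i]
    p <- cbind(p[, 1] + xyz[i, 1], p[, 2] + xyz[i, 2], p[, 3] + xyz[i, 3])
    acc <- rep(TRUE, n_sphere_points)
    # closest neighbours first: they remove the most points
    for (j in nb[order(d[i, nb])]) {
      if (!any(acc)) break
      dx <- p[acc, 1, drop = FALSE] - xyz[j, 1]
      dy <- p[acc, 2, drop = FALSE] - xyz[j, 2]
      dz <- p[acc, 3, drop = FALSE] - xyz[j, 3]
      acc[acc] <- (dx * dx + dy * dy + dz * dz) >= r[j]^2
    }
    per_atom[i] <- sum(acc) / n_sphere_points * 4 * pi * r[i]^2
  }
  structure(list(total_area = sum(per_atom), per_atom_area = per_atom,
                 probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points)),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("SASA: %.2f A^2 over %d atoms (probe %.2f A, %d points)\n",
              x$total_area, length(x$per_atom_area), x$probe_radius,
              x$n_sphere_points))
  invisible(x)
}

#' Buried surface area between two elements
#'
#' SASA(a) + SASA(b) - SASA(a united with b): the area each element hides
#' from solvent by the presence of the other. Positive burial means physical
#' contact; values are symmetric in the two arguments and never more than a
#' quadrature tolerance below zero.
#'
#' @param elem_a,elem_b Elements (or atom data frames) with disjoint atoms.
#' @inheritParams shrake_rupley_sasa
#' @return Buried area in square Angstrom.
#' @export
buried_area <- function(elem_a, elem_b, probe_radius = 1.4,
                        n_sphere_points = 960) {
  a <- .atoms_of(elem_a)
  b <- .atoms_of(elem_b)
  sa <- shrake_rupley_sasa(a, probe_radius, n_sphere_points)$total_area
  sb <- shrake_rupley_sasa(b, probe_radius, n_sphere_points)$total_area
  sab <- shrake_rupley_sasa(rbind(a[, c("x", "y", "z", "radius")],
                                  b[, c("x", "y", "z", "radius")]),
                            probe_radius, n_sphere_points)$total_area
  sa + sb - sab
}

# bounding sphere (centre, radius incl. vdw) of an element's atoms
.bounding_sphere <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  ctr <- colMeans(xyz)
  dev <- sqrt(rowSums(sweep(xyz, 2, ctr)^2)) + atoms$radius
  list(centre = ctr, radius = max(dev))
}

#' Call pairwise element-element interactions by buried area
#'
#' Evaluates every unordered element pair once; a pair interacts when pairing
#' buries more than `min_buried_area` of solvent-accessible area. Pairs whose
#' bounding spheres are separated by more than twice the probe radius cannot
#' bury any area and are called non-interacting without SASA evaluation.
#' Multiple atomic contacts between the same pair yield a single call.
#'
#' @param elements List of `element` objects (>= 2).
#' @inheritParams shrake_rupley_sasa
#' @param min_buried_area Burial threshold in square Angstrom; a small
#'   positive floor absorbs quadrature noise.
#' @param prune Use the bounding-sphere short cut (exact, only faster).
#' @return Data frame with columns `element_a`, `element_b`, `buried_area`,
#'   `is_interaction`, one row per unordered pair, with the parameters kept
#'   in attribute `params`.
#' @export
detect_interactions <- function(elements, probe_radius = 1.4,
                                n_sphere_points = 960,
                                min_buried_area = 0.1, prune = TRUE) {
  stopifnot(is.list(elements))
  nm <- vapply(elements, function(e) e$name, "")
  k <- length(elements)
  if (k < 1L) stop("no elements")
  if (k == 1L) {
    out <- data.frame(element_a = character(), element_b = character(),
                      buried_area = numeric(), is_interaction = logical())
  } else {
    bs <- lapply(elements, function(e) .bounding_sphere(e$atoms))
    pairs <- utils::combn(k, 2)
    ba <- numeric(ncol(pairs))
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1, q]; j <- pairs[2, q]
      if (prune) {
        gap <- sqrt(sum((bs[[i]]$centre - bs[[j]]$centre)^2)) -
          bs[[i]]$radius - bs[[j]]$radius
        if (gap > 2 * probe_radius) { ba[q] <- 0; next }
      }
      ba[q] <- buried_area(elements[[i]], elements[[j]],
                           probe_radius, n_sphere_points)
    }
    out <- data.frame(element_a = nm[pairs[1, ]], element_b = nm[pairs[2, ]],
                      buried_area = ba,
                      is_interaction = ba > min_buried_area,
                      stringsAsFactors = FALSE)
  }
  attr(out, "params") <- list(probe_radius = probe_radius,
                              n_sphere_points = n_sphere_points,
                              min_buried_area = min_buried_area)
  out
}

#' Write / read an interaction table
#'
#' Tab-separated `element_a`, `element_b`, `buried_area`, `is_interaction`;
#' the same format is read back to skip SASA recomputation.
#'
#' @param calls Data frame from [detect_interactions()].
#' @param path File path.
#' @return `path` invisibly (write); the calls data frame (read).
#' @export
write_interactions <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions
#' @export
read_interactions <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("element_a", "element_b", "buried_area", "is_interaction")
  if (!all(need %in% names(out)))
    stop("interaction table lacks column(s): ",
         paste(setdiff(need, names(out)), collapse = ", "))
  out$is_interaction <- as.logical(out$is_interaction)
  out
}
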