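#' Parameters for solvent-accessible surface area calculation
#'
#' Shrake-Rupley numerical SASA: each atom's surface is sampled with a
#' deterministic golden-spiral point set on the solvent-expanded sphere
#' (van der Waals radius + probe radius) and points buried inside any
#' neighbouring expanded sphere are discounted.
#'
#' @param probe_radius Solvent probe radius in Angstrom (default 1.4, water).
#' @param sphere_points Points per atom sphere (default 960).
#' @param radius_set Named vector of van der Waals radii per element symbol,
#'   Angstrom. Defaults to the Bondi set for common protein elements.
#' @return List of class `sasa_params`.
#' @export
sasa_params <- function(probe_radius = 1.4, sphere_points = 960,
                        radius_set = bondi_radii()) {
  stopifnot(probe_radius >= 0, sphere_points >= 64)
  structure(list(probe_radius = probe_radius, sphere_points = sphere_points,
                 radius_set = radius_set), class = "sasa_params")
}

#' Bondi van der Waals radii for common protein/ligand elements (Angstrom)
#' @return Named numeric vector.
#' @export
bondi_radii <- function() {
  c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_point_set <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Computes per-atom SASA for `atom_ids`, occluded by the atoms in
#' `context_ids` (default: the same set). Adding atoms to the context can
#' only bury surface, never expose it.
#'
#' @param frame Coordinates `n_atoms x 3`, Angstrom.
#' @param topology Topology tibble (elements used for radii).
#' @param atom_ids Atoms whose area is reported.
#' @param params [sasa_params()].
#' @param context_ids Atoms that occlude (must contain or equal `atom_ids`
#'   conceptually; default `atom_ids`).
#' @return Tibble `atom_id`, `area` (Angstrom^2); total SASA is
#'   `sum(area)`.
#' @export
sasa <- function(frame, topology, atom_ids, params = sasa_params(),
                 context_ids = atom_ids) {
  elems <- topology$element[match(context_ids, topology$atom_id)]
  unknown <- setdiff(unique(elems), names(params$radius_set))
  if (length(unknown) > 0) {
    abort(paste0("No van der Waals radius for element(s): ",
                 paste(unknown, collapse = ", ")))
  }
  radii <- unname(params$radius_set[elems]) + params$probe_radius
  pos <- frame[match(context_ids, topology$atom_id), , drop = FALSE]
  pts <- sphere_point_set(params$sphere_points)
  qidx <- match(atom_ids, context_ids)
  if (anyNA(qidx)) abort("atom_ids must be a subset of context_ids")

  areas <- vapply(qidx, function(i) {
    ri <- radii[i]
    # neighbours whose expanded sphere can reach atom i's surface
    d2 <- rowSums(sweep(pos, 2, pos[i, ])^2)
    nb <- which(d2 < (ri + radii)^2 & seq_along(radii) != i)
    surf <- sweep(pts * ri, 2, pos[i, ], "+")
    if (length(nb) > 0) {
      free <- rep(TRUE, nrow(surf))
      for (j in nb) {
        dj2 <- rowSums(sweep(surf, 2, pos[j, ])^2)
        free <- free & dj2 >= radii[j]^2
        if (!any(free)) break
      }
      frac <- mean(free)
    } else {
      frac <- 1
    }
    frac * 4 * pi * ri^2
  }, numeric(1))
  tibble::tibble(atom_id = atom_ids, area = areas)
}

#' Buried surface area between two atom groups
#'
#' `area_total = SASA(A) + SASA(B) - SASA(A union B)`, each term computed in
#' isolation (group A occluded only by A, etc.). `area_per_side` is half the
#' total — both conventions are reported because published "buried surface
#' area" figures use either.
#'
#' @param frame Coordinates `n_atoms x 3`, Angstrom.
#' @param topology Topology tibble.
#' @param group_a,group_b Disjoint atom-id vectors.
#' @param params [sasa_params()].
#' @return List of class `buried_area_result`: `area_total`, `area_per_side`,
#'   `dsasa_a`, `dsasa_b` (per-group losses), `sasa_a`, `sasa_b`, `sasa_ab`.
#' @export
buried_area <- function(frame, topology, group_a, group_b,
                        params = sasa_params()) {
  if (length(intersect(group_a, group_b)) > 0) {
    abort("Groups must be disjoint for buried-area calculation")
  }
  both <- c(group_a, group_b)
  sa <- sasa(frame, topology, group_a, params)
  sb <- sasa(frame, topology, group_b, params)
  sab_a <- sasa(frame, topology, group_a, params, context_ids = both)
  sab_b <- sasa(frame, topology, group_b, params, context_ids = both)
  total_a <- sum(sa$area); total_b <- sum(sb$area)
  total_ab <- sum(sab_a$area) + sum(sab_b$area)
  area_total <- max(0, total_a + total_b - total_ab)
  structure(list(area_total = area_total,
                 area_per_side = area_total / 2,
                 dsasa_a = total_a - sum(sab_a$area),
                 dsasa_b = total_b - sum(sab_b$area),
                 sasa_a = total_a, sasa_b = total_b, sasa_ab = total_ab),
            class = "buried_area_result")
}

#' @export
print.buried_area_result <- function(x, ...) {
  cat(sprintf("<buried_area> total dSASA %.1f A^2 (per side %.1f A^2)\n",
              x$area_total, x$area_per_side))
  invisible(x)
}
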