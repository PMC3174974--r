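#' Van der Waals radii used for surface-area calculations
#'
#' The Bondi (1964) radius set for the elements occurring in CISD models,
#' with iron assigned 2.00 A (a common working value for protein-bound
#' transition metals). The table in use is named in the attributes of every
#' [sasa()] result.
#'
#' @format Named numeric vector, Angstrom.
#' @export
vdw_radii_bondi <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                     SE = 1.90, FE = 2.00, ZN = 1.39, MG = 1.73)

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom solvent-accessible area by numerical quadrature: each atom's
#' solvent-expanded sphere (radius `r_vdw + probe`) is sampled at `n_points`
#' quasi-uniform points (golden-section spiral), and the accessible area is
#' the fraction of points falling outside every neighbouring expanded
#' sphere. Waters are excluded; het groups (e.g. the [2Fe-2S] cluster) are
#' included by default.
#'
#' @param model A `structure_model`, or an atom data frame.
#' @param probe Probe radius in Angstrom (water, default 1.4).
#' @param n_points Quadrature points per atom (default 960; error scales
#'   roughly as 1/n_points).
#' @param radii Named radius table (Angstrom) by element symbol.
#' @param default_radius Radius for elements missing from `radii`; if `NULL`
#'   (default) an unknown element is an error.
#' @param include_het Include het-group atoms (default TRUE).
#' @return Numeric vector of per-atom areas (A^2) for the retained atoms,
#'   with the retained atom table as attribute `atoms` and the radius-table
#'   name as attribute `radii_set`.
#' @export
sasa <- function(model, probe = 1.4, n_points = 960L,
                 radii = vdw_radii_bondi, default_radius = NULL,
                 include_het = TRUE) {
  a <- if (inherits(model, "structure_model")) model$atoms else model
  a <- a[!a$water, , drop = FALSE]
  if (!include_het) a <- a[!a$het, , drop = FALSE]
  if (nrow(a) == 0L) return(numeric(0))
  r <- unname(radii[a$element])
  if (anyNA(r)) {
    if (is.null(default_radius))
      stop("sasa: no van der Waals radius for element(s): ",
           paste(unique(a$element[is.na(r)]), collapse = ", "))
    r[is.na(r)] <- default_radius
  }
  xyz <- atom_xyz(a)
  re <- r + probe                      # expanded radii
  sph <- sphere_points(n_points)
  n <- nrow(a)
  areas <- numeric(n)
  maxre <- max(re)
  for (i in seq_len(n)) {
    ci <- xyz[i, ]
    d2 <- colSums((t(xyz) - ci)^2)
    nb <- which(d2 < (re[i] + maxre)^2 & seq_len(n) != i)
    nb <- nb[sqrt(d2[nb]) < re[i] + re[nb]]
    if (length(nb) == 0L) {
      areas[i] <- 4 * pi * re[i]^2
      next
    }
    pts <- sweep(sph * re[i], 2, ci, "+")        # n_points x 3
    free <- rep(TRUE, nrow(pts))
    for (j in nb) {
      if (!any(free)) break
      dj2 <- colSums((t(pts[free, , drop = FALSE]) - xyz[j, ])^2)
      free[free] <- dj2 >= re[j]^2
    }
    areas[i] <- 4 * pi * re[i]^2 * sum(free) / n_points
  }
  attr(areas, "atoms") <- a
  attr(areas, "radii_set") <- "Bondi (1964), Fe 2.00 A"
  areas
}

# golden-section spiral: n quasi-uniform points on the unit sphere
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Interface area buried on dimerization
#'
#' For each chain, the buried area is its solvent-accessible area computed
#' in isolation minus its accessible area in the two-chain complex (waters
#' and other chains excluded throughout).
#'
#' @param model A `structure_model` containing both chains.
#' @param chainA,chainB Chain identifiers.
#' @param ... Passed to [sasa()] (probe, n_points, radii, ...).
#' @return Named numeric vector `c(perA, perB)` in A^2.
#' @export
buried_area <- function(model, chainA, chainB, ...) {
  a <- model$atoms[!model$atoms$water, , drop = FALSE]
  for (ch in c(chainA, chainB))
    if (!any(a$chain == ch)) stop("buried_area: chain '", ch, "' absent")
  atA <- a[a$chain == chainA, , drop = FALSE]
  atB <- a[a$chain == chainB, , drop = FALSE]
  sasa_sum <- function(at) sum(sasa(at, ...))
  complexAB <- rbind(atA, atB)
  cx <- sasa(complexAB, ...)
  inA <- seq_len(nrow(atA))
  perA <- sasa_sum(atA) - sum(cx[inA])
  perB <- sasa_sum(atB) - sum(cx[-inA])
  c(perA = perA, perB = perB)
}
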