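#' Crystallographic symmetry information from a PDB header
#'
#' Parses the `CRYST1` cell and the `REMARK 290 SMTRY` operator records.
#' SMTRY operators apply directly to the deposited orthogonal coordinates;
#' neighbouring symmetry mates may additionally require integer lattice
#' translations along the (orthogonalized) cell vectors.
#'
#' @param path Path to a PDB file.
#' @return List with `cell` (a, b, c, alpha, beta, gamma), `ortho` (3 x 3
#'   matrix of cell vectors as rows, Angstrom) and `ops`: a list of
#'   `list(R, t)` operators (`R` 3 x 3, `t` length 3), identity first.
#' @export
crystal_symmetry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cr <- grep("^CRYST1", lines, value = TRUE)
  if (length(cr) == 0L) stop("no CRYST1 record in ", path)
  cell <- as.numeric(c(substr(cr[1], 7, 15), substr(cr[1], 16, 24),
                       substr(cr[1], 25, 33), substr(cr[1], 34, 40),
                       substr(cr[1], 41, 47), substr(cr[1], 48, 54)))
  names(cell) <- c("a", "b", "c", "alpha", "beta", "gamma")
  sm <- grep("^REMARK 290 +SMTRY", lines, value = TRUE)
  ops <- list()
  if (length(sm) >= 3L) {
    toks <- lapply(strsplit(trimws(sm), "\\s+"), function(t) t[-(1:2)])
    opno <- vapply(toks, function(t) as.integer(t[2]), 0L)
    rowno <- vapply(toks, function(t) as.integer(sub("SMTRY", "", t[1])), 0L)
    for (k in unique(opno)) {
      sel <- which(opno == k)
      sel <- sel[order(rowno[sel])]               # SMTRY1..3
      m <- t(vapply(toks[sel], function(t) as.numeric(t[3:6]), numeric(4)))
      ops[[length(ops) + 1L]] <- list(R = m[, 1:3, drop = FALSE],
                                      t = m[, 4])
    }
  }
  if (length(ops) == 0L) ops <- list(list(R = diag(3), t = c(0, 0, 0)))
  # orthogonalized cell vectors (rows), standard PDB frame
  al <- cell["alpha"] * pi / 180; be <- cell["beta"] * pi / 180
  ga <- cell["gamma"] * pi / 180
  v <- sqrt(1 - cos(al)^2 - cos(be)^2 - cos(ga)^2 +
              2 * cos(al) * cos(be) * cos(ga))
  ortho <- rbind(
    c(cell["a"], 0, 0),
    c(cell["b"] * cos(ga), cell["b"] * sin(ga), 0),
    c(cell["c"] * cos(be),
      cell["c"] * (cos(al) - cos(be) * cos(ga)) / sin(ga),
      cell["c"] * v / sin(ga)))
  dimnames(ortho) <- NULL
  list(cell = cell, ortho = ortho, ops = ops)
}

#' Apply a symmetry operator (plus lattice shift) to a model
#'
#' @param model A `structure_model`.
#' @param op An operator `list(R, t)` in orthogonal coordinates (column
#'   convention, `x' = R x + t`), e.g. from [crystal_symmetry()].
#' @param shift Integer lattice translation `(u, v, w)` in cell vectors.
#' @param ortho 3 x 3 matrix of orthogonalized cell vectors (rows).
#' @param chain_suffix Appended to every chain id of the mate.
#' @return The transformed `structure_model`.
#' @export
apply_symmetry <- function(model, op, shift = c(0, 0, 0),
                           ortho = diag(3) * 0, chain_suffix = "s") {
  xyz <- atom_xyz(model$atoms)
  moved <- t(op$R %*% t(xyz)) +
    matrix(op$t, nrow(xyz), 3, byrow = TRUE)
  if (any(shift != 0))
    moved <- moved + matrix(drop(shift %*% ortho), nrow(xyz), 3,
                            byrow = TRUE)
  out <- model
  out$atoms$x <- moved[, 1]; out$atoms$y <- moved[, 2]
  out$atoms$z <- moved[, 3]
  out$atoms$chain <- paste0(model$atoms$chain, chain_suffix)
  out
}

#' Closest crystallographic symmetry mate of a monomer
#'
#' Enumerates all header symmetry operators combined with lattice shifts in
#' `{-1,0,1}^3`, drops the identity, and returns the combined model
#' (original + mate) for the mate making the most atom contacts within
#' `d_max` — the crystallographic dimer partner for structures with one
#' molecule per asymmetric unit. The operator used is recorded in the
#' result's `sym_op` element.
#'
#' @param model A `structure_model` (from the same file as `path`).
#' @param path The PDB file whose header supplies cell and operators.
#' @param d_max Contact cutoff in Angstrom for ranking mates.
#' @return A `structure_model` containing the original chains plus the best
#'   mate (chain ids suffixed `"s"`), with `sym_op` describing the operator
#'   and shift used.
#' @export
best_crystal_mate <- function(model, path, d_max = 4.5) {
  sym <- crystal_symmetry(path)
  xyz <- atom_xyz(model$atoms[!model$atoms$water, , drop = FALSE])
  best <- NULL
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_along(sym$ops)) {
    op <- sym$ops[[i]]
    for (s in seq_len(nrow(shifts))) {
      sh <- shifts[s, ]
      if (i == 1L && all(sh == 0) &&
          all(abs(op$R - diag(3)) < 1e-8) && all(abs(op$t) < 1e-8))
        next
      moved <- t(op$R %*% t(xyz)) +
        matrix(op$t + drop(sh %*% sym$ortho), nrow(xyz), 3, byrow = TRUE)
      # quick reject by bounding boxes before counting contacts
      if (any(apply(moved, 2, min) > apply(xyz, 2, max) + d_max) ||
          any(apply(moved, 2, max) < apply(xyz, 2, min) - d_max))
        next
      ncont <- nrow(grid_pairs(xyz, moved, d_max))
      if (ncont > 0L && (is.null(best) || ncont > best$n))
        best <- list(n = ncont, op = op, shift = sh)
    }
  }
  if (is.null(best))
    stop("no contacting symmetry mate found for ", path)
  mate <- apply_symmetry(model, best$op, best$shift, sym$ortho)
  out <- model
  out$atoms <- rbind(model$atoms, mate$atoms)
  rownames(out$atoms) <- NULL
  out$sym_op <- best[c("op", "shift", "n")]
  out
}
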