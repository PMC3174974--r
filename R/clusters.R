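#' Detect [2Fe-2S] clusters in a structure
#'
#' Clusters are taken from het-groups named `FES` or `FE2` (the PDB chemical
#' component ids for a [2Fe-2S] cluster). If no such residue exists, clusters
#' are assembled de novo from het-group Fe atoms and inorganic sulfur atoms
#' within `pair_cutoff` of an iron. A valid cluster has exactly 2 Fe and 2 S
#' atoms with all pairwise distances below 5 A; Fe atoms without a sulfur
#' partner are excluded with a warning.
#'
#' @param model A `structure_model`.
#' @param pair_cutoff Fe-S association cutoff in Angstrom for de novo
#'   assembly (default 3.5).
#' @return A list of `fes_cluster` objects, each with `atoms` (4-row atom
#'   data frame), `centroid` (length-3, mean of the 4 atoms) and `chain`.
#' @export
find_clusters <- function(model, pair_cutoff = 3.5) {
  het <- model$atoms[model$atoms$het, , drop = FALSE]
  if (nrow(het) == 0L) return(list())
  named <- het[het$resid %in% c("FES", "FE2"), , drop = FALSE]
  groups <- list()
  if (nrow(named) > 0L) {
    key <- paste(named$chain, named$resno, named$insert)
    groups <- split(named, key)
  } else {
    fe <- het[het$element == "FE", , drop = FALSE]
    ss <- het[het$element == "S", , drop = FALSE]
    if (nrow(fe) == 0L) return(list())
    # connected components of the Fe/S graph under the pair cutoff
    pool <- rbind(fe, ss)
    xyz <- atom_xyz(pool)
    n <- nrow(pool)
    comp <- seq_len(n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      if (sum((xyz[i, ] - xyz[j, ])^2) < pair_cutoff^2) {
        old <- comp[j]; comp[comp == old] <- comp[i]
      }
    }
    groups <- split(pool, comp)
  }
  out <- list()
  for (g in groups) {
    nfe <- sum(g$element == "FE"); ns <- sum(g$element == "S")
    if (nfe != 2L || ns != 2L) {
      warning(sprintf(
        "skipping incomplete iron-sulfur group (%d Fe, %d S) near chain %s",
        nfe, ns, g$chain[1]))
      next
    }
    xyz <- atom_xyz(g)
    if (max(stats::dist(xyz)) >= 5)
      stop("iron-sulfur group with pairwise distance >= 5 A; not a [2Fe-2S] cluster")
    cl <- list(atoms = g, centroid = colMeans(xyz), chain = g$chain[1])
    class(cl) <- "fes_cluster"
    out[[length(out) + 1L]] <- cl
  }
  # stable order: chain, then residue number of first atom
  if (length(out) > 1L) {
    ord <- order(vapply(out, function(cl) cl$chain, ""),
                 vapply(out, function(cl) as.numeric(cl$atoms$resno[1]), 0))
    out <- out[ord]
  }
  out
}

#' Assign protein ligands to a [2Fe-2S] cluster
#'
#' Candidate coordinating atoms are the cysteine Sgamma and histidine
#' Ndelta1/Nepsilon2 side-chain atoms; a residue is a ligand when such an
#' atom lies within `cutoff` of either iron. The default 3.0 A leaves margin
#' over typical Fe-Sgamma (~2.3 A) and Fe-N (~2.1 A) bond lengths.
#'
#' @param model A `structure_model`.
#' @param cluster A `fes_cluster` from [find_clusters()].
#' @param cutoff Fe-to-ligand-atom heavy-atom cutoff in Angstrom.
#' @return A data frame of ligands sorted by residue number (`chain`,
#'   `resno`, `insert`, `resid`, `elety`, `dist`), with attribute
#'   `coordination` such as `"3Cys1His"`. More than four candidates keeps the
#'   four nearest with a warning; none returns an empty frame with a warning.
#' @export
assign_ligands <- function(model, cluster, cutoff = 3.0) {
  a <- model$atoms
  cand <- a[(a$resid == "CYS" & a$elety == "SG") |
            (a$resid == "HIS" & a$elety %in% c("ND1", "NE2")), , drop = FALSE]
  fe <- atom_xyz(cluster$atoms[cluster$atoms$element == "FE", , drop = FALSE])
  if (nrow(cand) == 0L) {
    warning("no candidate ligand atoms in model")
    return(empty_ligands())
  }
  cx <- atom_xyz(cand)
  d <- apply(cx, 1, function(p) sqrt(min(colSums((t(fe) - p)^2))))
  hit <- cand[d <= cutoff, , drop = FALSE]
  dhit <- d[d <= cutoff]
  if (nrow(hit) == 0L) {
    warning("no ligand residue within ", cutoff, " A of cluster")
    return(empty_ligands())
  }
  # one entry per residue, nearest atom
  key <- paste(hit$chain, hit$resno, hit$insert)
  ord <- order(dhit)
  hit <- hit[ord, , drop = FALSE]; dhit <- dhit[ord]; key <- key[ord]
  keep <- !duplicated(key)
  hit <- hit[keep, , drop = FALSE]; dhit <- dhit[keep]
  if (nrow(hit) > 4L) {
    warning(nrow(hit), " candidate ligand residues; keeping the 4 nearest")
    hit <- hit[1:4, , drop = FALSE]; dhit <- dhit[1:4]
  }
  ord <- order(hit$chain, hit$resno, hit$insert)
  out <- data.frame(chain = hit$chain, resno = hit$resno,
                    insert = hit$insert, resid = hit$resid,
                    elety = hit$elety, dist = dhit,
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  rownames(out) <- NULL
  ncys <- sum(out$resid == "CYS"); nhis <- sum(out$resid == "HIS")
  attr(out, "coordination") <- paste0(
    if (ncys) paste0(ncys, "Cys") else "",
    if (nhis) paste0(nhis, "His") else "")
  out
}

empty_ligands <- function() {
  out <- data.frame(chain = character(), resno = integer(),
                    insert = character(), resid = character(),
                    elety = character(), dist = numeric(),
                    stringsAsFactors = FALSE)
  attr(out, "coordination") <- ""
  out
}

#' Extract the iron-sulfur binding module around a cluster
#'
#' The module is anchored at the first cysteine ligand, which occupies motif
#' position 2 of the 17-residue CDGSH motif; the Calpha window therefore runs
#' from the residue before it (position 1, the hydrophobic Phi1) to position
#' 17 (the histidine ligand), i.e. author residues `C2-1 .. C2+15`.
#'
#' @param model A `structure_model`.
#' @param cluster A `fes_cluster`.
#' @param cutoff Passed to [assign_ligands()].
#' @return An `fes_module`: list with `cluster`, `ligands`, `chain`,
#'   `resnos` (the 17 residue numbers) and `ca_segment` (17 x 3 Calpha
#'   coordinate matrix, motif positions 1-17 in order).
#' @export
extract_module <- function(model, cluster, cutoff = 3.0) {
  lig <- assign_ligands(model, cluster, cutoff)
  cys <- lig[lig$resid == "CYS", , drop = FALSE]
  if (nrow(cys) == 0L) stop("extract_module: no cysteine ligand to anchor on")
  c2 <- cys$resno[1]
  chain <- cys$chain[1]
  resnos <- (c2 - 1L):(c2 + 15L)
  a <- model$atoms
  ca <- a[!a$het & !a$water & a$chain == chain & a$elety == "CA" &
          a$resno %in% resnos, , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  missing <- setdiff(resnos, ca$resno)
  if (length(missing) > 0L)
    stop("extract_module: chain break, missing Calpha for residue(s) ",
         paste(missing, collapse = ", "), " in chain ", chain)
  out <- list(cluster = cluster, ligands = lig, chain = chain,
              resnos = resnos, ca_segment = atom_xyz(ca))
  class(out) <- "fes_module"
  out
}

#' Extract all iron-sulfur binding modules of a model
#'
#' @param model A `structure_model`.
#' @param cutoff Passed to [assign_ligands()].
#' @return List of `fes_module` objects, one per detected cluster.
#' @export
extract_modules <- function(model, cutoff = 3.0) {
  lapply(find_clusters(model), function(cl) extract_module(model, cl, cutoff))
}

#' Center-to-center distance between two [2Fe-2S] clusters
#'
#' @param c1,c2 `fes_cluster` objects.
#' @return Euclidean distance between the 4-atom centroids, in Angstrom.
#' @export
cluster_distance <- function(c1, c2) {
  sqrt(sum((c1$centroid - c2$centroid)^2))
}

#' Shift angle between the second iron-sulfur modules of two structures
#'
#' Both structures must carry exactly two iron-sulfur binding modules. One
#' target module is superposed onto one reference module by its 17 Calpha
#' atoms (the best of the up-to-4 module pairings by anchor RMSD); the
#' reported angle is measured at the aligned cluster centroid, between the
#' vector to the reference partner's cluster centroid and the vector to the
#' transformed target partner's cluster centroid. This quantifies how far the
#' second cluster "swings" around the common module when structures of
#' different CISD types are aligned on one module.
#'
#' @param ref,target `structure_model` objects with two modules each.
#' @param cutoff Passed to [extract_module()].
#' @return Angle in degrees, in `[0, 180]`.
#' @export
intermodule_angle <- function(ref, target, cutoff = 3.0) {
  mr <- extract_modules(ref, cutoff)
  mt <- extract_modules(target, cutoff)
  if (length(mr) != 2L || length(mt) != 2L)
    stop("intermodule_angle: both structures must have exactly 2 modules (",
         length(mr), " and ", length(mt), " found)")
  best <- NULL
  for (i in 1:2) for (j in 1:2) {
    fit <- superpose(mt[[i]]$ca_segment, mr[[j]]$ca_segment)
    if (is.null(best) || fit$rmsd < best$rmsd)
      best <- list(rmsd = fit$rmsd, fit = fit, i = i, j = j)
  }
  vertex <- mr[[best$j]]$cluster$centroid
  v1 <- mr[[3 - best$j]]$cluster$centroid - vertex
  moved <- drop(best$fit$transform(rbind(mt[[3 - best$i]]$cluster$centroid)))
  v2 <- moved - vertex
  ct <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(min(1, max(-1, ct))) * 180 / pi
}

#' Internal pseudo two-fold (dyad) symmetry of a dual-module structure
#'
#' For a tandem-motif monomer or a two-chain dimer, superposes the first
#' module's 17 Calpha atoms plus its 4 cluster atoms onto the second
#' module's, and reports the residual RMSD together with the rotation angle
#' of the fitted transform; a true dyad gives RMSD 0 and 180 degrees.
#'
#' @param model A `structure_model` with exactly two modules.
#' @param cutoff Passed to [extract_module()].
#' @return List with `dyad_rmsd` (Angstrom) and `rotation` (degrees).
#' @export
pseudo_dyad <- function(model, cutoff = 3.0) {
  mods <- extract_modules(model, cutoff)
  if (length(mods) != 2L)
    stop("pseudo_dyad: expected exactly 2 modules, found ", length(mods))
  pts <- function(m) rbind(m$ca_segment, atom_xyz(m$cluster$atoms))
  fit <- superpose(pts(mods[[1]]), pts(mods[[2]]))
  list(dyad_rmsd = fit$rmsd, rotation = rotation_angle(fit$R))
}
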