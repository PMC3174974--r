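#' Detect hydrogen bonds by a heavy-atom distance criterion
#'
#' A pragmatic crystallographer's criterion: any nitrogen/oxygen pair from
#' different residues at a distance of at most `d_max` (default 3.5 A) and
#' more than a covalent bond length apart is reported as a hydrogen bond.
#' Donor/acceptor chemistry is not resolved (hydrogens are stripped on
#' read), so each pair is reported once.
#'
#' @param model A `structure_model`.
#' @param d_max Heavy-atom N/O - N/O distance cutoff in Angstrom.
#' @param selection Optional logical vector over `model$atoms` rows (or a
#'   function taking the atom table and returning one) restricting the atoms
#'   considered.
#' @return Data frame of unique pairs sorted by distance, with columns
#'   describing both atoms and `dist`.
#' @export
detect_hbonds <- function(model, d_max = 3.5, selection = NULL) {
  a <- model$atoms[!model$atoms$water, , drop = FALSE]
  if (!is.null(selection)) {
    keep <- if (is.function(selection)) selection(a) else selection
    a <- a[keep, , drop = FALSE]
  }
  a <- a[a$element %in% c("N", "O"), , drop = FALSE]
  if (nrow(a) < 2L) return(empty_pairs())
  pr <- pair_within(atom_xyz(a), d_max)
  if (nrow(pr) == 0L) return(empty_pairs())
  same_res <- a$chain[pr[, 1]] == a$chain[pr[, 2]] &
    a$resno[pr[, 1]] == a$resno[pr[, 2]] &
    a$insert[pr[, 1]] == a$insert[pr[, 2]]
  covalent <- pr[, 3] < 2.0            # closer than any H-bond: bonded or clash
  pr <- pr[!same_res & !covalent, , drop = FALSE]
  if (nrow(pr) == 0L) return(empty_pairs())
  out <- data.frame(
    chain1 = a$chain[pr[, 1]], resno1 = a$resno[pr[, 1]],
    resid1 = a$resid[pr[, 1]], elety1 = a$elety[pr[, 1]],
    chain2 = a$chain[pr[, 2]], resno2 = a$resno[pr[, 2]],
    resid2 = a$resid[pr[, 2]], elety2 = a$elety[pr[, 2]],
    dist = pr[, 3], stringsAsFactors = FALSE)
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pairs <- function() {
  data.frame(chain1 = character(), resno1 = integer(), resid1 = character(),
             elety1 = character(), chain2 = character(), resno2 = integer(),
             resid2 = character(), elety2 = character(), dist = numeric(),
             stringsAsFactors = FALSE)
}

#' Close inter-chain atom contacts
#'
#' All atom pairs between two chains within `d_max`, found with a uniform
#' cell grid of spacing `d_max` so only neighbouring cells are compared.
#'
#' @param model A `structure_model`.
#' @param chainA,chainB Chain identifiers.
#' @param d_max Distance cutoff in Angstrom (required).
#' @param atom_filter `NULL` for all atoms, `"backbone"` for N/CA/C/O, or a
#'   function over the atom table returning a logical vector.
#' @return Data frame of pairs (atom 1 from `chainA`, atom 2 from `chainB`)
#'   sorted by distance.
#' @export
close_contacts <- function(model, chainA, chainB, d_max, atom_filter = NULL) {
  a <- model$atoms[!model$atoms$water, , drop = FALSE]
  if (!is.null(atom_filter)) {
    keep <- if (is.function(atom_filter)) atom_filter(a)
            else if (identical(atom_filter, "backbone"))
              a$elety %in% c("N", "CA", "C", "O") & !a$het
            else stop("unknown atom_filter")
    a <- a[keep, , drop = FALSE]
  }
  A <- a[a$chain == chainA, , drop = FALSE]
  B <- a[a$chain == chainB, , drop = FALSE]
  if (nrow(A) == 0L || nrow(B) == 0L) return(empty_pairs())
  hits <- grid_pairs(atom_xyz(A), atom_xyz(B), d_max)
  if (nrow(hits) == 0L) return(empty_pairs())
  out <- data.frame(
    chain1 = A$chain[hits[, 1]], resno1 = A$resno[hits[, 1]],
    resid1 = A$resid[hits[, 1]], elety1 = A$elety[hits[, 1]],
    chain2 = B$chain[hits[, 2]], resno2 = B$resno[hits[, 2]],
    resid2 = B$resid[hits[, 2]], elety2 = B$elety[hits[, 2]],
    dist = hits[, 3], stringsAsFactors = FALSE)
  out <- out[order(out$dist), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all (i, j, dist) pairs within one point set
pair_within <- function(xyz, d_max) {
  n <- nrow(xyz)
  d <- as.matrix(stats::dist(xyz))
  idx <- which(upper.tri(d) & d <= d_max, arr.ind = TRUE)
  cbind(idx[, 1], idx[, 2], d[idx])
}

# grid-accelerated cross-set neighbour search
grid_pairs <- function(A, B, d_max) {
  cell <- function(x) paste(floor(x[, 1] / d_max), floor(x[, 2] / d_max),
                            floor(x[, 3] / d_max), sep = ",")
  keyB <- cell(B)
  binB <- split(seq_len(nrow(B)), keyB)
  ga <- floor(A / d_max)
  res <- vector("list", nrow(A))
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  for (i in seq_len(nrow(A))) {
    keys <- paste(ga[i, 1] + offs[, 1], ga[i, 2] + offs[, 2],
                  ga[i, 3] + offs[, 3], sep = ",")
    cand <- unlist(binB[keys], use.names = FALSE)
    if (length(cand) == 0L) next
    d <- sqrt(colSums((t(B[cand, , drop = FALSE]) - A[i, ])^2))
    sel <- d <= d_max
    if (any(sel))
      res[[i]] <- cbind(i, cand[sel], d[sel])
  }
  out <- do.call(rbind, res)
  if (is.null(out)) matrix(numeric(0), ncol = 3) else out
}
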