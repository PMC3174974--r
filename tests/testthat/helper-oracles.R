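# Independent oracles used across the suite. Each deliberately re-derives
# its quantity by a different route than the production code.

# Horn's quaternion method for optimal rigid superposition: the RMSD comes
# from the largest eigenvalue of the 4x4 quaternion matrix, with no SVD and
# no rotation matrix ever formed.
quaternion_rmsd <- function(A, B) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  S <- crossprod(A0, B0)
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]),
    4, 4, byrow = TRUE)
  lmax <- max(eigen(N, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(A0^2) + sum(B0^2) - 2 * lmax) / nrow(A)
  sqrt(max(0, msd))
}

# Sliding-window motif evaluation written as a literal transcription of the
# per-position consensus rules (no vectorization shared with the scanner).
brute_scan_cdgsh <- function(s, max_mismatch = 2L,
                             phi = c("A","C","F","I","L","M","P","V","W","Y")) {
  s <- gsub("-", "", toupper(s))
  rules <- list(`1` = phi, `2` = "C", `4` = "C", `7` = c("S","T"),
                `11` = "P", `12` = phi, `13` = "C", `14` = "D",
                `15` = "G", `16` = c("S","T","A"), `17` = "H")
  hits <- NULL
  for (st in seq_len(max(0, nchar(s) - 16L))) {
    mm <- integer(0)
    for (p in as.integer(names(rules))) {
      r <- substr(s, st + p - 1L, st + p - 1L)
      if (!(r %in% setdiff(rules[[as.character(p)]], c("U", "X"))))
        mm <- c(mm, p)
    }
    if (length(mm) > max_mismatch) next
    status <- if (length(mm) == 0L) "strict"
      else if (all(setdiff(mm, c(1,7,11,12,14,15,16)) == 17) &&
               substr(s, st + 16L, st + 16L) == "C" &&
               !any(mm %in% c(2, 4, 13))) "his_to_cys"
      else "disrupted"
    hits <- rbind(hits, data.frame(start = st, status = status,
                                   n_mismatch = length(mm)))
  }
  if (is.null(hits))
    return(data.frame(start = integer(), status = character(),
                      n_mismatch = integer()))
  strictC13 <- hits$start[hits$status == "strict"] + 12L
  hits[hits$status == "strict" | !((hits$start + 12L) %in% strictC13), ,
       drop = FALSE]
}

# all-pairs inter-chain contact search, O(n^2), no grid
brute_contacts <- function(model, chainA, chainB, d_max) {
  a <- model$atoms[!model$atoms$water, , drop = FALSE]
  A <- a[a$chain == chainA, , drop = FALSE]
  B <- a[a$chain == chainB, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B))) {
    d <- sqrt((A$x[i]-B$x[j])^2 + (A$y[i]-B$y[j])^2 + (A$z[i]-B$z[j])^2)
    if (d <= d_max) out <- rbind(out, data.frame(i = i, j = j, dist = d))
  }
  if (is.null(out)) data.frame(i = integer(), j = integer(),
                               dist = numeric()) else out
}

# single-atom row in structure_model format
make_atom <- function(x, y, z, element = "C", elety = element,
                      chain = "A", resno = 1L, resid = "UNK",
                      het = FALSE, water = FALSE) {
  data.frame(chain = chain, resno = as.integer(resno), insert = "",
             resid = resid, elety = elety, element = element,
             x = x, y = y, z = z, o = 1, het = het, water = water,
             stringsAsFactors = FALSE)
}

as_model <- function(atoms) {
  structure(list(atoms = atoms, source = "<test>"),
            class = "structure_model")
}

# random 17-point configuration pairs for superposition tests
random_pointset <- function(n = 17) matrix(stats::rnorm(n * 3), ncol = 3)

# path to optional reference data (deposited PDB entries, supplementary
# sequence collections); downloading them is a documented user step
ref_file <- function(name) {
  p <- system.file("extdata", "reference", name, package = "cisdtools")
  if (!nzchar(p) || !file.exists(p))
    stop("reference data file '", name, "' not available; download it to ",
         "inst/extdata/reference/ as described in the README", call. = FALSE)
  p
}
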