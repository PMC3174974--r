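#' Specification of the 17-residue CDGSH motif
#'
#' The consensus is `[Phi C X C X X (S/T) X X X P Phi C D G (S/T/A) H]`:
#' position 1 and 12 hydrophobic (Phi), positions 3/5/6/8/9/10 free (X), and
#' the remaining positions constrained. The cluster ligands sit at positions
#' 2, 4, 13 (cysteines) and 17 (histidine); position 11 is the lid-proline.
#'
#' @param hydrophobic Residue letters accepted at the Phi positions. The
#'   default covers the occupants observed across CISD alignments (W, F, A,
#'   L, ...); the consensus itself never enumerates Phi.
#' @return A `motif_spec`: list with `length`, `allowed` (per-position
#'   residue sets, `NULL` = unconstrained), `constrained` (positions that
#'   count mismatches), and `ligand_offsets` (0-based offsets 1, 3, 12, 16
#'   of C2, C4, C13, H17 from the window start).
#' @export
motif_spec <- function(hydrophobic = c("A","C","F","I","L","M","P","V","W","Y")) {
  allowed <- vector("list", 17L)
  allowed[[1]] <- hydrophobic
  allowed[[2]] <- "C"
  allowed[[4]] <- "C"
  allowed[[7]] <- c("S", "T")
  allowed[[11]] <- "P"
  allowed[[12]] <- hydrophobic
  allowed[[13]] <- "C"
  allowed[[14]] <- "D"
  allowed[[15]] <- "G"
  allowed[[16]] <- c("S", "T", "A")
  allowed[[17]] <- "H"
  out <- list(length = 17L,
              allowed = allowed,
              constrained = which(!vapply(allowed, is.null, TRUE)),
              ligand_offsets = c(1L, 3L, 12L, 16L),
              hydrophobic = hydrophobic)
  class(out) <- "motif_spec"
  out
}

#' Scan a sequence for CDGSH motifs
#'
#' Slides the 17-residue consensus over the de-gapped sequence and reports
#' every window with at most `max_mismatch` mismatches at the constrained
#' positions (X positions are always free; `U` and `X` residues never
#' satisfy a constrained position). Status:
#' \describe{
#'   \item{strict}{no mismatch.}
#'   \item{his_to_cys}{the characteristic histidine ligand (position 17) is
#'     replaced by a cysteine and no other ligand position is touched; such
#'     motifs may still bind a \[2Fe-2S\] cluster.}
#'   \item{disrupted}{any other constrained-position substitution (e.g. Cys
#'     to Ser; His to Gly, Ser, Gln or Asn), most likely abolishing
#'     iron-sulfur binding.}
#' }
#' A strict hit suppresses relaxed hits sharing its C13 position.
#'
#' @param seq A residue string, a single-row `cisd_seqs` record, or a
#'   `cisd_seqs` data frame (scanned row-wise).
#' @param spec A [motif_spec()].
#' @param max_mismatch Maximum constrained-position mismatches (0 = strict;
#'   default 2 suits degenerate-motif discovery).
#' @return A data frame of hits sorted by record then start: `id`, `start`
#'   (1-based, ungapped coordinates), `window`, `status`, `n_mismatch`,
#'   `mismatches` (`"pos:observed"` list, `;`-separated), `lig_c2`,
#'   `lig_c4`, `lig_c13`, `lig_h17` (sequence positions of the four
#'   ligands), `lid_p` (lid-proline present at position 11).
#' @export
#' @examples
#' scan_cdgsh("ACDCAATAAAPACDGSH", max_mismatch = 0)
scan_cdgsh <- function(seq, spec = motif_spec(), max_mismatch = 2L) {
  stopifnot(max_mismatch >= 0L)
  recs <- as_seq_records(seq)
  hits <- lapply(seq_len(nrow(recs)), function(i)
    scan_one(recs$id[i], ungap(recs$residues[i]), spec, max_mismatch))
  out <- do.call(rbind, hits)
  if (is.null(out)) empty_hits() else out
}

scan_one <- function(id, s, spec, max_mismatch) {
  L <- nchar(s)
  W <- spec$length
  if (L < W) return(NULL)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  nwin <- L - W + 1L
  mism_count <- integer(nwin)
  # per constrained position, vectorized membership over all windows
  mism_at <- matrix(FALSE, nwin, W)
  for (p in spec$constrained) {
    obs <- ch[p:(p + nwin - 1L)]
    ok <- obs %in% setdiff(spec$allowed[[p]], c("U", "X"))
    mism_at[, p] <- !ok
    mism_count <- mism_count + !ok
  }
  sel <- which(mism_count <= max_mismatch)
  if (length(sel) == 0L) return(NULL)
  rows <- lapply(sel, function(st) {
    win <- substr(s, st, st + W - 1L)
    mm <- which(mism_at[st, ])
    status <- if (length(mm) == 0L) "strict" else {
      lig_pos <- c(2L, 4L, 13L, 17L)
      lig_mm <- intersect(mm, lig_pos)
      if (identical(lig_mm, 17L) && ch[st + 16L] == "C") "his_to_cys"
      else "disrupted"
    }
    data.frame(id = id, start = st, window = win, status = status,
               n_mismatch = length(mm),
               mismatches = paste(sprintf("%d:%s", mm, ch[st + mm - 1L]),
                                  collapse = ";"),
               lig_c2 = st + 1L, lig_c4 = st + 3L,
               lig_c13 = st + 12L, lig_h17 = st + 16L,
               lid_p = ch[st + 10L] == "P", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  # strict hit suppresses relaxed hits sharing its C13
  strictC13 <- out$lig_c13[out$status == "strict"]
  out <- out[out$status == "strict" | !(out$lig_c13 %in% strictC13), ,
             drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(id = character(), start = integer(), window = character(),
             status = character(), n_mismatch = integer(),
             mismatches = character(), lig_c2 = integer(),
             lig_c4 = integer(), lig_c13 = integer(), lig_h17 = integer(),
             lid_p = logical(), stringsAsFactors = FALSE)
}

as_seq_records <- function(seq) {
  if (is.character(seq))
    return(data.frame(id = if (is.null(names(seq)))
                             paste0("seq", seq_along(seq)) else names(seq),
                      description = "", residues = toupper(seq),
                      stringsAsFactors = FALSE))
  stopifnot(is.data.frame(seq), all(c("id", "residues") %in% names(seq)))
  seq
}

#' Scan for the P motif ([G P Phi X Phi])
#'
#' The 5-residue element whose proline (the lid-proline) lies over a
#' bridging sulfide of the \[2Fe-2S\] cluster. Hits are exact: G at 1, P at
#' 2, hydrophobic at 3 and 5, any residue at 4.
#'
#' @param seq As in [scan_cdgsh()].
#' @param hydrophobic Hydrophobic residue set for the Phi positions.
#' @return Data frame of hits: `id`, `start` (ungapped), `window`, `lid_p_pos`
#'   (sequence position of the proline, `start + 1`).
#' @export
scan_pmotif <- function(seq, hydrophobic = motif_spec()$hydrophobic) {
  recs <- as_seq_records(seq)
  phi <- setdiff(hydrophobic, c("U", "X"))
  rows <- lapply(seq_len(nrow(recs)), function(i) {
    s <- ungap(recs$residues[i])
    L <- nchar(s)
    if (L < 5L) return(NULL)
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    n <- L - 4L
    ok <- ch[1:n] == "G" & ch[2:(n + 1L)] == "P" &
      ch[3:(n + 2L)] %in% phi & ch[5:(n + 4L)] %in% phi
    st <- which(ok)
    if (length(st) == 0L) return(NULL)
    data.frame(id = recs$id[i], start = st,
               window = substring(s, st, st + 4L),
               lid_p_pos = st + 1L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(id = character(), start = integer(),
                      window = character(), lid_p_pos = integer(),
                      stringsAsFactors = FALSE)
  out
}
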