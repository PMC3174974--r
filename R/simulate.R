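#' Idealized iron-sulfur binding module template
#'
#' A synthetic 17-residue Calpha trace plus a 4-atom [2Fe-2S] cluster, built
#' analytically (it is not copied from any deposited model): the trace is a
#' gentle helix wrapping the cluster with consecutive Calpha spacing of
#' 3.8 A; the cluster is a planar Fe2S2 rhombus (Fe-Fe 2.7 A, Fe-S 2.2 A)
#' centred at the origin; the ligand side-chain atoms (Sgamma of the
#' cysteines at motif positions 2, 4, 13 and Nepsilon2 of the histidine at
#' position 17) are placed 2.25 A from their iron on the Fe->Calpha
#' direction, so [assign_ligands()] recovers them with the default cutoff.
#'
#' @param chain Chain id (default `"A"`).
#' @param start_resno Author number of motif position 1 (default 20).
#' @return A `structure_model` containing one module: 17 Calpha atoms
#'   (polymer) and one `FES` het-group (`FE1`, `FE2`, `S1`, `S2`).
#' @export
template_module <- function(chain = "A", start_resno = 20L) {
  # Fe2S2 rhombus in the xy plane
  fes <- rbind(FE1 = c(-1.35, 0, 0), FE2 = c(1.35, 0, 0),
               S1 = c(0, 1.70, 0), S2 = c(0, -1.70, 0))
  # helical Calpha trace: radius 5 A, rise 1.5 A, consecutive spacing 3.8 A
  i <- 0:16
  th <- 2 * asin(sqrt(3.8^2 - 1.5^2) / (2 * 5)) * i
  ca <- cbind(5 * cos(th), 5 * sin(th), -12 + 1.5 * i)
  resid <- rep("GLY", 17)
  resid[c(2, 4, 13)] <- "CYS"
  resid[17] <- "HIS"
  resid[1] <- "LEU"                     # Phi1
  rows <- data.frame(
    chain = chain, resno = start_resno + i, insert = "", resid = resid,
    elety = "CA", element = "C", x = ca[, 1], y = ca[, 2], z = ca[, 3],
    o = 1, het = FALSE, water = FALSE, stringsAsFactors = FALSE)
  # ligand side-chain atoms, 2.25 A out of the iron toward the Calpha
  lig <- data.frame(pos = c(2, 4, 13, 17),
                    fe = c("FE1", "FE1", "FE2", "FE2"),
                    elety = c("SG", "SG", "SG", "NE2"),
                    element = c("S", "S", "S", "N"),
                    stringsAsFactors = FALSE)
  side <- lapply(seq_len(nrow(lig)), function(k) {
    p <- lig$pos[k]
    fe <- fes[lig$fe[k], ]
    v <- ca[p, ] - fe
    at <- fe + 2.25 * v / sqrt(sum(v^2))
    data.frame(chain = chain, resno = start_resno + p - 1L, insert = "",
               resid = resid[p], elety = lig$elety[k],
               element = lig$element[k], x = at[1], y = at[2], z = at[3],
               o = 1, het = FALSE, water = FALSE, stringsAsFactors = FALSE)
  })
  het <- data.frame(
    chain = chain, resno = 101L, insert = "", resid = "FES",
    elety = rownames(fes), element = c("FE", "FE", "S", "S"),
    x = fes[, 1], y = fes[, 2], z = fes[, 3], o = 1, het = TRUE,
    water = FALSE, stringsAsFactors = FALSE)
  atoms <- rbind(rows, do.call(rbind, side), het)
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, source = "<template_module>")
  class(out) <- "structure_model"
  out
}

#' Generate a synthetic dual-module (dimeric) coordinate set
#'
#' Places a second copy of the template iron-sulfur module at an exactly
#' controlled geometry relative to the first, so structural measurements
#' can be checked against construction parameters:
#' \itemize{
#'   \item the partner is first created by a 180-degree rotation about an
#'     axis through the midpoint of the two cluster centres (an exact dyad,
#'     so `symmetric = TRUE` yields [pseudo_dyad()] RMSD 0 at 180 degrees);
#'   \item [cluster_distance()] between the two cluster centroids equals
#'     `center_distance` exactly;
#'   \item the partner is then rotated rigidly by `shift_angle` about the
#'     first cluster's centroid, so [intermodule_angle()] against the
#'     unshifted reference returns `shift_angle` exactly (rotation about
#'     the vertex preserves the centre distance);
#'   \item Gaussian coordinate noise of width `noise_sigma` is added last.
#' }
#'
#' @param center_distance Cluster centre-to-centre distance in Angstrom
#'   (> 0; around 14-16 A in real CISD structures).
#' @param shift_angle Rotation of the partner module about the first
#'   cluster centre, degrees in `[0, 180]`.
#' @param symmetric Must the partner be an exact dyad image? (Only possible
#'   with `shift_angle = 0`; requesting both is an unreachable combination
#'   and an error.)
#' @param noise_sigma Gaussian noise SD in Angstrom (>= 0).
#' @param seed Integer seed; identical seeds give byte-identical models.
#' @param tandem If `TRUE`, both modules go on one chain (residues 20-36
#'   and 60-76: a tandem-motif, type 5/6-like monomer); otherwise chains A
#'   and B (a type 1/3/4-like homodimer).
#' @param n_waters Number of decoy water molecules scattered around the
#'   model (default 0).
#' @return A `structure_model`.
#' @export
gen_dimer <- function(center_distance = 14.2, shift_angle = 0,
                      symmetric = TRUE, noise_sigma = 0, seed = 1L,
                      tandem = FALSE, n_waters = 0L) {
  if (center_distance <= 0) stop("center_distance must be > 0")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (shift_angle < 0 || shift_angle > 180)
    stop("shift_angle must be in [0, 180] degrees")
  if (symmetric && shift_angle != 0)
    stop("unreachable combination: an exact dyad requires shift_angle = 0")
  m1 <- template_module(chain = "A", start_resno = 20L)
  a1 <- m1$atoms
  d <- center_distance
  # exact dyad: 180-degree rotation about the z axis through (d/2, 0, 0);
  # maps the cluster centroid (origin) onto (d, 0, 0)
  a2 <- a1
  a2$x <- d - a1$x
  a2$y <- -a1$y
  if (shift_angle != 0) {
    R <- rotation_about(c(0, 0, 1), shift_angle)
    xyz <- atom_xyz(a2) %*% R           # vertex = first cluster centroid = origin
    a2$x <- xyz[, 1]; a2$y <- xyz[, 2]; a2$z <- xyz[, 3]
  }
  if (tandem) {
    a2$chain <- "A"
    a2$resno <- a2$resno + 40L          # motif 2 at residues 60-76
  } else {
    a2$chain <- "B"
  }
  atoms <- rbind(a1, a2)
  set.seed(seed)
  if (n_waters > 0L) {
    wat <- data.frame(
      chain = "W", resno = 200L + seq_len(n_waters), insert = "",
      resid = "HOH", elety = "O", element = "O",
      x = stats::runif(n_waters, -20, 35),
      y = stats::runif(n_waters, -25, 25),
      z = stats::runif(n_waters, -25, 25),
      o = 1, het = FALSE, water = TRUE, stringsAsFactors = FALSE)
    atoms <- rbind(atoms, wat)
  }
  if (noise_sigma > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sigma)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sigma)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sigma)
  }
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, source = "<gen_dimer>")
  class(out) <- "structure_model"
  out
}

#' Generate synthetic CISD sequences with known ground truth
#'
#' Plants intact or degenerate CDGSH motifs in random background sequence
#' according to per-type rules, together with the fused-domain architecture
#' each type implies, and returns both the records and a truth table. Types
#' 5 and 6 get tandem motifs (spacing drawn uniformly from
#' `spacing_range`), type 5 additionally a C-terminal FMN-binding segment,
#' type 7 one or two motifs around a DUF1271 segment (subtypes DC, DCC,
#' CDC; motifs spaced beyond `spacing_range` so the tandem rule cannot
#' fire), and types 1/2/3/4 a single motif with the matching taxon.
#'
#' Degenerate motifs (second motif of a tandem pair, at rate
#' `degeneracy_rate`) follow the substitutions seen in real collections:
#' half replace the histidine ligand with cysteine (`his_to_cys`), half
#' disrupt the motif (Cys to Ser, or His to Gly/Ser/Gln/Asn).
#'
#' @param n Number of records (>= 0).
#' @param type_mix Named probability weights over
#'   `c("1","2","3","4","5","6","7")` (default uniform).
#' @param degeneracy_rate Fraction of tandem (type 5/6) records carrying one
#'   degenerate motif; default 0.17, the observed fraction in the tandem
#'   families.
#' @param seed Integer seed (identical seeds give identical output).
#' @param length_range Background sequence length range before insertions.
#' @param spacing_range Tandem spacing range, as in [assign_type()].
#' @param background Amino-acid sampling weights (named, over the 20
#'   standard letters); uniform by default.
#' @return List with `records` (a `cisd_seqs` data frame whose ids follow
#'   the underscore naming convention of [parse_record_name()]), `truth`
#'   (per-record: id, type, subtype7, taxon, degenerate flag/status, motif
#'   starts) and `arch` (architecture table: id, kind, start, end).
#' @export
gen_sequences <- function(n, type_mix = NULL, degeneracy_rate = 0.17,
                          seed = 1L, length_range = c(90L, 160L),
                          spacing_range = c(5, 40),
                          background = NULL) {
  stopifnot(n >= 0, degeneracy_rate >= 0, degeneracy_rate <= 1)
  set.seed(seed)
  if (is.null(type_mix))
    type_mix <- stats::setNames(rep(1, 7), c("1","2","3","4","5","6","7"))
  if (is.null(background))
    background <- stats::setNames(rep(1, 20), AA20)
  empty <- list(
    records = data.frame(id = character(), description = character(),
                         residues = character(), stringsAsFactors = FALSE),
    truth = data.frame(id = character(), cisd_type = character(),
                       subtype7 = character(), taxon = character(),
                       degenerate = logical(), degenerate_status = character(),
                       motif_starts = character(), stringsAsFactors = FALSE),
    arch = data.frame(id = character(), kind = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  if (n == 0L) return(empty)

  recs <- vector("list", n)
  truths <- vector("list", n)
  archs <- vector("list", n)
  types <- sample(names(type_mix), n, replace = TRUE,
                  prob = unname(type_mix))
  for (k in seq_len(n)) {
    g <- gen_one_record(k, types[k], degeneracy_rate, length_range,
                        spacing_range, background)
    recs[[k]] <- g$record; truths[[k]] <- g$truth; archs[[k]] <- g$arch
  }
  records <- do.call(rbind, recs)
  class(records) <- c("cisd_seqs", "data.frame")
  list(records = records, truth = do.call(rbind, truths),
       arch = do.call(rbind, archs))
}

# taxon and a plausible phylum for each type
TYPE_TAXON <- c(`1` = "eukaryote", `2` = "apicomplexa", `3` = "archaea",
                `4` = "bacteria", `5` = "bacteria", `6` = "bacteria",
                `7` = "bacteria")

rand_bg <- function(len, background) {
  paste(sample(names(background), len, replace = TRUE,
               prob = unname(background)), collapse = "")
}

# one consensus instance; phi/x positions randomized
instantiate_motif <- function(spec = motif_spec(), background) {
  xres <- function() sample(names(background), 1)
  ch <- character(17)
  for (p in 1:17) {
    ch[p] <- if (is.null(spec$allowed[[p]])) xres()
             else sample(spec$allowed[[p]], 1)
  }
  paste(ch, collapse = "")
}

# apply a degeneracy edit; returns list(window, status)
degenerate_motif <- function(win) {
  ch <- strsplit(win, "")[[1]]
  if (stats::runif(1) < 0.5) {
    ch[17] <- "C"
    status <- "his_to_cys"
  } else if (stats::runif(1) < 0.5) {
    ch[sample(c(2, 4, 13), 1)] <- "S"          # Cys -> Ser
    status <- "disrupted"
  } else {
    ch[17] <- sample(c("G", "S", "Q", "N"), 1) # His -> G/S/Q/N
    status <- "disrupted"
  }
  list(window = paste(ch, collapse = ""), status = status)
}

splice <- function(s, at, insert) {
  # overwrite s starting at 1-based position at
  paste0(substr(s, 1, at - 1L), insert,
         substr(s, at + nchar(insert), nchar(s)))
}

gen_one_record <- function(k, type, degeneracy_rate, length_range,
                           spacing_range, background) {
  spec <- motif_spec()
  L <- sample(length_range[1]:length_range[2], 1)
  taxon <- TYPE_TAXON[[type]]
  sub7 <- "none"
  degenerate <- FALSE
  dstatus <- ""
  segs <- data.frame(kind = character(), start = integer(),
                     end = integer(), stringsAsFactors = FALSE)
  w1 <- instantiate_motif(spec, background)
  if (type %in% c("5", "6")) {
    gap <- sample(spacing_range[1]:spacing_range[2], 1)
    w2 <- instantiate_motif(spec, background)
    if (stats::runif(1) < degeneracy_rate) {
      degenerate <- TRUE
      d <- degenerate_motif(w2)
      w2 <- d$window; dstatus <- d$status
    }
    need <- 34L + gap
    L <- max(L, need + 20L)
    s <- rand_bg(L, background)
    st1 <- sample(5:(L - need - 5L), 1)
    st2 <- st1 + 17L + gap
    s <- splice(s, st1, w1); s <- splice(s, st2, w2)
    starts <- c(st1, st2)
    segs <- rbind(segs,
                  data.frame(kind = "CISD_motif", start = c(st1, st2),
                             end = c(st1, st2) + 16L))
    if (type == "5") {
      fmn_start <- L + 1L
      s <- paste0(s, rand_bg(60L, background))    # FMN-binding fusion
      segs <- rbind(segs, data.frame(kind = "FMN_binding", start = fmn_start,
                                     end = fmn_start + 59L))
    }
  } else if (type == "7") {
    sub7 <- sample(SUBTYPES7, 1)
    duf_len <- 70L
    pad <- 50L                                   # > spacing_range, no tandem
    parts <- switch(sub7,
      DC  = c("D", "C"),
      DCC = c("D", "C", "C"),
      CDC = c("C", "D", "C"))
    s <- rand_bg(10L, background)
    starts <- integer(0)
    for (p in parts) {
      s <- paste0(s, rand_bg(pad, background))
      if (p == "D") {
        segs <- rbind(segs, data.frame(kind = "DUF1271",
                                       start = nchar(s) + 1L,
                                       end = nchar(s) + duf_len))
        s <- paste0(s, rand_bg(duf_len, background))
      } else {
        w <- instantiate_motif(spec, background)
        starts <- c(starts, nchar(s) + 1L)
        segs <- rbind(segs, data.frame(kind = "CISD_motif",
                                       start = nchar(s) + 1L,
                                       end = nchar(s) + 17L))
        s <- paste0(s, w)
      }
    }
    s <- paste0(s, rand_bg(10L, background))
  } else {
    if (L < 40L) stop("sequence too short to plant a motif")
    s <- rand_bg(L, background)
    st1 <- sample(10:(L - 27L), 1)
    s <- splice(s, st1, w1)
    starts <- st1
    segs <- rbind(segs, data.frame(kind = "CISD_motif", start = st1,
                                   end = st1 + 16L))
  }
  phylum <- switch(taxon,
    eukaryote = sample(c("Chor", "Arth", "Stre", "Nema"), 1),
    apicomplexa = "Prot",
    archaea = sample(ARCH_PHYLA, 1),
    bacteria = sample(c("Apro", "Bpro", "Gpro", "Acti", "Firm", "Bact",
                        "Cyan"), 1))
  meta <- data.frame(
    cisd_type = type, subtype7 = sub7, motif_index = NA_integer_,
    degenerate_flag = degenerate,
    eukaryote_prefix = taxon == "eukaryote" && type %in% c("5", "6"),
    phylum_abbrev = phylum,
    genus_initial = sample(LETTERS, 1),
    species = sprintf("sp%03d", k),
    genebank_id = sprintf("SY_%06d", k), stringsAsFactors = FALSE)
  id <- compose_record_name(meta)
  rec <- data.frame(id = id, description = "synthetic CISD record",
                    residues = s, stringsAsFactors = FALSE)
  truth <- data.frame(id = id, cisd_type = type, subtype7 = sub7,
                      taxon = taxon, degenerate = degenerate,
                      degenerate_status = dstatus,
                      motif_starts = paste(starts, collapse = ","),
                      stringsAsFactors = FALSE)
  segs$id <- id
  list(record = rec, truth = truth,
       arch = segs[, c("id", "kind", "start", "end")])
}
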