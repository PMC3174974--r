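#' Read a macromolecular structure (PDB or mmCIF)
#'
#' Parses a coordinate file into a `structure_model`: a flat atom table with
#' polymer, het-group and water flags. The dialect is chosen from the file
#' extension (`.pdb`/`.ent` vs `.cif`/`.mmcif`). Residues keep author
#' numbering (1-based, insertion codes retained), because all residue
#' references in the CISD literature (e.g. Cys25, His40) use author numbers.
#'
#' Alternate locations are resolved per (residue, atom name): the altloc with
#' the highest occupancy is kept, the first one on ties. Hydrogen (and
#' deuterium) atoms are stripped on read; high-resolution CISD models deposit
#' riding hydrogens which play no role in any computation here.
#'
#' @param path Path to a PDB or mmCIF file.
#' @param altloc_policy `"occupancy"` (default, highest occupancy wins) or
#'   `"first"` (first conformer wins).
#' @return An object of class `structure_model`: a list with `atoms` (data
#'   frame: `chain`, `resno`, `insert`, `resid`, `elety`, `element`, `x`,
#'   `y`, `z`, `o`, `het`, `water`) and `source` (the input path).
#' @seealso [find_clusters()], [write_structure()]
#' @export
read_structure <- function(path, altloc_policy = c("occupancy", "first")) {
  altloc_policy <- match.arg(altloc_policy)
  if (!file.exists(path)) stop("structure file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("pdb", "ent")) {
    quiet(bio3d::read.pdb(path, rm.alt = FALSE))
  } else if (ext %in% c("cif", "mmcif")) {
    quiet(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
  } else {
    stop("structure dialect error: unknown extension '.", ext, "'")
  }
  a <- raw$atom
  if (is.null(a) || nrow(a) == 0L)
    stop("structure format error: no atoms in ", path)
  structure_model_from_atoms(a, path, altloc_policy)
}

structure_model_from_atoms <- function(a, path, altloc_policy) {
  element <- toupper(trimws(a$elesy))
  missing_el <- is.na(element) | !nzchar(element)
  element[missing_el] <- guess_element(a$elety[missing_el])
  keep <- !(element %in% c("H", "D"))
  a <- a[keep, , drop = FALSE]
  element <- element[keep]
  if (nrow(a) == 0L) stop("structure format error: no heavy atoms in ", path)

  insert <- ifelse(is.na(a$insert), "", as.character(a$insert))
  o <- a$o
  o[is.na(o)] <- 1
  atoms <- data.frame(
    chain = as.character(a$chain), resno = as.integer(a$resno),
    insert = insert, resid = toupper(as.character(a$resid)),
    elety = toupper(trimws(as.character(a$elety))), element = element,
    x = a$x, y = a$y, z = a$z, o = o,
    het = a$type == "HETATM", water = FALSE, stringsAsFactors = FALSE)
  atoms$water <- atoms$resid %in% c("HOH", "WAT")
  atoms$het <- atoms$het & !atoms$water
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("structure format error: non-finite coordinates in ", path)

  # altloc resolution: one conformer per (residue, atom name)
  alt <- ifelse(is.na(a$alt), "", as.character(a$alt))
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$resid,
               atoms$elety, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- if (altloc_policy == "occupancy") {
      order(key, -atoms$o, seq_len(nrow(atoms)))
    } else {
      order(key, seq_len(nrow(atoms)))
    }
    keep <- ord[!duplicated(key[ord])]
    atoms <- atoms[sort(keep), , drop = FALSE]
  }
  rownames(atoms) <- NULL
  out <- list(atoms = atoms, source = path)
  class(out) <- "structure_model"
  out
}

# fallback element from atom-name leading letters (columns absent in
# minimal files); two-letter elements that occur in CISD models first
guess_element <- function(elety) {
  nm <- toupper(trimws(elety))
  el <- substr(gsub("[^A-Z]", "", nm), 1, 1)
  el[grepl("^FE", nm)] <- "FE"
  el[grepl("^ZN", nm)] <- "ZN"
  el[grepl("^MG", nm)] <- "MG"
  el[grepl("^SE", nm)] <- "SE"
  el
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("structure_model:", basename(x$source %||% "<memory>"), "\n")
  cat(sprintf("  %d atoms | %d polymer, %d het, %d water | chains: %s\n",
              nrow(a), sum(!a$het & !a$water), sum(a$het), sum(a$water),
              paste(sort(unique(a$chain)), collapse = " ")))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# silence a parser's console chatter and warnings, keep errors
quiet <- function(expr) {
  suppressWarnings(suppressMessages(
    withCallingHandlers(expr, message = function(m)
      invokeRestart("muffleMessage"))))
}

#' Count water molecules in a model
#'
#' Waters are residues named `HOH` or `WAT` on any chain.
#'
#' @param model A `structure_model`.
#' @return Integer number of distinct water residues.
#' @export
count_waters <- function(model) {
  a <- model$atoms[model$atoms$water, , drop = FALSE]
  if (nrow(a) == 0L) return(0L)
  length(unique(paste(a$chain, a$resno, a$insert)))
}

#' Write a structure model to PDB or mmCIF
#'
#' A deliberately minimal writer for the synthetic models produced by
#' [gen_dimer()] (single conformer, no hydrogens, no anisotropic records).
#' The dialect follows the file extension, as in [read_structure()].
#'
#' @param model A `structure_model`.
#' @param path Output path ending in `.pdb` or `.cif`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "pdb") write_model_pdb(model, path)
  else if (ext %in% c("cif", "mmcif")) write_model_cif(model, path)
  else stop("structure dialect error: unknown extension '.", ext, "'")
  invisible(path)
}

write_model_pdb <- function(model, path) {
  a <- model$atoms
  rec <- ifelse(a$het | a$water, "HETATM", "ATOM  ")
  nm <- ifelse(nchar(a$elety) < 4L & nchar(a$element) == 1L,
               sprintf(" %-3s", a$elety), sprintf("%-4s", a$elety))
  lines <- sprintf(
    "%s%5d %4s %-3s%2s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), nm, a$resid, a$chain, a$resno,
    ifelse(nzchar(a$insert), a$insert, " "),
    a$x, a$y, a$z, a$o, 0, a$element)
  writeLines(c(lines, "END"), path)
}

write_model_cif <- function(model, path) {
  # canonical wwPDB atom_site column set and order, which strict readers
  # assume even though the loop_ header names the fields
  a <- model$atoms
  grp <- ifelse(a$het | a$water, "HETATM", "ATOM")
  ins <- ifelse(nzchar(a$insert), a$insert, "?")
  lines <- sprintf(
    "%s %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    grp, seq_len(nrow(a)), a$element, a$elety, a$resid, a$chain, a$resno,
    ins, a$x, a$y, a$z, a$o, 0, a$resno, a$resid, a$chain, a$elety)
  hdr <- c("data_cisdtools",
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id",
           "_atom_site.type_symbol", "_atom_site.label_atom_id",
           "_atom_site.label_alt_id", "_atom_site.label_comp_id",
           "_atom_site.label_asym_id", "_atom_site.label_entity_id",
           "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
           "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
           "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num")
  writeLines(c(hdr, lines, "#"), path)
}

#' Extract the coordinate matrix of a set of atoms
#'
#' @param atoms Atom data frame (rows of `model$atoms`).
#' @return Numeric matrix with columns x, y, z.
#' @keywords internal
atom_xyz <- function(atoms) {
  m <- as.matrix(atoms[, c("x", "y", "z")])
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  m
}
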