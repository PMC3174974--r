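#' Assign a CISD type from motifs, domain architecture and taxonomy
#'
#' Implements the seven-type classification. Decision order (architecture
#' takes precedence over taxonomy):
#' \enumerate{
#'   \item Two CDGSH motifs whose spacing (end of one motif to start of the
#'     next) falls in `spacing_range`: tandem-motif type 6 — or type 5 when
#'     a C-terminal glutamate-synthase FMN-binding segment follows the last
#'     motif.
#'   \item A DUF1271 segment present: type 7, with subtype from
#'     [assign_subtype7()].
#'   \item A single motif: eukaryote -> 1, apicomplexa -> 2, archaea -> 3,
#'     bacteria -> 4; an optional homology override (nearest-seed identity)
#'     can refine 2 into 2a/2b or reassign bacterial sequences to type 3
#'     (a handful of bacterial sequences are clearly homologous to the
#'     archaeal type 3 family).
#'   \item Otherwise: orphan.
#' }
#'
#' Motif evidence is the union of scanner hits with status `strict` or
#' `his_to_cys` and any `CISD_motif` segments of the architecture
#' annotation (overlapping evidence is merged), so a tandem protein whose
#' second motif is degenerate beyond recognition still classifies by its
#' annotated architecture.
#'
#' @param motifs Data frame of hits from [scan_cdgsh()] for one record.
#' @param arch Optional architecture annotation: data frame with columns
#'   `kind` (`CISD_motif`, `DUF1271`, `FMN_binding`, `other`), `start`,
#'   `end` (non-overlapping, any order; sorted internally).
#' @param taxon One of `"eukaryote"`, `"apicomplexa"`, `"archaea"`,
#'   `"bacteria"`, `"unknown"`.
#' @param spacing_range Length-2 numeric: admissible inter-motif spacing in
#'   residues (default `c(5, 40)`; tandem motifs are separated by about 20).
#' @param seeds Optional named list of ungapped seed sequences per type
#'   (names like `"2a"`, `"2b"`, `"3"`, `"4"`) for the homology override;
#'   `sequence` must then be supplied.
#' @param sequence The record's residue string (only needed with `seeds`).
#' @return A `type_call`: list with `cisd_type`, `subtype7`, `evidence`
#'   (character rule ids) and `confidence` (`architectural`, `taxonomic` or
#'   `homology`).
#' @export
assign_type <- function(motifs, arch = NULL,
                        taxon = c("unknown", "eukaryote", "apicomplexa",
                                  "archaea", "bacteria"),
                        spacing_range = c(5, 40),
                        seeds = NULL, sequence = NULL) {
  taxon <- match.arg(taxon)
  ev <- character(0)
  segs <- normalize_arch(arch)
  mot <- motif_intervals(motifs, segs)

  has_duf <- any(segs$kind == "DUF1271")
  fmn_after <- FALSE
  if (nrow(mot) >= 2L) {
    gaps <- mot$start[-1] - mot$end[-nrow(mot)] - 1L
    tandem <- any(gaps >= spacing_range[1] & gaps <= spacing_range[2])
    if (tandem) {
      fmn <- segs[segs$kind == "FMN_binding", , drop = FALSE]
      fmn_after <- nrow(fmn) > 0L && any(fmn$start > max(mot$end))
      type <- if (fmn_after) "5" else "6"
      ev <- c(ev, "tandem_motifs", if (fmn_after) "fmn_fusion")
      return(type_call(type, "none", ev, "architectural"))
    }
  }
  if (has_duf && nrow(mot) >= 1L) {
    comb <- rbind(segs[segs$kind == "DUF1271", , drop = FALSE],
                  data.frame(kind = "CISD_motif", start = mot$start,
                             end = mot$end, stringsAsFactors = FALSE))
    st <- assign_subtype7(comb)
    return(type_call("7", st, c(ev, "duf1271_fusion"), "architectural"))
  }
  if (nrow(mot) == 1L || nrow(mot) >= 2L) {
    # >=2 motifs outside the tandem spacing: fall through on the first motif
    base <- switch(taxon, eukaryote = "1", apicomplexa = "2",
                   archaea = "3", bacteria = "4", NA_character_)
    if (!is.na(base)) {
      ev <- c(ev, paste0("single_motif_taxon_", taxon))
      conf <- "taxonomic"
      type <- base
      if (!is.null(seeds) && !is.null(sequence)) {
        hom <- nearest_seed(sequence, seeds)
        if (!is.na(hom$type)) {
          if (taxon == "apicomplexa" && hom$type %in% c("2a", "2b")) {
            type <- hom$type; conf <- "homology"
            ev <- c(ev, paste0("seed_identity_", hom$type))
          } else if (taxon == "bacteria" && hom$type == "3") {
            type <- "3"; conf <- "homology"
            ev <- c(ev, "seed_identity_3_bacterial")
          }
        }
        if (hom$tie) ev <- c(ev, "seed_identity_unresolved")
      }
      return(type_call(type, "none", ev, conf))
    }
  }
  ev <- if (nrow(mot) == 0L) c(ev, "no_motif") else c(ev, "unassigned")
  type_call("orphan", "none", ev, "taxonomic")
}

type_call <- function(type, sub7, evidence, confidence) {
  stopifnot((sub7 != "none") == (type == "7"))
  out <- list(cisd_type = type, subtype7 = sub7,
              evidence = evidence, confidence = confidence)
  class(out) <- "type_call"
  out
}

#' @export
print.type_call <- function(x, ...) {
  cat(sprintf("CISD type %s%s (%s; evidence: %s)\n", x$cisd_type,
              if (x$subtype7 != "none") paste0(" subtype ", x$subtype7) else "",
              x$confidence, paste(x$evidence, collapse = ", ")))
  invisible(x)
}

normalize_arch <- function(arch) {
  if (is.null(arch) || nrow(arch) == 0L)
    return(data.frame(kind = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  stopifnot(all(c("kind", "start", "end") %in% names(arch)))
  segs <- arch[order(arch$start), c("kind", "start", "end"), drop = FALSE]
  if (nrow(segs) > 1L && any(segs$start[-1] <= segs$end[-nrow(segs)]))
    stop("architecture segments overlap")
  segs
}

# merge scan hits (strict/his_to_cys) with annotated CISD_motif segments
motif_intervals <- function(motifs, segs) {
  iv <- data.frame(start = integer(), end = integer())
  if (!is.null(motifs) && nrow(motifs) > 0L) {
    ok <- motifs$status %in% c("strict", "his_to_cys")
    if (any(ok))
      iv <- data.frame(start = motifs$start[ok],
                       end = motifs$start[ok] + 16L)
  }
  ann <- segs[segs$kind == "CISD_motif", c("start", "end"), drop = FALSE]
  iv <- rbind(iv, ann)
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start), , drop = FALSE]
  # merge overlapping intervals (scan hit + its own annotation)
  merged <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv$start[i] <= merged$end[last]) {
      merged$end[last] <- max(merged$end[last], iv$end[i])
    } else {
      merged <- rbind(merged, iv[i, ])
    }
  }
  rownames(merged) <- NULL
  merged
}

#' Subtype of a type 7 (DUF1271-fused) architecture
#'
#' The DUF1271 domain (D) may be followed by one CISD motif (`DC`), two
#' (`DCC`), or flanked by one on each side (`CDC`).
#'
#' @param arch Architecture data frame (`kind`, `start`, `end`) containing
#'   exactly one `DUF1271` segment and one or two `CISD_motif` segments.
#' @return `"DC"`, `"DCC"` or `"CDC"`.
#' @export
assign_subtype7 <- function(arch) {
  segs <- normalize_arch(arch)
  segs <- segs[segs$kind %in% c("DUF1271", "CISD_motif"), , drop = FALSE]
  code <- paste(ifelse(segs$kind == "DUF1271", "D", "C"), collapse = "")
  if (!code %in% SUBTYPES7)
    stop("type 7 classification error: observed segment order '", code,
         "' is none of DC, DCC, CDC")
  code
}

#' Column conservation in an alignment
#'
#' Fraction of non-gap rows whose residue at an alignment column belongs to
#' a residue set (e.g. `c("K", "R")` to ask how often a position is basic).
#'
#' @param alignment A `cisd_seqs` data frame of equal-length gapped records.
#' @param column 1-based alignment column.
#' @param residue_set Character vector of residue letters.
#' @return Fraction in `[0, 1]` (`NaN` when every row is gapped there).
#' @export
column_conservation <- function(alignment, column, residue_set) {
  len <- nchar(alignment$residues)
  if (length(unique(len)) != 1L)
    stop("ragged alignment: records differ in aligned length")
  if (column < 1L || column > len[1])
    stop("column ", column, " outside alignment of width ", len[1])
  res <- substr(alignment$residues, column, column)
  nongap <- res != "-"
  sum(res[nongap] %in% residue_set) / sum(nongap)
}

# ungapped percent identity of seq against each seed; winner-takes-all
nearest_seed <- function(sequence, seeds) {
  s <- ungap(toupper(sequence))
  ids <- vapply(seeds, function(seed) {
    seed <- ungap(toupper(seed))
    n <- min(nchar(s), nchar(seed))
    if (n == 0L) return(0)
    a <- strsplit(substr(s, 1, n), "")[[1]]
    b <- strsplit(substr(seed, 1, n), "")[[1]]
    mean(a == b)
  }, 0)
  top <- max(ids)
  winners <- names(ids)[ids == top]
  list(type = if (length(winners) == 1L) winners[1] else NA_character_,
       tie = length(winners) > 1L, identity = top)
}
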