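#' Read protein sequences from a FASTA file
#'
#' Reads plain or gap-containing aligned FASTA. Gaps (`-`) are retained so
#' that alignment-coordinate operations (e.g. [column_conservation()]) work on
#' the records as read. Each header is split into an `id` (first whitespace
#' token) and the remaining `description`.
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `cisd_seqs` with columns `id`, `description`
#'   and `residues` (one row per record, input order preserved).
#' @details Residue letters are restricted to the 20 standard amino acids plus
#'   `X`, `U`, `B`, `Z` and the gap character `-`; anything else is an error.
#'   Records must have at least one non-gap residue.
#' @seealso [write_fasta()], [parse_record_name()]
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a demo", "MKV"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  if (file.size(path) == 0L) stop("FASTA format error: empty file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop("FASTA format error: no '>' header in ", path)
  set <- Biostrings::readAAStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- toupper(as.character(set))
  recs <- data.frame(id = id, description = description,
                     residues = unname(residues),
                     stringsAsFactors = FALSE)
  validate_seqs(recs)
  class(recs) <- c("cisd_seqs", "data.frame")
  recs
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: ids, descriptions and residues (including gaps)
#' round-trip losslessly.
#'
#' @param records A data frame with columns `id`, `description`, `residues`.
#' @param path Output path.
#' @param width Line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  validate_seqs(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    writeLines(paste0(">", hdr), con)
    seq <- records$residues[i]
    starts <- seq(1L, nchar(seq), by = width)
    writeLines(substring(seq, starts, pmin(starts + width - 1L, nchar(seq))),
               con)
  }
  invisible(path)
}

# residue alphabet check shared by read/write
validate_seqs <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("id", "description", "residues") %in% names(records)))
  bad <- grepl(sprintf("[^%s]", paste0(AA_LETTERS, collapse = "")),
               records$residues)
  if (any(bad))
    stop("invalid residue letters in record(s): ",
         paste(records$id[bad], collapse = ", "))
  empty <- !nzchar(gsub("-", "", records$residues))
  if (any(empty))
    stop("record(s) with no residues after removing gaps: ",
         paste(records$id[empty], collapse = ", "))
  invisible(records)
}

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")
AA_LETTERS <- c(AA20, "X", "U", "B", "Z", "-")

#' Remove alignment gaps from a residue string
#'
#' @param residues Character vector of (possibly gapped) residue strings.
#' @return Character vector with `-` removed.
#' @export
ungap <- function(residues) gsub("-", "", residues, fixed = TRUE)
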