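#' Controlled vocabulary of phylum / class abbreviations
#'
#' The abbreviations used in the underscore-joined record names of the CISD
#' sequence collections: eukaryote phyla (Arth..Prot), prokaryote phyla and
#' proteobacterial classes (Acid..Zpro) and the archaeal phyla Eury and Cren.
#'
#' @format Named character vector mapping abbreviation to full taxon name.
#' @export
cisd_phylum_codes <- c(
  # eukaryotes
  Arth = "Arthropoda",    Baci = "Bacillariophyta", Cnid = "Cnidaria",
  Chor = "Chordata",      Chlp = "Chlorophyta",     Echi = "Echinodermata",
  Nema = "Nematoda",      Phae = "Phaeophyceae",    Plac = "Placozoa",
  Plat = "Platyhelminthes", Stre = "Streptophyta",  Prot = "Protist",
  # prokaryotes (classes for proteobacteria)
  Acid = "Acidobacteria", Acti = "Actinobacteria",  Apro = "Alphaproteobacteria",
  Aqui = "Aquificae",     Bact = "Bacteroidetes",   Bpro = "Betaproteobacteria",
  Chlf = "Chloroflexi",   Chlo = "Chlorobi",        Cyan = "Cyanobacteria",
  Dein = "Deinococcus-Thermus", Dpro = "Deltaproteobacteria",
  Epro = "Epsilonproteobacteria", Firm = "Firmicutes", Fuso = "Fusobacteria",
  Gpro = "Gammaproteobacteria", Nitro = "Nitrospirae", Plan = "Planctomycetes",
  Spir = "Spirochaetes",  Verr = "Verrucomicrobia", Zpro = "Zetaproteobacteria",
  # archaea
  Eury = "Euryarchaeota", Cren = "Crenarchaeota")

# phyla grouped by superkingdom, used by the profiler and the generator
EUK_PHYLA  <- c("Arth","Baci","Cnid","Chor","Chlp","Echi","Nema","Phae",
                "Plac","Plat","Stre","Prot")
ARCH_PHYLA <- c("Eury","Cren")
BACT_PHYLA <- setdiff(names(cisd_phylum_codes), c(EUK_PHYLA, ARCH_PHYLA))

CISD_TYPES <- c("1","2","2a","2b","3","4","5","6","7","orphan")
SUBTYPES7  <- c("DC","DCC","CDC")

#' Parse an underscore-joined CISD record name
#'
#' Record names in the CISD sequence collections are five underscore-joined
#' fields: CISD type, phylum (or proteobacterial class) abbreviation, initial
#' of the genus name, species epithet, and GenBank id. GenBank ids themselves
#' contain underscores (e.g. `YP_423370`), so the name is split left-to-right:
#' fields 1-4 are positional and the remaining tokens are re-joined as the id.
#'
#' Decorations on the type field are stripped into flags: a leading `e` marks
#' a eukaryotic protein (used for tandem-motif types 5/6), a trailing prime
#' (`'`) marks a degenerated CDGSH motif, and type 7 names may embed the
#' subtype (`DC`, `DCC`, `CDC`) with an optional motif index digit.
#'
#' @param name Character vector of record names.
#' @return A data frame with one row per name: `name`, `cisd_type`,
#'   `subtype7` (`"none"` outside type 7), `motif_index` (NA or 1/2),
#'   `degenerate_flag`, `eukaryote_prefix`, `phylum_abbrev`, `genus_initial`,
#'   `species`, `genebank_id`.
#' @export
#' @examples
#' parse_record_name("Type6_Apro_M_magneticum_YP_423370")
parse_record_name <- function(name) {
  out <- lapply(name, parse_one_name)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

parse_one_name <- function(name) {
  toks <- strsplit(name, "_", fixed = TRUE)[[1]]
  if (length(toks) < 5L)
    stop("record name parse error: fewer than 5 underscore fields in '",
         name, "'")
  type_tok <- toks[1]
  phylum <- toks[2]
  genus <- toks[3]
  species <- toks[4]
  id <- paste(toks[-(1:4)], collapse = "_")
  if (!phylum %in% names(cisd_phylum_codes))
    stop("record name parse error: unknown phylum code '", phylum,
         "' in '", name, "'")
  if (nchar(genus) != 1L || !grepl("^[A-Za-z]$", genus))
    stop("record name parse error: genus initial '", genus,
         "' is not a single letter in '", name, "'")

  euk <- grepl("^e", type_tok)
  tok <- sub("^e", "", type_tok)
  degen <- grepl("'$", tok)
  tok <- sub("'$", "", tok)
  m <- regmatches(tok, regexec(
    "^Type(1|2a|2b|2|3|4|5|6|7|orphan)(DCC|CDC|DC)?([12])?$", tok))[[1]]
  if (length(m) == 0L)
    stop("record name parse error: unrecognised type field '", type_tok,
         "' in '", name, "'")
  type <- m[2]
  sub7 <- if (nzchar(m[3])) m[3] else "none"
  idx <- if (nzchar(m[4])) as.integer(m[4]) else NA_integer_
  if (sub7 != "none" && type != "7")
    stop("record name parse error: subtype on non-type-7 field '", type_tok,
         "'")
  data.frame(name = name, cisd_type = type, subtype7 = sub7,
             motif_index = idx, degenerate_flag = degen,
             eukaryote_prefix = euk, phylum_abbrev = phylum,
             genus_initial = genus, species = species, genebank_id = id,
             stringsAsFactors = FALSE)
}

#' Compose a record name from its parsed fields
#'
#' Inverse of [parse_record_name()]: `compose_record_name(parse_record_name(x))`
#' returns `x` for any name in the convention's namespace.
#'
#' @param meta Data frame as returned by [parse_record_name()].
#' @return Character vector of names.
#' @export
compose_record_name <- function(meta) {
  tok <- paste0("Type", meta$cisd_type)
  has7 <- meta$subtype7 != "none"
  tok[has7] <- paste0(tok[has7], meta$subtype7[has7])
  hasidx <- !is.na(meta$motif_index)
  tok[hasidx] <- paste0(tok[hasidx], meta$motif_index[hasidx])
  tok[meta$degenerate_flag] <- paste0(tok[meta$degenerate_flag], "'")
  tok[meta$eukaryote_prefix] <- paste0("e", tok[meta$eukaryote_prefix])
  paste(tok, meta$phylum_abbrev, meta$genus_initial, meta$species,
        meta$genebank_id, sep = "_")
}
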