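#' Deduplicate records to one species with its set of CISD types
#'
#' Multiple sequences of the same type in one species, and sequences from
#' multiple strains of one species, are counted once: the per-species result
#' is the union of types over all its records. The species key is
#' case-insensitive `(phylum, genus initial, species epithet)`; strain
#' designations are assumed already stripped from the epithet (record names
#' carry a single epithet token).
#'
#' @param meta Data frame as from [parse_record_name()] (needs
#'   `phylum_abbrev`, `genus_initial`, `species`, `cisd_type`).
#' @return Data frame with one row per species: `species_key`,
#'   `phylum_abbrev`, `genus_initial`, `species`, `types` (`,`-joined sorted
#'   type set). Records with an empty species are skipped; their number is
#'   in attribute `n_skipped` (with a warning when non-zero).
#' @export
dedup_species <- function(meta) {
  if (nrow(meta) == 0L) {
    out <- data.frame(species_key = character(), phylum_abbrev = character(),
                      genus_initial = character(), species = character(),
                      types = character(), stringsAsFactors = FALSE)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  bad <- is.na(meta$species) | !nzchar(meta$species)
  if (any(bad))
    warning(sum(bad), " record(s) without species skipped")
  meta <- meta[!bad, , drop = FALSE]
  key <- tolower(paste(meta$phylum_abbrev, meta$genus_initial, meta$species,
                       sep = "|"))
  sp <- split(seq_len(nrow(meta)), key)
  rows <- lapply(names(sp), function(k) {
    i <- sp[[k]]
    data.frame(species_key = k,
               phylum_abbrev = meta$phylum_abbrev[i[1]],
               genus_initial = meta$genus_initial[i[1]],
               species = meta$species[i[1]],
               types = paste(sort(unique(meta$cisd_type[i])), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species_key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Tabulate the phylogenetic distribution of CISD types
#'
#' Builds a distribution table in the layout of a per-taxon profile: one row
#' per taxon group, one column per type (1, 2, 2a, 2b counted under 2, 3-7,
#' orphan), plus `Any` (species with at least one CISD), `CISDpos` (those
#' also present in the reference genome set, when given), `Total` (genome
#' count for the group, when given) and `percent` (100 * CISDpos / Total).
#'
#' @param species_types Output of [dedup_species()].
#' @param taxonomy Data frame mapping `species_key` to `group` (taxon row
#'   label). Species without a mapping fall into `"unknown"`.
#' @param genome_set Optional character vector of species keys enumerating
#'   the sequenced-genome reference set; `CISDpos` counts `Any` species that
#'   are members. Default: equal to `Any`.
#' @param genome_totals Optional named numeric vector of per-group genome
#'   totals (reference-snapshot constants supplied by the user, not
#'   recomputed). Negative totals are an error.
#' @return Data frame, one row per group plus a `Total` row summing over
#'   groups (distinct species counted once).
#' @export
tabulate_profile <- function(species_types, taxonomy = NULL,
                             genome_set = NULL, genome_totals = NULL) {
  if (!is.null(genome_totals) && any(genome_totals < 0))
    stop("negative genome totals")
  tys <- c("1", "2", "3", "4", "5", "6", "7", "orphan")
  st <- species_types
  group <- rep("all", nrow(st))
  if (!is.null(taxonomy)) {
    idx <- match(st$species_key, taxonomy$species_key)
    group <- ifelse(is.na(idx), "unknown", taxonomy$group[idx])
  }
  type_list <- strsplit(st$types, ",", fixed = TRUE)
  # 2a/2b roll up into the type 2 column
  type_list <- lapply(type_list, function(t) unique(sub("^2[ab]$", "2", t)))
  groups <- unique(group)
  one_row <- function(sel, label) {
    counts <- vapply(tys, function(ty)
      sum(vapply(type_list[sel], function(t) ty %in% t, TRUE)), 0L)
    any_n <- sum(sel)
    pos <- if (is.null(genome_set)) any_n
           else sum(st$species_key[sel] %in% tolower(genome_set))
    tot <- if (!is.null(genome_totals) && label %in% names(genome_totals))
             as.numeric(genome_totals[[label]]) else NA_real_
    data.frame(group = label, t(counts), Any = any_n, CISDpos = pos,
               Total = tot,
               percent = if (is.na(tot) || tot == 0) NA_real_
                         else 100 * pos / tot,
               stringsAsFactors = FALSE, check.names = FALSE)
  }
  rows <- lapply(groups, function(g) one_row(group == g, g))
  rows <- c(rows, list(one_row(rep(TRUE, nrow(st)), "Total")))
  out <- do.call(rbind, rows)
  names(out)[2:9] <- tys
  rownames(out) <- NULL
  out
}

#' Within-genus gene-loss statistic
#'
#' For every genus of the sequenced-genome set with at least `min_genomes`
#' genomes and at least one CISD-positive species, computes the fraction of
#' its species that are CISD-positive, and summarises the fractions as mean
#' and standard deviation. A low mean indicates that sister species of
#' CISD-positive species frequently lack the gene, i.e. repeated gene loss.
#'
#' @param positives Character vector of CISD-positive species keys.
#' @param genome_set Data frame enumerating sequenced species: columns
#'   `species_key` and `genus`.
#' @param min_genomes Minimum genomes per qualifying genus (default 5).
#' @return List with `mean_percent`, `sd_percent` (population SD, divisor
#'   n), `sd_percent_sample` (divisor n - 1, `NA` for a single genus) and
#'   `n_genera`. All `NA`/0 when no genus qualifies (not an error).
#' @export
genus_loss_stat <- function(positives, genome_set, min_genomes = 5L) {
  positives <- tolower(positives)
  gs <- genome_set
  gs$species_key <- tolower(gs$species_key)
  per_genus <- split(gs$species_key, gs$genus)
  fracs <- c()
  for (members in per_genus) {
    members <- unique(members)
    npos <- sum(members %in% positives)
    if (length(members) >= min_genomes && npos >= 1L)
      fracs <- c(fracs, 100 * npos / length(members))
  }
  n <- length(fracs)
  if (n == 0L)
    return(list(mean_percent = NA_real_, sd_percent = NA_real_,
                sd_percent_sample = NA_real_, n_genera = 0L))
  m <- mean(fracs)
  list(mean_percent = m,
       sd_percent = sqrt(mean((fracs - m)^2)),
       sd_percent_sample = if (n > 1L) stats::sd(fracs) else NA_real_,
       n_genera = n)
}
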