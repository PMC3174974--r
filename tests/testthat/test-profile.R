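mk_meta <- function(type, phylum, genus, species) {
  n <- length(type)
  data.frame(cisd_type = type, subtype7 = rep("none", n),
             motif_index = rep(NA_integer_, n),
             degenerate_flag = rep(FALSE, n),
             eukaryote_prefix = rep(FALSE, n),
             phylum_abbrev = phylum, genus_initial = genus,
             species = species, stringsAsFactors = FALSE)
}

test_that("species deduplication merges strains and unions types", {
  meta <- rbind(mk_meta("4", "Bpro", "R", "solanacearum"),
                mk_meta("4", "Bpro", "R", "solanacearum"),   # second strain
                mk_meta("4", "Bpro", "R", "Solanacearum"))   # case variant
  sp <- dedup_species(meta)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$types, "4")

  expect_equal(nrow(dedup_species(mk_meta(character(0), character(0),
                                          character(0), character(0)))), 0L)

  meta <- rbind(mk_meta("1", "Chor", "H", "sapiens"),
                mk_meta("6", "Chor", "H", "sapiens"))
  sp <- dedup_species(meta)
  expect_equal(nrow(sp), 1L)
  expect_equal(sp$types, "1,6")

  skipped <- rbind(mk_meta("1", "Chor", "H", "sapiens"),
                   mk_meta("1", "Chor", "H", ""))
  expect_warning(sp <- dedup_species(skipped), "skipped")
  expect_equal(attr(sp, "n_skipped"), 1L)
})

test_that("the profile table counts species per type and group", {
  meta <- rbind(mk_meta("1", "Chor", "H", "sapiens"),
                mk_meta("6", "Chor", "H", "sapiens"),
                mk_meta("4", "Bpro", "R", "solanacearum"),
                mk_meta("4", "Acti", "T", "thermophilus"),
                mk_meta("3", "Cren", "P", "calidifontis"))
  sp <- dedup_species(meta)
  tax <- data.frame(species_key = sp$species_key,
                    group = phylum_group(sp$phylum_abbrev),
                    stringsAsFactors = FALSE)
  tab <- tabulate_profile(sp, tax,
                          genome_totals = c(bacteria = 10, eukaryote = 4))
  bac <- tab[tab$group == "bacteria", ]
  expect_equal(bac$`4`, 2)
  expect_equal(bac$Any, 2)
  expect_equal(bac$percent, 20)
  euk <- tab[tab$group == "eukaryote", ]
  expect_equal(euk$`1`, 1)      # one species despite two records
  expect_equal(euk$`6`, 1)
  expect_equal(euk$Any, 1)      # dual-type species counts once in Any
  tot <- tab[tab$group == "Total", ]
  expect_equal(tot$Any, 4)

  empty <- tabulate_profile(dedup_species(mk_meta(character(0),
    character(0), character(0), character(0))))
  expect_true(all(empty[, as.character(c(1:7))] == 0))
  expect_error(tabulate_profile(sp, tax, genome_totals = c(bacteria = -1)),
               "negative")
})

test_that("a genome reference set separates CISD+ from Any", {
  meta <- rbind(mk_meta("4", "Bpro", "R", "solanacearum"),
                mk_meta("4", "Acti", "T", "thermophilus"))
  sp <- dedup_species(meta)
  tab <- tabulate_profile(sp, genome_set = sp$species_key[1])
  row <- tab[tab$group == "all", ]
  expect_equal(row$Any, 2)
  expect_equal(row$CISDpos, 1)
})

test_that("tabulation is permutation-invariant and idempotent under strains", {
  set.seed(8)
  g <- gen_sequences(60, seed = 8)
  meta <- parse_record_name(g$records$id)
  sp1 <- dedup_species(meta)
  sp2 <- dedup_species(meta[sample(nrow(meta)), ])
  expect_equal(sp1, sp2, ignore_attr = TRUE)
  # duplicating every record as a "second strain" changes nothing
  sp3 <- dedup_species(rbind(meta, meta))
  expect_equal(sp1, sp3, ignore_attr = TRUE)
  t1 <- tabulate_profile(sp1)
  t3 <- tabulate_profile(sp3)
  expect_equal(t1, t3)
})

test_that("the within-genus gene-loss statistic does the arithmetic", {
  gs <- data.frame(species_key = paste0("sp", 1:5), genus = "g1",
                   stringsAsFactors = FALSE)
  r <- genus_loss_stat(c("sp1", "sp2"), gs, min_genomes = 5)
  expect_equal(r$mean_percent, 40)
  expect_equal(r$sd_percent, 0)
  expect_equal(r$n_genera, 1L)

  # saturation: every genome positive in every genus
  gs2 <- data.frame(species_key = paste0("sp", 1:10),
                    genus = rep(c("g1", "g2"), each = 5))
  r <- genus_loss_stat(paste0("sp", 1:10), gs2, min_genomes = 5)
  expect_equal(r$mean_percent, 100)
  expect_equal(r$sd_percent, 0)
  expect_equal(r$n_genera, 2L)

  # genera below the genome threshold or without positives do not qualify
  gs3 <- rbind(gs2, data.frame(species_key = "spX", genus = "g3"))
  r <- genus_loss_stat(c("sp1", "spX"), gs3, min_genomes = 5)
  expect_equal(r$n_genera, 1L)
  r <- genus_loss_stat(character(0), gs3)
  expect_equal(r$n_genera, 0L)
  expect_true(is.na(r$mean_percent))
})

test_that("planted per-genus retention is recovered within sampling error", {
  set.seed(17)
  p <- 0.35
  genera <- paste0("g", 1:40)
  gs <- data.frame(species_key = paste0("sp", 1:400),
                   genus = rep(genera, each = 10))
  pos <- gs$species_key[stats::runif(400) < p]
  r <- genus_loss_stat(pos, gs, min_genomes = 5)
  # binomial sampling error of the mean over ~40 genera of 10 genomes
  se <- 100 * sqrt(p * (1 - p) / 10 / r$n_genera)
  # conditioning on >=1 positive biases the mean up slightly; allow 4 se
  expect_lt(abs(r$mean_percent - 100 * p), 4 * se + 100 * (1 - p)^10)
  expect_gt(r$sd_percent, 0)
})
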