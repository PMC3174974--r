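mk_hits <- function(starts, status = "strict") {
  n <- length(starts)
  data.frame(id = rep("r", n), start = starts,
             window = rep("", n), status = rep(status, length.out = n),
             n_mismatch = rep(0L, n), mismatches = rep("", n),
             lig_c2 = starts + 1L,
             lig_c4 = starts + 3L, lig_c13 = starts + 12L,
             lig_h17 = starts + 16L, lid_p = rep(TRUE, n),
             stringsAsFactors = FALSE)
}
seg <- function(kind, start, end)
  data.frame(kind = kind, start = start, end = end, stringsAsFactors = FALSE)

test_that("the type decision order: tandem, fusion, DUF1271, taxon, orphan", {
  # two strict motifs 20 residues apart, bacterium: tandem type 6
  h2 <- mk_hits(c(10L, 47L))   # spacing = 47 - 26 - 1 = 20
  expect_equal(assign_type(h2, NULL, "bacteria")$cisd_type, "6")
  # with a C-terminal FMN-binding fusion: type 5
  call <- assign_type(h2, seg("FMN_binding", 80L, 140L), "bacteria")
  expect_equal(call$cisd_type, "5")
  expect_true("fmn_fusion" %in% call$evidence)
  # architecture beats taxonomy: a tandem archaeal sequence is 6, not 3
  expect_equal(assign_type(h2, NULL, "archaea")$cisd_type, "6")
  # FMN segment *before* the motifs does not make a type 5
  expect_equal(assign_type(mk_hits(c(100L, 137L)),
                           seg("FMN_binding", 10L, 70L),
                           "bacteria")$cisd_type, "6")

  # single motif + DUF1271: type 7 with subtype from segment order
  call <- assign_type(mk_hits(90L), seg("DUF1271", 10L, 70L), "bacteria")
  expect_equal(call$cisd_type, "7")
  expect_equal(call$subtype7, "DC")

  # single motif by taxon
  expect_equal(assign_type(mk_hits(30L), NULL, "eukaryote")$cisd_type, "1")
  expect_equal(assign_type(mk_hits(30L), NULL, "apicomplexa")$cisd_type, "2")
  expect_equal(assign_type(mk_hits(30L), NULL, "archaea")$cisd_type, "3")
  expect_equal(assign_type(mk_hits(30L), NULL, "bacteria")$cisd_type, "4")

  # no motif at all
  none <- assign_type(mk_hits(integer(0)), NULL, "bacteria")
  expect_equal(none$cisd_type, "orphan")
  expect_true("no_motif" %in% none$evidence)
  # every call carries evidence
  expect_gt(length(assign_type(mk_hits(30L), NULL, "archaea")$evidence), 0L)
})

test_that("his_to_cys hits count as motif-bearing, disrupted scan hits do not", {
  h <- mk_hits(c(10L, 47L), status = c("strict", "his_to_cys"))
  expect_equal(assign_type(h, NULL, "bacteria")$cisd_type, "6")
  h <- mk_hits(c(10L, 47L), status = c("strict", "disrupted"))
  expect_equal(assign_type(h, NULL, "bacteria")$cisd_type, "4")
  # ...unless the architecture annotation vouches for the second motif
  arch <- seg("CISD_motif", c(10L, 47L), c(26L, 63L))
  expect_equal(assign_type(h, arch, "bacteria")$cisd_type, "6")
})

test_that("tandem spacing bounds are respected", {
  expect_equal(assign_type(mk_hits(c(10L, 30L)),   # spacing 3: too close
                           NULL, "bacteria")$cisd_type, "4")
  expect_equal(assign_type(mk_hits(c(10L, 90L)),   # spacing 63: too far
                           NULL, "bacteria")$cisd_type, "4")
  expect_equal(assign_type(mk_hits(c(10L, 90L)), NULL, "bacteria",
                           spacing_range = c(5, 80))$cisd_type, "6")
})

test_that("type 7 subtypes follow the segment order", {
  expect_equal(assign_subtype7(seg(c("DUF1271", "CISD_motif"),
                                   c(1L, 80L), c(70L, 96L))), "DC")
  expect_equal(assign_subtype7(seg(c("DUF1271", "CISD_motif", "CISD_motif"),
                                   c(1L, 80L, 150L), c(70L, 96L, 166L))),
               "DCC")
  expect_equal(assign_subtype7(seg(c("CISD_motif", "DUF1271", "CISD_motif"),
                                   c(1L, 30L, 150L), c(17L, 120L, 166L))),
               "CDC")
  expect_error(assign_subtype7(seg(c("CISD_motif", "CISD_motif", "DUF1271"),
                                   c(1L, 30L, 60L), c(17L, 46L, 130L))),
               "CCD")
})

test_that("homology seeds refine apicomplexan and bacterial calls", {
  seeds <- list(`2a` = "MKKAAWWAACDGSHAAA", `2b` = "MQQLLYYVVCDGSHVVV",
                `3` = "MAAACCCDDDGGGSSSH")
  s2a <- "MKKAAWWAACDGSHAAT"    # near seed 2a
  call <- assign_type(mk_hits(3L), NULL, "apicomplexa",
                      seeds = seeds, sequence = s2a)
  expect_equal(call$cisd_type, "2a")
  expect_equal(call$confidence, "homology")
  call <- assign_type(mk_hits(3L), NULL, "bacteria",
                      seeds = seeds, sequence = "MAAACCCDDDGGGSSSR")
  expect_equal(call$cisd_type, "3")   # bacterial member of the archaeal family
  # a tie is flagged, not silently resolved
  call <- assign_type(mk_hits(3L), NULL, "apicomplexa",
                      seeds = list(`2a` = "AAAA", `2b` = "AAAA"),
                      sequence = "AAAA")
  expect_true("seed_identity_unresolved" %in% call$evidence)
})

test_that("classification is independent of record order and deterministic", {
  g <- gen_sequences(30, seed = 21)
  hits <- scan_cdgsh(g$records)
  call_for <- function(i) {
    id <- g$records$id[i]
    assign_type(hits[hits$id == id, , drop = FALSE],
                g$arch[g$arch$id == id, c("kind", "start", "end")],
                g$truth$taxon[i])$cisd_type
  }
  fwd <- vapply(seq_len(nrow(g$records)), call_for, "")
  rev_ <- vapply(rev(seq_len(nrow(g$records))), call_for, "")
  expect_equal(fwd, rev(rev_))
})

test_that("column conservation counts non-gap rows in the residue set", {
  aln <- data.frame(id = paste0("s", 1:5), description = "",
                    residues = c("AKA", "AKA", "AKC", "A-A", "AQA"),
                    stringsAsFactors = FALSE)
  expect_equal(column_conservation(aln, 1, "A"), 1.0)
  expect_equal(column_conservation(aln, 2, "K"), 0.75)      # 3 of 4 non-gap
  expect_equal(column_conservation(aln, 2, c("K", "Q")), 1.0)
  nogap <- transform(aln, residues = c("AKA", "AKA", "AKC", "AAA", "AQA"))
  expect_equal(column_conservation(nogap, 2, "K"), 0.6)     # 3 of 5 rows
  expect_error(column_conservation(aln, 9, "A"), "outside")
  ragged <- rbind(aln, data.frame(id = "s6", description = "",
                                  residues = "AAAA"))
  expect_error(column_conservation(ragged, 1, "A"), "ragged")
})
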