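test_that("cluster detection counts complete Fe2S2 groups", {
  expect_equal(length(find_clusters(template_module())), 1L)
  expect_equal(length(find_clusters(gen_dimer(14.2, seed = 2))), 2L)
  # apo model: no clusters
  apo <- template_module()
  apo$atoms <- apo$atoms[!apo$atoms$het, , drop = FALSE]
  expect_equal(length(find_clusters(apo)), 0L)
  # an incomplete group (lone Fe) is excluded with a warning
  lone <- template_module()
  lone$atoms <- rbind(lone$atoms,
                      make_atom(30, 30, 30, "FE", "FE1", resno = 300L,
                                resid = "FES", het = TRUE))
  expect_warning(cl <- find_clusters(lone), "incomplete")
  expect_equal(length(cl), 1L)
  # de novo assembly when the het group is not named FES/FE2
  anon <- template_module()
  anon$atoms$resid[anon$atoms$het] <- "UNL"
  expect_equal(length(find_clusters(anon)), 1L)
})

test_that("ligand assignment finds the 3Cys1His set at the right residues", {
  tm <- template_module(start_resno = 24L)   # motif position 1 at 24
  cl <- find_clusters(tm)[[1]]
  lig <- assign_ligands(tm, cl)
  expect_equal(lig$resno, c(25L, 27L, 36L, 40L))
  expect_equal(attr(lig, "coordination"), "3Cys1His")
  # isolated cluster far from the protein: empty with a warning
  far <- tm
  far$atoms[far$atoms$het, c("x", "y", "z")] <-
    far$atoms[far$atoms$het, c("x", "y", "z")] + 50
  expect_warning(lig <- assign_ligands(far, find_clusters(far)[[1]]),
                 "no ligand")
  expect_equal(nrow(lig), 0L)
})

test_that("module extraction anchors on the first cysteine ligand", {
  tm <- template_module(start_resno = 24L)
  mod <- extract_module(tm, find_clusters(tm)[[1]])
  expect_equal(mod$resnos, 24:40)
  expect_equal(nrow(mod$ca_segment), 17L)
  # identity: extraction returns the template Calpha coordinates exactly
  ca <- tm$atoms[tm$atoms$elety == "CA", ]
  expect_equal(mod$ca_segment, atom_xyz(ca[order(ca$resno), ]))
  # chain break inside the window is an error naming the missing residues
  broken <- tm
  broken$atoms <- broken$atoms[!(broken$atoms$resno == 30L &
                                   broken$atoms$elety == "CA"), ]
  expect_error(extract_module(broken, find_clusters(broken)[[1]]), "30")
})

test_that("Kabsch superposition is exact on rigid motions and optimal", {
  set.seed(31)
  A <- random_pointset()
  self <- superpose(A, A)
  expect_equal(self$rmsd, 0, tolerance = 1e-12)
  expect_equal(self$R, diag(3), tolerance = 1e-9)

  R <- rotation_about(c(1, -2, 0.5), 71)
  B <- sweep(A %*% R, 2, c(4, -3, 9), "+")
  expect_lt(superpose(A, B)$rmsd, 1e-9)

  # agreement with the independent quaternion oracle on noisy pairs
  for (i in 1:50) {
    A <- random_pointset()
    B <- random_pointset()
    expect_equal(superpose(A, B)$rmsd, quaternion_rmsd(A, B),
                 tolerance = 1e-9)
  }

  # optimality: no random rigid transform does better
  A <- random_pointset()
  B <- A + matrix(rnorm(51, sd = 0.3), ncol = 3)
  opt <- superpose(A, B)$rmsd
  for (i in 1:25) {
    R <- rotation_about(rnorm(3), runif(1, 0, 180))
    t <- rnorm(3)
    expect_gte(rmsd_raw(sweep(A %*% R, 2, t, "+"), B) + 1e-12, opt)
  }

  expect_error(superpose(A, A[1:10, ]), "mismatch")
  expect_true(all(abs(det(superpose(random_pointset(),
                                    random_pointset())$R) - 1) < 1e-9))
})

test_that("cluster distances come from 4-atom centroids", {
  tm <- template_module()
  cl <- find_clusters(tm)[[1]]
  expect_equal(cluster_distance(cl, cl), 0)
  md <- gen_dimer(center_distance = 10, seed = 3)
  cls <- find_clusters(md)
  expect_equal(cluster_distance(cls[[1]], cls[[2]]), 10, tolerance = 1e-9)
})

test_that("the inter-module shift angle recovers constructed rotations", {
  ref <- gen_dimer(14.2, shift_angle = 0, symmetric = TRUE)
  expect_equal(intermodule_angle(ref, ref), 0, tolerance = 1e-7)
  tg <- gen_dimer(14.2, shift_angle = 15, symmetric = FALSE)
  expect_equal(intermodule_angle(ref, tg), 15, tolerance = 1e-7)
  expect_error(intermodule_angle(ref, template_module()), "2 modules")
})

test_that("SASA matches closed forms and burial behaves", {
  # isolated atom: 4 pi (r + probe)^2 within quadrature error
  one <- as_model(make_atom(0, 0, 0, "C", "C"))
  a <- sasa(one)
  expect_equal(as.numeric(a), 4 * pi * (1.70 + 1.4)^2, tolerance = 0.01)

  # two overlapping equal spheres vs the analytic spherical-cap formula
  two <- as_model(rbind(make_atom(0, 0, 0, "C", "C"),
                        make_atom(2, 0, 0, "C", "C", resno = 2L)))
  r <- 1.70 + 1.4
  analytic <- 2 * (4 * pi * r^2 - 2 * pi * r * (r - 1))
  expect_equal(sum(sasa(two)), analytic, tolerance = 0.01 * analytic)

  # an atom enclosed by a shell is fully buried
  shell_pts <- 4 * cisdtools:::sphere_points(80)
  shell <- do.call(rbind, lapply(seq_len(80), function(i)
    make_atom(shell_pts[i, 1], shell_pts[i, 2], shell_pts[i, 3], "C", "C",
              resno = i + 1L)))
  enc <- as_model(rbind(make_atom(0, 0, 0, "C", "C"), shell))
  expect_equal(sasa(enc)[1], 0)

  # unknown element: error unless a default radius is given
  q <- as_model(make_atom(0, 0, 0, "QQ", "QQ"))
  expect_error(sasa(q), "radius")
  expect_gt(sasa(q, default_radius = 1.5)[1], 0)

  # buried area: symmetric dimers bury the same area per chain,
  # distant chains bury none
  md <- gen_dimer(center_distance = 13, symmetric = TRUE, seed = 5)
  ba <- buried_area(md, "A", "B", n_points = 240L)
  expect_gt(ba[["perA"]], 0)
  # the two chains sample the quadrature sphere in different orientations,
  # so equality holds to quadrature accuracy only
  expect_equal(ba[["perA"]], ba[["perB"]], tolerance = 0.02)
  far <- gen_dimer(center_distance = 100, shift_angle = 0,
                   symmetric = TRUE, seed = 5)
  bf <- buried_area(far, "A", "B", n_points = 240L)
  expect_equal(unname(bf), c(0, 0))
  expect_error(buried_area(md, "A", "Q"), "absent")
})

test_that("geometry is invariant under a global rigid motion", {
  md <- gen_dimer(14.2, symmetric = TRUE, seed = 9)
  R <- rotation_about(c(2, 1, -1), 53)
  moved <- md
  xyz <- sweep(atom_xyz(md$atoms) %*% R, 2, c(10, -4, 2), "+")
  moved$atoms$x <- xyz[, 1]; moved$atoms$y <- xyz[, 2]
  moved$atoms$z <- xyz[, 3]
  d0 <- cluster_distance(find_clusters(md)[[1]], find_clusters(md)[[2]])
  d1 <- cluster_distance(find_clusters(moved)[[1]], find_clusters(moved)[[2]])
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_equal(pseudo_dyad(md)$dyad_rmsd, pseudo_dyad(moved)$dyad_rmsd,
               tolerance = 1e-9)
  expect_equal(sum(sasa(md, n_points = 240L)),
               sum(sasa(moved, n_points = 240L)), tolerance = 0.005)
  expect_equal(intermodule_angle(md, moved), 0, tolerance = 1e-6)
})

test_that("hydrogen bonds use the heavy-atom N/O distance criterion", {
  pair <- as_model(rbind(
    make_atom(0, 0, 0, "N", "N", resno = 1L, resid = "ALA"),
    make_atom(2.9, 0, 0, "O", "O", resno = 5L, resid = "GLY")))
  hb <- detect_hbonds(pair)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$dist, 2.9)

  none <- as_model(rbind(
    make_atom(0, 0, 0, "N", "N", resno = 1L),
    make_atom(9, 0, 0, "O", "O", resno = 5L)))
  expect_equal(nrow(detect_hbonds(none)), 0L)

  # same-residue and covalent-range pairs are excluded; C atoms ignored
  excl <- as_model(rbind(
    make_atom(0, 0, 0, "N", "N", resno = 1L),
    make_atom(1.4, 0, 0, "O", "O", resno = 1L),
    make_atom(0, 3.0, 0, "C", "C", resno = 7L)))
  expect_equal(nrow(detect_hbonds(excl)), 0L)
})

test_that("grid-accelerated contacts equal the all-pairs oracle", {
  set.seed(23)
  for (trial in 1:3) {
    n <- 250
    at <- do.call(rbind, lapply(seq_len(2 * n), function(i)
      make_atom(runif(1, 0, 30), runif(1, 0, 30), runif(1, 0, 30),
                "C", "CA", chain = if (i <= n) "A" else "B",
                resno = i, resid = "GLY")))
    model <- as_model(at)
    got <- close_contacts(model, "A", "B", d_max = 3.8)
    want <- brute_contacts(model, "A", "B", d_max = 3.8)
    expect_equal(nrow(got), nrow(want))
    expect_equal(sort(got$dist), sort(want$dist), tolerance = 1e-12)
  }
  # backbone filter and empty case
  md <- gen_dimer(center_distance = 100, seed = 2)
  expect_equal(nrow(close_contacts(md, "A", "B", d_max = 3.8)), 0L)
})

test_that("pseudo-dyad symmetry: exact, noisy, and module-count errors", {
  sym <- gen_dimer(14.2, symmetric = TRUE, seed = 13)
  pd <- pseudo_dyad(sym)
  expect_equal(pd$dyad_rmsd, 0, tolerance = 1e-9)
  expect_equal(pd$rotation, 180, tolerance = 1e-6)

  # tandem single-chain variant behaves identically
  tand <- gen_dimer(14.2, symmetric = TRUE, seed = 13, tandem = TRUE)
  expect_equal(pseudo_dyad(tand)$rotation, 180, tolerance = 1e-6)

  noisy <- gen_dimer(14.2, symmetric = TRUE, noise_sigma = 0.3, seed = 13)
  pdn <- pseudo_dyad(noisy)
  expect_gt(pdn$dyad_rmsd, 0.1)
  expect_lt(pdn$dyad_rmsd, 0.9)            # ~ noise scale (sqrt(2) * sigma)
  expect_equal(pdn$rotation, 180, tolerance = 5)
  expect_error(pseudo_dyad(template_module()), "2 modules")
})
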