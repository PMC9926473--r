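# Backbone H-bond detection and structure annotation.

helix12 <- gen_ideal_helix(12)

test_that("ideal helix yields exactly the i -> i-4 bond set", {
  hb <- detect_hbonds(helix12$atoms, cutoff = 2.6)
  prim <- hb[hb$primary, ]
  expect_equal(prim$donor, 5:12)
  expect_equal(prim$acceptor, 1:8)
  expect_true(all(prim$helical_offset == 4))
  expect_true(all(prim$distance <= 2.6))
  # cutoff below the generated H...O distance empties the set
  expect_equal(nrow(detect_hbonds(helix12$atoms,
                                  cutoff = min(prim$distance) - 0.1)), 0)
  expect_equal(nrow(detect_hbonds(helix12$atoms, cutoff = 0)), 0)
})

test_that("detection is invariant under rigid-body motion", {
  hb0 <- detect_hbonds(helix12$atoms)
  hb1 <- detect_hbonds(transform_backbone(helix12$atoms))
  expect_equal(hb1$donor, hb0$donor)
  expect_equal(hb1$acceptor, hb0$acceptor)
  expect_equal(hb1$distance, hb0$distance, tolerance = 1e-9)
})

test_that("PDB round trip preserves coordinates and rebuilds protons", {
  pdb_file <- tempfile(fileext = ".pdb")
  gen_ideal_helix(12, file = pdb_file)
  atoms <- load_backbone(pdb_file)
  expect_equal(atoms$N, helix12$atoms$N, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_equal(atoms$H[-1, ], helix12$atoms$H[-1, ], tolerance = 1e-3,
               ignore_attr = TRUE)

  # strip the protons; loading must rebuild them at ideal geometry
  lines <- readLines(pdb_file)
  atom_name <- substr(lines, 13, 16)
  noh <- lines[!(startsWith(lines, "ATOM") & trimws(atom_name) == "H")]
  noh_file <- tempfile(fileext = ".pdb")
  writeLines(noh, noh_file)
  rebuilt <- load_backbone(noh_file)
  dev <- sqrt(rowSums((rebuilt$H - helix12$atoms$H)^2))
  expect_true(all(dev[-1] < 0.1))

  # dropping carbonyl oxygens is a malformed structure
  noo <- lines[!(startsWith(lines, "ATOM") & trimws(atom_name) == "O")]
  noo_file <- tempfile(fileext = ".pdb")
  writeLines(noo, noo_file)
  expect_error(load_backbone(noo_file), class = "hdx_malformed_structure")
})

test_that("annotation merges acceptors and flags non-native protection", {
  hb <- detect_hbonds(helix12$atoms)
  records <- data.frame(position = c(6, 9, 2, 3),
                        P = c(3.1, 5.0, 2.5, 1.2),
                        class = classify_protection(c(3.1, 5.0, 2.5, 1.2)))
  ann <- annotate_with_structure(records, hb)
  expect_equal(ann$acceptor[ann$position == 6], 2)
  expect_equal(ann$helical_offset[ann$position == 6], 4)
  expect_lt(ann$hbond_distance[ann$position == 9], 2.6)
  # protected but no native acceptor (donor 2 has no i-4 partner)
  expect_true(ann$non_native_protection[ann$position == 2])
  # unprotected without acceptor: carried, not flagged
  expect_false(ann$non_native_protection[ann$position == 3])
  expect_error(annotate_with_structure(data.frame(P = 1), hb),
               class = "hdx_join_failure")
})

test_that("the colormap writer stores P in the B-factor and tiers strictly", {
  records <- data.frame(position = c(5, 6, 7),
                        P = c(5.2, 3.0, NA))
  out <- tempfile(fileext = ".pdb")
  sidecar <- write_structure_colormap(helix12$atoms, records, out)
  expect_equal(sidecar$tier[sidecar$position == 5], ">5")
  # P exactly 3.0 exceeds only the 2.0 threshold under strict inequality
  expect_equal(sidecar$tier[sidecar$position == 6], ">2")
  expect_equal(sidecar$tier[sidecar$position == 7], "none")
  expect_equal(sidecar$P[sidecar$position == 7], 0)
  # round trip: the written B-factor recovers P to 2 decimals
  back <- bio3d::read.pdb(out, verbose = FALSE)
  b_at_res <- function(r) unique(back$atom$b[back$atom$resno == r])
  expect_equal(b_at_res(5), 5.2)
  expect_equal(b_at_res(6), 3.0)
  expect_equal(b_at_res(7), 0)
  expect_true(file.exists(paste0(out, ".tiers.tsv")))
})
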