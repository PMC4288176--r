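test_that("the ideal three-layer quadruplex yields exactly three
           quartets matching the construction", {
  q <- ideal_quadruplex()
  qs <- detect_quartets(q)
  expect_identical(nrow(qs), 3L)
  truth <- attr(q, "truth")$columns
  for (i in 1:3) {
    got <- sort(qs$members[[i]]$resno)
    lay <- truth$layer[match(got, truth$resno)]
    expect_identical(length(unique(lay)), 1L)  # one layer per quartet
    expect_identical(sort(unique(truth$column[match(got,
                                                    truth$resno)])), 1:4)
  }
  expect_true(all(qs$planarity_rms < 0.2))
})

test_that("an idealized B-DNA duplex contains no quartet", {
  expect_identical(nrow(detect_quartets(build_bdna_duplex())), 0L)
})

test_that("detection is invariant under rigid motion and file
           reordering", {
  q <- ideal_quadruplex()
  ref <- detect_quartets(q)
  set.seed(53)
  moved <- rigid_move(q)
  shuffled <- moved[sample.int(nrow(moved)), ]
  got <- detect_quartets(shuffled)
  expect_identical(nrow(got), nrow(ref))
  ref_sets <- lapply(ref$members, function(m) sort(m$resno))
  got_sets <- lapply(got$members, function(m) sort(m$resno))
  expect_setequal(got_sets, ref_sets)
})

test_that("layer count is recovered across the twist/rise window", {
  for (twist in c(20, 30, 40)) {
    for (rise in c(3.0, 3.3, 3.6)) {
      for (n_layers in c(2, 3, 4)) {
        q <- build_quadruplex(n_layers = n_layers, twist = twist,
                              rise = rise)
        expect_identical(nrow(detect_quartets(q)), as.integer(n_layers),
                         info = sprintf("twist %s rise %s layers %s",
                                        twist, rise, n_layers))
      }
    }
  }
})

test_that("guanines missing base atoms are skipped with a warning", {
  q <- ideal_quadruplex()
  broken <- dplyr::filter(q, !(resno == 1 & atom == "O6"))
  expect_warning(qs <- detect_quartets(broken), "missing base atoms")
  expect_identical(nrow(qs), 2L)  # layer 1 can no longer close its cycle
})

test_that("the core orders layers geometrically whatever the input
           order, with the prescribed rise", {
  q <- build_quadruplex(twist = 25, rise = 3.4)
  qs <- detect_quartets(q)
  core <- build_core(qs)
  expect_identical(core$n_layers, 3L)
  expect_equal(core$rise_per_layer, c(3.4, 3.4), tolerance = 1e-6)
  shuffled <- qs[c(2, 3, 1), ]
  core2 <- build_core(shuffled)
  expect_equal(core2$axis, core$axis, tolerance = 1e-9)
  expect_equal(core2$centroids, core$centroids, tolerance = 1e-9)
  # axis points away from the layer holding the 5'-most guanine
  b <- core$layers$members[[1]]
  expect_true(min(purrr::map_int(core$layers$members,
                                 function(m) min(m$resno))) %in% b$resno)
})

test_that("non-stacking quartets raise a stacking-break error", {
  q <- ideal_quadruplex()
  qs <- detect_quartets(q)
  far <- qs
  far$centroid[[3]] <- far$centroid[[3]] + c(0, 0, 20)
  expect_error(build_core(far[c(1, 3), ]), "stacking break")
})

test_that("channel ions are separated from external ions by the
           axial/radial rule", {
  q <- ideal_quadruplex_ions()
  core <- build_core(detect_quartets(q))
  ions <- assign_ions(core, q)
  expect_identical(nrow(ions), 2L)
  expect_setequal(ions$role, "channel")
  expect_identical(sort(ions$layer_gap), 1:2)
  # an ion 8 A off-axis is external, annotated with its nearest residue
  ext <- tibble::tibble(model = 1L, chain = "A", resno = 200L,
                        resname = "K", atom = "K", elem = "K",
                        x = 8, y = 0, z = 3.3, occ = 1, b = 15,
                        hetero = TRUE)
  ions2 <- assign_ions(core, dplyr::bind_rows(q, ext))
  out <- ions2[ions2$resno == 200, ]
  expect_identical(out$role, "external")
  expect_false(is.na(out$nearest))
  # an ion exactly midway between two layer centroids is channel
  mid <- dplyr::mutate(ext, resno = 201L, x = 0, y = 0, z = 1.65)
  expect_identical(
    assign_ions(core, dplyr::bind_rows(q, mid))$role[3], "channel")
  # no ions at all is an empty assignment, not an error
  expect_identical(nrow(assign_ions(core, ideal_quadruplex())), 0L)
})

test_that("the parallel fold classifies as four parallel columns joined
           by propeller loops", {
  q <- ideal_quadruplex()
  topo <- classify_topology(build_core(detect_quartets(q)), q)
  expect_identical(topo$n_layers, 3L)
  expect_identical(nrow(topo$loops), 3L)
  expect_setequal(topo$loops$type, "propeller")
  expect_true(all(topo$strand_senses$parallel))
  expect_identical(nrow(topo$snapback_residues), 0L)
  expect_identical(nrow(topo$tracts), 4L)
  g <- glance(topo)
  expect_identical(g$n_propeller, 3L)
  expect_true(g$all_parallel)
})

test_that("the antiparallel arrangement yields lateral loops and mixed
           senses", {
  q <- build_quadruplex(antiparallel = TRUE)
  topo <- classify_topology(build_core(detect_quartets(q)), q)
  expect_true(any(topo$loops$type == "lateral"))
  expect_false(all(topo$strand_senses$parallel))
})

test_that("a core guanine renumbered outside its tract is flagged as a
           snapback", {
  q <- ideal_quadruplex()
  # move the 5'-terminal guanine of column 4 to the end of the sequence,
  # as a snapback insertion would appear
  target <- attr(q, "truth")$columns
  res_move <- target$resno[target$column == 4 & target$layer == 1]
  q2 <- dplyr::mutate(q, resno = ifelse(resno == res_move, 99L, resno))
  topo <- classify_topology(build_core(detect_quartets(q2)), q2)
  expect_identical(topo$snapback_residues$resno, 99L)
})

test_that("topology refuses a chain that lacks the core", {
  q <- ideal_quadruplex()
  core <- build_core(detect_quartets(q))
  other <- dplyr::mutate(q, chain = "B")
  expect_error(classify_topology(core, dplyr::filter(other,
                                                     chain == "B")),
               "lacks the core")
})
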