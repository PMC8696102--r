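# two-residue toy structures with prescribed d_alpha / d_C geometry: residues
# far apart along x, side-chain centers placed to set the d_C distance.
two_residue <- function(d_alpha, d_c) {
  ca <- rbind(c(0, 0, 0), c(d_alpha, 0, 0))
  sc <- rbind(c((d_alpha - d_c) / 2, 1e-6, 0), c((d_alpha + d_c) / 2, 1e-6, 0))
  structure3d("toy", chain = c("A", "A"), resno = 1:2, ca = ca, sc = sc)
}

test_that("contact criterion implements both distance clauses", {
  crit <- contact_criterion()
  # d_alpha = 6.0: contact through the CA clause
  expect_equal(find_contacts(two_residue(6.0, 9.0), 1L, crit), 2L)
  # d_alpha = 7.0, d_C = 7.5 (excess only 0.5 < 0.75): no contact
  expect_length(find_contacts(two_residue(7.0, 7.5), 1L, crit), 0L)
  # d_alpha = 8.8, d_C = 8.0 (excess 0.8): contact through the side-chain clause
  expect_equal(find_contacts(two_residue(8.8, 8.0), 1L, crit), 2L)
})

test_that("contact relation is symmetric", {
  s <- small_chain()
  cm <- descalign:::contact_matrix(s)
  expect_true(isSymmetric(cm))
  for (i in c(3L, 12L, 25L)) {
    expect_equal(unname(which(cm[i, ])), find_contacts(s, i))
  }
})

test_that("merge_elements merges overlapping, touching and separate windows", {
  i <- 10L
  # centers i and i+2: windows overlap -> one 7-residue segment
  expect_equal(merge_elements(c(i, i + 2L)), list(c(8L, 14L)))
  # centers i and i+5: one uncovered residue between -> two 5-residue segments
  expect_equal(unname(merge_elements(c(i, i + 5L))), list(c(8L, 12L), c(13L, 17L)))
  # centers i and i+4: windows touch at i+2 -> one segment
  expect_equal(unname(merge_elements(c(i, i + 4L))), list(c(8L, 16L)))
})

test_that("descriptor construction follows the element and segment rules", {
  # isolated mid-chain residue with no contacts: central element only
  far <- structure3d("far", chain = rep("A", 9), resno = 1:9,
                     ca = cbind(seq(0, 160, by = 20), 0, 0))
  d <- build_descriptor(far, 5L)
  expect_length(d$contacts, 0L)
  expect_equal(d$element_centers, 5L)
  expect_equal(unname(d$segments), list(c(3L, 7L)))
  expect_length(d$members, 5L)
  # centers too close to a terminus have no descriptor
  expect_null(build_descriptor(far, 2L))
  expect_null(build_descriptor(far, 9L))
})

test_that("descriptor segments exactly cover the union of element windows", {
  s <- small_chain()
  for (i in seq_len(s$n)) {
    d <- build_descriptor(s, i)
    if (is.null(d)) next
    members <- sort(unique(unlist(lapply(d$element_centers, function(c) (c-2):(c+2)))))
    covered <- sort(unlist(lapply(d$segments, function(r) r[1]:r[2])))
    expect_equal(covered, members)
    expect_lte(length(d$segments), length(d$element_centers))
    expect_true(i %in% d$element_centers)
  }
})

test_that("descriptors are invariant under rigid transformation", {
  s <- small_chain()
  s2 <- rigid_copy(s, name = s$name)
  for (i in c(5L, 15L, 20L, 30L)) {
    d1 <- build_descriptor(s, i); d2 <- build_descriptor(s2, i)
    expect_equal(d1$contacts, d2$contacts)
    expect_equal(d1$segments, d2$segments)
  }
})

test_that("a descriptor aligned with itself (copied structure) is the identity", {
  s <- small_chain()
  s2 <- s; s2$name <- "copy"
  p <- msta_params()
  d <- build_descriptor(s, 15L)
  dp <- align_descriptors(d, build_descriptor(s2, 15L), s, s2, p)
  expect_equal(dp$corr[, 1], dp$corr[, 2])
  expect_equal(dp$size, length(d$members))
  expect_lt(dp$rmsd, 1e-9)
  expect_equal(dp$n_segments, length(d$segments))
})

test_that("descriptor alignment is invariant under rigid transformation", {
  s <- small_chain()
  s2 <- rigid_copy(s, name = "rt")
  p <- msta_params()
  dp <- align_descriptors(build_descriptor(s, 15L), build_descriptor(s2, 15L), s, s2, p)
  expect_equal(dp$corr[, 1], dp$corr[, 2])
  expect_lt(dp$rmsd, 1e-6)
})

test_that("helix and strand descriptors of equal element count do not align", {
  helix <- make_chain(list(list(type = "helix", len = 15)), seed = 1, name = "hx")
  strand <- make_chain(list(list(type = "strand", len = 15)), seed = 1, name = "st")
  p <- msta_params()
  # oracle: the central 5-residue windows alone superpose worse than rmsd_max
  centre_rmsd <- superpose(helix$ca[6:10, ], strand$ca[6:10, ])$rmsd
  expect_gt(centre_rmsd, p$rmsd_max)
  dh <- build_descriptor(helix, 8L); ds <- build_descriptor(strand, 8L)
  dp <- align_descriptors(dh, ds, helix, strand, p)
  # ...and the full correspondence cannot satisfy the global threshold
  expect_null(dp)
})

test_that("descriptor pair alignment is symmetric", {
  fam <- fam3()
  sa <- fam$structures[[1]]; sb <- fam$structures[[2]]
  p <- msta_params()
  for (i in c(10L, 18L, 25L)) {
    ab <- align_descriptors(build_descriptor(sa, i), build_descriptor(sb, i), sa, sb, p)
    ba <- align_descriptors(build_descriptor(sb, i), build_descriptor(sa, i), sb, sa, p)
    expect_false(is.null(ab)); expect_false(is.null(ba))
    expect_equal(unname(ab$corr[order(ab$corr[, 1]), ]),
                 unname(ba$corr[order(ba$corr[, 2]), 2:1]))
    expect_equal(ab$rmsd, ba$rmsd, tolerance = 1e-9)
  }
})

test_that("all_descriptor_pairs finds self matches on a copy and respects permutation", {
  s <- small_chain()
  s2 <- s; s2$name <- "copy"
  p <- msta_params()
  pool <- all_descriptor_pairs(s, s2, p)
  centers <- vapply(pool, function(x) x$a_central == x$b_central, TRUE)
  valid <- which(descalign:::element_valid(s))
  n_desc <- sum(vapply(valid, function(i)
    length(build_descriptor(s, i)$element_centers) >= p$min_elements, TRUE))
  expect_gte(sum(centers), n_desc)
  # circular permutation: interior centers still pair up, shifted by the cut
  spec <- family_spec(architecture = small_architecture(), n_copies = 2L,
                      noise_sigma = 0, permuted_copies = 2L, cut = 20L, seed = 2L)
  fam <- make_family(spec)
  pool2 <- all_descriptor_pairs(fam$structures[[1]], fam$structures[[2]], p)
  expect_gt(length(pool2), 0L)
  truth_map <- fam$truth$cols
  hits <- vapply(pool2, function(dp) {
    truth_map[dp$a_central, 2] == dp$b_central
  }, TRUE)
  # most valid centers keep a truth-consistent descriptor pair despite the cut
  truthful <- unique(vapply(pool2, function(dp) dp$a_central, 0L)[hits])
  valid <- which(descalign:::element_valid(fam$structures[[1]]))
  expect_gt(length(intersect(truthful, valid)) / length(valid), 0.8)
})

test_that("descriptor report lists contacts and segments in PDB numbering", {
  s <- small_chain()
  d <- build_descriptor(s, 15L)
  rep <- descriptor_report(d, s)
  expect_match(rep[1], "center A:15")
  expect_match(rep[2], sprintf("contacts \\(%d\\)", length(d$contacts)))
  expect_match(rep[3], sprintf("segments \\(%d\\)", length(d$segments)))
})
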