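# hand-built two-structure context: two chains of 10 residues whose columns
# and contacts can be enumerated by eye
toy_ctx <- function(displace = 0) {
  arch <- list(list(type = "helix", len = 12))
  a <- make_chain(arch, seed = 1, name = "A")
  b <- make_chain(arch, seed = 1, name = "B")
  if (displace > 0) b$ca[8:12, 1] <- b$ca[8:12, 1] + displace
  alignment_context(list(a, b), msta_params())
}

test_that("contact_pairs enumerates exactly the aligned in-contact columns", {
  ctx <- toy_ctx()
  # alignment of four spread columns: only 5~8 are in contact in a helix
  ma <- multiple_alignment(c("A", "B"), cbind(c(1L, 5L, 8L, 12L), c(1L, 5L, 8L, 12L)))
  cp <- contact_pairs(ma, ctx)
  cm <- descalign:::contact_matrix(ctx$structures[["A"]])
  manual <- 0L
  for (i in 1:3) for (j in (i + 1):4)
    manual <- manual + cm[c(1, 5, 8, 12)[i], c(1, 5, 8, 12)[j]]
  expect_equal(nrow(cp), manual)
  # no two columns sharing two structures: empty
  ma2 <- multiple_alignment(c("A", "B"), cbind(c(1L, NA), c(NA, 2L)))
  expect_equal(nrow(contact_pairs(ma2, ctx)), 0L)
})

test_that("contact tension is zero for identical and rigid copies", {
  ctx <- toy_ctx()
  expect_equal(contact_tension(ctx, 1L, 2L, 5L, 8L, 5L, 8L), 0, tolerance = 1e-12)
  a <- ctx$structures[["A"]]
  b2 <- rigid_copy(a, name = "B")
  ctx2 <- alignment_context(list(a, b2), msta_params())
  expect_lt(contact_tension(ctx2, 1L, 2L, 5L, 8L, 5L, 8L), 1e-9)
})

test_that("contact tension of a displaced element matches the superposition oracle", {
  ctx <- toy_ctx(displace = 1.0)
  got <- contact_tension(ctx, 1L, 2L, 5L, 8L, 5L, 8L)
  a <- ctx$structures[["A"]]; b <- ctx$structures[["B"]]
  ii <- unique(c(3:7, 6:10))
  oracle <- superpose(a$ca[ii, ], b$ca[ii, ])$rmsd
  expect_equal(got, oracle, tolerance = 1e-9)
  expect_gt(got, 0.05)
})

test_that("tension collapses to r^2 for a single contact and is averaged stepwise", {
  ctx <- toy_ctx(displace = 0.8)
  ma <- multiple_alignment(c("A", "B"), cbind(c(5L, 8L), c(5L, 8L)))
  r <- contact_tension(ctx, 1L, 2L, 5L, 8L, 5L, 8L)
  tn <- tension(ma, ctx)
  expect_equal(tn$total, r^2, tolerance = 1e-12)
  expect_equal(unname(tn$per_pair), r^2, tolerance = 1e-12)
})

test_that("tension equals an independent stepwise recomputation on a noisy family", {
  fam <- fam3()
  ctx <- ctx3()
  truth <- fam$truth
  tn <- tension(truth, ctx)
  # independent recomputation: contacts -> per-residue mean -> square ->
  # per-pair mean -> alignment mean, straight from definitions
  per_pair <- c()
  for (a in 1:2) for (b in (a + 1):3) {
    cm_a <- descalign:::contact_matrix(fam$structures[[a]])
    cm_b <- descalign:::contact_matrix(fam$structures[[b]])
    ra <- truth$cols[, a]; rb <- truth$cols[, b]
    n <- length(ra)
    acc <- setNames(vector("list", n), seq_len(n))
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (!(cm_a[ra[i], ra[j]] || cm_b[rb[i], rb[j]])) next
      va <- descalign:::element_valid(fam$structures[[a]])
      vb <- descalign:::element_valid(fam$structures[[b]])
      if (!(va[ra[i]] && va[ra[j]] && vb[rb[i]] && vb[rb[j]])) next
      ii <- c((ra[i]-2):(ra[i]+2), (ra[j]-2):(ra[j]+2))
      jj <- c((rb[i]-2):(rb[i]+2), (rb[j]-2):(rb[j]+2))
      keep <- !duplicated(paste(ii, jj))
      r <- superpose(fam$structures[[a]]$ca[ii[keep], ],
                     fam$structures[[b]]$ca[jj[keep], ])$rmsd
      acc[[i]] <- c(acc[[i]], r); acc[[j]] <- c(acc[[j]], r)
    }
    means <- vapply(acc[lengths(acc) > 0], mean, 0)
    per_pair <- c(per_pair, mean(means^2))
  }
  expect_equal(tn$total, mean(per_pair), tolerance = 1e-9)
})

test_that("tension is invariant under rigid transformation of one structure", {
  fam <- fam_id()
  ctx <- alignment_context(fam$structures, msta_params())
  t0 <- tension(fam$truth, ctx)$total
  moved <- fam$structures
  moved[[2]] <- rigid_copy(moved[[2]], name = moved[[2]]$name)
  ctx2 <- alignment_context(moved, msta_params())
  expect_equal(tension(fam$truth, ctx2)$total, t0, tolerance = 1e-9)
  expect_lt(t0, 1e-18)
})

test_that("region decomposition separates hinge domains and partitions pairs", {
  spec <- family_spec(architecture = small_architecture(), n_copies = 2L,
                      noise_sigma = 0, hinged_copies = 2L, hinge_pivot = 24L,
                      hinge_angle = 70, seed = 8L)
  fam <- make_family(spec)
  ctx <- alignment_context(fam$structures, msta_params())
  ma <- fam$truth
  regions <- region_decomposition(ma, ctx, "S1", "S2")
  expect_gte(length(regions), 1L)
  expect_equal(sum(vapply(regions, `[[`, 0L, "size")), nrow(ma$cols))
  # a fully connected single-helix case gives one region
  h <- make_chain(list(list(type = "helix", len = 12)), seed = 2, name = "H1")
  h2 <- h; h2$name <- "H2"
  ctx_h <- alignment_context(list(h, h2), msta_params())
  ma_h <- multiple_alignment(c("H1", "H2"), cbind(1:12, 1:12))
  expect_length(region_decomposition(ma_h, ctx_h, "H1", "H2"), 1L)
})

test_that("augmented size follows the (1 + cos alpha) / 2 law", {
  mkreg <- function(size, rot, reused = FALSE)
    list(rows = seq_len(size), pairs = cbind(seq_len(size), seq_len(size)),
         size = size, rotation = rot, reused = reused)
  r0 <- diag(3)
  expect_equal(augmented_size(list(mkreg(17, r0))), 17)
  # second region, same rotation: counted in full
  expect_equal(augmented_size(list(mkreg(10, r0), mkreg(4, r0))), 14)
  # opposite rotation (pi): contributes nothing
  rpi <- descalign:::rot_about(c(0, 0, 1), pi)
  expect_equal(augmented_size(list(mkreg(10, r0), mkreg(4, rpi))), 10)
  # right angle: half weight
  rq <- descalign:::rot_about(c(1, 0, 0), pi / 2)
  expect_equal(augmented_size(list(mkreg(10, r0), mkreg(4, rq))), 12)
  # proportionality constant scales the augmented part only
  expect_equal(augmented_size(list(mkreg(10, r0), mkreg(4, rq)), constant = 0.5), 11)
})

test_that("augmented size never exceeds the raw pair count", {
  spec <- family_spec(architecture = small_architecture(), n_copies = 2L,
                      noise_sigma = 0.2, hinged_copies = 2L, hinge_pivot = 24L,
                      hinge_angle = 50, seed = 9L)
  fam <- make_family(spec)
  ctx <- alignment_context(fam$structures, msta_params())
  regions <- region_decomposition(fam$truth, ctx, "S1", "S2")
  expect_lte(augmented_size(regions), nrow(fam$truth$cols) + 1e-9)
})

test_that("fitness is monotone in size and degrades with noise", {
  fam <- fam_id()
  ctx <- alignment_context(fam$structures, msta_params())
  full <- fam$truth
  reduced <- multiple_alignment(full$struct_names, full$cols[-(1:10), , drop = FALSE])
  expect_gt(fitness(full, ctx), fitness(reduced, ctx))
  expect_equal(fitness(multiple_alignment(full$struct_names,
                                          matrix(NA_integer_, 0, 3)), ctx), 0)
  # same alignment, increasingly perturbed coordinates: fitness decreases
  fits <- vapply(c(0.1, 0.5, 1.0), function(sig) {
    spec <- family_spec(architecture = small_architecture(), n_copies = 3L,
                        noise_sigma = sig, seed = 77L)
    fam_s <- make_family(spec)
    fitness(fam_s$truth, alignment_context(fam_s$structures, msta_params()))
  }, 0)
  expect_true(all(diff(fits) < 0))
})

test_that("ground truth outscores random alignments of the same size", {
  fam <- fam3()
  ctx <- ctx3()
  f_truth <- fitness(fam$truth, ctx)
  n <- fam$template$n
  set.seed(31)
  for (k in 1:10) {
    cols <- cbind(seq_len(n), sample(n), sample(n))
    expect_gt(f_truth, fitness(multiple_alignment(fam$truth$struct_names, cols), ctx))
  }
})

test_that("score report contains tension, regions and fitness", {
  fam <- fam_id()
  ctx <- alignment_context(fam$structures, msta_params())
  rep <- score_report(fam$truth, ctx)
  expect_true(any(grepl("^total_tension_A2", rep)))
  expect_true(any(grepl("^fitness", rep)))
  expect_true(any(grepl("alpha_deg", rep)))
})
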