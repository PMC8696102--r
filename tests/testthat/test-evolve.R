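test_that("stochastic NJ samples joins proportionally to similarity", {
  sim <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3, 3)
  set.seed(123)
  n_draws <- 10000L
  first_ab <- 0L
  for (k in seq_len(n_draws)) {
    tr <- stochastic_nj(sim)
    # the first join is the deepest internal node: find the cherry
    cherries <- Filter(function(p) length(p) > 0,
                       descalign:::internal_paths(tr))
    depths <- lengths(cherries)
    deepest <- cherries[[which.max(depths)]]
    node <- tr
    for (step in deepest) node <- node[[step]]
    pair <- sort(descalign:::tree_leaves(node))
    if (identical(pair, c(1L, 2L))) first_ab <- first_ab + 1L
  }
  # expected frequency 2 / (2 + 1 + 1) = 0.5
  expect_equal(first_ab / n_draws, 0.5, tolerance = 0.02)
})

test_that("a dominant similarity pair is joined first almost always", {
  sim <- matrix(1, 3, 3); diag(sim) <- 0
  sim[1, 2] <- sim[2, 1] <- 1e6
  set.seed(7)
  hits <- 0L
  for (k in 1:200) {
    tr <- stochastic_nj(sim)
    cherries <- Filter(function(p) length(p) > 0, descalign:::internal_paths(tr))
    deepest <- cherries[[which.max(lengths(cherries))]]
    node <- tr
    for (step in deepest) node <- node[[step]]
    if (identical(sort(descalign:::tree_leaves(node)), c(1L, 2L))) hits <- hits + 1L
  }
  expect_equal(hits, 200L)
  expect_error(stochastic_nj(matrix(0, 1, 1)), "at least 2")
})

test_that("two structures give the single join and trees cover leaves exactly once", {
  set.seed(1)
  tr <- stochastic_nj(matrix(c(0, 1, 1, 0), 2, 2))
  expect_setequal(descalign:::tree_leaves(tr), 1:2)
  sim <- matrix(runif(25), 5, 5); sim <- sim + t(sim); diag(sim) <- 0
  for (k in 1:10) {
    tr <- stochastic_nj(sim)
    expect_equal(sort(descalign:::tree_leaves(tr)), 1:5)
  }
})

test_that("progressive alignment of identical copies reaches the ground truth", {
  fam <- fam_id()
  ctx <- ctx_id()
  space <- initial_space(ctx)
  set.seed(2)
  tr <- stochastic_nj(matrix(1, 3, 3) - diag(3))
  sp <- progressive(tr, ctx, space)
  expect_s3_class(sp, "specimen")
  expect_gte(qp(sp$alignment, fam$truth), 95)
  expect_lt(tension(sp$alignment, ctx)$total, 1e-12)
})

test_that("a single-leaf tree gives the trivial singleton alignment", {
  ctx <- ctx_id()
  sp <- progressive(descalign:::tree_leaf(1L), ctx, initial_space(ctx))
  expect_equal(nrow(sp$alignment$cols), ctx$structures[[1]]$n)
  expect_true(all(rowSums(!is.na(sp$alignment$cols)) == 1L))
})

test_that("mutation preserves invariants and keeps perfect specimens perfect", {
  fam <- fam_id()
  ctx <- ctx_id()
  space <- initial_space(ctx)
  set.seed(3)
  sp <- progressive(stochastic_nj(matrix(1, 3, 3) - diag(3)), ctx, space)
  for (k in 1:5) {
    child <- mutate(sp, ctx, space)
    expect_silent(validate_alignment(child$alignment))
    expect_equal(child$fitness, sp$fitness, tolerance = 1e-6)
  }
  # the input specimen is unchanged
  expect_equal(sp$fitness, fitness(sp$alignment, ctx))
})

test_that("crossover partitions the structure set and handles identical parents", {
  fam <- fam3()
  ctx <- ctx3()
  space <- initial_space(ctx)
  set.seed(4)
  sim <- matrix(1, 3, 3) - diag(3)
  s1 <- progressive(stochastic_nj(sim), ctx, space)
  s2 <- progressive(stochastic_nj(sim), ctx, space)
  for (k in 1:5) {
    child <- crossover(s1, s2, ctx, space)
    expect_silent(validate_alignment(child$alignment))
    expect_setequal(child$alignment$struct_names, names(ctx$structures))
    expect_setequal(descalign:::tree_leaves(child$tree), 1:3)
  }
})

test_that("specimen identity is the Jaccard index of induced pair sets", {
  ma_full <- multiple_alignment(c("A", "B"), cbind(1:10, 1:10))
  ma_half <- multiple_alignment(c("A", "B"), cbind(1:5, 1:5))
  ma_disj <- multiple_alignment(c("A", "B"), cbind(11:20, 11:20))
  expect_equal(specimen_identity(ma_full, ma_full), 1.0)
  expect_equal(specimen_identity(ma_full, ma_disj), 0.0)
  expect_equal(specimen_identity(ma_full, ma_half), 0.5)
})

test_that("steady state applies the elitist insertion rule and never regresses", {
  fam <- fam_id()
  ctx <- ctx_id()
  space <- initial_space(ctx)
  p <- ctx$params
  set.seed(5)
  sim <- matrix(1, 3, 3) - diag(3)
  sp <- progressive(stochastic_nj(sim), ctx, space)
  res <- steady_state(list(sp), ctx, space, p)
  # perfect specimen on identical copies: unchanged best
  expect_equal(res$best$fitness, sp$fitness, tolerance = 1e-9)
  expect_true(all(diff(res$trace) >= 0))
  # at capacity 1, every child of the perfect specimen is (near-)identical and
  # no better, so the population never changes
  p2 <- fast_params(pop_max = 1L, max_evals = 6L, stall = 3L)
  res2 <- steady_state(list(sp), ctx, space, p2)
  expect_length(res2$pop, 1L)
  expect_equal(res2$pop[[1]]$fitness, sp$fitness, tolerance = 1e-9)
})

test_that("evolution on noisy copies never ends below its starting population", {
  fam <- fam3()
  ctx <- ctx3()
  space <- initial_space(ctx)
  p <- fast_params(max_evals = 12L, stall = 6L)
  sim <- matrix(1, 3, 3) - diag(3)
  for (seed in 1:3) {
    set.seed(seed)
    pop <- lapply(1:3, function(k) progressive(stochastic_nj(sim), ctx, space, p))
    start_best <- max(vapply(pop, `[[`, 0, "fitness"))
    res <- steady_state(pop, ctx, space, p)
    expect_gte(res$best$fitness, start_best)
    expect_gte(qc(res$best$alignment, fam$truth),
               qc(pop[[which.max(vapply(pop, `[[`, 0, "fitness"))]]$alignment,
                  fam$truth) - 1e-9)
  }
})

test_that("gradual extension frees all structures and recovers identical copies", {
  fam <- fam_id()
  ctx <- ctx_id()
  p <- fast_params(max_evals = 10L, stall = 4L)
  ge <- gradual_extension(ctx, p, seed = 6L)
  expect_setequal(ge$space$freed, 1:3)
  expect_gte(qc(ge$best$alignment, fam$truth), 95)
  expect_true(all(diff(ge$history) >= 0))
})

test_that("two-stage alignment is monotone and covers loops after stage 2", {
  fam <- fam3()
  ctx <- ctx3()
  p <- fast_params(max_evals = 10L, stall = 4L)
  res <- two_stage(params = p, seed = 7L, ctx = ctx)
  k1 <- descalign:::pair_keys(res$stage1_alignment)
  k2 <- descalign:::pair_keys(res$alignment)
  expect_true(all(k1 %in% k2))        # stage 2 never removes stage-1 pairs
  expect_gte(qp(res$alignment, fam$truth), 90)
})

test_that("the full run is deterministic given a seed", {
  ctx_a <- alignment_context(fam3()$structures, fast_params(max_evals = 8L, stall = 4L),
                             pools = ctx3()$pools)
  ctx_b <- alignment_context(fam3()$structures, fast_params(max_evals = 8L, stall = 4L),
                             pools = ctx3()$pools)
  r1 <- two_stage(params = ctx_a$params, seed = 9L, ctx = ctx_a)
  r2 <- two_stage(params = ctx_b$params, seed = 9L, ctx = ctx_b)
  expect_identical(r1$alignment$cols, r2$alignment$cols)
  expect_equal(r1$fitness, r2$fitness)
})
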