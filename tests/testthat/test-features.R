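# Window layout, SDF/CF assembly, scaling, dataset construction

test_that("the 3x3 window lists the 8 neighbours in row-major order, centre excluded", {
  w <- neighbor_window(10L, 20L)
  expect_equal(nrow(w), 8L)
  expect_equal(unname(w[1, ]), c(9L, 19L))
  expect_equal(unname(w[8, ]), c(11L, 21L))
  expect_false(any(w[, 1] == 10L & w[, 2] == 20L))
  expect_equal(unname(w),
               cbind(c(9L, 9L, 9L, 10L, 10L, 11L, 11L, 11L),
                     c(19L, 20L, 21L, 19L, 21L, 19L, 20L, 21L)))
  # middle rows of windows two apart do not intersect
  w2 <- neighbor_window(12L, 20L)
  mid1 <- w[w[, 1] == 10L, , drop = FALSE]
  mid2 <- w2[w2[, 1] == 12L, , drop = FALSE]
  expect_equal(nrow(merge(as.data.frame(mid1), as.data.frame(mid2))), 0L)
})

test_that("each SDF block equals the independently recomputed pair geometry", {
  b <- shared_bundle()
  axes <- helix_axes(b$chain, b$annotation)
  pairs <- enumerate_candidates(b$chain, b$annotation)
  # an interior pair: all neighbours inside the helices
  interior <- pairs[pairs$i == 3L & pairs$helix_j == 2L, ][2, ]
  sv <- sdf_vector(b$chain, b$annotation, interior, axes)
  expect_length(sv$x, 40L)
  expect_true(all(sv$valid))
  win <- neighbor_window(interior$i, interior$j)
  for (k in 1:8) {
    rp <- get_residue(b$chain, win[k, 1]); rq <- get_residue(b$chain, win[k, 2])
    hp <- helix_of(b$annotation, win[k, 1]); hq <- helix_of(b$annotation, win[k, 2])
    ref <- pair_geometry(rp, rq, axes[[as.character(hp)]], axes[[as.character(hq)]])
    expect_equal(unname(sv$x[(5 * (k - 1) + 1):(5 * k)]), unname(ref),
                 tolerance = 1e-12)
  }
})

test_that("window positions outside the chain produce zero blocks with a flag", {
  b <- shared_bundle()
  axes <- helix_axes(b$chain, b$annotation)
  pairs <- enumerate_candidates(b$chain, b$annotation)
  term <- pairs[pairs$i == 1L, ][1, ] # i - 1 = 0 is outside the chain
  sv <- sdf_vector(b$chain, b$annotation, term, axes)
  expect_false(all(sv$valid))
  bad <- which(!sv$valid)
  for (k in bad) expect_equal(sv$x[(5 * (k - 1) + 1):(5 * k)], rep(0, 5))
})

test_that("tilt of a neighbour outside every helix falls back to the central helices", {
  # two helices with a 1-residue annotation gap right next to helix 2's start
  b <- make_bundle(n_helices = 2L, helix_length = 12L, loop_length = 6L,
                   spacing = 8, seed = 3L)
  ann <- b$annotation
  axes <- helix_axes(b$chain, ann)
  # shrink helix 2's annotation by one at the front: position now unannotated
  seg <- ann$segments; seg$start[2] <- seg$start[2] + 1L
  ann_shrunk <- helix_annotation(ann$chain_id, seg)
  axes_shrunk <- helix_axes(b$chain, ann_shrunk)
  pairs <- enumerate_candidates(b$chain, ann_shrunk)
  border <- pairs[pairs$j == seg$start[2], ][1, ]
  sv <- sdf_vector(b$chain, ann_shrunk, border, axes_shrunk)
  # neighbours at j-1 lie outside the shrunk annotation yet still get a theta
  expect_true(all(is.finite(sv$x)))
  win <- neighbor_window(border$i, border$j)
  k <- which(win[, 2] == seg$start[2] - 1L & win[, 1] == border$i)
  expect_true(sv$valid[k])
  th <- sv$x[5 * k] # theta slot of that block uses the central helices' axes
  expect_equal(th, tilt_angle(axes_shrunk[[as.character(border$helix_i)]],
                              axes_shrunk[[as.character(border$helix_j)]]))
})

test_that("CF vectors are 192 raw coordinates and shift with translation", {
  b <- shared_bundle()
  pairs <- enumerate_candidates(b$chain, b$annotation)
  present <- residue_positions(b$chain)
  interior <- vapply(seq_len(nrow(pairs)), function(k)
    all(neighbor_window(pairs$i[k], pairs$j[k]) %in% present), logical(1))
  p <- pairs[which(interior)[10], ]
  cv <- cf_vector(b$chain, p)
  expect_length(cv$x, 192L)
  expect_true(all(cv$valid))
  a2 <- b$chain$atoms
  a2$x <- a2$x + 10
  shifted <- chain_structure(a2, "A", "synthetic")
  cv2 <- cf_vector(shifted, p)
  d <- cv2$x - cv$x
  xs <- seq(1, 192, by = 3) # every block is x,y,z triplets
  expect_equal(d[xs], rep(10, 64))
  expect_equal(d[-xs], rep(0, 128))
})

test_that("glycine CB slot repeats CA (or a virtual CB when configured)", {
  h <- ideal_helix(24)
  at <- h$atoms
  gly_pos <- 8L
  at <- at[!(at$resno == gly_pos & at$atom == "CB"), ]
  at$resname[at$resno == gly_pos] <- "GLY"
  ch <- chain_structure(at, "A", "synthetic")
  r <- get_residue(ch, gly_pos)
  p <- list(i = 7L, j = 14L, helix_i = 1L, helix_j = 2L)
  cv <- cf_vector(ch, p)
  # block 7 is (i+1, j) = (8, 14): first residue is the glycine
  blk <- cv$x[(24 * 6 + 1):(24 * 7)]
  expect_equal(blk[10:12], unname(r$coords["CA", ]))
  cvv <- cf_vector(ch, p, gly_cb = "virtual")
  blkv <- cvv$x[(24 * 6 + 1):(24 * 7)]
  vcb <- blkv[10:12]
  expect_equal(sqrt(sum((vcb - r$coords["CA", ])^2)), 1.53, tolerance = 1e-6)
})

test_that("min-max scaling maps training data into [-1,1] exactly", {
  set.seed(31)
  X <- cbind(rnorm(50), runif(50, 2, 4), rep(3, 50))
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  expect_equal(apply(Xs[, 1:2], 2, min), c(-1, -1))
  expect_equal(apply(Xs[, 1:2], 2, max), c(1, 1))
  expect_true(all(Xs >= -1 & Xs <= 1))
  # midpoint and endpoints of a column
  expect_equal(apply_scaler(matrix(c(2, 3, 4), 3, 1),
                            fit_scaler(matrix(c(2, 4), 2, 1)))[, 1],
               c(-1, 0, 1))
  # constant column maps to -1
  expect_equal(unique(Xs[, 3]), -1)
  # out-of-range test values land outside [-1,1], no refit
  expect_equal(apply_scaler(matrix(6, 1, 1),
                            fit_scaler(matrix(c(2, 4), 2, 1)))[1, 1], 3)
  expect_error(apply_scaler(X[, 1:2], sc), "columns")
})

test_that("datasets have canonical shape, order and labels", {
  b2 <- make_bundle(n_helices = 2L, helix_length = 16L, spacing = 9,
                    seed = 9L, random_pose = TRUE)
  chains <- list(A = b2$chain)
  anns <- list(A = b2$annotation)
  np <- nrow(enumerate_candidates(b2$chain, b2$annotation))
  ds <- build_dataset(chains, anns, "SDF")
  expect_s3_class(ds, "pair_feature_set")
  expect_equal(dim(ds$X), c(np, 40L))
  expect_equal(length(ds$labels), np)
  expect_true(all(is.finite(ds$X)))
  expect_identical(ds$labels, b2$truth$labels$labels)
  dcf <- build_dataset(chains, anns, "CF")
  expect_equal(dim(dcf$X), c(np, 192L))
  # canonical (chain_id, i, j) order
  expect_false(is.unsorted(ds$meta$i))
  # identical rerun
  ds2 <- build_dataset(chains, anns, "SDF")
  expect_identical(ds$X, ds2$X)
  # chains without annotation are skipped with a warning
  expect_warning(build_dataset(c(chains, list(B = b2$chain)), anns, "SDF"),
                 "skipped")
})

test_that("SDF matrices are rigid-invariant, CF matrices are not", {
  b <- shared_bundle()
  chains <- list(A = b$chain); anns <- list(A = b$annotation)
  ds_sdf <- build_dataset(chains, anns, "SDF")
  ds_cf <- build_dataset(chains, anns, "CF")
  set.seed(33)
  tr <- rigid_transform_chain(b$chain)
  moved <- list(A = tr$chain)
  ds_sdf2 <- build_dataset(moved, anns, "SDF", label_chains = moved)
  ds_cf2 <- build_dataset(moved, anns, "CF", label_chains = moved)
  expect_lt(max(abs(ds_sdf$X - ds_sdf2$X)), 1e-6)
  expect_gt(max(abs(ds_cf$X - ds_cf2$X)), 1)
})
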