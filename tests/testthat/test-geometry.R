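# The five structure-derived quantities against first-principles oracles

test_that("relative distances match the brute-force double loop", {
  r1 <- fix_residue(c(0, 0, 0))
  r2 <- fix_residue(c(0, 0, 5))
  expect_equal(d1_mean(r1, r2), 5)
  expect_equal(d1_sd(r1, r2), 0)
  r3 <- fix_residue(c(1, 0, 0, 3, 0, 0))
  expect_equal(d1_mean(r1, r3), 2)  # distances {1, 3}
  expect_equal(d1_sd(r1, r3), 1)

  set.seed(11)
  for (rep in 1:100) {
    a <- rand_residue(n_extra = sample(0:4, 1))
    b <- rand_residue(n_extra = sample(0:4, 1), center = rnorm(3, sd = 6))
    expect_equal(d1_mean(a, b), bf_d1_mean(a, b), tolerance = 1e-9)
    expect_equal(d1_sd(a, b), bf_d1_sd(a, b), tolerance = 1e-9)
    expect_equal(d_alpha(a, b),
                 sqrt(sum((a$coords["CA", ] - b$coords["CA", ])^2)),
                 tolerance = 1e-9)
  }
})

test_that("sd and mean of cross distances obey the second-moment identity", {
  set.seed(12)
  for (rep in 1:20) {
    a <- rand_residue(3); b <- rand_residue(2, center = c(4, 1, -2))
    d <- bf_cross_dists(a, b)
    expect_equal(d1_sd(a, b)^2 + d1_mean(a, b)^2, mean(d^2), tolerance = 1e-9)
  }
})

test_that("residue plane normal follows the right-hand rule and is translation invariant", {
  r <- fix_residue(c(1, 0, 0,   0, 0, 0,   0, 1, 0), atoms = c("N", "CA", "C"))
  expect_equal(residue_plane_normal(r), c(0, 0, 1))
  shifted <- r
  shifted$coords <- sweep(r$coords, 2L, c(13, -2, 7), "+")
  expect_equal(residue_plane_normal(shifted), c(0, 0, 1))
  degen <- fix_residue(c(1, 0, 0,  0, 0, 0,  2, 0, 0), atoms = c("N", "CA", "C"))
  expect_error(residue_plane_normal(degen), "degenerate|collinear")
  no_c <- fix_residue(c(1, 0, 0, 0, 0, 0), atoms = c("N", "CA"))
  expect_error(residue_plane_normal(no_c), "lacks")
})

test_that("relative residue angle matches an independent recomputation", {
  r <- rand_residue(0)
  expect_equal(relative_residue_angle(r, r), 0)
  # swapping the N and C atoms reverses the cross-product order, so the
  # plane normal flips and the relative angle is 180
  mirror <- r
  rn <- rownames(mirror$coords)
  rownames(mirror$coords) <- replace(rn, match(c("N", "C"), rn), c("C", "N"))
  expect_equal(relative_residue_angle(r, mirror), 180, tolerance = 1e-6)

  set.seed(13)
  for (rep in 1:100) {
    a <- rand_residue(1); b <- rand_residue(1, center = rnorm(3, sd = 5))
    expect_equal(relative_residue_angle(a, b),
                 bf_angle_deg(bf_plane_normal(a), bf_plane_normal(b)),
                 tolerance = 1e-9)
  }
})

test_that("tilt angle endpoints and symmetry", {
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  expect_equal(tilt_angle(z, z), 0)
  expect_equal(tilt_angle(z, x), 90)
  expect_equal(tilt_angle(z, -z), 180)
  set.seed(14)
  for (rep in 1:20) {
    u <- rnorm(3); v <- rnorm(3)
    expect_equal(tilt_angle(u, v), tilt_angle(v, u))
    expect_equal(tilt_angle(u, v, fold = TRUE), min(tilt_angle(u, v),
                                                    180 - tilt_angle(u, v)))
  }
})

test_that("helix axis recovers the construction axis and is rotation equivariant", {
  h <- ideal_helix(20)
  ch <- chain_structure(h$atoms, "A", "synthetic")
  ax <- helix_axis(ch, c(1, 20))
  expect_equal(ax$n_vectors, 16L)
  expect_lt(tilt_angle(ax, c(0, 0, 1)), 2)
  expect_equal(sqrt(sum(ax$direction^2)), 1, tolerance = 1e-9)

  expect_error(helix_axis(ch, c(1, 4)), "shorter than 5|undefined")

  set.seed(15)
  tr <- rigid_transform_chain(ch)
  ax2 <- helix_axis(tr$chain, c(1, 20))
  expect_equal(ax2$direction, as.numeric(tr$R %*% ax$direction),
               tolerance = 1e-6)
})

test_that("all five quantities are invariant under a rigid transform of the chain", {
  b <- shared_bundle()
  axes <- helix_axes(b$chain, b$annotation)
  set.seed(16)
  tr <- rigid_transform_chain(b$chain)
  axes2 <- helix_axes(tr$chain, b$annotation)
  pairs <- enumerate_candidates(b$chain, b$annotation)
  pick <- pairs[seq(1, nrow(pairs), length.out = 25), ]
  for (k in seq_len(nrow(pick))) {
    i <- pick$i[k]; j <- pick$j[k]
    g1 <- pair_geometry(get_residue(b$chain, i), get_residue(b$chain, j),
                        axes[[as.character(pick$helix_i[k])]],
                        axes[[as.character(pick$helix_j[k])]])
    g2 <- pair_geometry(get_residue(tr$chain, i), get_residue(tr$chain, j),
                        axes2[[as.character(pick$helix_i[k])]],
                        axes2[[as.character(pick$helix_j[k])]])
    expect_equal(g1, g2, tolerance = 1e-6)
  }
})

test_that("tilt between two placed helices recovers the specified angle at zero noise", {
  for (phi in c(0, 30, 60, 90, 150, 180)) {
    b <- make_bundle(n_helices = 2L, helix_length = 20L, spacing = 12,
                     inter_axis_angle = phi, seed = 21L)
    axs <- helix_axes(b$chain, b$annotation)
    expect_lt(abs(tilt_angle(axs[["1"]], axs[["2"]]) - phi), 2)
    expect_equal(b$truth$angles[1, 2], phi, tolerance = 1e-6)
  }
})
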