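#' @name synthetic
#' @title Synthetic alpha-helical bundle generator
#' @description
#' Generates multi-helix alpha-helical bundle chains with backbone + C-beta
#' heavy atoms, known helix axes and inter-axis angles, and contact labels
#' computed from the generated coordinates — a fully controlled stand-in for
#' experimentally determined TM-protein structures. A Gaussian coordinate
#' noise model emulates predicted-structure error: the noisy twin keeps the
#' clean structure's labels, mirroring the pairing of an experimental
#' structure with its computational prediction.
NULL

# place atom D given A, B, C with bond |C-D|, angle B-C-D and torsion A-B-C-D
# (natural extension of reference frame; angles in degrees)
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# ideal alpha-helix backbone dihedrals and geometry (textbook values)
.helix_geo <- list(phi = -57, psi = -47, omega = 180,
                   b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                   b_c_o = 1.231, b_ca_cb = 1.53,
                   a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
                   a_ca_c_o = 120.5, a_n_ca_cb = 110.4, t_cb = -122.5)

#' Ideal alpha-helix fragment
#'
#' Builds a poly-alanine-like helix (atoms N, CA, C, O, CB per residue) from
#' ideal internal coordinates (phi = -57, psi = -47 degrees, standard bond
#' lengths/angles), then rigidly aligns it so its axis is +z and its centroid
#' the origin. The construction is deterministic. Rise per residue is about
#' 1.5 Angstrom with about 100 degrees of twist, so consecutive CA atoms are
#' about 3.8 Angstrom apart and the O(i) -> N(i+4) hydrogen-bond vectors run
#' near the axis.
#'
#' @param length number of residues (>= 5).
#' @param start_resno first residue number.
#' @return List with `atoms` (data.frame resno/resname/atom/x/y/z) and
#'   `axis`, the true axis direction `c(0, 0, 1)`.
#' @export
ideal_helix <- function(length, start_resno = 1L) {
  if (length < 5L) stop("ideal_helix: length must be at least 5")
  g <- .helix_geo
  n <- length
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3L)
  # seed the first residue in an arbitrary frame
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1L) {
      N[i, ] <- nerf_place(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, g$psi)
      CA[i, ] <- nerf_place(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- nerf_place(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, g$phi)
    }
    O[i, ] <- nerf_place(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, g$psi + 180)
    CB[i, ] <- nerf_place(C[i, ], N[i, ], CA[i, ],
                          g$b_ca_cb, g$a_n_ca_cb, g$t_cb)
  }
  # align the screw axis (leading principal axis of the CA cloud) with +z
  ctr <- colMeans(CA)
  sv <- svd(sweep(CA, 2L, ctr))
  axis <- sv$v[, 1L]
  if (sum(axis * (CA[n, ] - CA[1, ])) < 0) axis <- -axis
  R <- rotation_to_z(axis)
  fix <- function(M) sweep(M, 2L, ctr) %*% t(R)
  N <- fix(N); CA <- fix(CA); C <- fix(C); O <- fix(O); CB <- fix(CB)
  resno <- start_resno + seq_len(n) - 1L
  atoms <- data.frame(
    resno = rep(resno, each = 5L),
    resname = "ALA",
    atom = rep(c("N", "CA", "C", "O", "CB"), n),
    x = as.numeric(t(cbind(N[, 1], CA[, 1], C[, 1], O[, 1], CB[, 1]))),
    y = as.numeric(t(cbind(N[, 2], CA[, 2], C[, 2], O[, 2], CB[, 2]))),
    z = as.numeric(t(cbind(N[, 3], CA[, 3], C[, 3], O[, 3], CB[, 3]))),
    stringsAsFactors = FALSE)
  list(atoms = atoms, axis = c(0, 0, 1))
}

# rotation matrix sending unit vector v onto +z
rotation_to_z <- function(v) {
  v <- unit(v); z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  ax <- unit(pracma_cross(v, z))
  s <- sqrt(1 - c_^2)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# rotation by `deg` degrees about a coordinate axis
rot_axis <- function(deg, axis = c("x", "y", "z")) {
  axis <- match.arg(axis)
  t <- deg * pi / 180; c_ <- cos(t); s <- sin(t)
  switch(axis,
         x = matrix(c(1, 0, 0, 0, c_, -s, 0, s, c_), 3, 3, byrow = TRUE),
         y = matrix(c(c_, 0, s, 0, 1, 0, -s, 0, c_), 3, 3, byrow = TRUE),
         z = matrix(c(c_, -s, 0, s, c_, 0, 0, 0, 1), 3, 3, byrow = TRUE))
}

# uniform random rotation matrix (QR of a Gaussian matrix, det fixed to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

apply_rigid <- function(atoms, R, t) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + t[1]; atoms$y <- xyz[, 2] + t[2]; atoms$z <- xyz[, 3] + t[3]
  atoms
}

#' Generate a synthetic alpha-helical bundle
#'
#' Places `n_helices` ideal helices either by a packing recipe — centres on a
#' circle sized so adjacent axes are `spacing` Angstrom apart (for two
#' helices, simply `spacing` apart), alternating up/down when `antiparallel`
#' — or at explicit per-helix rigid `placements`. Residue numbering is
#' contiguous within helices with a gap of `loop_length` positions between
#' them (connecting loops are not modelled as atoms, so helix termini
#' exercise the feature-window boundary rule). Each helix also receives a
#' deterministic, seed-dependent spin about its own axis; optionally the
#' whole bundle gets a random rigid pose, as a deposited structure would have
#' an arbitrary coordinate frame.
#'
#' @param n_helices number of helices (>= 2).
#' @param helix_length residues per helix (>= 10).
#' @param loop_length numbering gap between consecutive helices.
#' @param spacing inter-axis distance between adjacent helices, Angstrom.
#' @param inter_axis_angle for `n_helices = 2` only: the angle in degrees
#'   between the two helix axes (0 parallel ... 180 antiparallel); overrides
#'   `antiparallel`.
#' @param antiparallel alternate helix directions up/down (the common TM
#'   bundle topology).
#' @param placements optional list of per-helix `list(R = 3x3 rotation,
#'   t = translation)` overriding the packing recipe.
#' @param noise_sigma Gaussian noise SD (Angstrom, per coordinate) applied to
#'   the emitted chain; truth (axes, angles, labels) is always computed from
#'   the clean coordinates.
#' @param random_pose apply a random global rigid transform to the bundle.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param chain_id chain identifier.
#' @param threshold,min_sep contact definition used for the truth labels.
#' @return List with `chain` ([chain_structure()]), `clean_chain`,
#'   `annotation` ([helix_annotation()]), and `truth` (per-helix `axes`,
#'   pairwise `angles` matrix in degrees, `labels` from [label_contacts()]).
#' @export
make_bundle <- function(n_helices = 3L, helix_length = 20L, loop_length = 3L,
                        spacing = 9.5, inter_axis_angle = NULL,
                        antiparallel = TRUE, placements = NULL,
                        noise_sigma = 0, random_pose = FALSE, seed = 1L,
                        chain_id = "A", threshold = 5.5, min_sep = 5L) {
  stopifnot(n_helices >= 2L, helix_length >= 10L, spacing > 0, noise_sigma >= 0)
  if (!is.null(inter_axis_angle)) {
    stopifnot(n_helices == 2L, inter_axis_angle >= 0, inter_axis_angle <= 180)
  }
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)

  frag <- ideal_helix(helix_length)
  atoms_l <- vector("list", n_helices)
  axes <- vector("list", n_helices)
  seg <- data.frame(helix_index = seq_len(n_helices), start = NA_integer_,
                    end = NA_integer_)
  spins <- stats::runif(n_helices, 0, 360)
  for (h in seq_len(n_helices)) {
    if (!is.null(placements)) {
      R <- placements[[h]]$R; tvec <- placements[[h]]$t # taken literally, no spin
    } else {
      R <- rot_axis(spins[h], "z")
      if (!is.null(inter_axis_angle) && h == 2L) {
        R <- rot_axis(inter_axis_angle, "x") %*% R
      } else if (antiparallel && h %% 2L == 0L) {
        R <- rot_axis(180, "x") %*% R
      }
      tvec <- if (n_helices == 2L) c((h - 1L) * spacing, 0, 0) else {
        rad <- spacing / (2 * sin(pi / n_helices))
        ang <- 2 * pi * (h - 1L) / n_helices
        c(rad * cos(ang), rad * sin(ang), 0)
      }
    }
    a <- frag$atoms
    start <- 1L + (h - 1L) * (helix_length + loop_length)
    a$resno <- a$resno - 1L + start
    seg$start[h] <- start; seg$end[h] <- start + helix_length - 1L
    atoms_l[[h]] <- apply_rigid(a, R, tvec)
    axes[[h]] <- as.numeric(R %*% frag$axis)
  }
  atoms <- do.call(rbind, atoms_l)
  if (random_pose) {
    Rg <- random_rotation()
    tg <- stats::runif(3, -30, 30)
    atoms <- apply_rigid(atoms, Rg, tg)
    axes <- lapply(axes, function(v) as.numeric(Rg %*% v))
  }
  clean <- chain_structure(atoms, chain_id = chain_id, source = "synthetic")
  ann <- helix_annotation(chain_id, seg)

  # steric sanity: helices must not collapse onto each other
  ca <- atoms[atoms$atom == "CA", ]
  hel_of_ca <- rep(seq_len(n_helices), each = helix_length)
  cam <- as.matrix(ca[, c("x", "y", "z")])
  d2 <- cross_sqdist(cam, cam)
  same <- outer(hel_of_ca, hel_of_ca, "==")
  if (min(d2[!same]) < 1)
    stop("make_bundle: steric collapse (inter-helix CA-CA < 1 Angstrom)")

  pairs <- enumerate_candidates(clean, ann, min_sep = min_sep)
  labels <- if (nrow(pairs)) label_contacts(clean, pairs, threshold = threshold)
            else NULL
  angles <- matrix(NA_real_, n_helices, n_helices)
  for (a1 in seq_len(n_helices)) for (a2 in seq_len(n_helices))
    angles[a1, a2] <- tilt_angle(axes[[a1]], axes[[a2]])
  chain <- if (noise_sigma > 0)
    perturb(clean, noise_sigma, seed = seed + 7919L) else clean
  list(chain = chain, clean_chain = clean, annotation = ann,
       truth = list(axes = axes, angles = angles, labels = labels),
       spec = list(n_helices = n_helices, helix_length = helix_length,
                   loop_length = loop_length, spacing = spacing,
                   inter_axis_angle = inter_axis_angle,
                   antiparallel = antiparallel, noise_sigma = noise_sigma,
                   random_pose = random_pose, seed = seed))
}

#' Perturb a structure with Gaussian coordinate noise
#'
#' Adds i.i.d. Gaussian noise (SD `sigma` Angstrom, per coordinate) to every
#' atom — the package's model of predicted-structure coordinate error. The
#' result is tagged `source = "predicted"`. Contact labels are never
#' regenerated from a perturbed structure: truth stays with the clean chain.
#'
#' @param chain a [chain_structure()].
#' @param sigma noise SD in Angstrom; 0 returns the chain unchanged (but
#'   re-tagged).
#' @param seed integer seed.
#' @return A `chain_structure` with `source = "predicted"`.
#' @export
perturb <- function(chain, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  a <- chain$atoms
  if (sigma > 0) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
    n <- nrow(a)
    a$x <- a$x + stats::rnorm(n, 0, sigma)
    a$y <- a$y + stats::rnorm(n, 0, sigma)
    a$z <- a$z + stats::rnorm(n, 0, sigma)
  }
  chain_structure(a, chain_id = chain$chain_id, source = "predicted")
}

#' Preset synthetic study set
#'
#' Generates `n_chains` bundles with 2-4 helices (smaller bundles more
#' likely) of 12-16 residues in random global poses — a desk-scale stand-in
#' for a curated TM-protein dataset, yielding on the order of 500 candidate
#' pairs per chain. The default spacing puts the pooled contact ratio in the
#' natural regime of roughly 1-3% of candidate pairs.
#'
#' @param n_chains number of chains.
#' @param seed integer seed.
#' @param spacing inter-axis spacing passed to [make_bundle()].
#' @param noise_sigma if > 0, a noisy twin of every chain is also returned.
#' @return List with `chains`, `annotations` (named by chain id), `truth`
#'   (per-chain), and `noisy_chains` when `noise_sigma > 0`.
#' @export
synthetic_dataset <- function(n_chains = 10L, seed = 1L, spacing = 9.5,
                              noise_sigma = 0) {
  if (n_chains > 26L)
    stop("synthetic_dataset: at most 26 chains (single-letter PDB chain ids)")
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n_hel <- sample(2:4, n_chains, replace = TRUE, prob = c(0.4, 0.4, 0.2))
  h_len <- sample(12:16, n_chains, replace = TRUE)
  sub_seeds <- sample.int(1e6, n_chains)
  chains <- list(); anns <- list(); truth <- list(); noisy <- list()
  for (c_ in seq_len(n_chains)) {
    id <- LETTERS[c_]
    b <- make_bundle(n_helices = n_hel[c_], helix_length = h_len[c_],
                     spacing = spacing, random_pose = TRUE,
                     seed = sub_seeds[c_], chain_id = id)
    chains[[id]] <- b$chain
    anns[[id]] <- b$annotation
    truth[[id]] <- b$truth
    if (noise_sigma > 0) {
      # a predicted structure arrives in its own arbitrary coordinate frame:
      # re-pose the twin rigidly before adding coordinate noise
      set.seed(sub_seeds[c_] + 5L)
      a <- apply_rigid(b$chain$atoms, random_rotation(), stats::runif(3, -30, 30))
      reposed <- chain_structure(a, chain_id = id, source = "predicted")
      noisy[[id]] <- perturb(reposed, noise_sigma, seed = sub_seeds[c_] + 13L)
    }
  }
  out <- list(chains = chains, annotations = anns, truth = truth)
  if (noise_sigma > 0) out$noisy_chains <- noisy
  out
}
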