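# Independent brute-force oracles and tiny fixture builders shared by the
# suite. The oracles use plain double loops / first-principles formulas and
# never call the code paths they check.

# a residue fixture: coordinate matrix with named atoms
fix_residue <- function(coords, atoms = NULL, resname = "ALA", position = 1L) {
  coords <- matrix(coords, ncol = 3L, byrow = TRUE)
  if (is.null(atoms)) atoms <- paste0("X", seq_len(nrow(coords)))
  rownames(coords) <- atoms
  list(position = position, resname = resname, coords = coords)
}

# random residue with backbone atoms N, CA, C (+ extras), non-degenerate
rand_residue <- function(n_extra = 2L, center = c(0, 0, 0)) {
  repeat {
    base <- matrix(rnorm(9, sd = 1.5), 3L, 3L)
    v1 <- base[1, ] - base[2, ]; v2 <- base[3, ] - base[2, ]
    cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
            v1[3] * v2[1] - v1[1] * v2[3],
            v1[1] * v2[2] - v1[2] * v2[1])
    if (sqrt(sum(cr^2)) > 1e-3) break
  }
  extra <- if (n_extra > 0) matrix(rnorm(3 * n_extra, sd = 2), n_extra, 3L)
           else NULL
  coords <- sweep(rbind(base, extra), 2L, center, "+")
  rownames(coords) <- c("N", "CA", "C",
                        if (n_extra > 0) paste0("X", seq_len(n_extra)))
  list(position = 1L, resname = "UNK", coords = coords)
}

# brute-force cross atom-pair distances (double loop)
bf_cross_dists <- function(r1, r2) {
  out <- c()
  for (a in seq_len(nrow(r1$coords)))
    for (b in seq_len(nrow(r2$coords)))
      out <- c(out, sqrt(sum((r1$coords[a, ] - r2$coords[b, ])^2)))
  out
}

bf_d1_mean <- function(r1, r2) mean(bf_cross_dists(r1, r2))
bf_d1_sd <- function(r1, r2) {
  d <- bf_cross_dists(r1, r2)
  sqrt(sum((d - mean(d))^2) / length(d))
}
bf_min_dist <- function(r1, r2) min(bf_cross_dists(r1, r2))

bf_angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(min(1, max(-1, cosang))) * 180 / pi
}

bf_plane_normal <- function(r) {
  v1 <- r$coords["N", ] - r$coords["CA", ]
  v2 <- r$coords["C", ] - r$coords["CA", ]
  c(v1[2] * v2[3] - v1[3] * v2[2],
    v1[3] * v2[1] - v1[1] * v2[3],
    v1[1] * v2[2] - v1[2] * v2[1])
}

# average precision by an explicit threshold sweep: every distinct score is
# a threshold; predictions >= threshold are positive
bf_average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  th <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; ap <- 0
  for (t in th) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    p <- tp / sum(pred)
    r <- tp / sum(labels)
    ap <- ap + (r - prev_r) * p
    prev_r <- r
  }
  ap
}

# AUC as the normalized Mann-Whitney U statistic (rank formulation, ties 0.5)
bf_auc_mwu <- function(scores, labels) {
  labels <- as.numeric(labels)
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + if (p > q) 1 else if (p == q) 0.5 else 0
  wins / (length(pos) * length(neg))
}

bf_topk <- function(scores, labels, k, pairs) {
  ord <- order(-scores, pairs$i, pairs$j)
  tp <- sum(as.numeric(labels)[ord][seq_len(k)])
  c(precision = tp / k, recall = tp / sum(labels))
}

# random rigid transform of a chain (shared by invariance tests)
rigid_transform_chain <- function(chain) {
  M <- matrix(rnorm(9), 3, 3)
  qrm <- qr(M); R <- qr.Q(qrm) %*% diag(sign(diag(qr.R(qrm))))
  if (det(R) < 0) R[, 3] <- -R[, 3]
  tv <- runif(3, -20, 20)
  a <- chain$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + tv[1]; a$y <- xyz[, 2] + tv[2]; a$z <- xyz[, 3] + tv[3]
  list(chain = chain_structure(a, chain$chain_id, chain$source), R = R, t = tv)
}

# a small cached bundle shared across test files (built once per session)
shared_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- make_bundle(n_helices = 3L, helix_length = 16L, seed = 42L,
                            random_pose = TRUE)
    cache
  }
})
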