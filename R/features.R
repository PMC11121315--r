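#' The 3x3 neighbourhood window of a residue pair
#'
#' The eight positions surrounding (i, j) in the sequence-index plane, in
#' row-major order with the centre excluded: (i-1,j-1), (i-1,j), (i-1,j+1),
#' (i,j-1), (i,j+1), (i+1,j-1), (i+1,j), (i+1,j+1). The centre (i, j) is
#' excluded so the classifier cannot read off the very distance that defines
#' the contact label.
#'
#' @param i,j residue positions of the central pair.
#' @return An 8 x 2 integer matrix, columns `i` and `j`.
#' @export
neighbor_window <- function(i, j) {
  off <- cbind(i = c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L),
               j = c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L))
  cbind(i = i + off[, "i"], j = j + off[, "j"])
}

# residue usable for the 5 geometric features? needs N, CA, C (plane + CA)
sdf_res_ok <- function(r) {
  !is.null(r) && all(c("N", "CA", "C") %in% rownames(r$coords))
}

#' Structure-derived feature vector of one candidate pair
#'
#' For each of the eight window positions, in window order, a block of five
#' values: `d1_mean`, `d1_sd`, `d_alpha`, `delta` (relative residue angle)
#' and `theta` (inter-helical tilt angle). The tilt angle of a neighbour uses
#' the axes of the helices containing the neighbour residues; a neighbour
#' falling outside every annotated helix inherits the central residue's helix
#' axis. Neighbour positions whose residues are missing from the chain (or
#' lack the backbone atoms the quantities need) contribute a zero block and
#' are flagged invalid, so every candidate pair keeps a full-length row.
#'
#' @param chain a [chain_structure()].
#' @param helices a [helix_annotation()].
#' @param pair one-row data.frame (or list) with `i`, `j`, `helix_i`, `helix_j`.
#' @param axes named list of [helix_axis()] keyed by helix index (as
#'   character); see [helix_axes()].
#' @return List with `x` (numeric length 40) and `valid` (logical length 8).
#' @export
sdf_vector <- function(chain, helices, pair, axes) {
  ri <- get_residue(chain, pair$i)
  rj <- get_residue(chain, pair$j)
  if (is.null(ri) || is.null(rj))
    stop("sdf_vector: central pair (", pair$i, ",", pair$j,
         ") missing from chain ", chain$chain_id)
  win <- neighbor_window(pair$i, pair$j)
  x <- numeric(40L)
  valid <- logical(8L)
  for (k in 1:8) {
    p <- win[k, 1L]; q <- win[k, 2L]
    rp <- get_residue(chain, p)
    rq <- get_residue(chain, q)
    if (!sdf_res_ok(rp) || !sdf_res_ok(rq)) next
    hp <- helix_of(helices, p); if (is.na(hp)) hp <- pair$helix_i
    hq <- helix_of(helices, q); if (is.na(hq)) hq <- pair$helix_j
    ap <- axes[[as.character(hp)]]
    aq <- axes[[as.character(hq)]]
    if (is.null(ap) || is.null(aq)) next
    x[(5L * (k - 1L) + 1L):(5L * k)] <- pair_geometry(rp, rq, ap, aq)
    valid[k] <- TRUE
  }
  list(x = x, valid = valid)
}

#' Compute all helix axes of an annotated chain
#' @param chain a [chain_structure()].
#' @param helices a [helix_annotation()].
#' @return Named list of [helix_axis()] keyed by helix index.
#' @export
helix_axes <- function(chain, helices) {
  seg <- helices$segments
  axes <- lapply(seq_len(nrow(seg)),
                 function(k) helix_axis(chain, c(seg$start[k], seg$end[k])))
  names(axes) <- as.character(seg$helix_index)
  axes
}

cf_atom_order <- c("N", "CA", "O", "CB")

# 12 raw coordinates of one residue for the CF baseline: N, CA, O, CB (x,y,z
# each). A residue without a CB (glycine) repeats the CA coordinates in the
# CB slot, or uses an ideal tetrahedral virtual CB when gly_cb = "virtual".
cf_res_coords <- function(r, gly_cb = "ca") {
  cc <- r$coords
  if (!all(c("N", "CA", "O") %in% rownames(cc))) return(NULL)
  cb <- if ("CB" %in% rownames(cc)) {
    cc["CB", ]
  } else if (gly_cb == "virtual" && "C" %in% rownames(cc)) {
    virtual_cb(cc["N", ], cc["CA", ], cc["C", ])
  } else {
    cc["CA", ]
  }
  c(cc["N", ], cc["CA", ], cc["O", ], cb)
}

#' Ideal tetrahedral virtual C-beta position
#'
#' Places a C-beta 1.53 Angstrom from CA at the standard tetrahedral geometry
#' implied by the backbone N, CA and C atoms (used for glycine when the
#' raw-coordinate baseline is configured with a virtual CB).
#'
#' @param n,ca,c backbone atom coordinates (3-vectors).
#' @return 3-vector.
#' @export
virtual_cb <- function(n, ca, c) {
  v1 <- unit(n - ca)
  v2 <- unit(c - ca)
  bis <- unit(v1 + v2)              # in-plane bisector of N-CA-C
  perp <- unit(pracma_cross(v1, v2)) # normal of the N-CA-C plane
  # CB sits opposite the bisector, lifted out of plane (tetrahedral split)
  ca + 1.53 * unit(-bis * sin(0.9598) + perp * cos(0.9598))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Raw-coordinate feature vector of one candidate pair
#'
#' The coordinates-as-features baseline: for each of the eight window
#' positions, 24 values — the lower-position residue then the higher, each
#' contributing the raw x, y, z of its N, CA, O and CB atoms in Angstrom (no
#' centering or superposition, so these features are deliberately not
#' rigid-invariant). Missing neighbours contribute a zero block.
#'
#' @inheritParams sdf_vector
#' @param gly_cb how to fill the CB slot of CB-less residues: repeat the CA
#'   coordinates (`"ca"`, default) or place an ideal tetrahedral virtual CB
#'   (`"virtual"`).
#' @return List with `x` (numeric length 192) and `valid` (logical length 8).
#' @export
cf_vector <- function(chain, pair, gly_cb = c("ca", "virtual")) {
  gly_cb <- match.arg(gly_cb)
  ri <- get_residue(chain, pair$i)
  rj <- get_residue(chain, pair$j)
  if (is.null(ri) || is.null(rj))
    stop("cf_vector: central pair (", pair$i, ",", pair$j,
         ") missing from chain ", chain$chain_id)
  win <- neighbor_window(pair$i, pair$j)
  x <- numeric(192L)
  valid <- logical(8L)
  for (k in 1:8) {
    p <- win[k, 1L]; q <- win[k, 2L] # p < q by construction (j - i >= 5)
    rp <- get_residue(chain, p)
    rq <- get_residue(chain, q)
    if (is.null(rp) || is.null(rq)) next
    cp <- cf_res_coords(rp, gly_cb)
    cq <- cf_res_coords(rq, gly_cb)
    if (is.null(cp) || is.null(cq)) next
    x[(24L * (k - 1L) + 1L):(24L * k)] <- c(cp, cq)
    valid[k] <- TRUE
  }
  list(x = x, valid = valid)
}

#' Fit a per-column min-max scaler
#'
#' Records the per-column minimum and maximum of a training feature matrix.
#' Applying the scaler maps v to -1 + 2 (v - min) / (max - min), i.e. the
#' training data lands exactly in \[-1, 1\]; constant columns map to -1.
#' The scaler is fit on training data only and reused unchanged on
#' validation/test data, whose values may fall outside \[-1, 1\].
#'
#' @param X numeric training feature matrix.
#' @param fitted_on optional dataset identifier stored with the parameters.
#' @return A `feature_scaler` object with `min` and `max` vectors.
#' @export
fit_scaler <- function(X, fitted_on = NULL) {
  X <- as.matrix(X)
  if (nrow(X) == 0L) stop("fit_scaler: empty matrix")
  structure(list(min = apply(X, 2L, min), max = apply(X, 2L, max),
                 fitted_on = fitted_on),
            class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param params a `feature_scaler` from [fit_scaler()].
#' @export
apply_scaler <- function(X, params) {
  X <- as.matrix(X)
  if (ncol(X) != length(params$min))
    stop("apply_scaler: matrix has ", ncol(X), " columns, scaler expects ",
         length(params$min))
  rng <- params$max - params$min
  const <- rng == 0
  rng[const] <- 1 # constant columns map to -1
  Xs <- sweep(sweep(X, 2L, params$min, "-"), 2L, rng, "/")
  -1 + 2 * Xs
}

#' Assemble a per-pair feature dataset
#'
#' Enumerates candidate pairs for every annotated chain, computes SDF (40
#' columns) or CF (192 columns) feature rows, and attaches contact labels.
#' Labels are computed from `label_chains` (default: the feature chains
#' themselves); passing the clean structures there while `chains` holds their
#' noisy/predicted twins gives the train-on-clean / test-on-predicted
#' protocol, where truth stays with the experimental structure.
#'
#' Rows are in deterministic (chain_id, i, j) order. Chains without an
#' annotation are skipped with a warning.
#'
#' @param chains named list of [chain_structure()] keyed by chain id.
#' @param annotations named list of [helix_annotation()] keyed by chain id.
#' @param feature_kind `"SDF"` or `"CF"`.
#' @param label_chains named list of chains to compute labels from; or `NULL`
#'   to attach no labels.
#' @param labels optional precomputed labels: named list (by chain id) of
#'   data.frames `i`, `j`, `label` (as from [read_contact_labels()]);
#'   overrides `label_chains`.
#' @param threshold contact threshold (Angstrom) for label computation.
#' @param min_sep minimum sequence separation for candidate pairs.
#' @param gly_cb CB fill rule for the CF baseline, see [cf_vector()].
#' @return A `pair_feature_set`: `meta` (data.frame chain_id, i, j,
#'   helix_i, helix_j), `X` (feature matrix), `mask` (logical per row: all 8
#'   neighbours valid), `labels` (logical or `NULL`), `feature_kind`.
#' @export
build_dataset <- function(chains, annotations, feature_kind = c("SDF", "CF"),
                          label_chains = chains, labels = NULL,
                          threshold = 5.5, min_sep = 5L,
                          gly_cb = c("ca", "virtual")) {
  feature_kind <- match.arg(feature_kind)
  gly_cb <- match.arg(gly_cb)
  ids <- sort(names(chains))
  ncol_x <- if (feature_kind == "SDF") 40L else 192L
  meta_l <- list(); X_l <- list(); mask_l <- list(); lab_l <- list()
  for (id in ids) {
    ann <- annotations[[id]]
    if (is.null(ann)) {
      warning("build_dataset: no annotation for chain ", id, "; skipped")
      next
    }
    chain <- cache_residues(chains[[id]])
    pairs <- enumerate_candidates(chain, ann, min_sep = min_sep)
    if (nrow(pairs) == 0L) next
    if (feature_kind == "SDF") {
      axes <- helix_axes(chain, ann)
      fv <- lapply(seq_len(nrow(pairs)), function(k)
        sdf_vector(chain, ann, pairs[k, ], axes))
    } else {
      fv <- lapply(seq_len(nrow(pairs)), function(k)
        cf_vector(chain, pairs[k, ], gly_cb = gly_cb))
    }
    X <- do.call(rbind, lapply(fv, `[[`, "x"))
    mask <- vapply(fv, function(v) all(v$valid), logical(1L))
    lab <- NULL
    if (!is.null(labels)) {
      ltab <- labels[[id]]
      if (is.null(ltab)) stop("build_dataset: no labels provided for chain ", id)
      key <- paste(pairs$i, pairs$j)
      lkey <- paste(ltab$i, ltab$j)
      hit <- match(key, lkey)
      if (anyNA(hit))
        stop("build_dataset: labels for chain ", id, " do not cover all pairs")
      lab <- as.logical(ltab$label[hit])
    } else if (!is.null(label_chains)) {
      lch <- label_chains[[id]]
      if (is.null(lch)) stop("build_dataset: no label chain for ", id)
      lab <- label_contacts(lch, pairs, threshold = threshold)$labels
    }
    meta_l[[id]] <- data.frame(chain_id = id, pairs, stringsAsFactors = FALSE)
    X_l[[id]] <- X
    mask_l[[id]] <- mask
    lab_l[[id]] <- lab
  }
  if (length(X_l) == 0L)
    stop("build_dataset: no chain produced any candidate pair")
  labs <- if (all(vapply(lab_l, is.null, logical(1L)))) NULL else unlist(lab_l, use.names = FALSE)
  structure(list(meta = do.call(rbind, c(meta_l, list(make.row.names = FALSE))),
                 X = do.call(rbind, X_l),
                 mask = unlist(mask_l, use.names = FALSE),
                 labels = labs,
                 feature_kind = feature_kind),
            class = "pair_feature_set")
}

#' @export
print.pair_feature_set <- function(x, ...) {
  cat(sprintf("<pair_feature_set> %s: %d pairs x %d features, %d chains%s\n",
              x$feature_kind, nrow(x$X), ncol(x$X),
              length(unique(x$meta$chain_id)),
              if (is.null(x$labels)) "" else
                sprintf(", %d contacts (CR = %.4f)", sum(x$labels), mean(x$labels))))
  invisible(x)
}

#' Subset a pair_feature_set by chain id
#' @param fs a `pair_feature_set`.
#' @param chain_ids chain ids to keep.
#' @return A `pair_feature_set` restricted to those chains.
#' @export
subset_chains <- function(fs, chain_ids) {
  keep <- fs$meta$chain_id %in% chain_ids
  structure(list(meta = fs$meta[keep, , drop = FALSE],
                 X = fs$X[keep, , drop = FALSE],
                 mask = fs$mask[keep],
                 labels = if (is.null(fs$labels)) NULL else fs$labels[keep],
                 feature_kind = fs$feature_kind),
            class = "pair_feature_set")
}

#' Write a feature dataset to TSV
#' @param fs a `pair_feature_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(fs, path) {
  X <- fs$X
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  d <- cbind(fs$meta[, c("chain_id", "i", "j")],
             label = if (is.null(fs$labels)) NA_integer_ else as.integer(fs$labels),
             as.data.frame(X))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
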