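#' Enumerate inter-helical candidate residue pairs
#'
#' Candidate pairs are the (i, j), i < j, with both positions inside an
#' annotated TM helix, the two positions on different helices, and a sequence
#' separation of at least `min_sep` residues (j - i >= min_sep). Output is
#' ordered lexicographically by (i, j).
#'
#' @param chain a [chain_structure()] (used only for validation; candidates
#'   are defined by the annotation).
#' @param helices a [helix_annotation()].
#' @param min_sep minimum sequence separation (default 5).
#' @return data.frame with columns `i`, `j`, `helix_i`, `helix_j`.
#' @export
enumerate_candidates <- function(chain, helices, min_sep = 5L) {
  seg <- helices$segments
  if (nrow(seg) < 2L)
    return(data.frame(i = integer(0), j = integer(0),
                      helix_i = integer(0), helix_j = integer(0)))
  pos <- unlist(lapply(seq_len(nrow(seg)), function(k) seg$start[k]:seg$end[k]))
  hel <- rep(seg$helix_index, seg$end - seg$start + 1L)
  ord <- order(pos)
  pos <- pos[ord]; hel <- hel[ord]
  n <- length(pos)
  ii <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  jj <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  keep <- hel[ii] != hel[jj] & (pos[jj] - pos[ii]) >= min_sep
  out <- data.frame(i = pos[ii][keep], j = pos[jj][keep],
                    helix_i = hel[ii][keep], helix_j = hel[jj][keep])
  out <- out[order(out$i, out$j), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Minimum heavy-atom distance between two residues
#'
#' The smallest Euclidean distance over all cross pairs of the two residues'
#' heavy atoms; the quantity the contact definition thresholds.
#'
#' @param r1,r2 residues as returned by [get_residue()].
#' @return Distance in Angstrom.
#' @export
min_heavy_atom_distance <- function(r1, r2) {
  if (is.null(r1) || is.null(r2) || nrow(r1$coords) == 0L || nrow(r2$coords) == 0L)
    stop("min_heavy_atom_distance: residue with no atoms")
  sqrt(min(cross_sqdist(r1$coords, r2$coords)))
}

# all squared cross distances between two coordinate matrices (rows = atoms)
cross_sqdist <- function(a, b) {
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0 # guard tiny negative values from rounding
  d2
}

#' Label candidate pairs as contacts
#'
#' A pair is a contact when the minimum heavy-atom distance is strictly below
#' `threshold` (default 5.5 Angstrom); a pair at exactly the threshold is a
#' non-contact.
#'
#' @param chain a [chain_structure()].
#' @param pairs candidate pairs from [enumerate_candidates()].
#' @param threshold contact distance threshold in Angstrom.
#' @return A `contact_labels` object: `pairs` plus parallel logical `labels`,
#'   numeric `min_distance` and the threshold used.
#' @export
label_contacts <- function(chain, pairs, threshold = 5.5) {
  stopifnot(threshold > 0)
  n <- nrow(pairs)
  d <- numeric(n)
  res_cache <- new.env(parent = emptyenv())
  fetch <- function(p) {
    key <- as.character(p)
    r <- res_cache[[key]]
    if (is.null(r)) {
      r <- get_residue(chain, p)
      if (is.null(r))
        stop("label_contacts: residue ", p, " absent from chain ", chain$chain_id)
      res_cache[[key]] <- r
    }
    r
  }
  for (k in seq_len(n))
    d[k] <- min_heavy_atom_distance(fetch(pairs$i[k]), fetch(pairs$j[k]))
  structure(list(chain_id = chain$chain_id, pairs = pairs,
                 labels = d < threshold, min_distance = d,
                 threshold = threshold),
            class = "contact_labels")
}

#' @export
print.contact_labels <- function(x, ...) {
  cat(sprintf("<contact_labels> chain %s: %d/%d contacts (< %.2f A), CR = %.4f\n",
              x$chain_id, sum(x$labels), length(x$labels), x$threshold,
              if (length(x$labels)) mean(x$labels) else NA_real_))
  invisible(x)
}

#' Contact ratio
#'
#' The fraction of candidate residue-pair positions that are contacts; the
#' class-imbalance measure of a chain (around 2% for natural TM bundles).
#'
#' @param labels a `contact_labels` object or a logical vector.
#' @return Fraction in \[0, 1\].
#' @export
contact_ratio <- function(labels) {
  lab <- if (inherits(labels, "contact_labels")) labels$labels else labels
  if (length(lab) == 0L) stop("contact_ratio: undefined for an empty pair set")
  mean(lab)
}

#' Write contact labels to a TSV file
#' @param labels a `contact_labels` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_contact_labels <- function(labels, path) {
  d <- data.frame(chain_id = labels$chain_id,
                  i = labels$pairs$i, j = labels$pairs$j,
                  label = as.integer(labels$labels),
                  min_distance = sprintf("%.4f", labels$min_distance))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read contact labels from a TSV file written by [write_contact_labels()]
#' @param path TSV path.
#' @return Named list (by chain id) of data.frames with `i`, `j`, `label`.
#' @export
read_contact_labels <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chain_id", "i", "j", "label")
  if (!all(need %in% names(tab)))
    stop("read_contact_labels: expected columns ", paste(need, collapse = ", "))
  lapply(split(tab, tab$chain_id), function(d) {
    d <- d[order(d$i, d$j), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}
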