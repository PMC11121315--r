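#' Chain structure objects
#'
#' A `chain_structure` holds the heavy atoms of one protein chain: an atom
#' table with residue number (author numbering), residue name, atom name and
#' Cartesian coordinates in Angstrom, plus a source tag distinguishing
#' experimentally determined, computationally predicted and synthetic
#' structures.
#'
#' @param atoms data.frame with columns `resno` (integer), `resname`
#'   (3-letter code), `atom` (atom name, e.g. "N", "CA", "C", "O", "CB"),
#'   `x`, `y`, `z` (Angstrom).
#' @param chain_id single character chain identifier.
#' @param source one of "experimental", "predicted", "synthetic".
#' @return An object of class `chain_structure`.
#' @export
chain_structure <- function(atoms, chain_id = "A",
                            source = c("experimental", "predicted", "synthetic")) {
  source <- match.arg(source)
  stopifnot(is.data.frame(atoms),
            all(c("resno", "resname", "atom", "x", "y", "z") %in% names(atoms)))
  if (nrow(atoms) == 0L) stop("chain_structure: empty chain")
  atoms$resno <- as.integer(atoms$resno)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("chain_structure: non-finite coordinates")
  if (any(!nzchar(atoms$atom))) stop("chain_structure: empty atom name")
  atoms <- atoms[order(atoms$resno), , drop = FALSE]
  dup <- duplicated(atoms[, c("resno", "atom")])
  if (any(dup)) stop("chain_structure: duplicate atom name within a residue")
  rownames(atoms) <- NULL
  obj <- list(chain_id = as.character(chain_id), source = source, atoms = atoms)
  obj$index <- split(seq_len(nrow(atoms)), atoms$resno)
  class(obj) <- "chain_structure"
  obj
}

#' @export
print.chain_structure <- function(x, ...) {
  pos <- residue_positions(x)
  cat(sprintf("<chain_structure> chain %s (%s): %d residues [%d..%d], %d heavy atoms\n",
              x$chain_id, x$source, length(pos), min(pos), max(pos), nrow(x$atoms)))
  invisible(x)
}

#' Residue positions present in a chain
#' @param chain a `chain_structure`.
#' @return Sorted integer vector of residue numbers.
#' @export
residue_positions <- function(chain) {
  as.integer(names(chain$index))
}

#' Extract one residue from a chain
#'
#' @param chain a `chain_structure`.
#' @param pos residue number.
#' @return A list with `position`, `resname` and `coords` (matrix with one
#'   row per heavy atom, rownames are atom names), or `NULL` when the
#'   position is absent from the chain.
#' @export
get_residue <- function(chain, pos) {
  key <- as.character(pos)
  if (!is.null(chain$rescache)) return(chain$rescache[[key]])
  idx <- chain$index[[key]]
  if (is.null(idx)) return(NULL)
  sub <- chain$atoms[idx, , drop = FALSE]
  coords <- as.matrix(sub[, c("x", "y", "z")])
  rownames(coords) <- sub$atom
  list(position = as.integer(pos), resname = sub$resname[1L], coords = coords)
}

# precompute every residue once; repeated get_residue calls then hit the cache
cache_residues <- function(chain) {
  if (!is.null(chain$rescache)) return(chain)
  pos <- residue_positions(chain)
  chain$rescache <- stats::setNames(
    lapply(pos, function(p) get_residue(chain, p)), as.character(pos))
  chain
}

#' Read one chain from a PDB file
#'
#' Parses the ATOM records of a single chain into a [chain_structure()].
#' Hydrogens (and deuteriums) are dropped; HETATM records (waters, ligands)
#' are ignored; for alternate locations the first-listed conformer per atom
#' is kept. Only the first model of a multi-model file is read. Files using
#' residue insertion codes are rejected: all downstream sequence-separation
#' logic assumes plain integer author numbering.
#'
#' @param path PDB file path.
#' @param chain_id chain identifier to extract.
#' @param source source tag recorded on the result.
#' @return A [chain_structure()].
#' @export
read_pdb_chain <- function(path, chain_id,
                           source = c("experimental", "predicted", "synthetic")) {
  source <- match.arg(source)
  if (!file.exists(path)) stop("read_pdb_chain: file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                  verbose = FALSE),
                  error = function(e) stop("read_pdb_chain: cannot parse '", path,
                                           "': ", conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  if (nrow(at) == 0L)
    stop("read_pdb_chain: chain '", chain_id, "' not found in ", path)
  if (any(nzchar(at$insert) & !is.na(at$insert)))
    stop("read_pdb_chain: residue insertion codes are not supported (chain ",
         chain_id, ")")
  elem <- at$elesy
  miss <- is.na(elem) | !nzchar(trimws(elem))
  if (any(miss)) { # fall back to the first letter of the atom name
    guess <- sub("^[0-9]*", "", trimws(at$elety[miss]))
    elem[miss] <- substr(guess, 1L, 1L)
  }
  elem <- toupper(trimws(elem))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  if (nrow(at) == 0L) stop("read_pdb_chain: chain '", chain_id, "' has no heavy atoms")
  # altloc: keep the first-listed location per (residue, atom name)
  at <- at[!duplicated(at[, c("resno", "elety")]), , drop = FALSE]
  chain_structure(
    data.frame(resno = at$resno, resname = at$resid, atom = at$elety,
               x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE),
    chain_id = chain_id, source = source)
}

#' Write a chain to a PDB file
#'
#' Emits standard fixed-width ATOM records; [read_pdb_chain()] round-trips
#' coordinates to the format's 1e-3 Angstrom precision.
#'
#' @param chain a `chain_structure`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(chain, path) {
  a <- chain$atoms
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_pdb: directory does not exist: ", dir)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resname, elety = a$atom,
                   chain = rep(chain$chain_id, nrow(a)))
  invisible(path)
}

#' Shift residue numbering by an integer offset
#'
#' Used to sequentially align author numbering of deposited structures with
#' the numbering of predicted structures of the same sequence.
#'
#' @param chain a `chain_structure`.
#' @param offset integer added to every residue number.
#' @return A `chain_structure` with shifted positions.
#' @export
apply_offset <- function(chain, offset) {
  stopifnot(length(offset) == 1L, offset == round(offset))
  a <- chain$atoms
  a$resno <- a$resno + as.integer(offset)
  chain_structure(a, chain_id = chain$chain_id, source = chain$source)
}

#' TM-helix annotation of one chain
#'
#' @param chain_id chain identifier.
#' @param segments data.frame with columns `helix_index`, `start`, `end`
#'   (inclusive residue-number ranges, one row per TM helix).
#' @return An object of class `helix_annotation`.
#' @export
helix_annotation <- function(chain_id, segments) {
  stopifnot(is.data.frame(segments),
            all(c("helix_index", "start", "end") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  segments$helix_index <- as.integer(segments$helix_index)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  if (nrow(segments) == 0L) stop("helix_annotation: no segments")
  if (any(segments$start > segments$end))
    stop("helix_annotation: segment with start > end in chain ", chain_id)
  if (nrow(segments) > 1L &&
      any(segments$start[-1L] <= segments$end[-nrow(segments)]))
    stop("helix_annotation: overlapping segments in chain ", chain_id)
  rownames(segments) <- NULL
  structure(list(chain_id = as.character(chain_id), segments = segments),
            class = "helix_annotation")
}

#' @export
print.helix_annotation <- function(x, ...) {
  cat(sprintf("<helix_annotation> chain %s: %d TM helices, L = %d\n",
              x$chain_id, nrow(x$segments), tm_length(x)))
  invisible(x)
}

#' Combined TM helix length L
#'
#' The summed residue count of all annotated TM segments; the basis for the
#' top-L/L2/L5/L10 evaluation cutoffs.
#'
#' @param annotation a `helix_annotation`.
#' @return Integer L.
#' @export
tm_length <- function(annotation) {
  sum(annotation$segments$end - annotation$segments$start + 1L)
}

#' Helix index containing a residue position
#' @param annotation a `helix_annotation`.
#' @param pos residue number(s).
#' @return Integer helix index per position; `NA` when outside every segment.
#' @export
helix_of <- function(annotation, pos) {
  seg <- annotation$segments
  vapply(pos, function(p) {
    hit <- which(seg$start <= p & p <= seg$end)
    if (length(hit)) seg$helix_index[hit[1L]] else NA_integer_
  }, integer(1L))
}

#' Read TM-helix annotations from a TSV file
#'
#' Expects a header `chain_id  helix_index  start  end`, tab-separated,
#' positions inclusive. Validation (ordering, overlap) is enforced per chain.
#'
#' @param path TSV file path.
#' @return Named list of `helix_annotation`, one per chain; empty list for an
#'   empty (header-only or zero-byte) file.
#' @export
read_helix_annotation <- function(path) {
  if (!file.exists(path)) stop("read_helix_annotation: file not found: ", path)
  if (file.size(path) == 0L) return(list())
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L) return(list())
  need <- c("chain_id", "helix_index", "start", "end")
  if (!all(need %in% names(tab)))
    stop("read_helix_annotation: expected columns ", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$chain_id), function(d)
    helix_annotation(d$chain_id[1L],
                     d[, c("helix_index", "start", "end"), drop = FALSE]))
  out[order(names(out))]
}

#' Write TM-helix annotations to a TSV file
#' @param annotations list of `helix_annotation`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_helix_annotation <- function(annotations, path) {
  if (inherits(annotations, "helix_annotation")) annotations <- list(annotations)
  rows <- do.call(rbind, lapply(annotations, function(a)
    data.frame(chain_id = a$chain_id, a$segments, stringsAsFactors = FALSE)))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a residue-numbering offset table
#' @param path TSV with header `chain_id  offset`.
#' @return Named integer vector of offsets keyed by chain id.
#' @export
read_offset_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("chain_id", "offset") %in% names(tab)))
    stop("read_offset_table: expected columns chain_id, offset")
  stats::setNames(as.integer(tab$offset), tab$chain_id)
}
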