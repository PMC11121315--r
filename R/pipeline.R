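#' @name pipeline
#' @title Pipeline stages
#' @description
#' File-oriented wrappers that chain the package's stages the way the
#' command-line tool does: simulate -> annotate -> featurize -> train ->
#' predict -> evaluate. Every stage is deterministic given its seed, so a
#' rerun with identical inputs reproduces its outputs byte for byte.
NULL

#' Emit a synthetic dataset to disk
#'
#' Writes, per chain, a PDB file plus shared helix-annotation and
#' contact-label TSVs and a ground-truth geometry JSON.
#'
#' @param outdir output directory (created if needed).
#' @param n_chains,seed,spacing,noise_sigma passed to [synthetic_dataset()].
#' @return Invisible list of written paths.
#' @export
run_simulate <- function(outdir, n_chains = 10L, seed = 1L, spacing = 9.5,
                         noise_sigma = 0) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sd <- synthetic_dataset(n_chains, seed = seed, spacing = spacing,
                          noise_sigma = noise_sigma)
  pdbs <- character(0)
  for (id in names(sd$chains)) {
    p <- file.path(outdir, paste0(id, ".pdb"))
    write_pdb(sd$chains[[id]], p)
    pdbs <- c(pdbs, p)
    if (!is.null(sd$noisy_chains)) {
      pn <- file.path(outdir, paste0(id, "_noisy.pdb"))
      write_pdb(sd$noisy_chains[[id]], pn)
      pdbs <- c(pdbs, pn)
    }
  }
  ann_path <- file.path(outdir, "helices.tsv")
  write_helix_annotation(sd$annotations, ann_path)
  lab_path <- file.path(outdir, "contacts.tsv")
  lab_rows <- do.call(rbind, lapply(names(sd$truth), function(id) {
    l <- sd$truth[[id]]$labels
    data.frame(chain_id = id, i = l$pairs$i, j = l$pairs$j,
               label = as.integer(l$labels),
               min_distance = sprintf("%.4f", l$min_distance))
  }))
  utils::write.table(lab_rows, lab_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth_path <- file.path(outdir, "truth.json")
  truth <- lapply(sd$truth, function(t_)
    list(axes = lapply(t_$axes, function(v) round(v, 10)),
         angles = round(t_$angles, 6)))
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             truth_path)
  invisible(list(pdb = pdbs, helices = ann_path, contacts = lab_path,
                 truth = truth_path, dataset = sd))
}

#' Annotate contacts of structures on disk
#'
#' Reads each PDB, enumerates inter-helical candidate pairs and writes their
#' contact labels as TSV. Chains that fail are reported and skipped; the
#' call errors only if every chain fails.
#'
#' @param pdb_paths named character vector of PDB paths (names = chain ids).
#' @param helix_path helix-annotation TSV.
#' @param out_path output TSV.
#' @param threshold,min_sep contact definition.
#' @param source source tag for parsed chains.
#' @return Invisible `out_path`.
#' @export
run_annotate <- function(pdb_paths, helix_path, out_path, threshold = 5.5,
                         min_sep = 5L, source = "experimental") {
  anns <- read_helix_annotation(helix_path)
  ids <- names(pdb_paths)
  if (is.null(ids)) stop("run_annotate: pdb_paths must be named by chain id")
  rows <- list(); failures <- 0L
  for (id in ids) {
    res <- tryCatch({
      chain <- read_pdb_chain(pdb_paths[[id]], id, source = source)
      ann <- anns[[id]]
      if (is.null(ann)) stop("no annotation for chain ", id)
      pairs <- enumerate_candidates(chain, ann, min_sep = min_sep)
      lab <- label_contacts(chain, pairs, threshold = threshold)
      data.frame(chain_id = id, i = pairs$i, j = pairs$j,
                 label = as.integer(lab$labels),
                 min_distance = sprintf("%.4f", lab$min_distance))
    }, error = function(e) {
      message("run_annotate: chain ", id, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[id]] <- res
  }
  if (length(rows) == 0L) stop("run_annotate: all chains failed")
  utils::write.table(do.call(rbind, rows), out_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(out_path)
}

#' Featurize structures on disk
#'
#' @param pdb_paths named character vector of PDB paths (names = chain ids).
#' @param helix_path helix-annotation TSV.
#' @param out_path output feature TSV.
#' @param feature_kind `"SDF"` or `"CF"`.
#' @param labels_path optional contact-label TSV (as from [run_annotate()]).
#' @param threshold,min_sep contact definition for labels computed in-place.
#' @param source source tag for parsed chains.
#' @return The `pair_feature_set`, invisibly (written to `out_path`).
#' @export
run_featurize <- function(pdb_paths, helix_path, out_path,
                          feature_kind = c("SDF", "CF"), labels_path = NULL,
                          threshold = 5.5, min_sep = 5L,
                          source = "experimental") {
  feature_kind <- match.arg(feature_kind)
  anns <- read_helix_annotation(helix_path)
  chains <- lapply(stats::setNames(names(pdb_paths), names(pdb_paths)),
                   function(id) read_pdb_chain(pdb_paths[[id]], id, source))
  labels <- if (!is.null(labels_path)) read_contact_labels(labels_path) else NULL
  fs <- build_dataset(chains, anns, feature_kind, labels = labels,
                      threshold = threshold, min_sep = min_sep)
  write_feature_tsv(fs, out_path)
  invisible(fs)
}

#' Write an evaluation report as JSON
#' @param report an `eval_report` or `crossval_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(per_sequence = report$per_sequence,
              aggregate = report$aggregate)
  if (inherits(report, "crossval_report"))
    obj <- c(obj, list(k = report$k, repeats = report$repeats,
                       seeds = report$seeds,
                       feature_kind = report$feature_kind))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", na = "null"), path)
  invisible(path)
}

#' Deterministic end-to-end demonstration pipeline
#'
#' Simulates a synthetic bundle set, trains a contact classifier on the clean
#' structures, scores the noisy twins, and evaluates — writing the
#' predictions TSV, the report JSON, the model archive and a provenance
#' block. Everything is derived from `seed`; a rerun into another directory
#' produces byte-identical predictions and report.
#'
#' @param outdir run directory.
#' @param n_chains number of synthetic chains.
#' @param seed global seed.
#' @param epochs training epochs.
#' @param noise_sigma coordinate noise (Angstrom) of the evaluation twins.
#' @param feature_kind `"SDF"` or `"CF"`.
#' @return Invisible list with the report and the file paths.
#' @export
run_demo <- function(outdir, n_chains = 6L, seed = 1L, epochs = 40L,
                     noise_sigma = 1.0, feature_kind = c("SDF", "CF")) {
  feature_kind <- match.arg(feature_kind)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- run_simulate(outdir, n_chains = n_chains, seed = seed,
                      noise_sigma = noise_sigma)
  sd <- sim$dataset
  train_fs <- build_dataset(sd$chains, sd$annotations, feature_kind)
  cfg <- contact_net_config(epochs = epochs, seed = seed)
  model <- contact_net(train_fs, config = cfg)
  save_contact_net(model, file.path(outdir, "model.json"))
  test_fs <- build_dataset(sd$noisy_chains, sd$annotations, feature_kind,
                           label_chains = sd$chains)
  scores <- predict(model, test_fs)
  pred <- data.frame(chain_id = test_fs$meta$chain_id,
                     i = test_fs$meta$i, j = test_fs$meta$j,
                     score = sprintf("%.10f", scores),
                     label = as.integer(test_fs$labels))
  pred_path <- file.path(outdir, "predictions.tsv")
  utils::write.table(pred, pred_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  report <- eval_report(test_fs, scores, sd$annotations)
  report_path <- file.path(outdir, "report.json")
  write_eval_report(report, report_path)
  writeLines(jsonlite::toJSON(list(
    seed = seed, n_chains = n_chains, epochs = epochs,
    noise_sigma = noise_sigma, feature_kind = feature_kind,
    package_version = tryCatch(as.character(utils::packageVersion("tmhc")),
                               error = function(e) "dev")),
    auto_unbox = TRUE, pretty = TRUE), file.path(outdir, "provenance.json"))
  invisible(list(report = report, predictions = pred_path,
                 report_path = report_path, model = model))
}
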