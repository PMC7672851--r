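#' Run the aligner on files
#'
#' Reads two edge lists and three bit-score tables, runs the full
#' alignment, and writes `alignment.tsv`, `local_alignment.tsv` and
#' `summary.json` into `outdir`. With `debug = TRUE` the clusterings and
#' per-stage sizes are also dumped.
#'
#' @param net1_path,net2_path edge-list files.
#' @param bits1_path,bits2_path,bits12_path bit-score tables (within net1,
#'   within net2, cross-network).
#' @param outdir output directory (created if missing).
#' @param debug also write per-stage debug dumps.
#' @return The `ppin_alignment`, invisibly.
#' @export
run_align <- function(net1_path, net2_path, bits1_path, bits2_path,
                      bits12_path, outdir = ".", debug = FALSE) {
  net1 <- read_ppin(net1_path)
  net2 <- read_ppin(net2_path)
  b1 <- read_bit_scores(bits1_path)
  b2 <- read_bit_scores(bits2_path)
  b12 <- read_bit_scores(bits12_path)
  t0 <- proc.time()[["elapsed"]]
  al <- ppin_align(net1, net2, b1, b2, b12)
  elapsed <- proc.time()[["elapsed"]] - t0
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_alignment(al$global, file.path(outdir, "alignment.tsv"))
  write_alignment(al$local, file.path(outdir, "local_alignment.tsv"))
  jsonlite::write_json(
    c(al$summary,
      list(source = al$source_name, target = al$target_name,
           swapped = al$swapped, seconds = elapsed)),
    file.path(outdir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  if (debug) {
    stages <- table(al$global$stage)
    utils::write.table(
      data.frame(stage = names(stages), pairs = as.integer(stages)),
      file.path(outdir, "stages.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  message(sprintf("aligned %s -> %s: %d pairs in %.2fs",
                  al$source_name, al$target_name, nrow(al$global), elapsed))
  invisible(al)
}

#' Evaluate an alignment from files
#'
#' Computes whichever metrics the provided inputs enable and writes a JSON
#' report. Metrics whose inputs are missing, or whose preconditions fail,
#' are reported as `null` with a reason.
#'
#' @param alignment_path alignment TSV from [write_alignment()].
#' @param net1_path,net2_path edge-list files (source, target).
#' @param ann1_path,ann2_path optional annotation tables.
#' @param complexes1_path,complexes2_path optional complex catalogs.
#' @param essential1_path,essential2_path optional essential-protein lists.
#' @param out path of the JSON report.
#' @return The report list, invisibly.
#' @export
run_eval <- function(alignment_path, net1_path, net2_path,
                     ann1_path = NULL, ann2_path = NULL,
                     complexes1_path = NULL, complexes2_path = NULL,
                     essential1_path = NULL, essential2_path = NULL,
                     out = "eval.json") {
  mu <- read_alignment(alignment_path)
  net1 <- read_ppin(net1_path)
  net2 <- read_ppin(net2_path)
  report <- list()
  try_metric <- function(code) {
    tryCatch(code, error = function(e) list(value = NULL,
                                            reason = conditionMessage(e)))
  }
  report$ec <- try_metric(edge_correctness(mu, net1, net2))
  if (!is.null(ann1_path) && !is.null(ann2_path)) {
    ann1 <- read_annotations(ann1_path)
    ann2 <- read_annotations(ann2_path)
    report$fc <- try_metric(
      functional_coherence(mu, ann1, ann2, length(ppin_nodes(net1)))
    )
    report$fc_max <- try_metric(
      fc_max(ann1, ann2, ppin_nodes(net1), ppin_nodes(net2))
    )
  } else {
    report$fc <- list(value = NULL, reason = "no annotations given")
  }
  if (!is.null(complexes1_path) && !is.null(complexes2_path)) {
    report$cfc <- try_metric(unclass(complex_coherence(
      mu, read_complex_catalog(complexes1_path),
      read_complex_catalog(complexes2_path)
    )))
  }
  if (!is.null(essential1_path) && !is.null(essential2_path)) {
    report$essentiality <- try_metric(essentiality_metrics(
      mu, read_essential_proteins(essential1_path),
      read_essential_proteins(essential2_path)
    ))
  }
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}

#' Write a synthetic pair to files
#'
#' Generates a [generate_pair()] instance and writes the two edge lists,
#' the three bit-score tables, the two annotation tables and the planted
#' correspondence into `outdir`. Byte-identical across runs for a fixed
#' seed.
#'
#' @inheritParams generate_pair
#' @param outdir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
run_synth <- function(outdir, n1, n2, overlap = 1, edge_density = 0.15,
                      noise = 0, seed = 1) {
  sp <- generate_pair(n1, n2, overlap, edge_density, noise, seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    net1 = file.path(outdir, "net1.tsv"),
    net2 = file.path(outdir, "net2.tsv"),
    bits11 = file.path(outdir, "bits11.tsv"),
    bits22 = file.path(outdir, "bits22.tsv"),
    bits12 = file.path(outdir, "bits12.tsv"),
    ann1 = file.path(outdir, "ann1.tsv"),
    ann2 = file.path(outdir, "ann2.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_ppin(sp$net1, paths[["net1"]])
  write_ppin(sp$net2, paths[["net2"]])
  write_bit_scores(sp$bits11, paths[["bits11"]])
  write_bit_scores(sp$bits22, paths[["bits22"]])
  write_bit_scores(sp$bits12, paths[["bits12"]])
  write_annotations(sp$ann1, paths[["ann1"]])
  write_annotations(sp$ann2, paths[["ann2"]])
  utils::write.table(
    data.frame(source = names(sp$truth), target = unname(sp$truth)),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(paths)
}

#' Perturb an edge list on disk
#'
#' Applies the [perturb_edges()] protocol to a network file and writes the
#' perturbed edge list.
#'
#' @param net_path input edge list.
#' @param out output path.
#' @param fraction fraction of edges rewired.
#' @param seed integer seed.
#' @return `out`, invisibly.
#' @export
run_perturb <- function(net_path, out, fraction = 0.05, seed = 1) {
  net <- read_ppin(net_path)
  write_ppin(perturb_edges(net, fraction, seed), out)
  invisible(out)
}
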