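## End-to-end orchestration: enumerate stoichiometries, build bundles, score,
## dock the globular partner, filter by restraints, analyze interfaces,
## classify stability, and emit Table-style TSV reports.

.known_config_keys <- c("sequences", "start_ids", "stoichiometries", "crick",
                        "matrix_source", "training", "docking", "restraints",
                        "out_dir", "seed", "log_level")

#' Pipeline configuration
#'
#' Builds and validates the configuration consumed by [runPipeline()];
#' unknown keys are rejected.
#'
#' @param sequences Named character vector of the two chain sequences
#'   (default: the shipped synthetic periplasmic pair).
#' @param start_ids Integer author-numbering starts, one per sequence.
#' @param stoichiometries Subset of `c("1:1", "2:1", "1:2", "2:2")`.
#' @param crick Optional [CrickParams-class] override (default per chain
#'   count).
#' @param matrix_source `"derive"` (train on a synthetic interface set) or a
#'   path to a matrix TSV written by [writePairPotential()].
#' @param training Parameters of the synthetic training set when deriving:
#'   `kind` (`"bundles"`, the default — native-like coiled-coil interfaces —
#'   or `"controlled"` for [makeTrainingSet()] statistics), `n_interfaces`,
#'   and for controlled sets `enrichment`, `background`,
#'   `pairs_per_interface`.
#' @param docking List: `enabled`, `ligand` (path to a partner PDB or `NULL`
#'   for a synthetic stand-in), `angular_step`, `spacing`, `keep_top`,
#'   `per_rotation_keep`, `n_copies` (dock the partner once or twice).
#' @param restraints List: `slab` thickness in A (`NA` disables the
#'   membrane-orientation filter) and optional `distance` data frame as in
#'   [restraintSet()].
#' @param out_dir Report directory.
#' @param seed Integer seed covering every stochastic stage.
#' @param log_level `"info"` or `"quiet"`.
#' @return Validated configuration list (class `PipelineConfig`).
#' @export
pipelineConfig <- function(sequences = NULL, start_ids = NULL,
                           stoichiometries = c("1:1", "2:1", "1:2", "2:2"),
                           crick = NULL, matrix_source = "derive",
                           training = list(), docking = list(),
                           restraints = list(), out_dir = tempfile("coildock_"),
                           seed = 1L, log_level = c("info", "quiet")) {
  if (is.null(sequences)) {
    sequences <- syntheticPeriplasmicSequences()
    names(sequences) <- c("FtsB", "FtsL")
    if (is.null(start_ids)) start_ids <- c(25L, 61L)
  }
  if (is.null(start_ids)) start_ids <- c(1L, 1L)
  stopifnot(length(sequences) == 2, length(start_ids) == 2)
  bad <- setdiff(stoichiometries, c("1:1", "2:1", "1:2", "2:2"))
  if (length(bad)) stop("config error: unknown stoichiometry ", paste(bad, collapse = ","))
  tr_def <- list(kind = "bundles", n_interfaces = 20L, enrichment = numeric(),
                 pairs_per_interface = 50L, background = NULL)
  dk_def <- list(enabled = TRUE, ligand = NULL, angular_step = 60,
                 spacing = 2.0, keep_top = 50L, per_rotation_keep = 2L,
                 n_copies = 1L)
  rs_def <- list(slab = 8, distance = NULL)
  check_keys <- function(given, def, what) {
    bad <- setdiff(names(given), names(def))
    if (length(bad)) stop("config error: unknown ", what, " key(s): ",
                          paste(bad, collapse = ", "))
    utils::modifyList(def, given)
  }
  cfg <- list(sequences = sequences, start_ids = as.integer(start_ids),
              stoichiometries = stoichiometries, crick = crick,
              matrix_source = matrix_source,
              training = check_keys(training, tr_def, "training"),
              docking = check_keys(docking, dk_def, "docking"),
              restraints = check_keys(restraints, rs_def, "restraints"),
              out_dir = out_dir, seed = as.integer(seed),
              log_level = match.arg(log_level))
  class(cfg) <- "PipelineConfig"
  cfg
}

## short deterministic hash of the configuration, for output headers; the
## output directory is excluded so identical analyses hash identically
.config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- paste(utils::capture.output(utils::str(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97)) %% .Machine$integer.max)
}

.plog <- function(cfg, ...) {
  if (identical(cfg$log_level, "info")) message("[coilDock] ", ...)
}

## write a TSV with a deterministic provenance header line
.write_report_tsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# coilDock report; config ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full modelling pipeline
#'
#' For every requested stoichiometry: build the bundle, score it under the
#' pair potential, optionally dock the globular partner by FFT shape
#' complementarity and filter poses by the biological restraints, compute the
#' interface report and alanine-scan hotspots, and classify stability against
#' the mean-stable-complex reference. A top-level summary ranks the
#' stoichiometries by (restraint-passing pose count, stability verdict,
#' pair-potential score); the verdict is static-analysis only. Fully
#' deterministic given the seed.
#'
#' @param config A [pipelineConfig()].
#' @return Invisibly, a list with the per-stoichiometry results, the summary
#'   data frame and the output directory. Stage failures are logged and
#'   recorded; later independent stages still run.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  hash <- .config_hash(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ## pair potential
  if (identical(config$matrix_source, "derive")) {
    .plog(config, "deriving pair potential from synthetic training set")
    train <- if (identical(config$training$kind, "bundles")) {
      ## native-like coiled-coil interfaces: the family-specific filter
      lapply(seq_len(config$training$n_interfaces), function(k)
        list(structure = makeBundle(2L, 28L, seed = config$seed + k),
             partition = list("A", "B")))
    } else {
      bg <- config$training$background
      if (is.null(bg)) bg <- .default_background()
      makeTrainingSet(config$training$n_interfaces,
                      enrichment = config$training$enrichment,
                      seed = config$seed, background = bg,
                      pairs_per_interface = config$training$pairs_per_interface)
    }
    pp <- derivePairPotential(train, contactDefinition("CB-CB"))
  } else {
    pp <- readPairPotential(config$matrix_source)
  }
  writePairPotential(pp, file.path(config$out_dir, "pair_potential.tsv"))
  ## partner ligand for docking
  lig <- NULL
  if (isTRUE(config$docking$enabled)) {
    lig <- if (is.null(config$docking$ligand))
      makeRodLigand(20, 8) else readPDB(config$docking$ligand)
  }
  specs <- enumerateStoichiometries(
    stats::setNames(config$sequences[1], names(config$sequences)[1]),
    stats::setNames(config$sequences[2], names(config$sequences)[2]),
    start_A = config$start_ids[1], start_B = config$start_ids[2])
  results <- list()
  failed <- character()
  for (st in config$stoichiometries) {
    .plog(config, "stoichiometry ", st)
    sub <- file.path(config$out_dir, gsub(":", "to", st))
    dir.create(sub, showWarnings = FALSE)
    res <- list(stoichiometry = st)
    ok <- tryCatch({
      spec <- specs[[st]]
      bundle <- buildBundle(spec, config$crick)
      writePDB(bundle, file.path(sub, "bundle.pdb"))
      protA <- names(config$sequences)[1]
      prots <- vapply(spec@chains, function(ch) ch$protein, "")
      ids <- vapply(spec@chains, function(ch) ch$chainId, "")
      partition <- list(ids[prots == protA], ids[prots != protA])
      res$bundle <- bundle
      res$partition <- partition
      res$score <- scoreComplex(bundle, partition, pp)
      ## docking stage
      res$n_pass <- NA_integer_
      if (isTRUE(config$docking$enabled)) {
        poses <- generatePoses(bundle, lig,
                               angular_step = config$docking$angular_step,
                               spacing = config$docking$spacing,
                               keep_top = config$docking$keep_top,
                               per_rotation_keep = config$docking$per_rotation_keep)
        writePoseManifest(poses, file.path(sub, "poses.tsv"))
        rs <- restraintSet(config$restraints$distance,
                           slab_thickness = config$restraints$slab)
        filt <- applyRestraints(poses, bundle, lig, rs)
        writePoseManifest(filt, file.path(sub, "poses_filtered.tsv"))
        res$n_pass <- nrow(filt)
        if (nrow(filt)) {
          placed <- poseTransform(lig, filt[1, ], attr(poses, "ligand_center"))
          cplx <- combineStructures(bundle, placed)
          if (config$docking$n_copies >= 2L && nrow(filt) >= 2L) {
            placed2 <- poseTransform(lig, filt[2, ], attr(poses, "ligand_center"))
            cplx <- combineStructures(cplx, placed2)
          }
          writePDB(cplx, file.path(sub, "complex_top_pose.pdb"))
          lig_chains <- setdiff(chainIds(cplx), chainIds(bundle))
          cplx_report <- interfaceReport(cplx, list(chainIds(bundle), lig_chains))
          .write_report_tsv(.report_row(cplx_report, paste0(st, "+partner")),
                            file.path(sub, "interface_complex.tsv"), hash)
        }
      }
      ## interface analysis of the bundle itself
      rep <- interfaceReport(bundle, partition)
      res$report <- rep
      .write_report_tsv(.report_row(rep, st),
                        file.path(sub, "interface_bundle.tsv"), hash)
      hot <- alanineScan(bundle, partition, pp)
      .write_report_tsv(hot, file.path(sub, "hotspots.tsv"), hash)
      res$stability <- classifyStability(rep)
      .write_report_tsv(res$stability$fields,
                        file.path(sub, "stability.tsv"), hash)
      TRUE
    }, error = function(e) {
      .plog(config, "stage failed for ", st, ": ", conditionMessage(e))
      res$error <<- conditionMessage(e)
      FALSE
    })
    if (!ok) failed <- c(failed, st)
    results[[st]] <- res
  }
  ## summary ranking: restraint-pass count, stability verdict, score
  done <- results[!vapply(results, function(r) is.null(r$report), TRUE)]
  if (length(done)) {
    verdict_rank <- c(consistent = 0, borderline = 1, inconsistent = 2)
    summary <- data.frame(
      stoichiometry = vapply(done, `[[`, "", "stoichiometry"),
      helices = vapply(done, function(r) length(chainIds(r$bundle)), 0L),
      pair_potential_score = round(vapply(done, `[[`, 0, "score"), 4),
      poses_passing_restraints = vapply(done, `[[`, 0L, "n_pass"),
      interface_asa = round(vapply(done, function(r) r$report@interfaceASA, 0), 1),
      stability_verdict = vapply(done, function(r) r$stability$verdict, ""),
      note = "static-analysis only")
    np <- summary$poses_passing_restraints
    np[is.na(np)] <- 0L
    summary <- summary[order(-np, verdict_rank[summary$stability_verdict],
                             -summary$pair_potential_score), , drop = FALSE]
    .write_report_tsv(summary, file.path(config$out_dir, "summary.tsv"), hash)
    renderTables(lapply(done, `[[`, "report"),
                 labels = vapply(done, `[[`, "", "stoichiometry"),
                 out_dir = config$out_dir, hash = hash)
  } else summary <- NULL
  out <- list(results = results, summary = summary, out_dir = config$out_dir,
              failed = failed)
  if (length(failed)) {
    attr(out, "exit_status") <- 1L
    warning("pipeline stage failure for: ", paste(failed, collapse = ", "))
  } else attr(out, "exit_status") <- 0L
  invisible(out)
}

.report_row <- function(report, label) {
  data.frame(
    complex = label,
    interface_asa_A2 = round(report@interfaceASA, 2),
    interface_asa_pct = round(report@interfaceASAPercent, 2),
    pct_polar = round(report@interfaceComposition["polar"], 2),
    pct_nonpolar = round(report@interfaceComposition["nonpolar"], 2),
    pct_charged = round(report@interfaceComposition["charged"], 2),
    hbonds_per_100A2 = round(report@hbondsPer100A2, 3),
    saltbridges_per_100A2 = round(report@saltBridgesPer100A2, 3),
    dim_x = round(report@dimensions[1], 1),
    dim_y = round(report@dimensions[2], 1),
    dim_z = round(report@dimensions[3], 1),
    row.names = NULL)
}

#' Render interface and surface tables
#'
#' Writes the two report tables: interface parameters of the complexes and
#' surface distribution of amino-acid residues, one row per stoichiometry,
#' with the shipped mean-stable-complex reference row appended.
#'
#' @param reports List of [InterfaceReport-class] objects.
#' @param labels Character labels, one per report.
#' @param out_dir Output directory.
#' @param hash Optional provenance tag for the header line.
#' @return Invisibly, the two file paths.
#' @export
renderTables <- function(reports, labels = NULL, out_dir = ".", hash = "manual") {
  stopifnot(length(reports) >= 1)
  if (is.null(labels)) labels <- paste0("complex_", seq_along(reports))
  ref <- meanStableReference()
  rv <- function(f) ref$value_lo[ref$field == f]
  rvh <- function(f) ref$value_hi[ref$field == f]
  t1 <- do.call(rbind, Map(function(r, l) {
    d <- .report_row(r, l); d[, 1:8]
  }, reports, labels))
  t1 <- rbind(t1, data.frame(
    complex = "Mean stable complex", interface_asa_A2 = NA,
    interface_asa_pct = rv("interface_asa_percent"),
    pct_polar = rv("pct_polar"), pct_nonpolar = rv("pct_nonpolar"),
    pct_charged = rv("pct_charged"),
    hbonds_per_100A2 = rv("hbonds_per_100A2"),
    saltbridges_per_100A2 = paste0(rv("saltbridges_per_100A2"), " - ",
                                   rvh("saltbridges_per_100A2"))))
  t2 <- do.call(rbind, Map(function(r, l) data.frame(
    complex = l,
    pct_polar = round(r@surfaceComposition["polar"], 2),
    pct_nonpolar = round(r@surfaceComposition["nonpolar"], 2),
    pct_charged = round(r@surfaceComposition["charged"], 2),
    row.names = NULL), reports, labels))
  t2 <- rbind(t2, data.frame(
    complex = "Mean stable complex", pct_polar = rv("surface_pct_polar"),
    pct_nonpolar = rv("surface_pct_nonpolar"),
    pct_charged = rv("surface_pct_charged")))
  p1 <- file.path(out_dir, "table_interface_parameters.tsv")
  p2 <- file.path(out_dir, "table_surface_distribution.tsv")
  .write_report_tsv(t1, p1, hash)
  .write_report_tsv(t2, p2, hash)
  invisible(c(p1, p2))
}
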