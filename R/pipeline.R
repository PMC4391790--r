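# End-to-end orchestration: alignment -> complexity track -> structure
# tracks -> correlations + contact prediction -> TSV reports + manifest.

#' Build a pipeline run configuration
#'
#' Collects input paths and parameters, applying the canonical defaults:
#' the VAR/ENT "1:2 box" (VAR 0.5-1.5, ENT 50-60), the KOL 1.5-3.5 band,
#' an 8 angstrom CA-CA contact cutoff with minimum sequence separation 1,
#' and lag 0 for correlations.
#'
#' @param alignment path to the alignment file (required).
#' @param dialect alignment dialect, `"fasta"` or `"blocks"`.
#' @param pdb_a,pdb_i optional paths to the active / inactive structures.
#' @param chain_a,chain_i chain identifiers (`NULL`: first chain).
#' @param ss optional secondary-structure letter string, or a path to a
#'   file whose first line holds it.
#' @param var_lo,var_hi,ent_lo,ent_hi,kol_lo,kol_hi box-filter bounds.
#' @param cutoff,min_separation experimental contact definition.
#' @param lag correlation lag.
#' @param min_freq variability frequency threshold.
#' @param seed RNG seed recorded in the manifest.
#' @param out_dir output directory (created if absent).
#' @return A list of class `"run_config"`.
#' @export
make_run_config <- function(alignment, dialect = c("fasta", "blocks"),
                            pdb_a = NULL, pdb_i = NULL,
                            chain_a = NULL, chain_i = NULL, ss = NULL,
                            var_lo = 0.5, var_hi = 1.5,
                            ent_lo = 50, ent_hi = 60,
                            kol_lo = 1.5, kol_hi = 3.5,
                            cutoff = 8.0, min_separation = 1L,
                            lag = 0L, min_freq = 0.01, seed = 1L,
                            out_dir = "foldsignal_out") {
  dialect <- match.arg(dialect)
  cfg <- list(alignment = alignment, dialect = dialect,
              pdb_a = pdb_a, pdb_i = pdb_i,
              chain_a = chain_a, chain_i = chain_i, ss = ss,
              var_lo = var_lo, var_hi = var_hi,
              ent_lo = ent_lo, ent_hi = ent_hi,
              kol_lo = kol_lo, kol_hi = kol_hi,
              cutoff = cutoff, min_separation = as.integer(min_separation),
              lag = as.integer(lag), min_freq = min_freq,
              seed = as.integer(seed), out_dir = out_dir)
  for (b in list(c("var_lo", "var_hi"), c("ent_lo", "ent_hi"),
                 c("kol_lo", "kol_hi")))
    if (cfg[[b[1]]] > cfg[[b[2]]])
      stop("bound ", b[1], " exceeds ", b[2])
  if (!file.exists(alignment)) stop("alignment file not found: ", alignment)
  for (p in c(pdb_a, pdb_i))
    if (!is.null(p) && !file.exists(p)) stop("PDB file not found: ", p)
  structure(cfg, class = "run_config")
}

pipeline_log <- function(...) message("[foldsignal] ", ...)

#' Run the full analysis pipeline
#'
#' Stages: (1) read the alignment and write the per-position complexity
#' track; (2) if a structure is supplied, derive AREA (and HST/HSTD from a
#' secondary-structure string, and DISP when a second conformer is given)
#' and write the structure-track table; (3) correlate the complexity scores
#' with the structural tracks; (4) predict contacts with the VAR/ENT box
#' and the KOL band, evaluate both against the structure-derived contact
#' map, and write a confusion report; (5) write a manifest recording
#' package version, parameters and input checksums. Missing structure
#' input degrades gracefully: structure-dependent stages are skipped with
#' a logged notice and the complexity track is still produced. Identical
#' configuration and inputs give byte-identical outputs.
#'
#' @param config a `"run_config"` from [make_run_config()].
#' @return Invisibly, a list with the computed objects and the paths of
#'   the files written (`$files`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  out <- function(name) file.path(config$out_dir, name)

  pipeline_log("stage complexity: reading ", config$alignment)
  msa <- read_alignment(config$alignment, config$dialect)
  track <- complexity_track(msa, min_freq = config$min_freq)
  write_complexity_tsv(track, out("complexity.tsv"))
  files <- c(files, complexity = out("complexity.tsv"))
  pipeline_log("stage complexity: ", nrow(track), " positions scored")

  tracks <- list(var = track$var, ent = track$ent, kol = track$kol)
  result <- list(msa = msa, complexity = track)

  if (is.null(config$pdb_a)) {
    pipeline_log("no structure supplied; skipping structure-dependent stages")
  } else {
    trace_a <- read_ca_trace(config$pdb_a, config$chain_a)
    pipeline_log("stage structure: ", trace_a$length, " CA atoms")
    area <- triangle_area_track(trace_a)
    struct <- data.frame(position = seq_len(trace_a$length))
    struct$area <- c(area, rep(NA_real_, 2))
    tracks$area <- struct$area
    if (!is.null(config$ss)) {
      ss <- config$ss
      if (file.exists(ss)) ss <- readLines(ss, n = 1L)
      hst <- hst_encode(dssp_to_hst(ss))
      if (length(hst$values) != trace_a$length)
        stop("secondary-structure string length ", length(hst$values),
             " does not match trace length ", trace_a$length)
      struct$hst <- hst$values
      struct$hstd <- hst_differentiate(hst)$values
      tracks$hst <- struct$hst
      tracks$hstd <- struct$hstd
    }
    if (!is.null(config$pdb_i)) {
      trace_i <- read_ca_trace(config$pdb_i, config$chain_i)
      struct$disp <- displacement_track(trace_a, trace_i)
      tracks$disp <- struct$disp
    }
    write_structure_tsv(struct, out("tracks.tsv"))
    files <- c(files, tracks = out("tracks.tsv"))
    result$structure <- struct

    spec_rows <- expand.grid(x = c("ent", "var", "kol"),
                             y = setdiff(names(struct),
                                         c("position", "hst", "hstd")),
                             stringsAsFactors = FALSE)
    spec_rows <- rbind(spec_rows,
                       data.frame(x = "kol",
                                  y = intersect(c("hst", "hstd"),
                                                names(struct))))
    spec_rows$lag <- config$lag
    report <- correlation_report(tracks, spec_rows)
    write_correlation_tsv(report, out("correlation.tsv"))
    files <- c(files, correlation = out("correlation.tsv"))
    result$correlation <- report
    pipeline_log("stage correlation: ", nrow(report), " pairs")

    if (msa$length == trace_a$length) {
      actual <- contact_map_from_structure(trace_a, config$cutoff,
                                           config$min_separation)
      box_ve <- list(score_filter("var", config$var_lo, config$var_hi),
                     score_filter("ent", config$ent_lo, config$ent_hi))
      box_k <- score_filter("kol", config$kol_lo, config$kol_hi)
      preds <- list(
        VRN = predict_contacts(passing_positions(track, box_ve),
                               trace_a$length),
        KLM = predict_contacts(passing_positions(track, box_k),
                               trace_a$length))
      conf <- lapply(preds, confusion, actual = actual)
      rows <- do.call(rbind, lapply(names(conf), function(m) {
        cc <- conf[[m]]
        data.frame(protein = basename(config$pdb_a), method = m,
                   tp = cc$tp, fp = cc$fp, fn = cc$fn, tn = cc$tn,
                   mcc = cc$mcc)
      }))
      write_confusion_tsv(rows, out("confusion.tsv"))
      files <- c(files, confusion = out("confusion.tsv"))
      result$confusion <- rows
      result$contact_maps <- c(preds, list(actual = actual))
      pipeline_log("stage contacts: ",
                   trace_a$length * (trace_a$length - 1) / 2,
                   " pairs evaluated")
    } else {
      pipeline_log("alignment width ", msa$length, " != trace length ",
                   trace_a$length, "; skipping contact evaluation")
    }
  }

  manifest <- out("manifest.txt")
  write_manifest(config, files, manifest)
  files <- c(files, manifest = manifest)
  result$files <- files
  invisible(result)
}

write_structure_tsv <- function(struct, path) {
  out <- struct
  for (nm in setdiff(names(out), "position"))
    out[[nm]] <- ifelse(is.na(out[[nm]]), ".",
                        trimws(formatC(out[[nm]], format = "g",
                                       digits = 10)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

write_manifest <- function(config, files, path) {
  inputs <- Filter(Negate(is.null),
                   config[c("alignment", "pdb_a", "pdb_i")])
  sums <- vapply(unlist(inputs), function(p)
    unname(tools::md5sum(p)), character(1))
  params <- config[setdiff(names(config),
                           c("alignment", "pdb_a", "pdb_i", "out_dir"))]
  lines <- c(
    paste0("package=foldsignal ",
           as.character(utils::packageVersion("foldsignal"))),
    paste0("param.", names(params), "=",
           vapply(params, function(v)
             if (is.null(v)) "" else as.character(v), character(1))),
    paste0("input.", names(sums), "=", sums),
    paste0("output.", names(files), "=", basename(unlist(files))))
  writeLines(lines, path)
  invisible(path)
}
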