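#' Read a pipeline run configuration
#'
#' YAML with blocks: \code{paths} (manifest, output_dir), \code{segmentation}
#' (SegmentationConfig fields, see \code{\link{readSegmentationConfig}}),
#' \code{qtl} (lod_threshold, alpha, window_bp, n_perm) and \code{seed}.
#' Every stochastic stage derives its seed from the global seed plus a stage
#' offset, and the configuration is serialised into every JSON report for
#' provenance.
#'
#' @param path YAML file.
#' @return list with elements paths, segmentation
#'   (\linkS4class{SegmentationConfig}), qtl, seed.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  seg <- SegmentationConfig()
  if (!is.null(y$segmentation)) {
    s <- y$segmentation
    seg <- SegmentationConfig(
      cropRegion = s$crop_region,
      hueRange = if (!is.null(s$hsi_hue_range)) s$hsi_hue_range else c(60, 180),
      satMin = if (!is.null(s$hsi_sat_min)) s$hsi_sat_min else 0.15,
      intRange = if (!is.null(s$hsi_int_range)) s$hsi_int_range else c(0.02, 0.98),
      egThreshold = if (!is.null(s$eg_threshold)) s$eg_threshold else 20,
      minComponentArea = if (!is.null(s$min_component_area)) s$min_component_area else 64)
  }
  qtl <- list(lod_threshold = 2.5, alpha = 0.01, window_bp = 1e6,
              n_perm = 10000)
  qtl[names(y$qtl)] <- y$qtl
  list(paths = y$paths, segmentation = seg, qtl = qtl,
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}

# derive a stage seed (< 2^31) from the global seed and a stage name;
# double arithmetic avoids integer overflow for large global seeds
stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1009 + sum(utf8ToInt(stage))) %% 2147483587)
}

#' Extract the trait table for a manifest of images
#'
#' The manifest has one row per frame: line, replicate, season, time_point,
#' view ("side"/"top"), frame_index, path (relative to \code{root}). Frames
#' of one (line, replicate, season, time_point) cell form one inspection.
#'
#' @param manifest data.frame or CSV path.
#' @param root directory image paths are relative to.
#' @param config a \linkS4class{SegmentationConfig}.
#' @return long trait table data.frame.
#' @export
extractTraitTable <- function(manifest, root = ".",
                              config = SegmentationConfig()) {
  if (is.character(manifest)) manifest <- utils::read.csv(manifest)
  keys <- unique(manifest[c("line", "replicate", "season", "time_point")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- merge(manifest, keys[i, , drop = FALSE])
    sides <- sub[sub$view == "side", ]
    tops <- sub[sub$view == "top", ]
    sf <- lapply(file.path(root, sides$path), readFrame, view = "side")
    tf <- readFrame(file.path(root, tops$path[1]), view = "top")
    v <- extractInspection(sf, tf, config)
    data.frame(keys[i, , drop = FALSE], trait = names(v), value = unname(v),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  out[c("line", "replicate", "season", "time_point", "trait", "value")]
}

#' Run the full pipeline on a fixture directory
#'
#' Convenience composition used by the command-line interface: extracts
#' traits from the manifest, writes traits.csv, growth_traits.csv,
#' heritability.csv and, when genotypes.csv/markers.csv are present, qtl.csv
#' and hotspots.json into the output directory.
#'
#' @param inputDir directory with manifest.csv (+ images/, genotypes.csv,
#'   markers.csv).
#' @param outputDir output directory (created).
#' @param config a \linkS4class{SegmentationConfig}.
#' @param seed global seed.
#' @param lodThreshold,alpha,nPerm QTL-stage settings.
#' @return invisible list of the produced tables.
#' @export
runPipeline <- function(inputDir, outputDir, config = SegmentationConfig(),
                        seed = 1L, lodThreshold = 2.5, alpha = 0.01,
                        nPerm = 1000) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  traits <- extractTraitTable(file.path(inputDir, "manifest.csv"),
                              root = inputDir, config = config)
  writeTraitTable(traits, file.path(outputDir, "traits.csv"))
  out <- list(traits = traits)
  # growth traits need a TPA series per line/view
  series <- traits[traits$trait %in% c("TPA_SV", "TPA_TV") &
                     is.finite(traits$value), ]
  if (nrow(series) && length(unique(series$time_point)) >= 6) {
    series <- data.frame(line = series$line, season = series$season,
                         view = sub("^TPA_", "", series$trait),
                         t = series$time_point, value = series$value)
    gt <- growthTraitTable(series, seed = stageSeed(seed, "growth"))
    utils::write.csv(gt, file.path(outputDir, "growth_traits.csv"),
                     row.names = FALSE)
    out$growth <- gt
  }
  if (length(unique(paste(traits$season, traits$replicate))) > 1) {
    h2 <- heritabilityTable(traits)
    utils::write.csv(h2, file.path(outputDir, "heritability.csv"),
                     row.names = FALSE)
    out$heritability <- h2
  }
  gpath <- file.path(inputDir, "genotypes.csv")
  mpath <- file.path(inputDir, "markers.csv")
  if (file.exists(gpath) && file.exists(mpath)) {
    g <- utils::read.csv(gpath, check.names = FALSE)
    geno <- as.matrix(g[, -1, drop = FALSE])
    rownames(geno) <- g[[1]]
    mk <- utils::read.csv(mpath)
    recs <- list()
    cells <- unique(traits[c("trait", "time_point", "season")])
    for (i in seq_len(nrow(cells))) {
      d <- traits[traits$trait == cells$trait[i] &
                  traits$time_point == cells$time_point[i] &
                  traits$season == cells$season[i], ]
      pheno <- tapply(d$value, d$line, mean, na.rm = TRUE)
      if (sum(is.finite(pheno)) < 30) next
      scan <- tryCatch(qtlScan(geno, mk, pheno[is.finite(pheno)],
                               lodThreshold = lodThreshold),
                       error = function(e) NULL)
      if (!is.null(scan) && nrow(qtlRecords(scan)))
        recs[[length(recs) + 1L]] <- cbind(cells[i, , drop = FALSE],
                                           qtlRecords(scan),
                                           row.names = NULL)
    }
    if (length(recs)) {
      qdf <- do.call(rbind, recs)
      utils::write.csv(qdf, file.path(outputDir, "qtl.csv"),
                       row.names = FALSE)
      out$qtl <- qdf
    }
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the installed script
#' (\code{system.file("cli", "napuspheno.R", package = "napusPheno")}).
#' Subcommands: \code{simulate}, \code{extract-traits}, \code{run-all}.
#' Returns an exit status: 0 success, 2 unknown command, 3 bad or missing
#' input, 1 other error.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status.
#' @export
phenoCLI <- function(args) {
  if (!length(args)) {
    message("usage: napuspheno <simulate|extract-traits|run-all> [options]")
    return(2L)
  }
  cmd <- args[1]
  opts <- list()
  rest <- args[-1]
  i <- 1L
  while (i <= length(rest)) {
    if (startsWith(rest[i], "--")) {
      opts[[substring(rest[i], 3)]] <- rest[i + 1L]
      i <- i + 2L
    } else i <- i + 1L
  }
  tryCatch({
    switch(cmd,
      "simulate" = {
        if (is.null(opts$out) || is.null(opts$seed)) {
          message("simulate needs --out and --seed"); return(3L)
        }
        writeFixtureDir(opts$out, seed = as.integer(opts$seed))
        0L
      },
      "extract-traits" = {
        if (is.null(opts$manifest) || is.null(opts$out)) {
          message("extract-traits needs --manifest and --out"); return(3L)
        }
        if (!file.exists(opts$manifest)) {
          message("manifest not found: ", opts$manifest); return(3L)
        }
        tt <- extractTraitTable(opts$manifest, root = dirname(opts$manifest))
        writeTraitTable(tt, opts$out)
        0L
      },
      "run-all" = {
        if (is.null(opts$`in`) || is.null(opts$out)) {
          message("run-all needs --in and --out"); return(3L)
        }
        seed <- if (is.null(opts$seed)) 1L else as.integer(opts$seed)
        runPipeline(opts$`in`, opts$out, seed = seed)
        0L
      },
      {
        message("unknown command: ", cmd)
        2L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("not found|cannot open", conditionMessage(e))) 3L else 1L
  })
}
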