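#' Configuration for an end-to-end pipeline run
#'
#' Bundles the simulation scenario and per-stage parameter overrides for
#' [run_pipeline()]. Unknown parameter names are rejected up front, before
#' any stage runs.
#'
#' @param out_dir run directory (created if absent).
#' @param seed global seed; every stage derives its randomness from it.
#' @param trio overrides passed to [trio_sim_config()] (list).
#' @param plate overrides passed to [plate_sim_config()]; `genotypes` is
#'   required there, so a default 96-well layout with 8 NTC wells and three
#'   genotype clusters is supplied here.
#' @param window,step windowing parameters for [windowed_density()].
#' @param blocks overrides for [call_blocks()] thresholds (list with any of
#'   min_fraction, min_snps, min_windows).
#' @param verbose print per-stage progress.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, seed = 1, trio = list(), plate = NULL,
                            window = 1e5, step = 5e4, blocks = list(),
                            verbose = TRUE) {
  known_trio <- setdiff(names(formals(trio_sim_config)), "seed")
  bad <- setdiff(names(trio), known_trio)
  if (length(bad)) stopf("unknown trio parameter(s): %s", paste(bad, collapse = ", "))
  known_blocks <- c("min_fraction", "min_snps", "min_windows")
  bad <- setdiff(names(blocks), known_blocks)
  if (length(bad)) stopf("unknown block parameter(s): %s", paste(bad, collapse = ", "))
  if (is.null(plate)) {
    plate <- list(genotypes = c(rep("allele1_hom", 60), rep("allele2_hom", 18),
                                rep("het", 10), rep("ntc", 8)))
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), trio = trio,
                 plate = plate, window = window, step = step, blocks = blocks,
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Orchestrates simulate -> KASP call -> trio classification -> block calling
#' -> marker design with plain-file intermediates (VCF/CSV/TSV/BED) so each
#' stage is independently inspectable and re-runnable. The run is
#' deterministic given the configuration and seed. A machine-readable
#' `summary.json` collects the origin-category counts, called blocks, and
#' designed markers; a `MANIFEST` lists completed stages (on failure it marks
#' the run incomplete and names the failing stage).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the summary list (also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- file.path(config$out_dir, "MANIFEST")
  done <- character(0)
  note <- function(fmt, ...) if (config$verbose) message(sprintf(fmt, ...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(c(done, sprintf("INCOMPLETE: stage '%s' failed", name)), manifest)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    done <<- c(done, name)
    note("stage %-10s done in %.2fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }

  sim <- stage("simulate", {
    cfg <- do.call(trio_sim_config, c(config$trio, list(seed = derive_seed(config$seed, 11L))))
    tr <- simulate_trio(cfg)
    for (nm in c("donor", "receptor", "improved"))
      write_callset(tr[[nm]], file.path(config$out_dir, paste0(nm, ".vcf")),
                    genome = cfg$genome)
    data.table::fwrite(tr$truth$origins,
                       file.path(config$out_dir, "truth_origins.tsv"), sep = "\t")
    list(trio = tr, genome = cfg$genome)
  })

  kasp <- stage("kasp", {
    pcfg <- do.call(plate_sim_config,
                    c(config$plate, list(seed = derive_seed(config$seed, 12L))))
    pl <- simulate_plate(pcfg)
    write_plate_csv(pl$plate, file.path(config$out_dir, "plate.csv"))
    calls <- call_genotypes(normalize_plate(pl$plate), marker_id = pl$plate$marker_id)
    utils::write.table(calls, file.path(config$out_dir, "kasp_calls.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    calls
  })

  origin <- stage("classify", {
    tab <- classify_trio(sim$trio$improved, sim$trio$donor, sim$trio$receptor)
    write_origin_table(tab,
                       sites_path = file.path(config$out_dir, "origins.tsv"),
                       summary_path = file.path(config$out_dir, "origin_summary.tsv"))
    tab
  })

  blocks <- stage("blocks", {
    track <- windowed_density(origin, sim$genome,
                              window = config$window, step = config$step)
    b_args <- c(list(track = track, table = origin), config$blocks)
    bl <- rbind(do.call(call_blocks, c(b_args, list(category = "donor"))),
                do.call(call_blocks, c(b_args, list(category = "unknown"))))
    export_tracks(track, bl,
                  bedgraph_path = file.path(config$out_dir, "donor_fraction.bedgraph"),
                  bed_path = file.path(config$out_dir, "blocks.bed"))
    bl
  })

  markers <- stage("design", {
    amp <- simulate_amplicons(seed = derive_seed(config$seed, 13L))
    designed <- list()
    for (i in seq_len(nrow(amp$truth))) {
      t_i <- amp$truth[i, ]
      m <- if (t_i$type == "indel") {
        design_indel_marker(amp$ref_seqs[[t_i$id]], t_i$pos, t_i$indel_len)
      } else {
        design_caps(amp$ref_seqs[[t_i$id]], amp$donor_seqs[[t_i$id]])
      }
      if (!is.null(m)) designed[[t_i$id]] <- m
    }
    designed
  })

  summary <- list(
    version = as.character(utils::packageVersion("introtrace")),
    seed = config$seed,
    origin_counts = stats::setNames(as.list(origin$summary$count),
                                    origin$summary$category),
    origin_percent = stats::setNames(as.list(origin$summary$percent),
                                     origin$summary$category),
    kasp_calls = as.list(table(kasp$call)),
    blocks = blocks,
    markers = lapply(markers, function(m)
      m[intersect(names(m), c("marker_type", "enzyme", "product_length_ref",
                              "product_length_alt", "size_difference"))])
  )
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(c(done, "COMPLETE"), manifest)
  invisible(summary)
}
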