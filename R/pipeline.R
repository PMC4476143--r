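#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> alpha -> median rank -> RAD fits -> beta
#' structure -> composition as one reproducible run. The configuration is a
#' JSON file or an R list with exactly one of:
#' \describe{
#'   \item{`table`}{path to an OTU table (`table_dialect` selects the
#'     format), optionally `metadata` (CSV path);}
#'   \item{`simulation`}{a block of [generate_dataset()] arguments
#'     (`seed`, optional `design` / `bank` parameter lists).}
#' }
#' Optional blocks: `beta` (`metric`, `factor` — a metadata column, default
#' `month`; `permutations`, default 999), `composition` (`groups` — path to
#' an OTU-to-group CSV), `radfit` (`enabled`, default TRUE), `seed`.
#'
#' Outputs written to `out_dir`: `table.tsv` and `meta.csv` (simulated runs),
#' `alpha.csv`, `medianrank.csv`, `fits.csv`, `distance.csv`,
#' `dendrogram.nwk`, `permanova.csv`, `permanova_pairwise.csv`,
#' `top_otus.csv`, `occupancy.csv`, `group_composition.csv` (when a map is
#' given), `config.json` and `manifest.json`. The manifest records the
#' package version, config hash, seeds and per-stage row counts; identical
#' config and seed give byte-identical numeric outputs. A stage failure
#' aborts with the stage name after persisting the partial manifest.
#'
#' @param config List or path to a JSON config file.
#' @param out_dir Output directory (default `config$output_dir`).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stopf("config must be a list or a JSON file path")
  out_dir <- out_dir %||% config$output_dir
  if (is.null(out_dir)) stopf("no output directory given")
  has_table <- !is.null(config$table)
  has_sim <- !is.null(config$simulation)
  if (has_table == has_sim)
    stopf("config must name exactly one of 'table' (input path) or 'simulation' (generator block)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  config_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(config, config_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  seed <- config$seed %||% 1L
  manifest <- list(package = "rankbank",
                   version = as.character(utils::packageVersion("rankbank")),
                   config_hash = unname(tools::md5sum(config_path)),
                   seed = seed, started = format(Sys.time(), tz = "UTC"),
                   stages = list())
  results <- list()
  persist <- function()
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      manifest$failed_stage <<- name
      manifest$error <<- conditionMessage(e)
      persist()
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    manifest$stages[[name]] <<- list(rows = stage_rows(res))
    results[[name]] <<- res
    res
  }

  inputs <- stage("input", function() {
    if (has_sim) {
      sim <- config$simulation
      design <- do.call(dataset_design, sim$design %||% list())
      bank <- do.call(bank_model_params, sim$bank %||% list())
      ds <- generate_dataset(design, bank, seed = sim$seed %||% seed)
      write_otu_table(ds$table, file.path(out_dir, "table.tsv"),
                      "matrix_tsv")
      write_metadata(ds$metadata, file.path(out_dir, "meta.csv"))
      ds
    } else {
      tab <- read_otu_table(config$table,
                            config$table_dialect %||% "shared")
      meta <- if (!is.null(config$metadata)) read_metadata(config$metadata)
      list(table = tab, metadata = meta)
    }
  })
  tab <- inputs$table
  meta <- inputs$metadata

  alpha <- stage("alpha", function() {
    a <- alpha_diversity(tab)
    utils::write.csv(a, file.path(out_dir, "alpha.csv"), row.names = FALSE)
    a
  })

  stage("medianrank", function() {
    mr <- median_rank_table(tab)
    mr$class <- as.character(classify_median_ranks(mr)$class)
    utils::write.csv(mr, file.path(out_dir, "medianrank.csv"),
                     row.names = FALSE)
    mr
  })

  if (isTRUE(config$radfit$enabled %||% TRUE)) {
    stage("radfit", function() {
      fits <- fit_rad_all(tab)
      utils::write.csv(fits, file.path(out_dir, "fits.csv"),
                       row.names = FALSE)
      fits
    })
  }

  stage("beta", function() {
    metric <- config$beta$metric %||% "bray_curtis"
    dm <- distance_matrix(tab, metric)
    utils::write.csv(data.frame(sample_id = dm$ids, dm$d,
                                check.names = FALSE),
                     file.path(out_dir, "distance.csv"), row.names = FALSE)
    dend <- jaccard_stability(tab, metric,
                              B = config$beta$bootstrap %||% 100,
                              seed = seed)
    write_newick(dend, file.path(out_dir, "dendrogram.nwk"))
    out <- list(dm = dm, dendrogram = dend)
    fac <- config$beta$factor %||% "month"
    if (!is.null(meta) && fac %in% names(meta) &&
        length(unique(meta[[fac]])) > 1) {
      groups <- stats::setNames(as.character(meta[[fac]]), meta$sample_id)
      nperm <- config$beta$permutations %||% 999
      pv <- permanova(dm, groups, n_permutations = nperm, seed = seed,
                      factor_name = fac)
      utils::write.csv(
        data.frame(factor = pv$factor_name, f = pv$f, p = pv$p,
                   df_among = pv$df_among, df_within = pv$df_within,
                   n_permutations = pv$n_permutations),
        file.path(out_dir, "permanova.csv"), row.names = FALSE)
      pw <- suppressWarnings(
        permanova_pairwise(dm, groups, n_permutations = nperm, seed = seed))
      utils::write.csv(pw, file.path(out_dir, "permanova_pairwise.csv"),
                       row.names = FALSE)
      out$permanova <- pv
      out$pairwise <- pw
    }
    out
  })

  stage("composition", function() {
    top <- top_otu_summary(tab)
    utils::write.csv(top$otus, file.path(out_dir, "top_otus.csv"),
                     row.names = FALSE)
    occ <- occupancy(tab)
    utils::write.csv(occ, file.path(out_dir, "occupancy.csv"),
                     row.names = FALSE)
    out <- list(top = top, occupancy = occ)
    if (!is.null(config$composition$groups)) {
      gc <- group_composition(tab, read_group_map(config$composition$groups))
      utils::write.csv(data.frame(sample_id = rownames(gc), gc,
                                  check.names = FALSE),
                       file.path(out_dir, "group_composition.csv"),
                       row.names = FALSE)
      out$groups <- gc
    }
    out
  })

  manifest$finished <- format(Sys.time(), tz = "UTC")
  persist()
  invisible(c(results, list(manifest = manifest, out_dir = out_dir)))
}

stage_rows <- function(res) {
  if (is.data.frame(res)) nrow(res)
  else if (inherits(res, "otu_table")) nrow(res$counts)
  else if (is.list(res) && inherits(res$table, "otu_table"))
    nrow(res$table$counts)
  else NA_integer_
}
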