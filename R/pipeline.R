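#' Run the trajectory pipeline end to end
#'
#' Orchestrates simulate -> qc -> embed -> repact (RNA and/or ATAC) ->
#' intra-donor on a synthetic cohort, writing TSV/JSON artifacts per stage
#' into `outdir`.  Re-running with the same config and seed reproduces the
#' artifacts byte for byte.
#'
#' @param config list of cohort parameters passed to [cohort_config()]
#'   (unknown entries are an error); the `seed` argument overrides any seed
#'   in the config.
#' @param stages ordered subset of `c("simulate", "qc", "embed",
#'   "repact-rna", "repact-atac", "intra-donor")`.
#' @param outdir output directory.
#' @param seed integer seed for the whole run.
#' @return invisibly, a list of the in-memory stage results.
#' @export
run_pipeline <- function(config = list(),
                         stages = c("simulate", "qc", "embed", "repact-rna",
                                    "repact-atac", "intra-donor"),
                         outdir, seed = 1L) {
  all_stages <- c("simulate", "qc", "embed", "repact-rna", "repact-atac",
                  "intra-donor")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config$seed <- seed
  cfg <- do.call(cohort_config, config)
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  state <- list()
  tsv <- function(d, name)
    utils::write.table(d, file.path(outdir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)

  need <- function(what, producer) {
    if (is.null(state[[what]]))
      stop(sprintf("stage requires '%s'; run the '%s' stage first", what,
                   producer), call. = FALSE)
  }

  for (stage in stages) {
    message("[repactools] stage: ", stage)
    if (stage == "simulate") {
      state$cohort <- generate_cohort(cfg)
      write_cohort(state$cohort, outdir)
    } else if (stage == "qc") {
      need("cohort", "simulate")
      atac <- state$cohort$atac
      qc <- atac_cell_qc(Matrix::rowSums(atac$values),
                         Matrix::rowSums(atac$values),
                         cell_id = cell_ids(atac), min_frac = 0.0,
                         min_reads = 0)
      tsv(qc, "atac_qc.tsv")
      state$qc <- qc
    } else if (stage == "embed") {
      need("cohort", "simulate")
      genes <- select_informative_genes(state$cohort$rna,
                                        n = min(500,
                                                ncol(state$cohort$rna$values)))
      state$pca <- pca_embed(state$cohort$rna, genes)
      write_embedding(state$pca, file.path(outdir, "pca.tsv"))
      state$lsi <- lsi_embed(tfidf_transform(state$cohort$atac),
                             dims = min(50, dim(state$cohort$atac)) )
      write_embedding(state$lsi, file.path(outdir, "lsi.tsv"))
    } else if (stage == "repact-rna") {
      need("pca", "embed")
      ph <- stats::setNames(as.character(state$cohort$cells$phenotype),
                            state$cohort$cells$cell_id)
      state$rna_model <- fit_trajectory(state$pca, ph)
      state$rna_gate <- trajectory_phenotype_test(state$pca,
                                                  state$cohort$cells)
      if (state$rna_gate$p_value >= 0.05)
        warning("trajectory shows no donor-level phenotype association ",
                sprintf("(p = %.3g); calls should not be interpreted",
                        state$rna_gate$p_value))
      state$rna_bins <- bin_by_index(state$rna_model$pseudo_index)
      state$rna_results <- feature_trend_test(state$cohort$rna,
                                              state$rna_bins)
      tsv(state$rna_results, "repact_rna.tsv")
      write_trajectory_model(state$rna_model,
                             file.path(outdir, "rna_model.json"),
                             state$rna_bins)
    } else if (stage == "repact-atac") {
      need("lsi", "embed")
      ph <- stats::setNames(as.character(state$cohort$cells$phenotype),
                            state$cohort$cells$cell_id)
      state$atac_model <- fit_trajectory(state$lsi, ph)
      state$atac_bins <- bin_by_index(state$atac_model$pseudo_index)
      state$atac_results <- feature_trend_test(state$cohort$atac,
                                               state$atac_bins,
                                               scale = "zscore",
                                               q_cut = 0.01)
      tsv(state$atac_results, "repact_atac.tsv")
      write_trajectory_model(state$atac_model,
                             file.path(outdir, "atac_model.json"),
                             state$atac_bins)
    } else if (stage == "intra-donor") {
      need("rna_model", "repact-rna")
      dt <- per_donor_trends(state$cohort$rna, state$rna_model,
                             state$cohort$cells)
      het <- classify_heterogeneity(state$rna_results, dt)
      tsv(het, "heterogeneity_rna.tsv")
      state$heterogeneity <- het
    }
  }
  invisible(state)
}
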