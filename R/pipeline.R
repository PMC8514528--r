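#' Pipeline configuration
#'
#' Collects the inputs, stage toggles and tuning parameters of the
#' end-to-end analysis.  Inputs are either file paths (responses CSV +
#' schema) or `synthetic = TRUE`, in which case a cohort is generated from
#' `synthetic_params`.
#'
#' @param outdir output directory (created if missing).
#' @param responses,schema paths to a responses CSV and schema file, or
#'   `NULL` when `synthetic = TRUE`.
#' @param synthetic generate the input cohort instead of reading files.
#' @param synthetic_params a [cohort_params()]; default
#'   [default_cohort_params()] with the master seed.
#' @param external_corr optional path to a trait-level correlation matrix
#'   (CSV, square with header) to embed alongside the data-derived one.
#' @param target_trait scale refined in the refinement stage.
#' @param alpha_network edge significance level of the PC-stable stage.
#' @param theta_refine separability threshold of the refinement stage.
#' @param k_traits,k_subjects cluster counts for the trait and subject cuts.
#' @param embed an [embed_params()].
#' @param stages character vector of stages to run, a subset of
#'   `c("cluster", "network", "embed", "refine", "effects")`; scoring always
#'   runs.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, responses = NULL, schema = NULL,
                            synthetic = is.null(responses),
                            synthetic_params = NULL, external_corr = NULL,
                            target_trait = "sps", alpha_network = 0.01,
                            theta_refine = 0.05, k_traits = 2, k_subjects = 3,
                            embed = embed_params(),
                            stages = c("cluster", "network", "embed", "refine"),
                            seed = 1L) {
  if (!synthetic) {
    for (p in c(responses, schema))
      if (!file.exists(p)) stop_ts("input path does not exist: %s", p)
  }
  if (!is.null(external_corr) && !file.exists(external_corr))
    stop_ts("input path does not exist: %s", external_corr)
  bad <- setdiff(stages, c("cluster", "network", "embed", "refine", "effects"))
  if (length(bad)) stop_ts("unknown stage(s): %s", paste(bad, collapse = ", "))
  if ("refine" %in% stages && !all(c("cluster", "embed") %in% stages))
    stop_ts("the refine stage needs the cluster and embed stages")
  structure(list(outdir = outdir, responses = responses, schema = schema,
                 synthetic = synthetic, synthetic_params = synthetic_params,
                 external_corr = external_corr, target_trait = target_trait,
                 alpha_network = alpha_network, theta_refine = theta_refine,
                 k_traits = k_traits, k_subjects = k_subjects, embed = embed,
                 stages = stages, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full trait-space analysis
#'
#' Executes, in order: scoring (keyed trait/subdomain totals, z-scores,
#' reliability), hierarchical clustering of traits and subjects with
#' composites and group statistics, the PC-stable partial-correlation
#' graph, the MDS-initialized t-SNE item embedding, the embedding-based
#' refinement of the target scale followed by a rerun of clustering and
#' graph learning under the refined schema, and (optionally) the factorial
#' effects stage on synthetic parental-bonding scores.  Every artifact is
#' written to `config$outdir` in plain-text formats; the returned report
#' carries per-stage summaries and MD5 hashes of all outputs, so a rerun
#' with an identical configuration reproduces identical hashes.
#'
#' @param config a [pipeline_config()].
#' @return list of class `run_report` (also written to
#'   `<outdir>/run_report.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)
  report <- list(config = config[setdiff(names(config), "synthetic_params")],
                 stages = list())

  # ---- input / scoring stage -------------------------------------------
  if (config$synthetic) {
    params <- config$synthetic_params %||% default_cohort_params(seed = config$seed)
    cohort <- generate_cohort(params)
    rm <- cohort$responses
    schema <- cohort$schema
    write_responses(rm, out("responses.csv"))
    write_schema(schema, out("schema.yaml"))
  } else {
    schema <- read_schema(config$schema)
    rm <- read_responses(config$responses, schema)
    rm <- apply_key(rm, schema)
    cohort <- NULL
  }
  if (any(rm$meta$excluded)) rm <- exclude_subjects(rm)
  scores <- score_traits(rm, schema)
  trait_z <- zscore_columns(scores$traits)
  rel <- reliability_report(rm, schema)
  utils::write.csv(data.frame(subject_id = rownames(scores$traits),
                              scores$traits, check.names = FALSE),
                   out("trait_scores.csv"), row.names = FALSE)
  write_reliability(rel, out("reliability.json"))
  report$stages$scoring <- list(status = "ok", n_subjects = nrow(scores$traits),
                                n_traits = ncol(scores$traits),
                                n_items = ncol(rm$values))

  run_cluster <- function(tz, tag) {
    td <- wpgma_linkage(correlation_distance(tz, "columns"))
    sdnd <- wpgma_linkage(correlation_distance(tz, "rows"))
    tcl <- cut_tree(td, config$k_traits)
    scl <- cut_tree(sdnd, config$k_subjects)
    comp <- composite_scores(tz, tcl)
    writeLines(dendrogram_newick(td), out(paste0("dendrogram_traits", tag, ".nwk")))
    utils::write.csv(data.frame(label = names(tcl), cluster = tcl),
                     out(paste0("trait_clusters", tag, ".csv")), row.names = FALSE)
    utils::write.csv(data.frame(label = names(scl), cluster = scl),
                     out(paste0("subject_clusters", tag, ".csv")), row.names = FALSE)
    gc <- tryCatch(group_correlation(comp[, 1:2], scl), error = function(e) NULL)
    list(trait_dend = td, trait_clusters = tcl, subject_clusters = scl,
         composites = comp, group_correlations = gc)
  }
  run_network <- function(tz, tag) {
    g <- pc_stable_skeleton(tz, alpha = config$alpha_network)
    write_edge_list(g, out(paste0("graph_edges", tag, ".tsv")))
    write_graphml(g, out(paste0("graph", tag, ".graphml")))
    write_ci_log(g, out(paste0("ci_tests", tag, ".csv")))
    g
  }

  cl <- gr <- emb <- ref <- NULL
  if ("cluster" %in% config$stages) {
    cl <- run_cluster(trait_z, "")
    report$stages$cluster <- list(
      status = "ok",
      trait_clusters = split(names(cl$trait_clusters), cl$trait_clusters),
      subject_cluster_sizes = as.list(table(cl$subject_clusters)))
  }
  if ("network" %in% config$stages) {
    gr <- run_network(trait_z, "")
    report$stages$network <- list(status = "ok", n_edges = nrow(gr$edges),
                                  centrality = as.list(gr$centrality))
  }
  if ("embed" %in% config$stages) {
    item_z <- zscore_columns(rm)
    emb <- embed_items(item_z, schema, config$embed)
    write_embedding(emb, out("item_embedding.csv"))
    report$stages$embed <- list(status = "ok", n_points = nrow(emb),
                                kl_final = utils::tail(attr(emb, "kl_trace"), 1))
  }
  if ("refine" %in% config$stages) {
    ref <- prune_items(emb, schema, config$target_trait,
                       theta = config$theta_refine, responses = rm)
    write_refinement(ref, out("refinement.json"))
    write_schema(ref$schema_variant, out("schema_refined.yaml"))
    # rerun clustering and graph learning under the refined schema
    scores2 <- score_traits(rm2 <- restrict_responses(rm, ref$schema_variant),
                            ref$schema_variant)
    tz2 <- zscore_columns(scores2$traits)
    cl2 <- run_cluster(tz2, "_refined")
    gr2 <- run_network(tz2, "_refined")
    report$stages$refine <- list(
      status = "ok", removed = ref$removed,
      alpha_before = ref$alpha_before, alpha_after = ref$alpha_after,
      refined_edges = nrow(gr2$edges),
      refined_trait_clusters = split(names(cl2$trait_clusters), cl2$trait_clusters))
  }
  if ("effects" %in% config$stages) {
    if (is.null(cohort))
      stop_ts("the effects stage currently runs on synthetic cohorts (parental scores are generated)")
    pbi <- generate_pbi(cohort, seed = stage_seed(config$seed, "pbi"))
    care <- pbi_average(pbi$care_mother, pbi$care_father)
    over <- pbi_average(pbi$overprotection_mother, pbi$overprotection_father)
    sps_lv <- dichotomize(scores$traits[, config$target_trait])
    an <- list(care = two_way_anova(rowMeans(trait_z), sps_lv, dichotomize(care)),
               overprotection = two_way_anova(rowMeans(trait_z), sps_lv,
                                              dichotomize(over)))
    utils::write.csv(do.call(rbind, lapply(names(an), function(k)
      cbind(factor_b = k, an[[k]]))), out("anova.csv"), row.names = FALSE)
    report$stages$effects <- list(status = "ok",
                                  sps_by_care_p = an$care$p[1:3],
                                  sps_by_overprotection_p = an$overprotection$p[1:3])
  }
  if (!is.null(config$external_corr)) {
    C <- as.matrix(utils::read.csv(config$external_corr, row.names = 1,
                                   check.names = FALSE))
    e_ext <- embed_trait_matrix(C)
    trait_corr <- stats::cor(scores$traits)
    e_own <- embed_trait_matrix(trait_corr)
    cmp <- compare_embeddings(e_own, e_ext)
    write_embedding(e_ext, out("external_embedding.csv"))
    jsonlite::write_json(list(shared = cmp$labels, rmse = cmp$rmse),
                         out("embedding_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
    report$stages$external <- list(status = "ok", rmse = cmp$rmse)
  }

  files <- list.files(config$outdir, full.names = TRUE)
  files <- files[!grepl("run_report\\.json$", files)]
  report$artifacts <- as.list(tools::md5sum(files))
  class(report) <- "run_report"
  jsonlite::write_json(unclass(report), out("run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null", force = TRUE)
  report
}

# keep only the items a (possibly pruned) schema declares
restrict_responses <- function(rm, schema) {
  ids <- schema_items(schema)$id
  response_matrix(rm$values[, ids, drop = FALSE], rm$meta, keyed = rm$keyed)
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  for (s in names(x$stages))
    cat(sprintf("  %-9s %s\n", s, x$stages[[s]]$status))
  cat(sprintf("  %d artifact(s)\n", length(x$artifacts)))
  invisible(x)
}
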