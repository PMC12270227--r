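# End-to-end pipeline on a synthetic screen: simulate -> fingerprint ->
# score -> QC -> reduce -> cluster -> class analysis -> GR assay, with all
# artifacts written to an output directory.

#' Run the full pipeline on a synthetic screen
#'
#' Generates a planted synthetic screen, processes both activation
#' conditions through HistDiff fingerprinting, CP Activity scoring and
#' thresholding, the QC gates, feature reduction and clustering, class
#' enrichment and consolidation entropy, and GR translocation scoring, and
#' writes every artifact (plate maps, fingerprints, activity tables, QC
#' reports, reduced matrices, cluster labels, enrichment/entropy tables, a
#' summary JSON and the effective configuration) under `out_dir`. All
#' randomness derives from `config$seed`, so a repeated run reproduces the
#' outputs byte for byte.
#'
#' @param config Named list as from [default_config()]; unknown stages
#'   read their own keys. The demo screen size is controlled by
#'   `demo_n_both`, `demo_n_activated_only`, `demo_n_resting_only`,
#'   `demo_n_inert`, `n_features`, `cells_per_well_mean` (modest defaults
#'   keep a run to a couple of minutes).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the summary quantities (illumination
#'   counts, thresholds, QC verdicts, enrichment and entropy tables, GR
#'   percentages) and the written file paths.
#' @export
run_demo <- function(config = default_config(), out_dir = tempfile("cpdemo")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- utils::modifyList(default_config(), config)
  cfg$demo_n_both <- cfg$demo_n_both %||% 10L
  cfg$demo_n_activated_only <- cfg$demo_n_activated_only %||% 6L
  cfg$demo_n_resting_only <- cfg$demo_n_resting_only %||% 4L
  cfg$demo_n_inert <- cfg$demo_n_inert %||% 80L
  cfg$n_features <- min(cfg$n_features, 80L)
  cfg$cells_per_well_mean <- min(cfg$cells_per_well_mean, 150)
  seed <- cfg$seed
  write_pipeline_config(cfg, file.path(out_dir, "config.yaml"))

  cp_log("info", "demo: simulating synthetic screen (seed ", seed, ")")
  design <- planted_screen_design(
    n_both = cfg$demo_n_both, n_activated_only = cfg$demo_n_activated_only,
    n_resting_only = cfg$demo_n_resting_only, n_inert = cfg$demo_n_inert,
    classes = 2L, n_cytotoxic = 2L,
    n_features = cfg$n_features, n_plates = 1L,
    cells_per_well_mean = cfg$cells_per_well_mean,
    cells_per_well_dispersion = cfg$cells_per_well_dispersion,
    n_affected = max(5L, cfg$n_features %/% 6L), seed = seed)

  conditions <- c("resting", "activated")
  act <- list(); fp <- list(); pms <- list()
  for (cond in conditions) {
    pm <- generate_platemap(design, 1L, condition = cond)
    pms[[cond]] <- pm
    write_platemap(pm, file.path(out_dir, paste0("platemap_", cond, ".csv")))
    cells <- simulate_single_cells(design, pm, cond,
                                   seed = derive_seed(seed, match(cond, conditions)))
    f <- fingerprint_plate(cells, pm, bins = cfg$bins,
                           min_cells = cfg$min_cells)
    write_fingerprints(f, file.path(out_dir, paste0("fingerprints_", cond, ".tsv")))
    fp[[cond]] <- f
  }

  ref_scores <- unlist(lapply(conditions, function(cond) {
    pm <- pms[[cond]]
    rw <- intersect(pm$well[pm$role == "reference_control"], rownames(fp[[cond]]))
    cp_activity_score(unclass(fp[[cond]])[rw, , drop = FALSE])
  }))
  thresholds <- list(
    iqr = threshold_iqr(ref_scores),
    fdr5 = threshold_fdr(ref_scores, q = cfg$fdr_q),
    elbow = threshold_elbow(unlist(lapply(fp, cp_activity_score)))
  )
  thr <- thresholds[[cfg$threshold_method]]
  jsonlite::write_json(
    lapply(thresholds, function(t) list(method = t$method, value = t$value,
                                        provenance = t$provenance)),
    file.path(out_dir, "thresholds.json"), auto_unbox = TRUE, digits = NA)

  for (cond in conditions) {
    act[[cond]] <- activity_table(fp[[cond]], pms[[cond]], thr)
    utils::write.csv(as.data.frame(act[[cond]]),
                     file.path(out_dir, paste0("activity_", cond, ".csv")),
                     row.names = FALSE)
  }
  exp_only <- function(tab) tab[tab$role == "experimental", , drop = FALSE]
  venn <- illumination_summary(exp_only(act$resting), exp_only(act$activated))
  paired <- paired_condition_table(act$resting, act$activated, thr)
  utils::write.csv(paired, file.path(out_dir, "paired_conditions.csv"),
                   row.names = FALSE)

  qc <- lapply(conditions, function(cond) {
    pm <- pms[[cond]]
    ctrl <- intersect(control_wells(pm), act[[cond]]$well)
    sc <- stats::setNames(act[[cond]]$cp_score, act[[cond]]$well)[ctrl]
    roles <- stats::setNames(pm$role, pm$well)[ctrl]
    chp5_gate(sc, thr, roles, plate_id = attr(pm, "plate_id"))
  })
  names(qc) <- conditions

  # ChP2 brightfield gate on simulated control wells
  bf_frac <- c(rep(0.05, 8), rep(0.9, 8))
  bf_cond <- stats::setNames(rep(c("resting", "activated"), each = 8),
                             all_wells()[3:18])
  bf <- simulate_brightfield_cells(
    stats::setNames(bf_frac, names(bf_cond)), n_cells = 150L,
    junk_rate = 0.05, seed = derive_seed(seed, 11L))
  bf <- prefilter_cells(bf)
  train <- bf[bf$well %in% names(bf_cond)[c(1, 2, 9, 10)], ]
  train$label <- ifelse(bf_cond[train$well] == "activated",
                        "activated", "resting")
  clf <- train_activation_classifier(train)
  pct <- vapply(names(bf_cond), function(w) {
    percent_activated(clf, bf[bf$well == w, , drop = FALSE])
  }, 0)
  chp2 <- chp2_gate(pct, bf_cond, plate_id = "demo")

  # reduction and clustering on experimental-compound fingerprints
  key_rows <- function(cond) {
    pm <- pms[[cond]]
    w <- pm$well[!is.na(pm$compound_id) & pm$role == "experimental"]
    m <- unclass(fp[[cond]])[intersect(w, rownames(fp[[cond]])), , drop = FALSE]
    rownames(m) <- pm$compound_id[match(rownames(m), pm$well)]
    m[!apply(is.na(m), 1, any), , drop = FALSE]
  }
  m_rest <- key_rows("resting"); m_act <- key_rows("activated")
  common <- intersect(rownames(m_rest), rownames(m_act))
  reduced <- remove_collinear(drop_zero_variance(
    concat_conditions(m_rest[common, ], m_act[common, ])),
    r_cut = cfg$collinearity_cut)
  emb <- embed_fingerprints(reduced,
                            n_components = min(cfg$embed_components,
                                               nrow(reduced) - 1L))
  sim <- similarity_matrix(emb, metric = "pearson")
  labels <- cluster_hdbscan(sim, min_cluster_size = cfg$min_cluster_size)
  utils::write.csv(data.frame(compound_id = names(labels), cluster = labels),
                   file.path(out_dir, "clusters.csv"), row.names = FALSE)
  trees <- list(rows = cluster_hierarchical(reduced, "rows"),
                cols = cluster_hierarchical(reduced, "columns"))
  export_heatmap(reduced, trees$rows, trees$cols,
                 path_prefix = file.path(out_dir, "heatmap"))
  utils::write.csv(similarity_edges(sim, cut = 0.7),
                   file.path(out_dir, "network_edges.csv"), row.names = FALSE)

  classes <- design$compounds[!is.na(design$compounds$class),
                              c("compound_id", "class")]
  enr <- ks_class_enrichment(sim, classes, alpha = cfg$alpha)
  utils::write.csv(as.data.frame(enr), file.path(out_dir, "class_enrichment.csv"),
                   row.names = FALSE)
  lab_by_cond <- lapply(list(m_rest[common, ], m_act[common, ]), function(m) {
    cluster_hdbscan(similarity_matrix(m, metric = "euclidean"),
                    min_cluster_size = cfg$min_cluster_size,
                    input = "distance")
  })
  ent <- entropy_consolidation(classes, lab_by_cond[[1]], lab_by_cond[[2]])
  utils::write.csv(as.data.frame(ent), file.path(out_dir, "class_entropy.csv"),
                   row.names = FALSE)
  utils::write.csv(consolidation_scatter(ent),
                   file.path(out_dir, "consolidation_scatter.csv"),
                   row.names = FALSE)

  gr <- simulate_gr_cells(1000L, 0.6, seed = derive_seed(seed, 21L))
  gr$well <- rep(c("B02", "B03"), length.out = nrow(gr))
  gr_summary <- gr_well_summary(gr)
  utils::write.csv(gr_summary, file.path(out_dir, "gr_translocation.csv"),
                   row.names = FALSE)

  summary <- list(
    seed = seed,
    n_compounds = venn$n_compounds,
    illumination_counts = as.list(stats::setNames(as.vector(venn$counts),
                                                  names(venn$counts))),
    illumination_percent = as.list(venn$percentages),
    thresholds = lapply(thresholds, `[[`, "value"),
    qc_verdicts = c(lapply(qc, `[[`, "verdict"), chp2 = chp2$verdict),
    classifier_training_accuracy = clf$training_accuracy,
    n_clusters = attr(labels, "provenance")$n_clusters,
    fraction_classes_enriched = attr(enr, "fraction_significant"),
    gr_percent_nuclear = gr_summary$percent_nuclear
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  cp_log("info", "demo: outputs written to ", out_dir)
  invisible(c(summary, list(out_dir = out_dir)))
}
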