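#' Build a pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end pipeline with the
#' package defaults: per-analysis alpha 0.05, family-wise alpha 0.05 for
#' trajectory classification, enrichment FDR 0.05, young days {3, 6}, old
#' day {59}. The cluster count `k` is always an explicit choice (default 8,
#' matching the handful of trajectory shapes the default generator mixes);
#' use [scan_k()] to explore candidate values against a size band before
#' fixing it — the pipeline never chooses `k` on its own.
#'
#' @param out_dir Output directory (created if needed).
#' @param counts,samples Paths to input TSVs, or `NULL` when simulating.
#' @param simulate Logical; generate a synthetic cohort instead of reading
#'   inputs.
#' @param n_genes,class_mix,effect_size,dispersion_sim Generator settings
#'   (see [make_truth()]); used only when `simulate = TRUE`.
#' @param seed Integer seed; mandatory when simulating.
#' @param alpha,family_alpha,fdr Significance thresholds.
#' @param k Cluster count (explicit; see [scan_k()] to explore candidates).
#' @param linkage Clustering linkage.
#' @param size_band Cluster-size band reported alongside the chosen `k` in
#'   the manifest (at the study's reference scale of 6142 genes; rescaled
#'   to the analyzed gene count).
#' @param young_days,old_days Contrast day sets.
#' @param slide Logical; also run the sliding old-window contrasts.
#' @param gmt Character vector of GMT paths (may be empty).
#' @param log_transform Logical; compute trajectories on `log1p` of the
#'   normalized counts.
#' @param dispersion `NULL` to estimate dispersion from the data, or a
#'   scalar/per-gene vector passed through to the DE engine.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            counts = NULL, samples = NULL,
                            simulate = is.null(counts),
                            n_genes = 2000,
                            class_mix = c(null = 0.5, linear_up = 0.2,
                                          linear_down = 0.2,
                                          midlife_peak = 0.05, wave = 0.05),
                            effect_size = 1, dispersion_sim = 0.05,
                            seed = NULL,
                            alpha = 0.05, family_alpha = 0.05, fdr = 0.05,
                            k = 8, linkage = "complete",
                            size_band = c(50, 500),
                            young_days = c(3, 6), old_days = 59,
                            slide = FALSE, gmt = character(),
                            log_transform = FALSE, dispersion = NULL) {
  cfg <- list(out_dir = out_dir, counts = counts, samples = samples,
              simulate = simulate, n_genes = n_genes, class_mix = class_mix,
              effect_size = effect_size, dispersion_sim = dispersion_sim,
              seed = seed, alpha = alpha, family_alpha = family_alpha,
              fdr = fdr, k = k, linkage = linkage, size_band = size_band,
              young_days = young_days, old_days = old_days, slide = slide,
              gmt = gmt, log_transform = log_transform,
              dispersion = dispersion)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys match [pipeline_config()] arguments.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$class_mix)) raw$class_mix <- unlist(raw$class_mix)
  for (nm in c("size_band", "young_days", "old_days", "gmt")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(pipeline_config, raw)
}

validate_config <- function(cfg) {
  if (cfg$simulate) {
    if (is.null(cfg$seed)) stop("config error: seed is mandatory when simulating")
  } else {
    for (p in c("counts", "samples")) {
      if (is.null(cfg[[p]])) {
        stop("config error: '", p, "' path required when simulation is disabled")
      }
      if (!file.exists(cfg[[p]])) stop("config error: missing file: ", cfg[[p]])
    }
  }
  for (g in cfg$gmt) {
    if (!file.exists(g)) stop("config error: missing GMT file: ", g)
  }
  invisible(cfg)
}

#' Validate a count matrix against its sample table
#'
#' Checks sample-id agreement (fatal on mismatch), non-negative integer
#' counts, at least 2 sampling points, and survival monotonicity (a
#' warning, since real cohorts can have ties or recording quirks).
#'
#' @param counts Count matrix.
#' @param samples Sample table.
#' @return List with character vectors `errors` and `warnings`.
#' @export
validate_inputs <- function(counts, samples) {
  errors <- character()
  warnings <- character()
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      !setequal(colnames(counts), samples$sample_id)) {
    errors <- c(errors, "sample ids in counts and metadata do not agree")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    errors <- c(errors, "counts must be non-negative integers")
  }
  if (length(unique(samples$day)) < 2L) {
    errors <- c(errors, "need at least 2 sampling points")
  }
  ord <- order(samples$day)
  if (is.unsorted(-samples$survival_fraction[ord])) {
    warnings <- c(warnings, "survival_fraction is not non-increasing in day")
  }
  if ("mortality_fraction" %in% names(samples) &&
      any(abs(samples$mortality_fraction + samples$survival_fraction - 1) > 1e-9)) {
    errors <- c(errors, "mortality_fraction + survival_fraction != 1")
  }
  list(errors = errors, warnings = warnings)
}

#' Run the full trajectory pipeline
#'
#' Executes, in order: simulate (or read + validate), the three DE
#' analyses, Z-score trajectory clustering of the union genes,
#' cluster classification and naming, the young-versus-old contrast with
#' trajectory-class concordance (plus optional sliding windows), and
#' gene-set enrichment when GMT collections are supplied. All stage outputs
#' are written as TSVs under `cfg$out_dir`; a YAML run manifest records the
#' package version, the full parameter set, per-stage gene counts and an
#' md5 checksum for every file. Any stage failure halts with an error named
#' after the stage.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with the `manifest` (also written to
#'   `out_dir/manifest.yaml`) and the main in-memory stage results (`de`,
#'   `clusters`, `profiles`, `contrast`, `enrichment`, `truth`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  validate_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  outputs <- character()
  counts_log <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  emit <- function(x, file) {
    path <- file.path(cfg$out_dir, file)
    if (is.matrix(x)) {
      write_result_table(data.frame(id = rownames(x), x,
                                    check.names = FALSE), path)
    } else {
      write_result_table(x, path)
    }
    outputs <<- c(outputs, path)
    path
  }

  # -- stage: data --------------------------------------------------------
  dat <- stage("data", {
    if (cfg$simulate) {
      design <- make_design()
      truth <- make_truth(cfg$n_genes, class_mix = cfg$class_mix,
                          effect_size = cfg$effect_size,
                          dispersion = cfg$dispersion_sim,
                          days = design$day[!duplicated(design$day)])
      counts <- simulate_counts(truth, design)
      write_count_matrix(counts, file.path(cfg$out_dir, "counts.tsv"))
      write_sample_table(design, file.path(cfg$out_dir, "samples.tsv"))
      emit(truth$genes, "truth.tsv")
      outputs <<- c(outputs, file.path(cfg$out_dir, c("counts.tsv", "samples.tsv")))
      list(counts = counts, samples = design, truth = truth)
    } else {
      counts <- read_count_matrix(cfg$counts)
      samples <- read_sample_table(cfg$samples)
      chk <- validate_inputs(counts, samples)
      if (length(chk$errors)) {
        stop("input validation failed: ", paste(chk$errors, collapse = "; "))
      }
      for (w in chk$warnings) warning(w)
      list(counts = counts, samples = samples, truth = NULL)
    }
  })
  counts_log$input_genes <- nrow(dat$counts)

  # -- stage: de ----------------------------------------------------------
  de <- stage("de", run_three_analyses(dat$counts, dat$samples,
                                       alpha = cfg$alpha,
                                       dispersion = cfg$dispersion))
  for (an in names(de$tables)) {
    emit(de$tables[[an]], sprintf("de_%s.tsv", tolower(an)))
  }
  emit(de$membership, "de_membership.tsv")
  counts_log$expressed_genes <- length(de$background_genes)
  counts_log$union_genes <- length(de$union_genes)

  # -- stage: cluster -----------------------------------------------------
  clust <- stage("cluster", {
    if (length(de$union_genes) < 4L) {
      stop("too few significant genes to cluster (", length(de$union_genes), ")")
    }
    norm <- normalize_counts(dat$counts[de$background_genes, , drop = FALSE],
                             de$size_factors)
    if (cfg$log_transform) norm <- log1p(norm)
    traj <- zscore_trajectories(norm, dat$samples, genes = de$union_genes)
    dis <- pearson_dissimilarity(traj)
    hc <- hierarchical_cluster(dis, linkage = cfg$linkage)
    band <- cfg$size_band * nrow(traj) / 6142
    band[1] <- max(band[1], 2)
    if (is.null(cfg$k)) {
      stop("the cluster count 'k' must be chosen explicitly; ",
           "use scan_k() to explore candidates")
    }
    assignment <- cut_clusters(hc, cfg$k)
    list(traj = traj, hc = hc, assignment = assignment, k = cfg$k,
         band = band)
  })
  emit(data.frame(gene_id = rownames(clust$traj), unclass(clust$traj),
                  check.names = FALSE), "trajectories.tsv")
  emit(data.frame(gene_id = names(clust$assignment$cluster),
                  cluster = clust$assignment$cluster), "clusters.tsv")
  emit(data.frame(merge1 = clust$hc$merge[, 1], merge2 = clust$hc$merge[, 2],
                  height = clust$hc$height), "dendrogram_merges.tsv")
  counts_log$clusters <- clust$k

  # -- stage: classify ----------------------------------------------------
  days_sp <- dat$samples$day[!duplicated(dat$samples$sampling_point)]
  prof <- stage("classify",
                characterize_clusters(clust$traj, clust$assignment, days_sp,
                                      family_alpha = cfg$family_alpha))
  emit(prof$profiles, "cluster_profiles.tsv")
  curves <- do.call(rbind, lapply(seq_len(clust$k), function(i) {
    sc <- smooth_curve(prof$mean_curves[i, ], days_sp)
    data.frame(cluster = i, name = prof$profiles$name[i], sc)
  }))
  emit(curves, "cluster_curves.tsv")

  # -- stage: contrast ----------------------------------------------------
  contr <- stage("contrast", {
    ref <- two_group_de(dat$counts, dat$samples,
                        young_days = cfg$young_days, old_days = cfg$old_days,
                        alpha = cfg$alpha, dispersion = cfg$dispersion)
    conc <- concordance(clust$assignment, prof, ref)
    slide <- if (cfg$slide) {
      sliding_old_window(dat$counts, dat$samples,
                         young_days = cfg$young_days, alpha = cfg$alpha,
                         dispersion = cfg$dispersion)
    }
    list(ref = ref, conc = conc, slide = slide)
  })
  emit(contr$ref$table, "contrast_young_old.tsv")
  emit(contr$conc, "concordance.tsv")
  if (!is.null(contr$slide)) {
    slide_counts <- data.frame(
      window = names(contr$slide),
      n_significant = vapply(contr$slide, function(cr) {
        sum(cr$table$significant)
      }, integer(1))
    )
    emit(slide_counts, "sliding_windows.tsv")
  }

  # -- stage: enrich ------------------------------------------------------
  enr <- NULL
  if (length(cfg$gmt)) {
    enr <- stage("enrich", {
      colls <- lapply(cfg$gmt, read_gmt)
      enrich_all(clust$assignment, colls, background = de$background_genes,
                 fdr = cfg$fdr)
    })
    emit(enr, "enrichment.tsv")
  }

  manifest <- list(
    package = "agetraj",
    version = as.character(utils::packageVersion("agetraj")),
    parameters = cfg[setdiff(names(cfg), "class_mix")],
    class_mix = as.list(cfg$class_mix),
    gene_counts = counts_log,
    k = clust$k,
    size_band = as.numeric(clust$band),
    outputs = lapply(sort(unique(outputs)), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  yaml::write_yaml(manifest, file.path(cfg$out_dir, "manifest.yaml"))
  invisible(list(manifest = manifest, de = de, clusters = clust$assignment,
                 profiles = prof, contrast = contr, enrichment = enr,
                 truth = dat$truth))
}
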