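pipeline_defaults <- function() {
  list(
    synthetic = NULL,
    inputs = NULL,
    filters = list(min_total_reads = 100, min_samples = 5),
    rarefaction = list(depth = NULL),
    network = list(method = "fixed", lambda_frac = 0.3, n_lambda = 20,
                   beta_threshold = 0.05, n_subsamples = 50,
                   subsample_fraction = 0.8),
    cluster = list(n_restarts = 5),
    nulls = list(enabled = FALSE, R = 99),
    coupling = list(k = 9, family_alpha = 0.05, denominator = "clusters"),
    sem = list(enabled = TRUE, clusters_per_domain = 2, dsep = TRUE),
    seed = 1L,
    out_dir = "mesonet-out"
  )
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults))
      stop_config(sprintf("unknown configuration key `%s`", full))
    if (is.list(defaults[[key]]) && !is.null(defaults[[key]]) &&
        is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML/JSON file path or a list; fills stage defaults, type- and
#' range-checks every field, and rejects unknown keys with the full key
#' path. Exactly one of a `synthetic` block (passed to
#' [synthetic_config()]) or an `inputs` block (paths to plant, chemistry
#' and OTU files) must be present.
#'
#' @param config file path or list.
#' @return a validated `pipeline_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  cfg <- merge_config(pipeline_defaults(), config)
  if (is.null(cfg$synthetic) && is.null(cfg$inputs))
    stop_config("configuration needs a `synthetic` or an `inputs` block")
  if (!is.null(cfg$inputs)) {
    for (k in c("plants", "chemistry", "prok_otu", "fungal_otu")) {
      if (is.null(cfg$inputs[[k]]))
        stop_config(sprintf("inputs.%s is required", k))
      if (!file.exists(cfg$inputs[[k]]))
        stop_config(sprintf("inputs.%s: file not found (%s)", k,
                            cfg$inputs[[k]]))
    }
  }
  if (!is.null(cfg$synthetic))
    cfg$synthetic_config <- do.call(synthetic_config, cfg$synthetic)
  if (cfg$coupling$family_alpha <= 0 || cfg$coupling$family_alpha >= 1)
    stop_config("coupling.family_alpha must lie in (0, 1)")
  if (!cfg$coupling$denominator %in% c("clusters", "pairs"))
    stop_config("coupling.denominator must be 'clusters' or 'pairs'")
  if (cfg$network$method == "fixed") {
    check_range(cfg$network$lambda_frac, "network.lambda_frac", 1e-6, 1)
  } else if (cfg$network$method != "stars") {
    stop_config("network.method must be 'fixed' or 'stars'")
  }
  cfg$seed <- check_count(cfg$seed, "seed", min = 0L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — plant metrics, per-soil
#' per-domain OTU preparation and network inference, spin-glass clustering,
#' coupling scores and the stability-coupling test, optional rewiring null
#' models, specialisation/enrichment summaries, and per-soil path models
#' with the contribution ledger — writing every product under
#' `config$out_dir` and returning a manifest of outputs with md5 checksums.
#' Identical inputs, configuration and seed reproduce identical outputs.
#'
#' @param config a `pipeline_config` (or anything [validate_config()]
#'   accepts).
#' @param through last stage to execute, one of `"data"`,
#'   `"plant_metrics"`, `"prep"`, `"network"`, `"cluster"`, `"couple"`,
#'   `"null"`, `"sem"`, `"ledger"` (the default runs everything). Earlier
#'   stages always run; later ones are skipped.
#' @return a list: `manifest` (data.frame of stage, file, md5), `results`
#'   (in-memory stage products).
#' @export
run_pipeline <- function(config, through = "ledger") {
  stages_order <- c("data", "plant_metrics", "prep", "network", "cluster",
                    "couple", "null", "sem", "ledger")
  through <- match.arg(through, stages_order)
  rank <- match(through, stages_order)
  cfg <- if (inherits(config, "pipeline_config")) config else
    validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- cfg$seed
  files <- character(0)
  stage <- character(0)
  emit <- function(st, path) {
    files <<- c(files, path); stage <<- c(stage, st)
    path
  }
  finish <- function(results) {
    manifest <- data.frame(stage = stage, file = files,
                           md5 = unname(tools::md5sum(files)),
                           row.names = NULL)
    jsonlite::write_json(list(seed = seed, files = manifest),
                         file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
    list(manifest = manifest, results = results)
  }

  # --- data -------------------------------------------------------------
  if (!is.null(cfg$synthetic)) {
    ds <- generate_dataset(cfg$synthetic_config,
                           seed = derive_seed(seed, "synthetic"))
  } else {
    ds <- list(
      plants = read.csv(cfg$inputs$plants),
      chemistry = read.csv(cfg$inputs$chemistry),
      axes = if (!is.null(cfg$inputs$axes)) read.csv(cfg$inputs$axes)
    )
    meso <- unique(ds$plants[, c("mesocosm_id", "soil")])
    hab <- setNames(meso$soil, meso$mesocosm_id)
    ds$prok_table <- read_otu_table(cfg$inputs$prok_otu, habitat = hab,
                                    domain = "prokaryote")
    ds$fungal_table <- read_otu_table(cfg$inputs$fungal_otu, habitat = hab,
                                      domain = "fungal")
  }
  if (rank <= 1L) {
    if (!is.null(cfg$synthetic)) {
      paths <- write_synthetic_dataset(ds, cfg$out_dir)
      for (p in paths) emit("data", p)
    }
    return(finish(list(dataset = ds)))
  }

  # --- plant metrics ----------------------------------------------------
  pm <- plant_metrics(ds$plants, axes = ds$axes)
  write.table(pm$by_mesocosm, emit("plant_metrics",
                                   file.path(cfg$out_dir, "plant_metrics.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (rank <= 2L) return(finish(list(plant_metrics = pm)))

  # --- per soil, per domain: prep + network + clusters ------------------
  soils <- unique(ds$prok_table$habitat)
  tables <- list(prokaryote = ds$prok_table, fungal = ds$fungal_table)
  nets <- list(); parts <- list(); si <- list()
  for (dom in names(tables)) {
    tab <- tables[[dom]]
    rar <- rarefy(tab, depth = cfg$rarefaction$depth,
                  seed = derive_seed(seed, paste0("rarefy_", dom)))
    si[[dom]] <- specialisation_index(rar)
    write.table(si[[dom]]$per_otu,
                emit("specialisation",
                     file.path(cfg$out_dir, sprintf("si_%s.tsv", dom))),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (s in soils) {
      if (rank <= 3L) next
      key <- paste(dom, s, sep = ".")
      sub <- subset_otu_table(tab, samples = which(tab$habitat == s))
      sub <- filter_otus(sub, cfg$filters$min_total_reads,
                         cfg$filters$min_samples)
      x <- clr_transform(sub)
      if (cfg$network$method == "stars") {
        st <- stars_select(x, n_lambda = cfg$network$n_lambda,
                           beta_threshold = cfg$network$beta_threshold,
                           n_subsamples = cfg$network$n_subsamples,
                           subsample_fraction = cfg$network$subsample_fraction,
                           seed = derive_seed(seed, paste0("stars_", key)))
        net <- st$network
        write.table(st$path,
                    emit("network", file.path(cfg$out_dir,
                                              sprintf("stars_path_%s.tsv", key))),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      } else {
        lam <- cfg$network$lambda_frac *
          lambda_max_mb(standardize_columns(x))
        net <- mb_neighborhood_selection(x, lam)
      }
      nets[[key]] <- net
      write_signed_network(net,
                           emit("network", file.path(cfg$out_dir,
                                                     sprintf("network_%s.tsv", key))))
      if (rank <= 4L) next
      part <- spinglass_cluster(net, table = sub,
                                n_restarts = cfg$cluster$n_restarts,
                                seed = derive_seed(seed, paste0("spin_", key)))
      parts[[key]] <- part
      write_partition(part,
                      emit("cluster", file.path(cfg$out_dir,
                                                sprintf("partition_%s.tsv", key))))
    }
  }
  if (rank <= 5L) {
    return(finish(list(plant_metrics = pm, networks = nets,
                       partitions = parts, si = si)))
  }

  # --- coupling ---------------------------------------------------------
  scores <- list()
  for (s in soils) {
    pa <- parts[[paste("prokaryote", s, sep = ".")]]$abundance
    fa <- parts[[paste("fungal", s, sep = ".")]]$abundance
    sc <- coupling_scores(pa, fa, k = cfg$coupling$k)
    sc$soil <- s
    scores[[s]] <- sc
  }
  scores <- do.call(rbind, scores)
  write.table(scores, emit("couple", file.path(cfg$out_dir,
                                               "coupling_scores.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stab <- pm$by_mesocosm[match(scores$mesocosm_id,
                               pm$by_mesocosm$mesocosm_id), ]
  sc_test <- stability_coupling_test(stab$stability, scores$beta,
                                     scores$soil)
  jsonlite::write_json(sc_test,
                       emit("couple", file.path(cfg$out_dir,
                                                "stability_coupling.json")),
                       auto_unbox = TRUE, digits = NA)

  if (rank <= 6L) {
    return(finish(list(plant_metrics = pm, networks = nets,
                       partitions = parts, si = si, coupling = scores,
                       stability_coupling = sc_test)))
  }

  # --- null models ------------------------------------------------------
  nulls <- NULL
  if (isTRUE(cfg$nulls$enabled)) {
    nulls <- lapply(names(nets), function(key) {
      ens <- null_modularity_test(nets[[key]], R = cfg$nulls$R,
                                  seed = derive_seed(seed,
                                                     paste0("null_", key)),
                                  n_restarts = cfg$cluster$n_restarts)
      write_ensemble_report(
        ens, json_path = emit("null", file.path(cfg$out_dir,
                                                sprintf("null_%s.json", key))))
      ens
    })
    names(nulls) <- names(nets)
  }

  # --- path models + ledger --------------------------------------------
  sems <- NULL; ledgers <- NULL
  if (rank >= 8L && isTRUE(cfg$sem$enabled)) {
    sems <- list(); ledgers <- list()
    plant_vars <- intersect(
      c("productivity_sampling", "diversity_sampling", "axis1_sampling",
        "axis2_sampling", "axis3_sampling", "productivity_impact",
        "diversity_impact", "productivity_trajectory",
        "diversity_trajectory", "axis1_impact", "axis2_impact",
        "axis3_impact", "axis1_trajectory", "axis2_trajectory",
        "axis3_trajectory"),
      names(pm$by_mesocosm))
    for (s in soils) {
      d <- pm$by_mesocosm[pm$by_mesocosm$soil == s, ]
      d <- merge(d, ds$chemistry[, c("mesocosm_id", chem_names())],
                 by = "mesocosm_id")
      kc <- cfg$sem$clusters_per_domain
      mvars <- character(0); sizes <- numeric(0)
      for (dom in c("prokaryote", "fungal")) {
        ab <- parts[[paste(dom, s, sep = ".")]]$abundance
        for (k in seq_len(min(kc, ncol(ab)))) {
          v <- paste0(substr(dom, 1, 4), "_cluster", k)
          d[[v]] <- ab[match(d$mesocosm_id, rownames(ab)), k]
          mvars <- c(mvars, v)
          sizes[v] <- mean(ab[, k])
        }
      }
      fits <- build_and_run_sems(d, plant_vars, chem_names(), mvars,
                                 dsep = isTRUE(cfg$sem$dsep))
      led <- relative_contributions(fits, sizes)
      if (rank >= 9L)
        write_ledger(led, emit("ledger", file.path(cfg$out_dir,
                                                   sprintf("ledger_%s.tsv", s))))
      for (m in names(fits)) {
        write_model_report(fits[[m]],
                           emit("sem", file.path(cfg$out_dir,
                                                 sprintf("sem_%s_%s.json", s, m))))
      }
      sems[[s]] <- fits; ledgers[[s]] <- led
    }
  }

  finish(list(plant_metrics = pm, networks = nets,
              partitions = parts, si = si, coupling = scores,
              stability_coupling = sc_test, nulls = nulls,
              sems = sems, ledgers = ledgers))
}
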