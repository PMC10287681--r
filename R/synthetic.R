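#' Configuration for the synthetic mesocosm generator
#'
#' Describes a two-soil outdoor mesocosm experiment: per-soil replicate
#' communities sown at three density classes, annual censuses with a natural
#' invasion onset year, one soil sample per mesocosm at the final census,
#' and two amplicon domains (prokaryote 16S, fungal ITS) whose OTUs carry a
#' planted network-cluster block structure, planted habitat specialists and
#' a tunable prokaryote-fungal coupling.
#'
#' @param n_mesocosms_per_soil replicate communities per soil origin.
#' @param years inclusive census year range.
#' @param invasion_onset_year first year with natural species invasion.
#' @param n_sown_species,n_invader_species species pool sizes.
#' @param n_prok_otus,n_fungal_otus OTUs per domain.
#' @param n_prok_clusters,n_fungal_clusters planted clusters per domain.
#' @param coupling_rho_per_soil named (or length-2) vector in [-1, 1]: the
#'   correlation between rank-matched prokaryote and fungal cluster latent
#'   factors, per soil.
#' @param specialist_fraction fraction of OTUs planted as habitat
#'   specialists.
#' @param specialist_fold_change expected abundance ratio of a specialist
#'   between its preferred and non-preferred soil (>= 1).
#' @param depth_mean,depth_dispersion negative-binomial sequencing depth
#'   model (mean and size).
#' @param nb_dispersion sd of the per-count log-normal noise that
#'   overdisperses OTU counts beyond multinomial sampling.
#' @param cluster_signal_sd sd of the mesocosm-level cluster latent factors
#'   (the co-occurrence signal the networks recover).
#' @param path_coefficients list of standardized effect matrices
#'   `plant_chem` (plant drivers x chemical variables), `chem_microbe`
#'   (chemical variables x cluster factors) and `plant_microbe` (plant
#'   drivers x cluster factors); `NULL` for the package defaults
#'   (chemistry-mediated effects, no direct plant effects).
#' @param noise_sd residual sd of the chemistry and microbial linear
#'   responses (signals are unit-variance).
#' @param seed integer RNG seed; identical config and seed give identical
#'   output.
#' @return a validated `synthetic_config`.
#' @export
synthetic_config <- function(n_mesocosms_per_soil = 30,
                             years = 2007:2019,
                             invasion_onset_year = 2012,
                             n_sown_species = 12,
                             n_invader_species = 8,
                             n_prok_otus = 150,
                             n_fungal_otus = 150,
                             n_prok_clusters = 9,
                             n_fungal_clusters = 9,
                             coupling_rho_per_soil = c(
                               natural_grassland = 0.3,
                               abandoned_arable = 0.7),
                             specialist_fraction = 0.3,
                             specialist_fold_change = 8,
                             depth_mean = 5000,
                             depth_dispersion = 10,
                             nb_dispersion = 0.5,
                             cluster_signal_sd = 1.5,
                             path_coefficients = NULL,
                             noise_sd = 0.6,
                             seed = 1L) {
  cfg <- list(
    n_mesocosms_per_soil = check_count(n_mesocosms_per_soil,
                                       "n_mesocosms_per_soil"),
    years = years,
    invasion_onset_year = invasion_onset_year,
    n_sown_species = check_count(n_sown_species, "n_sown_species"),
    n_invader_species = check_count(n_invader_species, "n_invader_species",
                                    min = 0L),
    n_prok_otus = check_count(n_prok_otus, "n_prok_otus"),
    n_fungal_otus = check_count(n_fungal_otus, "n_fungal_otus"),
    n_prok_clusters = check_count(n_prok_clusters, "n_prok_clusters"),
    n_fungal_clusters = check_count(n_fungal_clusters, "n_fungal_clusters"),
    coupling_rho_per_soil = check_range(coupling_rho_per_soil,
                                        "coupling_rho_per_soil", -1, 1),
    specialist_fraction = check_range(specialist_fraction,
                                      "specialist_fraction", 0, 1),
    specialist_fold_change = specialist_fold_change,
    depth_mean = depth_mean,
    depth_dispersion = depth_dispersion,
    nb_dispersion = check_range(nb_dispersion, "nb_dispersion", 0, Inf),
    cluster_signal_sd = check_range(cluster_signal_sd, "cluster_signal_sd",
                                    0, Inf),
    path_coefficients = path_coefficients,
    noise_sd = check_range(noise_sd, "noise_sd", 0, Inf),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (length(cfg$coupling_rho_per_soil) == 1L)
    cfg$coupling_rho_per_soil <- rep(cfg$coupling_rho_per_soil, 2L)
  if (length(cfg$coupling_rho_per_soil) != 2L)
    stop_config("`coupling_rho_per_soil` must have one value per soil (2)")
  if (is.null(names(cfg$coupling_rho_per_soil)))
    names(cfg$coupling_rho_per_soil) <- soil_names()
  if (cfg$specialist_fold_change < 1)
    stop_config("`specialist_fold_change` must be >= 1")
  if (cfg$depth_mean < 1 || cfg$depth_dispersion <= 0)
    stop_config("`depth_mean` must be >= 1 and `depth_dispersion` > 0")
  if (!cfg$invasion_onset_year %in% cfg$years)
    stop_config("`years` must include `invasion_onset_year`")
  if (length(cfg$years) < 5L)
    stop_config("`years` must span at least 5 censuses")
  if (is.null(cfg$path_coefficients))
    cfg$path_coefficients <- default_path_coefficients(
      min(cfg$n_prok_clusters, cfg$n_fungal_clusters))
  validate_path_coefficients(cfg$path_coefficients,
                             min(cfg$n_prok_clusters, cfg$n_fungal_clusters))
  class(cfg) <- "synthetic_config"
  cfg
}

soil_names <- function() c("natural_grassland", "abandoned_arable")
chem_names <- function() c("total_N", "organic_C", "pH", "avail_P", "NO3",
                           "NH4", "NO2", "belowground_prod")
plant_driver_names <- function() c("productivity", "diversity", "axis1",
                                   "axis2", "axis3")

# default standardized path structure: plant community shapes soil
# chemistry, chemistry shapes the first cluster factors, no direct
# plant-microbe effects
default_path_coefficients <- function(n_factors) {
  pc <- matrix(0, 5, 8, dimnames = list(plant_driver_names(), chem_names()))
  pc["diversity", "total_N"] <- 0.5
  pc["diversity", "organic_C"] <- 0.4
  pc["productivity", "belowground_prod"] <- 0.6
  pc["productivity", "NO3"] <- -0.4
  pc["axis1", "pH"] <- 0.5
  pc["axis1", "avail_P"] <- 0.4
  pc["axis2", "NH4"] <- 0.4
  pc["axis3", "NO2"] <- 0.3
  cm <- matrix(0, 8, n_factors,
               dimnames = list(chem_names(), NULL))
  targets <- c("total_N", "pH", "NO3", "organic_C", "avail_P")
  for (i in seq_len(min(length(targets), n_factors)))
    cm[targets[i], i] <- c(0.4, 0.4, -0.4, 0.4, 0.3)[i]
  pm <- matrix(0, 5, n_factors,
               dimnames = list(plant_driver_names(), NULL))
  list(plant_chem = pc, chem_microbe = cm, plant_microbe = pm)
}

validate_path_coefficients <- function(pcs, n_factors) {
  need <- c("plant_chem", "chem_microbe", "plant_microbe")
  if (!is.list(pcs) || !all(need %in% names(pcs)))
    stop_config("`path_coefficients` needs plant_chem, chem_microbe, plant_microbe")
  if (!identical(dim(pcs$plant_chem), c(5L, 8L)))
    stop_config("`path_coefficients$plant_chem` must be 5 plant drivers x 8 chemical variables")
  if (nrow(pcs$chem_microbe) != 8L || ncol(pcs$chem_microbe) < n_factors)
    stop_config("`path_coefficients$chem_microbe` must be 8 x >= n shared cluster factors")
  if (nrow(pcs$plant_microbe) != 5L || ncol(pcs$plant_microbe) < n_factors)
    stop_config("`path_coefficients$plant_microbe` must be 5 x >= n shared cluster factors")
  invisible(pcs)
}

mesocosm_ids <- function(cfg) {
  n <- cfg$n_mesocosms_per_soil
  c(sprintf("NG%02d", seq_len(n)), sprintf("AA%02d", seq_len(n)))
}

sowing_densities <- function(n) {
  rep_len(rep(c("low", "medium", "high"), length.out = 3L * ceiling(n / 3)), n)
}

#' Generate the plant census series and latent compositional axes
#'
#' Emulates the qualitative community dynamics of a long-running invasion
#' experiment: species composition slowly concentrates (gradual diversity
#' decline), invading species appear at the onset year and ramp up (a
#' diversity jump and a growing invader biomass share, stronger on the
#' abandoned arable soil), while total productivity stays year-stationary
#' apart from a noisier establishment year.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return list with `plants` (long table: mesocosm_id, soil,
#'   sowing_density, year, species_id, invader_flag, biomass_g) and `axes`
#'   (mesocosm_id, year, axis1..axis3).
#' @export
generate_plant_series <- function(config, seed = NULL) {
  cfg <- config
  seed <- seed %||% cfg$seed
  with_seed(seed, {
    years <- cfg$years
    t0 <- match(cfg$invasion_onset_year, years)
    n <- cfg$n_mesocosms_per_soil
    ids <- mesocosm_ids(cfg)
    soils <- rep(soil_names(), each = n)
    dens <- rep(sowing_densities(n), 2L)
    S <- cfg$n_sown_species; V <- cfg$n_invader_species
    sown <- sprintf("sp%02d", seq_len(S))
    inv <- if (V) sprintf("inv%02d", seq_len(V)) else character(0)
    plants <- vector("list", length(ids))
    axes <- vector("list", length(ids))
    for (m in seq_along(ids)) {
      base <- -0.35 * (seq_len(S) - 1) + rnorm(S, 0, 0.3)
      inv_w <- if (V) exp(-0.3 * (seq_len(V) - 1) + rnorm(V, 0, 0.3)) else numeric(0)
      mu_prod <- 400 * exp(rnorm(1, 0, 0.10)) *
        c(low = 0.9, medium = 1, high = 1.1)[[dens[m]]]
      inv_affinity <- exp(rnorm(1, 0, 0.35))  # mesocosm invasibility
      a_axis <- rnorm(3, 0, 0.8)
      rows <- vector("list", length(years))
      ax <- matrix(0, length(years), 3)
      for (t in seq_along(years)) {
        # composition concentrates over time: spread of log-weights grows
        lw <- (1 + 0.06 * (t - 1)) * base + rnorm(S, 0, 0.08)
        p_sown <- exp(lw) / sum(exp(lw))
        share <- if (t >= t0 && V > 0) {
          s <- 0.30 * inv_affinity * (1 - exp(-(t - t0 + 1) / 2)) *
            exp(rnorm(1, 0, 0.15))
          if (soils[m] == "abandoned_arable") s <- 1.3 * s
          min(0.9, s)
        } else 0
        total <- mu_prod * exp(rnorm(1, 0, 0.12))
        if (t == 1L) total <- total * exp(rnorm(1, -0.1, 0.3))
        biom <- c((1 - share) * p_sown,
                  if (V) share * inv_w / sum(inv_w)) * total
        rows[[t]] <- data.frame(
          mesocosm_id = ids[m], soil = soils[m], sowing_density = dens[m],
          year = years[t], species_id = c(sown, inv),
          invader_flag = c(rep(FALSE, S), rep(TRUE, V)),
          biomass_g = biom)
        ax[t, 1] <- a_axis[1] + 0.8 * (4 * share - 1) + rnorm(1, 0, 0.3)
        ax[t, 2] <- a_axis[2] + 0.05 * (t - t0) + rnorm(1, 0, 0.3)
        ax[t, 3] <- a_axis[3] + rnorm(1, 0, 0.3)
      }
      plants[[m]] <- do.call(rbind, rows)
      axes[[m]] <- data.frame(mesocosm_id = ids[m], year = years,
                              axis1 = ax[, 1], axis2 = ax[, 2],
                              axis3 = ax[, 3])
    }
    list(plants = do.call(rbind, plants), axes = do.call(rbind, axes))
  })
}

# standardized plant drivers at the sampling (final) year, one row per
# mesocosm: productivity, Shannon diversity, compositional axes 1-3
plant_drivers <- function(plants, axes, sampling_year) {
  d <- plants[plants$year == sampling_year, ]
  sp <- split(d, d$mesocosm_id)
  ids <- names(sp)
  X <- cbind(
    productivity = vapply(sp, function(x) sum(x$biomass_g), numeric(1)),
    diversity = vapply(sp, function(x) shannon_diversity(x$biomass_g),
                       numeric(1))
  )
  a <- axes[axes$year == sampling_year, ]
  a <- a[match(ids, a$mesocosm_id), ]
  X <- cbind(X, axis1 = a$axis1, axis2 = a$axis2, axis3 = a$axis3)
  rownames(X) <- ids
  scale(X)[, , drop = TRUE]
}

#' Generate OTU counts from cluster-level latent abundances
#'
#' Count model: per sample, each OTU's expected mass is its cluster's latent
#' mass times a fixed per-OTU weight, perturbed by log-normal noise of sd
#' `nb_dispersion`; counts are a multinomial draw of a negative-binomial
#' sequencing depth over the normalized masses, so sample totals equal the
#' drawn depths exactly while per-OTU counts are overdispersed.
#'
#' @param latent_cluster samples x clusters matrix of non-negative cluster
#'   masses (linear scale).
#' @param membership integer vector assigning each OTU to a cluster column.
#' @param otu_weight optional positive per-OTU weight within its cluster
#'   (default equal).
#' @param depth_mean,depth_dispersion negative-binomial depth model; depths
#'   are clamped to >= 1.
#' @param nb_dispersion log-normal overdispersion sd (0 = pure multinomial).
#' @param seed RNG seed.
#' @return integer count matrix (samples x OTUs) with the drawn depths as
#'   attribute `"depths"`.
#' @export
generate_otu_counts <- function(latent_cluster, membership,
                                otu_weight = NULL, depth_mean = 5000,
                                depth_dispersion = 10, nb_dispersion = 0.5,
                                seed = NULL) {
  if (any(!is.finite(latent_cluster)) || any(latent_cluster < 0))
    stop_data("latent cluster masses must be finite and non-negative")
  n <- nrow(latent_cluster)
  p <- length(membership)
  otu_weight <- otu_weight %||% rep(1, p)
  if (any(otu_weight < 0)) stop_data("otu weights must be non-negative")
  with_seed(seed, {
    depths <- pmax(1L, rnbinom(n, mu = depth_mean, size = depth_dispersion))
    counts <- matrix(0L, n, p)
    for (i in seq_len(n)) {
      w <- latent_cluster[i, membership] * otu_weight
      if (nb_dispersion > 0) w <- w * exp(rnorm(p, 0, nb_dispersion))
      if (sum(w) <= 0) stop_data("zero total mass in a sample")
      counts[i, ] <- rmultinom(1, depths[i], w / sum(w))
    }
    rownames(counts) <- rownames(latent_cluster)
    structure(counts, depths = depths)
  })
}

# latent cluster factors with planted prokaryote-fungal coupling: cluster k
# of both domains shares a latent factor with correlation rho (per soil)
coupled_factors <- function(n, K_shared, K_prok, K_fung, rho) {
  U <- matrix(rnorm(n * K_shared), n, K_shared)
  Vp <- matrix(rnorm(n * K_prok), n, K_prok)
  Vf <- matrix(rnorm(n * K_fung), n, K_fung)
  fp <- Vp; ff <- Vf
  fp[, seq_len(K_shared)] <- U
  ff[, seq_len(K_shared)] <- rho * U +
    sqrt(1 - rho^2) * Vf[, seq_len(K_shared)]
  list(prok = fp, fungal = ff)
}

#' Generate a full synthetic mesocosm dataset
#'
#' Produces the pipeline's standard inputs plus the planted ground truth:
#' plant census table, latent compositional axes, soil chemistry generated
#' from the plant drivers through the configured path coefficients,
#' per-domain OTU tables with planted cluster blocks, habitat specialists
#' and per-soil prokaryote-fungal coupling, and a truth object for recovery
#' tests.
#'
#' @param config a [synthetic_config()].
#' @param seed RNG seed (default `config$seed`); identical config and seed
#'   reproduce identical output.
#' @return list with `plants`, `axes`, `chemistry`, `prok_table`,
#'   `fungal_table` ([otu_table]s over all mesocosms, habitat = soil) and
#'   `truth` (cluster labels, specialist flags, per-soil coupling rho, path
#'   coefficient matrices, latent axes, plant drivers).
#' @export
generate_dataset <- function(config, seed = NULL) {
  cfg <- config
  if (!inherits(cfg, "synthetic_config"))
    stop_config("`config` must be a synthetic_config")
  seed <- seed %||% cfg$seed
  ps <- generate_plant_series(cfg, seed = derive_seed(seed, "plants"))
  sampling_year <- max(cfg$years)
  X <- plant_drivers(ps$plants, ps$axes, sampling_year)

  with_seed(derive_seed(seed, "soil_microbes"), {
    ids <- rownames(X)
    n_tot <- length(ids)
    soils <- ps$plants$soil[match(ids, ps$plants$mesocosm_id)]
    # soil chemistry: standardized drivers -> chem + noise, shifted into
    # plausible ranges (affine, so downstream standardized fits are
    # unaffected)
    B <- cfg$path_coefficients$plant_chem
    chem_z <- X %*% B + cfg$noise_sd *
      matrix(rnorm(n_tot * 8), n_tot, 8)
    colnames(chem_z) <- chem_names()
    offs <- c(total_N = 2, organic_C = 25, pH = 6.2, avail_P = 12,
              NO3 = 8, NH4 = 3, NO2 = 0.4, belowground_prod = 150)
    scl <- c(total_N = 0.4, organic_C = 4, pH = 0.4, avail_P = 3,
             NO3 = 2, NH4 = 0.8, NO2 = 0.1, belowground_prod = 30)
    chemistry <- data.frame(mesocosm_id = ids, soil = soils,
                            sweep(sweep(chem_z, 2, scl, "*"), 2, offs, "+"),
                            row.names = NULL, check.names = FALSE)

    K_shared <- min(cfg$n_prok_clusters, cfg$n_fungal_clusters)
    CM <- cfg$path_coefficients$chem_microbe
    PM <- cfg$path_coefficients$plant_microbe

    build_domain <- function(n_otus, n_clusters, factors, prefix) {
      membership <- rep(seq_len(n_clusters), length.out = n_otus)
      membership <- sort(membership)
      base <- -0.7 * (seq_len(n_clusters) - 1)
      eta <- matrix(rep(base, each = n_tot), n_tot, n_clusters)
      eta <- eta + cfg$cluster_signal_sd * factors
      ksh <- seq_len(min(n_clusters, ncol(CM)))
      eta[, ksh] <- eta[, ksh] + chem_z %*% CM[, ksh, drop = FALSE] +
        X %*% PM[, ksh, drop = FALSE]
      eta <- eta + cfg$noise_sd * matrix(rnorm(n_tot * n_clusters),
                                         n_tot, n_clusters)
      otu_w <- exp(rnorm(n_otus, 0, 0.5))
      n_spec <- round(cfg$specialist_fraction * n_otus)
      spec <- rep(FALSE, n_otus)
      if (n_spec > 0) spec[sample.int(n_otus, n_spec)] <- TRUE
      pref <- ifelse(runif(n_otus) < 0.5, soil_names()[1], soil_names()[2])
      # specialists: expected abundance ratio fold_change between soils
      half <- log(cfg$specialist_fold_change) / 2
      soil_eff <- matrix(0, n_tot, n_otus)
      for (o in which(spec)) {
        soil_eff[, o] <- ifelse(soils == pref[o], half, -half)
      }
      mass <- sweep(exp(eta[, membership, drop = FALSE] + soil_eff),
                    2L, otu_w, "*")
      counts <- generate_otu_counts(
        mass, membership = seq_len(ncol(mass)),
        depth_mean = cfg$depth_mean, depth_dispersion = cfg$depth_dispersion,
        nb_dispersion = cfg$nb_dispersion)
      otu_ids <- sprintf("%s%03d", prefix, seq_len(n_otus))
      counts <- matrix(as.numeric(counts), nrow(counts), ncol(counts),
                       dimnames = list(ids, otu_ids))
      list(counts = counts,
           membership = setNames(membership, otu_ids),
           specialist = setNames(spec, otu_ids),
           preferred_soil = setNames(pref, otu_ids))
    }

    fs <- list(prok = matrix(0, n_tot, cfg$n_prok_clusters),
               fung = matrix(0, n_tot, cfg$n_fungal_clusters))
    for (s in soil_names()) {
      rows <- which(soils == s)
      cf <- coupled_factors(length(rows), K_shared, cfg$n_prok_clusters,
                            cfg$n_fungal_clusters,
                            cfg$coupling_rho_per_soil[[s]])
      fs$prok[rows, ] <- cf$prok
      fs$fung[rows, ] <- cf$fungal
    }
    prok <- build_domain(cfg$n_prok_otus, cfg$n_prok_clusters, fs$prok, "p")
    fung <- build_domain(cfg$n_fungal_otus, cfg$n_fungal_clusters, fs$fung,
                         "f")

    truth <- list(
      prok_cluster = prok$membership,
      fungal_cluster = fung$membership,
      prok_specialist = prok$specialist,
      fungal_specialist = fung$specialist,
      prok_preferred_soil = prok$preferred_soil,
      fungal_preferred_soil = fung$preferred_soil,
      coupling_rho_per_soil = cfg$coupling_rho_per_soil,
      path_coefficients = cfg$path_coefficients,
      axes = ps$axes,
      plant_drivers = X,
      chem_z = chem_z
    )
    list(plants = ps$plants, axes = ps$axes, chemistry = chemistry,
         prok_table = otu_table(prok$counts, habitat = soils,
                                domain = "prokaryote"),
         fungal_table = otu_table(fung$counts, habitat = soils,
                                  domain = "fungal"),
         truth = truth)
  })
}

#' Write a synthetic dataset in the pipeline's input formats
#'
#' @param dataset result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_synthetic_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    plants = file.path(dir, "plant_biomass.csv"),
    axes = file.path(dir, "compositional_axes.csv"),
    chemistry = file.path(dir, "soil_chemistry.csv"),
    prok = file.path(dir, "otu_prokaryote.tsv"),
    fungal = file.path(dir, "otu_fungal.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write.csv(dataset$plants, paths[["plants"]], row.names = FALSE)
  write.csv(dataset$axes, paths[["axes"]], row.names = FALSE)
  write.csv(dataset$chemistry, paths[["chemistry"]], row.names = FALSE)
  write_otu_table(dataset$prok_table, paths[["prok"]])
  write_otu_table(dataset$fungal_table, paths[["fungal"]])
  tr <- dataset$truth
  tr$plant_drivers <- as.data.frame(tr$plant_drivers)
  tr$chem_z <- NULL
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
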