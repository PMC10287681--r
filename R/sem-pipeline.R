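# Variable inventory conventions for the path models. Plant parameters come
# in four groups crossed from timing (year of sampling vs past) and axis
# (overall community vs compositional):
#   year.overall:        productivity_sampling, diversity_sampling
#   year.compositional:  axis1_sampling .. axis3_sampling
#   past.overall:        productivity_impact/_trajectory,
#                        diversity_impact/_trajectory
#   past.compositional:  axis1..3_impact, axis1..3_trajectory
default_plant_roles <- function(vars) {
  timing <- ifelse(grepl("_sampling$", vars), "year", "past")
  axis <- ifelse(grepl("^axis", vars), "compositional", "overall")
  data.frame(variable = vars, timing = timing, axis = axis)
}

plant_group <- function(roles, var, kind) {
  i <- match(var, roles$variable)
  paste(roles$timing[i], roles$axis[i], kind, sep = ".")
}

#' Build and run the per-soil piecewise path models
#'
#' Reproduces the two-stage model building scheme: three base models per
#' soil capture the plant community's effect on the soil chemical mediators
#' — (a) year-of-sampling parameters, (b) overall past parameters
#' (invasion impacts and trajectories of productivity and diversity), and
#' (c) compositional past parameters (axis impacts and trajectories) — each
#' simplified by AICc backward elimination. The retained plant-to-chemistry
#' edges are merged (union) into a combined base, and one final model is
#' fit per microbial variable, adding candidate direct plant-to-microbe
#' edges and chemistry-to-microbe edges before a final elimination. One
#' fitted model per microbial variable is returned, so the model count
#' equals the number of microbial variables.
#'
#' @param data data.frame with one row per mesocosm of one soil: plant
#'   parameters, chemical mediators, microbial variables and the grouping
#'   column.
#' @param plant_vars plant parameter column names (roles inferred from the
#'   naming convention unless `var_roles` is given).
#' @param chem_vars chemical mediator column names (canonically total N,
#'   organic C, pH, available P, NO3, NH4, NO2 and belowground
#'   productivity).
#' @param microbe_vars microbial variable column names (cluster abundances,
#'   biomass pools, alpha diversity, mean SI, ...).
#' @param grouping random-intercept column (default `"sowing_density"`).
#' @param var_roles optional override of [default_plant_roles()].
#' @param transform response transform policy.
#' @param dsep whether to run the d-separation test on each final model
#'   (see [backward_eliminate()]); base-model fits never need it.
#' @return list of `fitted_path_model`s, one per microbial variable, each
#'   with the pathway-group tags needed by [relative_contributions()].
#' @export
build_and_run_sems <- function(data, plant_vars, chem_vars, microbe_vars,
                               grouping = "sowing_density",
                               var_roles = NULL, transform = "auto",
                               dsep = TRUE) {
  miss <- setdiff(c(plant_vars, chem_vars, microbe_vars, grouping),
                  names(data))
  if (length(miss)) stop_data(paste("data missing variable(s):",
                                    paste(miss, collapse = ", ")))
  roles <- var_roles %||% default_plant_roles(plant_vars)

  base_groups <- list(
    year = roles$variable[roles$timing == "year"],
    past_overall = roles$variable[roles$timing == "past" &
                                    roles$axis == "overall"],
    past_compositional = roles$variable[roles$timing == "past" &
                                          roles$axis == "compositional"]
  )
  base_groups <- Filter(length, base_groups)

  plant_chem_edges <- function(pv) {
    expand.grid(from = pv, to = chem_vars, stringsAsFactors = FALSE)
  }
  base_retained <- lapply(base_groups, function(pv) {
    spec <- path_spec(plant_chem_edges(pv), grouping = grouping,
                      var_roles = roles)
    fit <- backward_eliminate(spec, data, transform = transform,
                              dsep = FALSE)
    fit$edges[, c("from", "to"), drop = FALSE]
  })
  combined_base <- unique(do.call(rbind, base_retained))

  lapply(setNames(microbe_vars, microbe_vars), function(m) {
    direct <- data.frame(from = roles$variable, to = m,
                         group = paste(roles$timing, roles$axis, "direct",
                                       sep = "."))
    mediated <- data.frame(from = chem_vars, to = m,
                           group = "chem.microbe")
    base <- combined_base
    if (nrow(base)) {
      base$group <- vapply(base$from, function(v)
        plant_group(roles, v, "indirect"), character(1))
    } else {
      base$group <- character(0)
    }
    spec <- path_spec(rbind(base, direct, mediated), grouping = grouping,
                      var_roles = roles)
    fit <- backward_eliminate(spec, data, transform = transform, dsep = dsep)
    fit$microbe_var <- m
    fit$var_roles <- roles
    fit$chem_vars <- chem_vars
    fit
  })
}

#' Microbial variable inventory for one soil's path models
#'
#' One path model is fit per microbial variable, so the model count equals
#' the inventory length. The canonical full-study inventory — per soil, 3
#' microbial biomass pools plus one variable per prokaryote and per fungal
#' network cluster (9 + 21 for one soil, 10 + 18 for the other) — gives
#' 33 + 31 = 64 models.
#'
#' @param n_biomass_pools number of microbial biomass pools.
#' @param n_prok_clusters,n_fungal_clusters network cluster counts.
#' @return character vector of microbial variable names.
#' @export
sem_microbe_inventory <- function(n_biomass_pools, n_prok_clusters,
                                  n_fungal_clusters) {
  c(if (n_biomass_pools) paste0("biomass", seq_len(n_biomass_pools)),
    if (n_prok_clusters) paste0("prok_cluster", seq_len(n_prok_clusters)),
    if (n_fungal_clusters) paste0("fung_cluster", seq_len(n_fungal_clusters)))
}

contribution_groups <- function() {
  as.vector(outer(c("year", "past"),
                  outer(c("overall", "compositional"),
                        c("direct", "indirect"), paste, sep = "."),
                  paste, sep = "."))
}

#' Grouped relative contributions of plant parameters to microbial change
#'
#' For every fitted path model (one per microbial variable), takes each
#' retained significant pathway (p < `alpha`): a direct plant-to-microbe
#' pathway contributes |beta| times the relative size of the microbial pool
#' or cluster it affects; an indirect pathway (plant to chemical mediator to
#' microbe, both edges retained and significant) contributes
#' |beta_plant_chem * beta_chem_microbe| times the same size. Contributions
#' are summed per pathway group — all combinations of year vs past, overall
#' vs compositional and direct vs indirect — and scaled by the number of
#' candidate (pre-elimination) pathways in the group, so groups with many
#' potential pathways are directly comparable to small ones.
#'
#' @param models list of `fitted_path_model`s from [build_and_run_sems()].
#' @param sizes named numeric vector in (0, 1]: relative size of each
#'   microbial variable (mean relative cluster abundance, or biomass pool
#'   share).
#' @param alpha significance cutoff for a pathway to contribute.
#' @return a `contribution_ledger` data.frame: group, raw (summed weighted
#'   contribution), n_potential (candidate pathways), scaled (raw /
#'   n_potential).
#' @export
relative_contributions <- function(models, sizes, alpha = 0.05) {
  groups <- contribution_groups()
  raw <- setNames(numeric(length(groups)), groups)
  pot <- setNames(numeric(length(groups)), groups)
  for (m in models) {
    mv <- m$microbe_var
    if (is.na(match(mv, names(sizes))))
      stop_data(sprintf("no size weight for microbial variable '%s'", mv))
    size <- sizes[[mv]]
    if (!is.finite(size) || size <= 0 || size > 1)
      stop_data(sprintf("size weight for '%s' must be in (0, 1]", mv))
    roles <- m$var_roles
    cand <- m$candidates
    # potential pathways per group, from the pre-elimination candidate set:
    # direct plant->microbe edges count as-is; indirect candidates are
    # plant->chem candidates composed with every chem->microbe candidate
    direct_cand <- cand[cand$to == mv & cand$from %in% roles$variable, ]
    for (v in direct_cand$from) {
      g <- plant_group(roles, v, "direct")
      pot[g] <- pot[g] + 1
    }
    chem_cand <- cand$from[cand$to == mv & cand$from %in% m$chem_vars]
    pc_cand <- cand[cand$to %in% m$chem_vars & cand$from %in% roles$variable, ]
    for (r in seq_len(nrow(pc_cand))) {
      g <- plant_group(roles, pc_cand$from[r], "indirect")
      pot[g] <- pot[g] + length(chem_cand)
    }
    ed <- m$edges
    if (!nrow(ed)) next
    sig <- ed[ed$p < alpha, , drop = FALSE]
    # direct pathways
    dsig <- sig[sig$to == mv & sig$from %in% roles$variable, , drop = FALSE]
    for (r in seq_len(nrow(dsig))) {
      g <- plant_group(roles, dsig$from[r], "direct")
      raw[g] <- raw[g] + abs(dsig$estimate[r]) * size
    }
    # indirect pathways: significant plant->chem composed with significant
    # chem->microbe sharing the mediator
    cm <- sig[sig$to == mv & sig$from %in% m$chem_vars, , drop = FALSE]
    pc <- sig[sig$to %in% m$chem_vars & sig$from %in% roles$variable, ,
              drop = FALSE]
    for (r in seq_len(nrow(pc))) {
      hit <- cm[cm$from == pc$to[r], , drop = FALSE]
      for (q in seq_len(nrow(hit))) {
        g <- plant_group(roles, pc$from[r], "indirect")
        raw[g] <- raw[g] + abs(pc$estimate[r] * hit$estimate[q]) * size
      }
    }
  }
  out <- data.frame(group = groups, raw = as.numeric(raw),
                    n_potential = as.numeric(pot),
                    scaled = ifelse(pot > 0, raw / pot, 0))
  class(out) <- c("contribution_ledger", class(out))
  out
}

#' Write a contribution ledger to TSV
#' @param ledger a `contribution_ledger`.
#' @param path output path.
#' @param min_scaled optional report filter: drop groups whose scaled value
#'   is below this share of the scaled total (default 0, keep all).
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path, min_scaled = 0) {
  d <- as.data.frame(ledger)
  if (min_scaled > 0) {
    tot <- sum(d$scaled)
    if (tot > 0) d <- d[d$scaled / tot >= min_scaled, , drop = FALSE]
  }
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write one fitted path model as a JSON report
#' @param model a `fitted_path_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(model, path) {
  jsonlite::write_json(list(
    microbe_var = model$microbe_var %||% NA,
    edges = model$edges,
    fisher_c = model$fisher_c,
    aicc = model$aicc,
    n = model$n,
    history = model$history
  ), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
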