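#' Shannon diversity of a biomass vector
#'
#' H = -sum p_s ln p_s over species with positive biomass, with p_s the
#' biomass share. Natural log, so H is in nats and bounded by ln(S).
#'
#' @param biomass non-negative biomass per species.
#' @return Shannon H (nats).
#' @export
shannon_diversity <- function(biomass) {
  if (any(!is.finite(biomass)) || any(biomass < 0))
    stop_data("biomass must be finite and non-negative")
  if (sum(biomass) <= 0) stop_data("all-zero biomass vector")
  as.numeric(vegan::diversity(matrix(biomass, nrow = 1), index = "shannon"))
}

#' Temporal stability of productivity (inverse coefficient of variation)
#'
#' Stability = mu / sigma of total aboveground productivity across years,
#' with sigma the sample (n-1) standard deviation. The first census year can
#' be dropped because establishing communities fluctuate disproportionately.
#'
#' @param productivity productivity per year (g dry weight).
#' @param years optional census years (used only to report the included
#'   range; series order is taken as given).
#' @param drop_first_year drop the first census year before computing.
#' @return a list with `mesocosm_id` (NA unless supplied), `stability`,
#'   `mu`, `sigma`, and `years_included`.
#' @export
temporal_stability <- function(productivity, years = NULL,
                               drop_first_year = TRUE) {
  years <- years %||% seq_along(productivity)
  if (drop_first_year) {
    productivity <- productivity[-1L]
    years <- years[-1L]
  }
  if (length(productivity) < 3L)
    stop_data("need at least 3 included years for temporal stability")
  if (any(productivity < 0)) stop_data("productivity must be non-negative")
  mu <- mean(productivity)
  if (mu <= 0) stop_data("mean productivity must be positive")
  sigma <- sd(productivity)
  if (sigma == 0)
    stop_degenerate("constant productivity series has undefined stability")
  list(stability = mu / sigma, mu = mu, sigma = sigma,
       years_included = range(years))
}

#' Initial invasion impact on a plant parameter
#'
#' Difference between the parameter's value in the first year with invasion
#' and the last year without. Diversity reacts to invasion over two seasons,
#' so its default post year is one later than for the other parameters.
#'
#' @param values parameter value per year.
#' @param years census years matching `values`.
#' @param pre_year last year without invasion (default 2011).
#' @param post_year first year reflecting invasion (default 2012; use 2013
#'   for Shannon diversity).
#' @return `values[post_year] - values[pre_year]`.
#' @export
invasion_impact <- function(values, years, pre_year = 2011, post_year = 2012) {
  for (y in c(pre_year, post_year)) {
    if (!y %in% years) stop_data(sprintf("year %s missing from series", y))
  }
  values[match(post_year, years)] - values[match(pre_year, years)]
}

#' Developmental trajectory (standardized slope) of a plant parameter
#'
#' Standardized regression slope of the parameter on (centered, numeric)
#' year, which equals the Pearson correlation between value and year; in
#' [-1, 1]. Years outside `year_range` are excluded first.
#'
#' @param values parameter value per year.
#' @param years census years.
#' @param year_range inclusive `c(from, to)` filter (default 2012-2019, the
#'   post-invasion window).
#' @return standardized slope (unitless).
#' @export
trajectory_beta <- function(values, years, year_range = c(2012, 2019)) {
  keep <- years >= year_range[1] & years <= year_range[2]
  values <- values[keep]; years <- as.numeric(years[keep])
  if (length(values) < 3L) stop_data("need >= 3 years inside year_range")
  if (sd(values) == 0) stop_degenerate("parameter series has zero variance")
  yr <- years - mean(years)
  b <- sum(yr * (values - mean(values))) / sum(yr^2)
  as.numeric(b * sd(years) / sd(values))
}

#' Invader biomass proportion in one mesocosm-year
#' @param biomass biomass per species record.
#' @param invader_flag logical, TRUE for species invading from outside the
#'   sown pool.
#' @return invader share of total biomass, in [0, 1].
#' @export
invader_proportion <- function(biomass, invader_flag) {
  tot <- sum(biomass)
  if (tot <= 0) stop_data("zero total biomass")
  sum(biomass[as.logical(invader_flag)]) / tot
}

#' Per-mesocosm plant community metrics
#'
#' Collapses a long plant biomass table (one row per mesocosm x year x
#' species) into per-mesocosm-year series (productivity, Shannon diversity,
#' invader proportion) and per-mesocosm summaries: temporal stability,
#' year-of-sampling values, and the two "past" parameter families (initial
#' invasion impact and post-invasion developmental trajectory) for
#' productivity, diversity and the compositional axes.
#'
#' @param plants data.frame with columns `mesocosm_id`, `soil`,
#'   `sowing_density`, `year`, `species_id`, `invader_flag`, `biomass_g`.
#' @param axes optional data.frame of compositional axis scores with columns
#'   `mesocosm_id`, `year`, `axis1`, `axis2`, `axis3`.
#' @param invasion_onset_year first year with natural invasion.
#' @param sampling_year year whose values are reported as "year of sampling"
#'   (default: last census year).
#' @param drop_first_year passed to [temporal_stability()].
#' @return a list with `by_year` (mesocosm x year series) and `by_mesocosm`
#'   (stability, year-of-sampling and past parameters).
#' @export
plant_metrics <- function(plants, axes = NULL, invasion_onset_year = 2012,
                          sampling_year = NULL, drop_first_year = TRUE) {
  need <- c("mesocosm_id", "soil", "sowing_density", "year", "species_id",
            "invader_flag", "biomass_g")
  miss <- setdiff(need, names(plants))
  if (length(miss)) stop_data(paste("plant table missing column(s):",
                                    paste(miss, collapse = ", ")))
  sampling_year <- sampling_year %||% max(plants$year)

  key <- interaction(plants$mesocosm_id, plants$year, drop = TRUE)
  rows <- split(seq_len(nrow(plants)), key)
  by_year <- do.call(rbind, lapply(rows, function(i) {
    d <- plants[i, ]
    data.frame(
      mesocosm_id = d$mesocosm_id[1], soil = d$soil[1],
      sowing_density = d$sowing_density[1], year = d$year[1],
      productivity = sum(d$biomass_g),
      shannon = shannon_diversity(d$biomass_g),
      invader_prop = invader_proportion(d$biomass_g, d$invader_flag)
    )
  }))
  by_year <- by_year[order(by_year$mesocosm_id, by_year$year), ]
  rownames(by_year) <- NULL
  if (!is.null(axes)) {
    by_year <- merge(by_year, axes, by = c("mesocosm_id", "year"),
                     all.x = TRUE, sort = FALSE)
    by_year <- by_year[order(by_year$mesocosm_id, by_year$year), ]
  }

  params <- c(productivity = "productivity", diversity = "shannon")
  if (!is.null(axes)) params <- c(params, axis1 = "axis1", axis2 = "axis2",
                                  axis3 = "axis3")

  by_mesocosm <- do.call(rbind, lapply(split(by_year, by_year$mesocosm_id),
                                       function(d) {
    d <- d[order(d$year), ]
    st <- temporal_stability(d$productivity, d$year,
                             drop_first_year = drop_first_year)
    out <- data.frame(
      mesocosm_id = d$mesocosm_id[1], soil = d$soil[1],
      sowing_density = d$sowing_density[1],
      stability = st$stability,
      invader_prop_sampling = d$invader_prop[d$year == sampling_year]
    )
    for (p in names(params)) {
      v <- d[[params[[p]]]]
      # diversity's invasion response spans two seasons
      post <- if (p == "diversity") invasion_onset_year + 1L else invasion_onset_year
      out[[paste0(p, "_sampling")]] <- v[d$year == sampling_year]
      out[[paste0(p, "_impact")]] <-
        invasion_impact(v, d$year, pre_year = invasion_onset_year - 1L,
                        post_year = post)
      out[[paste0(p, "_trajectory")]] <-
        trajectory_beta(v, d$year, year_range = c(invasion_onset_year,
                                                  max(d$year)))
    }
    out
  }))
  rownames(by_mesocosm) <- NULL
  list(by_year = by_year, by_mesocosm = by_mesocosm)
}
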