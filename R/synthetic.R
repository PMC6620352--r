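#' Configuration for the synthetic forest-census generator
#'
#' Defines the statistical structure of a generated census + trait table:
#' a species-abundance distribution (log-series by default, with Fisher's
#' alpha solved from the species and stem counts unless given; or a
#' lognormal), a right-skewed truncated power-law diameter distribution on
#' `[min_dbh, dbh_max]`, per-species multi-label disperser-group assignment
#' by independent inclusion probabilities (redrawn if empty), and
#' species-level wood specific gravity drawn from a truncated normal whose
#' mean is shifted by `delta` for LBF-dispersed species. `delta = 0` gives
#' the null community (no trait--disperser association); the defaults echo
#' a 30-ha seasonal-evergreen plot census (232 species, 33,844 stems >= 5
#' cm) with a modest positive WSG shift for LBF-dispersed species, but are
#' not calibrated to reproduce any particular plot's numbers.
#'
#' @param n_species,n_stems Community dimensions (every species gets at
#'   least one stem, so `n_stems >= n_species`).
#' @param abundance_model `"log_series"` or `"lognormal"`.
#' @param alpha Fisher's alpha for the log-series; `NULL` solves it from
#'   `n_species = alpha * log(1 + n_stems/alpha)`.
#' @param meanlog,sdlog Lognormal abundance parameters.
#' @param dbh_exponent,dbh_max Power-law exponent (density ~ D^-a) and
#'   upper truncation (cm) of the diameter distribution.
#' @param min_dbh Lower diameter truncation, cm.
#' @param p_group Named inclusion probabilities over the eight disperser
#'   groups (see [dispersal_group_codes()]).
#' @param mu_other,delta,sigma Wood-specific-gravity model: species-level
#'   draws from Normal(`mu_other + delta * is_lbf`, `sigma`) truncated to
#'   `wsg_bounds` (g/cm^3).
#' @param wsg_bounds Truncation bounds of the WSG distribution.
#' @param coords Also generate uniform x/y coordinates on a plot of
#'   `plot_area_ha` hectares (square).
#' @param plot_area_ha Plot area, hectares.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_species = 232, n_stems = 33844,
                         abundance_model = c("log_series", "lognormal"),
                         alpha = NULL, meanlog = 3, sdlog = 1.5,
                         dbh_exponent = 2, dbh_max = 150, min_dbh = 5,
                         p_group = c(gibbon = 0.08, macaque = 0.06,
                                     hornbills_large_pigeons = 0.08,
                                     smaller_birds = 0.60,
                                     terrestrial_mammals = 0.07,
                                     unknown_animals = 0.10,
                                     unclassified = 0.15, wind = 0.12),
                         mu_other = 0.55, delta = 0.06, sigma = 0.12,
                         wsg_bounds = c(0.1, 1.2), coords = FALSE,
                         plot_area_ha = 30) {
  abundance_model <- match.arg(abundance_model)
  stopifnot(n_species >= 1, n_stems >= n_species,
            dbh_max > min_dbh, min_dbh > 0, sigma > 0,
            all(p_group >= 0), all(p_group <= 1), sum(p_group) > 0,
            length(wsg_bounds) == 2, wsg_bounds[1] < wsg_bounds[2])
  missing_groups <- setdiff(dispersal_group_codes(), names(p_group))
  if (length(missing_groups)) {
    stop("p_group missing group(s): ", paste(missing_groups, collapse = ", "),
         call. = FALSE)
  }
  structure(list(n_species = n_species, n_stems = n_stems,
                 abundance_model = abundance_model, alpha = alpha,
                 meanlog = meanlog, sdlog = sdlog,
                 dbh_exponent = dbh_exponent, dbh_max = dbh_max,
                 min_dbh = min_dbh,
                 p_group = p_group[dispersal_group_codes()],
                 mu_other = mu_other, delta = delta, sigma = sigma,
                 wsg_bounds = wsg_bounds, coords = coords,
                 plot_area_ha = plot_area_ha),
            class = "synth_config")
}

# Fisher's alpha from S = alpha * log(1 + N/alpha).
fisher_alpha <- function(n_species, n_stems) {
  stats::uniroot(function(a) a * log(1 + n_stems / a) - n_species,
                 interval = c(1e-3, n_stems), tol = 1e-9)$root
}

# Species abundance weights under the configured model.
abundance_weights <- function(config) {
  if (config$abundance_model == "log_series") {
    alpha <- if (is.null(config$alpha))
      fisher_alpha(config$n_species, config$n_stems) else config$alpha
    x <- config$n_stems / (config$n_stems + alpha)
    k <- seq_len(config$n_stems)
    # log-series pmf ~ x^k / k; draw one abundance weight per species
    logp <- k * log(x) - log(k)
    p <- exp(logp - max(logp))
    k[sample.int(length(k), config$n_species, replace = TRUE, prob = p)]
  } else {
    stats::rlnorm(config$n_species, config$meanlog, config$sdlog)
  }
}

# Inverse-CDF draw from a power-law density ~ D^-a truncated to [lo, hi].
rtrunc_powerlaw <- function(n, a, lo, hi) {
  u <- stats::runif(n)
  if (abs(a - 1) < 1e-12) {
    lo * (hi / lo)^u
  } else {
    (lo^(1 - a) + u * (hi^(1 - a) - lo^(1 - a)))^(1 / (1 - a))
  }
}

# Truncated-normal draws by inverse CDF.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic census and trait table
#'
#' Draws a community under a [synth_config()]: species abundances from the
#' configured species-abundance distribution (each species guaranteed at
#' least one stem, stem total exact), stem diameters from the truncated
#' power law, disperser groups by per-group Bernoulli inclusion (redrawn
#' when empty), and species-level wood specific gravity from the truncated
#' normal with the configured LBF shift. Fully reproducible from `seed`.
#'
#' @param config A [synth_config()].
#' @param seed Integer seed.
#' @return List with `trees` (census data frame) and `traits` (trait table
#'   with `wsg_source = "field_sample"` since values are generated, not
#'   database lookups).
#' @export
generate_community <- function(config = synth_config(), seed = 1) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(stream_seed(seed, "synth"))
  ns <- config$n_species
  sp_codes <- sprintf("SP%03d", seq_len(ns))

  w <- abundance_weights(config)
  extra <- stats::rmultinom(1, config$n_stems - ns, prob = w / sum(w))[, 1]
  counts <- extra + 1L

  # disperser groups: independent inclusion, redraw on empty
  p <- config$p_group
  groups <- lapply(seq_len(ns), function(i) {
    repeat {
      inc <- stats::runif(length(p)) < p
      if (any(inc)) return(names(p)[inc])
    }
  })
  lbf <- vapply(groups, function(g) any(g %in% lbf_groups()), logical(1))

  wsg <- rtrunc_norm(ns, config$mu_other + config$delta * lbf, config$sigma,
                     config$wsg_bounds[1], config$wsg_bounds[2])

  genus <- sprintf("Genus%02d", 1 + (seq_len(ns) - 1) %% 40)
  family <- sprintf("Family%02d", 1 + (seq_len(ns) - 1) %% 15)
  traits <- data.frame(species = sp_codes, genus = genus, family = family,
                       wsg = wsg, wsg_source = "field_sample",
                       stringsAsFactors = FALSE)
  traits$dispersal_groups <- groups

  species <- rep(sp_codes, counts)
  dbh <- rtrunc_powerlaw(config$n_stems, config$dbh_exponent,
                         config$min_dbh, config$dbh_max)
  trees <- data.frame(tag = sprintf("T%06d", seq_len(config$n_stems)),
                      species = species, dbh = dbh,
                      stringsAsFactors = FALSE)
  if (config$coords) {
    side <- sqrt(config$plot_area_ha * 1e4)
    trees$x <- stats::runif(config$n_stems, 0, side)
    trees$y <- stats::runif(config$n_stems, 0, side)
  }
  list(trees = trees, traits = traits)
}

#' Two-wood-density toy community
#'
#' The minimal community for which the simulation outcome has a closed
#' form: one LBF-dispersed (gibbon) species of `n_target` stems with wood
#' specific gravity `w_l`, one wind-dispersed species of `n_pool` stems
#' with `w_o`, all stems sharing a single diameter (one size class). Under
#' the density-swap option at intensity 1 every replicate changes AGC by
#' exactly `100 * n_target * (w_o - w_l) / (n_target * w_l + n_pool * w_o)`
#' percent, because the allometry is linear in density and the donor pool
#' is single-valued.
#'
#' @param n_target,n_pool Stem counts of the two species.
#' @param w_l,w_o Wood specific gravities (g/cm^3).
#' @param dbh Common stem diameter, cm.
#' @return List with `trees` and `traits` as in [generate_community()].
#' @export
two_wsg_toy <- function(n_target = 10, n_pool = 10, w_l = 0.8, w_o = 0.6,
                        dbh = 10) {
  stopifnot(n_target >= 1, n_pool >= 1, dbh >= 5)
  n <- n_target + n_pool
  trees <- data.frame(tag = sprintf("T%04d", seq_len(n)),
                      species = rep(c("LBF1", "WIND1"),
                                    c(n_target, n_pool)),
                      dbh = dbh, stringsAsFactors = FALSE)
  traits <- data.frame(species = c("LBF1", "WIND1"),
                       genus = c("GenL", "GenW"),
                       family = c("FamL", "FamW"),
                       wsg = c(w_l, w_o), wsg_source = "field_sample",
                       stringsAsFactors = FALSE)
  traits$dispersal_groups <- list("gibbon", "wind")
  list(trees = trees, traits = traits)
}
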