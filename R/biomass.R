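#' Per-stem above-ground biomass from diameter and wood density
#'
#' Moist-forest allometry for stems with dbh >= 5 cm:
#' \deqn{AGB = \rho \exp(-1.499 + 2.148 \ln D + 0.207 (\ln D)^2
#'   - 0.0281 (\ln D)^3)}
#' with \eqn{\rho} the wood specific gravity (g/cm^3) and \eqn{D} the dbh
#' (cm). The result is in kg per stem; it is exactly linear in \eqn{\rho}
#' and strictly increasing in \eqn{D} over the sizes that occur in closed
#' tropical forest (5--300 cm). Above-ground carbon is taken as half the
#' biomass.
#'
#' @param wsg Wood specific gravity, g/cm^3 (> 0). Recycled against `dbh`.
#' @param dbh Diameter at breast height, cm (>= 5 unless `allow_small`).
#' @param allow_small Permit dbh below the 5 cm analysis filter (the curve
#'   itself is defined there, but such stems are outside the analysis).
#' @return Numeric vector of per-stem AGB in kg (`agb_single`) or AGC in kg
#'   (`agc_single`).
#' @export
#' @examples
#' agb_single(1.0, 5)    # ~ 10.774 kg
#' agb_single(0.5, 5)    # half of that: linear in wood density
agb_single <- function(wsg, dbh, allow_small = FALSE) {
  stopifnot(is.numeric(wsg), is.numeric(dbh))
  if (any(wsg <= 0)) stop("wsg must be positive", call. = FALSE)
  if (!allow_small && any(dbh < 5)) {
    stop("dbh below the 5 cm analysis filter; set allow_small = TRUE to override",
         call. = FALSE)
  }
  if (any(dbh <= 0)) stop("dbh must be positive", call. = FALSE)
  wsg * agb_size_term(dbh)
}

# Size term of the allometry: AGB for rho = 1. Factored out so community
# totals can be updated under wood-density swaps without re-evaluating it.
agb_size_term <- function(dbh) {
  ld <- log(dbh)
  exp(-1.499 + 2.148 * ld + 0.207 * ld^2 - 0.0281 * ld^3)
}

#' @rdname agb_single
#' @export
agc_single <- function(wsg, dbh, allow_small = FALSE) {
  agb_single(wsg, dbh, allow_small = allow_small) / 2
}

#' Total above-ground carbon of a census
#'
#' Sums per-stem AGC over the census (after species resolution and wood
#' specific gravity imputation) and converts kg to Mg. The per-hectare
#' density uses the plot area from the caller.
#'
#' @param trees Census data frame (`tag, species, dbh`), already filtered to
#'   the analysis diameter range.
#' @param traits Traits data frame with complete `wsg` (see [impute_wsg()]).
#' @param plot_area_ha Plot area in hectares; default 30 (the standard large
#'   forest-dynamics plot size this analysis targets).
#' @return List with `total_mg` (Mg over the plot), `per_ha` (Mg/ha) and
#'   `n_stems`.
#' @export
total_agc <- function(trees, traits, plot_area_ha = 30) {
  stopifnot(plot_area_ha > 0)
  if (nrow(trees) == 0) {
    return(list(total_mg = 0, per_ha = 0, n_stems = 0L))
  }
  trees <- resolve_species(trees, traits, strict = TRUE)
  wsg <- traits$wsg[match(trees$species, traits$species)]
  if (anyNA(wsg)) {
    stop("missing wood specific gravity for: ",
         paste(unique(trees$species[is.na(wsg)]), collapse = ", "),
         call. = FALSE)
  }
  total_kg <- sum(agc_single(wsg, trees$dbh))
  list(total_mg = total_kg / 1000, per_ha = total_kg / 1000 / plot_area_ha,
       n_stems = nrow(trees))
}

#' Above-ground carbon shares by dispersal category
#'
#' Splits total AGC across the three dispersal categories (`P` primates,
#' `TB` large terrestrial mammals and birds, `O` others; see
#' [share_category()]). Percentages sum to 100 and the category totals sum
#' to the plot total (conservation).
#'
#' @inheritParams total_agc
#' @param primates Passed to [share_category()].
#' @return Data frame with one row per category: `category, agc_mg,
#'   share_pct`.
#' @export
agc_shares <- function(trees, traits, plot_area_ha = 30,
                       primates = c("any", "alone")) {
  primates <- match.arg(primates)
  trees <- resolve_species(trees, traits, strict = TRUE)
  idx <- match(trees$species, traits$species)
  wsg <- traits$wsg[idx]
  if (anyNA(wsg)) {
    stop("missing wood specific gravity for: ",
         paste(unique(trees$species[is.na(wsg)]), collapse = ", "),
         call. = FALSE)
  }
  cat <- share_category(traits, primates = primates)[idx]
  agc_kg <- agc_single(wsg, trees$dbh)
  by_cat <- vapply(levels(cat), function(lv) sum(agc_kg[cat == lv]),
                   numeric(1))
  total <- sum(by_cat)
  data.frame(category = factor(levels(cat), levels = levels(cat)),
             agc_mg = unname(by_cat) / 1000,
             share_pct = if (total > 0) unname(by_cat) / total * 100
                         else rep(0, length(by_cat)))
}

#' Impute missing wood specific gravity
#'
#' Fills missing per-species WSG using, in order of precedence:
#' a species-level match in a reference wood-density database
#' (`species_db`), an already-present field-sampled value in the trait table
#' (`field_sample`), the median of species-level reference values in the
#' same genus (`genus_median`), then the same family (`family_median`).
#' Provenance is recorded in `wsg_source` for every species. A species with
#' no value at any level is a fatal error listing the species.
#'
#' @param traits Traits data frame; rows with non-missing `wsg` and no
#'   reference match are treated as field samples.
#' @param reference Optional reference database: data frame with columns
#'   `species, genus, family, wsg` (species-level values, one or more rows
#'   per species; the global wood-density database layout).
#' @param use_mean Use the mean instead of the median for genus/family
#'   aggregation (the median is the default).
#' @return `traits` with `wsg` complete and `wsg_source` set.
#' @export
impute_wsg <- function(traits, reference = NULL, use_mean = FALSE) {
  agg <- if (use_mean) mean else stats::median
  out <- traits
  if (is.null(reference)) {
    reference <- data.frame(species = character(), genus = character(),
                            family = character(), wsg = numeric())
  }
  stopifnot(all(c("species", "genus", "family", "wsg") %in% names(reference)))
  # species-level reference value: aggregate over entries per species
  ref_sp <- tapply(reference$wsg, reference$species, agg)

  src <- out$wsg_source
  if (is.null(src)) src <- rep(NA_character_, nrow(out))
  for (i in seq_len(nrow(out))) {
    sp <- out$species[i]
    if (sp %in% names(ref_sp)) {
      out$wsg[i] <- unname(ref_sp[[sp]])
      src[i] <- "species_db"
    } else if (!is.na(out$wsg[i])) {
      src[i] <- "field_sample"
    } else {
      gvals <- reference$wsg[reference$genus == out$genus[i]]
      fvals <- reference$wsg[reference$family == out$family[i]]
      if (length(gvals)) {
        out$wsg[i] <- agg(gvals)
        src[i] <- "genus_median"
      } else if (length(fvals)) {
        out$wsg[i] <- agg(fvals)
        src[i] <- "family_median"
      }
    }
  }
  if (anyNA(out$wsg)) {
    stop("no wood specific gravity available at any level for: ",
         paste(out$species[is.na(out$wsg)], collapse = ", "), call. = FALSE)
  }
  out$wsg_source <- src
  out
}
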