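#' Diameter size classes
#'
#' Stems are stratified into four diameter classes, 5--20, 20--40, 40--80
#' and >80 cm, and all removal--replacement happens within a class so that
#' the community size structure is (approximately) conserved. Intervals are
#' half-open on the upper end: 20 cm falls in class 2, 80 cm in class 4.
#'
#' @param dbh Diameter at breast height, cm (>= the first break).
#' @param breaks Lower bounds of the classes, increasing; default
#'   `c(5, 20, 40, 80)`.
#' @return Integer class index (1--4 for the default breaks).
#' @export
#' @examples
#' assign_size_class(c(5, 19.999, 20, 80))  # 1 1 2 4
assign_size_class <- function(dbh, breaks = c(5, 20, 40, 80)) {
  stopifnot(is.numeric(dbh), length(breaks) >= 1, !is.unsorted(breaks))
  if (any(dbh < breaks[1])) {
    stop("dbh below the smallest size class (", breaks[1], " cm)",
         call. = FALSE)
  }
  findInterval(dbh, breaks)
}

#' Build the simulation community state
#'
#' Joins the census to the trait table and precomputes everything the
#' zero-sum simulation needs per stem: wood specific gravity, size class,
#' the density-free term of the biomass allometry, and the LBF / primate
#' dispersal flags. The stem count and the per-class counts of this state
#' are the quantities the zero-sum assumption holds fixed.
#'
#' @param trees Census data frame; stems below `min_dbh` are dropped via
#'   [filter_min_dbh()].
#' @param traits Traits data frame with complete `wsg`.
#' @param min_dbh Analysis diameter threshold, cm (default 5).
#' @param breaks Size-class lower bounds (default `c(5, 20, 40, 80)`).
#' @return An object of class `community_state`: list with `stems` (data
#'   frame `tag, species, dbh, wsg, size_class, is_lbf, is_primate,
#'   agb_coef`), `agc_obs_kg`, `n_stems`, `class_counts`, `breaks`.
#' @export
community_state <- function(trees, traits, min_dbh = 5,
                            breaks = c(5, 20, 40, 80)) {
  trees <- filter_min_dbh(trees, min_dbh)
  trees <- resolve_species(trees, traits, strict = TRUE)
  idx <- match(trees$species, traits$species)
  wsg <- traits$wsg[idx]
  if (anyNA(wsg)) {
    stop("missing wood specific gravity for: ",
         paste(unique(trees$species[is.na(wsg)]), collapse = ", "),
         call. = FALSE)
  }
  lbf_sp <- is_lbf(traits)[idx]
  pri_sp <- is_primate_dispersed(traits)[idx]
  stems <- data.frame(tag = trees$tag, species = trees$species,
                      dbh = trees$dbh, wsg = wsg,
                      size_class = assign_size_class(trees$dbh, breaks),
                      is_lbf = lbf_sp, is_primate = pri_sp,
                      agb_coef = agb_size_term(trees$dbh),
                      stringsAsFactors = FALSE)
  structure(list(
    stems = stems,
    agc_obs_kg = sum(stems$wsg * stems$agb_coef) / 2,
    n_stems = nrow(stems),
    class_counts = tabulate(stems$size_class, nbins = length(breaks)),
    breaks = breaks
  ), class = "community_state")
}

#' @export
print.community_state <- function(x, ...) {
  cat("Community state:", x$n_stems, "stems,",
      length(unique(x$stems$species)), "species\n")
  cat("  per-class counts:", paste(x$class_counts, collapse = " / "), "\n")
  cat("  observed AGC:", format(x$agc_obs_kg / 1000, digits = 6), "Mg\n")
  invisible(x)
}

# Current community AGC in kg (wood density times the size term, halved).
state_agc_kg <- function(state) {
  sum(state$stems$wsg * state$stems$agb_coef) / 2
}

#' Define a defaunation scenario
#'
#' A scenario is a target rule (which stems can be extirpated), a
#' defaunation intensity, and a replacement option. Targets: `all_lbf` —
#' stems of species dispersed by any large-bodied frugivore;
#' `primates_only` — stems of species dispersed by gibbon or macaque;
#' `control` — every stem is a candidate, and the number removed is matched
#' to the `all_lbf` count at the same intensity, so the control isolates the
#' effect of the resampling procedure itself. Options: `wsg_swap` keeps each
#' removed stem's size and only reassigns its wood density from a random
#' same-class non-target stem (basal area conserved exactly);
#' `full_replace` clones a same-class non-target stem wholesale (species,
#' density and size).
#'
#' @param name One of `"all_lbf"`, `"primates_only"`, `"control"`.
#' @param intensity Fraction of target stems removed, in (0, 1].
#' @param option `"wsg_swap"` or `"full_replace"`.
#' @return A `scenario` object (list).
#' @export
scenario <- function(name = c("all_lbf", "primates_only", "control"),
                     intensity = 1, option = c("wsg_swap", "full_replace")) {
  name <- match.arg(name)
  option <- match.arg(option)
  stopifnot(is.numeric(intensity), length(intensity) == 1,
            intensity > 0, intensity <= 1)
  structure(list(name = name, intensity = intensity, option = option),
            class = "scenario")
}

# Logical mask of target stems under a scenario's rule.
target_mask <- function(state, scn) {
  switch(scn$name,
         all_lbf = state$stems$is_lbf,
         primates_only = state$stems$is_primate,
         control = rep(TRUE, state$n_stems))
}

# Number of stems a scenario removes. Control is tied to the all-LBF count
# at the same intensity. round() is round-half-even; the canonical 20%-step
# intensities never hit a half anyway for the plot-scale counts.
removal_count <- function(state, scn) {
  n_target <- if (scn$name == "control") sum(state$stems$is_lbf)
              else sum(target_mask(state, scn))
  round(scn$intensity * n_target)
}

#' Draw the stems removed in one replicate
#'
#' Samples `round(intensity * N_target)` target stems uniformly without
#' replacement across the whole plot (removal is per individual, not per
#' species). Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param state A [community_state()].
#' @param scn A [scenario()].
#' @return Integer row indices into `state$stems`.
#' @export
select_removals <- function(state, scn) {
  targets <- which(target_mask(state, scn))
  if (length(targets) == 0 && scn$name != "control") {
    stop("scenario '", scn$name, "' has no target stems", call. = FALSE)
  }
  n <- removal_count(state, scn)
  if (n > length(targets)) {
    stop("removal count ", n, " exceeds target pool of ", length(targets),
         call. = FALSE)
  }
  targets[sample.int(length(targets), n)]
}

# Shared replacement engine. Donors are drawn uniformly WITH replacement
# from the non-target stems of the same size class, fixed at pre-removal
# composition. In the control scenario every stem is a target, so the donor
# pool falls back to the non-removed stems of the class.
replace_stems <- function(state, removals, scn, mode) {
  if (length(removals) == 0) return(state)
  st <- state$stems
  is_target <- target_mask(state, scn)
  cls <- st$size_class
  for (cl in unique(cls[removals])) {
    rem_c <- removals[cls[removals] == cl]
    pool_c <- if (any(!is_target)) which(!is_target & cls == cl)
              else setdiff(which(cls == cl), removals)
    if (length(pool_c) == 0) {
      stop("size class ", cl, " has no replacement-pool stems", call. = FALSE)
    }
    donors <- pool_c[sample.int(length(pool_c), length(rem_c),
                                replace = TRUE)]
    if (mode == "wsg_swap") {
      st$wsg[rem_c] <- st$wsg[donors]
    } else {
      st$wsg[rem_c] <- st$wsg[donors]
      st$dbh[rem_c] <- st$dbh[donors]
      st$species[rem_c] <- st$species[donors]
      st$is_lbf[rem_c] <- st$is_lbf[donors]
      st$is_primate[rem_c] <- st$is_primate[donors]
      st$agb_coef[rem_c] <- st$agb_coef[donors]
      st$size_class[rem_c] <- st$size_class[donors]  # same class by pool
    }
  }
  out <- state
  out$stems <- st
  out
}

#' Replacement options
#'
#' `replace_wsg_swap()` keeps each removed stem's tag and diameter and
#' overwrites its wood specific gravity with that of a random non-target
#' stem of the same size class (drawn with replacement), so the dbh multiset
#' — hence total basal area — is conserved exactly. `replace_full()` clones
#' the donor stem wholesale (species, density, diameter); per-class stem
#' counts are conserved but within-class diameters may change. Both use the
#' current RNG state.
#'
#' @inheritParams select_removals
#' @param removals Integer indices from [select_removals()].
#' @return A new `community_state`.
#' @export
replace_wsg_swap <- function(state, removals, scn) {
  replace_stems(state, removals, scn, "wsg_swap")
}

#' @rdname replace_wsg_swap
#' @export
replace_full <- function(state, removals, scn) {
  replace_stems(state, removals, scn, "full_replace")
}

# Deterministic 31-bit stream seed from the master seed and a label path,
# so each replicate/bootstrap has its own substream and replicate r is
# invariant to n_reps.
stream_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) format(x, digits = 15),
                    character(1)), collapse = "/")
  h <- 17
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' Run the removal--replacement replicates
#'
#' Each replicate independently draws the removal set, applies the
#' scenario's replacement option, and records the relative change in
#' above-ground carbon, \eqn{\Delta AGC\% = 100 (AGC_{sim} -
#' AGC_{obs})/AGC_{obs}}. Replicates use deterministic per-replicate
#' substreams of `seed`, so replicate r does not depend on `n_reps`.
#'
#' @inheritParams select_removals
#' @param n_reps Number of replicates (default 200).
#' @param seed Master seed (integer).
#' @return Numeric vector of `n_reps` percent changes.
#' @export
run_replicates <- function(state, scn, n_reps = 200, seed = 1) {
  stopifnot(n_reps >= 1)
  agc_obs <- state$agc_obs_kg
  replace_fun <- if (scn$option == "wsg_swap") replace_wsg_swap
                 else replace_full
  vapply(seq_len(n_reps), function(r) {
    set.seed(stream_seed(seed, "rep", scn$name, scn$intensity, scn$option, r))
    removals <- select_removals(state, scn)
    sim <- replace_fun(state, removals, scn)
    100 * (state_agc_kg(sim) - agc_obs) / agc_obs
  }, numeric(1))
}

#' Bootstrap confidence interval for the mean percent change
#'
#' Resamples the replicate vector with replacement `n_boot` times (same
#' size), takes the mean of each resample, and reports the percentile
#' interval of those bootstrap means. The point estimate is the plain mean
#' of the original replicates.
#'
#' @param replicates Numeric vector of per-replicate percent changes
#'   (length >= 2).
#' @param n_boot Number of bootstrap resamples (default 200).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling stream.
#' @return List with `mean`, `ci_low`, `ci_high`, `se` (sd of the bootstrap
#'   means).
#' @export
bootstrap_ci <- function(replicates, n_boot = 200, level = 0.95, seed = 1) {
  stopifnot(length(replicates) >= 2, n_boot >= 2, level > 0, level < 1)
  set.seed(stream_seed(seed, "boot"))
  n <- length(replicates)
  boot_means <- vapply(seq_len(n_boot), function(b) {
    mean(replicates[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  qs <- stats::quantile(boot_means, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE)
  list(mean = mean(replicates), ci_low = qs[1], ci_high = qs[2],
       se = stats::sd(boot_means))
}

#' Run the full defaunation experiment
#'
#' Crosses scenarios, intensities and replacement options, runs the
#' replicates for each combination and summarises them with a bootstrap
#' confidence interval. The default grid (3 scenarios x 5 intensities x 2
#' options, 200 replicates, 200 bootstrap resamples) reproduces the study
#' design.
#'
#' @param trees Census data frame.
#' @param traits Traits data frame with complete `wsg`.
#' @param scenarios Character vector of scenario names.
#' @param intensities Numeric vector of defaunation intensities in (0, 1].
#' @param options Character vector of replacement options.
#' @param n_reps,n_boot Replicates and bootstrap resamples per combination.
#' @param seed Master seed; every random draw in the experiment derives
#'   from it.
#' @param min_dbh,breaks Passed to [community_state()].
#' @param keep_replicates Attach the full replicate vectors as the
#'   `"replicates"` attribute (a named list).
#' @return Data frame with one row per combination: `scenario, intensity,
#'   option, mean_delta_agc_pct, ci_low, ci_high, boot_se, n_reps, n_boot,
#'   seed`.
#' @export
run_experiment <- function(trees, traits,
                           scenarios = c("all_lbf", "primates_only",
                                         "control"),
                           intensities = seq(0.2, 1, by = 0.2),
                           options = c("wsg_swap", "full_replace"),
                           n_reps = 200, n_boot = 200, seed = 1,
                           min_dbh = 5, breaks = c(5, 20, 40, 80),
                           keep_replicates = FALSE) {
  state <- community_state(trees, traits, min_dbh = min_dbh, breaks = breaks)
  grid <- expand.grid(option = options, intensity = intensities,
                      scenario = scenarios, stringsAsFactors = FALSE)
  grid <- grid[, c("scenario", "intensity", "option")]
  reps_kept <- if (keep_replicates) vector("list", nrow(grid)) else NULL
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    scn <- scenario(grid$scenario[i], grid$intensity[i], grid$option[i])
    reps <- run_replicates(state, scn, n_reps = n_reps, seed = seed)
    bs <- bootstrap_ci(reps, n_boot = n_boot,
                       seed = stream_seed(seed, scn$name, scn$intensity,
                                          scn$option))
    rows[[i]] <- data.frame(scenario = scn$name, intensity = scn$intensity,
                            option = scn$option,
                            mean_delta_agc_pct = bs$mean,
                            ci_low = bs$ci_low, ci_high = bs$ci_high,
                            boot_se = bs$se, n_reps = n_reps,
                            n_boot = n_boot, seed = seed,
                            stringsAsFactors = FALSE)
    if (keep_replicates) {
      reps_kept[[i]] <- reps
      names(reps_kept)[i] <- paste(scn$name, scn$intensity, scn$option,
                                   sep = "_")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (keep_replicates) attr(out, "replicates") <- reps_kept
  out
}
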