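#' Per-species maximum diameter
#'
#' Maximum dbh over each species' stems, after applying the analysis
#' diameter filter. Species with no stems at or above the threshold are
#' excluded.
#'
#' @param trees Census data frame.
#' @param min_dbh Diameter filter applied first (cm, default 5).
#' @return Data frame `species, max_dbh` (cm), one row per species present.
#' @export
species_max_dbh <- function(trees, min_dbh = 5) {
  trees <- filter_min_dbh(trees, min_dbh)
  if (nrow(trees) == 0) {
    return(data.frame(species = character(), max_dbh = numeric()))
  }
  mx <- tapply(trees$dbh, trees$species, max)
  data.frame(species = names(mx), max_dbh = unname(mx),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sample trait comparison
#'
#' Welch two-sample t-test (Student's pooled test via `var_equal = TRUE`)
#' between two groups of per-species trait values; positive t means group A
#' has the larger mean. Group means and medians are reported alongside the
#' test, since for skewed traits like wood specific gravity the medians are
#' the more interpretable summary.
#'
#' @param values_a,values_b Numeric vectors of per-species trait values
#'   (each of length >= 2).
#' @param var_equal Assume equal variances (Student) instead of Welch.
#' @return One-row data frame: `t, df, p, n1, n2, mean1, mean2, median1,
#'   median2`.
#' @export
trait_t_test <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0 &&
      mean(values_a) == mean(values_b)) {
    # degenerate constant data: no variance, no difference
    ht <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = 1)
  } else {
    ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  }
  data.frame(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value,
             n1 = length(values_a), n2 = length(values_b),
             mean1 = mean(values_a), mean2 = mean(values_b),
             median1 = stats::median(values_a),
             median2 = stats::median(values_b))
}

#' Trait comparisons between disperser groupings
#'
#' Reproduces the species-level trait contrasts that motivate the carbon
#' simulation: wood specific gravity and maximum diameter, each compared
#' between (a) LBF-dispersed species and all others, and (b)
#' primate-dispersed species and the rest (terrestrial mammals, birds and
#' other agents). The unit of analysis is the species: one WSG and one
#' maximum dbh per species.
#'
#' @param trees Census data frame (used for per-species maximum dbh).
#' @param traits Traits data frame with complete `wsg`.
#' @param min_dbh Diameter filter for [species_max_dbh()].
#' @param var_equal Passed to [trait_t_test()].
#' @return Data frame with four rows (`grouping` x `trait`) and the
#'   [trait_t_test()] columns.
#' @export
compare_traits <- function(trees, traits, min_dbh = 5, var_equal = FALSE) {
  mx <- species_max_dbh(trees, min_dbh)
  traits <- traits[traits$species %in% mx$species, , drop = FALSE]
  maxd <- mx$max_dbh[match(traits$species, mx$species)]
  lbf <- is_lbf(traits)
  pri <- is_primate_dispersed(traits)
  grouping <- list(lbf_vs_others = lbf, primates_vs_tbo = pri)
  trait_vals <- list(wsg = traits$wsg, max_dbh = maxd)
  rows <- list()
  for (g in names(grouping)) {
    for (tr in names(trait_vals)) {
      flag <- grouping[[g]]
      row <- trait_t_test(trait_vals[[tr]][flag], trait_vals[[tr]][!flag],
                          var_equal = var_equal)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(grouping = g, trait = tr,
                         stringsAsFactors = FALSE), row)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
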