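#' Seed-disperser group codes
#'
#' The eight frugivore/disperser groups used to classify tree species:
#' gibbon, macaque, hornbills and large pigeons, smaller birds, terrestrial
#' mammals (deer, elephants, bears), unknown animals, unclassified (including
#' ballistic and unknown modes), and wind. Codes are stable and used for
#' serialization in trait tables (pipe-delimited lists).
#'
#' @return Character vector of the eight group codes, in canonical order.
#' @export
#' @examples
#' dispersal_group_codes()
dispersal_group_codes <- function() {
  c("gibbon", "macaque", "hornbills_large_pigeons", "smaller_birds",
    "terrestrial_mammals", "unknown_animals", "unclassified", "wind")
}

#' @rdname dispersal_group_codes
#' @details `lbf_groups()` returns the subset defining large-bodied
#'   frugivores (LBF): gibbon, macaque, hornbills/large pigeons and
#'   terrestrial mammals — the guild removed in the defaunation scenarios.
#'   `primate_groups()` returns the primate subset (gibbon, macaque).
#' @export
lbf_groups <- function() {
  c("gibbon", "macaque", "hornbills_large_pigeons", "terrestrial_mammals")
}

#' @rdname dispersal_group_codes
#' @export
primate_groups <- function() {
  c("gibbon", "macaque")
}

# Parse a pipe-delimited group string into a character vector, validating
# codes. Internal; used by read_traits and the classifiers.
parse_groups <- function(x, empty = c("error", "unclassified")) {
  empty <- match.arg(empty)
  known <- dispersal_group_codes()
  out <- strsplit(trimws(x), "|", fixed = TRUE)
  out <- lapply(out, function(g) {
    g <- trimws(g[nzchar(trimws(g))])
    if (length(g) == 0) {
      if (empty == "error") {
        stop("empty dispersal-group list; set empty = \"unclassified\" to coerce",
             call. = FALSE)
      }
      return("unclassified")
    }
    bad <- setdiff(g, known)
    if (length(bad)) {
      stop("unknown dispersal-group code(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    unique(g)
  })
  out
}

format_groups <- function(groups) {
  vapply(groups, function(g) paste(g, collapse = "|"), character(1))
}
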