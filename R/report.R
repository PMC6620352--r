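#' Write simulation summaries to CSV
#'
#' @param summaries Data frame from [run_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run: the configuration
#' snapshot, MD5 hashes of the input files, the master seed, package
#' version and a timestamp. Re-running with the same manifest reproduces
#' all numeric outputs (the timestamp is informational).
#'
#' @param path Output YAML path.
#' @param seed Master seed used.
#' @param config Arbitrary configuration list to snapshot.
#' @param inputs Character vector of input file paths to hash.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, seed, config = list(),
                           inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(
    package = "defaunacarbon",
    version = as.character(utils::packageVersion("defaunacarbon")),
    seed = seed,
    config = config,
    input_md5 = hashes,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}

#' Plot percent carbon change against defaunation intensity
#'
#' One panel per scenario, mean percent change in above-ground carbon with
#' the bootstrap confidence band, split by replacement option. Requires
#' ggplot2.
#'
#' @param summaries Data frame from [run_experiment()].
#' @return A ggplot object.
#' @export
plot_delta_agc <- function(summaries) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ggplot2::ggplot(summaries,
                  ggplot2::aes(x = .data$intensity * 100,
                               y = .data$mean_delta_agc_pct,
                               colour = .data$option,
                               fill = .data$option)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Defaunation intensity (%)",
                  y = expression(Delta * "AGC (%)"),
                  colour = "Replacement", fill = "Replacement") +
    ggplot2::theme_minimal()
}
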