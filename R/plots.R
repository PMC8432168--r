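#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

pvd_long <- function(pvd) {
  events <- rownames(pvd)
  if (is.null(events)) events <- paste0("event_", seq_len(nrow(pvd)))
  tibble::tibble(
    event = factor(rep(events, ncol(pvd)), levels = rev(events)),
    position = rep(seq_len(ncol(pvd)), each = nrow(pvd)),
    proportion = as.vector(pvd)
  )
}

#' Plot a positional variance diagram
#'
#' Grayscale tile map of how often each event (rows, maximum-likelihood
#' order top to bottom) occupies each sequence position (columns): 0 maps
#' to white, 1 to black, so a confident ordering shows as a dark diagonal.
#'
#' @param pvd `M x M` positional variance matrix (rows named by event, in
#'   ML order), e.g. `fit$pvd` or a bootstrap's `$pvd`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_positional_variance <- function(pvd, title = NULL) {
  stopifnot(is.matrix(pvd))
  if (nrow(pvd) != ncol(pvd)) {
    stop("positional variance matrix must be square", call. = FALSE)
  }
  ggplot2::ggplot(pvd_long(pvd),
                  ggplot2::aes(x = .data$position, y = .data$event,
                               fill = .data$proportion)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::scale_fill_gradient(low = "white", high = "black",
                                 limits = c(0, 1), name = "proportion") +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(pvd)),
                                expand = c(0, 0)) +
    ggplot2::labs(x = "sequence position", y = NULL, title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.grid = ggplot2::element_blank())
}

#' @describeIn plot_positional_variance autoplot method for a fitted model.
#' @param object An `ebm_fit`.
#' @param which `"mcmc"` (posterior) or `"bootstrap"`.
#' @param ... Unused.
#' @method autoplot ebm_fit
#' @export
autoplot.ebm_fit <- function(object, which = c("mcmc", "bootstrap"), ...) {
  which <- match.arg(which)
  if (which == "bootstrap") {
    if (is.null(object$bootstrap)) {
      stop("model has no bootstrap results", call. = FALSE)
    }
    plot_positional_variance(object$bootstrap$pvd,
                             title = "Bootstrap positional variance")
  } else {
    plot_positional_variance(object$pvd, title = "Positional variance")
  }
}

#' Write a positional variance diagram to CSV and PNG
#'
#' The CSV holds the exact matrix (row names = events in
#' maximum-likelihood order); the PNG is the grayscale rendering of
#' [plot_positional_variance()].
#'
#' @inheritParams plot_positional_variance
#' @param path Output path; its extension is replaced to produce
#'   `<base>.csv` and `<base>.png`.
#' @return Character vector of the two paths written, invisibly.
#' @export
write_positional_variance <- function(pvd, path) {
  stopifnot(is.matrix(pvd))
  if (nrow(pvd) != ncol(pvd)) {
    stop("positional variance matrix must be square", call. = FALSE)
  }
  if (any(pvd < 0 | pvd > 1)) {
    stop("positional variance entries must lie in [0, 1]", call. = FALSE)
  }
  base <- sub("\\.(csv|png)$", "", path)
  csv <- paste0(base, ".csv")
  png <- paste0(base, ".png")
  events <- rownames(pvd)
  if (is.null(events)) events <- paste0("event_", seq_len(nrow(pvd)))
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(event = events),
                     tibble::as_tibble(pvd, .name_repair = "minimal")),
    csv
  )
  ggplot2::ggsave(png, plot_positional_variance(pvd),
                  width = 6, height = 5, dpi = 150)
  invisible(c(csv, png))
}

#' Plot stage histograms per diagnostic group
#'
#' Side-by-side histograms of assigned model stages for controls and
#' patients; in a well-behaved model controls pile at early stages and
#' patients at later ones.
#'
#' @param stages Output of [stage_cohort()].
#' @param m Number of events (stage axis runs 0..`m`).
#' @return A ggplot object.
#' @export
plot_stage_histogram <- function(stages, m = max(stages$stage)) {
  ggplot2::ggplot(stage_histogram(stages, m),
                  ggplot2::aes(x = .data$stage, y = .data$n,
                               fill = .data$label)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_x_continuous(breaks = 0:m) +
    ggplot2::labs(x = "model stage", y = "subjects", fill = NULL) +
    ggplot2::theme_minimal()
}
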