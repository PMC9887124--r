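# ggplot2 views of the tabular result types.

#' Plot a 2D occupancy histogram
#'
#' @param object A `kh_hist2d`.
#' @param ... Unused.
#' @return A ggplot object (tile map of counts).
#' @method autoplot kh_hist2d
#' @export
autoplot.kh_hist2d <- function(object, ...) {
  ctr <- hist2d_centers(object)
  df <- expand.grid(x = ctr$x, y = ctr$y)
  df$count <- as.vector(object$counts)
  ggplot2::ggplot(df[df$count > 0, ],
                  ggplot2::aes(x = .data$x, y = .data$y, fill = .data$count)) +
    ggplot2::geom_tile(width = object$widths[1], height = object$widths[2]) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x", y = "y", fill = "count") +
    ggplot2::theme_minimal()
}

#' Plot the energy log of a trajectory
#'
#' @param object A `kh_trajectory`.
#' @param ... Unused.
#' @return A ggplot of decomposed energies over time.
#' @method autoplot kh_trajectory
#' @export
autoplot.kh_trajectory <- function(object, ...) {
  e <- object$energy
  df <- tibble::tibble(
    step = rep(e$step, 4),
    energy = c(e$bond, e$vdw, e$elec, e$total),
    term = rep(c("bond", "vdW", "electrostatic", "total"),
               each = nrow(e)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$energy,
                                   colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "step", y = "energy (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Plot replica-rung traces of a REMD run
#'
#' @param object A `kh_remd`.
#' @param ... Unused.
#' @return A ggplot of rung index versus sweep per replica.
#' @method autoplot kh_remd
#' @export
autoplot.kh_remd <- function(object, ...) {
  tr <- object$trace
  df <- tibble::tibble(
    sweep = rep(seq_len(nrow(tr)), ncol(tr)),
    rung = as.vector(tr),
    replica = factor(rep(seq_len(ncol(tr)), each = nrow(tr))))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sweep, y = .data$rung,
                                   colour = .data$replica)) +
    ggplot2::geom_step(show.legend = FALSE) +
    ggplot2::labs(x = "exchange sweep", y = "temperature rung") +
    ggplot2::theme_minimal()
}

#' Plot a dRMS series
#'
#' @param drms_table Tibble from [drms_series()].
#' @return A ggplot of dRMS versus frame.
#' @export
plot_drms <- function(drms_table) {
  ggplot2::ggplot(drms_table, ggplot2::aes(x = .data$frame, y = .data$drms)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "dRMS (Å)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
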