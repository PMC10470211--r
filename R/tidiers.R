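#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method tidy bla_result
#' @export
tidy.bla_result <- function(x, ...) {
  tibble(ligand = x$ligand, scope = x$scope, mean_single = x$mean_single,
         mean_double = x$mean_double, bla = x$bla,
         n_single = x$n_single, n_double = x$n_double)
}

#' @method tidy torsion_result
#' @export
tidy.torsion_result <- function(x, ...) {
  tibble(name = x$name, atoms = paste(x$atoms, collapse = "-"),
         angle = x$angle)
}

#' @method tidy ring_conformation
#' @export
tidy.ring_conformation <- function(x, ...) {
  tibble(ring = x$ring, angle = x$torsion$angle, klass = x$klass)
}

#' @method tidy plane_pair_geometry
#' @export
tidy.plane_pair_geometry <- function(x, ...) {
  tibble(interplanar_angle = x$interplanar_angle,
         min_distance = x$min_distance,
         crossing_dihedral = x$crossing_dihedral,
         axis_angle = x$axis_angle, axis_klass = x$axis_klass)
}

#' @method tidy superposition_result
#' @export
tidy.superposition_result <- function(x, ...) {
  tibble(n_matched = x$n_matched, rmsd = x$rmsd,
         rotation_angle = x$rotation_angle,
         axis_x = x$rotation_axis[1], axis_y = x$rotation_axis[2],
         axis_z = x$rotation_axis[3], n_trimmed = length(x$trimmed))
}

#' @method glance superposition_result
#' @export
glance.superposition_result <- function(x, ...) {
  tibble(n_matched = x$n_matched, rmsd = x$rmsd, n_trimmed = length(x$trimmed))
}

#' @method tidy sasa_partition
#' @export
tidy.sasa_partition <- function(x, ...) {
  bind_rows(
    tibble(entity = names(x$fraction_by_chain),
           fraction = unlist(x$fraction_by_chain), kind = "buried_by"),
    tibble(entity = "(solvent)", fraction = x$fraction_exposed,
           kind = "exposed")
  )
}

#' @method glance sasa_partition
#' @export
glance.sasa_partition <- function(x, ...) {
  tibble(ligand = x$ligand, total_isolated = x$total_isolated,
         fraction_exposed = x$fraction_exposed, overlap = x$overlap)
}

#' @method tidy fragment_bstats
#' @export
tidy.fragment_bstats <- function(x, ...) {
  tibble(fragment = x$fragment, n_atoms = x$n_atoms, mean_b = x$mean_b,
         sd_b = x$sd_b)
}

#' @method tidy cysteine_profile
#' @export
tidy.cysteine_profile <- function(x, ...) {
  tibble(position = x$positions)
}

#' @method glance cysteine_profile
#' @export
glance.cysteine_profile <- function(x, ...) {
  tibble(count = x$count, profile_label = x$profile_label)
}

#' @method tidy mass_result
#' @export
tidy.mass_result <- function(x, ...) {
  tibble(formula = paste0(names(x$formula), x$formula, collapse = ""),
         adduct = x$adduct, mz = x$mz)
}

#' @method tidy peak_call
#' @export
tidy.peak_call <- function(x, ...) {
  tibble(lambda_max = x$lambda_max, shoulder = x$shoulder,
         shift_vs_reference = x$shift_vs_reference)
}

#' Plot an absorption spectrum with its peak call
#'
#' @param object a [caro_spectrum].
#' @param peak optional [find_lambda_max()] result to annotate.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot caro_spectrum
#' @export
autoplot.caro_spectrum <- function(object, peak = NULL, ...) {
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$wavelength, y = .data$absorbance)) +
    ggplot2::geom_line(colour = "#1f4e79") +
    ggplot2::labs(x = "wavelength (nm)", y = "absorbance",
                  title = attr(object, "label")) +
    ggplot2::theme_minimal()
  if (!is.null(peak)) {
    p <- p + ggplot2::geom_vline(xintercept = peak$lambda_max,
                                 linetype = "dashed", colour = "#c0392b") +
      ggplot2::annotate("text", x = peak$lambda_max, y = max(object$absorbance),
                        label = sprintf("%.0f nm", peak$lambda_max),
                        hjust = -0.1, vjust = 1)
  }
  p
}

#' @rdname autoplot.caro_spectrum
#' @param spectrum a [caro_spectrum].
#' @export
plot_spectrum <- function(spectrum, peak = NULL) {
  autoplot.caro_spectrum(spectrum, peak)
}

#' Bar chart of per-fragment B-factor means
#'
#' @param stats_list list of [fragment_bfactor()] results.
#' @return a ggplot object.
#' @export
plot_fragment_bfactors <- function(stats_list) {
  df <- bind_rows(map(stats_list, tidy))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fragment, y = .data$mean_b)) +
    ggplot2::geom_col(fill = "#1f4e79") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_b - .data$sd_b,
                                        ymax = .data$mean_b + .data$sd_b),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = expression(mean~italic(B)~(ring(A)^2))) +
    ggplot2::theme_minimal()
}
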