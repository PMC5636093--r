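new_map_image <- function(grid, mask, value_kind, param_kind, params) {
  structure(list(grid = grid, mask = mask, value_kind = value_kind,
                 param_kind = param_kind, params = params),
            class = "map_image")
}

#' @export
print.map_image <- function(x, ...) {
  cat(sprintf("<map_image> %s: %d muscles x %d %s levels (%d masked cells)\n",
              x$value_kind, nrow(x$grid), ncol(x$grid), x$param_kind,
              sum(x$mask)))
  invisible(x)
}

#' Recruitment colormap for an intensity ramp
#'
#' One row per muscle, one column per stimulation voltage; each cell is the
#' mean peak-to-peak amplitude of that muscle's segments at that voltage.
#' Cells below the muscle's detected activation threshold `V_s0` are masked
#' (rendered gray): the pre-threshold part of the experiment where no
#' activation was induced. A muscle with no detected threshold has its whole
#' row masked.
#'
#' @param features Named list (per muscle) of feature tables from
#'   [build_feature_table()], all sharing one voltage ladder.
#' @param detections Named list (per muscle) of `detection_result`s.
#' @return A `map_image` with `value_kind = "vpp"`.
#' @export
intensity_map <- function(features, detections) {
  muscles <- names(features)
  if (is.null(muscles) || !identical(sort(muscles),
                                     sort(names(detections)))) {
    stop("`features` and `detections` must be named per muscle",
         call. = FALSE)
  }
  ladders <- lapply(features, function(f) sort(unique(f$param)))
  if (length(unique(lapply(ladders, unname))) != 1L) {
    stop("all muscles must share the voltage ladder", call. = FALSE)
  }
  volts <- ladders[[1L]]
  grid <- matrix(NA_real_, nrow = length(muscles), ncol = length(volts),
                 dimnames = list(muscles, format(volts)))
  mask <- matrix(FALSE, nrow = length(muscles), ncol = length(volts),
                 dimnames = dimnames(grid))
  for (m in muscles) {
    f <- features[[m]]
    for (j in seq_along(volts)) {
      grid[m, j] <- mean(f$vpp[f$param == volts[j]])
    }
    v_s0 <- detections[[m]]$v_s0
    mask[m, ] <- if (is.na(v_s0)) TRUE else volts < v_s0
  }
  new_map_image(grid, mask, "vpp", "voltage", volts)
}

#' Recruitment colormap for a frequency ramp
#'
#' One row per muscle, one column per stimulation frequency; each cell is
#' the mean integrated EMG at that frequency. No threshold masking is
#' applied.
#'
#' @param features Named list (per muscle) of feature tables.
#' @return A `map_image` with `value_kind = "iemg"`.
#' @export
frequency_map <- function(features) {
  muscles <- names(features)
  if (is.null(muscles)) stop("`features` must be named per muscle",
                             call. = FALSE)
  freqs <- sort(unique(features[[1L]]$param))
  grid <- matrix(NA_real_, nrow = length(muscles), ncol = length(freqs),
                 dimnames = list(muscles, format(freqs)))
  for (m in muscles) {
    f <- features[[m]]
    for (j in seq_along(freqs)) {
      grid[m, j] <- mean(f$iemg[f$param == freqs[j]])
    }
  }
  mask <- matrix(FALSE, nrow = length(muscles), ncol = length(freqs),
                 dimnames = dimnames(grid))
  new_map_image(grid, mask, "iemg", "frequency", freqs)
}

map_to_tibble <- function(map, config = NA_character_) {
  tibble::tibble(
    config = config,
    muscle = rep(rownames(map$grid), times = ncol(map$grid)),
    param = rep(map$params, each = nrow(map$grid)),
    value = as.vector(map$grid),
    masked = as.vector(map$mask)
  )
}

value_label <- function(kind) {
  switch(kind, vpp = "Peak-to-peak amplitude (µV)",
         iemg = "Integrated EMG (µV·ms)", kind)
}

param_label <- function(kind) {
  switch(kind, voltage = "Stimulation voltage (V)",
         frequency = "Stimulation frequency (Hz)", kind)
}

#' Plot a recruitment colormap
#'
#' Masked (pre-threshold) cells are rendered gray, outside the colour range
#' of the value scale; the colour mapping is monotone in value.
#'
#' @param map A `map_image`.
#' @param limits Optional shared colour limits `c(lo, hi)`.
#' @return A ggplot.
#' @export
plot_map <- function(map, limits = NULL) {
  stopifnot(inherits(map, "map_image"))
  df <- map_to_tibble(map)
  df$muscle <- factor(df$muscle, levels = rev(rownames(map$grid)))
  df$shown <- ifelse(df$masked, NA_real_, df$value)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$param),
                                   y = .data$muscle,
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value_label(map$value_kind),
                                  limits = limits, na.value = "grey70") +
    ggplot2::labs(x = param_label(map$param_kind), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Tile several recruitment maps with a shared colour scale
#'
#' Lays out the maps of multiple stimulation configurations side by side
#' under one colour bar, so identical values render identically across
#' tiles. All maps must share the value kind.
#'
#' @param maps List of `map_image` objects (named by configuration).
#' @return A faceted ggplot.
#' @export
multi_config_grid <- function(maps) {
  if (length(maps) == 0L) stop("need at least one map", call. = FALSE)
  kinds <- unique(vapply(maps, `[[`, character(1), "value_kind"))
  if (length(kinds) != 1L) {
    stop("all maps must share the value kind", call. = FALSE)
  }
  nms <- names(maps)
  if (is.null(nms)) nms <- paste("config", seq_along(maps))
  df <- do.call(rbind, lapply(seq_along(maps), function(i) {
    map_to_tibble(maps[[i]], config = nms[i])
  }))
  df$muscle <- factor(df$muscle, levels = rev(rownames(maps[[1L]]$grid)))
  df$shown <- ifelse(df$masked, NA_real_, df$value)
  df$config <- factor(df$config, levels = nms)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$param),
                                   y = .data$muscle,
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~config) +
    ggplot2::scale_fill_viridis_c(name = value_label(maps[[1L]]$value_kind),
                                  na.value = "grey70") +
    ggplot2::labs(x = param_label(maps[[1L]]$param_kind), y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Write a recruitment map to CSV (and optionally PNG)
#'
#' The grid values and mask are written as a tidy CSV for headless use; when
#' `png_path` is given the rendered map is also saved.
#'
#' @param map A `map_image`.
#' @param csv_path Output CSV path.
#' @param png_path Optional output PNG path.
#' @param width,height PNG geometry in inches.
#' @return Invisibly, the CSV path.
#' @export
write_map <- function(map, csv_path, png_path = NULL, width = 8, height = 5) {
  readr::write_csv(map_to_tibble(map), csv_path)
  if (!is.null(png_path)) {
    ggplot2::ggsave(png_path, plot_map(map), width = width, height = height,
                    dpi = 150)
  }
  invisible(csv_path)
}
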