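# Electrode montages.
#
# Two montages are built in:
#   * "ld1020" - the 19 scalp electrodes of the clinical 10/20 system.
#   * "hd91"   - an idealized 91-site superset following 10-10/10-5 naming,
#                used for high-density validation recordings. The exact
#                high-density layout of any given amplifier varies; any fixed
#                superset of the 10/20 sites preserves the cross-montage
#                validation design, so this layout is a synthetic/idealized
#                standard rather than a vendor cap file.
#
# Positions are defined on a 2D disc (azimuthal-equidistant layout: disc
# radius 1 corresponds to a 90 degree polar angle from the vertex) and
# projected onto the unit sphere; head radius is normalized to 1, so all
# distances downstream (modular span) are in head-radius units.

LD1020_LABELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "T7", "C3", "Cz", "C4", "T8",
                   "P7", "P3", "Pz", "P4", "P8", "O1", "O2")

# One coronal row of the idealized layout: midline site at disc radius r_mid
# (azimuth 0 front / 180 back), outermost lateral site at r_out with azimuth
# az_out (degrees from anterior, positive = left), lateral sites interpolated
# in (radius, azimuth) at the given fractions.
montage_row <- function(mid_label, r_mid, az_mid, az_out, lateral, r_out = 1) {
  out <- list()
  if (!is.na(mid_label))
    out[[length(out) + 1L]] <- data.frame(label = mid_label, r = r_mid, az = az_mid)
  for (k in seq_along(lateral$left)) {
    f <- lateral$frac[k]
    r <- r_mid + f * (r_out - r_mid)
    az <- az_mid + f * (az_out - az_mid)
    out[[length(out) + 1L]] <- data.frame(label = c(lateral$left[k], lateral$right[k]),
                                          r = r, az = c(az, -az))
  }
  do.call(rbind, out)
}

lat4 <- function(p) {
  # standard 10-10 lateral series, outermost first
  list(left = paste0(c(p[2], rep(p[1], 3)), c(7, 5, 3, 1)),
       right = paste0(c(p[2], rep(p[1], 3)), c(8, 6, 4, 2)),
       frac = c(1, 0.75, 0.5, 0.25))
}

hd91_layout <- function() {
  rows <- list(
    montage_row("Fpz", 0.8, 0, 18, list(left = "Fp1", right = "Fp2", frac = 1)),
    montage_row("AFpz", 0.7, 0, 27, list(left = "AFp1", right = "AFp2", frac = 1)),
    montage_row("AFz", 0.6, 0, 36, lat4(c("AF", "AF"))),
    montage_row("Fz", 0.4, 0, 54, lat4(c("F", "F"))),
    montage_row("FCz", 0.2, 0, 72, lat4(c("FC", "FT"))),
    montage_row("Cz", 0.0, 90, 90, lat4(c("C", "T"))),
    montage_row("CPz", 0.2, 180, 108, lat4(c("CP", "TP"))),
    montage_row("Pz", 0.4, 180, 126, lat4(c("P", "P"))),
    montage_row("POz", 0.6, 180, 144, lat4(c("PO", "PO"))),
    montage_row("POOz", 0.7, 180, 153, list(left = "POO1", right = "POO2", frac = 1)),
    montage_row("Oz", 0.8, 180, 162, list(left = "O1", right = "O2", frac = 1)),
    # inferior 10-5 ring, 10% below the outer ring
    montage_row(NA, 1.2, 0, 54, list(left = "F9", right = "F10", frac = 1), r_out = 1.2),
    montage_row(NA, 1.2, 0, 72, list(left = "FT9", right = "FT10", frac = 1), r_out = 1.2),
    montage_row(NA, 1.2, 0, 90, list(left = "T9", right = "T10", frac = 1), r_out = 1.2),
    montage_row(NA, 1.2, 0, 108, list(left = "TP9", right = "TP10", frac = 1), r_out = 1.2),
    montage_row(NA, 1.2, 0, 126, list(left = "P9", right = "P10", frac = 1), r_out = 1.2),
    montage_row(NA, 1.2, 0, 144, list(left = "PO9", right = "PO10", frac = 1), r_out = 1.2),
    montage_row(NA, 1.2, 0, 162, list(left = "O9", right = "O10", frac = 1), r_out = 1.2),
    data.frame(label = c("OIz", "Iz"), r = c(0.9, 1.0), az = c(180, 180))
  )
  do.call(rbind, rows)
}

layout_to_sphere <- function(layout) {
  theta <- layout$r * pi / 2        # polar angle from the vertex
  phi <- layout$az * pi / 180       # azimuth from anterior, positive left
  cbind(x = sin(theta) * cos(phi),  # +x anterior
        y = sin(theta) * sin(phi),  # +y left
        z = cos(theta))             # +z up
}

#' Load a built-in electrode montage
#'
#' @param name one of `"ld1020"` (19-channel clinical 10/20 layout) or
#'   `"hd91"` (idealized 91-site 10-10/10-5 superset used for high-density
#'   validation data).
#' @return An object of class `eeg_montage`: a list with `name`, `labels`
#'   and a channels-by-3 `coordinates` matrix of unit-sphere scalp positions
#'   (head radius 1).
#' @examples
#' m <- load_montage("ld1020")
#' nrow(m$coordinates)  # 19
#' @export
load_montage <- function(name) {
  available <- c("ld1020", "hd91")
  if (!is.character(name) || length(name) != 1L || !(name %in% available))
    stop_eegprog("unknown montage '%s'; available: %s",
                 as.character(name)[1], paste(available, collapse = ", "),
                 class = "eegprog_unknown_montage")
  layout <- hd91_layout()
  if (name == "ld1020")
    layout <- layout[match(LD1020_LABELS, layout$label), ]
  coords <- layout_to_sphere(layout)
  rownames(coords) <- layout$label
  structure(list(name = name, labels = layout$label, coordinates = coords),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> '%s': %d electrodes on the unit sphere\n",
              x$name, length(x$labels)))
  invisible(x)
}

#' Write / read a montage as CSV (columns label,x,y,z)
#' @param m an `eeg_montage`.
#' @param path output file.
#' @return `write_montage` returns `path` invisibly; `read_montage` returns
#'   an `eeg_montage`.
#' @export
write_montage <- function(m, path) {
  df <- data.frame(label = m$labels, m$coordinates)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @param name montage name to record on read.
#' @export
read_montage <- function(path, name = "custom") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, c("x", "y", "z")])
  rownames(coords) <- df$label
  structure(list(name = name, labels = df$label, coordinates = coords),
            class = "eeg_montage")
}
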