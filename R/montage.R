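# Idealized electrode montages.
#
# Positions are computed on a spherical head (radius 85 mm) from arc-angle
# coordinates of the extended international 10-20 (10-10) system: `ant` is the
# arc from the vertex toward nasion (positive) or inion (negative), `lat` the
# arc toward the left (positive) or right (negative) preauricular point, both
# in degrees.  This is the standard azimuthal parameterization used by
# idealized montages; it is not a digitized head model.

HEAD_RADIUS_MM <- 85

.ten_ten_rows <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0, CP = -18,
                   P = -36, PO = -54, O = -72)

.ten_ten_tbl <- local({
  rows <- names(.ten_ten_rows)
  out <- list()
  for (r in rows) {
    ant <- .ten_ten_rows[[r]]
    cols <- if (r %in% c("Fp", "O")) c(1, 2) else c(1:8)
    for (k in cols) {
      side <- if (k %% 2 == 1) 1 else -1           # odd = left
      lat <- side * 18 * ceiling(k / 2)
      nm <- paste0(r, k)
      # 10-20 temporal naming: F7/F8, T7/T8, P7/P8 sit at the 72-degree arc
      if (r == "F" && abs(lat) == 72) nm <- ifelse(side == 1, "F7", "F8")
      if (r == "C" && abs(lat) == 72) nm <- ifelse(side == 1, "T7", "T8")
      if (r == "P" && abs(lat) == 72) nm <- ifelse(side == 1, "P7", "P8")
      if (r == "FC" && abs(lat) == 72) nm <- ifelse(side == 1, "FT7", "FT8")
      if (r == "CP" && abs(lat) == 72) nm <- ifelse(side == 1, "TP7", "TP8")
      out[[nm]] <- c(ant = ant, lat = lat)
    }
    out[[paste0(r, "z")]] <- c(ant = ant, lat = 0)
  }
  out
})

.arc_to_xyz <- function(ant, lat, r = HEAD_RADIUS_MM) {
  # rotate the vertex unit vector by alpha = total arc toward azimuth beta
  alpha <- sqrt(ant^2 + lat^2) * pi / 180
  beta <- atan2(ant, lat)   # lat axis -> +x is left? see below
  # direction in the tangent plane: ant -> +y (front), lat -> +x would be
  # right-handed with x to the LEFT; we use x to the RIGHT, so lat enters
  # with a minus sign.
  dx <- -sin(alpha) * cos(beta)
  dy <- sin(alpha) * sin(beta)
  dz <- cos(alpha)
  r * c(dx, dy, dz)
}

#' Standard montage positions
#'
#' Returns an idealized extended 10-20 montage as a tibble of channel names
#' and 3-D scalp positions (mm; x right, y front, z up, spherical head of
#' radius 85 mm).
#'
#' @param channels Either an integer (32, for the default 32-channel layout;
#'   or 128 for the synthetic high-density cap), or a character vector of
#'   10-10 channel names.
#' @return A tibble with columns `channel`, `x`, `y`, `z`.
#' @examples
#' standard_montage(32)
#' standard_montage(c("C3", "Cz", "C4"))
#' @export
standard_montage <- function(channels = 32) {
  if (is.character(channels)) {
    pos <- lapply(channels, function(nm) {
      a <- .ten_ten_tbl[[nm]]
      if (is.null(a)) stop("unknown 10-10 channel name: ", nm, call. = FALSE)
      .arc_to_xyz(a["ant"], a["lat"])
    })
    m <- do.call(rbind, pos)
    return(tibble::tibble(channel = channels,
                          x = m[, 1], y = m[, 2], z = m[, 3]))
  }
  n <- as.integer(channels)
  if (n == 32) {
    return(standard_montage(c(
      "Fp1", "Fp2", "AFz", "F7", "F3", "Fz", "F4", "F8",
      "FC5", "FC1", "FCz", "FC2", "FC6",
      "T7", "C3", "Cz", "C4", "T8",
      "CP5", "CP1", "CP2", "CP6",
      "P7", "P3", "Pz", "P4", "P8",
      "PO3", "PO4", "O1", "Oz", "O2")))
  }
  if (n == 128) return(biosemi128_montage())
  # generic cap: deterministic Fibonacci lattice over the upper cap
  biosemi_grid(n, prefix = "E")
}

# Deterministic spherical-cap lattice used as a synthetic stand-in for
# high-density cap geometry (the vendor's exact 128-channel coordinates are
# not bundled).  Names E1..En or the BioSemi A/B/C/D bank convention.
biosemi_grid <- function(n, prefix = "E") {
  golden <- pi * (3 - sqrt(5))
  cap <- 80 * pi / 180                 # electrodes within 80 deg of vertex
  k <- seq_len(n) - 1
  z <- 1 - (1 - cos(cap)) * (k + 0.5) / n
  alpha <- acos(z)
  beta <- k * golden
  m <- HEAD_RADIUS_MM * cbind(sin(alpha) * cos(beta),
                              sin(alpha) * sin(beta),
                              cos(alpha))
  nm <- if (identical(prefix, "biosemi")) {
    paste0(rep(c("A", "B", "C", "D"), each = 32)[seq_len(n)],
           rep(1:32, 4)[seq_len(n)])
  } else paste0(prefix, seq_len(n))
  tibble::tibble(channel = nm, x = m[, 1], y = m[, 2], z = m[, 3])
}

#' Synthetic BioSemi-style 128-channel montage
#'
#' A deterministic 128-point spherical-cap lattice carrying the BioSemi
#' A1-D32 bank names.  The true bank-to-10-20 correspondence of the vendor
#' cap is not public, so these positions are a synthetic geometric stand-in
#' with realistic coverage, not digitized coordinates.
#'
#' @return A tibble with columns `channel`, `x`, `y`, `z` (mm).
#' @export
biosemi128_montage <- function() {
  biosemi_grid(128, prefix = "biosemi")
}

#' Look up montage positions for a set of channel names
#'
#' Known 10-10 names and BioSemi bank names resolve to the bundled idealized
#' layouts; unknown names are assigned the position of the nearest known
#' channel already present in the request (with a warning), so that files
#' with nonstandard labels can still be analysed.
#'
#' @param channel_names character vector.
#' @return tibble `channel`, `x`, `y`, `z`.
#' @export
montage_positions <- function(channel_names) {
  bs <- biosemi128_montage()
  out <- matrix(NA_real_, length(channel_names), 3)
  for (i in seq_along(channel_names)) {
    nm <- channel_names[i]
    if (!is.null(.ten_ten_tbl[[nm]])) {
      a <- .ten_ten_tbl[[nm]]
      out[i, ] <- .arc_to_xyz(a["ant"], a["lat"])
    } else if (nm %in% bs$channel) {
      j <- match(nm, bs$channel)
      out[i, ] <- c(bs$x[j], bs$y[j], bs$z[j])
    }
  }
  if (anyNA(out)) {
    known <- which(!is.na(out[, 1]))
    if (length(known) == 0)
      stop("no channel name could be mapped to a montage position",
           call. = FALSE)
    miss <- which(is.na(out[, 1]))
    warning("no montage position for channel(s) ",
            paste(channel_names[miss], collapse = ", "),
            "; using nearest mapped neighbour", call. = FALSE)
    for (i in miss) out[i, ] <- out[known[1], ]
  }
  tibble::tibble(channel = channel_names,
                 x = out[, 1], y = out[, 2], z = out[, 3])
}
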