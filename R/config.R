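#' Default stain basis (hematoxylin, DAB, alkaline-phosphatase red)
#'
#' Unit-norm RGB optical-density vectors from the standard published
#' stain-separation matrices.  The dual stain analysed here uses DAB
#' (brown, mitosis marker), AP red (cytoplasmic tumor marker) and a
#' hematoxylin counterstain.
#'
#' @return 3x3 matrix; rows = stains (hematoxylin, dab, red), columns = R, G, B.
#' @export
default_stain_basis <- function() {
  m <- rbind(
    hematoxylin = c(0.650, 0.704, 0.286),
    dab         = c(0.269, 0.568, 0.778),
    red         = c(0.214, 0.851, 0.478)
  )
  m / sqrt(rowSums(m^2))
}

#' Default analysis configuration
#'
#' All thresholds and radii of the pixel-classification, cell-detection and
#' hot-spot stages, unit-annotated.  The commercial system the protocol
#' derives from never published its threshold values; these defaults are
#' declared here and were fixed against the phantom generator.
#'
#' @return nested named list (class `ms_config`).
#' @export
default_config <- function() {
  cfg <- list(
    stains = list(
      basis = default_stain_basis(),
      od_eps = 1e-6,           # added to I before log to avoid log(0)
      bg_intensity = 200,      # mean RGB above this => candidate background
      density_min = 0.10,      # OD units; all-below confirms background
      t_brown = 0.35,          # OD threshold for the DAB channel
      t_red = 0.20,            # OD threshold for the AP-red channel
      t_blue = 0.20,           # OD threshold for the hematoxylin channel
      t_sd = 0.08,             # SD-filter response gate (OD units)
      t_dark = 120,            # intensity at or below => dark rescue
      sd_radius_px = 2
    ),
    detect = list(
      dilation_radius_um = 2.5,  # chromatin-fusion dilation
      ring_width_um = 2,         # perinuclear ring for MART1 surround
      min_area_um2 = 8,
      max_area_um2 = 120,
      od_min = 0.5,              # mean DAB OD over object pixels
      surround_min = 0.3,        # min MART1 fraction of the ring
      irregularity_max = 0.6,    # 1 - solidity gate (rejects speckle)
      hole_max_um2 = 50          # holes up to this size filled in tumor mask
    ),
    hotspot = list(
      radius_um = 200,           # circle radius of the object heat map
      grid_step_um = 10,         # heat-map grid spacing
      square_side_um = 1000,     # fixed reference square (1 mm^2)
      selector = "peak"          # "peak" (circle overlap) or "square" (oracle)
    ),
    calibration = list(um_per_px = NULL)  # override; otherwise sidecar
  )
  class(cfg) <- "ms_config"
  cfg
}

#' Load and validate a configuration file
#'
#' Reads a YAML file, fills unspecified keys with [default_config()] values
#' and rejects unknown or invalid keys with a message naming the key.  An
#' empty file yields the full defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return validated `ms_config`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    for (sect in names(user)) {
      if (!sect %in% names(cfg))
        stop("unknown config section: ", sect)
      if (sect == "calibration") {
        cfg$calibration <- modifyList(cfg$calibration, user[[sect]])
        next
      }
      for (key in names(user[[sect]])) {
        if (!key %in% names(cfg[[sect]]))
          stop("unknown config key: ", sect, "$", key)
        val <- user[[sect]][[key]]
        if (key == "basis") val <- as_stain_basis(val)
        cfg[[sect]][[key]] <- val
      }
    }
  }
  check_config(cfg)
  cfg
}

check_config <- function(cfg) {
  pos <- function(sect, key) {
    v <- cfg[[sect]][[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("config key must be a positive number: ", sect, "$", key)
  }
  nonneg <- function(sect, key) {
    v <- cfg[[sect]][[key]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stop("config key must be a non-negative number: ", sect, "$", key)
  }
  for (k in c("od_eps", "bg_intensity", "density_min", "t_brown", "t_red",
              "t_blue", "t_sd")) pos("stains", k)
  nonneg("stains", "t_dark")
  if (cfg$stains$sd_radius_px < 1) stop("config key must be >= 1: stains$sd_radius_px")
  for (k in c("ring_width_um", "min_area_um2", "max_area_um2", "od_min",
              "surround_min")) pos("detect", k)
  for (k in c("dilation_radius_um", "irregularity_max", "hole_max_um2"))
    nonneg("detect", k)
  if (cfg$detect$max_area_um2 <= cfg$detect$min_area_um2)
    stop("config: detect$max_area_um2 must exceed detect$min_area_um2")
  for (k in c("radius_um", "grid_step_um", "square_side_um")) pos("hotspot", k)
  if (!cfg$hotspot$selector %in% c("peak", "square"))
    stop("config key must be 'peak' or 'square': hotspot$selector")
  basis <- cfg$stains$basis
  if (any(basis < 0)) stop("config: stain basis vectors must be non-negative")
  if (kappa(basis, exact = TRUE) > 1e3)
    stop("config: stain basis is ill-conditioned")
  invisible(cfg)
}

as_stain_basis <- function(v) {
  m <- matrix(unlist(v), nrow = 3, byrow = TRUE)
  rownames(m) <- c("hematoxylin", "dab", "red")
  m / sqrt(rowSums(m^2))
}

#' Serialize a configuration to YAML
#' @param cfg an `ms_config`.
#' @param path output file.
#' @export
write_config <- function(cfg, path) {
  out <- unclass(cfg)
  out$stains$basis <- lapply(seq_len(3), function(i) as.numeric(out$stains$basis[i, ]))
  ## unset calibration entries are omitted (YAML null would delete the key
  ## on re-load via modifyList)
  out$calibration <- Filter(Negate(is.null), out$calibration)
  if (!length(out$calibration)) out$calibration <- NULL
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' Deterministic hash of a configuration
#'
#' Embedded in every output artifact so that any threshold change is
#' visible in downstream provenance.
#'
#' @param cfg an `ms_config`.
#' @return character scalar (md5).
#' @export
config_hash <- function(cfg) {
  canon <- rapply(unclass(cfg), function(x)
    if (is.numeric(x)) signif(x, 10) else x, how = "replace")
  digest::digest(canon, algo = "md5")
}
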