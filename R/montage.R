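#' Reference electrode coordinates for the dual-site frontoparietal montage
#'
#' MNI-space positions (mm, aligned from the SimNIBS "Ernie" head model) of
#' the ten high-definition electrodes: one centre and four return electrodes
#' over F4 (frontal site) and over P4 (parietal site).  The coordinates are
#' treated as opaque millimetre positions on a curved scalp; the inter-site
#' centre distance used by the analytic field formulas is the configured
#' nominal 13 cm, not the coordinate-derived chord.
#'
#' @format A data frame with columns \code{label}, \code{x}, \code{y},
#'   \code{z}, \code{role} (\code{"center"}/\code{"return"}) and \code{site}
#'   (\code{"frontal"}/\code{"parietal"}).
#' @export
default_electrode_positions <- function() {
  data.frame(
    label = c("F4", "R_F1", "R_F2", "R_F3", "R_F4",
              "P4", "R_P1", "R_P2", "R_P3", "R_P4"),
    x = c(49.65, 51.35, 25.05, 42.95, 64.83,
          48.73, 49.02, 25.63, 52.57, 65.54),
    y = c(53.71, 28.51, 58.87, 74.26, 41.57,
          -84.52, -95.93, -89.69, -62.68, -67.52),
    z = c(72.15, 86.09, 87.63, 51.96, 52.64,
          66.10, 38.49, 84.28, 85.96, 51.97),
    role = rep(c("center", rep("return", 4)), 2),
    site = rep(c("frontal", "parietal"), each = 5),
    stringsAsFactors = FALSE
  )
}

#' Region-of-interest centres used by the online connectivity engine
#'
#' The frontal and parietal sphere-ROI centres (MNI mm).  Note these sit in
#' the left hemisphere (negative x) although the stimulation sites F4/P4 are
#' right-hemisphere electrode positions; both coordinate sets are shipped
#' as published and the discrepancy is deliberately left unresolved.
#'
#' @return Named list of two 3-vectors, \code{frontal} and \code{parietal}.
#' @export
default_roi_centers <- function() {
  list(frontal = c(-45, 49, 27), parietal = c(-45, -75, 46))
}

#' Montage configuration
#'
#' @param positions Data frame of electrode positions as produced by
#'   [default_electrode_positions()] (columns label, x, y, z, role, site).
#' @param center_current Centre-electrode current, mA peak (default 1).
#' @param phase_condition `"in_phase"` or `"anti_phase"` - the sign
#'   convention applied to the parietal site's currents.
#' @param center_return_distance Nominal centre-to-return distance, mm.
#' @param distance_tolerance Relative tolerance on centre-return distances
#'   (default 0.2: the nominal 3 cm is laid out on a curved scalp).
#' @return A list of class `montage_config`.
#' @export
montage_config <- function(positions = default_electrode_positions(),
                           center_current = 1,
                           phase_condition = c("in_phase", "anti_phase"),
                           center_return_distance = 30,
                           distance_tolerance = 0.2) {
  phase_condition <- match.arg(phase_condition)
  stopifnot(is.data.frame(positions),
            all(c("label", "x", "y", "z", "role", "site") %in% names(positions)),
            is.finite(center_current),
            center_return_distance > 0, distance_tolerance >= 0)
  structure(list(positions = positions,
                 center_current = center_current,
                 phase_condition = phase_condition,
                 center_return_distance = center_return_distance,
                 distance_tolerance = distance_tolerance),
            class = "montage_config")
}

#' Build the dual-site 4x1 high-definition montage
#'
#' Assigns currents under the zero-net-current (Kirchhoff) constraint: each
#' centre electrode carries `center_current` and its four returns each carry
#' `-center_current/4`.  Under the anti-phase condition the parietal site's
#' current signs are flipped relative to in-phase.
#'
#' @param config A [montage_config()].
#' @return An object of class `tacs_montage`: a list with elements
#'   `electrodes` (data frame with columns label, x, y, z, current, role,
#'   site), `center_return_distance`, `distance_tolerance` and
#'   `phase_condition`.
#' @export
build_dual_site_montage <- function(config = montage_config()) {
  pos <- config$positions
  if (anyDuplicated(pos$label))
    stop("duplicate electrode labels: ",
         paste(unique(pos$label[duplicated(pos$label)]), collapse = ", "))
  if (!all(is.finite(as.matrix(pos[, c("x", "y", "z")]))))
    stop("non-finite electrode position")
  for (s in c("frontal", "parietal")) {
    sub <- pos[pos$site == s, ]
    if (sum(sub$role == "center") != 1L || sum(sub$role == "return") != 4L)
      stop("site '", s, "' must have exactly one center and four returns")
  }
  cc <- config$center_current
  pos$current <- ifelse(pos$role == "center", cc, -cc / 4)
  if (config$phase_condition == "anti_phase")
    pos$current[pos$site == "parietal"] <- -pos$current[pos$site == "parietal"]
  for (s in c("frontal", "parietal")) {
    net <- sum(pos$current[pos$site == s])
    if (abs(net) > 1e-9 * max(1, abs(cc)))
      stop("non-zero net current at site '", s, "': ", net, " mA")
  }
  structure(list(electrodes = pos[, c("label", "x", "y", "z",
                                      "current", "role", "site")],
                 center_return_distance = config$center_return_distance,
                 distance_tolerance = config$distance_tolerance,
                 phase_condition = config$phase_condition),
            class = "tacs_montage")
}

#' Switch a montage between the in-phase and anti-phase conditions
#'
#' Flips the sign of the five parietal-site currents when the requested
#' condition differs from the current one.  Applying the transformation
#' twice returns the original montage (involution).
#'
#' @param m A `tacs_montage`.
#' @param condition `"in_phase"` or `"anti_phase"`.
#' @return The montage under the requested phase condition.
#' @export
set_phase_condition <- function(m, condition = c("in_phase", "anti_phase")) {
  condition <- match.arg(condition)
  stopifnot(inherits(m, "tacs_montage"))
  if (condition != m$phase_condition) {
    par <- m$electrodes$site == "parietal"
    m$electrodes$current[par] <- -m$electrodes$current[par]
    m$phase_condition <- condition
  }
  m
}

site_center <- function(m, site) {
  e <- m$electrodes
  unlist(e[e$site == site & e$role == "center", c("x", "y", "z")])
}

#' Validate a montage against the dual-site design rules
#'
#' Report-only check of (a) the per-site zero-net-current budget, (b)
#' centre-return distances against the nominal spacing (within the
#' configured relative tolerance), and (c) the inter-site separation rules:
#' the return electrodes of the two sites must stay well apart (at least
#' twice the centre-return spacing) while each site's returns hug their own
#' centre.
#'
#' @param m A `tacs_montage`.
#' @return A list of class `montage_report` with per-site net currents,
#'   centre-return distance ranges, the minimum inter-site return-return
#'   distance, the centre-centre distance, and a character vector `flags`
#'   (empty when all rules hold).
#' @export
validate_montage <- function(m) {
  stopifnot(inherits(m, "tacs_montage"))
  e <- m$electrodes
  xyz <- as.matrix(e[, c("x", "y", "z")])
  flags <- character(0)

  net <- vapply(c(frontal = "frontal", parietal = "parietal"),
                function(s) sum(e$current[e$site == s]), numeric(1))
  for (s in names(net))
    if (abs(net[[s]]) > 1e-6)
      flags <- c(flags, sprintf("net current at %s site = %.4g mA", s, net[[s]]))

  d0 <- m$center_return_distance
  tol <- m$distance_tolerance
  cr <- list()
  for (s in c("frontal", "parietal")) {
    ctr <- site_center(m, s)
    ret <- xyz[e$site == s & e$role == "return", , drop = FALSE]
    d <- sqrt(rowSums(sweep(ret, 2, ctr)^2))
    cr[[s]] <- range(d)
    bad <- d < d0 * (1 - tol) | d > d0 * (1 + tol)
    if (any(bad))
      flags <- c(flags, sprintf(
        "%s site: %d return(s) outside %.0f mm +/- %.0f%% of the center",
        s, sum(bad), d0, 100 * tol))
  }

  rf <- xyz[e$site == "frontal" & e$role == "return", , drop = FALSE]
  rp <- xyz[e$site == "parietal" & e$role == "return", , drop = FALSE]
  dd <- outer(seq_len(nrow(rf)), seq_len(nrow(rp)),
              Vectorize(function(i, j) sqrt(sum((rf[i, ] - rp[j, ])^2))))
  min_rr <- min(dd)
  if (min_rr < 2 * d0)
    flags <- c(flags, sprintf(
      "inter-site return-return distance %.1f mm below %.0f mm", min_rr, 2 * d0))

  cc_dist <- sqrt(sum((site_center(m, "frontal") - site_center(m, "parietal"))^2))

  structure(list(net_current = net,
                 center_return_range = cr,
                 min_intersite_return_distance = min_rr,
                 center_center_distance = cc_dist,
                 flags = flags),
            class = "montage_report")
}

#' @export
print.montage_report <- function(x, ...) {
  cat("Montage validation report\n")
  cat(sprintf("  net current (mA): frontal %.4g, parietal %.4g\n",
              x$net_current[["frontal"]], x$net_current[["parietal"]]))
  for (s in names(x$center_return_range))
    cat(sprintf("  %s center-return distance: %.1f - %.1f mm\n", s,
                x$center_return_range[[s]][1], x$center_return_range[[s]][2]))
  cat(sprintf("  min inter-site return-return distance: %.1f mm\n",
              x$min_intersite_return_distance))
  cat(sprintf("  center-center distance: %.1f mm\n", x$center_center_distance))
  if (length(x$flags)) cat("  FLAGS:\n", paste("   -", x$flags, collapse = "\n"), "\n")
  else cat("  all design rules satisfied\n")
  invisible(x)
}

#' @export
as.data.frame.tacs_montage <- function(x, ...) x$electrodes

#' @export
print.tacs_montage <- function(x, ...) {
  cat(sprintf("Dual-site HD-tACS montage (%s), %d electrodes\n",
              x$phase_condition, nrow(x$electrodes)))
  print(x$electrodes)
  invisible(x)
}

#' Export a montage as a tab-separated electrode table
#'
#' @param m A `tacs_montage`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_electrode_table <- function(m, path) {
  stopifnot(inherits(m, "tacs_montage"))
  utils::write.table(m$electrodes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a montage configuration as a key-value text file
#'
#' One DCF (Debian-control-format) record per electrode with fields
#' `label`, `x`, `y`, `z`, `role`, `site`, preceded by a header record with
#' `center_current`, `phase_condition`, `center_return_distance` and
#' `distance_tolerance`.
#'
#' @param config A [montage_config()].
#' @param path File path.
#' @return `write_montage_config()` returns `path` invisibly;
#'   `read_montage_config()` returns a `montage_config`.
#' @export
write_montage_config <- function(config, path) {
  stopifnot(inherits(config, "montage_config"))
  hdr <- data.frame(record = "header",
                    center_current = config$center_current,
                    phase_condition = config$phase_condition,
                    center_return_distance = config$center_return_distance,
                    distance_tolerance = config$distance_tolerance)
  write.dcf(hdr, path)
  cat("\n", file = path, append = TRUE)
  el <- cbind(record = "electrode", config$positions)
  write.dcf(el, path, append = TRUE)
  invisible(path)
}

#' @rdname write_montage_config
#' @export
read_montage_config <- function(path) {
  d <- as.data.frame(read.dcf(path), stringsAsFactors = FALSE)
  hdr <- d[d$record == "header", , drop = FALSE]
  el <- d[d$record == "electrode", , drop = FALSE]
  pos <- data.frame(label = el$label,
                    x = as.numeric(el$x), y = as.numeric(el$y),
                    z = as.numeric(el$z),
                    role = el$role, site = el$site,
                    stringsAsFactors = FALSE)
  montage_config(positions = pos,
                 center_current = as.numeric(hdr$center_current),
                 phase_condition = hdr$phase_condition,
                 center_return_distance = as.numeric(hdr$center_return_distance),
                 distance_tolerance = as.numeric(hdr$distance_tolerance))
}
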