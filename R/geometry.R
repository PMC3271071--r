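## Backbone dihedral geometry and the angle <-> [0,1] normalization used as
## the regression target scale.

#' Wrap angles into (-180, 180]
#'
#' @param theta numeric vector of angles in degrees.
#' @return numeric vector on the half-open circle (-180, 180].
#' @examples
#' wrap_angle(c(190, -180, 360, 45))
#' @export
wrap_angle <- function(theta) {
  out <- ((theta + 180) %% 360) - 180
  out[!is.na(out) & out == -180] <- 180
  out
}

#' Signed dihedral angle of four points
#'
#' Computes the torsion angle defined by points `p1-p2-p3-p4` with the
#' right-handed (IUPAC) sign convention: looking from `p2` towards `p3`,
#' a clockwise rotation of the far bond relative to the near bond is
#' positive.  The eclipsed (cis) arrangement is 0 degrees and the
#' anti-periplanar (trans) arrangement is 180 degrees, matching DSSP
#' output ranges.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(2, 1, 0)) # trans
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  scale <- max(sqrt(sum(b1^2)), sqrt(sum(b2^2)), sqrt(sum(b3^2)))
  if (scale == 0 || sqrt(sum(b2^2)) == 0) {
    abort("degenerate dihedral: consecutive points coincide",
          class = "phipsi_degenerate_dihedral")
  }
  if (sqrt(sum(n1^2)) < 1e-9 * scale^2 || sqrt(sum(n2^2)) < 1e-9 * scale^2) {
    abort("degenerate dihedral: three consecutive points are collinear",
          class = "phipsi_degenerate_dihedral")
  }
  b2n <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2n), sum(n1 * n2)) * 180 / pi
  wrap_angle(ang)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Compute backbone phi/psi torsions for a chain
#'
#' For residue i, phi uses atoms C(i-1)-N(i)-CA(i)-C(i) and psi uses
#' N(i)-CA(i)-C(i)-N(i+1).  Angles whose neighbouring atoms are missing
#' (chain termini, incomplete residues) are `NA`.
#'
#' @param chain a backbone tibble as returned by [read_backbone_pdb()]:
#'   one row per residue with columns `chain`, `pos`, `resname` and the
#'   nine coordinate columns `n_x` ... `c_z`.
#' @return a tibble with columns `chain`, `pos`, `resname`, `aa`,
#'   `phi`, `psi` (degrees in (-180, 180] or `NA`).
#' @export
compute_backbone_torsions <- function(chain) {
  stopifnot(is.data.frame(chain), nrow(chain) >= 1)
  need <- c("chain", "pos", "resname",
            paste0(rep(c("n", "ca", "c"), each = 3), "_", c("x", "y", "z")))
  missing_cols <- setdiff(need, names(chain))
  if (length(missing_cols) > 0) {
    abort(paste0("backbone table lacks columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  nr <- nrow(chain)
  N  <- as.matrix(chain[, c("n_x", "n_y", "n_z")])
  CA <- as.matrix(chain[, c("ca_x", "ca_y", "ca_z")])
  CC <- as.matrix(chain[, c("c_x", "c_y", "c_z")])
  complete <- stats::complete.cases(N) & stats::complete.cases(CA) &
    stats::complete.cases(CC)
  if (any(!complete)) {
    warn(sprintf("%d residue(s) with missing backbone atoms; angles set to NA",
                 sum(!complete)))
  }
  safe_dihedral <- function(a, b, d, e) {
    tryCatch(dihedral_angle(a, b, d, e),
             phipsi_degenerate_dihedral = function(cnd) {
               warn(conditionMessage(cnd))
               NA_real_
             })
  }
  phi <- rep(NA_real_, nr)
  psi <- rep(NA_real_, nr)
  for (i in seq_len(nr)) {
    if (!complete[i]) next
    if (i > 1 && complete[i - 1]) {
      phi[i] <- safe_dihedral(CC[i - 1, ], N[i, ], CA[i, ], CC[i, ])
    }
    if (i < nr && complete[i + 1]) {
      psi[i] <- safe_dihedral(N[i, ], CA[i, ], CC[i, ], N[i + 1, ])
    }
  }
  out <- tibble(
    chain_id = chain$chain,
    pos = chain$pos,
    resname = chain$resname,
    aa = `%|NA|%`(unname(AA_ONE[chain$resname]), "X"),
    phi = phi,
    psi = psi)
  names(out)[1] <- "chain"
  out
}

# tiny helper: replace NA by a default (used for unknown residue names)
`%|NA|%` <- function(x, default) {
  x[is.na(x)] <- default
  x
}

#' Fit the angle normalizer
#'
#' Stores the training-set mean and standard deviation of phi and psi and
#' maps angles onto the unit interval via
#' `v = 0.5 + (theta - mu) / (span * sigma)`; with the default
#' `span = 6`, angles within three standard deviations of the mean land
#' in `[0, 1]`.
#'
#' @param phi,psi numeric vectors of observed angles in degrees
#'   (`NA` dropped).
#' @param span dimensionless width of the mapped interval in standard
#'   deviations (default 6, i.e. +/- 3 sigma).
#' @return an object of class `angle_normalizer`.
#' @export
fit_angle_normalizer <- function(phi, psi, span = 6) {
  phi <- phi[!is.na(phi)]
  psi <- psi[!is.na(psi)]
  if (length(phi) < 2 || length(psi) < 2) {
    abort("need at least two defined phi and psi angles to fit a normalizer")
  }
  s_phi <- sd(phi)
  s_psi <- sd(psi)
  if (s_phi == 0 || s_psi == 0) {
    abort("zero variance in the training angles; cannot normalize")
  }
  structure(
    list(mu = c(phi = mean(phi), psi = mean(psi)),
         sigma = c(phi = s_phi, psi = s_psi),
         span = span),
    class = "angle_normalizer")
}

#' @export
print.angle_normalizer <- function(x, ...) {
  cat(sprintf(
    "<angle_normalizer> span = %g\n  phi: mu = %8.3f  sigma = %7.3f\n  psi: mu = %8.3f  sigma = %7.3f\n",
    x$span, x$mu[["phi"]], x$sigma[["phi"]], x$mu[["psi"]], x$sigma[["psi"]]))
  invisible(x)
}

#' Normalize / denormalize torsion angles
#'
#' @param theta angles in degrees.
#' @param v normalized (unitless) values.
#' @param which `"phi"` or `"psi"`.
#' @param norm an [fit_angle_normalizer()] object.
#' @return `normalize_angle()` returns unitless values centred at 0.5;
#'   `denormalize_angle()` inverts the mapping and wraps the result into
#'   (-180, 180].
#' @export
normalize_angle <- function(theta, which = c("phi", "psi"), norm) {
  which <- match.arg(which)
  stopifnot(inherits(norm, "angle_normalizer"))
  0.5 + (theta - norm$mu[[which]]) / (norm$span * norm$sigma[[which]])
}

#' @rdname normalize_angle
#' @export
denormalize_angle <- function(v, which = c("phi", "psi"), norm) {
  which <- match.arg(which)
  stopifnot(inherits(norm, "angle_normalizer"))
  wrap_angle(norm$mu[[which]] + (v - 0.5) * norm$span * norm$sigma[[which]])
}

#' Absolute difference between two angles
#'
#' `mode = "circular"` measures the shorter arc on the circle and lies in
#' `[0, 180]`; `mode = "linear"` is the plain `|a - b|` on the raw
#' values.  Error metrics take the mode explicitly because published
#' angle MAEs do not always state which convention was used.
#'
#' @param a,b angles in degrees (vectorized).
#' @param mode `"circular"` (default) or `"linear"`.
#' @return non-negative differences in degrees.
#' @examples
#' angular_difference(-175, 175)            # 10
#' angular_difference(-175, 175, "linear")  # 350
#' @export
angular_difference <- function(a, b, mode = c("circular", "linear")) {
  mode <- match.arg(mode)
  if (mode == "linear") {
    return(abs(a - b))
  }
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}
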