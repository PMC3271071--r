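# Independent geometry oracle: an internal-coordinate (NeRF) chain
# builder.  Places each atom from a bond length, bond angle and torsion,
# so backbone fragments with prescribed phi/psi can be constructed
# without using the package's dihedral code.

place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  angle <- angle_deg * pi / 180
  torsion <- torsion_deg * pi / 180
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(torsion),
          bond * sin(angle) * sin(torsion))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# Ideal backbone internal coordinates (Engh-Huber-like averages).
BOND_N_CA <- 1.458
BOND_CA_C <- 1.525
BOND_C_N  <- 1.329
ANGLE_N_CA_C <- 111.2
ANGLE_CA_C_N <- 116.2
ANGLE_C_N_CA <- 121.7

# Build an n-residue backbone with the given per-residue phi/psi
# (omega fixed at 180).  phi[1] and psi[n] are ignored.
build_peptide <- function(phis, psis, resname = "ALA") {
  n <- length(phis)
  stopifnot(length(psis) == n, n >= 2)
  atoms <- list()   # sequence N1 CA1 C1 N2 CA2 C2 ...
  atoms[[1]] <- c(0, 0, 0)
  atoms[[2]] <- c(BOND_N_CA, 0, 0)
  ang <- ANGLE_N_CA_C * pi / 180
  atoms[[3]] <- atoms[[2]] + BOND_CA_C * c(-cos(ang), sin(ang), 0)
  for (i in 2:n) {
    base <- (i - 2) * 3
    atoms[[base + 4]] <- place_atom(atoms[[base + 1]], atoms[[base + 2]],
                                    atoms[[base + 3]], BOND_C_N,
                                    ANGLE_CA_C_N, psis[i - 1])
    atoms[[base + 5]] <- place_atom(atoms[[base + 2]], atoms[[base + 3]],
                                    atoms[[base + 4]], BOND_N_CA,
                                    ANGLE_C_N_CA, 180)   # omega
    atoms[[base + 6]] <- place_atom(atoms[[base + 3]], atoms[[base + 4]],
                                    atoms[[base + 5]], BOND_CA_C,
                                    ANGLE_N_CA_C, phis[i])
  }
  m <- do.call(rbind, atoms)
  tibble::tibble(
    chain = "A",
    pos = as.character(seq_len(n)),
    resname = resname,
    n_x = m[seq(1, 3 * n, 3), 1], n_y = m[seq(1, 3 * n, 3), 2],
    n_z = m[seq(1, 3 * n, 3), 3],
    ca_x = m[seq(2, 3 * n, 3), 1], ca_y = m[seq(2, 3 * n, 3), 2],
    ca_z = m[seq(2, 3 * n, 3), 3],
    c_x = m[seq(3, 3 * n, 3), 1], c_y = m[seq(3, 3 * n, 3), 2],
    c_z = m[seq(3, 3 * n, 3), 3])
}

# Minimal fixed-width PDB writer for backbone test fixtures.
write_backbone_pdb_fixture <- function(bb, path) {
  lines <- character(0)
  serial <- 1L
  for (i in seq_len(nrow(bb))) {
    for (el in c("N", "CA", "C")) {
      pre <- tolower(el)
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %3s %s%4s    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        serial, el, bb$resname[i], bb$chain[i], bb$pos[i],
        bb[[paste0(pre, "_x")]][i], bb[[paste0(pre, "_y")]][i],
        bb[[paste0(pre, "_z")]][i], substr(el, 1, 1)))
      serial <- serial + 1L
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
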