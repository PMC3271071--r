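## PDB backbone input, via bio3d.

#' Read backbone N/CA/C coordinates from a PDB file
#'
#' Parses ATOM records (PDB v3.3 columns, handled by [bio3d::read.pdb()];
#' alternate locations resolved to the first/'A' conformer) and returns
#' one row per residue with the three backbone atom coordinates needed
#' for phi/psi computation.  Insertion codes are preserved in `pos`, so
#' author numbering like `"52A"` survives round trips.
#'
#' @param path path to a PDB-format file.
#' @param chain optional chain identifier(s) to keep (default: all).
#' @return a tibble with columns `chain`, `pos` (author numbering, as
#'   character), `resname`, `complete` (all of N, CA, C present) and
#'   coordinate columns `n_x`, `n_y`, `n_z`, `ca_x`, ..., `c_z` in
#'   Angstrom.  Residues missing backbone atoms carry `NA` coordinates
#'   and `complete = FALSE`.
#' @export
read_backbone_pdb <- function(path, chain = NULL) {
  if (!file.exists(path)) {
    abort(paste0("PDB file not found: ", path), class = "phipsi_io_error")
  }
  pdb <- bio3d::read.pdb(path, rm.alt = TRUE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C"), , drop = FALSE]
  if (!is.null(chain)) {
    at <- at[at$chain %in% chain, , drop = FALSE]
  }
  if (nrow(at) == 0) {
    abort("no backbone ATOM records found", class = "phipsi_format_error")
  }
  at$insert[is.na(at$insert)] <- ""
  at$pos <- paste0(at$resno, at$insert)
  key <- paste(at$chain, at$pos, sep = "\r")
  # preserve file order of residues
  ord <- !duplicated(key)
  res <- tibble(
    chain = at$chain[ord],
    pos = at$pos[ord],
    resname = at$resid[ord])
  grab <- function(elety, axis) {
    sel <- at$elety == elety
    idx <- match(paste(res$chain, res$pos, sep = "\r"), key[sel])
    at[[axis]][sel][idx]
  }
  for (el in c("N", "CA", "C")) {
    pre <- tolower(el)
    res[[paste0(pre, "_x")]] <- grab(el, "x")
    res[[paste0(pre, "_y")]] <- grab(el, "y")
    res[[paste0(pre, "_z")]] <- grab(el, "z")
  }
  coord_cols <- setdiff(names(res), c("chain", "pos", "resname"))
  res$complete <- stats::complete.cases(res[, coord_cols])
  if (any(!res$complete)) {
    warn(sprintf("%d residue(s) have incomplete backbones", sum(!res$complete)))
  }
  res
}
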