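## The profile bundle: all per-residue tracks for one chain, aligned to
## the sequence, plus the global sequence features.

#' Assemble a profile bundle for one chain
#'
#' A bundle aligns the four per-residue tracks (PSSM, secondary
#' structure, accessibility, disorder) to the amino-acid sequence and
#' carries the global sequence features.  All tracks must have exactly
#' one row per residue.
#'
#' @param id chain identifier.
#' @param seq one-letter amino-acid sequence (string).
#' @param pssm a `pssm_profile` from [read_pssm()] (or a list with a
#'   `normalized` `L x 20` matrix).
#' @param ss an `ss_profile` from [read_psipred_ss2()].
#' @param sa an `sa_profile` from [read_accessibility()].
#' @param diso a `disorder_profile` from [read_disorder()].
#' @return a `profile_bundle` object.
#' @export
profile_bundle <- function(id, seq, pssm, ss, sa, diso) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  L <- nchar(seq)
  lens <- c(pssm = nrow(pssm$normalized), ss = nrow(ss$probs),
            sa = nrow(sa$encoding), diso = length(diso$p_disordered))
  if (any(lens != L)) {
    off <- names(lens)[lens != L]
    abort(sprintf(
      "track length mismatch for chain %s (sequence %d): %s", id, L,
      paste(sprintf("%s=%d", off, lens[off]), collapse = ", ")),
      class = "phipsi_consistency_error")
  }
  structure(
    list(id = id, seq = seq, pssm = pssm, ss = ss, sa = sa, diso = diso,
         global = compute_global_features(seq)),
    class = "profile_bundle")
}

#' @export
print.profile_bundle <- function(x, ...) {
  cat(sprintf("<profile_bundle> %s: %d residues, tracks: pssm ss sa diso\n",
              x$id, nchar(x$seq)))
  invisible(x)
}

#' Read a full profile bundle from its four track files
#'
#' @param id chain identifier.
#' @param seq one-letter sequence, or `NULL` to take the letters from
#'   the PSSM rows.
#' @param pssm,ss2,acc,diso paths to the PSSM, ss2, accessibility and
#'   disorder files.
#' @return a `profile_bundle`.
#' @export
read_profile_bundle <- function(id, pssm, ss2, acc, diso, seq = NULL) {
  p <- read_pssm(pssm, seq_length = if (is.null(seq)) NULL else nchar(seq))
  if (is.null(seq)) {
    seq <- paste(p$letters, collapse = "")
  }
  profile_bundle(id, seq,
                 pssm = p,
                 ss = read_psipred_ss2(ss2),
                 sa = read_accessibility(acc),
                 diso = read_disorder(diso))
}

#' Per-residue view of a profile bundle
#'
#' @param x a `profile_bundle`.
#' @param ... unused.
#' @return a tibble with one row per residue: `pos` (1-based), `aa`,
#'   `ss` state, `sa` state, `p_disordered`, and the three
#'   secondary-structure probabilities.
#' @method tidy profile_bundle
#' @export
tidy.profile_bundle <- function(x, ...) {
  L <- nchar(x$seq)
  tibble(
    pos = seq_len(L),
    aa = strsplit(x$seq, "")[[1]],
    ss = x$ss$state,
    sa = x$sa$state,
    p_disordered = x$diso$p_disordered,
    p_helix = x$ss$probs[, "H"],
    p_strand = x$ss$probs[, "E"],
    p_coil = x$ss$probs[, "C"])
}
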