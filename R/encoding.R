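## Sliding-window feature encoding.  A residue is encoded by
## concatenating, position by position across a window of L = 2l+1
## residues, the per-residue track blocks of the chosen scheme in the
## fixed order PSSM (20), secondary structure (3), accessibility (2),
## disorder (2).  Window positions outside the chain contribute exact
## zeros.  The ALL scheme appends the global sequence features once at
## the end of the vector.

SCHEME_TRACKS <- list(
  "PB"            = c("pssm"),
  "PB+PP"         = c("pssm", "ss"),
  "PB+PP+SC"      = c("pssm", "ss", "sa"),
  "PB+PP+DISO"    = c("pssm", "ss", "diso"),
  "PB+PP+SC+DISO" = c("pssm", "ss", "sa", "diso"),
  "ALL"           = c("pssm", "ss", "sa", "diso"))

TRACK_WIDTH <- c(pssm = 20, ss = 3, sa = 2, diso = 2)

#' Encoding schemes
#'
#' @return character vector of the recognised scheme names.
#' @export
encoding_schemes <- function() names(SCHEME_TRACKS)

scheme_tracks <- function(scheme) {
  if (!scheme %in% names(SCHEME_TRACKS)) {
    abort(sprintf("unknown encoding scheme '%s' (use one of: %s)", scheme,
                  paste(names(SCHEME_TRACKS), collapse = ", ")),
          class = "phipsi_config_error")
  }
  SCHEME_TRACKS[[scheme]]
}

per_residue_width <- function(scheme) {
  sum(TRACK_WIDTH[scheme_tracks(scheme)])
}

#' Dimensionality of an encoding scheme
#'
#' Number of feature columns produced for one residue: the per-residue
#' track width times the window length, e.g. 20L for `PB`, 23L for
#' `PB+PP`, 25L for `PB+PP+SC` and `PB+PP+DISO`, 27L for
#' `PB+PP+SC+DISO`, plus the global block for `ALL`.
#'
#' @param scheme scheme name, see [encoding_schemes()].
#' @param L odd window length (`L = 2l + 1`).
#' @param global_width number of global feature columns appended by the
#'   `ALL` scheme (default 22: 20 composition fractions, scaled length,
#'   scaled weight).
#' @return integer number of columns.
#' @examples
#' scheme_dimension("PB+PP+SC+DISO", 9)  # 243
#' @export
scheme_dimension <- function(scheme, L, global_width = 22) {
  if (L %% 2 != 1 || L < 1) {
    abort("window length L must be odd and positive",
          class = "phipsi_config_error")
  }
  w <- per_residue_width(scheme) * L
  if (scheme == "ALL") w <- w + global_width
  as.integer(w)
}

#' Global sequence features
#'
#' Twenty amino-acid composition fractions (counts over sequence length;
#' `X` is excluded from the numerators but counted in the length),
#' the sequence length scaled by 1/1000 and capped at 1, and the
#' approximate molecular weight (sum of average residue masses, Da)
#' scaled by 1e-5 so that typical proteins land in `[0, 1]`.
#'
#' @param seq one-letter amino-acid sequence.
#' @return named numeric vector of length 22.
#' @export
compute_global_features <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1, nchar(seq) >= 1)
  letters <- strsplit(seq, "")[[1]]
  nres <- length(letters)
  comp <- vapply(AA_ALPHABET, function(a) sum(letters == a) / nres, numeric(1))
  mass <- AA_RESIDUE_MASS[letters]
  mass[is.na(mass)] <- mean(AA_RESIDUE_MASS)   # X: mean residue mass
  c(comp,
    length = min(nres / 1000, 1),
    weight = sum(mass) / 1e5)
}

# Stack the scheme's tracks into one L x width matrix.
track_matrix <- function(bundle, scheme) {
  blocks <- lapply(scheme_tracks(scheme), function(tr) {
    switch(tr,
      pssm = bundle$pssm$normalized,
      ss   = bundle$ss$probs,
      sa   = bundle$sa$encoding,
      diso = bundle$diso$encoding,
      abort(sprintf("bundle lacks track '%s' required by the scheme", tr),
            class = "phipsi_config_error"))
  })
  do.call(cbind, blocks)
}

#' Encode one residue
#'
#' @param bundle a [profile_bundle()].
#' @param index 1-based residue position.
#' @param scheme encoding scheme name.
#' @param l half window size (window length `L = 2l + 1`).
#' @param global_width width of the `ALL` global block.
#' @return numeric feature vector of length
#'   `scheme_dimension(scheme, 2 * l + 1)`.
#' @export
encode_residue <- function(bundle, index, scheme = "PB+PP", l = 4,
                           global_width = 22) {
  encode_positions(bundle, index, scheme, l, global_width)[1, ]
}

#' Encode every residue of a chain
#'
#' @inheritParams encode_residue
#' @param indices residue positions to encode (default: all).
#' @return numeric matrix, one row per requested residue.
#' @export
encode_positions <- function(bundle, indices = NULL, scheme = "PB+PP", l = 4,
                             global_width = 22) {
  stopifnot(inherits(bundle, "profile_bundle"), l >= 1)
  L <- 2L * l + 1L
  nres <- nchar(bundle$seq)
  indices <- indices %||% seq_len(nres)
  if (any(indices < 1 | indices > nres)) {
    abort("residue index outside the chain", class = "phipsi_config_error")
  }
  tm <- track_matrix(bundle, scheme)
  width <- ncol(tm)
  # zero-pad l rows on both ends, then each window is a contiguous slab
  padded <- rbind(matrix(0, l, width), tm, matrix(0, l, width))
  X <- matrix(0, nrow = length(indices), ncol = width * L)
  for (k in seq_along(indices)) {
    rows <- padded[indices[k]:(indices[k] + 2L * l), , drop = FALSE]
    X[k, ] <- as.vector(t(rows))   # position-major, track blocks within
  }
  if (scheme == "ALL") {
    g <- bundle$global
    if (length(g) != global_width) {
      g <- rep_len(c(g, numeric(global_width)), global_width)
    }
    X <- cbind(X, matrix(rep(g, each = nrow(X)), nrow = nrow(X)))
  }
  X
}

#' Encode a chain against its target angles
#'
#' Produces the training design for one chain and one angle type: rows
#' only for residues whose target angle is defined (and outside any
#' extra terminal trim), in sequence order, with targets on the
#' normalized scale.
#'
#' @inheritParams encode_residue
#' @param targets per-residue tibble aligned to the sequence with
#'   columns `phi` and `psi` in degrees (`NA` when undefined).
#' @param which `"phi"` or `"psi"`.
#' @param norm an [fit_angle_normalizer()] object.
#' @param extra_trim additionally exclude this many residues at each
#'   terminus (default 0).
#' @return list with `X` (feature matrix), `y` (normalized targets) and
#'   `index` (1-based residue positions of the rows).
#' @export
encode_chain <- function(bundle, targets, which = c("phi", "psi"), norm,
                         scheme = "PB+PP", l = 4, extra_trim = 0,
                         global_width = 22) {
  which <- match.arg(which)
  nres <- nchar(bundle$seq)
  if (nrow(targets) != nres) {
    abort(sprintf("targets (%d rows) not aligned to sequence (%d residues)",
                  nrow(targets), nres),
          class = "phipsi_consistency_error")
  }
  keep <- !is.na(targets[[which]])
  if (extra_trim > 0) {
    trim <- c(seq_len(min(extra_trim, nres)),
              seq.int(max(1, nres - extra_trim + 1), nres))
    keep[trim] <- FALSE
  }
  idx <- which(keep)
  if (length(idx) == 0) {
    return(list(X = matrix(0, 0, scheme_dimension(scheme, 2 * l + 1,
                                                  global_width)),
                y = numeric(0), index = integer(0)))
  }
  list(X = encode_positions(bundle, idx, scheme, l, global_width),
       y = normalize_angle(targets[[which]][idx], which, norm),
       index = idx)
}

#' Write / read feature matrices in SVM-light sparse format
#'
#' One line per row: `target index:value ...` with 1-based feature
#' indices and zero entries omitted.
#'
#' @param X numeric feature matrix.
#' @param y numeric targets (length `nrow(X)`).
#' @param path file path.
#' @param ncol number of feature columns (read); inferred from the data
#'   when `NULL`.
#' @return `write_svmlight()` returns `path` invisibly;
#'   `read_svmlight()` returns a list with dense `X` and `y`.
#' @export
write_svmlight <- function(X, y, path) {
  stopifnot(nrow(X) == length(y))
  lines <- vapply(seq_len(nrow(X)), function(i) {
    nz <- which(X[i, ] != 0)
    paste(c(format(y[i], digits = 12),
            sprintf("%d:%.10g", nz, X[i, nz])), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_svmlight
#' @export
read_svmlight <- function(path, ncol = NULL) {
  lines <- read_nonempty_lines(path)
  toks <- strsplit(trimws(lines), "\\s+")
  y <- vapply(toks, function(x) as.numeric(x[1]), numeric(1))
  feats <- lapply(toks, function(x) {
    if (length(x) < 2) {
      return(cbind(integer(0), numeric(0)))
    }
    kv <- do.call(rbind, strsplit(x[-1], ":", fixed = TRUE))
    cbind(as.integer(kv[, 1]), as.numeric(kv[, 2]))
  })
  width <- ncol %||% max(1L, max(unlist(lapply(feats, function(m) m[, 1])),
                                 0L))
  X <- matrix(0, nrow = length(y), ncol = width)
  for (i in seq_along(feats)) {
    m <- feats[[i]]
    if (nrow(m) > 0) X[i, m[, 1]] <- m[, 2]
  }
  list(X = X, y = y)
}
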